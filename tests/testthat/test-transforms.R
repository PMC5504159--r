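test_that("reconstruction grids have the contracted spacing and coverage", {
  geo <- acquisition_geometry(128, 3000, 0.01, 0.8, 0.01, 256, 256, 0.5, 5)
  fg <- frequency_grid(geo)
  expect_length(fg, 256)
  expect_equal(diff(fg), rep(3000 / 256, 255))
  expect_gt(min(fg), -1500)
  expect_equal(max(fg), 1500)
  rg <- rate_grid(geo)
  expect_equal(rg[1], 0.5)
  expect_equal(rg[256], 5)
  expect_true(all(diff(rg) > 0))
  rl <- rate_grid(geo, log_spacing = TRUE)
  expect_equal(range(rl), c(0.5, 5))
  expect_equal(diff(log(rl)), rep(diff(log(c(0.5, 5))) / 255, 255))
})

test_that("Fourier rows follow the synthesis convention and invert on-grid", {
  fg <- frequency_grid(small_geometry(nf = 4, nr = 4))
  expect_equal(fourier_row(0, fg), rep(0.25 + 0i, 4))

  # rows at the canonical t1 values form a unitary-up-to-1/n matrix
  geo <- small_geometry(n_t1 = 4, nf = 4, nr = 4)
  Fm <- t(vapply(t1_values(geo), fourier_row, complex(4), fgrid = fg))
  G <- Fm %*% Conj(t(Fm))
  expect_lt(max(Mod(G - diag(4) / 4)), 1e-12)

  # a pure on-grid sinusoid synthesized through rows then analyzed by a
  # discrete FT lights a single bin
  k0 <- 3
  spec <- rep(0 + 0i, 4); spec[k0] <- 1
  fid <- Fm %*% spec
  back <- vapply(seq_along(fg), function(k)
    sum(fid * exp(-2i * pi * fg[k] * t1_values(geo))), complex(1))
  expect_equal(which.max(Mod(back)), k0)
  expect_lt(max(Mod(back[-k0])), 1e-10)
})

test_that("Laplace entries are exponential kernels, decreasing in rate", {
  expect_equal(laplace_entry(0, c(0.5, 2, 5)), c(1, 1, 1))
  expect_equal(laplace_entry(0.5, 2), exp(-1))
  r <- seq(0.5, 5, length.out = 50)
  expect_true(all(diff(laplace_entry(0.3, r)) < 0))
  expect_error(laplace_entry(-0.1, 1), "delays")
  expect_error(laplace_entry(0.1, 0), "rates")
})

test_that("separable and FFT operator actions match the dense Kronecker matrix", {
  for (case in list(c(8, 8, 8), c(16, 12, 10), c(16, 7, 5))) {
    geo <- small_geometry(n_t1 = case[1], nf = case[2], nr = case[3])
    sch <- generate_schedule(geo, 60, seed = case[1])
    A <- dense_dictionary(geo, sch)
    set.seed(case[2])
    Q <- matrix(random_complex(case[2] * case[3]), case[2], case[3])
    q <- random_complex(60)
    for (fft in c(TRUE, FALSE)) {
      op <- joint_operator(geo, sch, use_fft = fft)
      fwd <- joint_forward(Q, op)
      expect_equal(fwd, as.vector(A %*% as.vector(Q)), tolerance = 1e-12)
      adj <- joint_adjoint(q, op)
      expect_equal(as.vector(adj), as.vector(Conj(t(A)) %*% q),
                   tolerance = 1e-12)
    }
    expect_equal(as_dense_matrix(joint_operator(geo, sch)), A,
                 tolerance = 1e-12)
  }
})

test_that("adjoint satisfies the inner-product identity on random draws", {
  geo <- small_geometry(n_t1 = 16, nf = 16, nr = 12)
  sch <- generate_schedule(geo, 64, seed = 3)
  op <- joint_operator(geo, sch)
  set.seed(42)
  for (i in 1:100) {
    Q <- matrix(random_complex(16 * 12), 16, 12)
    q <- random_complex(64)
    lhs <- sum(joint_forward(Q, op) * Conj(q))
    rhs <- sum(Q * Conj(joint_adjoint(q, op)))
    expect_lt(Mod(lhs - rhs),
              1e-10 * sqrt(sum(Mod(Q)^2)) * sqrt(sum(Mod(q)^2)))
  }
})

test_that("one-hot plane produces the analytic sample vector", {
  geo <- small_geometry(n_t1 = 8, nf = 8, nr = 6)
  sch <- generate_schedule(geo, 20, seed = 6)
  op <- joint_operator(geo, sch)
  fg <- frequency_grid(geo); rg <- rate_grid(geo)
  Q <- matrix(0 + 0i, 8, 6); Q[3, 4] <- 1
  t1 <- sch$t1_index / geo$sw_indirect
  expected <- exp(2i * pi * fg[3] * t1) / 8 * exp(-rg[4] * sch$trelax)
  expect_equal(joint_forward(Q, op), expected, tolerance = 1e-12)
  expect_equal(joint_forward(matrix(0 + 0i, 8, 6), op), rep(0 + 0i, 20))
})

test_that("single-sample adjoint is the rank-one conjugated outer product", {
  geo <- small_geometry(n_t1 = 8, nf = 8, nr = 6)
  sch <- joint_schedule(5L, 0.37, geo)
  op <- joint_operator(geo, sch)
  adj <- joint_adjoint(1 + 0i, op)
  fg <- frequency_grid(geo); rg <- rate_grid(geo)
  t1 <- 5 / geo$sw_indirect
  expect_equal(adj,
               outer(Conj(exp(2i * pi * fg * t1) / 8), exp(-rg * 0.37)),
               tolerance = 1e-12)
})

test_that("full sampling with a single decay inverts the Fourier axis", {
  # every (t1, trelax) pair sampled; one rate bin only: the frequency
  # dimension must invert exactly
  geo <- acquisition_geometry(16, 100, 0.01, 0.1, 0.01, 16, 1, 2, 2.0001)
  uni <- delay_universe(geo)
  sch <- joint_schedule(rep(0:15, each = length(uni)),
                        rep(uni, 16), geo)
  fg <- frequency_grid(geo)
  k0 <- 11
  pk <- peak_table(fg[k0], 0, 1, rate_grid(geo)[1])
  s <- simulate_joint_fid(pk, geo, sch)
  op <- joint_operator(geo, sch)
  plane <- joint_adjoint(s, op)
  # P^H s for unit-column L and orthogonal F concentrates on (k0, 1)
  expect_equal(which.max(Mod(plane[, 1])), k0)
  # least-squares inversion restricted to the frequency axis is exact:
  # a unit-amplitude sinusoid has plane coefficient n (1/n synthesis)
  Amat <- as_dense_matrix(op)
  x <- qr.solve(Amat, s)
  expect_equal(Mod(x[k0]), 16, tolerance = 1e-8)
  expect_lt(max(Mod(x[-k0])), 1e-7)
})

test_that("operator validates plane shape and data length", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 10, seed = 1)
  op <- joint_operator(geo, sch)
  expect_error(joint_forward(matrix(0i, 3, 3), op), "must be 8 x 8")
  expect_error(joint_adjoint(complex(9), op), "does not match")
})
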