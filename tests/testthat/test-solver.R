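test_that("complex soft thresholding shrinks magnitude and keeps phase", {
  expect_equal(soft_threshold(3 + 0i, 1), 2 + 0i)
  expect_equal(soft_threshold(3 + 4i, 5), 0 + 0i)   # |x| exactly at threshold
  expect_equal(soft_threshold(6 + 8i, 5), 3 + 4i)   # half magnitude, same phase
  expect_equal(soft_threshold(0 + 0i, 2), 0 + 0i)
  x <- complex(modulus = c(0.5, 1, 2, 10), argument = c(0.3, -1, 2, 3))
  y <- soft_threshold(x, 1)
  expect_equal(Mod(y), pmax(Mod(x) - 1, 0))
  keep <- Mod(y) > 0
  expect_equal(Arg(y[keep]), Arg(x[keep]))
  expect_error(soft_threshold(1 + 1i, -0.1), "threshold")
})

test_that("power iteration matches the dense largest eigenvalue", {
  set.seed(5)
  for (trial in 1:3) {
    geo <- small_geometry(n_t1 = 8, nf = 8, nr = 8)
    sch <- generate_schedule(geo, 32, seed = trial)
    op <- joint_operator(geo, sch)
    A <- dense_dictionary(geo, sch)
    lam_dense <- max(Re(eigen(Conj(t(A)) %*% A, only.values = TRUE)$values))
    lam <- lipschitz_estimate(op, n_power_iter = 100, seed = trial)
    expect_lte(lam, lam_dense * 1.01)       # never overshoots by > 1%
    expect_gte(lam, lam_dense * 0.99)
  }
  # homogeneity: doubling the kernel quadruples the eigenvalue
  geo <- small_geometry()
  sch <- generate_schedule(geo, 20, seed = 1)
  op <- joint_operator(geo, sch)
  op2 <- op
  op2$Fs <- 2 * op$Fs
  op2$use_fft <- FALSE
  op$use_fft <- FALSE
  expect_equal(lipschitz_estimate(op2, 60, seed = 2),
               4 * lipschitz_estimate(op, 60, seed = 2), tolerance = 1e-6)
})

test_that("zero data yields the exact zero plane for any positive tau", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 24, seed = 2)
  op <- joint_operator(geo, sch)
  res <- fista_solve(op, complex(24), solver_config(tau = 0.3, n_iter = 20))
  expect_equal(res$Q, matrix(0 + 0i, 8, 8))
  expect_false(res$diverged)
})

test_that("tau at or above twice the max adjoint magnitude zeroes the solution", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 24, seed = 7)
  op <- joint_operator(geo, sch)
  set.seed(7)
  q <- random_complex(24)
  tau_crit <- 2 * max(Mod(joint_adjoint(q, op)))
  res <- fista_solve(op, q, solver_config(tau = tau_crit * 1.0001,
                                          tau_mode = "absolute",
                                          n_iter = 200, continuation = FALSE))
  expect_equal(res$Q, matrix(0 + 0i, 8, 8))
  # just below the critical weight something must survive
  res2 <- fista_solve(op, q, solver_config(tau = tau_crit * 0.95,
                                           tau_mode = "absolute",
                                           n_iter = 400, continuation = FALSE))
  expect_gt(sum(Mod(res2$Q)), 0)
})

test_that("FISTA reaches the ADMM global optimum on random instances", {
  set.seed(31)
  n_inst <- 6
  rel_gap <- numeric(n_inst)
  for (i in seq_len(n_inst)) {
    geo <- small_geometry(n_t1 = 8, nf = 8, nr = 8)
    m <- sample(16:32, 1)
    sch <- generate_schedule(geo, m, seed = 100 + i)
    op <- joint_operator(geo, sch)
    # mix of structured signal and noise keeps instances non-trivial
    pk <- peak_table(freq_hz = runif(2, -40, 40), linewidth_hz = c(0, 2),
                     amplitude = runif(2, 0.5, 2), rate_hz = runif(2, 1, 4))
    q <- simulate_joint_fid(pk, geo, sch) + 0.05 * random_complex(m)
    tau <- 0.1
    res <- fista_solve(op, q,
                       solver_config(tau = tau, tau_mode = "absolute",
                                     n_iter = 3000, tolerance = 1e-14))
    A <- dense_dictionary(geo, sch)
    x_oracle <- admm_lasso(A, q, tau, n_iter = 20000)
    o_fista <- tail(res$objective_trace, 1)
    o_oracle <- lasso_objective(A, q, tau, x_oracle)
    rel_gap[i] <- (o_fista - o_oracle) / o_oracle
  }
  # within 0.1% of the global optimum on every instance
  expect_true(all(rel_gap < 1e-3))
})

test_that("objective decreases monotonically with the safeguard enabled", {
  geo <- small_geometry(n_t1 = 8, nf = 8, nr = 8)
  sch <- generate_schedule(geo, 24, seed = 3)
  op <- joint_operator(geo, sch)
  set.seed(3)
  q <- random_complex(24)
  res_m <- fista_solve(op, q, solver_config(tau = 0.05, tau_mode = "absolute",
                                            n_iter = 300, monotone = TRUE,
                                            continuation = FALSE))
  expect_true(all(diff(res_m$objective_trace) <= 1e-12))
  # plain FISTA: the running best is non-increasing
  res_p <- fista_solve(op, q, solver_config(tau = 0.05, tau_mode = "absolute",
                                            n_iter = 300, continuation = FALSE,
                                            restart = FALSE))
  expect_true(all(diff(cummin(res_p$objective_trace)) <= 0))
  # both approach the same optimum
  expect_equal(tail(res_m$objective_trace, 1), tail(res_p$objective_trace, 1),
               tolerance = 5e-3)
})

test_that("noiseless single component concentrates mass at the true bin", {
  # full joint sampling, on-grid truth, tiny tau
  geo <- acquisition_geometry(16, 100, 0.01, 0.2, 0.01, 16, 8, 0.5, 5)
  uni <- delay_universe(geo)
  sch <- joint_schedule(rep(0:15, each = length(uni)), rep(uni, 16), geo)
  fg <- frequency_grid(geo); rg <- rate_grid(geo)
  k0 <- 5; j0 <- 4
  pk <- peak_table(fg[k0], 0, 1, rg[j0])
  q <- simulate_joint_fid(pk, geo, sch)
  op <- joint_operator(geo, sch)
  res <- fista_solve(op, q, solver_config(tau = 1e-4, tau_mode = "relative",
                                          n_iter = 4000))
  mass <- Mod(res$Q)
  nb <- mass[max(1, k0 - 1):min(16, k0 + 1), max(1, j0 - 1):min(8, j0 + 1)]
  expect_gte(sum(nb) / sum(mass), 0.99)
})

test_that("solver rejects corrupt input and flags divergence", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 10, seed = 1)
  op <- joint_operator(geo, sch)
  expect_error(fista_solve(op, complex(9)), "length")
  expect_error(fista_solve(op, c(complex(9), NaN + 0i)), "non-finite")
})
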