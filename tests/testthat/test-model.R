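test_that("simulated FID matches the closed-form signal model", {
  geo <- acquisition_geometry(4, 100, 0, 0.8, 0.01, 4, 4, 0.5, 5)

  # empty peak table gives the empty sum
  sch <- joint_schedule(c(0L, 1L, 2L), c(0.1, 0.2, 0.3), geo)
  expect_equal(simulate_joint_fid(peak_table(), geo, sch), rep(0 + 0i, 3))

  # single undamped on-resonance peak at one (t1 = 0, trelax) point
  pk <- peak_table(0, 0, 1, 2)
  s <- simulate_joint_fid(pk, geo, joint_schedule(0L, 0.5, geo))
  expect_equal(s, complex(real = exp(-1)), tolerance = 1e-12)

  # general single peak against a hand-written evaluation
  geo2 <- small_geometry()
  sch2 <- generate_schedule(geo2, 30, seed = 4)
  pk2 <- peak_table(12.5, 3, 2.5, 1.7)
  t1 <- sch2$t1_index / geo2$sw_indirect
  expected <- 2.5 * exp(2i * pi * 12.5 * t1) * exp(-pi * 3 * t1) *
    exp(-1.7 * sch2$trelax)
  expect_equal(simulate_joint_fid(pk2, geo2, sch2), expected, tolerance = 1e-12)
})

test_that("simulation is linear in the peak list (superposition)", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 40, seed = 1)
  set.seed(11)
  pks <- peak_table(freq_hz = runif(3, -40, 40), linewidth_hz = runif(3, 0, 5),
                    amplitude = runif(3, 0.5, 2), rate_hz = runif(3, 1, 4))
  whole <- simulate_joint_fid(pks, geo, sch)
  parts <- Reduce(`+`, lapply(1:3, function(i)
    simulate_joint_fid(pks[i, , drop = FALSE], geo, sch)))
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("zero relaxation delay reduces to the pure t1 FID model", {
  geo <- acquisition_geometry(16, 100, 0, 0.8, 0.01, 16, 8, 0.5, 5)
  sch <- joint_schedule(0:15, rep(0, 16), geo)
  pk <- peak_table(c(10, -20), c(2, 4), c(1, 3), c(1.5, 3.5))
  s <- simulate_joint_fid(pk, geo, sch)
  t1 <- t1_values(geo)
  fid2d <- 1 * exp(2i * pi * 10 * t1) * exp(-pi * 2 * t1) +
    3 * exp(2i * pi * -20 * t1) * exp(-pi * 4 * t1)
  expect_equal(s, fid2d, tolerance = 1e-12)
})

test_that("noise is seed-reproducible with variance matching sigma^2", {
  geo <- small_geometry(n_t1 = 128)
  sch <- generate_schedule(geo, 10000, seed = 2)
  z1 <- simulate_joint_fid(peak_table(), geo, sch, noise_model(0.5, seed = 9))
  z2 <- simulate_joint_fid(peak_table(), geo, sch, noise_model(0.5, seed = 9))
  expect_identical(z1, z2)
  z3 <- simulate_joint_fid(peak_table(), geo, sch, noise_model(0.5, seed = 10))
  expect_false(isTRUE(all.equal(z1, z3)))
  expect_equal(var(Re(z1)), 0.25, tolerance = 0.1)
  expect_equal(var(Im(z1)), 0.25, tolerance = 0.1)
})

test_that("schedule points outside the geometry are rejected by name", {
  geo <- small_geometry()
  sch <- generate_schedule(geo, 10, seed = 1)
  bad <- sch
  bad$trelax[3] <- 0.005  # off the 0.01 s mesh
  expect_error(simulate_joint_fid(peak_table(), geo, bad), "row\\(s\\) 3")
  bad2 <- sch
  bad2$t1_index[5] <- 99L
  expect_error(simulate_joint_fid(peak_table(), geo, bad2), "row\\(s\\) 5")
})

test_that("protein fixture honours separation, band margins and seed", {
  geo <- acquisition_geometry(128, 3000, 0.01, 0.8, 0.01, 256, 256, 0.5, 5)
  pk1 <- protein_fixture(1, geo, seed = 3)
  expect_equal(nrow(pk1), 1)
  expect_true(abs(pk1$freq_hz) <= 1500)
  expect_true(pk1$rate_hz > 0.5 && pk1$rate_hz < 5)

  pk <- protein_fixture(20, geo, seed = 3)
  expect_true(all(pk$rate_hz > 0.5 & pk$rate_hz < 5))
  expect_true(min(dist(pk$freq_hz)) >= 2 * 3000 / 256)
  expect_lte(max(pk$amplitude) / min(pk$amplitude), 10)
  expect_identical(pk, protein_fixture(20, geo, seed = 3))
  expect_false(isTRUE(all.equal(pk, protein_fixture(20, geo, seed = 4))))

  # separation constraint infeasible for absurd peak counts
  tiny <- acquisition_geometry(8, 50, 0.01, 0.8, 0.01, 8, 8, 0.5, 5)
  expect_error(protein_fixture(10, tiny, seed = 1), "separation|peaks")
})

test_that("peak tables validate fields and round-trip through TSV", {
  expect_error(peak_table(0, 0, -1, 2), "amplitude")
  expect_error(peak_table(0, -1, 1, 2), "linewidth")
  expect_error(peak_table(0, 0, 1, 0), "rate")

  geo <- small_geometry(n_t1 = 64, nf = 64, nr = 8)
  pk <- protein_fixture(5, geo, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pk, path)
  expect_equal(read_peak_table(path), pk, tolerance = 1e-15)
})
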