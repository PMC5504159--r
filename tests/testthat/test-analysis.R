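make_trace_cube <- function(trace, rg, fg = c(0, 10, 20), bin = 2) {
  cube <- array(0, c(1, length(fg), length(rg)))
  cube[1, bin, ] <- trace
  structure(cube, fgrid = fg, rgrid = rg, planes = list(),
            solver_info = list(), class = "spectrum_cube")
}

test_that("Gaussian read-off recovers the center of an exact Gaussian trace", {
  rg <- seq(0.5, 5, length.out = 128)
  trace <- 3 * exp(-(rg - 2.5)^2 / (2 * 0.2^2))
  est <- gaussian_rate_readoff(make_trace_cube(trace, rg), 10, id = "p1")
  expect_equal(est$rate_hz, 2.5, tolerance = 1e-6)
  expect_equal(est$height, 3, tolerance = 1e-6)
  expect_false(est$edge_flag)
  expect_false(est$no_peak)
})

test_that("two equal adjacent bins center at their midpoint", {
  rg <- seq(0.5, 5, length.out = 64)
  trace <- rep(0, 64)
  trace[30:31] <- 1
  est <- gaussian_rate_readoff(make_trace_cube(trace, rg), 10)
  expect_equal(est$rate_hz, mean(rg[30:31]), tolerance = 1e-4)
})

test_that("empty and edge traces are distinguished and flagged", {
  rg <- seq(0.5, 5, length.out = 64)
  est0 <- gaussian_rate_readoff(make_trace_cube(rep(0, 64), rg), 10)
  expect_true(est0$no_peak)
  edge <- exp(-(rg - 5)^2 / (2 * 0.1^2))
  est_e <- gaussian_rate_readoff(make_trace_cube(edge, rg), 10)
  expect_true(est_e$edge_flag)
  expect_error(gaussian_rate_readoff(make_trace_cube(edge, rg), 1e6),
               "outside")
})

test_that("mono-exponential fit is exact on noiseless decays", {
  delays <- canonical_delays(small_geometry())
  est <- mono_exponential_fit(exp(-2 * delays), delays, id = 1)
  expect_equal(est$rate_hz, 2, tolerance = 1e-6)
  expect_equal(est$height, 1, tolerance = 1e-6)
  expect_false(est$flagged)
  # scale equivariance: rescaling intensities leaves R unchanged
  est2 <- mono_exponential_fit(7.3 * exp(-2 * delays), delays, id = 1)
  expect_equal(est2$rate_hz, est$rate_hz, tolerance = 1e-9)
  # constant (non-decaying) intensities are flagged
  est3 <- mono_exponential_fit(rep(2, 10), delays, id = 1)
  expect_true(est3$flagged || abs(est3$rate_hz) < 1e-6)
  expect_error(mono_exponential_fit(c(1, 0.5), c(0.1, 0.2)), "3 delays")
  expect_error(mono_exponential_fit(c(1, -0.5, 1), c(0.1, 0.2, 0.3)),
               "non-negative")
})

test_that("fit errors are calibrated against Monte-Carlo replicates", {
  delays <- seq(0.01, 0.8, length.out = 10)
  R_true <- 2; a <- 1; sigma <- 0.01
  set.seed(77)
  n_rep <- 1000
  est <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    y <- pmax(a * exp(-R_true * delays) + rnorm(10, 0, sigma * a), 0)
    f <- mono_exponential_fit(y, delays)
    est[i, ] <- c(f$rate_hz, f$std_error)
  }
  bias <- mean(est[, 1]) - R_true
  expect_lt(abs(bias) / R_true, 0.005)          # < 0.5% bias
  sd_emp <- sd(est[, 1])
  expect_lt(abs(mean(est[, 2]) - sd_emp) / sd_emp, 0.2)  # SE within 20%
})

test_that("rate correlation matches, excludes flags and conserves counts", {
  a <- do.call(rbind, lapply(1:6, function(i)
    nusrelax:::rate_estimate_row(i, i * 0.5, "joint-gaussian")))
  b <- do.call(rbind, lapply(1:6, function(i)
    nusrelax:::rate_estimate_row(i, i * 1.0, "mono-exponential")))
  r <- correlate_rates(a, b)
  expect_equal(r$r2, 1, tolerance = 1e-12)      # exact linear map
  expect_equal(r$n_matched, 6)

  # flagged rows are excluded and counted; unmatched ids tracked
  a$edge_flag[2] <- TRUE
  b2 <- b[1:5, ]; b2$id <- c(1:4, 99)
  r2 <- correlate_rates(a, b2)
  expect_equal(r2$n_matched, 3)                  # ids 1,3,4
  expect_equal(r2$n_excluded, 1)                 # id 2 edge-flagged
  expect_equal(r2$n_unmatched, 3)                # ids 5, 6, 99
  expect_equal(r2$n_matched + r2$n_excluded + r2$n_unmatched,
               length(union(a$id, b2$id)))
  expect_error(correlate_rates(a[1:3, ], b[4:6, ]), "at least 3")
})

test_that("noisy-reference correlation matches the analytic attenuation", {
  set.seed(123)
  truth <- runif(2000, 1, 4)
  sigma <- 0.5
  noisy <- truth + rnorm(2000, 0, sigma)
  a <- do.call(rbind, lapply(seq_along(truth), function(i)
    nusrelax:::rate_estimate_row(i, truth[i], "joint-gaussian")))
  b <- do.call(rbind, lapply(seq_along(noisy), function(i)
    nusrelax:::rate_estimate_row(i, noisy[i], "mono-exponential")))
  r <- correlate_rates(a, b)
  expected <- 1 / (1 + sigma^2 / var(truth))
  expect_equal(r$r2, expected, tolerance = 0.05)
})

test_that("peak lists and rate tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pl <- data.frame(id = c("A1", "B2"), direct_hz = c(100, 200),
                   freq_hz = c(-12.5, 40))
  write_peak_list(pl, path)
  expect_equal(read_peak_list(path), pl)
  writeLines("id\tdirect_hz\n1\t2", path)
  expect_error(read_peak_list(path), "freq_hz")

  est <- nusrelax:::rate_estimate_row("A1", 2.2, "joint-gaussian")
  write_rate_table(est, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$rate_hz, 2.2)
  expect_equal(back$method, "joint-gaussian")
})
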