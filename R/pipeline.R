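#' Reconstruct a pseudo-3D spectrum cube
#'
#' Runs the sparse joint Fourier-Laplace inversion independently for each
#' direct-dimension column and stacks the resulting frequency x rate
#' planes into a cube.  The returned intensities are magnitudes; the
#' complex planes are retained as an attribute.
#'
#' @param samples A complex sample vector, or a list of such vectors (one
#'   per direct column), all acquired under the same `schedule`.
#' @param schedule A [joint_schedule()].
#' @param geometry An [acquisition_geometry()].
#' @param config A [solver_config()].
#' @param normalize_laplace,log_spacing Passed to [joint_operator()].
#' @return An object of class `"spectrum_cube"`: a numeric array
#'   `n_cols x n_f1_recon x n_r_recon` with axis coordinates in attributes
#'   `fgrid` (Hz) and `rgrid` (1/s), complex planes in attribute `planes`,
#'   and per-column solver diagnostics in attribute `solver_info`.
#' @export
reconstruct_cube <- function(samples, schedule, geometry,
                             config = solver_config(),
                             normalize_laplace = FALSE,
                             log_spacing = FALSE,
                             record_objective = TRUE) {
  if (!is.list(samples)) samples <- list(samples)
  n <- vapply(samples, length, integer(1))
  if (length(unique(n)) > 1)
    stop(sprintf("inconsistent sample-vector lengths across direct columns: %s",
                 paste(unique(n), collapse = ", ")))
  op <- joint_operator(geometry, schedule,
                       normalize_laplace = normalize_laplace,
                       log_spacing = log_spacing)
  L <- lipschitz_estimate(op, config$n_power_iter, config$seed)
  cube <- array(0, c(length(samples), length(op$fgrid), length(op$rgrid)))
  planes <- vector("list", length(samples))
  info <- vector("list", length(samples))
  for (c_idx in seq_along(samples)) {
    res <- fista_solve(op, as.complex(samples[[c_idx]]), config,
                       lipschitz = L, record_objective = record_objective)
    # undo any Laplace column normalization so intensities are comparable
    Qc <- sweep(res$Q, 2, op$col_scale, "/")
    planes[[c_idx]] <- Qc
    cube[c_idx, , ] <- Mod(Qc)
    info[[c_idx]] <- list(objective_trace = res$objective_trace,
                          tau_effective = res$tau_effective,
                          n_iter_used = res$n_iter_used,
                          diverged = res$diverged)
  }
  structure(cube, fgrid = op$fgrid, rgrid = op$rgrid,
            planes = planes, solver_info = info,
            class = "spectrum_cube")
}

#' @export
print.spectrum_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Spectrum cube: %d direct column(s) x %d frequency x %d rate bins\n",
              d[1], d[2], d[3]))
  cat(sprintf("  frequency %.3g..%.3g Hz, rate %.3g..%.3g 1/s\n",
              min(attr(x, "fgrid")), max(attr(x, "fgrid")),
              min(attr(x, "rgrid")), max(attr(x, "rgrid"))))
  invisible(x)
}

#' Conventional processing of a fully sampled relaxation series
#'
#' The baseline path: each delay's full t1 FID is apodized (cosine bell,
#' optional), zero-filled to the reconstruction grid size and Fourier
#' transformed; magnitude spectra are returned on the same frequency grid
#' as the joint reconstruction.  Peak intensities across the series decay
#' as `exp(-R * delay)` and are fit downstream by
#' [mono_exponential_fit()].
#'
#' @param series Complex matrix `n_t1 x n_delays` (a full FID per column),
#'   e.g. from [simulate_full_series()]; its `"delays"` attribute (or the
#'   `delays` argument) gives the delay of each column.
#' @param geometry An [acquisition_geometry()].
#' @param delays Delays (s), strictly increasing, one per column.
#' @param apodize Apply a cosine half-bell window along t1 (default TRUE).
#' @return An object of class `"relaxation_series"`: numeric matrix
#'   `n_f1_recon x n_delays` of magnitude spectra with `fgrid` and
#'   `delays` attributes.
#' @export
conventional_process <- function(series, geometry,
                                 delays = attr(series, "delays"),
                                 apodize = TRUE) {
  stopifnot(inherits(geometry, "acquisition_geometry"), is.matrix(series))
  if (is.null(delays)) stop("delays must be supplied (attribute or argument)")
  if (nrow(series) != geometry$n_t1)
    stop(sprintf("series has %d t1 points, geometry expects %d; missing grid points",
                 nrow(series), geometry$n_t1))
  if (length(delays) != ncol(series))
    stop("one delay per series column required")
  if (is.unsorted(delays, strictly = TRUE))
    stop("delays must be strictly increasing")
  n <- geometry$n_t1
  nz <- geometry$n_f1_recon
  win <- if (apodize) cos(pi * (0:(n - 1)) / (2 * n)) else rep(1, n)
  out <- matrix(0, nz, length(delays))
  fg <- frequency_grid(geometry)
  t1 <- t1_values(geometry)
  E <- if (nz < n) exp(-2i * pi * outer(fg, t1)) else NULL
  for (d in seq_along(delays)) {
    fid <- series[, d] * win
    if (nz < n) {
      # target grid coarser than the acquisition grid: direct DFT
      out[, d] <- Mod(E %*% fid)
    } else {
      fid <- c(fid, rep(0 + 0i, nz - n))
      sp <- stats::fft(fid)               # analysis: sum s_t exp(-2i pi k t / N)
      out[, d] <- Mod(fftshift_to_grid(sp))
    }
  }
  structure(out, fgrid = frequency_grid(geometry), delays = delays,
            class = "relaxation_series")
}

# reorder raw FFT bins (0..N-1 cycles) onto the package frequency grid
# (-sw/2, +sw/2]: bins above N/2 are negative frequencies; the bin at
# exactly N/2 cycles is placed at +sw/2.
fftshift_to_grid <- function(sp) {
  N <- length(sp)
  half <- N %/% 2
  c(sp[(half + 2):N], sp[1:(half + 1)])
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf("Conventional relaxation series: %d frequency bins x %d delays (%.3g-%.3g s)\n",
              nrow(x), ncol(x), min(attr(x, "delays")), max(attr(x, "delays"))))
  invisible(x)
}

#' Peak intensities across a relaxation series
#'
#' Reads, for each peak, the magnitude at the nearest frequency bin in
#' every delay plane of a [conventional_process()] result.
#'
#' @param series A `"relaxation_series"`.
#' @param peak_freqs Peak frequencies in Hz.
#' @return Numeric matrix `length(peak_freqs) x n_delays`.
#' @export
series_intensities <- function(series, peak_freqs) {
  stopifnot(inherits(series, "relaxation_series"))
  fg <- attr(series, "fgrid")
  bins <- vapply(peak_freqs, function(f) which.min(abs(fg - f)), integer(1))
  series[bins, , drop = FALSE]
}

#' Reconstruction quality versus sampling level
#'
#' For each sampling level: subsample the schedule (and the corresponding
#' data rows), reconstruct the cube, read off per-peak rates, and
#' correlate them against the supplied baseline rates.  Levels are
#' validated before any computation starts.
#'
#' @param samples Complex sample vector acquired under `schedule`, or a
#'   list of such vectors (one per direct column).
#' @param schedule A [joint_schedule()].
#' @param geometry An [acquisition_geometry()].
#' @param peaks A data frame with at least `id` and `freq_hz` columns (the
#'   peak list at which rates are read off; a `column` column selects the
#'   direct column per peak).
#' @param baseline_rates Numeric vector of reference rates, one per peak
#'   list row (e.g. mono-exponential fits of the conventional series).
#' @param levels Integer vector of sampling levels, each `<= nrow(schedule)`.
#' @param seeds Integer vector of subsampling seeds; the sweep is repeated
#'   per seed.
#' @param config A [solver_config()].
#' @param normalize_laplace Passed to [reconstruct_cube()].
#' @return A data frame with columns `level`, `seed`, `r2`, plus a
#'   `"median_r2"` attribute: the per-level median r² across seeds.
#' @export
sampling_level_sweep <- function(samples, schedule, geometry, peaks,
                                 baseline_rates, levels, seeds = 1L,
                                 config = solver_config(),
                                 normalize_laplace = FALSE) {
  stopifnot(inherits(schedule, "joint_schedule"))
  bad <- levels[levels > nrow(schedule) | levels < 1]
  if (length(bad))
    stop(sprintf("invalid sampling level(s): %s (schedule has %d points)",
                 paste(bad, collapse = ", "), nrow(schedule)))
  if (length(baseline_rates) != nrow(peaks))
    stop("one baseline rate per peak required")
  if (!is.list(samples)) samples <- list(samples)
  rows <- expand.grid(seed = seeds, level = levels)
  out <- data.frame(level = rows$level, seed = rows$seed, r2 = NA_real_)
  key <- paste(schedule$t1_index, format(schedule$trelax, digits = 12))
  for (i in seq_len(nrow(rows))) {
    sub <- subsample_schedule(schedule, rows$level[i], rows$seed[i])
    sel <- match(paste(sub$t1_index, format(sub$trelax, digits = 12)), key)
    cube <- reconstruct_cube(lapply(samples, `[`, sel), sub, geometry, config,
                             normalize_laplace = normalize_laplace,
                             record_objective = FALSE)
    est <- rates_from_cube(cube, peaks)
    ref <- data.frame(id = peaks$id, rate_hz = baseline_rates,
                      edge_flag = FALSE)
    out$r2[i] <- correlate_rates(est, ref)$r2
  }
  med <- stats::aggregate(r2 ~ level, data = out, FUN = stats::median)
  attr(out, "median_r2") <- med[order(med$level), ]
  out
}
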