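#' Peak tables
#'
#' A peak table describes the resonances of a simulated relaxation
#' experiment, one row per peak: indirect frequency offset (Hz), Lorentzian
#' linewidth in t1 (Hz), amplitude (arbitrary units, non-negative) and
#' longitudinal decay rate R (1/s).  An optional `freq_direct` column is
#' carried along when a direct dimension is simulated.
#'
#' @param freq_hz Indirect frequency offsets in Hz, each inside
#'   `(-sw/2, +sw/2]` of the geometry the table is used with.
#' @param linewidth_hz Lorentzian linewidths in t1 (Hz), `>= 0`.
#' @param amplitude Peak amplitudes, `>= 0`.
#' @param rate_hz Longitudinal decay rates R in 1/s, `> 0`.
#' @param freq_direct_hz Optional direct-dimension frequencies (Hz).
#'
#' @return A `data.frame` of class `"peak_table"` with columns
#'   `freq_hz`, `linewidth_hz`, `amplitude`, `rate_hz` (and optionally
#'   `freq_direct_hz`).
#' @export
peak_table <- function(freq_hz = numeric(), linewidth_hz = numeric(),
                       amplitude = numeric(), rate_hz = numeric(),
                       freq_direct_hz = NULL) {
  n <- length(freq_hz)
  stopifnot(length(linewidth_hz) == n, length(amplitude) == n,
            length(rate_hz) == n)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(linewidth_hz < 0)) stop("linewidths must be >= 0")
  if (n > 0 && any(rate_hz <= 0)) stop("decay rates must be > 0")
  df <- data.frame(freq_hz = as.numeric(freq_hz),
                   linewidth_hz = as.numeric(linewidth_hz),
                   amplitude = as.numeric(amplitude),
                   rate_hz = as.numeric(rate_hz))
  if (!is.null(freq_direct_hz)) {
    stopifnot(length(freq_direct_hz) == n)
    df$freq_direct_hz <- as.numeric(freq_direct_hz)
  }
  class(df) <- c("peak_table", "data.frame")
  df
}

check_peaks_in_band <- function(peaks, geometry) {
  sw <- geometry$sw_indirect
  bad <- which(peaks$freq_hz <= -sw / 2 | peaks$freq_hz > sw / 2)
  if (length(bad))
    stop(sprintf("peak frequency outside (-sw/2, +sw/2]: row(s) %s",
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Random protein-like peak fixture
#'
#' Draws a peak table emulating a well-resolved 15N HSQC relaxation series
#' of a small globular protein: frequencies are drawn without
#' near-collisions (minimum separation of two reconstruction bins), decay
#' rates uniformly inside the reconstruction band with a safety margin,
#' amplitudes within one order of magnitude, and Lorentzian linewidths in a
#' realistic amide 15N range.
#'
#' @param n_peaks Number of peaks (`>= 1`).
#' @param geometry An [acquisition_geometry()]; supplies the spectral width,
#'   the reconstruction bin width and the rate band.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param linewidth_range Range (Hz) from which linewidths are drawn
#'   uniformly.  Default 2-15 Hz, narrow relative to the ~23 Hz digital
#'   resolution of a 128-point/3000 Hz grid, as for a small protein with
#'   moderate field and relaxation broadening.
#' @param rate_margin Fraction of the band width kept clear at both band
#'   edges when drawing rates (default 0.1), so that true rates never sit
#'   on the reconstruction boundary where edge artifacts accumulate.
#'
#' @return A [peak_table()] with `n_peaks` rows.
#' @export
protein_fixture <- function(n_peaks, geometry, seed,
                            linewidth_range = c(2, 15),
                            rate_margin = 0.1) {
  stopifnot(inherits(geometry, "acquisition_geometry"), n_peaks >= 1)
  sw <- geometry$sw_indirect
  min_sep <- 2 * sw / geometry$n_f1_recon
  # feasibility of the separation constraint on the open band
  if (n_peaks * min_sep > 0.9 * sw)
    stop(sprintf("cannot place %d peaks with minimum separation %.3g Hz in a %.0f Hz width",
                 n_peaks, min_sep, sw))
  set.seed(seed)
  freqs <- numeric(0)
  tries <- 0L
  while (length(freqs) < n_peaks) {
    cand <- stats::runif(1, -sw / 2 * 0.95, sw / 2 * 0.95)
    if (!length(freqs) || min(abs(freqs - cand)) >= min_sep) {
      freqs <- c(freqs, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L * n_peaks)
      stop("could not satisfy the frequency-separation constraint; too many peaks")
  }
  band <- geometry$r_max - geometry$r_min
  rates <- stats::runif(n_peaks,
                        geometry$r_min + rate_margin * band,
                        geometry$r_max - rate_margin * band)
  # amplitudes within one order of magnitude: log-uniform on [1, 10]
  amps <- 10 ^ stats::runif(n_peaks, 0, 1)
  lws <- stats::runif(n_peaks, linewidth_range[1], linewidth_range[2])
  peak_table(freq_hz = freqs, linewidth_hz = lws,
             amplitude = amps, rate_hz = rates)
}

#' Read or write a peak table as TSV
#'
#' Files are tab-separated with a header line
#' `freq_hz  linewidth_hz  amplitude  rate_hz` (plus `freq_direct_hz` when
#' present); full double precision is preserved on write.
#'
#' @param peaks A [peak_table()].
#' @param path File path.
#' @return `read_peak_table()` returns a [peak_table()];
#'   `write_peak_table()` returns `path` invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_table"))
  df <- as.data.frame(peaks)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("freq_hz", "linewidth_hz", "amplitude", "rate_hz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table file is missing column(s): ", paste(miss, collapse = ", "))
  peak_table(df$freq_hz, df$linewidth_hz, df$amplitude, df$rate_hz,
             freq_direct_hz = df$freq_direct_hz)
}
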