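#' Gaussian rate read-off from a reconstructed cube
#'
#' Extracts the rate-axis trace of the cube at the frequency bin nearest
#' to a peak and fits a single Gaussian `h * exp(-(r - c)^2 / (2 w^2))`
#' (zero baseline) by least squares; the fitted center `c` is the decay
#' rate estimate.  The fit is initialized at the trace argmax and the
#' width is bounded below by half a rate-grid spacing so that a
#' single-bin (delta-like) trace cannot collapse the fit.
#'
#' Reconstruction noise collects as false intensity at the extremes of
#' the rate band (which is why the band should be set wider than the
#' rates one expects).  The read-off therefore locates the peak over the
#' interior of the band — the outermost `edge_frac` of bins at each end
#' are ignored when choosing the initialization — and fits the Gaussian
#' in a window around that maximum, so an artifact ridge at the band edge
#' cannot drag the fit away from a genuine interior peak.  Estimates
#' whose center still converges next to the excluded zone are flagged
#' (`edge_flag = TRUE`) as suspected artifacts.  The fitted width
#' reflects the sparsity constraint as much as the data and must not be
#' read as an uncertainty of R; it is reported separately for inspection
#' only.
#'
#' @param cube A [reconstruct_cube()] result.
#' @param freq_hz Peak indirect frequency (Hz).
#' @param id Peak identifier carried into the result.
#' @param column Direct-dimension column of the cube (default 1).
#' @param edge_frac Fraction of rate bins at each band end excluded from
#'   the peak search (default 0.05).
#' @param window_frac Half-width of the fit window as a fraction of the
#'   band (default 0.1, at least 4 bins).
#' @return A one-row data frame of class `"rate_estimate"`: columns `id`,
#'   `rate_hz`, `method` (`"joint-gaussian"`), `width`, `height`,
#'   `residual_norm`, `edge_flag`, `no_peak`.
#' @export
gaussian_rate_readoff <- function(cube, freq_hz, id = NA, column = 1L,
                                  edge_frac = 0.05, window_frac = 0.1) {
  stopifnot(inherits(cube, "spectrum_cube"))
  fg <- attr(cube, "fgrid"); rg <- attr(cube, "rgrid")
  if (freq_hz < min(fg) - diff(fg[1:2]) || freq_hz > max(fg) + diff(fg[1:2]))
    stop("peak frequency falls outside the cube's frequency axis")
  bin <- which.min(abs(fg - freq_hz))
  trace <- cube[column, bin, ]
  nr <- length(rg)
  if (all(trace == 0)) {
    return(rate_estimate_row(id, NA_real_, "joint-gaussian",
                             width = NA, height = 0, residual_norm = 0,
                             edge_flag = FALSE, no_peak = TRUE))
  }
  dr <- if (nr > 1) rg[2] - rg[1] else 1
  n_edge <- min(floor(edge_frac * nr), (nr - 1) %/% 2)
  interior <- (1 + n_edge):(nr - n_edge)
  i0 <- interior[which.max(trace[interior])]
  half <- max(4, round(window_frac * nr))
  win <- max(1, i0 - half):min(nr, i0 + half)
  fit <- if (length(win) >= 4)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ h * exp(-(r - c)^2 / (2 * w^2)),
        data = data.frame(r = rg[win], y = trace[win]),
        start = list(h = trace[i0], c = rg[i0], w = dr),
        lower = c(h = 0, c = rg[win[1]], w = dr / 2),
        upper = c(h = Inf, c = rg[win[length(win)]], w = diff(range(rg))),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    else simpleError("window too small")
  edge_lo <- rg[1 + n_edge] + dr
  edge_hi <- rg[nr - n_edge] - dr
  if (inherits(fit, "error")) {
    # fall back to the intensity-weighted argmax neighborhood
    lo <- max(1, i0 - 1); hi <- min(nr, i0 + 1)
    cen <- sum(rg[lo:hi] * trace[lo:hi]) / sum(trace[lo:hi])
    return(rate_estimate_row(id, cen, "joint-gaussian",
                             width = dr, height = trace[i0],
                             residual_norm = NA_real_,
                             edge_flag = cen < edge_lo | cen > edge_hi,
                             no_peak = FALSE))
  }
  cf <- stats::coef(fit)
  rate_estimate_row(id, unname(cf["c"]), "joint-gaussian",
                    width = unname(cf["w"]), height = unname(cf["h"]),
                    residual_norm = sqrt(sum(stats::resid(fit)^2)),
                    edge_flag = cf["c"] < edge_lo | cf["c"] > edge_hi,
                    no_peak = FALSE)
}

rate_estimate_row <- function(id, rate, method, width = NA, height = NA,
                              residual_norm = NA, std_error = NA,
                              edge_flag = FALSE, no_peak = FALSE,
                              flagged = FALSE) {
  structure(data.frame(id = id, rate_hz = rate, method = method,
                       width = width, height = height,
                       residual_norm = residual_norm, std_error = std_error,
                       edge_flag = edge_flag, no_peak = no_peak,
                       flagged = flagged, stringsAsFactors = FALSE),
            class = c("rate_estimate", "data.frame"))
}

#' Rates for a whole peak list
#'
#' Applies [gaussian_rate_readoff()] to every row of a peak list.
#'
#' @param cube A [reconstruct_cube()] result.
#' @param peaks Data frame with columns `id` and `freq_hz` (and optionally
#'   `column` for multi-column cubes).
#' @return A `"rate_estimate"` data frame, one row per peak.
#' @export
rates_from_cube <- function(cube, peaks) {
  cols <- if ("column" %in% names(peaks)) peaks$column else rep(1L, nrow(peaks))
  rows <- lapply(seq_len(nrow(peaks)), function(i)
    gaussian_rate_readoff(cube, peaks$freq_hz[i], id = peaks$id[i],
                          column = cols[i]))
  out <- do.call(rbind, rows)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of `a * exp(-R * t)` to peak intensities across the
#' relaxation delays — the conventional route to a longitudinal decay
#' rate.  Initialization comes from a log-linear regression on the
#' positive intensities; the asymptotic standard error of R is reported
#' from the fit's covariance (the quantity conventional processing quotes
#' as the error of the rate).
#'
#' @param intensities Non-negative intensities, one per delay.
#' @param delays Delays (s), at least 3.
#' @param id Peak identifier.
#' @return A one-row `"rate_estimate"` data frame with `method =
#'   "mono-exponential"`, `std_error` (asymptotic), `residual_norm`, and
#'   `flagged = TRUE` for non-decaying data (best R <= 0).
#' @export
mono_exponential_fit <- function(intensities, delays, id = NA) {
  if (length(delays) < 3) stop("at least 3 delays are required")
  if (length(intensities) != length(delays))
    stop("one intensity per delay required")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  pos <- intensities > 0
  if (sum(pos) < 2) {
    return(rate_estimate_row(id, NA_real_, "mono-exponential",
                             flagged = TRUE, residual_norm = NA_real_))
  }
  init <- stats::lm(log(intensities[pos]) ~ delays[pos])
  R0 <- -unname(stats::coef(init)[2])
  a0 <- exp(unname(stats::coef(init)[1]))
  if (!is.finite(R0)) R0 <- 1
  if (!is.finite(a0) || a0 <= 0) a0 <- max(intensities)
  if (R0 * diff(range(delays)) < 1e-8) {
    # non-decaying data: the best mono-exponential has R <= 0 (or loses
    # no measurable intensity across the whole delay range)
    return(rate_estimate_row(id, max(R0, 0), "mono-exponential",
                             height = a0, flagged = TRUE,
                             residual_norm = NA_real_))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-R * t),
                      data = data.frame(t = delays, y = intensities),
                      start = list(a = a0, R = max(R0, 1e-6)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("mono-exponential fit failed: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["R"], error = function(e) NA_real_)
  rate_estimate_row(id, unname(cf["R"]), "mono-exponential",
                    height = unname(cf["a"]),
                    residual_norm = sqrt(sum(stats::resid(fit)^2)),
                    std_error = unname(se),
                    flagged = cf["R"] <= 0)
}

#' Rates for a peak list from a conventional series
#'
#' Reads per-delay intensities at each peak's frequency bin and fits a
#' mono-exponential decay to every peak.
#'
#' @param series A [conventional_process()] result.
#' @param peaks Data frame with columns `id` and `freq_hz`.
#' @return A `"rate_estimate"` data frame, one row per peak.
#' @export
rates_from_series <- function(series, peaks) {
  ints <- series_intensities(series, peaks$freq_hz)
  delays <- attr(series, "delays")
  rows <- lapply(seq_len(nrow(peaks)), function(i)
    mono_exponential_fit(ints[i, ], delays, id = peaks$id[i]))
  out <- do.call(rbind, rows)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Cross-method rate correlation
#'
#' Squared Pearson correlation between two sets of rate estimates,
#' matched by peak id.  Edge-flagged or otherwise flagged estimates are
#' excluded from the correlation and counted separately, so that
#' `matched + excluded + unmatched` always accounts for every peak.
#'
#' @param a,b `"rate_estimate"` data frames (or data frames with `id` and
#'   `rate_hz` columns; missing flag columns are treated as all-FALSE).
#' @return List with `r2`, `n_matched`, `n_excluded`, `n_unmatched`, and
#'   `pairs` (the matched id/rate table used for the correlation).
#' @export
correlate_rates <- function(a, b) {
  flag_of <- function(x) {
    f <- rep(FALSE, nrow(x))
    for (col in c("edge_flag", "no_peak", "flagged"))
      if (col %in% names(x)) f <- f | (x[[col]] %in% TRUE)
    f | !is.finite(x$rate_hz)
  }
  ids <- union(a$id, b$id)
  ia <- match(ids, a$id); ib <- match(ids, b$id)
  matched <- !is.na(ia) & !is.na(ib)
  ok <- matched & !flag_of(a)[ia] & !flag_of(b)[ib]
  ok[is.na(ok)] <- FALSE
  n_excluded <- sum(matched & !ok)
  if (sum(ok) < 3)
    stop(sprintf("need at least 3 matched unflagged pairs, got %d", sum(ok)))
  x <- a$rate_hz[ia[ok]]; y <- b$rate_hz[ib[ok]]
  pairs <- data.frame(id = ids[ok], rate_a = x, rate_b = y)
  list(r2 = stats::cor(x, y)^2,
       n_matched = sum(ok), n_excluded = n_excluded,
       n_unmatched = sum(!matched), pairs = pairs)
}

#' Read and write peak lists and rate tables as TSV
#'
#' Peak lists carry `id`, an optional direct coordinate and the indirect
#' frequency in Hz; rate tables are [correlate_rates()]-ready estimate
#' tables.
#'
#' @param path File path.
#' @param peaks,rates Data frames to write.
#' @return Readers return data frames; writers return `path` invisibly.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("id", "freq_hz") %in% names(df)))
    stop("peak list needs at least 'id' and 'freq_hz' columns")
  if (anyDuplicated(df$id)) stop("peak ids must be unique")
  df
}

#' @rdname read_peak_list
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_peak_list
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(as.data.frame(rates), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
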