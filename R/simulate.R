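#' Complex noise specification
#'
#' Additive circular complex Gaussian noise, i.i.d. across samples:
#' real and imaginary parts are independent `N(0, sigma^2)`.
#'
#' @param sigma Standard deviation of the real and of the imaginary
#'   component of each sample (`>= 0`).
#' @param seed Integer seed; the same seed reproduces the realization
#'   bit-for-bit.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0, seed = 1L) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a jointly sampled relaxation FID
#'
#' Evaluates the pseudo-3D signal model at the scheduled
#' `(t1, trelax)` pairs: each peak contributes a complex exponential in t1
#' (analytic signal), damped by a Lorentzian linewidth, and scaled by a
#' mono-exponential decay in the relaxation delay,
#' \deqn{s_m = \sum_i a_i \, e^{\,2\pi i f_i t_{1,m}} \,
#'       e^{-\pi \lambda_i t_{1,m}} \, e^{-R_i t_{relax,m}} + \epsilon_m,}
#' with `\epsilon` drawn from the noise model.
#'
#' @param peaks A [peak_table()].
#' @param geometry An [acquisition_geometry()]; every peak frequency must
#'   lie inside its spectral width.
#' @param schedule A [joint_schedule()] whose pairs all belong to the
#'   geometry's grid.
#' @param noise A [noise_model()] (default: noiseless).
#' @return Complex vector, one entry per schedule row.
#' @export
simulate_joint_fid <- function(peaks, geometry, schedule,
                               noise = noise_model(0)) {
  stopifnot(inherits(peaks, "peak_table"),
            inherits(geometry, "acquisition_geometry"),
            inherits(schedule, "joint_schedule"))
  validate_schedule_against(schedule, geometry)
  check_peaks_in_band(peaks, geometry)
  t1 <- schedule$t1_index / geometry$sw_indirect
  tr <- schedule$trelax
  s <- complex(real = numeric(nrow(schedule)), imaginary = 0)
  for (i in seq_len(nrow(peaks))) {
    s <- s + peaks$amplitude[i] *
      exp(2i * pi * peaks$freq_hz[i] * t1) *
      exp(-pi * peaks$linewidth_hz[i] * t1) *
      exp(-peaks$rate_hz[i] * tr)
  }
  if (noise$sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
    s <- s + complex(real = stats::rnorm(length(s), 0, noise$sigma),
                     imaginary = stats::rnorm(length(s), 0, noise$sigma))
  }
  s
}

# schedule rows must live on the geometry's joint grid
validate_schedule_against <- function(schedule, geometry) {
  bad <- which(schedule$t1_index < 0L | schedule$t1_index >= geometry$n_t1)
  if (length(bad))
    stop(sprintf("schedule t1 index outside the geometry grid at row(s) %s",
                 paste(bad, collapse = ", ")))
  j <- delay_index(schedule$trelax, geometry)
  bad <- which(is.na(j))
  if (length(bad))
    stop(sprintf("schedule delay outside the geometry's delay universe at row(s) %s",
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Simulate the fully sampled conventional relaxation series
#'
#' Full t1 grid at each of a set of canonical relaxation delays, as in a
#' conventional pseudo-3D T1 experiment (a series of 2D planes).
#'
#' @param peaks A [peak_table()].
#' @param geometry An [acquisition_geometry()].
#' @param delays Canonical delays (s); defaults to
#'   [canonical_delays()] of the geometry.
#' @param noise A [noise_model()].
#' @return Complex matrix `n_t1 x length(delays)`, column `d` holding the
#'   full FID at `delays[d]`; delays attached as an attribute.
#' @export
simulate_full_series <- function(peaks, geometry,
                                 delays = canonical_delays(geometry),
                                 noise = noise_model(0)) {
  stopifnot(inherits(peaks, "peak_table"),
            inherits(geometry, "acquisition_geometry"))
  check_peaks_in_band(peaks, geometry)
  t1 <- t1_values(geometry)
  m <- matrix(0 + 0i, geometry$n_t1, length(delays))
  for (i in seq_len(nrow(peaks))) {
    ft <- peaks$amplitude[i] *
      exp(2i * pi * peaks$freq_hz[i] * t1) *
      exp(-pi * peaks$linewidth_hz[i] * t1)
    m <- m + outer(ft, exp(-peaks$rate_hz[i] * delays))
  }
  if (noise$sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
    m <- m + matrix(complex(real = stats::rnorm(length(m), 0, noise$sigma),
                            imaginary = stats::rnorm(length(m), 0, noise$sigma)),
                    nrow(m), ncol(m))
  }
  attr(m, "delays") <- delays
  m
}

#' Canonical relaxation delays of a geometry
#'
#' Ten delays spread evenly from the smallest to the largest delay of the
#' universe and snapped to the mesh — the delay list a conventional
#' (fully sampled) longitudinal relaxation series would use.
#'
#' @param geometry An [acquisition_geometry()].
#' @param n Number of delays (default 10).
#' @return Numeric vector of `n` strictly increasing delays (s).
#' @export
canonical_delays <- function(geometry, n = 10) {
  d <- seq(geometry$trelax_min, geometry$trelax_max, length.out = n)
  d <- geometry$trelax_min +
    round((d - geometry$trelax_min) / geometry$trelax_mesh) * geometry$trelax_mesh
  unique(d)
}
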