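#' Acquisition geometry for a joint t1/relaxation-delay experiment
#'
#' Describes the sampling universe and the reconstruction grids of a
#' pseudo-3D relaxation experiment: the indirect evolution grid
#' (`n_t1` points at multiples of `1/sw_indirect`), the finite universe of
#' relaxation delays (`trelax_min` to `trelax_max` on a mesh of
#' `trelax_mesh` seconds), and the frequency x decay-rate grid on which
#' spectra are reconstructed.
#'
#' @param n_t1 Number of indirect (t1) grid points; t1 values are
#'   `k / sw_indirect` for `k = 0 .. n_t1 - 1`.
#' @param sw_indirect Indirect spectral width in Hz.
#' @param trelax_min,trelax_max Smallest and largest relaxation delay (s).
#' @param trelax_mesh Granularity of the relaxation-delay universe (s).
#' @param n_f1_recon Reconstruction grid size along indirect frequency.
#' @param n_r_recon Reconstruction grid size along decay rate.
#' @param r_min,r_max Decay-rate reconstruction band (1/s), `0 < r_min < r_max`.
#'
#' @return An object of class `"acquisition_geometry"`.
#' @examples
#' geo <- acquisition_geometry(n_t1 = 128, sw_indirect = 3000,
#'                             trelax_min = 0.01, trelax_max = 0.8,
#'                             trelax_mesh = 0.01,
#'                             n_f1_recon = 256, n_r_recon = 256,
#'                             r_min = 0.5, r_max = 5)
#' length(delay_universe(geo))  # 80 candidate delays
#' @export
acquisition_geometry <- function(n_t1, sw_indirect,
                                 trelax_min, trelax_max, trelax_mesh,
                                 n_f1_recon, n_r_recon,
                                 r_min, r_max) {
  stopifnot(n_t1 >= 1, sw_indirect > 0,
            trelax_min >= 0, trelax_max >= trelax_min, trelax_mesh > 0,
            n_f1_recon >= 1, n_r_recon >= 1)
  if (!(r_min > 0 && r_min < r_max))
    stop("decay-rate band requires 0 < r_min < r_max")
  structure(list(
    n_t1        = as.integer(n_t1),
    sw_indirect = sw_indirect,
    trelax_min  = trelax_min,
    trelax_max  = trelax_max,
    trelax_mesh = trelax_mesh,
    n_f1_recon  = as.integer(n_f1_recon),
    n_r_recon   = as.integer(n_r_recon),
    r_min       = r_min,
    r_max       = r_max
  ), class = "acquisition_geometry")
}

#' Relaxation-delay universe of a geometry
#'
#' The finite set of delays `trelax_min + j * trelax_mesh` that fall inside
#' `[trelax_min, trelax_max]`.  Joint schedules may only use delays from
#' this set.
#'
#' @param geometry An [acquisition_geometry()].
#' @return Numeric vector of delays in seconds, strictly increasing.
#' @export
delay_universe <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  n <- floor((geometry$trelax_max - geometry$trelax_min) /
               geometry$trelax_mesh + 1e-9)
  geometry$trelax_min + (0:n) * geometry$trelax_mesh
}

#' t1 values of a geometry
#'
#' @param geometry An [acquisition_geometry()].
#' @return Numeric vector `0:(n_t1-1) / sw_indirect` in seconds.
#' @export
t1_values <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  (seq_len(geometry$n_t1) - 1) / geometry$sw_indirect
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  du <- delay_universe(x)
  cat("Acquisition geometry\n")
  cat(sprintf("  indirect:  %d t1 points, sw = %g Hz\n", x$n_t1, x$sw_indirect))
  cat(sprintf("  delays:    %d values, %g-%g s (mesh %g s)\n",
              length(du), x$trelax_min, x$trelax_max, x$trelax_mesh))
  cat(sprintf("  recon:     %d x %d grid, rate band %g-%g 1/s\n",
              x$n_f1_recon, x$n_r_recon, x$r_min, x$r_max))
  invisible(x)
}
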