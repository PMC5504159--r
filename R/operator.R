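#' Reconstruction grids
#'
#' `frequency_grid()` returns the `n_f1_recon` indirect-frequency bin
#' centers covering `(-sw/2, +sw/2]` with uniform spacing `sw/n`;
#' `rate_grid()` returns `n_r_recon` decay rates spanning
#' `[r_min, r_max]`, linearly spaced by default.
#'
#' @param geometry An [acquisition_geometry()].
#' @param log_spacing For `rate_grid()`: logarithmic instead of linear
#'   spacing (non-default).
#' @return Numeric vector of bin coordinates (Hz, resp. 1/s),
#'   strictly increasing.
#' @export
frequency_grid <- function(geometry) {
  n <- geometry$n_f1_recon
  sw <- geometry$sw_indirect
  -sw / 2 + (1:n) * sw / n
}

#' @rdname frequency_grid
#' @export
rate_grid <- function(geometry, log_spacing = FALSE) {
  if (log_spacing)
    exp(seq(log(geometry$r_min), log(geometry$r_max),
            length.out = geometry$n_r_recon))
  else
    seq(geometry$r_min, geometry$r_max, length.out = geometry$n_r_recon)
}

#' One row of the inverse-Fourier synthesis matrix
#'
#' Entry `k` is `exp(+2i*pi*f_k*t1) / n` — the synthesis (spectrum to
#' time) convention with positive exponent and `1/n` scaling, so a
#' standard inverse DFT of the reconstruction reproduces the time signal.
#'
#' @param t1 Evolution time (s).
#' @param fgrid Frequency grid (Hz), as from [frequency_grid()].
#' @return Complex vector of length `length(fgrid)`.
#' @export
fourier_row <- function(t1, fgrid) {
  exp(2i * pi * fgrid * t1) / length(fgrid)
}

#' Laplace kernel entry
#'
#' `exp(-rate * trelax)`: the contribution of a component decaying at
#' `rate` to a sample taken after a relaxation delay `trelax`.  Columns of
#' the assembled Laplace matrix are not normalized by default (see the
#' `normalize_laplace` switch of [joint_operator()]).
#'
#' @param trelax Relaxation delay (s), `>= 0`.
#' @param rate Decay rate (1/s), `> 0`.
#' @return `exp(-rate * trelax)`, vectorized over both arguments.
#' @export
laplace_entry <- function(trelax, rate) {
  if (any(trelax < 0)) stop("relaxation delays must be >= 0")
  if (any(rate <= 0)) stop("decay rates must be > 0")
  exp(-rate * trelax)
}

#' Sampled joint Fourier-Laplace operator
#'
#' The linear map from a frequency x rate spectral plane `Q` to the vector
#' of jointly scheduled time-domain samples: row `m` of the (conceptual)
#' Kronecker dictionary is the outer product of the inverse-Fourier row at
#' `t1_m` and the Laplace kernel row at `trelax_m`.  Forward and adjoint
#' actions are evaluated by separable contraction without materializing
#' the Kronecker matrix; [as_dense_matrix()] assembles it explicitly for
#' small-grid verification.
#'
#' @param geometry An [acquisition_geometry()].
#' @param schedule A [joint_schedule()] on that geometry.
#' @param normalize_laplace Scale each rate column of the Laplace kernel to
#'   unit Euclidean norm over the scheduled delays.  Off by default (raw
#'   `exp(-R t)` kernels); turning it on removes the l1 shrinkage bias
#'   against fast-decaying components at the cost of rescaling the plane.
#' @param log_spacing Use a logarithmic rate grid (default linear).
#' @return An object of class `"joint_operator"` with fields
#'   `fgrid`, `rgrid`, the per-sample Fourier (`Fs`) and Laplace (`Ls`)
#'   factor matrices, and `col_scale` (the applied Laplace column norms).
#' @export
#' @param use_fft Evaluate the Fourier factor through the FFT over the
#'   reconstruction grid instead of the explicit factor matrix.  Exact
#'   (the t1 samples lie on the DFT grid of the frequency axis by
#'   construction) and much faster on large grids; default `TRUE`.
joint_operator <- function(geometry, schedule,
                           normalize_laplace = FALSE,
                           log_spacing = FALSE,
                           use_fft = TRUE) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(schedule, "joint_schedule"))
  validate_schedule_against(schedule, geometry)
  fgrid <- frequency_grid(geometry)
  rgrid <- rate_grid(geometry, log_spacing)
  t1 <- schedule$t1_index / geometry$sw_indirect
  # Fs[m, k] = exp(2i pi f_k t1_m)/n ; Ls[m, j] = exp(-r_j trelax_m)
  Fs <- exp(2i * pi * outer(t1, fgrid)) / length(fgrid)
  Ls <- exp(-outer(schedule$trelax, rgrid))
  col_scale <- rep(1, length(rgrid))
  if (normalize_laplace && nrow(Ls) > 0) {
    col_scale <- sqrt(colSums(Ls ^ 2))
    col_scale[col_scale == 0] <- 1
    Ls <- sweep(Ls, 2, col_scale, "/")
  }
  nf <- length(fgrid)
  # with f_k = -sw/2 + k*sw/nf and t1 = m/sw:
  # exp(2i pi f_k t1) = (-1)^m * exp(2i pi m k / nf), so the Fourier factor
  # is an (aliased) nf-point DFT regardless of n_t1
  structure(list(geometry = geometry, schedule = schedule,
                 fgrid = fgrid, rgrid = rgrid,
                 Fs = Fs, Ls = Ls, col_scale = col_scale,
                 use_fft = isTRUE(use_fft),
                 t1_mod = schedule$t1_index %% nf + 1L,
                 t1_sign = 1 - 2 * (schedule$t1_index %% 2L)),
            class = "joint_operator")
}

#' Forward action of the joint operator
#'
#' Sample `m` is `sum_{k,j} Fs[m,k] * Ls[m,j] * Q[k,j]`, computed as a
#' separable contraction `rowSums((Fs %*% Q) * Ls)`.
#'
#' @param Q Complex matrix `n_f1_recon x n_r_recon` (the spectral plane).
#' @param op A [joint_operator()].
#' @return Complex sample vector, one entry per schedule row.
#' @export
joint_forward <- function(Q, op) {
  stopifnot(inherits(op, "joint_operator"))
  if (!is.matrix(Q) ||
      nrow(Q) != length(op$fgrid) || ncol(Q) != length(op$rgrid))
    stop(sprintf("plane must be %d x %d, got %d x %d",
                 length(op$fgrid), length(op$rgrid),
                 NROW(Q), NCOL(Q)))
  if (op$use_fft) {
    nf <- length(op$fgrid)
    # frequency-grid bin k corresponds to DFT bin k mod nf (bin nf is DC)
    Qp <- if (nf > 1) Q[c(nf, seq_len(nf - 1)), , drop = FALSE] else Q
    V <- stats::mvfft(Qp, inverse = TRUE) / nf    # rows: exp(+2i pi m k/nf)
    op$t1_sign * rowSums(V[op$t1_mod, , drop = FALSE] * op$Ls)
  } else {
    rowSums(op$Fs %*% Q * op$Ls)
  }
}

#' Adjoint action of the joint operator
#'
#' The exact algebraic adjoint of [joint_forward()]:
#' `Qhat[k,j] = sum_m Conj(Fs[m,k]) * Ls[m,j] * q_m`, so that
#' `<P Q, q> == <Q, P^H q>` for all planes and sample vectors.
#'
#' @param q Complex sample vector of schedule length.
#' @param op A [joint_operator()].
#' @return Complex plane `n_f1_recon x n_r_recon`.
#' @export
joint_adjoint <- function(q, op) {
  stopifnot(inherits(op, "joint_operator"))
  if (length(q) != nrow(op$Fs))
    stop(sprintf("sample vector length %d does not match schedule length %d",
                 length(q), nrow(op$Fs)))
  if (op$use_fft) {
    nf <- length(op$fgrid); nr <- length(op$rgrid)
    B <- (op$t1_sign * q) * op$Ls              # samples x rates
    U <- matrix(0, nf, nr); Ui <- matrix(0, nf, nr)
    rs <- rowsum(Re(B), op$t1_mod)             # scatter-add per t1 cell
    U[as.integer(rownames(rs)), ] <- rs
    rs <- rowsum(Im(B), op$t1_mod)
    Ui[as.integer(rownames(rs)), ] <- rs
    out <- stats::mvfft(matrix(complex(real = U, imaginary = Ui), nf, nr)) / nf
    if (nf > 1) out[c(2:nf, 1), , drop = FALSE] else out
  } else {
    crossprod(Conj(op$Fs), q * op$Ls)
  }
}

#' Dense Kronecker matrix of a joint operator
#'
#' Assembles the full `n_samples x (n_f1 * n_r)` matrix whose action on
#' `vec(Q)` (column-major) equals [joint_forward()].  Intended for
#' small-grid verification only; memory grows as the product of all sizes.
#'
#' @param op A [joint_operator()].
#' @return Complex matrix.
#' @export
as_dense_matrix <- function(op) {
  stopifnot(inherits(op, "joint_operator"))
  m <- nrow(op$Fs); nf <- ncol(op$Fs); nr <- ncol(op$Ls)
  A <- matrix(0 + 0i, m, nf * nr)
  for (j in seq_len(nr))
    A[, (j - 1) * nf + seq_len(nf)] <- op$Fs * op$Ls[, j]
  A
}
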