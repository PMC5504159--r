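# Independent dense-matrix oracles used to cross-check the separable
# operator and the FISTA solver.  Deliberately share no code with the
# package internals: the dictionary is assembled as an explicit matrix and
# the lasso oracle is ADMM with an exact Hermitian x-update.

# min ||A x - b||_2^2 + tau ||x||_1 over complex x, by ADMM
admm_lasso <- function(A, b, tau, rho = NULL, n_iter = 20000) {
  n <- ncol(A)
  if (is.null(rho)) rho <- max(tau, max(Mod(crossprod(Conj(A), b))))
  Mi <- solve(2 * Conj(t(A)) %*% A + diag(rho, n))
  Ahb2 <- 2 * as.vector(crossprod(Conj(A), b))
  x <- z <- u <- complex(n)
  for (k in seq_len(n_iter)) {
    x <- as.vector(Mi %*% (Ahb2 + rho * (z - u)))
    v <- x + u
    a <- Mod(v)
    z <- v * ifelse(a > tau / rho, (a - tau / rho) / a, 0)
    u <- u + x - z
  }
  z
}

lasso_objective <- function(A, b, tau, x) {
  sum(Mod(A %*% x - b)^2) + tau * sum(Mod(x))
}

# reference dense Kronecker dictionary built independently of the package:
# row m is the outer product of the Fourier synthesis row at t1_m and the
# exponential kernel at trelax_m, vec() in column-major plane order
dense_dictionary <- function(geometry, schedule) {
  fg <- frequency_grid(geometry)
  rg <- rate_grid(geometry)
  t1 <- schedule$t1_index / geometry$sw_indirect
  m <- nrow(schedule)
  A <- matrix(0 + 0i, m, length(fg) * length(rg))
  for (i in seq_len(m)) {
    frow <- exp(2i * pi * fg * t1[i]) / length(fg)
    lrow <- exp(-rg * schedule$trelax[i])
    A[i, ] <- as.vector(outer(frow, lrow))
  }
  A
}

small_geometry <- function(n_t1 = 8, nf = 8, nr = 8, n_delay_max = 0.8) {
  acquisition_geometry(n_t1 = n_t1, sw_indirect = 100,
                       trelax_min = 0.01, trelax_max = n_delay_max,
                       trelax_mesh = 0.01,
                       n_f1_recon = nf, n_r_recon = nr,
                       r_min = 0.5, r_max = 5)
}

random_complex <- function(n) complex(real = stats::rnorm(n),
                                      imaginary = stats::rnorm(n))
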