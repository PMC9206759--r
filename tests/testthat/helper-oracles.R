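# Independent brute-force oracles.  These deliberately mirror the printed
# formulas with plain loops and never call the implementation paths they
# check.

oracle_cov <- function(x_stack, L) {
  if (is.vector(x_stack)) x_stack <- matrix(x_stack, ncol = 1L)
  N <- nrow(x_stack); nt <- ncol(x_stack); ns <- N - L + 1L
  R <- matrix(0+0i, L, L)
  for (k in seq_len(nt)) for (l in seq_len(ns)) {
    xl <- x_stack[l:(l + L - 1L), k]
    R <- R + outer(xl, Conj(xl))
  }
  R / (nt * ns)
}

oracle_smooth <- function(x, Lp) oracle_cov(matrix(x, ncol = 1L), Lp)

oracle_rotary <- function(R) {
  n <- nrow(R)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) J[i, n - i + 1L] <- 1
  (R + J %*% t(R) + J %*% R %*% J + t(R) %*% J) / 4
}

oracle_msr <- function(M, cap = 1e6) {
  v <- as.vector(Re(M))
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / length(v))
  if (s <= 1e-12 * abs(m)) { if (m == 0) 0 else cap } else m / s
}

# dense grid search for the constrained 2x2 Capon minimum:
# w = [u + iv, (1 - u) - iv] satisfies w^H 1 = 1 for all (u, v)
oracle_mv_power_min2 <- function(Rhat, n_grid = 121L) {
  us <- seq(-2, 3, length.out = n_grid)
  vs <- seq(-2.5, 2.5, length.out = n_grid)
  best <- Inf
  for (u in us) for (v in vs) {
    w <- c(complex(real = u, imaginary = v),
           complex(real = 1 - u, imaginary = -v))
    p <- Re(Conj(w) %*% Rhat %*% w)
    if (p < best) best <- p
  }
  best
}

random_hermitian_psd <- function(n, load = 0) {
  A <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  A %*% Conj(t(A)) / n + load * diag(n)
}

random_cx <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))
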