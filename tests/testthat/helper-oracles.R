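# Independent oracles used to cross-check the Liouville machinery.

# Classic fixed-step RK4 integration of d v/dt = M v.
rk4_propagate <- function(M, v0, t_end, n_steps) {
  h <- t_end / n_steps
  v <- v0
  for (k in seq_len(n_steps)) {
    k1 <- M %*% v
    k2 <- M %*% (v + h / 2 * k1)
    k3 <- M %*% (v + h / 2 * k2)
    k4 <- M %*% (v + h * k3)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v
}

# Element-wise partial trace over the spins in `traced` (brute force over
# basis indices; spin 1 = most significant bit).
partial_trace_oracle <- function(rho, n, traced) {
  keep <- setdiff(seq_len(n), traced)
  dA <- 2^length(keep)
  dB <- 2^length(traced)
  bits_of <- function(i) as.integer(intToBits(i - 1))[n:1][1:n]  # MSB first
  idx_from_bits <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1)) + 1
  out <- matrix(0 + 0i, dA, dA)
  d <- 2^n
  for (i in seq_len(d)) for (j in seq_len(d)) {
    bi <- bits_of(i); bj <- bits_of(j)
    if (all(bi[traced] == bj[traced])) {
      ia <- idx_from_bits(bi[keep])
      ja <- idx_from_bits(bj[keep])
      out[ia, ja] <- out[ia, ja] + rho[i, j]
    }
  }
  out
}

random_hermitian <- function(d) {
  A <- matrix(stats::rnorm(d * d), d, d) +
    1i * matrix(stats::rnorm(d * d), d, d)
  (A + Conj(t(A))) / 2
}

random_density <- function(d) {
  A <- matrix(stats::rnorm(d * d), d, d) +
    1i * matrix(stats::rnorm(d * d), d, d)
  rho <- A %*% Conj(t(A))
  rho / sum(diag(rho))
}

hermitian_error <- function(m) max(abs(m - Conj(t(m))))

# All transition frequencies (Hz) of Hamiltonian H (rad/s) connected by
# operator F: exhaustive eigendecomposition oracle.
allowed_transitions_hz <- function(H, F, tol = 1e-8) {
  eg <- eigen(H, symmetric = TRUE)
  Ft <- Conj(t(eg$vectors)) %*% F %*% eg$vectors
  d <- length(eg$values)
  out <- c()
  for (i in seq_len(d)) for (j in seq_len(d)) if (i != j) {
    if (Mod(Ft[i, j]) > tol * max(Mod(F))) {
      out <- c(out, abs(eg$values[i] - eg$values[j]) / (2 * pi))
    }
  }
  sort(unique(round(out, 6)))
}
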