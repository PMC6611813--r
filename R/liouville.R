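# Superoperator algebra on column-vectorized density matrices.
#
# Vectorization convention: vec() stacks the columns of a d x d matrix into a
# length-d^2 column (column-wise concatenation), so that
# vec(P %*% rho %*% Q) == (t(Q) %x% P) %*% vec(rho). This identity is the
# normative contract; everything else (commutator, trace, partial-trace and
# attachment superoperators) is built on it.

#' Vectorize a density matrix (column stacking)
#'
#' @param rho Square matrix.
#' @return Complex column vector of length `nrow(rho)^2`.
#' @seealso [unvec_dm()]
#' @export
vec_dm <- function(rho) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop("rho must be a square matrix", call. = FALSE)
  dim(rho) <- c(length(rho), 1)
  rho
}

#' Restore a square matrix from its column-stacked vector
#'
#' @param v Vector of length d^2.
#' @return d x d matrix.
#' @export
unvec_dm <- function(v) {
  v <- as.vector(v)
  d <- sqrt(length(v))
  if (d != round(d)) stop("length is not a perfect square", call. = FALSE)
  matrix(v, d, d)
}

#' Trace of a vectorized state
#'
#' Sums the entries at the positions of the diagonal elements.
#'
#' @param v Vectorized d x d matrix.
#' @return Scalar trace.
#' @export
trace_vec <- function(v) {
  v <- as.vector(v)
  d <- as.integer(round(sqrt(length(v))))
  sum(v[(seq_len(d) - 1L) * d + seq_len(d)])
}

# Linear functional w such that sum(w * vec(rho)) == Tr(A %*% rho).
.trace_functional <- function(A) as.vector(t(A))

#' Hamiltonian commutator superoperator
#'
#' Returns the matrix of rho -> [H, rho] on vectorized states:
#' (1 %x% H) - (t(H) %x% 1). The coherent part of a Liouvillian is -i times
#' this matrix.
#'
#' @param H Hamiltonian matrix (rad/s); a warning is issued if it is not
#'   Hermitian (the superoperator is still computed).
#' @return d^2 x d^2 complex matrix.
#' @export
hamiltonian_superop <- function(H) {
  d <- nrow(H)
  if (max(abs(H - Conj(t(H)))) > 1e-10 * max(1, max(abs(H))))
    warning("H is not Hermitian; commutator superoperator computed anyway")
  Id <- diag(d)
  kronecker(Id, H) - kronecker(t(H), Id)
}

#' Liouvillian from a Hamiltonian and an optional relaxation superoperator
#'
#' L = -i [H, .] + R acting on vectorized density matrices.
#'
#' @param H Hamiltonian (rad/s).
#' @param R Optional relaxation superoperator from [relaxation_superop()].
#' @return d^2 x d^2 complex matrix.
#' @export
liouvillian <- function(H, R = NULL) {
  L <- -1i * hamiltonian_superop(H)
  if (!is.null(R)) L <- L + R
  L
}

# Bits of basis indices: spin 1 is the leftmost Kronecker factor, i.e. the
# most significant bit. Returns the 1-based sub-index formed by the bits of
# `spins` (in the given order) of each 1-based full-space index in `i`.
.sub_index <- function(i, spins, n) {
  i0 <- i - 1L
  m <- length(spins)
  out <- integer(length(i))
  for (k in seq_len(m)) {
    bit <- (i0 %/% 2L^(n - spins[k])) %% 2L
    out <- out + bit * 2L^(m - k)
  }
  out + 1L
}

#' Partial-trace superoperator
#'
#' The exact linear map T with T %*% vec(rho_C) == vec(Tr_B rho_C), where B is
#' the set of traced spins. In the exchange master equation this implements
#' dissociation: removal of subsystem B from species C. The map is trace
#' preserving.
#'
#' @param system_C The full species as a [spin_system()] (or an integer spin
#'   count).
#' @param traced Integer indices of the spins to remove (a proper subset).
#' @return d_A^2 x d_C^2 complex matrix, where A is the residual system.
#' @export
partial_trace_superop <- function(system_C, traced) {
  n <- if (inherits(system_C, "spin_system")) system_C$n_spins else
    as.integer(system_C)
  traced <- as.integer(traced)
  if (length(traced) == 0 || anyDuplicated(traced) ||
      any(traced < 1 | traced > n) || length(traced) >= n)
    stop("traced must be a proper, in-range subset of the spins",
         call. = FALSE)
  keep <- setdiff(seq_len(n), traced)
  dC <- 2L^n
  dA <- 2L^length(keep)
  iC <- rep(seq_len(dC), times = dC)       # row index of rho_C
  jC <- rep(seq_len(dC), each = dC)        # column index of rho_C
  same_B <- .sub_index(iC, traced, n) == .sub_index(jC, traced, n)
  iA <- .sub_index(iC[same_B], keep, n)
  jA <- .sub_index(jC[same_B], keep, n)
  Tm <- matrix(0 + 0i, dA^2, dC^2)
  Tm[cbind((jA - 1L) * dA + iA, which(same_B))] <- 1
  Tm
}

#' Attachment (direct-product) superoperator
#'
#' The map D with D %*% vec(rho_A) == vec of rho_A tensor rho_B, reordered so
#' that the attached spins occupy `positions` in the combined system. In the
#' exchange master equation this implements association: formation of species
#' C by adding subsystem B (in the fixed bath state rho_B) to species A. It is
#' trace preserving, and composing it with the partial trace over the same
#' spins gives the identity on species-A states.
#'
#' @param system_A Residual species ([spin_system()] or spin count).
#' @param attached Attached subsystem B ([spin_system()] or spin count).
#' @param positions Positions (1-based, within the combined system) that the
#'   spins of B occupy, in B's spin order.
#' @param rho_B Bath state of B; defaults to the maximally mixed (unpolarized)
#'   state. Must have unit trace.
#' @return d_C^2 x d_A^2 complex matrix.
#' @export
attach_superop <- function(system_A, attached, positions, rho_B = NULL) {
  nA <- if (inherits(system_A, "spin_system")) system_A$n_spins else
    as.integer(system_A)
  nB <- if (inherits(attached, "spin_system")) attached$n_spins else
    as.integer(attached)
  positions <- as.integer(positions)
  n <- nA + nB
  if (length(positions) != nB || anyDuplicated(positions) ||
      any(positions < 1 | positions > n))
    stop("positions must be ", nB, " distinct indices in 1..", n,
         call. = FALSE)
  dB <- 2L^nB
  if (is.null(rho_B)) rho_B <- diag(dB) / dB + 0i
  if (abs(sum(diag(rho_B)) - 1) > 1e-12)
    stop("rho_B must have unit trace", call. = FALSE)
  a_pos <- setdiff(seq_len(n), positions)
  dC <- 2L^n
  dA <- 2L^nA
  iC <- rep(seq_len(dC), times = dC)
  jC <- rep(seq_len(dC), each = dC)
  iA <- .sub_index(iC, a_pos, n)
  jA <- .sub_index(jC, a_pos, n)
  iB <- .sub_index(iC, positions, n)
  jB <- .sub_index(jC, positions, n)
  D <- matrix(0 + 0i, dC^2, dA^2)
  D[cbind(seq_len(dC^2), (jA - 1L) * dA + iA)] <- rho_B[cbind(iB, jB)]
  D
}

#' Fluctuating-field relaxation superoperator
#'
#' Extreme-narrowing, isotropic, spin-uncorrelated local-field model:
#' R = -sum_i b_i sum_{q in x,y,z} [I_iq, [I_iq, . ]], with b_i = 1/(2 T1_i)
#' calibrated so that an isolated spin i relaxes its longitudinal
#' magnetization with the given high-field time constant T1_i. The map is
#' trace preserving and leaves the identity state stationary; at zero field
#' the same operator damps all spin order of spin i at rates set by T1_i.
#'
#' @param system A [spin_system()].
#' @param T1_s Per-spin longitudinal relaxation times in seconds (positive,
#'   finite); recycled if scalar.
#' @param ops Optional precomputed [spin_operators()].
#' @return d^2 x d^2 complex matrix.
#' @export
relaxation_superop <- function(system, T1_s, ops = spin_operators(system)) {
  n <- system$n_spins
  T1_s <- rep_len(T1_s, n)
  if (any(!is.finite(T1_s)) || any(T1_s <= 0))
    stop("T1 values must be finite and positive", call. = FALSE)
  d <- system$dim
  R <- matrix(0 + 0i, d^2, d^2)
  for (i in seq_len(n)) {
    b <- 1 / (2 * T1_s[i])
    for (q in c("x", "y", "z")) {
      C <- hamiltonian_superop(ops[[i]][[q]])
      R <- R - b * (C %*% C)
    }
  }
  R
}

#' Matrix exponential of a complex matrix
#'
#' Scaling-and-squaring with a degree-13 Pade approximant. Needed because the
#' combined exchange + spin-dynamics generator is complex and non-Hermitian.
#'
#' @param A Square complex (or real) matrix.
#' @return exp(A) as a complex matrix.
#' @export
expm_complex <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix", call. = FALSE)
  n <- nrow(A)
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  nrmA <- max(colSums(abs(A)))
  theta13 <- 5.371920351148152
  s <- if (nrmA > theta13) ceiling(log2(nrmA / theta13)) else 0
  if (s > 0) A <- A / 2^s
  Id <- diag(n) + 0i
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
              b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * Id)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
       b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * Id
  Fm <- solve(V - U, V + U)
  for (k in seq_len(s)) Fm <- Fm %*% Fm
  Fm
}
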