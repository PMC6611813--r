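# Spin-1/2 systems: isotopes, J-coupling networks, Hamiltonians, thermal states.
# Internal unit convention: all Hamiltonians are in angular-frequency units
# (rad/s); every user-facing coupling, field-derived frequency and spectral
# axis is in Hz.

.hbar <- 1.054571817e-34   # J s
.kB   <- 1.380649e-23      # J/K

# Gyromagnetic ratios, rad s^-1 T^-1 (signed, CODATA-style values).
.gamma_table <- c(
  "1H"  =  267.52218744e6,
  "13C" =   67.2828e6,
  "15N" =  -27.126e6,
  "19F" =  251.815e6,
  "31P" =  108.291e6
)

#' Supported isotopes
#'
#' The package models spin-1/2 nuclei only. This returns the lookup table of
#' supported isotopes with their signed gyromagnetic ratios.
#'
#' @return A data frame with columns `symbol`, `spin`, and `gamma_rad_s_T`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  data.frame(
    symbol = names(.gamma_table),
    spin = 0.5,
    gamma_rad_s_T = unname(.gamma_table),
    stringsAsFactors = FALSE
  )
}

#' Gyromagnetic ratio of a supported isotope
#'
#' @param symbol Isotope symbol, e.g. `"1H"`, `"13C"`, `"15N"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1 (signed).
#' @export
gyromagnetic_ratio <- function(symbol) {
  if (!all(symbol %in% names(.gamma_table))) {
    bad <- setdiff(symbol, names(.gamma_table))
    stop("unsupported isotope(s): ", paste(bad, collapse = ", "),
         " (only spin-1/2 nuclei ", paste(names(.gamma_table), collapse = ", "),
         " are supported)", call. = FALSE)
  }
  unname(.gamma_table[symbol])
}

#' Define a spin-1/2 system
#'
#' A spin system is an ordered list of spin-1/2 isotopes together with the
#' symmetric matrix of scalar (J) couplings in Hz. The Hilbert-space dimension
#' is 2^n and all operator matrices produced from the system are 2^n x 2^n.
#' Spins are indexed 1..n in declaration order; all tensor products use that
#' order (spin 1 is the leftmost Kronecker factor).
#'
#' @param isotopes Character vector of isotope symbols (see [isotope_table()]).
#' @param J Symmetric n x n numeric matrix of J couplings in Hz with zero
#'   diagonal. A scalar is accepted for a two-spin system.
#' @param label Optional species label.
#' @return An object of class `spin_system`.
#' @export
#' @examples
#' spin_system(c("1H", "13C"), 120, label = "AX")
spin_system <- function(isotopes, J = NULL, label = NULL) {
  stopifnot(is.character(isotopes), length(isotopes) >= 1)
  gamma <- gyromagnetic_ratio(isotopes)
  n <- length(isotopes)
  if (is.null(J)) J <- matrix(0, n, n)
  if (length(J) == 1 && n == 2) J <- matrix(c(0, J, J, 0), 2, 2)
  J <- as.matrix(J)
  if (!all(dim(J) == c(n, n)))
    stop("J must be an ", n, " x ", n, " matrix", call. = FALSE)
  if (max(abs(J - t(J))) > 1e-12 * max(1, max(abs(J))))
    stop("J matrix must be symmetric", call. = FALSE)
  if (any(diag(J) != 0))
    stop("J matrix must have a zero diagonal", call. = FALSE)
  structure(
    list(isotopes = isotopes, gamma = gamma, J_Hz = (J + t(J)) / 2,
         n_spins = n, dim = 2L^n, label = label),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>", if (!is.null(x$label)) paste0("'", x$label, "'") else "",
      "\n  spins:", paste(x$isotopes, collapse = " "),
      "\n  Hilbert dimension:", x$dim, "\n")
  nz <- which(upper.tri(x$J_Hz) & x$J_Hz != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("  couplings (Hz):\n")
    for (k in seq_len(nrow(nz)))
      cat(sprintf("    J(%d,%d) = %g\n", nz[k, 1], nz[k, 2],
                  x$J_Hz[nz[k, 1], nz[k, 2]]))
  }
  invisible(x)
}

.pauli <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i,
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = diag(c(0.5, -0.5)) + 0i
)

#' Cartesian spin operators in the full Hilbert space
#'
#' Builds, for each spin of the system, the three angular-momentum operator
#' matrices I_x, I_y, I_z embedded in the 2^n-dimensional product space by
#' Kronecker products (spin 1 leftmost).
#'
#' @param system A [spin_system()].
#' @return A list of length n; element i is a list with complex matrices
#'   `x`, `y`, `z`.
#' @export
spin_operators <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  n <- system$n_spins
  one <- function(k, s) {
    m <- matrix(1 + 0i, 1, 1)
    for (j in seq_len(n)) {
      m <- kronecker(m, if (j == k) s else diag(2) + 0i)
    }
    m
  }
  lapply(seq_len(n), function(k)
    list(x = one(k, .pauli$x), y = one(k, .pauli$y), z = one(k, .pauli$z)))
}

#' Zero-field J-coupling Hamiltonian
#'
#' H = 2*pi * sum_{i<j} J_ij (I_i . I_j), in rad/s. At zero magnetic field the
#' spectrum of transitions between its eigenstates is the J-spectrum.
#'
#' @param system A [spin_system()].
#' @param ops Optional precomputed [spin_operators()] (performance).
#' @return Hermitian complex matrix (rad/s).
#' @export
zero_field_hamiltonian <- function(system, ops = spin_operators(system)) {
  d <- system$dim
  H <- matrix(0 + 0i, d, d)
  n <- system$n_spins
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    Jij <- system$J_Hz[i, j]
    if (Jij != 0) {
      H <- H + 2 * pi * Jij *
        (ops[[i]]$x %*% ops[[j]]$x + ops[[i]]$y %*% ops[[j]]$y +
         ops[[i]]$z %*% ops[[j]]$z)
    }
  }
  H
}

#' High-field secular Hamiltonian (doubly rotating frame)
#'
#' Heteronuclear couplings are truncated to their secular part
#' 2*pi*J_ij I_iz I_jz; couplings between spins of the same isotope (zero
#' chemical-shift difference in this model) keep the full scalar form. All
#' chemical-shift offsets are zero, so the frame is on resonance for every
#' isotope.
#'
#' @inheritParams zero_field_hamiltonian
#' @return Hermitian complex matrix (rad/s).
#' @export
highfield_hamiltonian <- function(system, ops = spin_operators(system)) {
  d <- system$dim
  H <- matrix(0 + 0i, d, d)
  n <- system$n_spins
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    Jij <- system$J_Hz[i, j]
    if (Jij == 0) next
    if (system$isotopes[i] == system$isotopes[j]) {
      H <- H + 2 * pi * Jij *
        (ops[[i]]$x %*% ops[[j]]$x + ops[[i]]$y %*% ops[[j]]$y +
         ops[[i]]$z %*% ops[[j]]$z)
    } else {
      H <- H + 2 * pi * Jij * (ops[[i]]$z %*% ops[[j]]$z)
    }
  }
  H
}

#' Zeeman Hamiltonian for an applied magnetic field
#'
#' H = -sum_i gamma_i (B_x I_ix + B_y I_iy + B_z I_iz), in rad/s. Used for the
#' guiding field during shuttling and for residual fields at detection.
#'
#' @inheritParams zero_field_hamiltonian
#' @param B_T Magnetic field in tesla: a scalar (taken along z) or a length-3
#'   vector (x, y, z).
#' @return Hermitian complex matrix (rad/s).
#' @export
zeeman_hamiltonian <- function(system, B_T, ops = spin_operators(system)) {
  if (length(B_T) == 1) B_T <- c(0, 0, B_T)
  stopifnot(length(B_T) == 3)
  d <- system$dim
  H <- matrix(0 + 0i, d, d)
  for (i in seq_len(system$n_spins)) {
    g <- system$gamma[i]
    if (B_T[1] != 0) H <- H - g * B_T[1] * ops[[i]]$x
    if (B_T[2] != 0) H <- H - g * B_T[2] * ops[[i]]$y
    if (B_T[3] != 0) H <- H - g * B_T[3] * ops[[i]]$z
  }
  H
}

#' Thermal-equilibrium density matrix (high-temperature approximation)
#'
#' rho = (1 + sum_i gamma_i*hbar*B/(kB*T) * I_iz) / 2^n. The deviation from
#' the maximally mixed state is linear in the field, which is what makes the
#' detected signal linear in the polarizing field.
#'
#' @inheritParams zero_field_hamiltonian
#' @param B_T Polarizing field along z, tesla (>= 0).
#' @param temperature_K Temperature in kelvin (> 0).
#' @return Hermitian, unit-trace complex matrix.
#' @export
thermal_state <- function(system, B_T, temperature_K,
                          ops = spin_operators(system)) {
  if (temperature_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (B_T < 0) stop("polarizing field must be non-negative", call. = FALSE)
  d <- system$dim
  rho <- diag(d) + 0i
  for (i in seq_len(system$n_spins)) {
    eps <- system$gamma[i] * .hbar * B_T / (.kB * temperature_K)
    rho <- rho + eps * ops[[i]]$z
  }
  rho / d
}

# Traceless deviation part of the high-temperature thermal state, computed
# directly (no cancellation against the identity; exactly linear in B).
.thermal_deviation <- function(system, B_T, temperature_K,
                               ops = spin_operators(system)) {
  d <- system$dim
  rho <- matrix(0 + 0i, d, d)
  for (i in seq_len(system$n_spins)) {
    eps <- system$gamma[i] * .hbar * B_T / (.kB * temperature_K)
    rho <- rho + eps * ops[[i]]$z
  }
  rho / d
}
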