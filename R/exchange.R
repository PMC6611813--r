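# Chemical kinetics, acid-base speciation and assembly of the combined
# exchange + spin-dynamics generator M (a Bloch-McConnell-type block matrix
# acting on the concatenated vectorized density matrices of the residual
# species A and the full species C).

#' Acid-base speciation
#'
#' Mole fractions of the associated (acidic, C) and dissociated (conjugate
#' base, A) forms: x_C = 10^-pH / (10^-pH + K_a), x_A = 1 - x_C.
#'
#' @param pH Solution pH.
#' @param pKa Acid dissociation constant as pK_a = -log10(K_a).
#' @return Named numeric vector with elements `x_A` and `x_C`, both in [0, 1].
#' @export
#' @examples
#' speciation(pH = 9.25, pKa = 9.25)  # x_C = 0.5 at pH = pKa
speciation <- function(pH, pKa) {
  Ka <- 10^(-pKa)
  h <- 10^(-pH)
  xC <- h / (h + Ka)
  c(x_A = 1 - xC, x_C = xC)
}

#' Pseudo-first-order association rate
#'
#' W_a = k_a [B] derived from the dissociation rate constant and the
#' equilibrium condition K_a = k_d / k_a with [B] = 10^-pH:
#' W_a = k_d * 10^(pKa - pH). Satisfies detailed balance
#' x_C * k_d = x_A * W_a with [speciation()].
#'
#' @param k_d Dissociation rate constant, s^-1 (>= 0).
#' @param pH Solution pH.
#' @param pKa pK_a of the associated form.
#' @return Association rate W_a in s^-1.
#' @export
association_rate <- function(k_d, pH, pKa) {
  if (any(k_d < 0)) stop("k_d must be non-negative", call. = FALSE)
  k_d * 10^(pKa - pH)
}

#' Two-species concentration kinetics
#'
#' Analytic solution of the linear kinetics
#' d/dt (\[A], \[C]) = ((-W_a, +k_d), (+W_a, -k_d)) (\[A], \[C]).
#' The total concentration is conserved and the approach to equilibrium is a
#' single exponential with rate k_d + W_a; the equilibrium ratio is
#' \[C]/\[A] = W_a/k_d.
#'
#' @param k_d Dissociation rate, s^-1.
#' @param W_a Association rate, s^-1.
#' @param A0,C0 Initial concentrations (non-negative).
#' @param t Numeric vector of times, s.
#' @return Data frame with columns `t_s`, `A`, `C`.
#' @export
concentration_kinetics <- function(k_d, W_a, A0, C0, t) {
  stopifnot(k_d >= 0, W_a >= 0, A0 >= 0, C0 >= 0)
  tot <- A0 + C0
  r <- k_d + W_a
  if (r == 0) {
    A <- rep(A0, length(t))
  } else {
    Aeq <- tot * k_d / r
    A <- Aeq + (A0 - Aeq) * exp(-r * t)
  }
  data.frame(t_s = t, A = A, C = tot - A)
}

#' Exchange pair: species C, residual species A and exchanged subsystem B
#'
#' Describes the reversible process A + B <-> C at the spin level: C is the
#' full spin system, B the set of exchanged spins (attached/removed in a fixed
#' bath state, unpolarized by default), and A what remains. The constructor
#' precomputes the partial-trace superoperator T (dissociation) and the
#' attachment superoperator D (association).
#'
#' @param system_C Full species as a [spin_system()].
#' @param traced Indices of the exchanged spins (subsystem B) within C.
#' @param rho_B Fixed bath state for B; default maximally mixed. The bath
#'   state is never tracked dynamically.
#' @param mechanism Mechanism tag, `"generic"` here; see [ammonium_pair()] for
#'   the site-averaged variants.
#' @return An object of class `exchange_pair` with elements `system_C`,
#'   `system_A`, `system_B`, `traced`, `T` and `D`.
#' @export
#' @examples
#' ax <- spin_system(c("1H", "13C"), 120)
#' pr <- exchange_pair(ax, traced = 2)   # AX <-> A + X
#' dim(pr$T)
exchange_pair <- function(system_C, traced, rho_B = NULL,
                          mechanism = "generic") {
  stopifnot(inherits(system_C, "spin_system"))
  traced <- sort(as.integer(traced))
  keep <- setdiff(seq_len(system_C$n_spins), traced)
  system_A <- spin_system(system_C$isotopes[keep],
                          system_C$J_Hz[keep, keep, drop = FALSE],
                          label = paste0(system_C$label %||% "C", "-residual"))
  system_B <- spin_system(system_C$isotopes[traced],
                          system_C$J_Hz[traced, traced, drop = FALSE],
                          label = "exchanged")
  Tm <- partial_trace_superop(system_C, traced)
  D <- attach_superop(system_A, system_B, positions = traced, rho_B = rho_B)
  structure(
    list(system_C = system_C, system_A = system_A, system_B = system_B,
         traced = traced, T = Tm, D = D, mechanism = mechanism),
    class = "exchange_pair"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ammonium exchange pair (site-averaged mechanisms)
#'
#' Builds the 15NH4+ (A4X) exchange pair for one of the two dissociation
#' mechanisms:
#' \describe{
#'   \item{`"single"`}{one (random) proton exchanges at a time. A is 15NH3;
#'     T and D are the uniform averages of the four per-site trace-and-attach
#'     superoperators. This is the ensemble version of random-site exchange in
#'     a deterministic master equation.}
#'   \item{`"all"`}{all four protons dissociate simultaneously; A is the bare
#'     15N nucleus.}
#' }
#' Both conserve the total trace. In the fast-exchange regime the two
#' mechanisms give the same coalesced linewidth when the `"all"` rate is four
#' times smaller than the `"single"` rate.
#'
#' @param mechanism `"single"` or `"all"`.
#' @param J_NH N-H scalar coupling in Hz (default 73.4).
#' @param rho_B Bath state per exchanged proton set; default unpolarized.
#' @return An `exchange_pair` (see [exchange_pair()]).
#' @export
ammonium_pair <- function(mechanism = c("single", "all"), J_NH = 73.4,
                          rho_B = NULL) {
  mechanism <- match.arg(mechanism)
  n <- 5L
  J <- matrix(0, n, n)
  J[1:4, 5] <- J_NH
  J[5, 1:4] <- J_NH
  sysC <- spin_system(c("1H", "1H", "1H", "1H", "15N"), J, label = "15NH4+")
  if (mechanism == "all") {
    pr <- exchange_pair(sysC, traced = 1:4, rho_B = rho_B, mechanism = "all")
    pr$system_A$label <- "15N"
    return(pr)
  }
  # single random site: average the four per-site superoperators; removing
  # any one proton leaves the same 15NH3 spin system by symmetry
  keep <- 2:5
  sysA <- spin_system(sysC$isotopes[keep], sysC$J_Hz[keep, keep],
                      label = "15NH3")
  proton <- spin_system("1H")
  Tm <- matrix(0 + 0i, sysA$dim^2, sysC$dim^2)
  D <- matrix(0 + 0i, sysC$dim^2, sysA$dim^2)
  for (j in 1:4) {
    Tm <- Tm + partial_trace_superop(sysC, j) / 4
    D <- D + attach_superop(sysA, proton, positions = j, rho_B = rho_B) / 4
  }
  structure(
    list(system_C = sysC, system_A = sysA, system_B = proton,
         traced = NA_integer_, T = Tm, D = D, mechanism = "single"),
    class = "exchange_pair"
  )
}

#' Assemble the combined exchange + spin-dynamics generator
#'
#' M = \[\[L_A - W_a 1, +k_d T], \[+W_a D, L_C - k_d 1]] acting on the
#' concatenation (vec rho_A, vec rho_C). The total trace
#' Tr rho_A + Tr rho_C is conserved exactly, and the unpolarized state with
#' equilibrium mole fractions is a fixed point of the exchange part.
#'
#' @param pair An [exchange_pair()].
#' @param k_d Dissociation rate, s^-1.
#' @param W_a Association rate, s^-1.
#' @param L_A,L_C Liouvillians of the two species on their own Liouville
#'   spaces (see [liouvillian()]); defaults are the bare zero-field coherent
#'   Liouvillians.
#' @return A list of class `exchange_generator`: `M`, block sizes `n_A`,
#'   `n_C`, and the rates.
#' @export
build_generator <- function(pair, k_d, W_a,
                            L_A = liouvillian(zero_field_hamiltonian(pair$system_A)),
                            L_C = liouvillian(zero_field_hamiltonian(pair$system_C))) {
  stopifnot(inherits(pair, "exchange_pair"), k_d >= 0, W_a >= 0)
  nA <- pair$system_A$dim^2
  nC <- pair$system_C$dim^2
  if (!all(dim(L_A) == nA) || !all(dim(L_C) == nC))
    stop("L_A / L_C dimensions do not match the pair", call. = FALSE)
  if (!all(dim(pair$T) == c(nA, nC)) || !all(dim(pair$D) == c(nC, nA)))
    stop("pair T/D dimensions are inconsistent", call. = FALSE)
  M <- rbind(
    cbind(L_A - W_a * diag(nA), k_d * pair$T),
    cbind(W_a * pair$D, L_C - k_d * diag(nC))
  )
  structure(list(M = M, n_A = nA, n_C = nC, k_d = k_d, W_a = W_a),
            class = "exchange_generator")
}

#' Exchange model: a pair (or bare system) with rates and relaxation
#'
#' Binds an [exchange_pair()] to its kinetic parameters. The association rate
#' can be given explicitly (`W_a`) or derived from `pH` and `pKa` via
#' [association_rate()]. Equilibrium mole fractions follow from the rates:
#' x_C = W_a / (W_a + k_d) (all-associated when exchange is off). A bare
#' [spin_system()] may be supplied instead of a pair for exchange-free
#' simulations.
#'
#' @param x An [exchange_pair()] or a [spin_system()].
#' @param k_d Dissociation rate constant, s^-1.
#' @param W_a Explicit association rate, s^-1 (overrides pH/pKa).
#' @param pH,pKa Acid-base parameters used to derive W_a when it is not given.
#' @param T1_C,T1_A Optional per-spin T1 values (s) for the fluctuating-field
#'   relaxation superoperators of each species.
#' @return Object of class `exchange_model`.
#' @export
exchange_model <- function(x, k_d = 0, W_a = NULL, pH = NULL, pKa = NULL,
                           T1_C = NULL, T1_A = NULL) {
  if (inherits(x, "spin_system")) {
    if (k_d != 0 || !is.null(W_a))
      stop("exchange rates require an exchange_pair, not a bare spin_system",
           call. = FALSE)
    return(structure(
      list(pair = NULL, system_C = x, k_d = 0, W_a = 0,
           x_A = 0, x_C = 1, T1_C = T1_C, T1_A = NULL, pH = pH, pKa = pKa),
      class = "exchange_model"))
  }
  stopifnot(inherits(x, "exchange_pair"))
  if (is.null(W_a)) {
    W_a <- if (!is.null(pH) && !is.null(pKa))
      association_rate(k_d, pH, pKa) else 0
  }
  if (k_d < 0 || W_a < 0) stop("rates must be non-negative", call. = FALSE)
  xC <- if (k_d + W_a > 0) W_a / (W_a + k_d) else 1
  structure(
    list(pair = x, system_C = x$system_C, k_d = k_d, W_a = W_a,
         x_A = 1 - xC, x_C = xC, T1_C = T1_C, T1_A = T1_A,
         pH = pH, pKa = pKa),
    class = "exchange_model"
  )
}
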