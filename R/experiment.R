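# Measurement protocols: propagation by matrix exponentiation, the ZULF
# prepolarize/shuttle/sudden-drop/detect sequence, and high-field
# pulse-acquire with exchange.

.condition_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' ZULF measurement protocol
#'
#' Defaults mirror a typical prepolarized shuttling experiment: polarization
#' at 2 T, 0.5 s pneumatic shuttling under a 30 uT guiding field, sudden
#' (non-adiabatic) field drop, then detection of total z-magnetization with a
#' 1 kHz sampling rate for 16 s. The density matrix is taken continuous
#' across the sudden drop (no evolution during the ~50 us switch).
#'
#' @param B_polarize_T Prepolarizing field, tesla.
#' @param temperature_K Polarizing temperature, kelvin.
#' @param t_shuttle_s Shuttle time between polarizer and zero-field region, s.
#' @param B_guide_T Guiding field (applied along z) during shuttling, tesla.
#' @param B_residual_T Residual field vector (x, y, z) at detection, tesla.
#' @param dwell_s Dwell time, s.
#' @param n_points Number of acquired points (>= 2).
#' @param detection_axis Magnetometer sensitive axis: "x", "y" or "z".
#' @return Object of class `nmr_protocol`.
#' @export
zulf_protocol <- function(B_polarize_T = 2, temperature_K = 298,
                          t_shuttle_s = 0.5, B_guide_T = 30e-6,
                          B_residual_T = c(0, 0, 0), dwell_s = 1e-3,
                          n_points = 16000, detection_axis = "z") {
  stopifnot(dwell_s > 0, n_points >= 2, t_shuttle_s >= 0, B_polarize_T >= 0,
            detection_axis %in% c("x", "y", "z"))
  if (length(B_residual_T) == 1) B_residual_T <- c(0, 0, B_residual_T)
  structure(
    list(type = "zulf", B_polarize_T = B_polarize_T,
         temperature_K = temperature_K, t_shuttle_s = t_shuttle_s,
         B_guide_T = B_guide_T, B_residual_T = B_residual_T,
         dwell_s = dwell_s, n_points = as.integer(n_points),
         detection_axis = detection_axis),
    class = "nmr_protocol"
  )
}

#' High-field pulse-acquire protocol
#'
#' Ideal instantaneous 90-degree pulse on the observed isotope, then
#' acquisition of the complex FID in the doubly rotating frame (all offsets
#' zero).
#'
#' @param dwell_s Dwell time, s.
#' @param n_points Number of complex points (>= 2).
#' @param observe Observed isotope symbol (e.g. "15N").
#' @param offset_Hz Transmitter offset of the observed isotope in the
#'   rotating frame, Hz. A nonzero offset shifts the whole multiplet away
#'   from zero frequency, which keeps a symmetric multiplet's center line
#'   off the spectrum edge.
#' @return Object of class `nmr_protocol`.
#' @export
highfield_protocol <- function(dwell_s = 2e-3, n_points = 4000,
                               observe = "15N", offset_Hz = 0) {
  stopifnot(dwell_s > 0, n_points >= 2)
  structure(
    list(type = "highfield", dwell_s = dwell_s,
         n_points = as.integer(n_points), observe = observe,
         offset_Hz = offset_Hz),
    class = "nmr_protocol"
  )
}

#' Propagate a vectorized state under a time-independent generator
#'
#' Solves d rho/dt = M rho by exponentiation, rho(t) = exp(M t) rho(0). On a
#' uniform time grid the single-step propagator U = exp(M dt) is computed
#' once and applied iteratively; a non-uniform grid falls back to
#' per-interval exponentials (slower) with a warning. When `observable` is
#' given, the eigendecomposition route (one decomposition, then a scalar
#' recurrence per eigenmode) can be used; it is selected automatically for
#' large generators and falls back to the propagator route if the
#' eigenvector basis is ill-conditioned.
#'
#' @param M Square generator matrix (s^-1 units throughout).
#' @param state0 Initial vectorized state (length = nrow(M)).
#' @param times Numeric vector of times (s), starting at 0.
#' @param observable Optional linear functional w (complex vector, same
#'   length as the state): the recorded signal is s(t) = sum(w * rho(t)).
#'   For an operator A use `as.vector(t(A))`, which gives Tr(A rho).
#' @param method `"auto"`, `"expm"` or `"eigen"`.
#' @return A list of class `nmr_trajectory` with `time_s` and either
#'   `signal` (if `observable` was given) or `states` (columns = time points).
#' @export
propagate <- function(M, state0, times, observable = NULL,
                      method = c("auto", "expm", "eigen")) {
  method <- match.arg(method)
  n <- nrow(M)
  stopifnot(length(state0) == n, length(times) >= 1)
  state0 <- as.vector(state0) + 0i
  dts <- diff(times)
  uniform <- length(dts) == 0 ||
    max(abs(dts - dts[1])) <= 1e-9 * max(abs(dts[1]), 1e-300)
  if (!uniform) {
    warning("non-uniform time grid: using per-interval matrix exponentials")
    states <- matrix(0 + 0i, n, length(times))
    rho <- if (times[1] == 0) state0 else
      expm_complex(M * times[1]) %*% state0
    states[, 1] <- rho
    for (k in seq_along(dts)) {
      rho <- expm_complex(M * dts[k]) %*% rho
      states[, k + 1] <- rho
    }
    return(.finish_traj(times, states, observable))
  }
  if (is.null(observable) && method == "eigen")
    stop("the eigendecomposition route records a signal; supply `observable`",
         call. = FALSE)
  if (method == "auto")
    method <- if (!is.null(observable) && n >= 400) "eigen" else "expm"
  if (method == "eigen") {
    eg <- eigen(M)
    w0 <- tryCatch(solve(eg$vectors, state0), error = function(e) NULL)
    ok <- !is.null(w0) &&
      max(abs(eg$vectors %*% w0 - state0)) <=
        1e-8 * max(abs(state0), 1e-300)
    if (ok) {
      cj <- as.vector(crossprod(observable, eg$vectors)) * w0
      dt <- if (length(dts)) dts[1] else 0
      step <- exp(eg$values * dt)
      e <- exp(eg$values * times[1])
      sig <- complex(length(times))
      for (k in seq_along(times)) {
        sig[k] <- sum(cj * e)
        e <- e * step
      }
      return(.finish_traj(times, NULL, observable, signal = sig))
    }
    method <- "expm"  # ill-conditioned eigenbasis: fall back
  }
  dt <- if (length(dts)) dts[1] else 0
  U <- if (dt > 0) expm_complex(M * dt) else diag(n) + 0i
  rho <- if (times[1] == 0) state0 else
    as.vector(expm_complex(M * times[1]) %*% state0)
  if (is.null(observable)) {
    states <- matrix(0 + 0i, n, length(times))
    states[, 1] <- rho
    for (k in seq_along(dts)) {
      rho <- as.vector(U %*% rho)
      states[, k + 1] <- rho
    }
    .finish_traj(times, states, observable)
  } else {
    sig <- complex(length(times))
    sig[1] <- sum(observable * rho)
    for (k in seq_along(dts)) {
      rho <- as.vector(U %*% rho)
      sig[k + 1] <- sum(observable * rho)
    }
    .finish_traj(times, NULL, observable, signal = sig)
  }
}

.finish_traj <- function(times, states, observable, signal = NULL) {
  if (is.null(signal) && !is.null(observable) && !is.null(states))
    signal <- as.vector(crossprod(observable, states))
  out <- list(time_s = times,
              dwell_s = if (length(times) > 1) times[2] - times[1] else NA_real_,
              signal = signal, states = states)
  class(out) <- "nmr_trajectory"
  out
}

# Per-species building blocks shared by the experiment pipelines.
.species_blocks <- function(model) {
  sysC <- model$system_C
  opsC <- spin_operators(sysC)
  out <- list(C = list(system = sysC, ops = opsC, T1 = model$T1_C))
  two_block <- !is.null(model$pair) &&
    (model$k_d > 0 || model$W_a > 0 || model$x_A > 0)
  if (two_block) {
    sysA <- model$pair$system_A
    out$A <- list(system = sysA, ops = spin_operators(sysA), T1 = model$T1_A)
  }
  out
}

.detection_vec <- function(sp, axis, weights = "gamma") {
  F <- matrix(0 + 0i, sp$system$dim, sp$system$dim)
  gH <- gyromagnetic_ratio("1H")
  for (i in seq_len(sp$system$n_spins)) {
    wgt <- if (identical(weights, "gamma")) sp$system$gamma[i] / gH else 1
    F <- F + wgt * sp$ops[[i]][[axis]]
  }
  F
}

.nyquist_check <- function(H, dwell_s) {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  fmax <- (max(ev) - min(ev)) / (2 * pi)
  fny <- 1 / (2 * dwell_s)
  if (fmax > fny)
    .condition_error(
      sprintf(paste0("Nyquist violation: a transition can reach %.2f Hz but ",
                     "the sampling rate only covers %.2f Hz"), fmax, fny),
      "zulfspin_physics_error")
  invisible(fmax)
}

.stage_generator <- function(model, blocks, hamiltonian_fun) {
  Ls <- lapply(blocks, function(sp) {
    H <- hamiltonian_fun(sp)
    R <- if (!is.null(sp$T1)) relaxation_superop(sp$system, sp$T1, sp$ops)
    liouvillian(H, R)
  })
  if (length(blocks) == 1) {
    list(M = Ls$C, split = c(A = 0L, C = ncol(Ls$C)))
  } else {
    gen <- build_generator(model$pair, model$k_d, model$W_a,
                           L_A = Ls$A, L_C = Ls$C)
    list(M = gen$M, split = c(A = gen$n_A, C = gen$n_C))
  }
}

# Concatenate per-species vectors in block order (A first when present).
# `f` receives the species block and its name ("A" or "C").
.concat_blocks <- function(blocks, f) {
  nms <- intersect(c("A", "C"), names(blocks))
  parts <- lapply(nms, function(nm) f(blocks[[nm]], nm))
  do.call(c, parts)
}

#' ZULF NMR experiment: prepolarize, shuttle, sudden drop, detect
#'
#' Simulates the full measurement pipeline: (i) high-temperature thermal
#' states of both species at the polarizing field, weighted by the
#' equilibrium mole fractions; (ii) evolution for the shuttle time under the
#' guiding field with exchange and relaxation active; (iii) instantaneous
#' field drop to the residual field (state continuous); (iv) detection of the
#' magnetometer observable sum_i (gamma_i/gamma_H) I_i-axis, sampled at the
#' protocol dwell time. Amplitudes are in arbitrary units.
#'
#' @param model An [exchange_model()].
#' @param protocol A [zulf_protocol()].
#' @param x_init Optional named vector `c(A =, C =)` overriding the
#'   equilibrium initial mole fractions (e.g. a pure-C relaxation
#'   experiment).
#' @param propagator Passed to [propagate()] (`"auto"` recommended).
#' @return An `nmr_trajectory` with a real `signal`.
#' @export
zulf_experiment <- function(model, protocol = zulf_protocol(), x_init = NULL,
                            propagator = c("auto", "eigen", "expm")) {
  propagator <- match.arg(propagator)
  stopifnot(inherits(model, "exchange_model"),
            inherits(protocol, "nmr_protocol"))
  if (protocol$type != "zulf")
    stop("protocol is not a ZULF protocol", call. = FALSE)
  if (!is.null(x_init)) {
    model$x_A <- unname(x_init[["A"]])
    model$x_C <- unname(x_init[["C"]])
  }
  blocks <- .species_blocks(model)

  # detection-stage Hamiltonians and Nyquist validation
  det_H <- lapply(blocks, function(sp)
    zero_field_hamiltonian(sp$system, sp$ops) +
      zeeman_hamiltonian(sp$system, protocol$B_residual_T, sp$ops))
  for (H in det_H) .nyquist_check(H, protocol$dwell_s)

  # initial thermal states, mole-fraction weighted. Only the traceless
  # deviation is propagated: the uniform (identity) component of each block
  # stays in the identity sector under every generator used here and has
  # zero overlap with the detection operator, so dropping it is exact and
  # keeps the detected signal free of cancellation noise.
  xfrac <- c(A = model$x_A, C = model$x_C)
  rho0 <- .concat_blocks(blocks, function(sp, nm) {
    as.vector(xfrac[[nm]] *
      .thermal_deviation(sp$system, protocol$B_polarize_T,
                         protocol$temperature_K, sp$ops))
  })

  # shuttle under the guiding field
  if (protocol$t_shuttle_s > 0) {
    sh <- .stage_generator(model, blocks, function(sp)
      zero_field_hamiltonian(sp$system, sp$ops) +
        zeeman_hamiltonian(sp$system, c(0, 0, protocol$B_guide_T), sp$ops))
    rho0 <- as.vector(expm_complex(sh$M * protocol$t_shuttle_s) %*% rho0)
  }

  # sudden drop, then detection
  st <- .stage_generator(model, blocks, function(sp)
    zero_field_hamiltonian(sp$system, sp$ops) +
      zeeman_hamiltonian(sp$system, protocol$B_residual_T, sp$ops))
  w <- .concat_blocks(blocks, function(sp, nm)
    .trace_functional(.detection_vec(sp, protocol$detection_axis)))
  times <- protocol$dwell_s * (seq_len(protocol$n_points) - 1)
  traj <- propagate(st$M, rho0, times, observable = w, method = propagator)
  traj$signal <- Re(traj$signal)
  traj$protocol <- protocol
  traj$model <- model[c("k_d", "W_a", "x_A", "x_C")]
  traj
}

#' High-field pulse-acquire experiment with exchange
#'
#' Initial state: equilibrium mole fractions with unit transverse
#' magnetization on the observed isotope in each species
#' (post-90-degree-pulse convention). Evolution under the secular high-field
#' Hamiltonians plus exchange and relaxation; the recorded FID is
#' s(t) = Tr(sum_i I_i+ rho(t)) over the observed spins (complex).
#'
#' @param model An [exchange_model()].
#' @param protocol A [highfield_protocol()].
#' @param propagator Passed to [propagate()].
#' @return An `nmr_trajectory` with a complex `signal` (FID).
#' @export
highfield_experiment <- function(model, protocol = highfield_protocol(),
                                 propagator = c("auto", "eigen", "expm")) {
  propagator <- match.arg(propagator)
  stopifnot(inherits(model, "exchange_model"),
            inherits(protocol, "nmr_protocol"))
  if (protocol$type != "highfield")
    stop("protocol is not a high-field protocol", call. = FALSE)
  if (!protocol$observe %in% model$system_C$isotopes)
    stop("observed isotope ", protocol$observe, " is absent from species C",
         call. = FALSE)
  blocks <- .species_blocks(model)
  stage_H <- function(sp) {
    H <- highfield_hamiltonian(sp$system, sp$ops)
    off <- protocol$offset_Hz %||% 0
    if (off != 0) {
      for (i in which(sp$system$isotopes == protocol$observe))
        H <- H + 2 * pi * off * sp$ops[[i]]$z
    }
    H
  }
  for (sp in blocks) .nyquist_check(stage_H(sp), protocol$dwell_s)

  # post-pulse deviation only (the identity component carries no signal)
  xfrac <- c(A = model$x_A, C = model$x_C)
  mk_rho0 <- function(sp, x) {
    d <- sp$system$dim
    rho <- matrix(0 + 0i, d, d)
    for (i in which(sp$system$isotopes == protocol$observe))
      rho <- rho + sp$ops[[i]]$x
    as.vector(x * rho)
  }
  mk_obs <- function(sp) {
    Fp <- matrix(0 + 0i, sp$system$dim, sp$system$dim)
    for (i in which(sp$system$isotopes == protocol$observe))
      Fp <- Fp + sp$ops[[i]]$x + 1i * sp$ops[[i]]$y
    .trace_functional(Fp)
  }
  rho0 <- .concat_blocks(blocks, function(sp, nm) mk_rho0(sp, xfrac[[nm]]))
  w <- .concat_blocks(blocks, function(sp, nm) mk_obs(sp))
  st <- .stage_generator(model, blocks, stage_H)
  times <- protocol$dwell_s * (seq_len(protocol$n_points) - 1)
  traj <- propagate(st$M, rho0, times, observable = w, method = propagator)
  traj$protocol <- protocol
  traj$model <- model[c("k_d", "W_a", "x_A", "x_C")]
  traj
}
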