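test_that("propagation by exponentiation matches an RK4 oracle", {
  set.seed(31)
  n <- 8
  M <- matrix(rnorm(n * n), n, n) + 1i * matrix(rnorm(n * n), n, n)
  M <- M - diag(n) * 3          # keep modes non-exploding
  v0 <- rnorm(n) + 1i * rnorm(n)
  times <- seq(0, 1, length.out = 101)
  tr <- propagate(M, v0, times)
  oracle <- rk4_propagate(M, v0, 1, 4000)
  expect_lt(max(abs(tr$states[, 101] - oracle)), 1e-8)
  # zero generator: constant state
  tr0 <- propagate(matrix(0, 2, 2), c(1, 2i), c(0, 0.5, 1))
  expect_equal(tr0$states[, 3], c(1 + 0i, 2i))
})

test_that("eigendecomposition and propagator routes agree", {
  pair <- zulf_fixture("AX")$pair
  gen <- build_generator(pair, k_d = 5, W_a = 5)
  set.seed(32)
  state <- c(vec_dm(random_density(2)) * 0.5, vec_dm(random_density(4)) * 0.5)
  w <- rnorm(20) + 1i * rnorm(20)
  times <- seq(0, 2, by = 1e-3)
  s1 <- propagate(gen$M, state, times, observable = w, method = "expm")$signal
  s2 <- propagate(gen$M, state, times, observable = w, method = "eigen")$signal
  expect_lt(max(abs(s1 - s2)), 1e-8 * max(abs(s1)))
})

test_that("non-uniform grids fall back to per-interval exponentials", {
  set.seed(33)
  M <- matrix(rnorm(9), 3, 3) + 0i
  v0 <- c(1, 0, 0) + 0i
  expect_warning(tr <- propagate(M, v0, c(0, 0.1, 0.4)), "non-uniform")
  expect_lt(max(abs(tr$states[, 3] - expm_complex(0.4 * M) %*% v0)), 1e-10)
})

test_that("AX zero-field coherence oscillates at exactly J", {
  fx <- zulf_fixture("AX")
  m <- exchange_model(fx$system)
  pr <- zulf_protocol(t_shuttle_s = 0, dwell_s = 1e-3, n_points = 8000)
  tr <- zulf_experiment(m, pr)
  pk <- find_peaks(fft_spectrum(tr, apodization_s = 0.5))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position_Hz, 120, tolerance = 1e-3)
  # periodicity: s(t + 1/J) = s(t) for the exchange-free pair
  i0 <- 1 + 600                      # t = 0.6 s
  i1 <- i0 + round(1000 / 120 * 12)  # + 12 periods (on the sample grid)
  expect_equal(tr$signal[i0], tr$signal[i1], tolerance = 1e-6)
})

test_that("signal is linear in the polarizing field and zero without it", {
  fx <- zulf_fixture("pyruvate")
  m <- exchange_model(fx$system)
  pr2 <- zulf_protocol(B_polarize_T = 2, dwell_s = 1e-3, n_points = 512)
  pr4 <- zulf_protocol(B_polarize_T = 4, dwell_s = 1e-3, n_points = 512)
  pr0 <- zulf_protocol(B_polarize_T = 0, dwell_s = 1e-3, n_points = 512)
  s2 <- zulf_experiment(m, pr2)$signal
  s4 <- zulf_experiment(m, pr4)$signal
  s0 <- zulf_experiment(m, pr0)$signal
  expect_lt(max(abs(s4 - 2 * s2)), 1e-10 * max(abs(s2)))
  expect_lt(max(abs(s0)), 1e-18)
})

test_that("exchange-free peaks appear only at allowed transition frequencies", {
  fx <- zulf_fixture("AXB")
  m <- exchange_model(fx$system)
  tr <- zulf_experiment(m, zulf_protocol(dwell_s = 1e-3, n_points = 8000))
  pk <- find_peaks(fft_spectrum(tr, apodization_s = 0.3),
                   min_rel_amplitude = 0.02)
  sys <- fx$system
  ops <- spin_operators(sys)
  gH <- gyromagnetic_ratio("1H")
  F <- Reduce(`+`, lapply(seq_len(3), function(i)
    sys$gamma[i] / gH * ops[[i]]$z))
  allowed <- allowed_transitions_hz(zero_field_hamiltonian(sys, ops), F)
  for (p in pk$position_Hz) {
    expect_lt(min(abs(allowed - p)), 0.05)
  }
})

test_that("Nyquist violations raise a physics error naming the frequency", {
  fx <- zulf_fixture("pyruvate")
  m <- exchange_model(fx$system)
  err <- tryCatch(
    zulf_experiment(m, zulf_protocol(dwell_s = 0.1, n_points = 64)),
    condition = function(e) e)
  expect_s3_class(err, "zulfspin_physics_error")
  expect_match(conditionMessage(err), "Hz")
})

test_that("residual z-field splits the 2J line of A3X but not the J line", {
  fx <- zulf_fixture("pyruvate")
  m <- exchange_model(fx$system)
  pr <- zulf_protocol(dwell_s = 1e-3, n_points = 16000,
                      B_residual_T = c(0, 0, 30e-9))
  pk <- find_peaks(fft_spectrum(zulf_experiment(m, pr)),
                   min_rel_amplitude = 0.02)
  nJ <- sum(pk$position_Hz > 5 & pk$position_Hz < 7.5)
  n2J <- sum(pk$position_Hz > 11 & pk$position_Hz < 14)
  expect_equal(nJ, 1)
  expect_gte(n2J, 2)
  # without the field both lines are single
  pk0 <- find_peaks(fft_spectrum(zulf_experiment(m, zulf_protocol(
    dwell_s = 1e-3, n_points = 16000))), min_rel_amplitude = 0.02)
  expect_equal(nrow(pk0), 2)
})

test_that("AXB spectral weight varies continuously across the rate sweep", {
  fx <- zulf_fixture("AXB")
  pr <- zulf_protocol(dwell_s = 1e-3, n_points = 4000)
  integ <- vapply(c(10, 30, 90, 270, 810), function(k) {
    m <- exchange_model(fx$pair, k_d = k, W_a = k)
    sp <- fft_spectrum(zulf_experiment(m, pr), apodization_s = 1)
    sel <- sp$freq_Hz > 2
    sum(Mod(sp$amplitude[sel])) * (sp$freq_Hz[2] - sp$freq_Hz[1])
  }, 0)
  expect_true(all(integ > 0))
  steps <- abs(diff(log(integ)))
  expect_lt(max(steps), log(3))   # no discontinuous jump along the sweep
})

test_that("high-field FID is monochromatic for an uncoupled observed spin", {
  m <- exchange_model(spin_system(c("13C", "1H")))  # no coupling
  pr <- highfield_protocol(dwell_s = 1e-3, n_points = 1024, observe = "13C",
                           offset_Hz = 50)
  tr <- highfield_experiment(m, pr)
  expect_lt(diff(range(Mod(tr$signal))), 1e-10 * max(Mod(tr$signal)))
  phase_step <- Arg(tr$signal[-1] / tr$signal[-1024])
  expect_equal(stats::sd(phase_step), 0, tolerance = 1e-10)
  expect_equal(abs(phase_step[1]) / (2 * pi * 1e-3), 50, tolerance = 1e-8)
  expect_error(
    highfield_experiment(m, highfield_protocol(observe = "15N")),
    "absent")
})
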