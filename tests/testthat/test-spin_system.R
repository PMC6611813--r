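test_that("spin operators obey the angular-momentum algebra", {
  sys <- spin_system(c("1H", "13C", "1H"))
  ops <- spin_operators(sys)
  d <- sys$dim
  for (i in seq_len(3)) {
    comm <- ops[[i]]$x %*% ops[[i]]$y - ops[[i]]$y %*% ops[[i]]$x
    expect_lt(max(abs(comm - 1i * ops[[i]]$z)), 1e-12)
    expect_lt(hermitian_error(ops[[i]]$x), 1e-14)
    expect_equal(dim(ops[[i]]$x), c(d, d))
  }
  # orthogonality of operators on different spins
  expect_lt(abs(sum(diag(ops[[1]]$z %*% ops[[2]]$z))), 1e-13)
  # defining representation for one spin
  one <- spin_system("1H")
  expect_equal(Re(diag(spin_operators(one)[[1]]$z)), c(0.5, -0.5))
})

test_that("system validation rejects bad inputs", {
  expect_error(spin_system("2H"), "unsupported isotope")
  J <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(spin_system(c("1H", "13C"), J), "symmetric")
  expect_error(spin_system(c("1H", "13C"), matrix(1, 2, 2)), "diagonal")
  expect_error(spin_system(c("1H", "13C"), matrix(0, 3, 3)), "matrix")
})

test_that("zero-field Hamiltonian is Hermitian, traceless and isotropic", {
  fx <- zulf_fixture("AXB")
  sys <- fx$system
  ops <- spin_operators(sys)
  H <- zero_field_hamiltonian(sys, ops)
  expect_lt(hermitian_error(H), 1e-10)
  expect_lt(abs(sum(diag(H))), 1e-10)
  for (q in c("x", "y", "z")) {
    Fq <- Reduce(`+`, lapply(ops, `[[`, q))
    comm <- H %*% Fq - Fq %*% H
    expect_lt(max(abs(comm)), 1e-10 * max(abs(H)))
  }
  expect_equal(max(abs(zero_field_hamiltonian(spin_system(c("1H", "1H"))))), 0)
})

test_that("AX pair has the singlet-triplet gap J", {
  sys <- spin_system(c("1H", "13C"), 120)
  ev <- sort(eigen(zero_field_hamiltonian(sys), symmetric = TRUE,
                   only.values = TRUE)$values) / (2 * pi)
  expect_equal(ev, c(-90, 30, 30, 30), tolerance = 1e-10)
  expect_equal(diff(range(ev)), 120, tolerance = 1e-10)
})

test_that("A4X zero-field transitions sit at 3J/2 and 5J/2", {
  pair <- ammonium_pair("single")
  sys <- pair$system_C
  ops <- spin_operators(sys)
  H <- zero_field_hamiltonian(sys, ops)
  gH <- gyromagnetic_ratio("1H")
  F <- Reduce(`+`, lapply(seq_len(5), function(i)
    sys$gamma[i] / gH * ops[[i]]$z))
  freqs <- allowed_transitions_hz(H, F)
  freqs <- freqs[freqs > 1e-6]   # drop degenerate/zero-frequency elements
  J <- 73.4
  expect_equal(freqs, c(1.5 * J, 2.5 * J), tolerance = 1e-6)
})

test_that("high-field secular Hamiltonians produce the expected splittings", {
  # A4X: 15N transitions at m_H * J, m_H in -2..2
  pair <- ammonium_pair("single")
  sys <- pair$system_C
  ops <- spin_operators(sys)
  H <- highfield_hamiltonian(sys, ops)
  Fn <- ops[[5]]$x + 1i * ops[[5]]$y
  freqs <- allowed_transitions_hz(H, Fn)
  expect_equal(freqs, 73.4 * c(0, 1, 2), tolerance = 1e-6)
  # AX doublet at +/- J/2 about the offset
  ax <- spin_system(c("1H", "13C"), 120)
  oax <- spin_operators(ax)
  Hax <- highfield_hamiltonian(ax, oax)
  fx <- allowed_transitions_hz(Hax, oax[[2]]$x + 1i * oax[[2]]$y)
  expect_equal(fx, 60, tolerance = 1e-9)
  # single spin: H = 0 in its rotating frame
  expect_equal(max(abs(highfield_hamiltonian(spin_system("13C")))), 0)
})

test_that("thermal state has the high-temperature deviation", {
  sys <- spin_system(c("1H", "15N"))
  ops <- spin_operators(sys)
  rho0 <- thermal_state(sys, 0, 298, ops)
  expect_equal(rho0, diag(4) / 4 + 0i, tolerance = 1e-15)
  rho <- thermal_state(sys, 2, 298, ops)
  expect_equal(sum(diag(rho)), 1 + 0i, tolerance = 1e-14)
  expect_lt(hermitian_error(rho), 1e-15)
  # <I_z> per 1H at 2 T, 298 K: gamma*hbar*B/(4 kB T) ~ 3.4e-6
  hbar <- 1.054571817e-34; kB <- 1.380649e-23
  expected <- gyromagnetic_ratio("1H") * hbar * 2 / (4 * kB * 298)
  got <- Re(sum(diag(rho %*% ops[[1]]$z)))
  # the deviation is buried in the unit matrix, so recovery is limited by
  # double-precision cancellation (~1e-16 / 3.4e-6 relative)
  expect_equal(got, expected, tolerance = 1e-8)
  expect_equal(expected, 3.4e-6, tolerance = 0.02)
  # deviation amplitude ratio between 1H and 15N is gamma_H/gamma_N ~ -9.87
  ratio <- Re(sum(diag(rho %*% ops[[1]]$z))) / Re(sum(diag(rho %*% ops[[2]]$z)))
  expect_equal(ratio, gyromagnetic_ratio("1H") / gyromagnetic_ratio("15N"),
               tolerance = 1e-8)
  expect_equal(ratio, -9.86, tolerance = 0.005)
  # linearity in B (absolute comparison: entries are O(1e-6))
  rho4 <- thermal_state(sys, 4, 298, ops)
  expect_lt(max(abs((rho4 - diag(4) / 4) - 2 * (rho - diag(4) / 4))), 1e-15)
  expect_error(thermal_state(sys, 2, -1), "positive")
})
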