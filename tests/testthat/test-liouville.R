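test_that("vectorization satisfies the Kronecker identity", {
  set.seed(11)
  rho <- matrix(rnorm(9) + 1i * rnorm(9), 3, 3)
  expect_equal(unvec_dm(vec_dm(rho)), rho)
  P <- matrix(rnorm(9) + 1i * rnorm(9), 3, 3)
  Q <- matrix(rnorm(9) + 1i * rnorm(9), 3, 3)
  lhs <- vec_dm(P %*% rho %*% Q)
  rhs <- kronecker(t(Q), P) %*% vec_dm(rho)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  expect_equal(as.vector(vec_dm(diag(2))), c(1, 0, 0, 1))
  expect_equal(trace_vec(vec_dm(rho)), sum(diag(rho)))
  expect_error(vec_dm(matrix(1, 2, 3)), "square")
})

test_that("Hamiltonian superoperator reproduces the commutator", {
  set.seed(12)
  H <- random_hermitian(4)
  rho <- random_density(4)
  got <- unvec_dm(hamiltonian_superop(H) %*% vec_dm(rho))
  expect_lt(max(abs(got - (H %*% rho - rho %*% H))), 1e-12)
  # identity commutes with everything
  expect_equal(max(abs(hamiltonian_superop(diag(4) + 0i))), 0)
  expect_warning(hamiltonian_superop(matrix(c(0, 1, 0, 0), 2, 2)),
                 "not Hermitian")
  # -i * commutator superoperator has a purely imaginary spectrum
  ev <- eigen(-1i * hamiltonian_superop(H), only.values = TRUE)$values
  expect_lt(max(abs(Re(ev))), 1e-10 * max(abs(ev)))
})

test_that("partial-trace superoperator matches the element-wise oracle", {
  set.seed(13)
  sys3 <- spin_system(c("1H", "13C", "1H"))
  rho <- random_density(8)
  for (traced in list(1, 3, c(2, 3))) {
    Tm <- partial_trace_superop(sys3, traced)
    got <- unvec_dm(Tm %*% vec_dm(rho))
    want <- partial_trace_oracle(rho, 3, traced)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_equal(sum(diag(got)), sum(diag(rho)), tolerance = 1e-12)
  }
  # product state: tracing B returns the A factor exactly
  rhoA <- random_density(2)
  rhoB <- random_density(4)
  got <- unvec_dm(partial_trace_superop(3, c(2, 3)) %*%
                    vec_dm(kronecker(rhoA, rhoB)))
  expect_lt(max(abs(got - rhoA)), 1e-13)
  # |aa><aa| -> |a><a|
  up2 <- matrix(0 + 0i, 4, 4); up2[1, 1] <- 1
  got <- unvec_dm(partial_trace_superop(2, 2) %*% vec_dm(up2))
  expect_equal(got, matrix(c(1, 0, 0, 0) + 0i, 2, 2))
  expect_error(partial_trace_superop(sys3, 4), "subset")
  expect_error(partial_trace_superop(sys3, 1:3), "subset")
})

test_that("attachment superoperator is the trace's right inverse", {
  set.seed(14)
  sysA <- spin_system(c("1H", "13C"), 120)
  proton <- spin_system("1H")
  for (pos in 1:3) {
    D <- attach_superop(sysA, proton, positions = pos)
    Tm <- partial_trace_superop(3, pos)
    expect_lt(max(abs(Tm %*% D - diag(16))), 1e-12)
    rhoA <- random_density(4)
    rhoC <- unvec_dm(D %*% vec_dm(rhoA))
    expect_equal(sum(diag(rhoC)), sum(diag(rhoA)), tolerance = 1e-13)
    # attached spin is maximally mixed: tracing the others recovers 1/2
    TmB <- partial_trace_superop(3, setdiff(1:3, pos))
    expect_lt(max(abs(unvec_dm(TmB %*% vec_dm(rhoC)) - diag(2) / 2)), 1e-13)
  }
  # attaching to a sub-unit-trace state preserves its trace
  rhoA <- 0.3 * random_density(4)
  D <- attach_superop(sysA, proton, positions = 3)
  expect_equal(sum(diag(unvec_dm(D %*% vec_dm(rhoA)))), 0.3 + 0i,
               tolerance = 1e-13)
  expect_error(attach_superop(sysA, proton, positions = 3,
                              rho_B = diag(2)), "unit trace")
})

test_that("fluctuating-field relaxation is calibrated to T1", {
  sys <- spin_system("1H")
  ops <- spin_operators(sys)
  R <- relaxation_superop(sys, T1_s = 10, ops)
  # identity state is stationary
  expect_lt(max(abs(R %*% vec_dm(diag(2) / 2 + 0i))), 1e-14)
  # longitudinal deviation decays with the nominal T1 under propagation
  mz <- function(v) Re(sum(diag(unvec_dm(v) %*% ops[[1]]$z)))
  rho0 <- vec_dm(ops[[1]]$z)
  rho_t <- expm_complex(R * 3) %*% rho0
  expect_equal(mz(rho_t) / mz(rho0), exp(-3 / 10), tolerance = 1e-10)
  expect_error(relaxation_superop(sys, T1_s = -1), "positive")
  expect_error(relaxation_superop(sys, T1_s = Inf), "positive")
})

test_that("generators preserve Hermiticity of the state", {
  set.seed(15)
  sys <- spin_system(c("1H", "13C"), 120)
  ops <- spin_operators(sys)
  H <- zero_field_hamiltonian(sys, ops)
  R <- relaxation_superop(sys, c(5, 8), ops)
  rho <- random_density(4)
  for (G in list(-1i * hamiltonian_superop(H), R, liouvillian(H, R))) {
    drho <- unvec_dm(G %*% vec_dm(rho))
    expect_lt(hermitian_error(drho), 1e-12 * max(1, max(abs(drho))))
  }
})

test_that("complex matrix exponential agrees with reference results", {
  set.seed(16)
  # diagonal case: exact
  lam <- rnorm(5) + 1i * rnorm(5)
  expect_lt(max(abs(expm_complex(diag(lam)) - diag(exp(lam)))), 1e-12)
  # real case: agree with Matrix::expm
  skip_if_not_installed("Matrix")
  A <- matrix(rnorm(36), 6, 6)
  expect_lt(max(abs(expm_complex(A + 0i) -
                      as.matrix(Matrix::expm(A)))), 1e-10)
  # group property exp(A) exp(-A) = 1 for a large-norm skew-Hermitian input
  # (the norm forces the scaling-and-squaring branch; unitarity keeps the
  # comparison well conditioned)
  B <- 50i * random_hermitian(4)
  expect_lt(max(abs(expm_complex(B) %*% expm_complex(-B) - diag(4))), 1e-10)
  U <- expm_complex(B)
  expect_lt(max(abs(Conj(t(U)) %*% U - diag(4))), 1e-10)
})
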