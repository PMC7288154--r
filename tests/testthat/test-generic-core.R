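test_that("the canonical Poisson block has the expected algebra", {
  L1 <- hamiltonian_block(1)
  expect_equal(L1, matrix(c(0, -1, 1, 0), 2, 2))
  for (k in c(1, 3)) {
    L <- hamiltonian_block(k)
    expect_equal(L + t(L), matrix(0, 2 * k, 2 * k))
    expect_equal(L %*% L, -diag(2 * k))
  }
})

test_that("midpoint integration conserves quadratic energy and matches the oscillator", {
  L <- hamiltonian_block(1)
  A <- diag(c(4, 1))                    # k = 4, m = 1, omega = 2
  m <- generic_model(L = L, A = A, dt = 1e-3)
  Z <- integrate_generic(m, c(1, 0), n_steps = 2000)
  E <- 0.5 * rowSums((Z %*% A) * Z)
  expect_lt(max(abs(E - E[1])) / E[1], 1e-12)
  tt <- seq(0, by = 1e-3, length.out = 2001)
  expect_lt(max(abs(Z[, 1] - cos(2 * tt))), 1e-5)   # O(dt^2) phase error
  # reversing the sign of L reverses the conservative flow
  m_rev <- generic_model(L = -L, A = A, dt = 1e-3)
  Z_rev <- integrate_generic(m_rev, Z[11, ], n_steps = 10)
  expect_equal(Z_rev[11, ], Z[1, ], tolerance = 1e-10)
})

test_that("a zero generator leaves the state unchanged and steps are exact solves", {
  m0 <- generic_model(A = matrix(0, 3, 3), dt = 0.1)
  z <- c(1, -2, 3)
  expect_equal(generic_step(m0, z), z)
  Z <- integrate_generic(m0, z, n_steps = 5)
  expect_equal(Z[6, ], z)
  # backward Euler option damps a dissipative system monotonically
  K <- -diag(c(1, 2))
  z1 <- generic_step(K, c(1, 1), dt = 0.1, theta = 1)
  expect_equal(z1, c(1 / 1.1, 1 / 1.2), tolerance = 1e-12)
})

test_that("degeneracy residuals vanish for conservative and orthogonal-block models", {
  m <- generic_model(L = hamiltonian_block(1), A = diag(2), dt = 1e-2)
  r <- degeneracy_residuals(m, diag(2))
  expect_equal(r$LB, 0)
  expect_equal(r$MA, 0)
  # M acting on a block orthogonal to A's range
  d <- 4
  A <- diag(c(1, 1, 0, 0))
  B <- diag(c(0, 0, 1, 1))
  M <- diag(c(0, 0, 2, 3))
  L <- matrix(0, d, d); L[1, 2] <- 1; L[2, 1] <- -1
  m2 <- generic_model(L = L, M = M, A = A, B = B, dt = 1e-2)
  set.seed(1)
  Z <- matrix(rnorm(20), 5, 4)
  r2 <- degeneracy_residuals(m2, Z)
  expect_lt(r2$LB_rel, 1e-15)
  expect_lt(r2$MA_rel, 1e-15)
  expect_error(degeneracy_residuals(m2, matrix(0, 2, 3)), "dimension")
})

test_that("entropy increments are non-negative for PSD friction with L = 0", {
  d <- 3
  set.seed(2)
  R <- matrix(rnorm(9), 3, 3)
  M <- crossprod(R)                     # PSD
  B <- -diag(3)                         # gradient of a concave S
  m <- generic_model(M = M, A = matrix(0, d, d), B = B, dt = 1e-3)
  Z <- integrate_generic(m, c(1, -1, 2), n_steps = 500)
  aud <- energy_entropy_audit(Z, m)
  expect_true(all(aud$dS >= -1e-10 * attr(aud, "S_scale")))
  # zero trajectory: all increments vanish
  Z0 <- matrix(0, 10, d)
  aud0 <- energy_entropy_audit(Z0, m)
  expect_true(all(aud0$dE == 0) && all(aud0$dS == 0))
})

test_that("singular integration systems are reported with a diagnostic", {
  K <- diag(2) / 1e-3 * 2   # makes I/dt - K/2 exactly singular at dt = 1e-3
  expect_error(generic_step(K, c(1, 1), dt = 1e-3, theta = 0.5), "singular")
})
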