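test_that("invariants follow the closed-form identities", {
  # undeformed state
  iv <- invariants_of(diag(3))
  expect_equal(unlist(iv), c(I1 = 3, I2 = 3, J = 1, I1_bar = 3, I2_bar = 3))
  # incompressible uniaxial stretch 1.1
  lam <- c(1.1, 1.1^-0.5, 1.1^-0.5)
  iv <- invariants_of(lam)
  expect_equal(iv$J, 1, tolerance = 1e-12)
  expect_equal(iv$I1, 1.21 + 2 / 1.1, tolerance = 1e-12)
  expect_equal(iv$I2, 2 * 1.1 + 1 / 1.21, tolerance = 1e-12)
  # scaling law for C = c I
  cc <- 1.7
  iv <- invariants_of(sqrt(cc) * c(1, 1, 1))
  expect_equal(iv$I1, 3 * cc)
  expect_equal(iv$I2, 3 * cc^2)
  expect_equal(iv$J, cc^1.5)
  expect_error(invariants_of(matrix(c(1, 2, 0, 2, 1, 0, 0, 0, -1), 3)),
               "positive definite")
})

test_that("energy density matches independent evaluation and is frame-indifferent", {
  p <- mooney_rivlin()
  expect_identical(mr_energy(diag(3), p), 0)
  # incompressible uniaxial lambda = 1.1: J = 1 so only the isochoric terms
  # contribute; evaluate the printed form directly from the invariants
  lam <- c(1.1, 1.1^-0.5, 1.1^-0.5)
  I1 <- 1.21 + 2 / 1.1
  I2 <- 2 * 1.1 + 1 / 1.21
  expect_equal(mr_energy(lam, p),
               p$C1 * (I1 - 3) + p$C2 * (I2 - 3), tolerance = 1e-12)
  # linearity in the coefficients: doubling C1 doubles only its term
  p2 <- mooney_rivlin(C1 = 2 * p$C1, C2 = p$C2, D1 = p$D1)
  expect_equal(mr_energy(lam, p2) - mr_energy(lam, p),
               p$C1 * (I1 - 3), tolerance = 1e-12)
  # frame indifference: permuting principal stretches leaves w unchanged
  lam2 <- c(0.9, 1.3, 1.05)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(mr_energy(lam2[perm], p), mr_energy(lam2, p),
                 tolerance = 1e-12)
  }
})

test_that("analytic stress matches the finite-difference derivative of the energy", {
  p <- mooney_rivlin()
  expect_equal(mr_stress(diag(3), p), matrix(0, 3, 3))
  C <- matrix(c(1.3, 0.1, 0.05, 0.1, 1.1, 0.02, 0.05, 0.02, 0.9), 3, 3)
  S <- mr_stress(C, p)
  expect_equal(S, t(S))
  fd <- matrix(0, 3, 3)
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[i, j] + h / 2
    dC[j, i] <- dC[j, i] + h / 2
    fd[i, j] <- (mr_energy(C + dC, p) - mr_energy(C - dC, p)) / h
  }
  expect_lt(max(abs(S - fd)) / max(abs(S)), 1e-6)
  # the principal-frame fast path agrees with the tensor path
  lam <- c(1.2, 0.95, 1.05)
  Sp <- generictda:::mr_stress_principal(lam, p)
  expect_equal(Sp$iso + Sp$vol, diag(mr_stress(lam, p)), tolerance = 1e-12)
})

test_that("small-strain tangent modulus equals 6 (C1 + C2)", {
  p <- mooney_rivlin()
  expect_equal(tangent_modulus(p), 6 * (p$C1 + p$C2), tolerance = 1e-6)
  expect_equal(tangent_modulus(p), 206.7, tolerance = 1e-4)
})

test_that("Prony relaxation functions obey their limits and monotonicity", {
  pr <- prony_series()
  r0 <- prony_ratio(0, pr)
  expect_equal(r0$shear, 1)
  expect_equal(r0$bulk, 1)
  rinf <- prony_ratio(1e9, pr)
  expect_equal(rinf$shear, 0.7, tolerance = 1e-12)
  expect_equal(rinf$bulk, 0.3, tolerance = 1e-12)
  # direct evaluation at t = tau_1
  r1 <- prony_ratio(0.1, pr)
  expect_equal(r1$shear,
               1 - 0.2 * (1 - exp(-1)) - 0.1 * (1 - exp(-0.5)),
               tolerance = 1e-12)
  # monotone non-increasing, bounded in (1 - sum(weights), 1]
  tt <- seq(0, 2, by = 0.01)
  rs <- prony_ratio(tt, pr)$shear
  expect_true(all(diff(rs) <= 0))
  expect_true(all(rs > 0.7 - 1e-12 & rs <= 1))
  expect_error(prony_ratio(-1, pr), "non-negative")
})

test_that("viscoelastic update reduces to hyperelasticity and relaxes correctly", {
  p <- mooney_rivlin()
  lam <- rbind(c(1, 1, 1),
               matrix(rep(c(1.05, 0.98, 1.0), each = 1500), 1500, 3))
  # zero weights -> purely elastic path
  pr0 <- prony_series(shear = c(0, 0), bulk = c(0, 0), tau = c(0.1, 0.2))
  v0 <- viscoelastic_stress_history(lam, p, pr0, dt = 1e-3)
  ve <- viscoelastic_stress_history(lam, p, NULL, dt = 1e-3)
  expect_equal(v0$S, ve$S)
  # step strain held fixed: ratio matches the closed-form relaxation
  pr <- prony_series()
  vh <- viscoelastic_stress_history(lam, p, pr, dt = 1e-3)
  s0 <- generictda:::mr_stress_principal(c(1.05, 0.98, 1.0), p)
  for (krow in c(501, 1001, 1501)) {
    rat <- prony_ratio((krow - 2) * 1e-3, pr)
    pred <- s0$iso * rat$shear + s0$vol * rat$bulk
    expect_equal(vh$S[krow, ], pred, tolerance = 1e-3)  # O(dt) recurrence
  }
  # halving the step changes the final stress within first order in dt
  lam2 <- rbind(c(1, 1, 1),
                matrix(rep(c(1.05, 0.98, 1.0), each = 3000), 3000, 3))
  vh2 <- viscoelastic_stress_history(lam2, p, pr, dt = 5e-4)
  expect_lt(max(abs(vh2$S[3001, ] - vh$S[1501, ])) / max(abs(vh$S[1501, ])),
            5e-3)
})
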