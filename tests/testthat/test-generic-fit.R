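test_that("the generator is recovered from noise-free linear dynamics", {
  set.seed(42)
  d <- 5
  S <- matrix(rnorm(d * d), d, d)
  G <- (S - t(S)) - 0.3 * crossprod(matrix(rnorm(d * d), d, d))
  # several initial conditions give a well-conditioned regression
  Z <- do.call(rbind, lapply(1:3, function(i)
    linear_trajectory(G, rnorm(d), dt = 1e-2, n_steps = 120)))
  reg <- assemble_regression(Z[1:121, ], 1e-2, theta = 0.5)
  for (i in 2:3) {
    more <- assemble_regression(Z[(i - 1) * 121 + 1:121, ], 1e-2, 0.5)
    reg$X <- rbind(reg$X, more$X)
    reg$Y <- rbind(reg$Y, more$Y)
  }
  Ghat <- regress_generator(reg$X, reg$Y, ridge = 1e-12)
  expect_lt(norm(Ghat - G, "F") / norm(G, "F"), 1e-8)
  # duplication invariance: stacking the same window twice changes nothing
  Ghat2 <- regress_generator(rbind(reg$X, reg$X), rbind(reg$Y, reg$Y), 1e-12)
  expect_equal(Ghat2, Ghat, tolerance = 1e-9)
})

test_that("degenerate regressions behave as documented", {
  # constant trajectory: G = 0 is the minimiser
  Zc <- matrix(rep(c(1, 2, 3), each = 30), 30, 3)
  reg <- assemble_regression(Zc, 0.1)
  G <- regress_generator(reg$X, reg$Y)
  expect_lt(norm(G, "F"), 1e-10)
  # under-determined windows are refused with the minimum count in the message
  expect_error(assemble_regression(matrix(1, 3, 5), 0.1), "at least 6")
})

test_that("the split finds admissible factors for canonical generators", {
  # skew generator: conservative solution with M ~ 0
  Gsk <- matrix(c(0, 1, -0.5, -1, 0, 2, 0.5, -2, 0), 3, 3)
  sp <- split_generator(Gsk, diag(3))
  expect_lt(sp$residual, 1e-8)
  expect_lt(norm(sp$M, "F") / norm(Gsk, "F"), 1e-6)
  expect_equal(sp$L, -t(sp$L))
  # symmetric negative semidefinite generator: dissipative solution, L ~ 0
  set.seed(1)
  Gn <- -crossprod(matrix(rnorm(9), 3, 3))
  sp2 <- split_generator(Gn, diag(3))
  expect_lt(sp2$residual, 1e-6)
  expect_lt(norm(sp2$L %*% sp2$A, "F") / norm(Gn, "F"), 1e-6)
  expect_gte(min(eigen(sp2$M, symmetric = TRUE)$values), -1e-10)
  # zero generator: all zeros
  sp0 <- split_generator(matrix(0, 4, 4))
  expect_true(all(unlist(sp0[c("L", "M", "A", "B")]) == 0))
})

test_that("split factors satisfy the degeneracy conditions on the data span", {
  set.seed(3)
  for (rep_i in 1:4) {
    d <- 6
    G <- matrix(rnorm(d * d), d, d)
    Z <- matrix(rnorm(3 * d), 3, d)
    sp <- split_generator(G, Z)
    gn <- norm(G, "F")
    expect_lt(max(abs(sp$L %*% sp$B %*% t(Z))), 1e-6 * gn * max(abs(Z)) * d)
    expect_lt(max(abs(sp$M %*% sp$A %*% t(Z))), 1e-6 * gn * max(abs(Z)) * d)
    expect_equal(sp$L, -t(sp$L))
    expect_gte(min(eigen((sp$M + t(sp$M)) / 2, symmetric = TRUE)$values),
               -1e-10 * gn)
  }
})

test_that("a noise-free visco-hyperelastic test is reconstructed within 1%", {
  fit <- fit_generic(fixture_curve())
  expect_lt(fit$errors[["headline"]], 0.01)
  adm <- admissibility(fit$model, fit$Zs)
  expect_true(adm$ok)
})

test_that("a purely elastic test yields a purely conservative model", {
  ce <- biaxial_test(biaxial_protocol(), prony = NULL, dt = 2e-3)
  fe <- fit_generic(ce)
  expect_lt(fe$errors[["headline"]], 0.01)
  rat <- max(vapply(fe$model$windows, function(w)
    norm(w$M %*% w$B, "F") / max(norm(w$L %*% w$A, "F"), 1e-300), 0))
  expect_lt(rat, 1e-3)
})

test_that("refitting a model-generated trajectory is self-consistent", {
  fit <- fit_generic(fixture_curve())
  Zsim <- predict(fit)
  fit2 <- fit_generic(Zsim, fit$config, dt = fit$dt,
                      boundaries = fit$boundaries)
  expect_lt(fit2$errors[["headline"]], 1e-3)
})

test_that("fitting noise is visible relative to the noise-free fit", {
  curve <- fixture_curve()
  f0 <- fit_generic(curve)
  errs <- vapply(1:20, function(s) {
    f <- fit_generic(add_noise(curve, 0.1, seed = s), f0$config)
    # error against the noise-free truth
    Zs_ref <- f0$Zs
    Zh <- integrate_generic(f$model, Zs_ref[1, ],
                            restarts = Zs_ref[f0$boundaries, , drop = FALSE])
    nc <- ncol(f0$Z)
    Zp <- sweep(Zh[, seq_len(nc)], 2, f$model$scales, "*")
    reconstruction_error(Zp[, 1:2], f0$Z[, 1:2])
  }, 0)
  expect_gt(median(errs), f0$errors[["headline"]])
})

test_that("reconstruction error matches hand calculations", {
  ref <- matrix(c(3, 4, 0, 0), 2, 2)
  expect_equal(reconstruction_error(ref, ref), 0)
  expect_equal(reconstruction_error(1.01 * ref, ref), 0.01)
  # unit perturbation of norm ||ref|| on one entry
  pert <- ref
  pert[1, 1] <- pert[1, 1] + 5
  expect_equal(reconstruction_error(pert, ref), 1)
  expect_error(reconstruction_error(ref * 0, ref * 0), "zero norm")
  expect_error(reconstruction_error(ref, ref[1, , drop = FALSE]),
               "equal dimensions")
})
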