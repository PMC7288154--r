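test_that("empirical semivariances follow their definition", {
  coords <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  # constant field: all semivariances vanish
  emp <- empirical_variogram(coords, rep(3, 4))
  expect_true(all(emp$gamma == 0))
  # two sites: single pair, gamma = (v1 - v2)^2 / 2
  emp2 <- empirical_variogram(coords[1:2, ], c(1, 5), n_bins = 1)
  expect_equal(emp2$gamma, 0.5 * 16)
  expect_equal(emp2$n, 1L)
  expect_error(empirical_variogram(coords[1, , drop = FALSE], 1), "2 sites")
  # pure-nugget (white noise) field: flat within sampling error
  set.seed(4)
  cw <- matrix(runif(400), 200, 2)
  vw <- rnorm(200)
  empw <- empirical_variogram(cw, vw, n_bins = 5)
  expect_lt(diff(range(empw$gamma)) / mean(empw$gamma), 0.5)
})

test_that("variogram fitting recovers a known exponential model", {
  # simulate a Gaussian field with exponential covariance, range 2
  set.seed(8)
  n <- 120
  coords <- matrix(runif(2 * n, 0, 6), n, 2)
  D <- as.matrix(dist(coords))
  truth <- variogram_model("exponential", nugget = 0, sill = 2, range = 2)
  Cov <- truth$sill - variogram_value(truth, D)
  vals <- drop(chol(Cov + 1e-10 * diag(n)) %*% rnorm(n))
  emp <- empirical_variogram(coords, vals, n_bins = 10)
  fitted <- fit_variogram(emp, "exponential")
  expect_equal(fitted$range, truth$range, tolerance = 0.3)
  # monotone families stay monotone
  hh <- seq(0, 10, by = 0.1)
  expect_true(all(diff(variogram_value(fitted, hh)) >= 0))
  # constant field falls back gracefully
  fb <- fit_variogram(empirical_variogram(coords[1:5, ], rep(1, 5)))
  expect_equal(fb$sill, 0)
})

test_that("kriging is exact at sites and respects the unit-sum constraint", {
  coords <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 1, 3), 5, 2, byrow = TRUE)
  vals <- c(1, 3, 2, 5, 4)
  vgm <- variogram_model("exponential", sill = 2, range = 2)
  # target on a site: that site's value, weight one
  kr <- krige("ordinary", coords, vals, coords[3, ], vgm = vgm)
  expect_equal(kr$estimate, vals[3])
  expect_equal(as.numeric(kr$weights), c(0, 0, 1, 0, 0))
  # generic target: weights sum to one
  kr2 <- krige("ordinary", coords, vals, c(0.7, 0.9), vgm = vgm)
  expect_equal(sum(kr2$weights), 1, tolerance = 1e-10)
  kr3 <- krige("local", coords, vals, c(0.7, 0.9), vgm = vgm)
  expect_equal(sum(kr3$weights), 1, tolerance = 1e-10)
  # two equidistant sites share the weight equally
  kr4 <- krige("ordinary", coords[1:2, ], vals[1:2], c(1, 0), vgm = vgm)
  expect_equal(as.numeric(kr4$weights), c(0.5, 0.5), tolerance = 1e-10)
  # constant field: every variant returns the constant
  kc <- rep(7, 5)
  for (v in c("simple", "ordinary", "local")) {
    expect_equal(krige(v, coords, kc, c(1, 1), vgm = vgm)$estimate, 7,
                 tolerance = 1e-8)
  }
  # simple kriging uses the supplied mean
  ks <- krige("simple", coords, vals, c(10, 10), vgm = vgm, mean_value = 2.5)
  expect_equal(ks$estimate, 2.5, tolerance = 1e-6)  # far target -> the mean
})

test_that("model interpolation preserves structure and has the stated identities", {
  curve <- fixture_curve()
  fit <- fit_generic(curve)
  m <- fit$model
  # identical models: the combination reproduces them (same generator)
  comb <- interpolate_generic_model(list(m, m, m), rep(1 / 3, 3), Z = fit$Zs)
  K0 <- with(m$windows[[2]], L %*% A + M %*% B) %*%
    (m$windows[[2]]$Q %*% t(m$windows[[2]]$Q))
  K1 <- with(comb$windows[[2]], L %*% A + M %*% B) %*%
    (m$windows[[2]]$Q %*% t(m$windows[[2]]$Q))
  expect_lt(norm(K1 - K0, "F") / norm(K0, "F"), 1e-2)
  # the mean model is the uniform-weight interpolation
  noisy <- lapply(1:3, function(s)
    fit_generic(add_noise(curve, 0.1, seed = s), fit$config)$model)
  m1 <- mean_generic_model(noisy, Z = fit$Zs)
  m2 <- interpolate_generic_model(noisy, rep(1 / 3, 3), Z = fit$Zs)
  expect_equal(m1$windows[[1]]$L, m2$windows[[1]]$L)
  # admissibility of the combination
  adm <- admissibility(m1, fit$Zs)
  expect_true(adm$ok)
  # a convex combination of PSD frictions is PSD before any projection
  M1 <- crossprod(matrix(rnorm(9), 3, 3))
  M2 <- crossprod(matrix(rnorm(9), 3, 3))
  Mc <- 0.3 * M1 + 0.7 * M2
  expect_gte(min(eigen(Mc, symmetric = TRUE)$values), 0)
  # incompatible models are refused
  short <- fit_generic(fixture_state()[1:400, ], fit$config, dt = 2e-3,
                       boundaries = c(1L, 200L))
  expect_error(interpolate_generic_model(list(m, short$model), c(0.5, 0.5)),
               "incompatible")
})
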