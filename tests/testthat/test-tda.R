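test_that("persistence of canonical fixtures matches hand enumeration", {
  # single point: one essential H0 bar, nothing else
  d1 <- rips_persistence(matrix(0, 1, 1), max_dim = 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$dimension, 0)
  expect_false(is.finite(d1$death))
  # unit square: three H0 merges at 1, one H1 bar born at the side length
  # and killed at the diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dg <- rips_persistence(sq, max_dim = 2, threshold = 2)
  h0 <- dg[dg$dimension == 0, ]
  expect_equal(sum(is.finite(h0$death)), 3)
  expect_equal(h0$death[is.finite(h0$death)], rep(1, 3))
  h1 <- dg[dg$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  expect_equal(nrow(dg[dg$dimension == 2, ]), 0)
  expect_error(rips_persistence(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("reduction agrees with an independent naive implementation", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(16), 8, 2)
    D <- as.matrix(dist(X))
    thr <- max(D)
    got <- rips_persistence(D, max_dim = 2, threshold = thr)
    want <- naive_rips(D, max_dim = 2)
    # compare multisets of finite bars per dimension
    for (k in 0:2) {
      g <- got[got$dimension == k & is.finite(got$death), c("birth", "death")]
      w <- want[want$dimension == k & is.finite(want$death),
                c("birth", "death")]
      expect_equal(nrow(g), nrow(w))
      if (nrow(g)) {
        expect_equal(g[order(g$birth, g$death), ],
                     w[order(w$birth, w$death), ],
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
    expect_equal(sum(!is.finite(got$death) & got$dimension == 0),
                 sum(!is.finite(want$death) & want$dimension == 0))
  }
})

test_that("a noisy circle has one dominant H1 bar", {
  X <- circle_cloud(n = 40, noise = 0.08, seed = 7)
  dg <- rips_persistence(X, max_dim = 1)
  h1 <- dg[dg$dimension == 1, ]
  pers <- ifelse(is.finite(h1$death), h1$death - h1$birth,
                 attr(dg, "threshold") - h1$birth)
  pers <- sort(pers, decreasing = TRUE)
  expect_gte(length(pers), 1)
  if (length(pers) > 1) expect_gt(pers[1] / pers[2], 3)
  # H0 bar count at R = 0 equals the number of points
  expect_equal(nrow(dg[dg$dimension == 0, ]), 40)
  # duplicating a point does not change H1
  X2 <- rbind(X, X[1, ])
  dg2 <- rips_persistence(X2, max_dim = 1)
  h1b <- dg2[dg2$dimension == 1, ]
  expect_equal(sort(h1$birth), sort(h1b$birth), tolerance = 1e-12)
})

test_that("the selected scale sits in the dominant-persistence regime", {
  X <- circle_cloud(n = 40, noise = 0.05, seed = 3)
  dg <- rips_persistence(X, max_dim = 1)
  h1 <- dg[dg$dimension == 1, ]
  dom <- h1[which.max(ifelse(is.finite(h1$death), h1$death, 1e6) - h1$birth), ]
  r_star <- select_scale(dg)
  expect_gt(r_star, dom$birth)
  expect_lt(r_star, min(dom$death, attr(dg, "threshold")))
  # two well-separated clusters: R* below the inter-cluster distance
  set.seed(5)
  Y <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 10, 0.2), 15, 2))
  dgy <- rips_persistence(Y, max_dim = 0)
  ry <- select_scale(dgy)
  expect_lt(ry, 9)
  # degenerate diagram falls back with a warning
  expect_warning(select_scale(rips_persistence(matrix(0, 1, 1))),
                 "degenerate")
})

test_that("neighbourhoods use the scale ball with a k-nearest fallback", {
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(20, 8, 0.3), 10, 2))
  # reference inside the first cluster: neighbours stay in that cluster
  nb <- neighbors_of(1, X, r_star = 2)
  expect_true(all(nb <= 20))
  expect_false(isTRUE(attr(nb, "fallback")))
  # isolated reference beyond R*: k-nearest fallback, flagged
  nb2 <- neighbors_of(21, X, r_star = 0.0001, k_min = 4)
  expect_length(nb2, 4)
  expect_true(attr(nb2, "fallback"))
  # all points identical: everything is a neighbour
  Z <- matrix(1, 6, 3)
  nb3 <- neighbors_of(2, Z, r_star = 0.5)
  expect_equal(sort(nb3), setdiff(1:6, 2))
})

test_that("tangent charts reproduce planar neighbourhoods exactly", {
  set.seed(11)
  basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  coords <- matrix(rnorm(16), 8, 2)
  X <- coords %*% t(basis) + 5        # plane offset from the origin
  chart <- tangent_chart(X, neighbors = 1:8)
  expect_equal(chart$d, 2)
  expect_equal(crossprod(chart$basis), diag(chart$d))
  lifted <- chart_lift(chart, chart_project(chart, X))
  expect_lt(max(abs(lifted - X)), 1e-10)
  # discarded orthogonal variance equals the trailing eigenvalue mass
  Xn <- X + matrix(rnorm(80, 0, 0.01), 8, 10)
  ch2 <- tangent_chart(Xn, neighbors = 1:8, var_frac = 0.95, d_max = 2)
  res <- Xn - chart_lift(ch2, chart_project(ch2, Xn))
  expect_equal(sum(res^2), sum(ch2$eigenvalues[-(1:ch2$d)]),
               tolerance = 1e-8)
  # full-dimensional chart loses nothing
  small <- matrix(rnorm(12), 4, 3)
  ch3 <- tangent_chart(small, neighbors = 1:4, var_frac = 1, d_max = 3)
  expect_lt(max(abs(chart_lift(ch3, chart_project(ch3, small)) - small)),
            1e-10)
})

test_that("curve descriptors are linear in the curve and standardised over the cloud", {
  curve <- fixture_curve()
  n1 <- add_noise(curve, 0.05, seed = 1)
  n2 <- add_noise(curve, 0.05, seed = 2)
  d1 <- curve_descriptor(n1)
  expect_identical(d1, curve_descriptor(n1))
  # linearity: descriptor of the pointwise mean = mean of descriptors
  mix <- n1
  mix$P_11 <- (n1$P_11 + n2$P_11) / 2
  mix$P_22 <- (n1$P_22 + n2$P_22) / 2
  expect_equal(curve_descriptor(mix),
               (d1 + curve_descriptor(n2)) / 2, tolerance = 1e-12)
  cloud <- descriptor_cloud(lapply(1:6, function(s)
    add_noise(curve, 0.05, seed = s)))
  expect_equal(colMeans(cloud), rep(0, ncol(cloud)), tolerance = 1e-12)
  expect_equal(apply(cloud, 2, sd), rep(1, ncol(cloud)), tolerance = 1e-12)
})
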