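# shared fixtures, all generated in code

# trajectory of the theta-discretised linear system z' = G z
linear_trajectory <- function(G, z0, dt, n_steps, theta = 0.5) {
  d <- nrow(G)
  Phi <- solve(diag(d) / dt - theta * G, diag(d) / dt + (1 - theta) * G)
  Z <- matrix(0, n_steps + 1L, d)
  Z[1, ] <- z0
  for (k in seq_len(n_steps)) Z[k + 1, ] <- Phi %*% Z[k, ]
  Z
}

# seeded noisy circle cloud
circle_cloud <- function(n = 40, radius = 1, noise = 0.05, seed = 1) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  cbind(radius * cos(th) + rnorm(n, 0, noise),
        radius * sin(th) + rnorm(n, 0, noise))
}

# independent brute-force Vietoris-Rips persistence for tiny clouds:
# enumerate every simplex up to dimension 2, sort by (filtration, dim),
# and reduce the full boundary matrix over Z/2.  Deliberately naive - it
# shares no code with the package's reduction.
naive_rips <- function(D, max_dim = 2) {
  n <- nrow(D)
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <- list(v = i, f = 0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    simp[[length(simp) + 1]] <- list(v = c(i, j), f = D[i, j])
  if (max_dim >= 1 && n >= 3)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      simp[[length(simp) + 1]] <- list(v = c(i, j, k),
                                       f = max(D[i, j], D[i, k], D[j, k]))
  if (max_dim >= 2 && n >= 4)
    for (i in 1:(n - 3)) for (j in (i + 1):(n - 2))
      for (k in (j + 1):(n - 1)) for (l in (k + 1):n)
        simp[[length(simp) + 1]] <- list(v = c(i, j, k, l),
          f = max(D[i, j], D[i, k], D[i, l], D[j, k], D[j, l], D[k, l]))
  dims <- vapply(simp, function(s) length(s$v) - 1L, 0L)
  filt <- vapply(simp, function(s) s$f, 0)
  ord <- order(filt, dims)
  simp <- simp[ord]; dims <- dims[ord]; filt <- filt[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = ","), "")
  idx <- setNames(seq_along(simp), key)
  m <- length(simp)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    v <- simp[[j]]$v
    cols[[j]] <- if (length(v) == 1) integer(0) else
      sort(vapply(seq_along(v), function(r)
        idx[[paste(v[-r], collapse = ",")]], 0L))
  }
  low <- function(col) if (length(col)) max(col) else 0L
  owner <- integer(m)
  pairs <- NULL
  for (j in seq_len(m)) {
    repeat {
      l <- low(cols[[j]])
      if (l == 0L || owner[l] == 0L) break
      cols[[j]] <- sort(union(setdiff(cols[[j]], cols[[owner[l]]]),
                              setdiff(cols[[owner[l]]], cols[[j]])))
    }
    l <- low(cols[[j]])
    if (l > 0L) {
      owner[l] <- j
      if (filt[j] > filt[l])
        pairs <- rbind(pairs, c(dims[l], filt[l], filt[j]))
    }
  }
  paired <- c(which(owner > 0L), owner[owner > 0L])
  for (j in setdiff(seq_len(m), paired)) {
    if (length(cols[[j]]) == 0 && dims[j] < max_dim + 1L)
      pairs <- rbind(pairs, c(dims[j], filt[j], Inf))
  }
  out <- data.frame(dimension = pairs[, 1], birth = pairs[, 2],
                    death = pairs[, 3])
  out[order(out$dimension, out$birth, out$death), , drop = FALSE]
}

# short biaxial fixture shared by fitting tests (coarse grid for speed)
fixture_curve <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- biaxial_test(biaxial_protocol(), dt = 2e-3)
    cache
  }
})

fixture_state <- function(curve = fixture_curve()) {
  cbind(u_h = curve$u_h, u_v = curve$u_v, w_3 = curve$lambda_3 - 1,
        P_11 = curve$P_11, P_22 = curve$P_22)
}
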