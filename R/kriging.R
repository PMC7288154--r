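#' Empirical semivariogram
#'
#' Binned method-of-moments semivariances
#' \eqn{\gamma(h) = \frac{1}{2|N(h)|}\sum_{(i,j)\in N(h)} \|v_i - v_j\|^2 / m}
#' over `n_bins` equal-width lag bins (for multivariate `values` the squared
#' differences are averaged over the `m` components, giving a pooled
#' variogram for fields interpolated with shared weights).
#'
#' @param coords site coordinates (rows).
#' @param values numeric vector or matrix (rows aligned with `coords`).
#' @param n_bins number of lag bins.
#' @return data frame with `h` (bin midpoint), `gamma`, `n` (pair count);
#'   empty bins dropped.
#' @export
empirical_variogram <- function(coords, values, n_bins = 8L) {
  coords <- rbind(coords)
  values <- cbind(values)
  if (nrow(coords) < 2) stop("need at least 2 sites")
  D <- as.matrix(stats::dist(coords))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[ij]
  sq <- rowMeans((values[ij[, 1], , drop = FALSE] -
                  values[ij[, 2], , drop = FALSE])^2) / 2
  hmax <- max(h)
  if (hmax == 0) return(data.frame(h = 0, gamma = mean(sq), n = length(sq)))
  bin <- pmin(floor(h / hmax * n_bins) + 1L, n_bins)
  out <- data.frame(h = (tapply(h, bin, mean)),
                    gamma = (tapply(sq, bin, mean)),
                    n = as.integer(table(bin)))
  rownames(out) <- NULL
  out
}

#' Parametric variogram model
#'
#' @param family `"exponential"`, `"gaussian"` or `"spherical"`.
#' @param nugget,sill,range variogram parameters (`sill >= nugget >= 0`,
#'   `range > 0`); `range` is the practical range.
#' @export
variogram_model <- function(family = c("exponential", "gaussian", "spherical"),
                            nugget = 0, sill = 1, range = 1) {
  family <- match.arg(family)
  stopifnot(sill >= nugget, nugget >= 0, range > 0)
  structure(list(family = family, nugget = nugget, sill = sill,
                 range = range), class = "variogram_model")
}

#' Evaluate a variogram model
#'
#' @param vgm a [variogram_model()].
#' @param h lag distance(s).
#' @export
variogram_value <- function(vgm, h) {
  psill <- vgm$sill - vgm$nugget
  g <- switch(vgm$family,
    exponential = psill * (1 - exp(-3 * h / vgm$range)),
    gaussian = psill * (1 - exp(-3 * (h / vgm$range)^2)),
    spherical = ifelse(h >= vgm$range, psill,
                       psill * (1.5 * h / vgm$range - 0.5 * (h / vgm$range)^3)))
  ifelse(h > 0, vgm$nugget + g, 0)
}

#' Fit a variogram model to empirical semivariances
#'
#' Weighted least squares over the bins (weights = pair counts).  With fewer
#' than 3 non-empty bins the fit falls back to an exponential model with
#' range equal to the median lag and sill equal to the mean semivariance.
#'
#' @param emp data frame from [empirical_variogram()].
#' @param family variogram family.
#' @param nugget fixed nugget (0 keeps Kriging an exact interpolator).
#' @return a [variogram_model()].
#' @export
fit_variogram <- function(emp, family = "exponential", nugget = 0) {
  if (nrow(emp) < 3 || all(emp$gamma == 0)) {
    sill <- max(mean(emp$gamma), 0)
    rng <- max(median(emp$h), .Machine$double.eps)
    return(variogram_model(family, nugget = min(nugget, sill),
                           sill = max(sill, nugget), range = rng))
  }
  w <- emp$n / sum(emp$n)
  obj <- function(par) {
    vg <- variogram_model(family, nugget = nugget,
                          sill = nugget + exp(par[1]), range = exp(par[2]))
    sum(w * (variogram_value(vg, emp$h) - emp$gamma)^2)
  }
  init <- c(log(max(max(emp$gamma) - nugget, 1e-8)),
            log(max(max(emp$h) / 2, 1e-8)))
  op <- optim(init, obj, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-12))
  variogram_model(family, nugget = nugget, sill = nugget + exp(op$par[1]),
                  range = exp(op$par[2]))
}

#' Kriging interpolation weights and estimate
#'
#' Best-linear-unbiased interpolation of site values at a target location.
#' `"simple"` Kriging assumes a known mean and leaves the weights
#' unconstrained; `"ordinary"` Kriging estimates the mean through the
#' unit-sum constraint on the weights; `"local"` is ordinary Kriging meant to
#' be applied in tangent-chart coordinates restricted to a manifold
#' neighbourhood (the solve is identical to ordinary Kriging - the variant
#' name records the geometry supplied by the caller).  With a zero nugget
#' every variant interpolates exactly at the sites.
#'
#' @param variant `"simple"`, `"ordinary"` or `"local"`.
#' @param coords site coordinates (rows).
#' @param values site values, vector or matrix (one row per site).
#' @param target target coordinate vector.
#' @param vgm a [variogram_model()]; by default fitted to the sites by
#'   [fit_variogram()] on the pooled empirical variogram.
#' @param mean_value known mean for simple Kriging (vector of the value
#'   dimension; defaults to the site mean).
#' @return list with `estimate`, `weights` (class `kriging_weights`), and
#'   the variogram used.
#' @export
krige <- function(variant = c("ordinary", "simple", "local"), coords, values,
                  target, vgm = NULL, mean_value = NULL) {
  variant <- match.arg(variant)
  coords <- rbind(coords)
  values <- cbind(values)
  ns <- nrow(coords)
  stopifnot(nrow(values) == ns, ns >= 1)
  if (is.null(vgm)) vgm <- fit_variogram(empirical_variogram(coords, values))
  # exact-match shortcut (also covers the degenerate all-sites-coincident
  # case, up to floating-point identity)
  dtar <- sqrt(colSums((t(coords) - as.numeric(target))^2))
  coord_scale <- max(1e-300, max(abs(coords)), max(abs(target)))
  hit <- dtar <= 1e-10 * coord_scale
  if (any(hit)) {
    w <- as.numeric(hit); w <- w / sum(w)
    return(list(estimate = unname(drop(crossprod(w, values))),
                weights = structure(w, variant = variant,
                                    class = "kriging_weights"),
                vgm = vgm))
  }
  D <- as.matrix(stats::dist(coords))
  # covariance form: C(h) = sill - gamma(h)
  C <- vgm$sill - variogram_value(vgm, D)
  c0 <- vgm$sill - variogram_value(vgm, dtar)
  ridge_flag <- FALSE
  if (variant == "simple") {
    sol <- try(solve(C, c0), silent = TRUE)
    if (inherits(sol, "try-error")) {
      ridge_flag <- TRUE
      sol <- try(solve(C + 1e-6 * mean(diag(C) + 1e-12) * diag(ns), c0),
                 silent = TRUE)
      if (inherits(sol, "try-error")) sol <- rep(1 / ns, ns)
    }
    w <- as.numeric(sol)
    if (is.null(mean_value)) mean_value <- colMeans(values)
    est <- unname(mean_value + drop(crossprod(w, sweep(values, 2, mean_value))))
  } else {
    K <- rbind(cbind(C, 1), c(rep(1, ns), 0))
    rhs <- c(c0, 1)
    sol <- try(solve(K, rhs), silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol))) {
      ridge_flag <- TRUE
      K[seq_len(ns), seq_len(ns)] <- C + 1e-6 * mean(diag(C) + 1e-12) *
        diag(ns)
      sol <- try(solve(K, rhs), silent = TRUE)
      if (inherits(sol, "try-error") || any(!is.finite(sol)))
        sol <- c(rep(1 / ns, ns), 0)   # degenerate geometry: uniform weights
    }
    w <- sol[seq_len(ns)]
    est <- unname(drop(crossprod(w, values)))
  }
  list(estimate = est,
       weights = structure(w, variant = variant, ridged = ridge_flag,
                           class = "kriging_weights"),
       vgm = vgm)
}

#' @export
print.kriging_weights <- function(x, ...) {
  cat(sprintf("%s Kriging weights (%d sites, sum = %.6f)%s\n",
              attr(x, "variant"), length(x), sum(x),
              if (isTRUE(attr(x, "ridged"))) " [ridged]" else ""))
  print(as.numeric(x))
  invisible(x)
}

# --- interpolation of model terms ------------------------------------------

check_compatible_models <- function(models) {
  m0 <- models[[1]]
  for (m in models[-1]) {
    if (m$d != m0$d || length(m$windows) != length(m0$windows) ||
        abs(m$dt - m0$dt) > 1e-12)
      stop("incompatible models: dimensions, windows and dt must agree")
  }
  m0
}

#' Interpolate GENERIC models with Kriging weights
#'
#' Weighted combination of compatible models followed by re-projection onto
#' the admissible set.  The decomposition `(L, M, A, B)` of a fitted model
#' is a gauge choice - only the generator `K = L A + M B` acts on data - so
#' the interpolation averages the per-window generators (the identified,
#' gauge-invariant components of the model) and re-derives one admissible
#' split of the combined generator per window with [split_generator()],
#' carrying the degeneracy conditions on the span of `Z` when supplied.
#'
#' @param models list of compatible `generic_model`s.
#' @param weights numeric weights (length = number of models).
#' @param Z optional state matrix (model coordinates) carrying the data span
#'   for the degeneracy conditions of the re-split.
#' @param conservative force a purely Hamiltonian re-split; defaults to
#'   `TRUE` when every input model is conservative.
#' @return an admissible `generic_model`.
#' @export
interpolate_generic_model <- function(models, weights, Z = NULL,
                                      conservative = NULL) {
  stopifnot(length(models) == length(weights))
  m0 <- check_compatible_models(models)
  nw <- length(m0$windows)
  d <- m0$d
  if (is.null(conservative)) {
    conservative <- all(vapply(models, function(m)
      all(vapply(m$windows, function(w) all(w$M == 0) && all(w$B == 0),
                 TRUE)), TRUE))
  }
  windows <- vector("list", nw)
  bnds <- c(m0$boundaries, (m0$n_total %||% 0) + 1L)
  for (wi in seq_len(nw)) {
    K <- matrix(0, d, d)
    for (k in seq_along(models)) {
      w <- models[[k]]$windows[[wi]]
      Kk <- w$L %*% w$A + w$M %*% w$B
      # only the action on the window's own data span is identified by the
      # fit; off-span action is projection arbitrariness and must not enter
      # the combination
      if (!is.null(w$Q)) Kk <- Kk %*% (w$Q %*% t(w$Q))
      K <- K + weights[k] * Kk
    }
    Zw <- if (!is.null(Z)) {
      rows <- seq.int(bnds[wi], min(bnds[wi + 1L], nrow(Z)))
      Z[rows, , drop = FALSE]
    } else NULL
    # the re-projection is scored against the combined generator's own
    # trajectory (started from the window-start state), not against the
    # reference data: the admissible model should reproduce what the
    # unconstrained combination predicts
    target <- NULL
    if (!is.null(Zw) && nrow(Zw) > 2) {
      Phi <- tryCatch(propagator(K, m0$dt, m0$theta),
                      error = function(e) NULL)
      if (!is.null(Phi)) {
        target <- matrix(0, nrow(Zw), d)
        target[1, ] <- Zw[1, ]
        for (k in 2:nrow(Zw)) target[k, ] <- Phi %*% target[k - 1L, ]
        if (!all(is.finite(target))) target <- NULL
      }
    }
    sp <- split_generator(K, Zw, conservative = conservative,
                          max_iter = 15L, polish = FALSE,
                          dt = m0$dt, theta = m0$theta,
                          score_target = target)
    win <- sp[c("L", "M", "A", "B")]
    # the component-wise average of the factors is a second candidate: for
    # coherent inputs (e.g. identical models) it is exact, but it is only
    # usable when the averaged factors happen to remain admissible
    fa <- list(L = matrix(0, d, d), M = matrix(0, d, d),
               A = matrix(0, d, d), B = matrix(0, d, d))
    for (k in seq_along(models)) {
      w <- models[[k]]$windows[[wi]]
      for (nm in names(fa)) fa[[nm]] <- fa[[nm]] + weights[k] * w[[nm]]
    }
    fa$L <- skew_part(fa$L)
    fa$M <- clip_psd(fa$M)
    if (!is.null(Zw) && !is.null(target)) {
      fa_scale <- max(norm(fa$L %*% fa$A + fa$M %*% fa$B, "F"), 1e-300)
      deg_ok <- max(norm(fa$L %*% fa$B, "F"),
                    norm(fa$M %*% fa$A, "F")) < 1e-8 * fa_scale
      if (deg_ok) {
        score_of <- function(w) {
          Kc <- w$L %*% w$A + w$M %*% w$B
          Phi <- tryCatch(propagator(Kc, m0$dt, m0$theta),
                          error = function(e) NULL)
          if (is.null(Phi)) return(Inf)
          z <- target[1, ]; e2 <- 0
          for (k in 2:nrow(target)) {
            z <- Phi %*% z
            e2 <- e2 + sum((z - target[k, ])^2)
            if (!is.finite(e2)) return(Inf)
          }
          e2
        }
        if (score_of(fa) < score_of(win)) win <- fa
      }
    }
    windows[[wi]] <- win
  }
  generic_model(windows = windows, boundaries = m0$boundaries,
                n_total = m0$n_total, dt = m0$dt, theta = m0$theta,
                channels = m0$channels, scales = m0$scales, check = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean GENERIC model
#'
#' Component-wise unweighted average of the model terms (the baseline the
#' Kriging variants are compared against), with the same admissibility
#' re-projection as [interpolate_generic_model()].
#'
#' @inheritParams interpolate_generic_model
#' @export
mean_generic_model <- function(models, Z = NULL) {
  interpolate_generic_model(models, rep(1 / length(models), length(models)),
                            Z = Z)
}
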