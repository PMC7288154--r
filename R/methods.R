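#' @export
print.generic_fit <- function(x, ...) {
  cat(sprintf("GENERIC fit: %d samples, %d channel(s), %d window(s)\n",
              nrow(x$Z), ncol(x$Z), length(x$model$windows)))
  cat(sprintf("  reconstruction error (%s): %.4g%%; all channels: %.4g%%\n",
              paste(x$error_channels, collapse = ", "),
              100 * x$errors[["headline"]], 100 * x$errors[["all"]]))
  invisible(x)
}

#' @export
summary.generic_fit <- function(object, ...) {
  adm <- admissibility(object$model, object$Zs)
  res <- vapply(object$diagnostics, function(d) d$residual, 0)
  out <- list(errors = object$errors, admissibility = adm,
              split_residuals = res,
              iterations = vapply(object$diagnostics,
                                  function(d) d$iterations, 0L),
              n_windows = length(object$model$windows),
              channels = colnames(object$Z))
  class(out) <- "summary.generic_fit"
  out
}

#' @export
print.summary.generic_fit <- function(x, ...) {
  cat("GENERIC fit summary\n")
  cat(sprintf("  windows: %d; split residuals (span-relative): %s\n",
              x$n_windows, paste(signif(x$split_residuals, 3),
                                 collapse = ", ")))
  cat(sprintf("  reconstruction error: %.4g%% (headline), %.4g%% (all)\n",
              100 * x$errors[["headline"]], 100 * x$errors[["all"]]))
  a <- x$admissibility
  cat(sprintf(
    "  admissibility: |L+L'| = %.2e, min eig(M) = %.2e, degeneracy = %.2e/%.2e %s\n",
    a$skew, a$m_min_eig, a$deg_LB_rel, a$deg_MA_rel,
    if (a$ok) "[ok]" else "[VIOLATED]"))
  invisible(x)
}

#' Extract the fitted model matrices
#'
#' @param object a `generic_fit`.
#' @param ... unused.
#' @return list (one element per window) of `L`, `M`, `A`, `B` matrices.
#' @export
coef.generic_fit <- function(object, ...) {
  lapply(object$model$windows, function(w) w[c("L", "M", "A", "B")])
}

#' Reconstruct or predict trajectories from a fitted model
#'
#' With no arguments, returns the windowed reconstruction of the fitted
#' trajectory (each window restarted from the measured window-start state) in
#' physical units.  With `z0`, integrates freely from that state.
#'
#' @param object a `generic_fit`.
#' @param z0 optional initial state in physical channel units.
#' @param n_steps number of steps for the free run.
#' @param restart restart each window at the measured states (reconstruction
#'   convention) or run freely across windows.
#' @param ... unused.
#' @export
predict.generic_fit <- function(object, z0 = NULL, n_steps = NULL,
                                restart = TRUE, ...) {
  model <- object$model
  nc <- ncol(object$Z)
  if (is.null(z0)) {
    restarts <- if (restart)
      object$Zs[object$boundaries, , drop = FALSE] else NULL
    Zh <- integrate_generic(model, object$Zs[1, ], n_steps = n_steps,
                            restarts = restarts)
  } else {
    z0s <- c(as.numeric(z0) / model$scales, 1)
    Zh <- integrate_generic(model, z0s, n_steps = n_steps)
  }
  out <- sweep(Zh[, seq_len(nc), drop = FALSE], 2, model$scales, "*")
  colnames(out) <- colnames(object$Z)
  out
}

#' @export
residuals.generic_fit <- function(object, ...) {
  object$Z - object$reconstruction
}

#' Simulate trajectories from a fitted model
#'
#' Free-running integration of the fitted piecewise model from the measured
#' initial state (no window restarts), optionally perturbing the initial
#' state with Gaussian noise per simulation.
#'
#' @param object a `generic_fit`.
#' @param nsim number of simulated trajectories.
#' @param seed RNG seed.
#' @param sd relative standard deviation of the initial-state perturbation.
#' @param ... unused.
#' @return a list of trajectory matrices in physical units.
#' @export
simulate.generic_fit <- function(object, nsim = 1, seed = NULL, sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  nc <- ncol(object$Z)
  scale0 <- pmax(abs(object$Z[1, ]), apply(abs(object$Z), 2, max) * 1e-3)
  lapply(seq_len(nsim), function(i) {
    z0 <- object$Z[1, ] + if (sd > 0) rnorm(nc, 0, sd * scale0) else 0
    predict(object, z0 = z0, n_steps = object$model$n_total - 1L)
  })
}

#' Plot a fitted GENERIC model against its data
#'
#' One panel per channel: measured trajectory and windowed reconstruction.
#'
#' @param x a `generic_fit`.
#' @param channels channels to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.generic_fit <- function(x, channels = NULL, ...) {
  if (is.null(channels)) channels <- colnames(x$Z)
  time <- seq(0, by = x$dt, length.out = nrow(x$Z))
  old <- par(mfrow = c(length(channels), 1), mar = c(3, 4, 1, 1))
  on.exit(par(old))
  for (ch in channels) {
    matplot(time, cbind(x$Z[, ch], x$reconstruction[, ch]), type = "l",
            lty = c(1, 2), col = c("black", "red"), xlab = "time [s]",
            ylab = ch, ...)
    abline(v = time[x$boundaries], col = "grey80", lty = 3)
  }
  invisible(x)
}
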