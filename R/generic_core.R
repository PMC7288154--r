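#' Canonical Poisson block matrix
#'
#' The constant skew-symmetric Poisson operator of a Hamiltonian
#' (position/momentum) pair structure,
#' \deqn{L = \begin{pmatrix} 0 & I \\ -I & 0 \end{pmatrix}.}
#'
#' @param dim_x dimension of the position (stretch) block.
#' @return a `2 * dim_x` square skew-symmetric matrix with `L %*% L = -I`.
#' @export
hamiltonian_block <- function(dim_x) {
  stopifnot(dim_x >= 1)
  I <- diag(dim_x)
  rbind(cbind(matrix(0, dim_x, dim_x), I),
        cbind(-I, matrix(0, dim_x, dim_x)))
}

sym_part <- function(X) (X + t(X)) / 2
skew_part <- function(X) (X - t(X)) / 2

#' Construct a (piecewise) GENERIC model
#'
#' A GENERIC model is the quadruple of matrices per time window: a
#' skew-symmetric Poisson operator `L`, a symmetric positive semidefinite
#' friction operator `M`, and the matrix forms `A`, `B` of the discrete
#' energy and entropy gradients, `DE = A z`, `DS = B z`.  The induced
#' dynamics is \eqn{\dot z = (LA + MB) z}; the reconstructed potentials are
#' the quadratic forms \eqn{E = \tfrac12 z^\top \mathrm{sym}(A) z} and
#' \eqn{S = \tfrac12 z^\top \mathrm{sym}(B) z} (additive constants fixed to
#' zero at `z = 0`).
#'
#' For a single window pass plain matrices; fitted models are piecewise with
#' closed-open index windows (the state at a boundary belongs to the later
#' window).
#'
#' @param L,M,A,B d x d matrices (single-window form), or `windows` a list of
#'   lists with those elements.
#' @param dt time step, seconds.
#' @param theta implicitness of the linear update: 1/2 (midpoint discrete
#'   gradient; conserves quadratic invariants exactly) or 1 (backward Euler).
#' @param windows optional list of per-window `list(L, M, A, B, ...)`.
#' @param boundaries integer start indices of each window in the fitted
#'   trajectory (first element 1).
#' @param n_total number of samples of the fitted trajectory.
#' @param channels optional channel names of the state vector.
#' @param scales optional per-channel scale factors mapping physical to model
#'   coordinates.
#' @param check validate skewness/PSD-ness on construction.
#' @return object of class `generic_model`.
#' @export
generic_model <- function(L = NULL, M = NULL, A = NULL, B = NULL, dt,
                          theta = 0.5, windows = NULL, boundaries = NULL,
                          n_total = NULL, channels = NULL, scales = NULL,
                          check = TRUE) {
  if (is.null(windows)) {
    d <- nrow(A)
    if (is.null(L)) L <- matrix(0, d, d)
    if (is.null(M)) M <- matrix(0, d, d)
    if (is.null(B)) B <- matrix(0, d, d)
    windows <- list(list(L = L, M = M, A = A, B = B))
    boundaries <- 1L
  }
  d <- nrow(windows[[1]]$A)
  m <- structure(list(windows = windows, d = d, dt = dt, theta = theta,
                      boundaries = as.integer(boundaries), n_total = n_total,
                      channels = channels, scales = scales),
                 class = "generic_model")
  if (check) {
    chk <- model_structure_check(m)
    if (chk$skew > 1e-10)
      warning(sprintf("L deviates from skew-symmetry by %.3g", chk$skew))
    if (chk$m_min_eig < -1e-8)
      warning(sprintf("M has eigenvalue %.3g below zero", chk$m_min_eig))
  }
  m
}

#' @export
print.generic_model <- function(x, ...) {
  cat(sprintf("GENERIC model: d = %d, %d window(s), dt = %g s, theta = %g\n",
              x$d, length(x$windows), x$dt, x$theta))
  chk <- model_structure_check(x)
  cat(sprintf("  max |L + t(L)| = %.2e, min eig(M) = %.2e\n",
              chk$skew, chk$m_min_eig))
  invisible(x)
}

# worst-case structural deviations across windows
model_structure_check <- function(model) {
  skew <- 0; m_min <- 0
  for (w in model$windows) {
    skew <- max(skew, max(abs(w$L + t(w$L))))
    if (any(w$M != 0)) {
      ev <- eigen(sym_part(w$M), symmetric = TRUE, only.values = TRUE)$values
      m_min <- min(m_min, min(ev))
      skew <- max(skew, 0)
    }
  }
  list(skew = skew, m_min_eig = m_min)
}

generator_of <- function(w) w$L %*% w$A + w$M %*% w$B

#' Degeneracy residuals of a GENERIC model at data points
#'
#' The degeneracy conditions \eqn{L \nabla S = 0} and \eqn{M \nabla E = 0}
#' are what turn skewness and positive semidefiniteness into energy
#' conservation and entropy production.  With matrix gradients they read
#' `L B z = 0` and `M A z = 0`; this evaluates both over the rows of `Z`
#' (windowed for piecewise models) and reports the worst 2-norms, raw and
#' relative to `||G||_F ||z||`.
#'
#' @param model a `generic_model`.
#' @param Z state matrix (samples in rows, model coordinates).
#' @return list with `LB`, `MA` (raw norms) and `LB_rel`, `MA_rel`.
#' @export
degeneracy_residuals <- function(model, Z) {
  Z <- rbind(Z)
  if (ncol(Z) != model$d) stop("dimension mismatch between model and states")
  worst <- c(LB = 0, MA = 0, LB_rel = 0, MA_rel = 0)
  bnds <- c(model$boundaries, nrow(Z) + 1L)
  for (wi in seq_along(model$windows)) {
    w <- model$windows[[wi]]
    rows <- seq.int(bnds[wi], min(bnds[wi + 1] - 1L, nrow(Z)))
    if (length(rows) == 0) next
    Zw <- Z[rows, , drop = FALSE]
    gnorm <- sqrt(sum(generator_of(w)^2))
    rl <- sqrt(rowSums((Zw %*% t(w$L %*% w$B))^2))
    rm <- sqrt(rowSums((Zw %*% t(w$M %*% w$A))^2))
    znorm <- pmax(sqrt(rowSums(Zw^2)), .Machine$double.eps)
    worst["LB"] <- max(worst["LB"], rl)
    worst["MA"] <- max(worst["MA"], rm)
    if (gnorm > 0) {
      worst["LB_rel"] <- max(worst["LB_rel"], rl / (gnorm * znorm))
      worst["MA_rel"] <- max(worst["MA_rel"], rm / (gnorm * znorm))
    }
  }
  as.list(worst)
}

# one-window propagator of the theta-discretised linear update
# (I/dt - theta K) z_{n+1} = (I/dt + (1-theta) K) z_n
propagator <- function(K, dt, theta) {
  d <- nrow(K)
  lhs <- diag(d) / dt - theta * K
  rc <- rcond(lhs)
  if (rc < 1e-14)
    stop(sprintf("singular integration system (rcond = %.2e)", rc))
  solve(lhs, diag(d) / dt + (1 - theta) * K)
}

#' Advance a GENERIC model by one time step
#'
#' Solves the linear implicit update
#' \eqn{(I/\Delta t - \theta K)\, z_{n+1} = (I/\Delta t + (1-\theta) K)\,
#' z_n} with \eqn{K = LA + MB}.  With `theta = 1/2` this is the midpoint
#' (discrete-gradient) scheme, which conserves the quadratic energy exactly
#' for conservative models.
#'
#' @param model a single-window `generic_model` (or a plain generator matrix
#'   `K`).
#' @param z state vector.
#' @param dt,theta step and scheme (taken from the model when available).
#' @export
generic_step <- function(model, z, dt = NULL, theta = NULL) {
  if (is.matrix(model)) {
    K <- model
  } else {
    K <- generator_of(model$windows[[1]])
    if (is.null(dt)) dt <- model$dt
    if (is.null(theta)) theta <- model$theta
  }
  drop(propagator(K, dt, theta) %*% z)
}

#' Integrate a GENERIC model
#'
#' Rolls out the theta-discretised dynamics.  For piecewise models each
#' window uses its own matrices; when `restarts` is supplied (a matrix of
#' measured states at the window start indices) integration restarts there,
#' which is the reconstruction convention used to score fitted models.
#'
#' @param model a `generic_model`.
#' @param z0 initial state (model coordinates).
#' @param n_steps number of steps; defaults to the fitted trajectory length.
#' @param restarts optional `n_windows x d` matrix of window-start states.
#' @return `(n_steps + 1) x d` matrix of states.
#' @export
integrate_generic <- function(model, z0, n_steps = NULL, restarts = NULL) {
  if (is.null(n_steps)) {
    if (is.null(model$n_total)) stop("n_steps required for this model")
    n_steps <- model$n_total - 1L
  }
  d <- model$d
  Z <- matrix(0, n_steps + 1L, d)
  bnds <- c(model$boundaries, n_steps + 2L)
  z <- as.numeric(z0)
  Z[1, ] <- z
  for (wi in seq_along(model$windows)) {
    first <- bnds[wi]; last <- min(bnds[wi + 1] - 1L, n_steps + 1L)
    if (first > n_steps + 1L) break
    if (!is.null(restarts)) z <- restarts[wi, ]
    Z[first, ] <- z
    if (last > first) {
      Phi <- propagator(generator_of(model$windows[[wi]]), model$dt,
                        model$theta)
      for (k in (first + 1L):last) {
        z <- drop(Phi %*% z)
        Z[k, ] <- z
      }
    }
  }
  colnames(Z) <- model$channels
  Z
}

#' Energy and entropy increments along a trajectory
#'
#' Evaluates the reconstructed quadratic potentials
#' \eqn{E = \tfrac12 z^\top \mathrm{sym}(A) z},
#' \eqn{S = \tfrac12 z^\top \mathrm{sym}(B) z} along `Z` and returns their
#' per-step increments within each window (potentials are per-window objects,
#' so increments across a window boundary are not meaningful and are
#' dropped).  For a conservative window (`M = 0`) the midpoint scheme keeps
#' `dE` at round-off; for PSD `M` with satisfied degeneracy conditions `dS`
#' is non-negative up to round-off.
#'
#' @param Z trajectory matrix (model coordinates).
#' @param model the `generic_model` that generated it.
#' @return data frame with columns `window`, `step`, `dE`, `dS`, plus
#'   attributes `E_scale` and `S_scale` (max absolute potential values, for
#'   relative tolerances).
#' @export
energy_entropy_audit <- function(Z, model) {
  Z <- rbind(Z)
  bnds <- c(model$boundaries, nrow(Z) + 1L)
  out <- NULL
  E_scale <- 0; S_scale <- 0
  for (wi in seq_along(model$windows)) {
    w <- model$windows[[wi]]
    rows <- seq.int(bnds[wi], min(bnds[wi + 1] - 1L, nrow(Z)))
    if (length(rows) < 2) next
    Zw <- Z[rows, , drop = FALSE]
    E <- 0.5 * rowSums((Zw %*% sym_part(w$A)) * Zw)
    S <- 0.5 * rowSums((Zw %*% sym_part(w$B)) * Zw)
    E_scale <- max(E_scale, abs(E)); S_scale <- max(S_scale, abs(S))
    out <- rbind(out, data.frame(window = wi, step = rows[-length(rows)],
                                 dE = diff(E), dS = diff(S)))
  }
  structure(out, E_scale = E_scale, S_scale = S_scale)
}

#' Thermodynamic admissibility report for a model
#'
#' Checks the three structural guarantees on a fitted or interpolated model:
#' exact skewness of `L`, positive semidefiniteness of `M`, and degeneracy
#' residuals at the supplied data points.
#'
#' @param model a `generic_model`.
#' @param Z data matrix in model coordinates (defaults to the fitted states
#'   stored in the model windows when available).
#' @param tol_skew,tol_psd,tol_deg tolerances for the three checks.
#' @return list with the measured deviations and a logical `ok`.
#' @export
admissibility <- function(model, Z, tol_skew = 1e-12, tol_psd = 1e-10,
                          tol_deg = 1e-6) {
  chk <- model_structure_check(model)
  deg <- degeneracy_residuals(model, Z)
  ok <- chk$skew <= tol_skew && chk$m_min_eig >= -tol_psd &&
    max(deg$LB_rel, deg$MA_rel) <= tol_deg
  list(skew = chk$skew, m_min_eig = chk$m_min_eig,
       deg_LB_rel = deg$LB_rel, deg_MA_rel = deg$MA_rel, ok = ok)
}
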