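# --- parameterisations of structured matrices ------------------------------
# vec-basis matrices mapping free parameter vectors to vec(L) (skew) and
# vec(A) (symmetric); d is small (<= 8) so dense bases are fine.

skew_basis <- function(d) {
  ij <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  K <- matrix(0, d * d, nrow(ij))
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    K[(j - 1) * d + i, k] <- 1
    K[(i - 1) * d + j, k] <- -1
  }
  K
}

sym_basis <- function(d) {
  ij <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  K <- matrix(0, d * d, nrow(ij))
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    K[(j - 1) * d + i, k] <- 1
    if (i != j) K[(i - 1) * d + j, k] <- 1
  }
  K
}

mat_from <- function(par, basis, d) matrix(basis %*% par, d, d)

clip_psd <- function(M) {
  es <- eigen(sym_part(M), symmetric = TRUE)
  ev <- pmax(es$values, 0)
  es$vectors %*% (ev * t(es$vectors))
}

# orthonormal basis of the row space of Z (the data span used for data-
# weighted fitting and for the degeneracy constraints); the relative
# singular values are attached as direction weights
span_basis <- function(Z, tol = 1e-8) {
  sv <- svd(t(Z))
  keep <- sv$d > tol * sv$d[1]
  structure(sv$u[, keep, drop = FALSE], weights = sv$d[keep] / sv$d[1])
}

# equality-constrained least squares: min ||C x - y||^2 s.t. E x = 0,
# solved by restriction to the (numerical) null space of E.  The null-space
# threshold is absolute on the caller's problem scale, not relative to E:
# when the operator generating the constraints is itself numerically zero
# (e.g. L ~ 1e-9 in a purely dissipative split) the constraints are vacuous
# and must not be enforced.
constrained_ls <- function(C, y, E, tol = 1e-8, scale = 1) {
  if (is.null(E) || nrow(E) == 0) return(qr.solve(C, y))
  p <- ncol(E)
  sv <- svd(E, nu = 0, nv = p)
  dvals <- c(sv$d, rep(0, p - length(sv$d)))
  keep <- dvals <= tol * scale
  N <- sv$v[, keep, drop = FALSE]
  if (ncol(N) == 0) return(numeric(ncol(C)))
  drop(N %*% qr.solve(C %*% N, y))
}

# --- regression of the generator -------------------------------------------

#' Assemble the finite-difference regression system for one window
#'
#' For a trajectory window the theta-discretised dynamics
#' \eqn{(z_{n+1} - z_n)/\Delta t = G\,(\theta z_{n+1} + (1-\theta) z_n)}
#' is linear in the generator `G = L A + M B`.  This returns the feature and
#' target matrices of that least-squares system; on noise-free linear
#' dynamics produced with the same scheme its exact solution recovers `G`.
#'
#' @param Z window state matrix (samples in rows), at least `d + 1` rows.
#' @param dt uniform time step.
#' @param theta scheme parameter (1/2 midpoint, 1 backward Euler).
#' @return list with `X` (features) and `Y` (finite-difference targets).
#' @export
assemble_regression <- function(Z, dt, theta = 0.5) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < ncol(Z) + 1L)
    stop(sprintf("window under-determined: need at least %d samples, got %d",
                 ncol(Z) + 1L, n))
  Z1 <- Z[-n, , drop = FALSE]
  Z2 <- Z[-1, , drop = FALSE]
  list(X = theta * Z2 + (1 - theta) * Z1, Y = (Z2 - Z1) / dt)
}

#' Ridge least-squares estimate of the generator matrix
#'
#' @param X,Y matrices from [assemble_regression()].
#' @param ridge ridge weight, relative to the mean feature variance.
#' @return the `d x d` generator estimate `G`.
#' @export
regress_generator <- function(X, Y, ridge = 1e-8) {
  XtX <- crossprod(X)
  lam <- ridge * mean(diag(XtX))
  t(solve(XtX + lam * diag(ncol(X)), crossprod(X, Y)))
}

# --- structure-preserving split of the generator ---------------------------

# Exact Hamiltonian representation of G on the data span: find L skew and A
# symmetric with L A Q = G Q =: Y.  Parameterise the span action T = A Q
# directly; a symmetric A with that action exists iff t(Q) T is symmetric,
# and a skew L with L T = Y exists iff t(T) Y + t(Y) T = 0 -- both *linear*
# in T, so the feasible T form a null space.  Inside it, the representative
# minimising the off-span anchor ||L A - G|| (with a conditioning guard on
# T) is picked by a small derivative-free optimisation, and L is built in
# closed form:  with W = (T'T)^-1,
#   L = Y W T' - T W Y' - T W (T'Y) W T'
# is skew and satisfies L T = Y exactly.  Exactness is imposed on the
# leading data directions (relative singular value >= lead_tol) -- richer
# spans admit no Hamiltonian representation -- and the residual on the weak
# tail directions enters the data-weighted objective instead.  Returns NULL
# when even the leading directions admit no representation.
split_conservative_exact <- function(G, Z, full_weight = 0.05,
                                     lead_tol = 1e-3, re_cap = Inf,
                                     spec_weight = 10, rc_force = NULL) {
  d <- nrow(G)
  gnorm <- sqrt(sum(G^2))
  if (gnorm == 0) return(NULL)
  Gs <- G / gnorm
  Q <- span_basis(Z)
  wq <- attr(Q, "weights")
  r <- ncol(Q)
  Qw <- Q * rep(wq, each = d)
  Poff <- diag(d) - Q %*% t(Q)
  denom <- max(sum((Gs %*% Qw)^2), .Machine$double.eps)
  wres <- function(L, A) {
    E <- L %*% A - Gs
    sqrt(sum((E %*% Qw)^2) / denom)
  }

  rc_max <- max(1L, min(sum(wq >= lead_tol), d - 1L))
  if (!is.null(rc_force)) rc_max <- max(1L, min(rc_force, rc_max))
  for (rc in seq(rc_max, 1L)) {
    Qc <- Q[, seq_len(rc), drop = FALSE]
    Y <- Gs %*% Qc
    n_un <- d * rc
    sym_pairs <- which(upper.tri(matrix(0, rc, rc)), arr.ind = TRUE)
    skew_pairs <- which(upper.tri(matrix(0, rc, rc), diag = TRUE),
                        arr.ind = TRUE)
    Cmat <- matrix(0, nrow(sym_pairs) + nrow(skew_pairs), n_un)
    Tk <- matrix(0, d, rc)
    for (k in seq_len(n_un)) {
      Tk[k] <- 1
      S1 <- crossprod(Qc, Tk)                    # symmetric-A conditions
      S2 <- crossprod(Tk, Y) + crossprod(Y, Tk)  # skew-L conditions
      Cmat[, k] <- c(if (rc > 1) S1[sym_pairs] - t(S1)[sym_pairs],
                     S2[skew_pairs])
      Tk[k] <- 0
    }
    sv <- svd(Cmat, nu = 0, nv = n_un)
    dv <- c(sv$d, rep(0, n_un - length(sv$d)))
    N <- sv$v[, dv <= 1e-10 * max(dv[1], 1), drop = FALSE]
    if (ncol(N) == 0) next

    build <- function(u) {
      nu <- sqrt(sum(u^2))
      if (nu == 0) return(NULL)
      T <- matrix(N %*% (u / nu), d, rc)
      svt <- svd(T, nu = 0, nv = 0)$d
      if (svt[rc] < 1e-5 * max(svt[1], 1e-12)) return(NULL)
      W <- solve(crossprod(T))
      TW <- T %*% W
      L <- Y %*% t(TW) - TW %*% t(Y) - TW %*% crossprod(T, Y) %*% t(TW)
      A <- T %*% t(Qc) + Qc %*% t(T) - Qc %*% crossprod(Qc, T) %*% t(Qc)
      list(L = L, A = A)
    }
    obj <- function(u) {
      b <- build(u)
      if (is.null(b)) return(1e8)
      K <- b$L %*% b$A
      E <- K - Gs
      pen <- if (is.finite(re_cap)) {
        # Bendixson bound: Re(eig(K)) <= max eig(sym(K)); the symmetric
        # eigenproblem is far cheaper inside the search loop
        ex <- eigen(sym_part(K), symmetric = TRUE,
                    only.values = TRUE)$values[1] - re_cap
        spec_weight * max(ex, 0)^2
      } else 0
      sum((E %*% Qw)^2) + full_weight * sum(E^2) + pen
    }
    u0 <- drop(crossprod(N, as.numeric(Qc)))
    if (sqrt(sum(u0^2)) < 1e-10) u0 <- rep(1, ncol(N))
    if (is.null(build(u0))) {
      # deterministic fallback starts: family basis directions and their sum
      cands <- c(lapply(seq_len(min(ncol(N), 10L)),
                        function(j) replace(rep(0, ncol(N)), j, 1)),
                 list(rep(1, ncol(N))))
      found <- FALSE
      for (u_try in cands) {
        if (!is.null(build(u_try))) { u0 <- u_try; found <- TRUE; break }
      }
      if (!found) next
    }
    op <- optim(u0, obj, method = "Nelder-Mead",
                control = list(maxit = 800, reltol = 1e-12))
    b <- build(op$par)
    if (is.null(b)) next
    L <- (b$L - t(b$L)) / 2; A <- (b$A + t(b$A)) / 2
    res <- wres(L, A)
    if (!is.finite(res) || res > 1 || sqrt(sum(L^2)) > 1e3) next
    sa <- sqrt(sum(A^2))
    if (sa > 0) { A <- A / sa; L <- L * sa }
    return(list(L = L * gnorm, M = matrix(0, d, d), A = A,
                B = matrix(0, d, d), residual = res, iterations = 0L,
                converged = TRUE))
  }
  NULL
}

#' Split a generator into thermodynamically admissible factors
#'
#' Decomposes a regressed generator `G` into `L A + M B` with `L`
#' skew-symmetric, `M` symmetric positive semidefinite, and `A`, `B`
#' symmetric, enforcing the degeneracy conditions `L B z = 0`, `M A z = 0` on
#' the span of the window data.  The decomposition is not identifiable from
#' one trajectory (only the product acts on data); the gauge is fixed by
#' symmetric `A`, `B`, unit Frobenius norm of `A` absorbed into `L`, and a
#' deterministic initialisation from the skew/symmetric parts of `G`.
#'
#' The solver alternates penalised least-squares steps in `(L, M)` and
#' `(A, B)` (degeneracy as a quadratic penalty, eigenvalue clipping of `M`),
#' optionally polishes with BFGS, and finishes with equality-constrained
#' steps that impose the degeneracy conditions on the data span exactly.
#' Fitting is span-weighted: the residual of the product is measured on the
#' subspace actually visited by the data, with a small full-matrix anchor for
#' off-span behaviour.
#'
#' @param G square generator matrix.
#' @param Z data matrix whose row span carries the degeneracy constraints
#'   (defaults to the full space).
#' @param conservative force `M = B = 0` (purely Hamiltonian split).
#' @param deg_weight quadratic penalty weight on the degeneracy residuals.
#' @param full_weight weight of the full-matrix anchor term.
#' @param max_iter alternating iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param ridge parameter ridge for the generator regression scale.
#' @param mag_ridge Frobenius-norm penalty on the factors in the inner
#'   least-squares solves; keeps operator norms of order one so that the
#'   degeneracy conditions are not amplified off the data span.
#' @param polish run a BFGS polish of the span residual between the
#'   alternating and the constrained phases.
#' @param init optional starting point, a list with `L`, `M`, `A`, `B` (used
#'   when re-projecting interpolated models onto the admissible set).
#' @return list with `L`, `M`, `A`, `B`, the data-weighted relative span
#'   residual `residual`, `iterations`, and `converged`.
#' @export
split_generator <- function(G, Z = NULL, conservative = FALSE,
                            deg_weight = 1e3, full_weight = 0.05,
                            max_iter = 40L, tol = 1e-10, ridge = 1e-8,
                            mag_ridge = 1e-5, polish = TRUE, init = NULL,
                            dt = NULL, theta = 0.5, score_target = NULL) {
  d <- nrow(G)
  if (is.null(Z)) Z <- diag(d)
  gnorm <- sqrt(sum(G^2))
  if (gnorm == 0)
    return(list(L = matrix(0, d, d), M = matrix(0, d, d),
                A = matrix(0, d, d), B = matrix(0, d, d),
                residual = 0, iterations = 0L, converged = TRUE))
  Gs <- G / gnorm
  Q <- span_basis(Z)
  r <- ncol(Q)
  # product accuracy is weighted by the data content of each span direction;
  # the full-matrix anchor keeps weakly excited and off-span directions
  # bounded; degeneracy constraints are unweighted (they must hold at every
  # datum)
  Qw <- Q * rep(attr(Q, "weights"), each = d)
  Ksk <- skew_basis(d)
  Ksy <- sym_basis(d)
  Id <- diag(d)
  Poff <- Id - Q %*% t(Q)
  wf <- sqrt(full_weight)
  wd <- sqrt(deg_weight)

  span_res <- function(L, M, A, B) {
    E <- (L %*% A + M %*% B - Gs)
    sqrt(sum((E %*% Qw)^2) / max(sum((Gs %*% Qw)^2), .Machine$double.eps))
  }

  if (!is.null(init)) {
    L <- init$L / gnorm; A <- init$A
    M <- clip_psd(init$M) / gnorm; B <- init$B
    if (conservative) M <- B <- matrix(0, d, d)
  } else {
    # deterministic initialisation: exact for stable dissipative generators
    L <- skew_part(Gs); A <- Id
    if (conservative) {
      M <- B <- matrix(0, d, d)
    } else {
      M <- clip_psd(-sym_part(Gs)); B <- -Id
    }
  }

  objective <- function(L, M, A, B) {
    E <- L %*% A + M %*% B - Gs
    sum((E %*% Qw)^2) + full_weight * sum(E^2) +
      if (conservative) 0 else
        deg_weight * (sum((L %*% B %*% Q)^2) + sum((M %*% A %*% Q)^2))
  }

  solve_LM <- function(A, B, rho = mag_ridge) {
    AQw <- A %*% Qw; BQw <- B %*% Qw
    AQd <- A %*% Q;  BQd <- B %*% Q
    rows_l <- rbind(t(AQw) %x% Id, wf * (t(A) %x% Id)) %*% Ksk
    tgt <- c(as.numeric(Gs %*% Qw), wf * as.numeric(Gs))
    if (!conservative) {
      rows_m <- rbind(t(BQw) %x% Id, wf * (t(B) %x% Id)) %*% Ksy
      pen <- rbind(cbind(wd * ((t(BQd) %x% Id) %*% Ksk),
                         matrix(0, d * r, ncol(Ksy))),
                   cbind(matrix(0, d * r, ncol(Ksk)),
                         wd * ((t(AQd) %x% Id) %*% Ksy)))
      C <- rbind(cbind(rows_l, rows_m), pen)
      y <- c(tgt, rep(0, 2 * d * r))
      np <- ncol(C)
      C <- rbind(C, sqrt(rho) * diag(np))
      y <- c(y, rep(0, np))
      x <- qr.solve(C, y)
      L <- mat_from(x[seq_len(ncol(Ksk))], Ksk, d)
      M <- clip_psd(mat_from(x[-seq_len(ncol(Ksk))], Ksy, d))
      list(L = L, M = M)
    } else {
      np <- ncol(rows_l)
      C <- rbind(rows_l, sqrt(rho) * diag(np))
      y <- c(tgt, rep(0, np))
      list(L = mat_from(qr.solve(C, y), Ksk, d), M = matrix(0, d, d))
    }
  }

  solve_AB <- function(L, M, rho = mag_ridge) {
    rows_a <- rbind(t(Qw) %x% L, wf * (Id %x% L)) %*% Ksy
    tgt <- c(as.numeric(Gs %*% Qw), wf * as.numeric(Gs))
    if (!conservative) {
      rows_b <- rbind(t(Qw) %x% M, wf * (Id %x% M)) %*% Ksy
      pen <- rbind(cbind(wd * ((t(Q) %x% M) %*% Ksy),
                         matrix(0, d * r, ncol(Ksy))),
                   cbind(matrix(0, d * r, ncol(Ksy)),
                         wd * ((t(Q) %x% L) %*% Ksy)))
      C <- rbind(cbind(rows_a, rows_b), pen)
      y <- c(tgt, rep(0, 2 * d * r))
      np <- ncol(C)
      C <- rbind(C, sqrt(rho) * diag(np))
      y <- c(y, rep(0, np))
      x <- qr.solve(C, y)
      list(A = mat_from(x[seq_len(ncol(Ksy))], Ksy, d),
           B = mat_from(x[-seq_len(ncol(Ksy))], Ksy, d))
    } else {
      np <- ncol(rows_a)
      C <- rbind(rows_a, sqrt(rho) * diag(np))
      y <- c(tgt, rep(0, np))
      list(A = mat_from(qr.solve(C, y), Ksy, d), B = matrix(0, d, d))
    }
  }

  # update (A, B) first: the initial (L, M) carry the skew/symmetric parts of
  # G, and re-solving the gradients under the degeneracy penalty before
  # touching the operators prevents the penalty from collapsing L and M.
  # clip_psd breaks strict monotonicity, so the best iterate is retained.
  obj_prev <- objective(L, M, A, B)
  best <- list(obj = obj_prev, L = L, M = M, A = A, B = B)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    ab <- solve_AB(L, M); A <- ab$A; B <- ab$B
    lm <- solve_LM(A, B); L <- lm$L; M <- lm$M
    obj <- objective(L, M, A, B)
    if (obj < best$obj) best <- list(obj = obj, L = L, M = M, A = A, B = B)
    if (abs(obj_prev - obj) <= tol * max(obj_prev, 1e-300)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  L <- best$L; M <- best$M; A <- best$A; B <- best$B
  obj_prev <- best$obj

  # debias pass: once the structure has settled, relax the magnitude ridge
  # in proportion to the attained misfit, so exactly representable
  # generators are recovered to solver precision while ill-fitting windows
  # keep the full regularisation
  mr_eff <- max(1e-12, min(mag_ridge, obj_prev))
  if (mr_eff < mag_ridge) {
    ab <- solve_AB(L, M, rho = mr_eff)
    lm <- solve_LM(ab$A, ab$B, rho = mr_eff)
    obj_db <- objective(lm$L, lm$M, ab$A, ab$B)
    if (is.finite(obj_db) && obj_db < obj_prev) {
      A <- ab$A; B <- ab$B; L <- lm$L; M <- lm$M
      obj_prev <- obj_db
    }
  }

  if (polish) {
    # BFGS with analytic gradients on the bilinear problem; the friction
    # operator is parameterised as M = C^2 with C symmetric, so positive
    # semidefiniteness is built into the search space.
    nl <- ncol(Ksk); na <- ncol(Ksy)
    Pq <- Q %*% t(Q)                       # degeneracy weight (unweighted)
    W <- Qw %*% t(Qw) + full_weight * diag(d)  # data-weighted product term
    skew_par <- function(Lm) (crossprod(Ksk, as.numeric(Lm)) / 2)[, 1]
    # parameter extraction consistent with sym_basis column order
    sym_par <- function(Sm) {
      ij <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
      Sm[ij]
    }
    grad_sym <- function(Gm) {
      ij <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
      ifelse(ij[, 1] == ij[, 2], Gm[ij], Gm[ij] + t(Gm)[ij])
    }
    grad_skew <- function(Gm) {
      ij <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
      Gm[ij] - t(Gm)[ij]
    }
    unpack <- function(par) {
      L <- mat_from(par[seq_len(nl)], Ksk, d)
      A <- mat_from(par[nl + seq_len(na)], Ksy, d)
      if (conservative) {
        list(L = L, A = A, Cm = matrix(0, d, d), B = matrix(0, d, d))
      } else {
        list(L = L, A = A,
             Cm = mat_from(par[nl + na + seq_len(na)], Ksy, d),
             B = mat_from(par[nl + 2 * na + seq_len(na)], Ksy, d))
      }
    }
    fn <- function(par) {
      p <- unpack(par)
      M <- p$Cm %*% p$Cm
      E <- p$L %*% p$A + M %*% p$B - Gs
      sum((E %*% Qw)^2) + full_weight * sum(E^2) + mag_ridge * sum(par^2) +
        if (conservative) 0 else
          deg_weight * (sum((p$L %*% p$B %*% Q)^2) +
                        sum((M %*% p$A %*% Q)^2))
    }
    gr <- function(par) {
      p <- unpack(par)
      M <- p$Cm %*% p$Cm
      E <- p$L %*% p$A + M %*% p$B - Gs
      EW <- E %*% W
      gL <- 2 * EW %*% t(p$A)
      gA <- 2 * t(p$L) %*% EW
      if (!conservative) {
        BPB <- p$B %*% Pq %*% t(p$B)
        APA <- p$A %*% Pq %*% t(p$A)
        gL <- gL + 2 * deg_weight * p$L %*% BPB
        gA <- gA + 2 * deg_weight * M %*% M %*% p$A %*% Pq
        gM <- 2 * EW %*% t(p$B) + 2 * deg_weight * M %*% APA
        gC <- gM %*% p$Cm + p$Cm %*% gM
        gB <- 2 * M %*% EW + 2 * deg_weight * t(p$L) %*% p$L %*% p$B %*% Pq
        c(grad_skew(gL), grad_sym(gA), grad_sym(gC), grad_sym(gB)) +
          2 * mag_ridge * par
      } else {
        c(grad_skew(gL), grad_sym(gA)) + 2 * mag_ridge * par
      }
    }
    Cm0 <- if (conservative) NULL else {
      es <- eigen(sym_part(M), symmetric = TRUE)
      es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
    }
    par0 <- c(skew_par(L), sym_par(A),
              if (!conservative) c(sym_par(Cm0), sym_par(B)))
    op <- optim(par0, fn, gr, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    p <- unpack(op$par)
    cand <- list(L = p$L, M = p$Cm %*% p$Cm, A = p$A, B = p$B)
    if (objective(cand$L, cand$M, cand$A, cand$B) <= obj_prev) {
      L <- cand$L; M <- cand$M; A <- cand$A; B <- cand$B
    }
  }

  if (!conservative) {
    # final phase: degeneracy as hard *matrix-level* equality constraints
    # (L B = 0, M A = 0).  This is stricter than the pointwise conditions,
    # but it is what makes the audits exact along any trajectory: with
    # symmetric A, B it gives z' A (L A + M B) z = 0 and
    # z' B (L A + M B) z = z' B M B z >= 0 identically, not just on the
    # fitted data span.
    mr2 <- max(1e-12, min(mag_ridge, obj_prev))
    for (pass in 1:2) {
      # A given (L, M): minimise span+anchor residual s.t. M A Q = 0
      RA <- Gs - M %*% B
      C <- rbind(t(Qw) %x% L, wf * (Id %x% L),
                 sqrt(mr2) * diag(d * d)) %*% cbind(Ksy)
      y <- c(as.numeric(RA %*% Qw), wf * as.numeric(RA), rep(0, d * d))
      A <- mat_from(constrained_ls(C, y, (Id %x% M) %*% Ksy), Ksy, d)
      # B given (L, M): s.t. L B Q = 0
      RB <- Gs - L %*% A
      C <- rbind(t(Qw) %x% M, wf * (Id %x% M),
                 sqrt(mr2) * diag(d * d)) %*% cbind(Ksy)
      y <- c(as.numeric(RB %*% Qw), wf * as.numeric(RB), rep(0, d * d))
      B <- mat_from(constrained_ls(C, y, (Id %x% L) %*% Ksy), Ksy, d)
      # L given (A, B): s.t. L (B Q) = 0
      RL <- Gs - M %*% B
      C <- rbind(t(A %*% Qw) %x% Id, wf * (t(A) %x% Id),
                 sqrt(mr2) * diag(d * d)) %*% cbind(Ksk)
      y <- c(as.numeric(RL %*% Qw), wf * as.numeric(RL), rep(0, d * d))
      L <- mat_from(constrained_ls(C, y, (t(B) %x% Id) %*% Ksk), Ksk, d)
      # M given (A, B): s.t. M (A Q) = 0, then PSD clip (null space of the
      # clip contains A Q, so the constraint survives the projection)
      RM <- Gs - L %*% A
      C <- rbind(t(B %*% Qw) %x% Id, wf * (t(B) %x% Id),
                 sqrt(mr2) * diag(d * d)) %*% cbind(Ksy)
      y <- c(as.numeric(RM %*% Qw), wf * as.numeric(RM), rep(0, d * d))
      M <- clip_psd(mat_from(constrained_ls(C, y, (t(A) %x% Id) %*% Ksy),
                             Ksy, d))
    }
  }

  # gauge: a potential whose operator vanished is undetermined - set its
  # gradient to zero so vestigial entropy (or energy) gradients cannot
  # violate the degeneracy conditions
  if (sqrt(sum(M^2)) <= 1e-10) { M[] <- 0; B[] <- 0 }
  if (sqrt(sum(L^2)) <= 1e-10) { L[] <- 0; A[] <- 0 }
  # gauge: unit Frobenius norm of A (and B) absorbed into L (and M)
  sa <- sqrt(sum(A^2))
  if (sa > 0) { A <- A / sa; L <- L * sa }
  sb <- sqrt(sum(B^2))
  if (sb > 0) { B <- B / sb; M <- M * sb }

  out <- list(L = L * gnorm, M = M * gnorm, A = A, B = B,
              residual = span_res(L, M, A, B), iterations = it,
              converged = converged)

  # spectral cap used to steer the Hamiltonian construction: an admissible
  # representation should not introduce growth rates far beyond the rate
  # scale the regression itself saw (the magnitude is used because a
  # Hamiltonian representation of a relaxation mode -1/tau legitimately
  # carries the mirrored rate +1/tau)
  re_cap <- 1.5 * max(abs(eigen(sym_part(Gs), symmetric = TRUE,
                               only.values = TRUE)$values)) + 0.02

  # candidate 2: exact Hamiltonian representation on the leading data span
  # (loses exactly when the dissipative structure is real)
  ce <- split_conservative_exact(G, if (is.null(Z)) diag(d) else Z,
                                 full_weight, re_cap = re_cap)
  # candidate 3: guaranteed-stable purely dissipative approximation
  # (degeneracy holds identically since L = A = 0)
  Mfb <- clip_psd(-sym_part(Gs))
  fb <- list(L = matrix(0, d, d), M = Mfb * sqrt(d) * gnorm,
             A = matrix(0, d, d), B = -Id / sqrt(d),
             residual = span_res(matrix(0, d, d), Mfb * sqrt(d),
                                 matrix(0, d, d), -Id / sqrt(d)),
             iterations = 0L, converged = TRUE)

  cands <- Filter(Negate(is.null), list(out, ce, fb))
  # selection: when the time grid is known, candidates are scored by the
  # quantity the model is for -- the relative error of their integrated
  # trajectory against the target trajectory (the window data for fits, or
  # the unconstrained generator's own trajectory for re-projections); this
  # penalises both span misfit and spurious growth modes.  Without a time
  # grid the data-weighted span residual decides.
  if (!is.null(dt) && !is.null(Z) && nrow(Z) > 2) {
    target <- if (is.null(score_target)) Z else score_target
    n_st <- nrow(target) - 1L
    tnorm <- sqrt(sum(target^2))
    traj_err <- function(cd) {
      K <- cd$L %*% cd$A + cd$M %*% cd$B
      Phi <- tryCatch(propagator(K, dt, theta), error = function(e) NULL)
      if (is.null(Phi)) return(Inf)
      z <- target[1, ]
      err2 <- 0
      for (k in seq_len(n_st)) {
        z <- Phi %*% z
        err2 <- err2 + sum((z - target[k + 1L, ])^2)
        if (!is.finite(err2)) return(Inf)
      }
      sqrt(err2) / tnorm
    }
    score <- vapply(cands, traj_err, 0)
    if (min(score) > 0.02) {
      # escalation: when no candidate tracks the target well, noisy content
      # in the weak span directions is usually to blame; exact conservative
      # representations restricted to the leading two or three directions
      # bound the damage by the span-tail content
      for (rc in c(3L, 2L)) {
        ce_rc <- split_conservative_exact(G, if (is.null(Z)) diag(d) else Z,
                                          full_weight, re_cap = re_cap,
                                          rc_force = rc)
        if (!is.null(ce_rc)) {
          cands <- c(cands, list(ce_rc))
          score <- c(score, traj_err(ce_rc))
        }
      }
    }
    if (all(!is.finite(score)))
      score <- vapply(cands, `[[`, 0, "residual")
  } else {
    score <- vapply(cands, `[[`, 0, "residual")
  }
  cands[[which.min(score)]]
}

# --- the fitting front end -------------------------------------------------

#' Fitting configuration
#'
#' @param n_windows number of regression windows (used when the trajectory
#'   carries no segment boundaries; protocol-aligned boundaries take
#'   precedence).
#' @param theta time-discretisation parameter: 1/2 (midpoint discrete
#'   gradients, default) or 1 (backward Euler).
#' @param conservative force a purely Hamiltonian model (`M = B = 0`),
#'   appropriate for quasi-static elastic data.
#' @param deg_weight,full_weight,max_iter,tol,polish passed to
#'   [split_generator()].
#' @param ridge regression ridge for the generator estimate.  The fitting
#'   default (1e-3, relative to the mean feature variance) is a variance
#'   control: finite-difference targets amplify measurement noise by 1/dt,
#'   and weakly excited feature directions would otherwise receive spurious
#'   O(1/dt) rates.  For noise-free oracle work use
#'   [regress_generator()]'s conditioning-level default (1e-8).
#' @param scales optional named per-channel scale factors defining the model
#'   coordinates; when fitting ensembles the same scales must be shared by
#'   all member fits so that their model components are commensurable.
#' @param error_channels channels over which the headline reconstruction
#'   error is computed.
#' @export
fit_config <- function(n_windows = 4L, theta = 0.5, conservative = FALSE,
                       deg_weight = 1e3, full_weight = 0.05, max_iter = 15L,
                       tol = 1e-10, ridge = 1e-3, polish = FALSE,
                       scales = NULL, error_channels = c("u_h", "u_v")) {
  stopifnot(n_windows >= 1, theta %in% c(0.5, 1))
  structure(list(n_windows = as.integer(n_windows), theta = theta,
                 conservative = conservative, deg_weight = deg_weight,
                 full_weight = full_weight, max_iter = max_iter, tol = tol,
                 ridge = ridge, polish = polish, scales = scales,
                 error_channels = error_channels),
            class = "fit_config")
}

#' Fit a GENERIC model to a measured trajectory
#'
#' The dynamical-systems regression at the heart of the package: per time
#' window, the generator of the theta-discretised linear dynamics is
#' estimated by ridge least squares ([assemble_regression()],
#' [regress_generator()]) and split into thermodynamically admissible
#' factors ([split_generator()]).  Channels are standardised to their
#' root-mean-square (the model's phase space) and a constant channel is
#' appended so that ramp-type inputs are representable by linear dynamics.
#'
#' The fit is scored by re-integrating the fitted model (restarted per
#' window from the measured window-start states) and reporting the relative
#' 2-norm error on the displacement channels.
#'
#' @param x an `experiment_curve` from [biaxial_test()], or a numeric matrix
#'   of state samples (rows) for the default method.
#' @param config a [fit_config()].
#' @param ... further arguments: for the default method `dt` (required) and
#'   `boundaries` (window start indices).
#' @return an object of class `generic_fit` with components `model` (a
#'   [generic_model()]), `Z` (physical state matrix), `reconstruction`,
#'   `errors`, and per-window `diagnostics`.
#' @seealso [predict.generic_fit()], [coef.generic_fit()],
#'   [residuals.generic_fit()]
#' @examples
#' \donttest{
#' curve <- biaxial_test(biaxial_protocol(), dt = 5e-3)
#' fit <- fit_generic(curve)
#' fit
#' }
#' @export
fit_generic <- function(x, config = fit_config(), ...) UseMethod("fit_generic")

#' @rdname fit_generic
#' @export
fit_generic.experiment_curve <- function(x, config = fit_config(), ...) {
  Z <- cbind(u_h = x$u_h, u_v = x$u_v, w_3 = x$lambda_3 - 1,
             P_11 = x$P_11, P_22 = x$P_22)
  fit_generic.default(Z, config, dt = attr(x, "dt"),
                      boundaries = attr(x, "boundaries"),
                      metadata = attr(x, "metadata"))
}

#' @rdname fit_generic
#' @export
fit_generic.default <- function(x, config = fit_config(), ..., dt,
                                boundaries = NULL, metadata = NULL) {
  Z <- as.matrix(x)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  n <- nrow(Z)
  if (is.null(boundaries)) {
    boundaries <- as.integer(round(seq(1, n, length.out = config$n_windows +
                                         1L)))[-(config$n_windows + 1L)]
  }
  boundaries <- sort(unique(as.integer(boundaries)))
  # model coordinates: per-channel rms scaling + constant channel
  scales <- config$scales
  if (is.null(scales)) {
    scales <- apply(Z, 2, function(v) max(sqrt(mean(v^2)), 1e-12))
  }
  Zs <- sweep(Z, 2, scales, "/")
  Zs <- cbind(Zs, one = 1)
  d <- ncol(Zs)
  bnds <- c(boundaries, n + 1L)
  windows <- vector("list", length(boundaries))
  diagnostics <- vector("list", length(boundaries))
  for (wi in seq_along(boundaries)) {
    rows <- seq.int(bnds[wi], min(bnds[wi + 1L], n))  # includes next start
    Zw <- Zs[rows, , drop = FALSE]
    reg <- assemble_regression(Zw, dt, config$theta)
    G <- regress_generator(reg$X, reg$Y, config$ridge)
    sp <- split_generator(G, Zw, conservative = config$conservative,
                          deg_weight = config$deg_weight,
                          full_weight = config$full_weight,
                          max_iter = config$max_iter, tol = config$tol,
                          ridge = config$ridge, polish = config$polish,
                          dt = dt, theta = config$theta)
    windows[[wi]] <- list(L = sp$L, M = sp$M, A = sp$A, B = sp$B,
                          Q = span_basis(Zw))
    diagnostics[[wi]] <- list(residual = sp$residual,
                              iterations = sp$iterations,
                              converged = sp$converged,
                              G = G)
  }
  model <- generic_model(windows = windows, boundaries = boundaries,
                         n_total = n, dt = dt, theta = config$theta,
                         channels = colnames(Zs), scales = scales,
                         check = FALSE)
  Zhat_s <- integrate_generic(model, Zs[1, ],
                              restarts = Zs[boundaries, , drop = FALSE])
  Zhat <- sweep(Zhat_s[, seq_len(ncol(Z)), drop = FALSE], 2, scales, "*")
  colnames(Zhat) <- colnames(Z)
  err_ch <- intersect(config$error_channels, colnames(Z))
  if (length(err_ch) == 0) err_ch <- colnames(Z)
  errors <- c(
    headline = reconstruction_error(Zhat, Z, channels = err_ch),
    all = reconstruction_error(Zhat, Z))
  structure(list(model = model, Z = Z, Zs = Zs, reconstruction = Zhat,
                 errors = errors, error_channels = err_ch,
                 diagnostics = diagnostics, config = config, dt = dt,
                 boundaries = boundaries, metadata = metadata),
            class = "generic_fit")
}

#' Relative 2-norm reconstruction error
#'
#' \eqn{\|pred - ref\|_2 / \|ref\|_2} over the concatenation of the selected
#' channels, the error measure used to score all models.
#'
#' @param predicted,reference matrices or data frames of equal size.
#' @param channels column names (or indices) to include; default all shared
#'   columns.
#' @export
reconstruction_error <- function(predicted, reference, channels = NULL) {
  predicted <- as.matrix(as.data.frame(predicted))
  reference <- as.matrix(as.data.frame(reference))
  if (!is.null(channels)) {
    predicted <- predicted[, channels, drop = FALSE]
    reference <- reference[, channels, drop = FALSE]
  }
  if (!all(dim(predicted) == dim(reference)))
    stop("predicted and reference must have equal dimensions")
  refnorm <- sqrt(sum(reference^2))
  if (refnorm == 0) stop("reference has zero norm")
  sqrt(sum((predicted - reference)^2)) / refnorm
}
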