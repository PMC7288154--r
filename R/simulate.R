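#' Principal-frame Mooney-Rivlin stress (internal fast path)
#'
#' Same algebra as [mr_stress()] specialised to diagonal kinematics
#' `C = diag(lambda^2)`; returns the diagonal of the isochoric and volumetric
#' second Piola-Kirchhoff parts.  Used in the inner loop of the biaxial
#' simulator.
#' @noRd
mr_stress_principal <- function(lambda, p) {
  l2 <- lambda^2
  I1 <- sum(l2)
  I2 <- l2[1] * l2[2] + l2[2] * l2[3] + l2[3] * l2[1]
  J <- lambda[1] * lambda[2] * lambda[3]
  iso <- 2 * (p$C1 * J^(-2 / 3) * (1 - I1 / (3 * l2)) +
              p$C2 * J^(-4 / 3) * (I1 - l2 - 2 * I2 / (3 * l2)))
  vol <- 2 * p$Dv * (J - 1) * J / l2
  list(iso = iso, vol = vol)
}

#' Viscoelastic stress history for a prescribed stretch history
#'
#' Quasi-linear viscoelasticity with a Prony kernel: the instantaneous
#' hyperelastic second Piola-Kirchhoff stress is split into its isochoric and
#' volumetric parts, each convolved with the corresponding normalised
#' relaxation function through the standard recursive exponential
#' (internal-variable) update.  Writing \eqn{x = \Delta t/\tau_i} and the
#' exponential memory \eqn{h_i(t) = \int_0^t e^{-(t-s)/\tau_i}\,\dot
#' S_0(s)\,ds} (rate assumed constant within a step),
#' \deqn{h_i^{n} = e^{-x} h_i^{n-1} + \frac{1 - e^{-x}}{x}
#'   (S_0^{n} - S_0^{n-1}), \qquad
#'   S^n = \bigl(1 - \sum_i \bar g_i\bigr) S_0^n + \sum_i \bar g_i h_i^n.}
#' With all weights zero the output equals the purely hyperelastic path.
#'
#' @param stretches n x 3 matrix of principal stretches (uniform time grid).
#' @param p a [mooney_rivlin()] parameter set.
#' @param prony a [prony_series()], or `NULL` for the elastic limit.
#' @param dt uniform time step, seconds.
#' @return list with n x 3 matrices `S` (second Piola-Kirchhoff principal
#'   values) and `P` (first Piola-Kirchhoff, `P_i = lambda_i S_i`).
#' @export
viscoelastic_stress_history <- function(stretches, p, prony = NULL, dt = 1e-3) {
  stretches <- as.matrix(stretches)
  stopifnot(ncol(stretches) == 3L, all(stretches > 0), dt > 0)
  n <- nrow(stretches)
  S <- matrix(0, n, 3)
  elastic <- is.null(prony) || (sum(prony$shear) == 0 && sum(prony$bulk) == 0)
  if (elastic) {
    for (k in seq_len(n)) {
      s0 <- mr_stress_principal(stretches[k, ], p)
      S[k, ] <- s0$iso + s0$vol
    }
  } else {
    nt <- length(prony$tau)
    e <- exp(-dt / prony$tau)
    cc <- (1 - e) / (dt / prony$tau)
    gG <- 1 - sum(prony$shear); gK <- 1 - sum(prony$bulk)
    h_iso <- matrix(0, nt, 3)
    h_vol <- matrix(0, nt, 3)
    prev <- mr_stress_principal(stretches[1, ], p)
    S[1, ] <- prev$iso + prev$vol
    for (k in seq_len(n)[-1]) {
      s0 <- mr_stress_principal(stretches[k, ], p)
      h_iso <- h_iso * e + outer(cc, s0$iso - prev$iso)
      h_vol <- h_vol * e + outer(cc, s0$vol - prev$vol)
      S[k, ] <- gG * s0$iso + gK * s0$vol +
        colSums(prony$shear * h_iso) + colSums(prony$bulk * h_vol)
      prev <- s0
    }
  }
  P <- S * stretches
  list(S = S, P = P)
}

#' Loading protocol for the biaxial test
#'
#' Ordered ramp/hold segments with in-plane stretch targets.  Stretches are
#' the controlled channels of the virtual test rig; stresses are measured
#' outputs.
#'
#' @param kind character vector, each `"ramp"` or `"hold"`.
#' @param duration segment durations, seconds.
#' @param lambda1,lambda2 in-plane stretch targets at the end of each segment
#'   (a hold repeats the previous target).
#' @return object of class `loading_protocol`.
#' @export
loading_protocol <- function(kind, duration, lambda1, lambda2) {
  stopifnot(all(kind %in% c("ramp", "hold")), all(duration > 0),
            length(kind) == length(duration),
            length(lambda1) == length(kind), length(lambda2) == length(kind))
  structure(data.frame(kind = kind, duration = duration,
                       lambda1 = lambda1, lambda2 = lambda2),
            class = c("loading_protocol", "data.frame"))
}

#' Default load-relax-load-relax biaxial protocol
#'
#' Two stretch-controlled ramps, each followed by a relaxation hold.  The
#' `scale` argument scales the stretch amplitudes (`lambda - 1`) and is how
#' the different loading states of an ensemble are produced.
#'
#' @param scale amplitude scale factor.
#' @param ramp,hold segment durations, seconds.
#' @export
biaxial_protocol <- function(scale = 1, ramp = 0.5, hold = 1.0) {
  l1 <- 1 + scale * (c(1.15, 1.15, 1.30, 1.30) - 1)
  l2 <- 1 + scale * (c(1.08, 1.08, 1.16, 1.16) - 1)
  loading_protocol(kind = c("ramp", "hold", "ramp", "hold"),
                   duration = c(ramp, hold, ramp, hold),
                   lambda1 = l1, lambda2 = l2)
}

# expand a protocol into a per-step in-plane stretch schedule
protocol_schedule <- function(protocol, dt) {
  t_end <- cumsum(protocol$duration)
  n <- round(t_end[length(t_end)] / dt)
  time <- seq(0, by = dt, length.out = n + 1)
  l1 <- numeric(n + 1); l2 <- numeric(n + 1)
  l1[1] <- 1; l2[1] <- 1
  cur1 <- 1; cur2 <- 1
  t0 <- 0
  boundaries <- integer(0)
  idx <- 2L
  for (s in seq_len(nrow(protocol))) {
    n_s <- round(protocol$duration[s] / dt)
    boundaries <- c(boundaries, idx - 1L)
    frac <- seq_len(n_s) / n_s
    if (protocol$kind[s] == "ramp") {
      l1[idx:(idx + n_s - 1)] <- cur1 + frac * (protocol$lambda1[s] - cur1)
      l2[idx:(idx + n_s - 1)] <- cur2 + frac * (protocol$lambda2[s] - cur2)
      cur1 <- protocol$lambda1[s]; cur2 <- protocol$lambda2[s]
    } else {
      l1[idx:(idx + n_s - 1)] <- cur1
      l2[idx:(idx + n_s - 1)] <- cur2
    }
    t0 <- t0 + protocol$duration[s]
    idx <- idx + n_s
  }
  list(time = time, lambda1 = l1, lambda2 = l2, boundaries = boundaries)
}

#' Simulate a plane-stress biaxial test
#'
#' Drives the in-plane principal stretches through the protocol and solves,
#' at every step, a scalar Newton iteration on the out-of-plane stretch so
#' that the total (viscoelastic) out-of-plane stress vanishes.  Displacement
#' channels are derived from the in-plane stretches with a unit reference
#' gauge length, `u_h = lambda_1 - 1`, `u_v = lambda_2 - 1`.
#'
#' @param protocol a [loading_protocol()].
#' @param p a [mooney_rivlin()] parameter set.
#' @param prony a [prony_series()] or `NULL` for a purely elastic test.
#' @param dt time step, seconds; should be well below the smallest
#'   relaxation time.
#' @param newton_tol plane-stress residual tolerance, relative to the
#'   running in-plane stress scale.
#' @param max_iter Newton iteration cap per step.
#' @return an `experiment_curve`: a data frame with columns `time`,
#'   `lambda_1`, `lambda_2`, `lambda_3`, `P_11`, `P_22`, `u_h`, `u_v`, with
#'   segment boundaries and provenance in attributes.
#' @export
biaxial_test <- function(protocol, p = mooney_rivlin(), prony = prony_series(),
                         dt = 1e-3, newton_tol = 1e-10, max_iter = 50L) {
  sched <- protocol_schedule(protocol, dt)
  n <- length(sched$time)
  lam3 <- numeric(n)
  S11 <- numeric(n); S22 <- numeric(n)
  elastic <- is.null(prony) || (sum(prony$shear) == 0 && sum(prony$bulk) == 0)
  if (!elastic) {
    nt <- length(prony$tau)
    e <- exp(-dt / prony$tau)
    cc <- (1 - e) / (dt / prony$tau)
    # total stress is affine in the instantaneous stress of the current step:
    # S^n = alpha * S0^n + (history terms), with
    # alpha = 1 - sum g_i (1 - c_i)
    aG <- 1 - sum(prony$shear * (1 - cc))
    aK <- 1 - sum(prony$bulk * (1 - cc))
    h_iso <- matrix(0, nt, 3)
    h_vol <- matrix(0, nt, 3)
  }
  lam3[1] <- 1
  prev <- mr_stress_principal(c(1, 1, 1), p)
  stress_scale <- 1e-3
  for (k in 2:n) {
    l12 <- c(sched$lambda1[k], sched$lambda2[k])
    if (elastic) {
      resid <- function(l3) {
        s0 <- mr_stress_principal(c(l12, l3), p)
        s0$iso[3] + s0$vol[3]
      }
    } else {
      const3 <- sum(prony$shear * (e * h_iso[, 3] - cc * prev$iso[3])) +
                sum(prony$bulk * (e * h_vol[, 3] - cc * prev$vol[3]))
      resid <- function(l3) {
        s0 <- mr_stress_principal(c(l12, l3), p)
        aG * s0$iso[3] + aK * s0$vol[3] + const3
      }
    }
    l3 <- lam3[k - 1]
    f <- resid(l3)
    it <- 0L
    f_scale <- max(1, stress_scale, abs(f))
    tol <- newton_tol * f_scale
    while (abs(f) > tol) {
      it <- it + 1L
      if (it > max_iter)
        stop(sprintf("plane-stress Newton failed to converge at step %d", k))
      eps <- 1e-7 * max(1, abs(l3))
      df <- (resid(l3 + eps) - f) / eps
      step <- f / df
      # damped step, stretches must stay positive
      while (l3 - step <= 0) step <- step / 2
      l3 <- l3 - step
      f <- resid(l3)
      # stop once the update is at round-off: the residual is then limited
      # by cancellation noise in the stiff volumetric term, not by lambda_3
      if (abs(step) < 1e-13 * max(1, abs(l3))) break
    }
    lam3[k] <- l3
    s0 <- mr_stress_principal(c(l12, l3), p)
    if (elastic) {
      Sk <- s0$iso + s0$vol
    } else {
      h_iso <- h_iso * e + outer(cc, s0$iso - prev$iso)
      h_vol <- h_vol * e + outer(cc, s0$vol - prev$vol)
      Sk <- (1 - sum(prony$shear)) * s0$iso + (1 - sum(prony$bulk)) * s0$vol +
        colSums(prony$shear * h_iso) + colSums(prony$bulk * h_vol)
      prev <- s0
    }
    S11[k] <- Sk[1]; S22[k] <- Sk[2]
    stress_scale <- max(stress_scale, abs(Sk[1]), abs(Sk[2]))
  }
  curve <- data.frame(time = sched$time,
                      lambda_1 = sched$lambda1,
                      lambda_2 = sched$lambda2,
                      lambda_3 = lam3,
                      P_11 = sched$lambda1 * S11,
                      P_22 = sched$lambda2 * S22,
                      u_h = sched$lambda1 - 1,
                      u_v = sched$lambda2 - 1)
  structure(curve,
            class = c("experiment_curve", "data.frame"),
            boundaries = sched$boundaries,
            dt = dt,
            metadata = list(state_id = NA_integer_, replicate_id = NA_integer_,
                            seed = NA_integer_, scale = NA_real_,
                            noise_sdv = 0))
}

#' Add measurement noise to the stress channels of a curve
#'
#' Gaussian noise with standard deviation `relative_sdv` times the mean
#' absolute value of each stress channel, applied to `P_11` and `P_22` only:
#' the stretch (and hence displacement) channels are controlled inputs of the
#' virtual rig.  Deterministic under a fixed seed.
#'
#' @param curve an `experiment_curve`.
#' @param relative_sdv noise level as a fraction of the per-channel mean
#'   absolute stress (0.10 emulates a 10\%-of-mean dispersion).
#' @param seed integer RNG seed.
#' @param replicate_id optional replicate label stored in the metadata.
#' @export
add_noise <- function(curve, relative_sdv, seed, replicate_id = NA_integer_) {
  stopifnot(relative_sdv >= 0)
  if (relative_sdv > 0) {
    set.seed(seed)
    for (ch in c("P_11", "P_22")) {
      sdv <- relative_sdv * mean(abs(curve[[ch]]))
      curve[[ch]] <- curve[[ch]] + rnorm(nrow(curve), 0, sdv)
    }
  }
  md <- attr(curve, "metadata")
  md$seed <- seed
  md$noise_sdv <- relative_sdv
  md$replicate_id <- replicate_id
  attr(curve, "metadata") <- md
  curve
}

#' Generate the pseudo-experimental test ensemble
#'
#' Simulates `n_loading_states` stretch-controlled biaxial tests whose ramp
#' amplitudes scale linearly between 0.5x and 1.5x of the base protocol, then
#' derives `n_replicates` noisy replicates per state.  A designated
#' noise-free reference curve is kept for every state; the ensemble's overall
#' reference state is the one with amplitude scale closest to 1.  The default
#' configuration (20 states x 50 replicates) yields one thousand test curves.
#'
#' @param n_loading_states,n_replicates ensemble dimensions.
#' @param relative_sdv stress-channel noise level (fraction of channel mean).
#' @param base_seed integer seed from which all replicate seeds are derived.
#' @param p,prony material and relaxation parameters.
#' @param dt time step, seconds.
#' @param ramp,hold protocol segment durations, seconds.
#' @return an `experiment_ensemble`: list with `curves` (noisy replicates),
#'   `references` (noise-free per state), `manifest`, and `reference_state`.
#' @export
generate_ensemble <- function(n_loading_states = 20L, n_replicates = 50L,
                              relative_sdv = 0.1, base_seed = 1L,
                              p = mooney_rivlin(), prony = prony_series(),
                              dt = 1e-3, ramp = 0.5, hold = 1.0) {
  stopifnot(n_loading_states >= 1, n_replicates >= 1)
  scales <- if (n_loading_states == 1) 1 else
    seq(0.5, 1.5, length.out = n_loading_states)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      n_loading_states * n_replicates)
  references <- vector("list", n_loading_states)
  curves <- vector("list", n_loading_states * n_replicates)
  manifest <- data.frame(idx = seq_along(curves),
                         state = rep(seq_len(n_loading_states),
                                     each = n_replicates),
                         replicate = rep(seq_len(n_replicates),
                                         n_loading_states),
                         seed = seeds,
                         scale = rep(scales, each = n_replicates))
  k <- 1L
  for (s in seq_len(n_loading_states)) {
    ref <- biaxial_test(biaxial_protocol(scale = scales[s], ramp = ramp,
                                         hold = hold),
                        p = p, prony = prony, dt = dt)
    md <- attr(ref, "metadata"); md$state_id <- s; md$scale <- scales[s]
    attr(ref, "metadata") <- md
    references[[s]] <- ref
    for (r in seq_len(n_replicates)) {
      cv <- add_noise(ref, relative_sdv, seeds[k], replicate_id = r)
      curves[[k]] <- cv
      k <- k + 1L
    }
  }
  structure(list(curves = curves, references = references,
                 manifest = manifest,
                 reference_state = which.min(abs(scales - 1)),
                 config = list(n_loading_states = n_loading_states,
                               n_replicates = n_replicates,
                               relative_sdv = relative_sdv,
                               base_seed = base_seed, dt = dt,
                               scales = scales)),
            class = "experiment_ensemble")
}

#' @export
print.experiment_ensemble <- function(x, ...) {
  cat(sprintf(
    "experiment ensemble: %d loading state(s) x %d replicate(s) = %d curves\n",
    x$config$n_loading_states, x$config$n_replicates, length(x$curves)))
  cat(sprintf("  noise sdv %.3g of channel mean; reference state %d\n",
              x$config$relative_sdv, x$reference_state))
  invisible(x)
}
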