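# --- shared pipeline helpers -----------------------------------------------

# physical state matrix of a biaxial curve (fit channel convention)
curve_state <- function(curve) {
  cbind(u_h = curve$u_h, u_v = curve$u_v, w_3 = curve$lambda_3 - 1,
        P_11 = curve$P_11, P_22 = curve$P_22)
}

to_model_coords <- function(Z, scales) cbind(sweep(Z, 2, scales, "/"), one = 1)

rms_scales <- function(Z) apply(Z, 2, function(v) max(sqrt(mean(v^2)), 1e-12))

# gauge-invariant model fingerprint used as the Kriging field: the
# per-window generator entries (the decomposition L, M, A, B is a gauge)
flatten_model <- function(model) {
  unlist(lapply(model$windows, function(w)
    as.numeric(w$L %*% w$A + w$M %*% w$B)), use.names = FALSE)
}

# integrate a model against a reference trajectory and score it
evaluate_model <- function(model, Z_ref, Zs_ref, boundaries, error_channels) {
  Zh_s <- integrate_generic(model, Zs_ref[1, ],
                            n_steps = nrow(Zs_ref) - 1L,
                            restarts = Zs_ref[boundaries, , drop = FALSE])
  nc <- ncol(Z_ref)
  Zh <- sweep(Zh_s[, seq_len(nc), drop = FALSE], 2, model$scales, "*")
  colnames(Zh) <- colnames(Z_ref)
  audit <- energy_entropy_audit(Zh_s, model)
  adm <- admissibility(model, Zs_ref)
  list(error = reconstruction_error(Zh, Z_ref, channels = error_channels),
       error_all = reconstruction_error(Zh, Z_ref),
       prediction = Zh,
       audit = list(
         max_dE_rel = if (is.null(audit)) 0 else
           max(abs(audit$dE)) / max(attr(audit, "E_scale"), 1e-300),
         min_dS_rel = if (is.null(audit)) 0 else
           min(audit$dS) / max(attr(audit, "S_scale"), 1e-300)),
       admissibility = adm)
}

fit_quietly <- function(Z, config, dt, boundaries) {
  tryCatch({
    f <- fit_generic.default(Z, config, dt = dt, boundaries = boundaries)
    list(ok = TRUE, model = f$model, errors = f$errors)
  }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
}

# --- pseudo-experimental study ---------------------------------------------

#' Configuration of the pseudo-experimental study
#'
#' Defaults are the full study: 20 loading states, 50 noisy replicates each
#' (one thousand tests), stress noise with standard deviation 10\% of the
#' channel mean.  Reduced configurations share the same code path.
#'
#' @param n_states,n_replicates ensemble dimensions.
#' @param relative_sdv stress noise level.
#' @param seed master seed; every downstream draw derives from it.
#' @param dt time step of the virtual tests, seconds.
#' @param ramp,hold protocol durations, seconds.
#' @param n_bins descriptor bins per stress channel.
#' @param k_min minimum TDA neighbourhood size.
#' @param max_dim homology dimension cap for the persistence diagram.
#' @param variants model-combination variants to evaluate.
#' @param fit a [fit_config()] (channel scales are overridden by the
#'   reference-curve scales so all fits share one phase space).
#' @param p,prony material parameters.
#' @export
pseudo_config <- function(n_states = 20L, n_replicates = 50L,
                          relative_sdv = 0.1, seed = 1L, dt = 1e-3,
                          ramp = 0.5, hold = 1.0, n_bins = 24L, k_min = 4L,
                          max_dim = 1L,
                          variants = c("mean", "simple", "ordinary", "local"),
                          fit = fit_config(), p = mooney_rivlin(),
                          prony = prony_series()) {
  list(n_states = n_states, n_replicates = n_replicates,
       relative_sdv = relative_sdv, seed = seed, dt = dt, ramp = ramp,
       hold = hold, n_bins = n_bins, k_min = k_min, max_dim = max_dim,
       variants = variants, fit = fit, p = p, prony = prony)
}

#' Run the pseudo-experimental learning study end to end
#'
#' Generates the noisy biaxial ensemble, fits a GENERIC model to every noisy
#' curve, and compares four ways of combining them against the held-out
#' noise-free reference test: the mean model over the reference state's
#' replicates, and simple / ordinary / local Kriging interpolation over the
#' TDA-identified neighbours of the reference on the constitutive manifold.
#' Every combined model is integrated (windowed restarts from the reference
#' states) and scored by the relative 2-norm error on the displacement
#' channels; stress-channel errors are reported alongside.
#'
#' @param config a [pseudo_config()].
#' @return a `run_report`: list with the error table, neighbour set, chosen
#'   scale R*, persistence diagram, Kriging weights, audits and settings.
#' @export
run_pseudo_experiment <- function(config = pseudo_config()) {
  ens <- generate_ensemble(config$n_states, config$n_replicates,
                           config$relative_sdv, config$seed,
                           p = config$p, prony = config$prony,
                           dt = config$dt, ramp = config$ramp,
                           hold = config$hold)
  ref <- ens$references[[ens$reference_state]]
  Z_ref <- curve_state(ref)
  boundaries <- attr(ref, "boundaries")
  scales <- rms_scales(Z_ref)
  Zs_ref <- to_model_coords(Z_ref, scales)
  fitcfg <- config$fit
  fitcfg$scales <- scales

  # per-curve fits (failures isolated)
  fits <- vector("list", length(ens$curves))
  for (i in seq_along(ens$curves)) {
    fits[[i]] <- fit_quietly(curve_state(ens$curves[[i]]), fitcfg,
                             config$dt, boundaries)
  }
  ok <- vapply(fits, `[[`, TRUE, "ok")
  failures <- which(!ok)
  models <- lapply(fits, function(f) if (f$ok) f$model else NULL)

  # diagnostic: fit of the noise-free reference itself
  ref_fit <- fit_quietly(Z_ref, fitcfg, config$dt, boundaries)

  # descriptor cloud (noisy curves + reference last), persistent topology
  cloud <- descriptor_cloud(c(ens$curves, list(ref)), n_bins = config$n_bins)
  diagram <- rips_persistence(cloud, max_dim = config$max_dim)
  r_star <- select_scale(diagram)
  ref_idx <- nrow(cloud)
  nb <- neighbors_of(ref_idx, cloud, r_star, k_min = config$k_min)
  nb <- nb[ok[nb]]
  if (length(nb) == 0) stop("no fitted neighbour models available")

  variants <- config$variants
  combined <- list()
  weights_out <- list()

  if ("mean" %in% variants) {
    ref_state_idx <- which(ens$manifest$state == ens$reference_state)
    ref_models <- models[ref_state_idx]
    ref_models <- ref_models[!vapply(ref_models, is.null, TRUE)]
    combined$mean <- mean_generic_model(ref_models, Z = Zs_ref)
    weights_out$mean <- rep(1 / length(ref_models), length(ref_models))
  }

  need_kriging <- any(c("simple", "ordinary", "local") %in% variants)
  if (need_kriging && length(nb) == 1L) {
    # a single neighbour admits no kriging system: every variant reduces to
    # that neighbour's model
    single <- interpolate_generic_model(models[nb], 1, Z = Zs_ref)
    for (v in intersect(c("simple", "ordinary", "local"), variants)) {
      combined[[v]] <- single
      weights_out[[v]] <- 1
    }
  } else if (need_kriging) {
    vals <- t(vapply(models[nb], flatten_model,
                     flatten_model(models[[nb[1]]])))
    target <- cloud[ref_idx, ]
    sites <- cloud[nb, , drop = FALSE]
    if ("ordinary" %in% variants) {
      ko <- krige("ordinary", sites, vals, target)
      combined$ordinary <- interpolate_generic_model(models[nb],
                                                     as.numeric(ko$weights),
                                                     Z = Zs_ref)
      weights_out$ordinary <- as.numeric(ko$weights)
    }
    if ("simple" %in% variants) {
      all_models <- models[!vapply(models, is.null, TRUE)]
      mean_all <- interpolate_generic_model(
        all_models, rep(1 / length(all_models), length(all_models)))
      ks <- krige("simple", sites, vals, target)
      w <- as.numeric(ks$weights)
      combined$simple <- interpolate_generic_model(
        c(models[nb], list(mean_all)), c(w, 1 - sum(w)), Z = Zs_ref)
      weights_out$simple <- w
    }
    if ("local" %in% variants) {
      chart <- tangent_chart(cloud, nb, base = cloud[ref_idx, ])
      kl <- krige("local", chart$coords, vals,
                  chart_project(chart, cloud[ref_idx, ]))
      combined$local <- interpolate_generic_model(models[nb],
                                                  as.numeric(kl$weights),
                                                  Z = Zs_ref)
      weights_out$local <- as.numeric(kl$weights)
    }
  } else {
    chart <- NULL
  }

  evals <- lapply(combined, evaluate_model, Z_ref = Z_ref, Zs_ref = Zs_ref,
                  boundaries = boundaries,
                  error_channels = fitcfg$error_channels)
  errors <- data.frame(
    variant = c(names(evals), "reference_fit"),
    error_pct = c(vapply(evals, `[[`, 0, "error"),
                  if (ref_fit$ok) ref_fit$errors[["headline"]] else NA) * 100,
    error_all_pct = c(vapply(evals, `[[`, 0, "error_all"),
                      if (ref_fit$ok) ref_fit$errors[["all"]] else NA) * 100)
  rownames(errors) <- NULL

  structure(list(
    experiment = "pseudo",
    errors = errors,
    models = combined,
    evaluations = evals,
    diagram = diagram,
    r_star = as.numeric(r_star),
    neighbors = as.integer(nb),
    weights = weights_out,
    audits = lapply(evals, `[[`, "audit"),
    admissibility = lapply(evals, `[[`, "admissibility"),
    reference = ref,
    n_curves = length(ens$curves),
    manifest = ens$manifest,
    failures = failures,
    seeds = list(master = config$seed),
    settings = config[c("n_states", "n_replicates", "relative_sdv", "dt",
                        "n_bins", "k_min", "max_dim", "seed")]),
    class = "run_report")
}

# --- synthetic arterial study ----------------------------------------------

#' Configuration of the synthetic arterial study
#'
#' @param n_specimens specimen curves per location.
#' @param dispersion inter-specimen scatter multiplier.
#' @param seed master seed (shared across locations, emulating re-tested
#'   specimens).
#' @param n_points samples per curve.
#' @param stress_cap loading cap, kPa.
#' @param n_bins,k_min,max_dim TDA settings.
#' @param variants combination variants.
#' @param fit a [fit_config()]; quasi-static elastic data call for a purely
#'   Hamiltonian model, so `conservative = TRUE` is the default here.
#' @export
carotid_config <- function(n_specimens = 14L, dispersion = 1, seed = 1L,
                           n_points = 201L, stress_cap = 240,
                           n_bins = 16L, k_min = 4L, max_dim = 1L,
                           variants = c("mean", "ordinary", "local"),
                           fit = fit_config(conservative = TRUE,
                                            error_channels = c("sigma_c",
                                                               "sigma_l"))) {
  list(n_specimens = n_specimens, dispersion = dispersion, seed = seed,
       n_points = n_points, stress_cap = stress_cap, n_bins = n_bins,
       k_min = k_min, max_dim = max_dim, variants = variants, fit = fit)
}

carotid_state <- function(curve) {
  cbind(w_c = curve$lambda_c - 1, sigma_c = curve$sigma_c,
        w_l = curve$lambda_l - 1, sigma_l = curve$sigma_l)
}

#' Run the synthetic arterial learning study end to end
#'
#' Emulates the paired circumferential/longitudinal specimen families at the
#' distal location plus their mean reference curve, fits a purely Hamiltonian
#' GENERIC model per specimen (quasi-static loading carries no viscous
#' information), finds the TDA neighbours of the mean curve, and compares
#' mean-model averaging with ordinary and local (tangent-chart) Kriging
#' interpolation of the neighbour models against the reference.  The Kriging
#' weights computed on the distal family are then transferred verbatim to
#' the proximal family (same specimens, different location) and scored
#' against the proximal reference.
#'
#' @param config a [carotid_config()].
#' @return a `run_report` with distal and transferred-proximal error tables.
#' @export
run_carotid_experiment <- function(config = carotid_config()) {
  fams <- lapply(c("distal", "proximal"), function(loc)
    carotid_like_family(loc, "both", n_specimens = config$n_specimens,
                        dispersion = config$dispersion, seed = config$seed,
                        n_points = config$n_points,
                        stress_cap = config$stress_cap))
  names(fams) <- c("distal", "proximal")
  dt <- 1 / (config$n_points - 1)

  per_loc <- lapply(fams, function(fam) {
    Z_ref <- carotid_state(fam$mean_curve)
    scales <- rms_scales(Z_ref)
    Zs_ref <- to_model_coords(Z_ref, scales)
    fitcfg <- config$fit
    fitcfg$scales <- scales
    boundaries <- as.integer(round(seq(1, nrow(Z_ref),
                                       length.out = fitcfg$n_windows + 1L)))
    boundaries <- boundaries[-length(boundaries)]
    fits <- lapply(fam$curves, function(cv)
      fit_quietly(carotid_state(cv), fitcfg, dt, boundaries))
    list(fam = fam, Z_ref = Z_ref, Zs_ref = Zs_ref, scales = scales,
         boundaries = boundaries, fits = fits, fitcfg = fitcfg)
  })

  dl <- per_loc$distal
  ok <- vapply(dl$fits, `[[`, TRUE, "ok")
  models_d <- lapply(dl$fits, function(f) if (f$ok) f$model else NULL)
  models_p <- lapply(per_loc$proximal$fits,
                     function(f) if (f$ok) f$model else NULL)

  # TDA on the distal family (curves + mean reference last)
  cloud <- descriptor_cloud(c(dl$fam$curves, list(dl$fam$mean_curve)),
                            channels = c("sigma_c", "sigma_l"),
                            n_bins = config$n_bins)
  diagram <- rips_persistence(cloud, max_dim = config$max_dim)
  r_star <- select_scale(diagram)
  ref_idx <- nrow(cloud)
  nb <- neighbors_of(ref_idx, cloud, r_star, k_min = config$k_min)
  nb <- nb[ok[nb] & !vapply(models_p[nb], is.null, TRUE)]
  if (length(nb) == 0) stop("no fitted neighbour models available")

  vals <- t(vapply(models_d[nb], flatten_model,
                   flatten_model(models_d[[nb[1]]])))
  target <- cloud[ref_idx, ]
  sites <- cloud[nb, , drop = FALSE]
  chart <- tangent_chart(cloud, nb, base = target)

  weights <- list(mean = rep(1 / length(nb), length(nb)))
  if ("ordinary" %in% config$variants)
    weights$ordinary <- as.numeric(
      krige("ordinary", sites, vals, target)$weights)
  if ("local" %in% config$variants)
    weights$local <- as.numeric(
      krige("local", chart$coords, vals, chart_project(chart, target))$weights)
  weights <- weights[intersect(c("mean", "ordinary", "local"),
                               union("mean", config$variants))]

  score <- function(models, loc) {
    pl <- per_loc[[loc]]
    out <- lapply(weights, function(w)
      interpolate_generic_model(models[nb], w, Z = pl$Zs_ref))
    evals <- lapply(out, evaluate_model, Z_ref = pl$Z_ref,
                    Zs_ref = pl$Zs_ref, boundaries = pl$boundaries,
                    error_channels = pl$fitcfg$error_channels)
    list(models = out, evals = evals)
  }
  distal <- score(models_d, "distal")
  proximal <- score(models_p, "proximal")

  ref_fit <- fit_quietly(dl$Z_ref, dl$fitcfg, dt, dl$boundaries)
  errors <- rbind(
    data.frame(location = "distal",
               variant = names(distal$evals),
               error_pct = 100 * vapply(distal$evals, `[[`, 0, "error")),
    data.frame(location = "proximal",
               variant = names(proximal$evals),
               error_pct = 100 * vapply(proximal$evals, `[[`, 0, "error")),
    data.frame(location = "distal", variant = "reference_fit",
               error_pct = if (ref_fit$ok)
                 100 * ref_fit$errors[["headline"]] else NA))
  rownames(errors) <- NULL

  structure(list(
    experiment = "carotid",
    errors = errors,
    models = list(distal = distal$models, proximal = proximal$models),
    evaluations = list(distal = distal$evals, proximal = proximal$evals),
    diagram = diagram,
    r_star = as.numeric(r_star),
    neighbors = as.integer(nb),
    weights = weights,
    audits = lapply(c(distal$evals, proximal$evals), `[[`, "audit"),
    admissibility = lapply(c(distal$evals, proximal$evals), `[[`,
                           "admissibility"),
    failures = which(!ok),
    seeds = list(master = config$seed),
    settings = config[c("n_specimens", "dispersion", "seed", "n_points",
                        "stress_cap", "n_bins", "k_min", "seed")]),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run report (%s experiment)\n", x$experiment))
  print(x$errors)
  cat(sprintf("R* = %.4g; %d neighbour(s); %d failed fit(s)\n",
              x$r_star, length(x$neighbors), length(x$failures)))
  invisible(x)
}
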