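#' Synthetic arterial stress-stretch curve family
#'
#' Emulates the statistical structure of quasi-static uniaxial tests on
#' arterial strips sampled at two anatomical locations (distal, proximal) and
#' two directions (circumferential, longitudinal): exponential-stiffening
#' curves \deqn{\sigma(\lambda) = a\,(e^{b(\lambda - 1)} - 1)} with
#' log-normal inter-specimen scatter on both coefficients, loaded
#' quasi-statically up to a stress cap (240 kPa by default) over a unit
#' pseudo-time.  A mean reference curve is computed pointwise on a common
#' stretch grid, giving the `n_specimens + 1`-th curve of the family.
#'
#' This is a synthetic stand-in for tissue data: only its statistical shape
#' (monotone stiffening, strong dispersion, direction- and location-dependent
#' stiffness, stress cap) matters to the downstream learning pipeline.
#' Location and direction change the `(a, b)` priors, so circumferential and
#' longitudinal responses differ, as do distal and proximal ones.  Using the
#' same seed for both locations reuses the same specimen-level scatter, which
#' emulates re-testing the same animals at a second location.
#'
#' @param location `"distal"` or `"proximal"`.
#' @param direction `"circumferential"`, `"longitudinal"`, or `"both"` for
#'   paired curves sharing a pseudo-time axis.
#' @param n_specimens number of specimen curves (>= 2).
#' @param dispersion scatter multiplier; 1 gives the default log-normal
#'   scatter (sdlog 0.25 on `a`, 0.10 on `b`), 0 collapses the family onto
#'   identical curves.
#' @param seed integer seed for the specimen draws.
#' @param n_points samples per curve on the pseudo-time grid.
#' @param stress_cap maximum stress, kPa.
#' @return object of class `carotid_family`: list with `curves` (each a data
#'   frame over pseudo-time), `mean_curve`, `params`, and the call settings.
#' @export
carotid_like_family <- function(location = c("distal", "proximal"),
                                direction = c("both", "circumferential",
                                              "longitudinal"),
                                n_specimens = 14L, dispersion = 1, seed = 1L,
                                n_points = 201L, stress_cap = 240) {
  location <- match.arg(location)
  direction <- match.arg(direction)
  stopifnot(n_specimens >= 2, dispersion >= 0)
  priors <- list(
    distal = list(circumferential = c(a = 12, b = 6.0),
                  longitudinal = c(a = 7, b = 8.5)),
    proximal = list(circumferential = c(a = 20, b = 4.5),
                    longitudinal = c(a = 11, b = 7.0)))
  dirs <- if (direction == "both") c("circumferential", "longitudinal")
          else direction
  # specimen scatter: same seed -> same multiplicative draws per specimen,
  # reused across locations
  set.seed(seed)
  draws <- lapply(c("circumferential", "longitudinal"), function(d)
    cbind(a = rlnorm(n_specimens, 0, 0.25 * dispersion),
          b = rlnorm(n_specimens, 0, 0.10 * dispersion)))
  names(draws) <- c("circumferential", "longitudinal")

  tgrid <- seq(0, 1, length.out = n_points)
  params <- list()
  per_dir <- list()
  for (d in dirs) {
    pr <- priors[[location]][[d]]
    a <- pr["a"] * draws[[d]][, "a"]
    b <- pr["b"] * draws[[d]][, "b"]
    lmax <- 1 + log(stress_cap / a + 1) / b
    curves_d <- lapply(seq_len(n_specimens), function(i) {
      lam <- 1 + (lmax[i] - 1) * tgrid
      data.frame(stretch = lam, stress = a[i] * (exp(b[i] * (lam - 1)) - 1))
    })
    # pointwise mean on a common stretch grid
    lgrid <- seq(1, min(lmax), length.out = n_points)
    smean <- rowMeans(vapply(seq_len(n_specimens), function(i)
      a[i] * (exp(b[i] * (lgrid - 1)) - 1), numeric(n_points)))
    per_dir[[d]] <- list(curves = curves_d,
                         mean = data.frame(stretch = lgrid, stress = smean))
    params[[d]] <- data.frame(a = a, b = b, lambda_max = lmax)
  }

  assemble <- function(get) {
    if (direction == "both") {
      cbind(data.frame(time = tgrid),
            setNames(get("circumferential"), c("lambda_c", "sigma_c")),
            setNames(get("longitudinal"), c("lambda_l", "sigma_l")))
    } else {
      cbind(data.frame(time = tgrid),
            setNames(get(direction), c("stretch", "stress")))
    }
  }
  curves <- lapply(seq_len(n_specimens), function(i)
    assemble(function(d) per_dir[[d]]$curves[[i]]))
  mean_curve <- assemble(function(d) per_dir[[d]]$mean)

  structure(list(curves = curves, mean_curve = mean_curve, params = params,
                 location = location, direction = direction,
                 dispersion = dispersion, seed = seed,
                 stress_cap = stress_cap),
            class = "carotid_family")
}

#' @export
print.carotid_family <- function(x, ...) {
  cat(sprintf(
    "synthetic %s arterial family (%s): %d specimen curves + mean reference\n",
    x$location, x$direction, length(x$curves)))
  cat(sprintf("  dispersion %.2g, stress cap %g kPa, seed %d\n",
              x$dispersion, x$stress_cap, x$seed))
  invisible(x)
}
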