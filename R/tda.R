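#' Fixed-length descriptor of an experiment curve
#'
#' Embeds a whole curve as a point of the descriptor cloud: the stress
#' channels are averaged over `n_bins` equal time bins and concatenated.
#' Binned means are linear in the curve values, so the descriptor of a
#' pointwise mean of curves is the mean of their descriptors.
#'
#' @param curve an `experiment_curve` or data frame.
#' @param channels stress channels to embed; defaults to the biaxial pair.
#' @param n_bins number of time bins per channel.
#' @return numeric vector of length `length(channels) * n_bins`.
#' @export
curve_descriptor <- function(curve, channels = c("P_11", "P_22"),
                             n_bins = 24L) {
  n <- nrow(curve)
  if (n < n_bins) stop("curve shorter than the descriptor grid")
  bin <- pmin(floor((seq_len(n) - 1) / n * n_bins) + 1L, n_bins)
  unlist(lapply(channels, function(ch) {
    v <- curve[[ch]]
    if (is.null(v)) stop(sprintf("channel %s not present in curve", ch))
    as.numeric(tapply(v, bin, mean))
  }), use.names = FALSE)
}

#' Descriptor cloud of an ensemble of curves
#'
#' Stacks [curve_descriptor()] rows and standardises each coordinate to zero
#' mean and unit variance over the cloud (coordinates with no variance are
#' left centred).  The standardisation makes the Euclidean metric of the
#' cloud scale-free across channels.
#'
#' @param curves list of curves.
#' @param channels,n_bins passed to [curve_descriptor()].
#' @return matrix with one standardised descriptor per row; attributes
#'   `center` and `scale`.
#' @export
descriptor_cloud <- function(curves, channels = c("P_11", "P_22"),
                             n_bins = 24L) {
  X <- t(vapply(curves, curve_descriptor, channels = channels,
                n_bins = n_bins,
                FUN.VALUE = numeric(length(channels) * n_bins)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

#' Vietoris-Rips persistence diagram
#'
#' Computes the persistent homology of the Vietoris-Rips filtration over a
#' point cloud or distance matrix: as the scale parameter R grows, points
#' within distance R are joined by edges, triangles and tetrahedra, and the
#' birth and death scales of connected components (H0), loops (H1) and voids
#' (H2) are recorded.  Long bars reflect the persistent topology of the
#' data; short bars are noise.
#'
#' @param x points matrix (rows = points) or a symmetric distance matrix
#'   (class `dist` also accepted).
#' @param max_dim largest homology dimension (0, 1 or 2; dimension 2
#'   enumerates all tetrahedra and is only meant for small clouds).
#' @param threshold filtration cutoff; defaults to the enclosing radius
#'   (features beyond it cannot die, so H0/H1 are complete).
#' @return a `persistence_diagram`: data frame with `dimension`, `birth`,
#'   `death` (`Inf` for features alive at the threshold).
#' @export
rips_persistence <- function(x, max_dim = 1L, threshold = NULL) {
  D <- as_distance_matrix(x)
  n <- nrow(D)
  if (is.null(threshold)) {
    # enclosing radius: min over points of their eccentricity
    threshold <- if (n > 1) min(apply(D, 1, max)) else 0
  }
  stopifnot(max_dim %in% 0:2)
  if (max_dim >= 2 && n > 60)
    warning("H2 on a large cloud enumerates O(n^4) tetrahedra; this may be slow")
  df <- .rips_persistence_cpp(D, as.integer(max_dim), threshold)
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("persistence_diagram", "data.frame"),
            threshold = threshold, n_points = n)
}

as_distance_matrix <- function(x) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  x <- as.matrix(x)
  # a square non-negative matrix with a zero diagonal is read as a distance
  # matrix; anything else as a point cloud
  if (nrow(x) == ncol(x) && all(diag(x) == 0) && all(x >= 0)) {
    if (max(abs(x - t(x))) > 1e-12 * max(1, max(abs(x))))
      stop("asymmetric distance matrix")
    return((x + t(x)) / 2)
  }
  as.matrix(stats::dist(x))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("persistence diagram: %d points, threshold %.4g\n",
              attr(x, "n_points"), attr(x, "threshold")))
  for (k in sort(unique(x$dimension))) {
    bars <- x[x$dimension == k, ]
    cat(sprintf("  H%d: %d bar(s), %d essential\n", k, nrow(bars),
                sum(!is.finite(bars$death))))
  }
  invisible(x)
}

#' Barcode / diagram plot
#'
#' @param x a `persistence_diagram`.
#' @param style `"barcode"` or `"diagram"` (birth-death scatter).
#' @param ... passed through to the underlying plot call.
#' @export
plot.persistence_diagram <- function(x, style = c("barcode", "diagram"), ...) {
  style <- match.arg(style)
  thr <- attr(x, "threshold")
  death <- ifelse(is.finite(x$death), x$death, thr)
  cols <- c("black", "red", "blue")[x$dimension + 1]
  if (style == "barcode") {
    ord <- order(x$dimension, x$birth)
    plot(NULL, xlim = c(0, thr), ylim = c(0, nrow(x) + 1), xlab = "R",
         ylab = "bar", ...)
    segments(x$birth[ord], seq_along(ord), death[ord], seq_along(ord),
             col = cols[ord], lwd = 2)
  } else {
    plot(x$birth, death, col = cols, xlab = "birth", ylab = "death",
         xlim = c(0, thr), ylim = c(0, thr), ...)
    abline(0, 1, col = "grey60")
  }
  invisible(x)
}

#' Select the connectivity scale from a persistence diagram
#'
#' Chooses the scale R* that "best describes the topology" of the cloud: the
#' midpoint of the widest interval of R over which the multiset of alive
#' bars in dimensions 0-1 does not change (the largest persistence gap).
#' Over that interval the simplicial complex sees no topological event, so
#' the complex at R* reflects the dominant (most persistent) topology.
#'
#' @param diagram a `persistence_diagram`.
#' @return the scale R*, with the gap endpoints in attribute `gap`.
#' @export
select_scale <- function(diagram) {
  d01 <- diagram[diagram$dimension <= 1, ]
  events <- sort(unique(c(d01$birth, d01$death)))
  # the connectivity-free regime below the first edge (all components born
  # at R = 0) describes no topology; only positive events delimit the
  # intervals of interest
  events <- events[is.finite(events) & events > 0]
  if (length(events) < 2) {
    warning("degenerate diagram; falling back to the median death scale")
    deaths <- d01$death[is.finite(d01$death)]
    return(if (length(deaths)) median(deaths) else 0)
  }
  gaps <- diff(events)
  k <- which.max(gaps)
  structure((events[k] + events[k + 1]) / 2, gap = events[k + (0:1)])
}

#' Neighbours of a reference point at scale R*
#'
#' All points within the R*-ball of the reference; when the ball holds fewer
#' than `k_min` points, the neighbourhood is expanded to the `k_min` nearest
#' points (flagged in the `fallback` attribute).
#'
#' @param reference index of the reference point in the cloud.
#' @param x cloud or distance matrix.
#' @param r_star connectivity scale, e.g. from [select_scale()].
#' @param k_min minimum neighbourhood size.
#' @return integer vector of neighbour indices (reference excluded).
#' @export
neighbors_of <- function(reference, x, r_star, k_min = 4L) {
  D <- as_distance_matrix(x)
  stopifnot(reference >= 1, reference <= nrow(D))
  dref <- D[reference, ]
  nb <- setdiff(which(dref <= r_star), reference)
  fallback <- FALSE
  if (length(nb) < k_min) {
    fallback <- TRUE
    ord <- order(dref)
    nb <- setdiff(ord, reference)[seq_len(min(k_min, nrow(D) - 1L))]
  }
  structure(sort(nb), fallback = fallback)
}

#' Local tangent-plane chart of the constitutive manifold
#'
#' Principal directions of the centred neighbour descriptors give an
#' orthonormal basis of the local tangent space at the reference datum; the
#' intrinsic dimension is the smallest number of directions capturing at
#' least `var_frac` of the local variance, capped at `d_max`.  Interpolation
#' in these coordinates (rather than in the ambient Euclidean space) is what
#' the manifold-learning stage is for: noise orthogonal to the manifold is
#' projected out.
#'
#' @param cloud descriptor matrix (rows = points).
#' @param neighbors indices of the chart's neighbourhood.
#' @param base optional base-point descriptor (defaults to the neighbourhood
#'   centroid).
#' @param var_frac local variance fraction to capture.
#' @param d_max cap on the intrinsic dimension.
#' @return a `tangent_chart` with fields `base`, `center`, `basis`
#'   (orthonormal columns), `d`, `neighbors`, and the projected neighbour
#'   coordinates `coords`.
#' @export
tangent_chart <- function(cloud, neighbors, base = NULL, var_frac = 0.95,
                          d_max = 3L) {
  X <- cloud[neighbors, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  lam <- sv$d^2
  pos <- lam > max(lam[1], .Machine$double.eps) * 1e-12
  if (!any(pos)) {
    # all neighbours coincide: zero-dimensional chart
    basis <- matrix(0, ncol(cloud), 1)
    d <- 0L
  } else {
    frac <- cumsum(lam[pos]) / sum(lam[pos])
    d <- min(which(frac >= var_frac)[1], d_max, sum(pos))
    basis <- sv$v[, seq_len(d), drop = FALSE]
  }
  if (is.null(base)) base <- ctr
  coords <- Xc %*% basis
  structure(list(base = base, center = ctr, basis = basis, d = d,
                 neighbors = neighbors, coords = coords,
                 eigenvalues = lam),
            class = "tangent_chart")
}

#' Project points into (and lift from) a tangent chart
#'
#' `chart_project()` maps ambient descriptors to chart coordinates;
#' `chart_lift()` maps chart coordinates back to the ambient space.  For
#' points lying exactly on the chart plane `chart_lift(chart_project(x))`
#' recovers `x`.
#'
#' @param chart a [tangent_chart()].
#' @param X ambient points (rows) or chart coordinates for the lift.
#' @export
chart_project <- function(chart, X) {
  sweep(rbind(X), 2, chart$center) %*% chart$basis
}

#' @rdname chart_project
#' @export
chart_lift <- function(chart, X) {
  sweep(rbind(X) %*% t(chart$basis), 2, chart$center, "+")
}

#' @export
print.tangent_chart <- function(x, ...) {
  cat(sprintf(
    "tangent chart: intrinsic dimension %d over %d neighbours (D = %d)\n",
    x$d, length(x$neighbors), length(x$base)))
  invisible(x)
}
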