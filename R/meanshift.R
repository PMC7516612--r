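#' Min-max normalization of a point cloud
#'
#' Each dimension is scaled to `[0, 1]` using its observed minimum and
#' maximum, so the mean-shift distances `D` and `ell` are dimensionless. A
#' degenerate dimension (max equal to min) is mapped to the constant 0.5 and
#' flagged; flagged dimensions are excluded from distance computations, since
#' their normalized spread would be artificial.
#'
#' @param X Numeric matrix (points in rows) or vector (one dimension).
#' @return A list with `points` (normalized matrix), `transform` (2 x J
#'   matrix of per-dimension min and max) and `degenerate` (logical per
#'   dimension), of class `normalized_cloud`.
#' @export
normalize_points <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  degenerate <- mx <= mn
  Z <- X
  for (j in seq_len(ncol(X))) {
    if (degenerate[j]) Z[, j] <- 0.5
    else Z[, j] <- (X[, j] - mn[j]) / (mx[j] - mn[j])
  }
  structure(list(points = Z, transform = rbind(min = mn, max = mx),
                 degenerate = degenerate),
            class = "normalized_cloud")
}

denormalize_points <- function(Z, transform, degenerate) {
  X <- as.matrix(Z)
  for (j in seq_len(ncol(X))) {
    if (degenerate[j]) X[, j] <- transform["min", j]
    else X[, j] <- transform["min", j] +
        X[, j] * (transform["max", j] - transform["min", j])
  }
  X
}

#' Mean-shift kernel weight
#'
#' The neighborhood `NH` is the Euclidean ball of radius `D`; outside it the
#' weight is zero for both kernels. Inside, the flat kernel weighs every
#' neighbor by 1 and the Gaussian kernel by `exp(-d / ell)` (note: distance,
#' not squared distance).
#'
#' @param d Nonnegative distance(s), in normalized units.
#' @param kernel `"flat"` or `"gaussian"`.
#' @param D Neighborhood radius.
#' @param ell Gaussian bandwidth.
#' @return Numeric weight(s) in `[0, 1]`.
#' @export
kernel_weight <- function(d, kernel = c("gaussian", "flat"), D = 0.6,
                          ell = 0.2) {
  kernel <- match.arg(kernel)
  d <- as.numeric(d)
  if (any(d < 0)) stop("distances must be nonnegative")
  w <- if (kernel == "flat") rep(1, length(d)) else exp(-d / ell)
  w[d >= D] <- 0
  w
}

#' Mean-shift cluster recognition
#'
#' Every point of the normalized cloud seeds a query that is moved, each
#' iteration, to the kernel-weighted mean of its neighbors within radius
#' `D`, until the largest displacement falls below `tol` or `max_iter` is
#' reached; converged queries within `merge_dist` of one another (single
#' linkage) belong to the same cluster. By default the *data* stay fixed and
#' only the queries move (the textbook mode-seeking iteration, which keeps
#' distinct modes closer than `D` apart from one another separate); with
#' `blurring = TRUE` the shifted ensemble replaces the data each iteration,
#' which contracts — and eventually merges — any groups of points within `D`
#' of each other. The number of clusters is an *output*, not an input — the
#' property that motivates this algorithm for live-point ensembles with an
#' unknown number of likelihood modes.
#'
#' @param X Numeric matrix of points in original units (rows = points), or a
#'   `normalized_cloud` from [normalize_points()].
#' @param kernel,D,ell,merge_dist See [kernel_weight()] and [ns_config()].
#' @param tol Convergence tolerance on the per-iteration displacement.
#' @param max_iter Iteration cap.
#' @param blurring Replace the data by the shifted ensemble each iteration
#'   (default `FALSE`).
#' @return An object of class `cluster_assignment`: `labels` (1..C per
#'   point), `n_clusters`, `sizes`, `modes` (converged representatives, in
#'   original units when `X` was unnormalized), `modes_normalized`,
#'   `cluster_mean` and `cluster_sigma` (per-cluster per-dimension population
#'   statistics in original units), `iterations`, `converged`.
#' @examples
#' X <- cbind(c(rnorm(20), rnorm(20, 5)))
#' mean_shift(X, kernel = "flat", D = 0.3)$n_clusters
#' @export
mean_shift <- function(X, kernel = c("gaussian", "flat"), D = 0.6, ell = 0.2,
                       tol = 1e-4, max_iter = 100, merge_dist = 0.05,
                       blurring = FALSE) {
  kernel <- match.arg(kernel)
  if (inherits(X, "normalized_cloud")) {
    cloud <- X
    orig <- denormalize_points(cloud$points, cloud$transform, cloud$degenerate)
  } else {
    orig <- as.matrix(X)
    cloud <- normalize_points(orig)
  }
  if (nrow(cloud$points) < 1) stop("empty cloud")
  res <- mean_shift_cpp(cloud$points, !cloud$degenerate,
                        if (kernel == "gaussian") 1L else 0L,
                        D, ell, tol, as.integer(max_iter), merge_dist,
                        isTRUE(blurring))
  labels <- res$labels
  C <- res$n_clusters
  sizes <- tabulate(labels, nbins = C)
  J <- ncol(orig)
  cmean <- matrix(NA_real_, C, J)
  csig <- matrix(NA_real_, C, J)
  for (c in seq_len(C)) {
    sub <- orig[labels == c, , drop = FALSE]
    cmean[c, ] <- colMeans(sub)
    csig[c, ] <- sqrt(pmax(colMeans(sub^2) - colMeans(sub)^2, 0))
  }
  colnames(cmean) <- colnames(csig) <- colnames(orig)
  structure(list(labels = labels, n_clusters = C, sizes = sizes,
                 modes = denormalize_points(res$modes, cloud$transform,
                                            cloud$degenerate),
                 modes_normalized = res$modes,
                 cluster_mean = cmean, cluster_sigma = csig,
                 iterations = res$iterations, converged = res$converged,
                 kernel = kernel, D = D, ell = ell,
                 transform = cloud$transform, degenerate = cloud$degenerate),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "Mean-shift assignment: %d clusters over %d points (%s kernel, D=%g%s)\n",
    x$n_clusters, length(x$labels), x$kernel, x$D,
    if (x$kernel == "gaussian") sprintf(", ell=%g", x$ell) else ""))
  cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Per-cluster step scale for the constrained walk
#'
#' Population standard deviation (n denominator) of the members of cluster
#' `c`, per dimension, in original units, floored at
#' `floor_rel * (upper - lower)` so singleton clusters keep a usable scale.
#' When labels are present, the walk uses this cluster scale instead of the
#' global live-point standard deviation — the step that makes multimodal
#' exploration efficient.
#'
#' @param points Matrix of live points (rows).
#' @param labels Integer cluster labels (1..C).
#' @param c Cluster label to summarize.
#' @param lower,upper Optional bounds used for the floor.
#' @param floor_rel Relative floor (default `1e-12`).
#' @return Numeric vector of per-dimension standard deviations.
#' @export
cluster_sigma <- function(points, labels, c, lower = NULL, upper = NULL,
                          floor_rel = 1e-12) {
  points <- as.matrix(points)
  if (!c %in% labels) stop("unknown cluster label: ", c)
  sub <- points[labels == c, , drop = FALSE]
  s <- sqrt(pmax(colMeans(sub^2) - colMeans(sub)^2, 0))
  if (is.null(lower) || is.null(upper)) {
    # fall back to the spread of the whole ensemble for the floor
    lower <- apply(points, 2, min)
    upper <- apply(points, 2, max)
  }
  pmax(s, floor_rel * (upper - lower), .Machine$double.xmin)
}
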