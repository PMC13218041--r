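# Conformational-state analysis of (SASA, Rg) series: min-max
# normalization, k-means state maps, GROMOS trajectory clustering and the
# dispersion-based stability score.

#' Min-max normalize a metric series
#'
#' (X_t - X_min) / (X_max - X_min): maps the observed minimum to 0 and the
#' maximum to 1 so that Rg and SASA series from different systems share a
#' common unit square.
#'
#' @param X_t raw per-frame values (length >= 2, non-constant).
#' @return object of class `metric_series`: list with `X_t`, `X_norm`,
#'   `X_min`, `X_max`.
#' @export
normalize_series <- function(X_t) {
  X_t <- as.numeric(X_t)
  if (length(X_t) < 2L) stopf("series must have at least 2 points")
  X_min <- min(X_t); X_max <- max(X_t)
  if (X_max <= X_min)
    stopf("degenerate normalization: series is constant (min = max = %g)", X_min)
  structure(list(X_t = X_t, X_norm = (X_t - X_min) / (X_max - X_min),
                 X_min = X_min, X_max = X_max),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("Metric series: %d points, raw range [%g, %g]\n",
              length(x$X_t), x$X_min, x$X_max))
  invisible(x)
}

#' Seeded k-means state map of (SASA, Rg) points
#'
#' Partitions normalized (SASA, Rg) observations into k conformational
#' states with Lloyd/Hartigan-Wong k-means, 10 seeded restarts, best
#' within-cluster sum of squares kept. k = 3 is the conventional choice
#' when the metric distributions show three patterns.
#'
#' @param points n x 2 matrix (or data.frame) of normalized observations.
#' @param k cluster count (default 3).
#' @param seed RNG seed for reproducible initialisation.
#' @param nstart random restarts (default 10).
#' @return list with `assignments` (integer vector), `centers`,
#'   `proportions` (per-cluster fraction) and `tot_withinss`.
#' @export
kmeans_states <- function(points, k = 3L, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  if (nrow(points) < k)
    stopf("need at least k = %d points, got %d", k, nrow(points))
  km <- with_seed(seed, kmeans(points, centers = k, nstart = nstart,
                               iter.max = 100L))
  list(assignments = km$cluster,
       centers = km$centers,
       proportions = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) /
         nrow(points),
       tot_withinss = km$tot.withinss)
}

# Kabsch optimal-superposition RMSD between two conformations
# (uniform weights). Both frames are centred; the optimal rotation comes
# from the SVD of the 3x3 covariance, with a reflection guard.
rmsd_kabsch <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  H <- crossprod(a, b)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  ar <- a %*% t(R)
  sqrt(mean(rowSums((ar - b)^2)))
}

#' Pairwise RMSD matrix of a trajectory
#'
#' @param traj `bead_trajectory`.
#' @param selection bead indices (default all).
#' @return symmetric frame x frame RMSD matrix, nm.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  frames <- traj$frames
  if (!is.null(selection))
    frames <- lapply(frames, function(f) f[selection, , drop = FALSE])
  nf <- length(frames)
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      M[i, j] <- M[j, i] <- rmsd_kabsch(frames[[i]], frames[[j]])
    }
  }
  M
}

# One pass of the GROMOS neighbour-count algorithm at a fixed cutoff.
gromos_pass <- function(M, cutoff) {
  nf <- nrow(M)
  remaining <- seq_len(nf)
  clusters <- list()
  adj <- M <= cutoff
  while (length(remaining)) {
    counts <- colSums(adj[remaining, remaining, drop = FALSE])
    centre <- remaining[which.max(counts)]
    members <- remaining[adj[centre, remaining]]
    clusters[[length(clusters) + 1L]] <- list(centre = centre,
                                              members = sort(members))
    remaining <- setdiff(remaining, members)
  }
  clusters
}

#' GROMOS conformational clustering
#'
#' Iterative neighbour-count clustering of trajectory frames on pairwise
#' RMSD after optimal superposition: the frame with the most neighbours
#' within `cutoff` seeds a cluster, that cluster is removed, and the
#' procedure repeats. When `target_fraction` is given the cutoff is found
#' by bisection so that the largest cluster covers the target fraction of
#' frames to within +/- 5 percentage points (the "approximately 50%"
#' convention for picking representative conformers).
#'
#' @param traj `bead_trajectory` (>= 2 frames), or a precomputed RMSD
#'   matrix.
#' @param cutoff RMSD cutoff, nm. Ignored when `target_fraction` is given.
#' @param target_fraction optional target for the largest-cluster fraction
#'   (e.g. 0.5).
#' @param selection bead indices used for the RMSD (default all).
#' @param tol acceptance half-width around `target_fraction` (default 0.05).
#' @param max_iter bisection iterations (default 60).
#' @return object of class `gromos_clusters`: list with `clusters` (each
#'   with `centre` and `members`), `sizes`, `cutoff`,
#'   `largest_fraction`.
#' @export
gromos_cluster <- function(traj, cutoff = NULL, target_fraction = NULL,
                           selection = NULL, tol = 0.05, max_iter = 60L) {
  M <- if (is.matrix(traj)) traj else rmsd_matrix(traj, selection)
  nf <- nrow(M)
  if (nf < 2L) stopf("need at least 2 frames to cluster")
  frac_at <- function(co) {
    cl <- gromos_pass(M, co)
    max(vapply(cl, function(x) length(x$members), integer(1L))) / nf
  }
  if (!is.null(target_fraction)) {
    lo <- 0
    hi <- max(M)
    f_lo <- frac_at(lo)              # singleton clusters: 1/nf
    f_hi <- frac_at(hi)              # everything in one cluster: 1
    if (target_fraction < f_lo - tol || target_fraction > f_hi + tol)
      stopf("target fraction %.2f unreachable; achievable bracket [%.3f, %.3f]",
            target_fraction, f_lo, f_hi)
    cutoff <- NA_real_
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      f_mid <- frac_at(mid)
      if (abs(f_mid - target_fraction) <= tol) { cutoff <- mid; break }
      if (f_mid < target_fraction) lo <- mid else hi <- mid
    }
    if (is.na(cutoff))
      stopf("cutoff search failed: fraction jumps across the target; bracket [%.4f, %.4f] nm gives [%.3f, %.3f]",
            lo, hi, frac_at(lo), frac_at(hi))
  } else if (is.null(cutoff)) {
    stopf("supply either `cutoff` or `target_fraction`")
  }
  clusters <- gromos_pass(M, cutoff)
  sizes <- vapply(clusters, function(x) length(x$members), integer(1L))
  structure(list(clusters = clusters, sizes = sizes, cutoff = cutoff,
                 largest_fraction = max(sizes) / nf, n_frames = nf),
            class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat(sprintf("GROMOS clustering: %d clusters over %d frames (cutoff %.4g nm); largest covers %.1f%%\n",
              length(x$clusters), x$n_frames, x$cutoff,
              100 * x$largest_fraction))
  invisible(x)
}

#' Structural stability score from cluster dispersion
#'
#' Stability = log10(N_max / S): N_max is the population of the largest
#' conformational cluster and S the fraction of a `grid` x `grid` lattice
#' over the normalized (SASA, Rg) unit square occupied by that cluster's
#' points (floored at one cell). Tight, well-populated clusters score
#' high; diffuse ensembles score low.
#'
#' @param points n x 2 matrix of normalized (SASA, Rg) values in \[0, 1\].
#' @param assignments cluster label per point (e.g. from
#'   [kmeans_states()] or GROMOS membership).
#' @param grid lattice resolution per axis (default 50).
#' @return object of class `stability_score`: list with `stability`,
#'   `N_max`, `S`, `cluster` (label of the largest cluster).
#' @export
stability_score <- function(points, assignments, grid = 50L) {
  points <- as.matrix(points)
  if (!nrow(points)) stopf("empty input")
  if (nrow(points) != length(assignments))
    stopf("one assignment per point required")
  tab <- table(assignments)
  top <- names(tab)[which.max(tab)]
  sel <- points[assignments == top, , drop = FALSE]
  N_max <- nrow(sel)
  cx <- pmin(pmax(ceiling(sel[, 1L] * grid), 1L), grid)
  cy <- pmin(pmax(ceiling(sel[, 2L] * grid), 1L), grid)
  occupied <- max(1L, nrow(unique(cbind(cx, cy))))
  S <- occupied / grid^2
  structure(list(stability = log10(N_max / S), N_max = N_max, S = S,
                 cluster = top, grid = grid),
            class = "stability_score")
}

#' @export
print.stability_score <- function(x, ...) {
  cat(sprintf("Stability = log10(N_max/S) = %.3f (N_max = %d, S = %.4f)\n",
              x$stability, x$N_max, x$S))
  invisible(x)
}

#' Stability with k-fold random subsampling
#'
#' Splits the points of each replicate fold at random and reports the
#' stability score per fold, the conventional way to attach a spread to a
#' single-trajectory score.
#'
#' @inheritParams stability_score
#' @param folds number of random folds (default 3).
#' @param seed RNG seed.
#' @return data.frame with one row per fold (`fold`, `stability`,
#'   `N_max`, `S`) plus attributes `mean` and `sd`.
#' @export
stability_subsample <- function(points, assignments, folds = 3L, grid = 50L,
                                seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  idx <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  rows <- lapply(seq_len(folds), function(f) {
    sub <- idx == f
    sc <- stability_score(points[sub, , drop = FALSE], assignments[sub], grid)
    data.frame(fold = f, stability = sc$stability, N_max = sc$N_max, S = sc$S)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- mean(out$stability)
  attr(out, "sd") <- sd(out$stability)
  out
}
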