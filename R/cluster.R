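#' Cluster assignment on an embedding
#'
#' Seeded k-means (10 restarts) on the embedding coordinates. When `k =
#' "auto"`, candidate counts 2..min(6, n - 2) are scored by mean silhouette
#' and the maximizer is kept. Deterministic given `seed`.
#'
#' @param Y n x d coordinates
#' @param k cluster count, or `"auto"`
#' @param seed RNG seed
#' @param nstart k-means restarts
#' @return An object of class `cluster_assignment`: `labels` (integer per
#'   point), `k`, `method`, `selection_trace` (silhouette per candidate k,
#'   when auto).
#' @export
assign_clusters <- function(Y, k = "auto", seed = 1, nstart = 10) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 4) stop_dustrisk("clustering needs at least 4 points")
  trace <- NULL
  if (identical(k, "auto")) {
    cand <- 2:min(6, n - 2)
    sil <- vapply(cand, function(kk) {
      lab <- kmeans_seeded(Y, kk, seed, nstart)
      if (length(unique(lab)) < 2) return(-Inf)
      silhouette_score(Y, lab)$mean
    }, numeric(1))
    trace <- stats::setNames(sil, cand)
    k <- cand[which.max(sil)]
  }
  if (k < 2 || k > n - 1) stop_dustrisk("k must be in [2, n-1]")
  labels <- kmeans_seeded(Y, k, seed, nstart)
  structure(list(labels = labels, k = as.integer(k),
                 method = sprintf("kmeans (nstart=%d, seed=%d)", nstart, seed),
                 selection_trace = trace),
            class = "cluster_assignment")
}

kmeans_seeded <- function(Y, k, seed, nstart) {
  with_seed(seed, {
    km <- stats::kmeans(Y, centers = k, nstart = nstart, iter.max = 100)
    as.integer(km$cluster)
  })
}

#' Average intra- and inter-cluster distances
#'
#' Intra-cluster distance per cluster: mean pairwise Euclidean distance
#' among its members (0, with a flag, for singletons). Inter-cluster
#' distance: mean distance over all cross-cluster point pairs, pooled.
#'
#' @param Y n x d coordinates
#' @param labels cluster label per point
#' @param inter_method `"pairs"` (default) pools every cross-cluster point
#'   pair into one mean; `"centroid"` averages the pairwise distances between
#'   cluster centroids instead
#' @return list with `intra_per_cluster`, `singleton` (logical per cluster),
#'   `inter_mean`
#' @export
intra_inter_distances <- function(Y, labels, inter_method = c("pairs", "centroid")) {
  inter_method <- match.arg(inter_method)
  Y <- as.matrix(Y)
  D <- dist_matrix(Y)
  labels <- as.vector(labels)
  if (length(labels) != nrow(D)) stop_dustrisk("labels must match the number of points")
  cl <- sort(unique(labels))
  intra <- stats::setNames(numeric(length(cl)), cl)
  singleton <- stats::setNames(logical(length(cl)), cl)
  for (g in seq_along(cl)) {
    idx <- which(labels == cl[g])
    if (length(idx) < 2) { intra[g] <- 0; singleton[g] <- TRUE }
    else intra[g] <- mean(D[idx, idx][upper.tri(D[idx, idx])])
  }
  inter <- if (inter_method == "centroid" && length(cl) > 1) {
    cents <- t(vapply(cl, function(g) colMeans(Y[labels == g, , drop = FALSE]),
                      numeric(ncol(Y))))
    Dc <- dist_matrix(cents)
    mean(Dc[upper.tri(Dc)])
  } else {
    same <- outer(labels, labels, "==")
    cross <- !same & upper.tri(D)
    if (any(cross)) mean(D[cross]) else 0
  }
  list(intra_per_cluster = intra, singleton = singleton, inter_mean = inter)
}

#' Silhouette scores
#'
#' Per point: `s(i) = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' distance to the other members of its cluster and `b_i` the smallest mean
#' distance to another cluster. Points in singleton clusters score 0; points
#' with `a_i = b_i = 0` (coincident) score 0.
#'
#' @param Y n x d coordinates, or a precomputed symmetric distance matrix
#'   (passed with `is_dist = TRUE`)
#' @param labels cluster label per point (at least two distinct clusters)
#' @param is_dist interpret `Y` as a distance matrix
#' @return list with `mean` and `s` (per-point values in `[-1, 1]`)
#' @export
silhouette_score <- function(Y, labels, is_dist = FALSE) {
  D <- if (is_dist) as.matrix(Y) else dist_matrix(as.matrix(Y))
  labels <- as.vector(labels)
  n <- nrow(D)
  cl <- unique(labels)
  if (length(cl) < 2) stop_dustrisk("silhouette needs at least two clusters")
  sizes <- table(factor(labels, levels = cl))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1) { s[i] <- 0; next }
    a <- mean(D[i, labels == own & seq_len(n) != i])
    b <- min(vapply(cl[cl != own], function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean = mean(s), s = s)
}

#' Sammon mapping error
#'
#' `E = (1 / sum_{i<j} d*_ij) * sum_{i<j} (d*_ij - d_ij)^2 / d*_ij`, where
#' `d*` are pairwise distances in the original space and `d` in the
#' embedding. Zero when the embedding reproduces every distance.
#'
#' @param X original data matrix
#' @param Y embedding with matching row count
#' @return non-negative scalar
#' @export
sammon_error <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_dustrisk("X and Y must have the same number of rows")
  Dx <- dist_matrix(X); Dy <- dist_matrix(Y)
  up <- upper.tri(Dx)
  zero <- which(Dx == 0 & up, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop_dustrisk("coincident rows %d and %d in X: Sammon error undefined",
                  zero[1, 1], zero[1, 2])
  dstar <- Dx[up]; d <- Dy[up]
  sum((dstar - d)^2 / dstar) / sum(dstar)
}

#' Cluster quality report for an embedding
#'
#' Bundles the intra/inter-cluster distances, silhouette scores and the
#' Sammon error of an embedding against its source data.
#'
#' @param X original (standardized) data matrix
#' @param Y embedding coordinates
#' @param labels cluster label per point
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(X, Y, labels) {
  dists <- intra_inter_distances(Y, labels)
  sil <- silhouette_score(Y, labels)
  structure(list(intra_per_cluster = dists$intra_per_cluster,
                 singleton = dists$singleton,
                 inter_mean = dists$inter_mean,
                 silhouette_mean = sil$mean, silhouette = sil$s,
                 sammon_error = sammon_error(X, Y)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Cluster quality: silhouette %.3f; inter-cluster mean %.3f; Sammon error %.4f\n",
              x$silhouette_mean, x$inter_mean, x$sammon_error))
  cat("  intra-cluster means:", paste(sprintf("%s=%.3f", names(x$intra_per_cluster),
                                              x$intra_per_cluster), collapse = ", "), "\n")
  invisible(x)
}
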