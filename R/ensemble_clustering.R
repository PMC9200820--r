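#' Cut a hierarchical clustering of an RMSD matrix into k clusters
#'
#' Standard agglomerative clustering on the precomputed pairwise-RMSD
#' dissimilarity, cut to exactly `k` non-empty clusters. Cluster labels are
#' renumbered by decreasing cluster size, ties broken by the smallest
#' member index, so the labelling is deterministic and invariant to input
#' order up to that rule.
#'
#' @param mat symmetric pairwise RMSD matrix (see [pairwise_rmsd_matrix]).
#' @param k number of clusters, `1 <= k <= n`.
#' @param linkage agglomeration rule: `"average"` (default), `"complete"`
#'   or `"single"`. Ward-type linkages are deliberately not offered: RMSD
#'   after independent pairwise fits is not guaranteed Euclidean.
#' @return named integer vector mapping model id to cluster index `1..k`.
#' @export
cut_hierarchy <- function(mat, k, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(mat)
  if (k < 1L || k > n) stop("k out of range 1..", n)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) return(stats::setNames(seq_len(n), ids))
  hc <- stats::hclust(stats::as.dist(mat), method = linkage)
  raw <- stats::cutree(hc, k = k)
  relabel_by_size(stats::setNames(raw, ids))
}

# renumber cluster labels by decreasing size, ties by smallest member index
relabel_by_size <- function(labels) {
  size <- table(labels)
  firsts <- vapply(names(size), function(l) min(which(labels == l)), integer(1L))
  ord <- names(size)[order(-as.integer(size), firsts)]
  stats::setNames(match(as.character(labels), ord), names(labels))
}

#' Within-cluster dispersion curve W(k)
#'
#' W(k) is the size-weighted mean over clusters of the mean within-cluster
#' squared RMSD (singletons contribute zero), computed by cutting the same
#' hierarchy at each `k = 1..k_max`. This is the curve the elbow criterion
#' is applied to.
#'
#' @inheritParams cut_hierarchy
#' @param k_max largest cluster count to evaluate, `< n`.
#' @return numeric vector of length `k_max`, `W(1)..W(k_max)`, in Angstrom^2.
#' @export
dispersion_curve <- function(mat, k_max,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(mat)
  if (k_max >= n) stop("k_max must be smaller than the number of models")
  sq <- mat^2
  vapply(seq_len(k_max), function(k) {
    labels <- cut_hierarchy(mat, k, linkage)
    w <- 0
    for (c in unique(labels)) {
      idx <- which(labels == c)
      nc <- length(idx)
      if (nc > 1L) {
        mean_sq <- sum(sq[idx, idx]) / (nc * (nc - 1L))
        w <- w + (nc / n) * mean_sq
      }
    }
    w
  }, numeric(1L))
}

#' Elbow selection of the cluster count
#'
#' A deterministic surrogate for the visual elbow criterion: compute the
#' dispersion curve W(k), return 1 when W(1) is already below the flatness
#' floor (all models near-identical), and otherwise return the k in
#' `2..(k_max - 1)` maximizing the discrete second difference
#' `W(k-1) - 2 W(k) + W(k+1)`, ties broken towards the smallest k.
#'
#' @inheritParams dispersion_curve
#' @param flatness_floor W(1) level (Angstrom^2) below which the ensemble
#'   is considered homogeneous and k = 1 is returned. The default, 0.25
#'   Angstrom^2, corresponds to a typical within-cluster RMSD of 0.5 A.
#' @return selected k (integer), with the dispersion curve attached as
#'   attribute `"dispersion"`.
#' @export
elbow_select_k <- function(mat, k_max,
                           linkage = c("average", "complete", "single"),
                           flatness_floor = 0.25) {
  linkage <- match.arg(linkage)
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 models to select k")
  if (k_max < 2L || k_max >= n) stop("k_max must satisfy 2 <= k_max < n")
  w <- dispersion_curve(mat, k_max, linkage)
  k <- if (w[1L] < flatness_floor) {
    1L
  } else if (k_max == 2L) {
    2L  # no interior point for a second difference
  } else {
    ks <- 2:(k_max - 1L)
    d2 <- w[ks - 1L] - 2 * w[ks] + w[ks + 1L]
    ks[which.max(d2)]
  }
  attr(k, "dispersion") <- w
  k
}

#' Lowest-energy cluster representatives
#'
#' The representative (centroid, in the decoy-selection sense) of each
#' cluster is the member with the lowest energy; ties are broken by the
#' smallest member index in the labelling order.
#'
#' @param labels named integer vector, model id -> cluster index (see
#'   [cut_hierarchy]).
#' @param energies an [energy_table] covering every labelled model.
#' @return named character vector, cluster index (as name) -> model id.
#' @export
select_centroids <- function(labels, energies) {
  ids <- names(labels)
  e <- lookup_energies(energies, ids)
  cl <- sort(unique(labels))
  out <- vapply(cl, function(c) {
    idx <- which(labels == c)
    idx[which.min(e[idx])]  # which.min -> first (smallest index) on ties
  }, integer(1L))
  stats::setNames(ids[out], cl)
}

#' Cluster an ensemble's RMSD matrix end to end
#'
#' Convenience wrapper: elbow-select k, cut the hierarchy, and (when
#' energies are given) extract lowest-energy centroids.
#'
#' @inheritParams elbow_select_k
#' @param energies optional [energy_table] for centroid extraction.
#' @return object of class `clustering_result`: list with `k`, `labels`,
#'   `dispersion_curve`, `linkage` and (if energies given) `centroid_ids`
#'   and `centroid_energies`.
#' @export
cluster_ensemble <- function(mat, energies = NULL, k_max = 10L,
                             linkage = c("average", "complete", "single"),
                             flatness_floor = 0.25) {
  linkage <- match.arg(linkage)
  k_max <- min(k_max, nrow(mat) - 1L)
  k <- elbow_select_k(mat, k_max, linkage, flatness_floor)
  labels <- cut_hierarchy(mat, as.integer(k), linkage)
  res <- list(k = as.integer(k), labels = labels,
              dispersion_curve = attr(k, "dispersion"), linkage = linkage)
  if (!is.null(energies)) {
    res$centroid_ids <- select_centroids(labels, energies)
    res$centroid_energies <- lookup_energies(energies, res$centroid_ids)
  }
  class(res) <- "clustering_result"
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("hierarchical RMSD clustering (%s linkage): k = %d\n",
              x$linkage, x$k))
  sz <- table(x$labels)
  cat("  cluster sizes:", paste(sz, collapse = ", "), "\n")
  if (!is.null(x$centroid_ids)) {
    cat("  centroids:",
        paste(sprintf("%s (%.1f kcal/mol)", x$centroid_ids,
                      x$centroid_energies), collapse = "; "), "\n")
  }
  invisible(x)
}
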