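#' Cartesian principal component analysis of an aligned ensemble
#'
#' Eigendecomposition (via SVD) of the covariance of the flattened selected
#' coordinates about the ensemble mean — the "essential dynamics" analysis
#' used to extract collective motions from structure ensembles and MD
#' trajectories. Covariance is unweighted (no mass weighting). For
#' reproducibility each component's largest-magnitude entry is made
#' positive.
#'
#' @param aligned an [ensemble], already superposed to a common frame (see
#'   [align_to_mean]); at least 2 models.
#' @param selection atoms entering the covariance, `"calpha"` (default) or
#'   `"backbone"`.
#' @return object of class `pc_model`: list with `mean` (flattened 3N
#'   vector, Angstrom), `components` (3N x p orthonormal matrix, columns
#'   sorted by decreasing variance), `variances` (Angstrom^2, sample
#'   variance with denominator n - 1), `variance_fraction` (NA when the
#'   total variance is zero, with `degenerate = TRUE`), `atoms` and
#'   `selection` (used to check topology at projection time).
#' @export
fit_cartesian_pca <- function(aligned, selection = c("calpha", "backbone")) {
  selection <- match.arg(selection)
  n <- n_models(aligned)
  if (n < 2L) stop("need at least 2 models for PCA")
  sub <- extract_atoms(aligned, selection)
  x <- sub$xyz
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  p <- min(n - 1L, ncol(x))
  comps <- sv$v[, seq_len(p), drop = FALSE]
  vars <- (sv$d[seq_len(p)]^2) / (n - 1L)
  # sign convention: largest-magnitude entry of each component positive
  for (j in seq_len(p)) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  total <- sum(vars)
  degenerate <- total <= 0
  structure(list(mean = mu, components = comps, variances = vars,
                 variance_fraction = if (degenerate) rep(NA_real_, p)
                                     else vars / total,
                 degenerate = degenerate,
                 atoms = sub$atoms, selection = selection),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("Cartesian PCA (%s): %d components over %d atoms\n",
              x$selection, ncol(x$components), nrow(x$atoms)))
  if (x$degenerate) {
    cat("  degenerate: all models identical (zero total variance)\n")
  } else {
    cat(sprintf("  PC1 variance fraction: %.3f\n", x$variance_fraction[1L]))
  }
  invisible(x)
}

#' Project an ensemble onto a principal component
#'
#' Scores each model along one learned component: the inner product of the
#' model's centered flattened coordinates with the component vector.
#' External ensembles (e.g. trajectory frames projected onto components
#' learned from a decoy cluster) are first superposed model-by-model onto
#' the PC mean so that both ensembles share a frame; set `refit = FALSE`
#' when projecting the fitting ensemble itself, which is already in that
#' frame.
#'
#' @param pc a `pc_model` from [fit_cartesian_pca].
#' @param ens an [ensemble] whose selected atoms match `pc` (same atom
#'   keys, same order).
#' @param component component index, default 1.
#' @param refit superpose each model onto the PC mean before scoring
#'   (default `TRUE`).
#' @return data.frame with columns `model_id`, `score` (Angstrom).
#' @export
project_models <- function(pc, ens, component = 1L, refit = TRUE) {
  if (component < 1L || component > ncol(pc$components)) {
    stop("component out of range 1..", ncol(pc$components))
  }
  sub <- extract_atoms(ens, pc$selection)
  if (!identical(paste(sub$atoms$chain, sub$atoms$resno, sub$atoms$elety),
                 paste(pc$atoms$chain, pc$atoms$resno, pc$atoms$elety))) {
    stop("topology mismatch between ensemble and PC model")
  }
  mu <- vec2coords(pc$mean)
  v <- pc$components[, component]
  scores <- vapply(seq_len(n_models(sub)), function(i) {
    m <- model_coords(sub, i)
    if (refit) m <- apply_superposition(kabsch_superpose(m, mu), m)
    sum((coords2vec(m) - pc$mean) * v)
  }, numeric(1L))
  data.frame(model_id = sub$model_ids, score = scores,
             stringsAsFactors = FALSE)
}

#' Overlap coefficient of two projection-score densities
#'
#' Gaussian kernel density estimates (Silverman bandwidth) of both score
#' series are evaluated on a shared grid spanning both supports (padded by
#' three bandwidths), and the overlap is the integral of the pointwise
#' minimum — 1 for identical distributions, 0 for disjoint ones. This is
#' the score used to ask whether the collective motion explored by a decoy
#' cluster is compatible with that of a reference trajectory.
#'
#' Each density is normalized independently, so unequal sample counts need
#' no correction. A zero-variance series is treated as a point mass: the
#' overlap falls back to the fraction of the other series within one
#' bandwidth of that point (1 or 0 when both series are degenerate).
#'
#' @param scores_a,scores_b numeric vectors of scores (or data.frames from
#'   [project_models], whose `score` column is used), each of length >= 5.
#' @param n_grid number of grid points, default 512.
#' @return overlap coefficient in \[0, 1\].
#' @export
density_overlap <- function(scores_a, scores_b, n_grid = 512L) {
  a <- if (is.data.frame(scores_a)) scores_a$score else as.numeric(scores_a)
  b <- if (is.data.frame(scores_b)) scores_b$score else as.numeric(scores_b)
  if (length(a) < 5L || length(b) < 5L) stop("need at least 5 scores per series")
  sda <- stats::sd(a); sdb <- stats::sd(b)
  if (sda == 0 && sdb == 0) return(as.numeric(abs(mean(a) - mean(b)) <= 1e-8))
  if (sda == 0 || sdb == 0) {
    pt <- if (sda == 0) mean(a) else mean(b)
    other <- if (sda == 0) b else a
    h <- stats::bw.nrd0(other)
    return(mean(abs(other - pt) <= h))
  }
  ha <- stats::bw.nrd0(a); hb <- stats::bw.nrd0(b)
  pad <- 3 * max(ha, hb)
  lo <- min(a, b) - pad; hi <- max(a, b) + pad
  da <- stats::density(a, bw = ha, from = lo, to = hi, n = n_grid)
  db <- stats::density(b, bw = hb, from = lo, to = hi, n = n_grid)
  dx <- da$x[2L] - da$x[1L]
  min(1, max(0, sum(pmin(da$y, db$y)) * dx))
}
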