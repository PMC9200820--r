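#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD of `mobile` onto `target`, via singular value
#' decomposition of the cross-covariance matrix with the determinant
#' correction that excludes reflections (chirality is preserved).
#'
#' @param mobile,target numeric `n x 3` coordinate matrices (Angstrom) with
#'   the same number of rows, `n >= 3`.
#' @param weights optional non-negative per-atom weights (not all zero).
#'   The default is the unweighted, purely geometric fit.
#' @return an object of class `superposition`: list with `rotation` (3x3,
#'   orthonormal, det +1), `translation` (length-3, Angstrom) and `rmsd`
#'   (the minimized value, Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (see [apply_superposition]).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L) stop("coordinates must be n x 3")
  if (nrow(mobile) != nrow(target)) stop("mismatched atom counts")
  if (nrow(mobile) < 3L) stop("need at least 3 atoms to superpose")
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("weights must be non-negative, one per atom")
  }
  sw <- sum(weights)
  if (sw <= 0) stop("all-zero weights")
  cm <- colSums(mobile * weights) / sw
  ct <- colSums(target * weights) / sw
  mc <- sweep(mobile, 2L, cm)
  tc <- sweep(target, 2L, ct)
  if (max(abs(mc)) == 0 && max(abs(tc)) == 0) stop("all points coincident")
  h <- crossprod(mc * weights, tc)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(sum(weights * rowSums((fitted - tc)^2)) / sw)
  structure(list(rotation = rot, translation = as.vector(ct - rot %*% cm),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sup a `superposition` from [kabsch_superpose].
#' @param coords numeric `n x 3` matrix.
#' @return the transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Minimized RMSD between two coordinate sets
#'
#' Convenience wrapper returning only the RMSD of the optimal rigid fit.
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, target, weights = NULL) {
  kabsch_superpose(mobile, target, weights)$rmsd
}

# fast minimized RMSD from pre-centered coordinates and their squared norms
rmsd_centered <- function(ci, cj, ssqi, ssqj) {
  h <- crossprod(ci, cj)
  s <- svd(h, nu = 0L, nv = 0L)$d
  if (det(h) < 0) s[3L] <- -s[3L]
  sqrt(max(0, (ssqi + ssqj - 2 * sum(s)) / nrow(ci)))
}

#' Pairwise minimized-RMSD matrix of an ensemble
#'
#' Entry (i, j) is the RMSD between models i and j after an independent
#' optimal superposition of that pair. Because each pair is fitted
#' independently the result is a dissimilarity, not necessarily a metric;
#' only symmetry, non-negativity and a zero diagonal are guaranteed.
#'
#' @param ens an [ensemble] with at least 2 models. Apply [extract_atoms]
#'   first to compute e.g. a backbone RMSD matrix.
#' @return symmetric numeric matrix (Angstrom) with `model_ids` as
#'   dimnames and a zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ens) {
  n <- n_models(ens)
  if (n < 2L) stop("need at least 2 models for a pairwise RMSD matrix")
  cen <- lapply(seq_len(n), function(i) {
    m <- model_coords(ens, i)
    sweep(m, 2L, colMeans(m))
  })
  ssq <- vapply(cen, function(m) sum(m * m), numeric(1L))
  v <- matrix(0, n, n, dimnames = list(ens$model_ids, ens$model_ids))
  for (i in seq_len(n - 1L)) {
    ci <- cen[[i]]
    for (j in seq.int(i + 1L, n)) {
      v[i, j] <- v[j, i] <- rmsd_centered(ci, cen[[j]], ssq[i], ssq[j])
    }
  }
  v
}

#' Iteratively align an ensemble onto its mean conformation
#'
#' Superposes every model onto the current mean, recomputes the mean, and
#' repeats until the mean shifts by less than `tol` (plain RMSD between
#' successive means) or `max_iter` is reached. The first model seeds the
#' initial reference, making the procedure deterministic.
#'
#' @param ens an [ensemble] with at least 2 models.
#' @param tol convergence tolerance on the mean shift, Angstrom.
#' @param max_iter maximum number of mean-refit iterations; non-convergence
#'   is reported as a warning, not a failure.
#' @return list with `ensemble` (transformed copies), `mean`
#'   (`n_atoms x 3` matrix), `iterations` and `converged`.
#' @export
align_to_mean <- function(ens, tol = 1e-6, max_iter = 10L) {
  n <- n_models(ens)
  if (n < 2L) stop("need at least 2 models to align")
  coords <- lapply(seq_len(n), function(i) model_coords(ens, i))
  ref <- coords[[1L]]
  fit_all <- function(cs, target) {
    lapply(cs, function(m) apply_superposition(kabsch_superpose(m, target), m))
  }
  coords <- fit_all(coords, ref)
  m_old <- Reduce(`+`, coords) / n
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    coords <- fit_all(coords, m_old)
    m_new <- Reduce(`+`, coords) / n
    shift <- sqrt(mean(rowSums((m_new - m_old)^2)))
    m_old <- m_new
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("align_to_mean did not converge in ", max_iter, " iterations")
  }
  xyz <- do.call(rbind, lapply(coords, coords2vec))
  list(ensemble = ensemble(xyz, ens$atoms, ens$model_ids),
       mean = m_old, iterations = it, converged = converged)
}

#' Per-residue root-mean-square fluctuation of an aligned ensemble
#'
#' For each residue, the fluctuation is the root of the mean (over models)
#' squared displacement of the residue's selected-atom centroid from its
#' ensemble-mean position. With `selection = "calpha"` the centroid is the
#' CA atom itself; with `"backbone"` it is the centroid of the backbone
#' atoms. Values are reported in nm (coordinates are Angstrom; 1 nm = 10 A)
#' to match the conventional trajectory-analysis scale.
#'
#' @param aligned an [ensemble] that has already been aligned (see
#'   [align_to_mean]); at least 2 models.
#' @param selection `"calpha"` (default) or `"backbone"`.
#' @return data.frame with columns `chain`, `residue_number`, `rmsf_nm`.
#' @export
rmsf_profile <- function(aligned, selection = c("calpha", "backbone")) {
  selection <- match.arg(selection)
  if (n_models(aligned) < 2L) {
    stop("fluctuation undefined for a single-model ensemble")
  }
  sub <- extract_atoms(aligned, selection)
  key <- paste(sub$atoms$chain, sub$atoms$resno)
  groups <- split(seq_len(n_atoms(sub)), factor(key, levels = unique(key)))
  n <- n_models(sub)
  out <- vapply(groups, function(idx) {
    cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
    # per-model residue centroid, n x 3
    cen <- sapply(1:3, function(a) {
      rowMeans(sub$xyz[, cols[seq(a, length(cols), by = 3L)], drop = FALSE])
    })
    cen <- matrix(cen, nrow = n)
    mu <- colMeans(cen)
    sqrt(mean(rowSums(sweep(cen, 2L, mu)^2))) / 10
  }, numeric(1L))
  first <- !duplicated(key)
  data.frame(chain = sub$atoms$chain[first],
             residue_number = sub$atoms$resno[first],
             rmsf_nm = unname(out), stringsAsFactors = FALSE)
}

#' RMSD of a residue region after superposition on a wider selection
#'
#' Superposes model `b` onto model `a` using all atoms of `fit_selection`,
#' then reports the RMSD over the region atoms without refitting. This is
#' the usual way a local conformational change (e.g. the displacement of
#' one helix between an apo and a holo crystal form) is quantified after a
#' global backbone fit. Atoms are matched by (chain, residue number, atom
#' name); atoms present in only one structure are dropped.
#'
#' @param a,b single-model [ensemble]s.
#' @param region a [region_spec] (one or more rows) delimiting the residues
#'   to score.
#' @param fit_selection selection used for the global fit, `"backbone"` or
#'   `"calpha"`.
#' @return RMSD over the region atoms, Angstrom.
#' @export
region_shift_rmsd <- function(a, b, region,
                              fit_selection = c("backbone", "calpha")) {
  fit_selection <- match.arg(fit_selection)
  a <- extract_atoms(a, fit_selection)
  b <- extract_atoms(b, fit_selection)
  common <- intersect(atom_keys(a), atom_keys(b))
  if (length(common) < 3L) stop("fewer than 3 shared atoms")
  a <- subset_atoms_by_key(a, common)
  b <- subset_atoms_by_key(b, common)
  ca <- model_coords(a, 1L)
  cb <- apply_superposition(kabsch_superpose(model_coords(b, 1L), ca),
                            model_coords(b, 1L))
  in_reg <- rep(FALSE, n_atoms(a))
  for (r in seq_len(nrow(region))) {
    in_reg <- in_reg | (a$atoms$chain == region$chain[r] &
                        a$atoms$resno >= region$first[r] &
                        a$atoms$resno <= region$last[r])
  }
  if (!any(in_reg)) stop("empty selection: region outside structure")
  sqrt(mean(rowSums((ca[in_reg, , drop = FALSE] -
                     cb[in_reg, , drop = FALSE])^2)))
}

# restrict an ensemble to the atoms whose keys appear in `keys`,
# preserving ensemble atom order
subset_atoms_by_key <- function(ens, keys) {
  idx <- which(atom_keys(ens) %in% keys)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  ensemble(ens$xyz[, cols, drop = FALSE], ens$atoms[idx, , drop = FALSE],
           ens$model_ids)
}
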