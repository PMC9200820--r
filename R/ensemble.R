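#' Construct an ensemble of topology-consistent structure models
#'
#' An `ensemble` is the central container of the package: an ordered set of
#' conformers (predicted decoys, trajectory frames, or reference structures)
#' that share exactly the same atoms in the same order, stored as a
#' coordinate matrix in the trajectory layout used by bio3d
#' (one row per model, columns `x1, y1, z1, x2, ...`, in Angstrom).
#'
#' @param xyz numeric matrix, `n_models x (3 * n_atoms)`, Angstrom.
#' @param atoms data.frame with one row per atom and columns `elety`
#'   (atom name), `resid` (residue name), `chain` (chain identifier) and
#'   `resno` (author residue number, integer).
#' @param model_ids character vector of unique model identifiers, one per
#'   row of `xyz`. Used as the join key against energy tables.
#'
#' @return An object of class `ensemble`: a list with elements `xyz`,
#'   `atoms` and `model_ids`.
#' @export
ensemble <- function(xyz, atoms, model_ids) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz)) stop("'xyz' must be numeric")
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one model")
  if (ncol(xyz) %% 3L != 0L) stop("'xyz' must have 3 columns per atom")
  n_at <- ncol(xyz) %/% 3L
  req <- c("elety", "resid", "chain", "resno")
  if (!all(req %in% names(atoms))) {
    stop("'atoms' must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) != n_at) stop("'atoms' rows must match xyz atom count")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  atoms$resno <- as.integer(atoms$resno)
  model_ids <- as.character(model_ids)
  if (length(model_ids) != nrow(xyz)) {
    stop("'model_ids' length must match the number of models")
  }
  if (anyDuplicated(model_ids)) stop("duplicate model_ids")
  keys <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(keys)) {
    stop("duplicate atom keys (chain, residue_number, atom_name): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  }
  atoms <- atoms[, req]
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, atoms = atoms, model_ids = model_ids),
            class = "ensemble")
}

#' Number of models in an ensemble
#' @param x an `ensemble`.
#' @return integer count.
#' @export
n_models <- function(x) nrow(x$xyz)

#' Number of atoms shared by every model of an ensemble
#' @param x an `ensemble`.
#' @return integer count.
#' @export
n_atoms <- function(x) ncol(x$xyz) %/% 3L

#' Shared atom keys of an ensemble
#'
#' @param x an `ensemble`.
#' @return character vector `"chain resno atom_name"`, one per atom, in
#'   ensemble atom order.
#' @export
atom_keys <- function(x) paste(x$atoms$chain, x$atoms$resno, x$atoms$elety)

#' Subset the models of an ensemble
#'
#' @param x an `ensemble`.
#' @param i integer, logical or character (model id) index.
#' @return an `ensemble` with the selected models, atom set unchanged.
#' @export
subset_models <- function(x, i) {
  if (is.character(i)) {
    j <- match(i, x$model_ids)
    if (anyNA(j)) stop("unknown model ids: ", paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  ensemble(x$xyz[i, , drop = FALSE], x$atoms, x$model_ids[i])
}

#' Coordinates of one model as an n_atoms x 3 matrix
#'
#' @param x an `ensemble`.
#' @param i single model index or model id.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
model_coords <- function(x, i = 1L) {
  if (is.character(i)) i <- match(i, x$model_ids)
  vec2coords(x$xyz[i, ])
}

# flattened xyz vector (x1,y1,z1,...) -> n x 3 matrix
vec2coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

# n x 3 matrix -> flattened xyz vector
coords2vec <- function(m) as.vector(t(m))

#' @export
print.ensemble <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("ensemble: %d model(s), %d atoms, %d residues\n",
              n_models(x), n_atoms(x), length(res)))
  cat("  model_ids:", paste(utils::head(x$model_ids, 5L), collapse = ", "),
      if (n_models(x) > 5L) "..." else "", "\n")
  invisible(x)
}

# assert two ensembles carry the same atoms in the same order
check_same_topology <- function(a, b, what = "ensembles") {
  if (n_atoms(a) != n_atoms(b) || !identical(atom_keys(a), atom_keys(b))) {
    stop("topology mismatch between ", what,
         ": atom keys differ or are ordered differently")
  }
  invisible(TRUE)
}
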