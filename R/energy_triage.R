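#' Mean-energy decoy filter
#'
#' Removes from a decoy set every model whose energy is strictly greater
#' than the arithmetic mean energy of the listed models; models at exactly
#' the threshold are kept. The threshold is computed once, over exactly the
#' ids passed in, so the caller controls the averaging population.
#' Re-running the filter on the kept subset recomputes a (lower) mean and
#' generally removes more models; the filter is intended to be applied once.
#'
#' @param energies an [energy_table].
#' @param model_ids ordered character vector of ids to filter; every id
#'   must be present in `energies`.
#' @return object of class `filter_result`: list with `threshold`
#'   (kcal/mol), `kept_ids` and `removed_ids` (both in input order).
#' @export
mean_energy_filter <- function(energies, model_ids) {
  model_ids <- as.character(model_ids)
  if (length(model_ids) < 1L) stop("need at least one model id")
  e <- lookup_energies(energies, model_ids)
  threshold <- mean(e)
  removed <- e > threshold
  structure(list(threshold = threshold,
                 kept_ids = model_ids[!removed],
                 removed_ids = model_ids[removed]),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("mean-energy filter: threshold %.2f kcal/mol; kept %d, removed %d\n",
              x$threshold, length(x$kept_ids), length(x$removed_ids)))
  invisible(x)
}

#' Energy-RMSD correlation diagnostic
#'
#' Pearson correlation between per-model energy and per-model RMSD to a
#' reference structure, the standard diagnostic of whether an energy
#' function discriminates near-native from distant decoys (a funnel-shaped
#' landscape gives a clear positive correlation).
#'
#' @param energies an [energy_table] covering every model of `ens`.
#' @param reference a single-model [ensemble] with the same topology as
#'   `ens` on the comparison selection.
#' @param ens an [ensemble] of at least 3 models.
#' @param selection atom selection for the RMSD, default `"backbone"`.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
energy_rmsd_correlation <- function(energies, reference, ens,
                                    selection = c("backbone", "calpha")) {
  selection <- match.arg(selection)
  if (n_models(ens) < 3L) stop("need at least 3 models")
  if (n_models(reference) != 1L) stop("'reference' must hold exactly one model")
  sub <- extract_atoms(ens, selection)
  ref <- extract_atoms(reference, selection)
  check_same_topology(sub, ref, "ensemble and reference")
  rc <- model_coords(ref, 1L)
  r <- vapply(seq_len(n_models(sub)), function(i) {
    rmsd_fit(model_coords(sub, i), rc)
  }, numeric(1L))
  e <- lookup_energies(energies, sub$model_ids)
  if (stats::sd(e) == 0 || stats::sd(r) == 0) {
    stop("correlation undefined: zero variance in energy or RMSD")
  }
  stats::cor(e, r)
}

#' Write a filter result as CSV
#'
#' Columns `model_id,energy_kcal_mol,kept`, in the original model order.
#'
#' @param x a `filter_result`.
#' @param energies the [energy_table] the filter was computed from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_result <- function(x, energies, path) {
  ids <- c(x$kept_ids, x$removed_ids)
  ids <- ids[order(match(ids, energies$model_id))]
  df <- data.frame(model_id = ids,
                   energy_kcal_mol = unname(lookup_energies(energies, ids)),
                   kept = ids %in% x$kept_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
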