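#' Configure an ensemble-analysis run
#'
#' Exactly one of `models` (paths to real input) or `synthetic` (a
#' generator spec) must be given. All randomness in a run flows from
#' `seed`: in synthetic mode the generator, the energy noise and the
#' pseudo-trajectory are reseeded deterministically from it.
#'
#' @param models path to a multi-model PDB file or directory of decoy
#'   models (real-input mode).
#' @param energies path to the energy CSV (required with `models`).
#' @param references path to a PDB file/directory of labelled reference
#'   conformations (model ids become class labels).
#' @param regions path to a region config file; the first three regions
#'   are used as arm A, hinge and arm B for the descriptor stage.
#' @param md_models optional path to reference/MD conformer models for the
#'   projection-overlap stage.
#' @param synthetic a [synthetic_spec] (synthetic mode).
#' @param emodel an [energy_model_spec] (synthetic mode).
#' @param md a [pseudo_md_spec] (synthetic mode).
#' @param selection `"backbone"` or `"calpha"`: selection used for the
#'   RMSD matrix, classification and spread.
#' @param pca_selection selection for RMSF and PCA, default `"calpha"`.
#' @param linkage clustering linkage, default `"average"`.
#' @param k_max largest cluster count scanned by the elbow, default 10.
#' @param flatness_floor see [elbow_select_k].
#' @param intermediate_margin see [classify_by_reference].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @return validated list of class `run_config`.
#' @export
pipeline_config <- function(models = NULL, energies = NULL, references = NULL,
                            regions = NULL, md_models = NULL,
                            synthetic = NULL, emodel = energy_model_spec(),
                            md = pseudo_md_spec(),
                            selection = c("backbone", "calpha"),
                            pca_selection = c("calpha", "backbone"),
                            linkage = c("average", "complete", "single"),
                            k_max = 10L, flatness_floor = 0.25,
                            intermediate_margin = 0, seed = 1L,
                            out_dir = tempfile("confens_run_")) {
  selection <- match.arg(selection)
  pca_selection <- match.arg(pca_selection)
  linkage <- match.arg(linkage)
  if (is.null(models) == is.null(synthetic)) {
    stop("exactly one of 'models' or 'synthetic' must be given")
  }
  if (!is.null(models) && is.null(energies)) {
    stop("'energies' is required with 'models'")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  structure(list(models = models, energies = energies,
                 references = references, regions = regions,
                 md_models = md_models, synthetic = synthetic,
                 emodel = emodel, md = md,
                 selection = selection, pca_selection = pca_selection,
                 linkage = linkage, k_max = as.integer(k_max),
                 flatness_floor = flatness_floor,
                 intermediate_margin = intermediate_margin,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full ensemble-analysis pipeline
#'
#' Executes the post-prediction stages in order — ingest, atom selection,
#' mean-energy filtering, pairwise RMSD, elbow cluster-count selection,
#' hierarchy cut, lowest-energy centroids, alignment to the mean, RMSF,
#' Cartesian PCA, cross-ensemble projection and density overlap, hinge
#' descriptors, reference classification and ensemble spread — writing
#' each stage's CSV, a structured JSON summary and a run log into
#' `config$out_dir`. Identical config and seed produce byte-identical
#' outputs. Any stage error aborts with a stage-named message.
#'
#' @param config a [pipeline_config].
#' @return the run summary (named list), invisibly identical to the
#'   contents of `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  ## ingest ----------------------------------------------------------------
  inp <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- config$seed
      draw <- sample_two_state_ensemble(spec)
      energies <- assign_energies(draw$truth, config$emodel,
                                  seed = config$seed + 1L)
      md <- config$md
      md$seed <- config$seed + 2L
      traj <- sample_pseudo_md(spec, md)
      refs <- ensemble(rbind(draw$endpoints$open$xyz,
                             draw$endpoints$closed$xyz),
                       draw$endpoints$open$atoms, c("open", "closed"))
      list(models = draw$ensemble, energies = energies, refs = refs,
           regions = draw$endpoints$regions, md = traj$ensemble)
    } else {
      models <- read_pdb_models(config$models)
      energies <- read_energy_table(config$energies)
      refs <- if (!is.null(config$references)) {
        read_pdb_models(config$references)
      }
      regions <- if (!is.null(config$regions)) {
        read_region_config(config$regions)
      }
      mdens <- if (!is.null(config$md_models)) {
        read_pdb_models(config$md_models)
      }
      list(models = models, energies = energies, refs = refs,
           regions = regions, md = mdens)
    }
  })
  note("ingest: %d models, %d atoms", n_models(inp$models),
       n_atoms(inp$models))

  sel <- stage("extract", extract_atoms(inp$models, config$selection))

  ## energy filter ---------------------------------------------------------
  filt <- stage("energy_filter",
                mean_energy_filter(inp$energies, sel$model_ids))
  write_filter_result(filt, inp$energies, out("energy_filter.csv"))
  note("energy_filter: threshold %.4f kcal/mol; kept %d of %d",
       filt$threshold, length(filt$kept_ids), n_models(sel))
  kept <- stage("energy_filter", subset_models(sel, filt$kept_ids))
  kept_full <- subset_models(inp$models, filt$kept_ids)

  ## clustering ------------------------------------------------------------
  mat <- stage("pairwise_rmsd", pairwise_rmsd_matrix(kept))
  utils::write.csv(mat, out("rmsd_matrix.csv"))
  clus <- stage("clustering",
                cluster_ensemble(mat, inp$energies, k_max = config$k_max,
                                 linkage = config$linkage,
                                 flatness_floor = config$flatness_floor))
  utils::write.csv(data.frame(k = seq_along(clus$dispersion_curve),
                              W = clus$dispersion_curve),
                   out("dispersion.csv"), row.names = FALSE)
  e_kept <- lookup_energies(inp$energies, kept$model_ids)
  utils::write.csv(data.frame(model_id = kept$model_ids,
                              cluster = unname(clus$labels[kept$model_ids]),
                              energy_kcal_mol = unname(e_kept),
                              is_centroid = kept$model_ids %in%
                                clus$centroid_ids),
                   out("clusters.csv"), row.names = FALSE)
  note("clustering: k = %d (%s linkage); centroids: %s", clus$k,
       clus$linkage,
       paste(sprintf("cluster %s -> %s (%.1f kcal/mol)",
                     names(clus$centroid_ids), clus$centroid_ids,
                     clus$centroid_energies), collapse = "; "))

  ## alignment, RMSF, PCA --------------------------------------------------
  aligned <- stage("align", align_to_mean(kept))
  rmsf <- stage("rmsf", rmsf_profile(aligned$ensemble, config$pca_selection))
  utils::write.csv(rmsf, out("rmsf.csv"), row.names = FALSE)
  pc <- stage("pca", fit_cartesian_pca(aligned$ensemble,
                                       config$pca_selection))
  utils::write.csv(data.frame(component = seq_along(pc$variances),
                              variance_A2 = pc$variances,
                              fraction = pc$variance_fraction),
                   out("pc_variances.csv"), row.names = FALSE)
  proj_models <- stage("projection",
                       project_models(pc, aligned$ensemble, 1L,
                                      refit = FALSE))
  scores <- cbind(proj_models, component = 1L)
  overlap <- NULL
  if (!is.null(inp$md)) {
    proj_md <- stage("projection", project_models(pc, inp$md, 1L))
    scores <- rbind(scores, cbind(proj_md, component = 1L))
    overlap <- stage("overlap", density_overlap(proj_models, proj_md))
    note("overlap: PC1 density overlap models vs reference trajectory = %.4f",
         overlap)
  }
  utils::write.csv(data.frame(model_id = scores$model_id,
                              component = scores$component,
                              score_A = scores$score),
                   out("pc_scores.csv"), row.names = FALSE)

  ## descriptors and classification ----------------------------------------
  desc <- NULL
  if (!is.null(inp$regions) && nrow(inp$regions) >= 3L) {
    rg <- inp$regions
    pick <- function(nm, i) {
      j <- match(nm, rg$name)
      rg[if (is.na(j)) i else j, , drop = FALSE]
    }
    desc <- stage("descriptors",
                  descriptor_series(kept_full, pick("arm_a", 1L),
                                    pick("hinge", 2L), pick("arm_b", 3L)))
  }
  cls <- NULL
  if (!is.null(inp$refs)) {
    cls <- stage("classification",
                 classify_by_reference(kept_full, inp$refs,
                                       config$intermediate_margin,
                                       config$selection))
    pop <- data.frame(label = names(cls$fractions),
                      count = as.integer(table(cls$labels)[names(cls$fractions)]),
                      fraction = unname(cls$fractions))
    utils::write.csv(pop, out("populations.csv"), row.names = FALSE)
    note("classification: %s",
         paste(sprintf("%s %.3f", pop$label, pop$fraction), collapse = "; "))
  }
  if (!is.null(desc)) {
    desc$label <- if (!is.null(cls)) unname(cls$labels[desc$model_id]) else NA
    utils::write.csv(desc, out("descriptors.csv"), row.names = FALSE)
  }

  spread <- stage("spread", ensemble_spread(kept_full, config$selection))
  note("spread: delta RMSD = %.4f A over %d kept models", spread,
       n_models(kept_full))

  ## summary ----------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    selection = config$selection,
    linkage = config$linkage,
    n_models = n_models(sel),
    energy_threshold_kcal_mol = filt$threshold,
    n_kept = length(filt$kept_ids),
    n_removed = length(filt$removed_ids),
    k = clus$k,
    centroids = data.frame(cluster = as.integer(names(clus$centroid_ids)),
                           model_id = unname(clus$centroid_ids),
                           energy_kcal_mol = unname(clus$centroid_energies)),
    delta_rmsd_A = spread,
    pc1_variance_fraction = pc$variance_fraction[1L],
    pc1_density_overlap = overlap,
    populations = if (!is.null(cls)) as.list(cls$fractions),
    max_rmsf_nm = max(rmsf$rmsf_nm)
  )
  summary <- summary[!vapply(summary, is.null, logical(1L))]
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run_log.txt"))
  invisible(summary)
}
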