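#' Read a multi-model PDB file (or a directory of PDB files) as an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one model (a single implicit model if
#' the file has none); a directory is read as one model per file, in sorted
#' file order. All models must share the same atoms in the same order;
#' models whose atom set differs from the first model's are rejected with a
#' warning naming them.
#'
#' Alternate locations are resolved to a single conformer before any
#' analysis: per atom key the highest-occupancy altloc is kept, with the
#' blank altloc preferred on ties and ties otherwise broken alphabetically.
#' Files with insertion codes are rejected so residue keys stay integers.
#'
#' Model identifiers are taken from the `MODEL` serial numbers when present,
#' and from the file stem otherwise (directory mode); both give a stable
#' join key against an energy table.
#'
#' @param path path to a PDB file or to a directory containing `.pdb` files.
#' @param het_policy `"strip"` (default) removes all HETATM records,
#'   including waters, keeping protein atoms only, as is done when
#'   preprocessing experimental structures for ensemble comparison;
#'   `"keep"` retains every atom.
#' @return an [ensemble].
#' @export
read_pdb_models <- function(path, het_policy = c("strip", "keep")) {
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no .pdb files found in directory: ", path)
    parts <- lapply(files, read_pdb_models, het_policy = het_policy)
    ids <- unlist(lapply(seq_along(parts), function(i) {
      stem <- sub("\\.pdb$", "", basename(files[[i]]), ignore.case = TRUE)
      if (n_models(parts[[i]]) == 1L) stem
      else paste0(stem, "_", parts[[i]]$model_ids)
    }))
    ref <- parts[[1L]]
    keep <- vapply(parts, function(p) {
      identical(atom_keys(p), atom_keys(ref))
    }, logical(1L))
    if (!all(keep)) {
      bad <- ids[rep(!keep, vapply(parts, n_models, integer(1L)))]
      warning("rejected models with inconsistent atom sets: ",
              paste(bad, collapse = ", "))
    }
    if (!any(keep)) stop("no topology-consistent models to read")
    xyz <- do.call(rbind, lapply(parts[keep], function(p) p$xyz))
    return(ensemble(xyz, ref$atoms,
                    ids[rep(keep, vapply(parts, n_models, integer(1L)))]))
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert))) {
    stop("insertion codes are not supported (file: ", path, ")")
  }
  keep <- rep(TRUE, nrow(at))
  if (het_policy == "strip") {
    sel <- bio3d::atom.select(pdb, "protein", verbose = FALSE)
    keep <- seq_len(nrow(at)) %in% sel$atom
  }
  # altloc resolution: one conformer per (chain, resno, atom name)
  keep <- keep & altloc_mask(at)
  if (!any(keep)) stop("zero protein atoms after filtering in: ", path)
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                          3L * which(keep)))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  at$alt[] <- NA

  ids <- model_serials(path)
  if (length(ids) != nrow(xyz)) {
    ids <- if (nrow(xyz) == 1L) {
      sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
    } else {
      as.character(seq_len(nrow(xyz)))
    }
  }
  atoms <- data.frame(elety = at$elety, resid = at$resid, chain = at$chain,
                      resno = at$resno, stringsAsFactors = FALSE)
  ensemble(xyz, atoms, ids)
}

# MODEL record serial numbers, in file order
model_serials <- function(path) {
  ln <- readLines(path, warn = FALSE)
  m <- ln[startsWith(ln, "MODEL ") | ln == "MODEL"]
  trimws(substr(m, 7L, 14L))
}

# TRUE for rows surviving altloc resolution: per atom key keep the
# highest-occupancy altloc, blank preferred on ties, then alphabetical
altloc_mask <- function(at) {
  key <- paste(at$chain, at$resno, at$elety)
  if (!anyDuplicated(key)) return(rep(TRUE, nrow(at)))
  occ <- ifelse(is.na(at$o), 1, at$o)
  blank <- is.na(at$alt) | at$alt == ""
  alt <- ifelse(blank, "", at$alt)
  ord <- order(key, -occ, !blank, alt)
  mask <- logical(nrow(at))
  mask[ord[!duplicated(key[ord])]] <- TRUE
  mask
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written in fixed PDB format (3 decimal places); reading
#' the file back reproduces coordinates to that precision and the identical
#' atom keys.
#'
#' @param ens an [ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(ens, path) {
  bio3d::write.pdb(file = path, xyz = ens$xyz,
                   elety = ens$atoms$elety, resid = ens$atoms$resid,
                   chain = ens$atoms$chain, resno = ens$atoms$resno,
                   verbose = FALSE)
  invisible(path)
}

#' Read a per-model energy table
#'
#' Ingests the scores produced by an external rescoring step (e.g. a
#' coarse-grained force-field evaluation of each decoy) as a two-column CSV
#' with header `model_id,energy_kcal_mol`.
#'
#' @param path CSV file path.
#' @return data.frame of class `energy_table` with columns `model_id`
#'   (character) and `energy_kcal_mol` (numeric, finite).
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("model_id", "energy_kcal_mol"))) {
    stop("energy table must have header 'model_id,energy_kcal_mol'")
  }
  if (nrow(df) == 0L) stop("no entries in energy table: ", path)
  energy_table(df$model_id, df$energy_kcal_mol)
}

#' Construct an energy table in memory
#'
#' @param model_id character vector of unique model ids.
#' @param energy_kcal_mol numeric vector of finite energies (kcal/mol).
#' @return data.frame of class `energy_table`.
#' @export
energy_table <- function(model_id, energy_kcal_mol) {
  model_id <- as.character(model_id)
  energy <- suppressWarnings(as.numeric(energy_kcal_mol))
  bad <- which(!is.finite(energy))
  if (length(bad)) {
    stop("non-finite energy for model_id(s): ",
         paste(model_id[bad], collapse = ", "),
         " (row ", paste(bad, collapse = ", "), ")")
  }
  if (anyDuplicated(model_id)) {
    stop("duplicate model_id in energy table: ",
         paste(unique(model_id[duplicated(model_id)]), collapse = ", "))
  }
  structure(data.frame(model_id = model_id, energy_kcal_mol = energy,
                       stringsAsFactors = FALSE),
            class = c("energy_table", "data.frame"))
}

# energies for the given ids, erroring on any id absent from the table
lookup_energies <- function(energies, model_ids) {
  i <- match(model_ids, energies$model_id)
  if (anyNA(i)) {
    stop("model_id(s) missing from energy table: ",
         paste(model_ids[is.na(i)], collapse = ", "))
  }
  stats::setNames(energies$energy_kcal_mol[i], model_ids)
}

#' Define a residue region
#'
#' Regions name contiguous author-numbered residue ranges (inclusive on
#' both ends), e.g. the ATP-binding lid of adenylate kinase spans residues
#' 26-78 of chain A.
#'
#' @param name region label.
#' @param chain chain identifier (single character).
#' @param first,last first and last residue number, `first <= last`.
#' @return one-row data.frame of class `region_spec`.
#' @export
region_spec <- function(name, chain, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first > last) {
    stop("invalid region '", name, "': need first <= last")
  }
  structure(data.frame(name = as.character(name), chain = as.character(chain),
                       first = first, last = last, stringsAsFactors = FALSE),
            class = c("region_spec", "data.frame"))
}

#' Read a region configuration file
#'
#' A flat text file with one region per line, `name chain first last`
#' (whitespace separated); blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return data.frame of class `region_spec`, one row per region.
#' @export
read_region_config <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("no regions in config: ", path)
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed region line(s): ", paste(ln[bad], collapse = "; "))
  rows <- lapply(parts, function(p) region_spec(p[1L], p[2L], p[3L], p[4L]))
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop("duplicate region names in: ", path)
  class(out) <- c("region_spec", "data.frame")
  out
}

#' Select backbone or C-alpha atoms, optionally within regions
#'
#' @param ens an [ensemble].
#' @param selection `"backbone"` (atoms N, CA, C and the carbonyl O) or
#'   `"calpha"` (CA only). The backbone set degrades gracefully for
#'   C-alpha-only models, where it selects the CA trace. Set
#'   `include_o = FALSE` for an N, CA, C backbone.
#' @param regions optional [region_spec] data.frame; when given, only atoms
#'   whose (chain, residue number) fall inside some region are kept.
#' @param include_o logical; include the carbonyl O in `"backbone"`.
#' @return an [ensemble] restricted to the selected atoms, order preserved.
#' @export
extract_atoms <- function(ens, selection = c("backbone", "calpha"),
                          regions = NULL, include_o = TRUE) {
  selection <- match.arg(selection)
  names_ok <- if (selection == "calpha") "CA"
              else if (include_o) c("N", "CA", "C", "O") else c("N", "CA", "C")
  keep <- ens$atoms$elety %in% names_ok
  if (!is.null(regions)) {
    if (!all(regions$chain %in% ens$atoms$chain)) {
      miss <- setdiff(regions$chain, ens$atoms$chain)
      stop("region chain(s) absent from structure: ", paste(miss, collapse = ", "))
    }
    in_reg <- rep(FALSE, nrow(ens$atoms))
    for (r in seq_len(nrow(regions))) {
      in_reg <- in_reg | (ens$atoms$chain == regions$chain[r] &
                          ens$atoms$resno >= regions$first[r] &
                          ens$atoms$resno <= regions$last[r])
    }
    keep <- keep & in_reg
  }
  if (!any(keep)) stop("empty selection: no atoms match")
  idx <- which(keep)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  ensemble(ens$xyz[, cols, drop = FALSE], ens$atoms[idx, , drop = FALSE],
           ens$model_ids)
}
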