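#' Fetch PDB entries by accession
#'
#' Optional real-data mode: downloads `<id>.pdb` files from the RCSB file
#' server into `dir`, skipping files already present. Requires network
#' access; every other function in the package works on local files.
#'
#' @param ids character vector of 4-character PDB accessions
#'   (e.g. `c("2EB8", "2JHO")`).
#' @param dir download directory, created if missing.
#' @return character vector of file paths, named by accession.
#' @export
fetch_pdb <- function(ids, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ids, function(id) {
    id <- toupper(id)
    dest <- file.path(dir, paste0(id, ".pdb"))
    if (!file.exists(dest)) {
      url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
      status <- tryCatch(
        utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
        error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.exists(dest)) {
        unlink(dest)
        stop("could not fetch PDB entry ", id, " (no network access?)")
      }
    }
    dest
  }, character(1L))
}
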