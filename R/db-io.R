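#' Serialize a peptide database to a directory
#'
#' Writes the database as plain tab-delimited tables (`proteins.tsv`,
#' `peptides.tsv`, `observations.tsv`, `samples.tsv`, `occurrences.tsv`)
#' plus a JSON manifest carrying the format version and build parameters.
#'
#' @param db A `peptidome_db`.
#' @param dir Output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  check_db(db)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  tsv(db$proteins, "proteins.tsv")
  tsv(db$peptides, "peptides.tsv")
  tsv(db$observations, "observations.tsv")
  tsv(db$samples, "samples.tsv")
  tsv(db$occurrences, "occurrences.tsv")
  manifest <- list(
    format = "peptidome_db",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("hlahotspots")),
    params = db$params
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read a serialized peptide database
#'
#' @param dir Directory produced by [write_db()].
#' @return A `peptidome_db` object.
#' @export
read_db <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a peptidome_db directory (no manifest.json): ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "peptidome_db")) {
    stop("manifest does not describe a peptidome_db: ", dir, call. = FALSE)
  }
  tsv <- function(name, types) {
    readr::read_tsv(
      file.path(dir, name),
      col_types = types, progress = FALSE
    )
  }
  structure(
    list(
      proteins = tsv("proteins.tsv", readr::cols(
        protein_id = "c", sequence = "c", length = "i"
      )),
      peptides = tsv("peptides.tsv", readr::cols(
        sequence = "c", length = "i", class1 = "l", class2 = "l",
        shared = "l", n_placements = "i", mapped = "l"
      )),
      observations = tsv("observations.tsv", readr::cols(
        sequence = "c", sample_id = "c", hla_class = "c"
      )),
      samples = tsv("samples.tsv", readr::cols(
        sample_id = "c", group = "c", hla2_peptide_count = "i",
        hla2_expressing = "l"
      )),
      occurrences = tsv("occurrences.tsv", readr::cols(
        sequence = "c", protein_id = "c", start = "i", end = "i"
      )),
      params = manifest$params
    ),
    class = "peptidome_db"
  )
}
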