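#' Read a peptide identification table
#'
#' Reads MS peptide identifications from delimited text (tab by default,
#' comma accepted). Two dialects are supported:
#'
#' * `"plain"`: columns `sequence`, `sample`, `hla_class` (values `I`/`II`).
#' * `"maxquant"`: a reduced MaxQuant `peptides.txt`-style table with at
#'   least a `Sequence` column; the sample identifier and HLA class are
#'   supplied via `sample` and `hla_class` because MaxQuant output carries
#'   neither per row.
#'
#' Rows whose sequence contains characters outside the 20-letter amino-acid
#' alphabet, and rows shorter than 7 residues (below a credible HLA ligand
#' length), are dropped with a message giving the counts. No other
#' filtering is applied.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"plain"` or `"maxquant"`.
#' @param sample,hla_class Sample identifier and HLA class (`"I"` or
#'   `"II"`) applied to every row; required for the `"maxquant"` dialect.
#' @return A tibble of peptide observations with columns `sequence`,
#'   `sample_id` and `hla_class`.
#' @export
read_peptide_table <- function(path, dialect = c("plain", "maxquant"),
                               sample = NULL, hla_class = NULL) {
  dialect <- match.arg(dialect)
  tab <- read_delimited(path)
  if (dialect == "plain") {
    need <- c("sequence", "sample", "hla_class")
    missing <- setdiff(need, names(tab))
    if (length(missing) > 0L) {
      stop(
        "peptide table is missing column(s): ",
        paste(missing, collapse = ", "),
        "; expected columns: ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    obs <- tibble::tibble(
      sequence = toupper(as.character(tab$sequence)),
      sample_id = as.character(tab$sample),
      hla_class = as.character(tab$hla_class)
    )
  } else {
    if (!"Sequence" %in% names(tab)) {
      stop(
        "maxquant dialect requires a 'Sequence' column; expected columns: ",
        "Sequence (plus sample/hla_class via arguments)",
        call. = FALSE
      )
    }
    if (is.null(sample) || is.null(hla_class)) {
      stop(
        "maxquant dialect requires 'sample' and 'hla_class' arguments",
        call. = FALSE
      )
    }
    obs <- tibble::tibble(
      sequence = toupper(as.character(tab$Sequence)),
      sample_id = as.character(sample),
      hla_class = as.character(hla_class)
    )
  }
  bad_class <- !obs$hla_class %in% c("I", "II")
  if (any(bad_class)) {
    stop(
      "hla_class must be 'I' or 'II'; offending value(s): ",
      paste(unique(obs$hla_class[bad_class]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_alpha <- !stringr::str_detect(obs$sequence, AA_REGEX_PEPTIDE)
  too_short <- !bad_alpha & nchar(obs$sequence) < MIN_PEPTIDE_LENGTH
  if (any(bad_alpha)) {
    message(
      sum(bad_alpha), " row(s) dropped: non-amino-acid characters in sequence"
    )
  }
  if (any(too_short)) {
    message(
      sum(too_short), " row(s) dropped: sequence shorter than ",
      MIN_PEPTIDE_LENGTH, " residues"
    )
  }
  obs[!bad_alpha & !too_short, ]
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `group` and `hla2_peptide_count`. A derived
#' logical `hla2_expressing` flags samples with at least 100 HLA-II
#' peptides; samples below that threshold are treated as lacking HLA-II
#' expression.
#'
#' @param path Path to a delimited text file (tab default, comma accepted).
#' @return A tibble with one row per sample.
#' @export
read_sample_table <- function(path) {
  tab <- read_delimited(path)
  need <- c("sample_id", "group", "hla2_peptide_count")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop(
      "sample table is missing column(s): ", paste(missing, collapse = ", "),
      "; expected columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample_id = as.character(tab$sample_id),
    group = as.character(tab$group),
    hla2_peptide_count = as.integer(tab$hla2_peptide_count)
  )
  if (anyDuplicated(out$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if (any(out$hla2_peptide_count < 0L, na.rm = TRUE)) {
    stop("hla2_peptide_count must be non-negative", call. = FALSE)
  }
  out$hla2_expressing <- out$hla2_peptide_count >= HLA2_EXPRESSING_MIN_PEPTIDES
  out
}

# tab- or comma-delimited reader; sniffs the delimiter from the header line
read_delimited <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}
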