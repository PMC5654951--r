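#' Read a proteome from a FASTA file
#'
#' Parses a protein FASTA file into a tibble with one row per entry.
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased and any terminal `*` stop characters are
#' stripped.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id`, `sequence` and `length`,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "ACDEFGHIKL"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) {
    stop("proteome FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    stop("proteome FASTA is empty: ", path, call. = FALSE)
  }
  ids <- stringr::str_extract(names(seqs), "^\\S+")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(
      "duplicate protein identifier(s) in proteome: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  sequence <- toupper(as.character(seqs))
  sequence <- stringr::str_remove_all(sequence, "\\*+$")
  sequence <- stringr::str_remove_all(sequence, "^\\*+")
  bad <- !stringr::str_detect(sequence, AA_REGEX_PROTEIN)
  if (any(bad)) {
    stop(
      "protein sequence(s) with non-amino-acid characters or empty: ",
      paste(ids[bad], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    protein_id = ids,
    sequence = unname(sequence),
    length = nchar(sequence)
  )
}

#' Write a proteome tibble to FASTA
#'
#' Output is deterministic: one header line per protein followed by the
#' sequence wrapped at 60 columns.
#'
#' @param proteome A tibble with columns `protein_id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  check_proteome(proteome)
  lines <- purrr::map2(proteome$protein_id, proteome$sequence, function(id, s) {
    c(paste0(">", id), wrap_sequence(s, 60L))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

wrap_sequence <- function(s, width) {
  n <- nchar(s)
  starts <- seq.int(1L, n, by = width)
  stringr::str_sub(s, starts, pmin(starts + width - 1L, n))
}

check_proteome <- function(proteome) {
  stopifnot(is.data.frame(proteome))
  need <- c("protein_id", "sequence")
  missing <- setdiff(need, names(proteome))
  if (length(missing) > 0L) {
    stop(
      "proteome is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(proteome$protein_id)) {
    stop("proteome protein_id values must be unique", call. = FALSE)
  }
  if (any(!nzchar(proteome$sequence))) {
    stop("proteome sequences must be non-empty", call. = FALSE)
  }
  invisible(proteome)
}
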