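#' Build an immunopeptidomics peptide database
#'
#' Deduplicates MS peptide observations into per-class sets of unique
#' sequences, maps every unique sequence exactly onto the proteome
#' (recording all placements), and bundles proteins, peptides, per-sample
#' observations and the occurrence index into a `peptidome_db` object.
#' This is the in-memory analogue of a ligandome database compiled from
#' many immunopeptidomics experiments.
#'
#' A peptide observed in both class I and class II samples belongs to both
#' class sets and to the derived shared (I/II) set. Peptides with no exact
#' placement in the proteome (contaminants, variant sequences) stay in the
#' class sets — they count towards class totals — but are flagged unmapped
#' and never contribute to density profiles or match scores.
#'
#' @param proteome Tibble from [read_proteome()] (columns `protein_id`,
#'   `sequence`).
#' @param observations Tibble from [read_peptide_table()] (columns
#'   `sequence`, `sample_id`, `hla_class`).
#' @param samples Optional tibble from [read_sample_table()]. When given,
#'   every observation's `sample_id` must appear in it (unknown sample is a
#'   hard error). When `NULL`, minimal metadata is derived from the
#'   observations (group `"other"`, class-II counts tallied per sample).
#' @param collapse_il If `TRUE`, isoleucine and leucine are treated as
#'   identical during matching (MS cannot distinguish them). Default
#'   `FALSE` preserves exactness.
#' @param razor If `TRUE`, a peptide matching several proteins is assigned
#'   only to its single best protein (the one with the most mapped
#'   peptides, ties broken by lexicographic identifier), emulating
#'   razor-protein assignment. Default `FALSE`: a peptide contributes to
#'   every matching protein.
#' @return An object of class `peptidome_db`: a list of tibbles
#'   (`proteins`, `peptides`, `observations`, `samples`, `occurrences`)
#'   plus the build parameters. Occurrence coordinates are 1-based
#'   inclusive.
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", sequence = "ACDEFGHIKL")
#' obs <- tibble::tibble(
#'   sequence = c("ACDEF", "DEFGH", "GHIKL"),
#'   sample_id = "s1", hla_class = "I"
#' )
#' db <- build_db(prot, obs)
#' db$occurrences
#' @export
build_db <- function(proteome, observations, samples = NULL,
                     collapse_il = FALSE, razor = FALSE) {
  check_proteome(proteome)
  need <- c("sequence", "sample_id", "hla_class")
  missing <- setdiff(need, names(observations))
  if (length(missing) > 0L) {
    stop(
      "observations missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(observations$hla_class %in% c("I", "II"))) {
    stop("hla_class must be 'I' or 'II'", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- observations |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        group = "other",
        hla2_peptide_count = sum(.data$hla_class == "II"),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        hla2_expressing = .data$hla2_peptide_count >= HLA2_EXPRESSING_MIN_PEPTIDES
      )
  } else {
    unknown <- setdiff(observations$sample_id, samples$sample_id)
    if (length(unknown) > 0L) {
      stop(
        "observation sample_id(s) absent from sample table: ",
        paste(unique(unknown), collapse = ", "),
        call. = FALSE
      )
    }
    if (!"hla2_expressing" %in% names(samples)) {
      samples$hla2_expressing <-
        samples$hla2_peptide_count >= HLA2_EXPRESSING_MIN_PEPTIDES
    }
  }

  class1 <- unique(observations$sequence[observations$hla_class == "I"])
  class2 <- unique(observations$sequence[observations$hla_class == "II"])
  all_seqs <- unique(observations$sequence)

  occurrences <- locate_peptides(proteome, all_seqs, collapse_il = collapse_il)
  if (razor) {
    occurrences <- apply_razor(occurrences)
  }

  n_placements <- table(occurrences$sequence)
  peptides <- tibble::tibble(
    sequence = all_seqs,
    length = nchar(all_seqs),
    class1 = all_seqs %in% class1,
    class2 = all_seqs %in% class2
  ) |>
    dplyr::mutate(
      shared = .data$class1 & .data$class2,
      n_placements = as.integer(n_placements[.data$sequence]),
      n_placements = dplyr::coalesce(.data$n_placements, 0L),
      mapped = .data$n_placements > 0L
    )

  structure(
    list(
      proteins = tibble::as_tibble(proteome[, c("protein_id", "sequence")]) |>
        dplyr::mutate(length = nchar(.data$sequence)),
      peptides = peptides,
      observations = tibble::as_tibble(observations[, need]),
      samples = tibble::as_tibble(samples),
      occurrences = occurrences,
      params = list(collapse_il = collapse_il, razor = razor)
    ),
    class = "peptidome_db"
  )
}

# exact multi-pattern placement of peptides on a proteome; coordinates are
# 1-based inclusive and overlapping self-matches are reported
locate_peptides <- function(proteome, peptides, collapse_il = FALSE) {
  empty <- tibble::tibble(
    sequence = character(), protein_id = character(),
    start = integer(), end = integer()
  )
  if (length(peptides) == 0L || nrow(proteome) == 0L) {
    return(empty)
  }
  pep_search <- if (collapse_il) gsub("I", "L", peptides, fixed = TRUE) else peptides
  seqs <- proteome$sequence
  if (collapse_il) seqs <- gsub("I", "L", seqs, fixed = TRUE)
  if (length(peptides) == 1L) {
    # fast path: one vectorized search across all proteins, no per-call
    # validation overhead
    loc <- stringi::stri_locate_all_fixed(
      seqs, pep_search,
      overlap = TRUE, omit_no_match = TRUE
    )
    n <- vapply(loc, nrow, integer(1), USE.NAMES = FALSE)
    total <- sum(n)
    if (total == 0L) return(empty)
    mat <- do.call(rbind, loc[n > 0L])
    pid <- rep.int(proteome$protein_id, n)
    start <- as.integer(mat[, 1L])
    ord <- order(pid, start)
    return(tibble::new_tibble(
      list(
        sequence = rep.int(peptides, total),
        protein_id = pid[ord],
        start = start[ord],
        end = as.integer(mat[, 2L])[ord]
      ),
      nrow = total
    ))
  }
  seq_col <- vector("list", nrow(proteome))
  id_col <- vector("list", nrow(proteome))
  mat_col <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    loc <- stringi::stri_locate_all_fixed(
      seqs[i], pep_search,
      overlap = TRUE, omit_no_match = TRUE
    )
    n <- vapply(loc, nrow, integer(1))
    total <- sum(n)
    if (total == 0L) next
    seq_col[[i]] <- rep(peptides, n)
    id_col[[i]] <- rep(proteome$protein_id[i], total)
    mat_col[[i]] <- do.call(rbind, loc[n > 0L])
  }
  mat <- do.call(rbind, mat_col)
  if (is.null(mat)) return(empty)
  out <- tibble::tibble(
    sequence = unlist(seq_col),
    protein_id = unlist(id_col),
    start = as.integer(mat[, 1L]),
    end = as.integer(mat[, 2L])
  )
  dplyr::arrange(out, .data$sequence, .data$protein_id, .data$start)
}

# razor-like single-protein assignment: keep each peptide's placements only
# in the protein with the most mapped peptides (ties: lexicographic id)
apply_razor <- function(occurrences) {
  if (nrow(occurrences) == 0L) return(occurrences)
  protein_rank <- occurrences |>
    dplyr::distinct(.data$sequence, .data$protein_id) |>
    dplyr::count(.data$protein_id, name = "n_peptides")
  occurrences |>
    dplyr::left_join(protein_rank, by = "protein_id") |>
    dplyr::group_by(.data$sequence) |>
    dplyr::filter(
      .data$n_peptides == max(.data$n_peptides),
      .data$protein_id == min(.data$protein_id[.data$n_peptides == max(.data$n_peptides)])
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_peptides") |>
    dplyr::arrange(.data$sequence, .data$protein_id, .data$start)
}

#' Summarise a peptide database
#'
#' Reports unique class-I and class-II peptide counts, the shared (I/II)
#' count, the shared percentage `100 * shared / (class I + class II)`, the
#' number of proteins with at least one mapped peptide, and per-class
#' length histograms.
#'
#' @param db A `peptidome_db` from [build_db()].
#' @return A list of class `peptidome_db_summary` with elements
#'   `n_class1`, `n_class2`, `n_shared`, `shared_pct`, `n_proteins`,
#'   `n_proteins_mapped` and `length_histograms` (a tibble).
#' @export
db_summary <- function(db) {
  check_db(db)
  p <- db$peptides
  n1 <- sum(p$class1)
  n2 <- sum(p$class2)
  ns <- sum(p$shared)
  hist <- dplyr::bind_rows(
    length_distribution(db, "I") |> dplyr::mutate(class_selector = "I"),
    length_distribution(db, "II") |> dplyr::mutate(class_selector = "II"),
    length_distribution(db, "I/II") |> dplyr::mutate(class_selector = "I/II")
  )
  structure(
    list(
      n_class1 = n1,
      n_class2 = n2,
      n_shared = ns,
      shared_pct = shared_percentage(n1, n2, ns),
      n_proteins = nrow(db$proteins),
      n_proteins_mapped = dplyr::n_distinct(db$occurrences$protein_id),
      length_histograms = hist
    ),
    class = "peptidome_db_summary"
  )
}

#' Shared-peptide percentage from class counts
#'
#' The percentage of peptide sequences detected in both class I and class
#' II elution samples, with the sum of the two class counts as the
#' denominator: `100 * n_shared / (n_class1 + n_class2)`. Zero when both
#' class sets are empty.
#'
#' @param n_class1,n_class2 Unique peptide counts per class.
#' @param n_shared Count of sequences present in both classes.
#' @return A percentage.
#' @examples
#' shared_percentage(131402, 66420, 6819) # 3.4 after rounding
#' @export
shared_percentage <- function(n_class1, n_class2, n_shared) {
  total <- n_class1 + n_class2
  if (total == 0) return(0)
  100 * n_shared / total
}

#' Count mapped peptides per source protein
#'
#' For the chosen class selector, counts the unique peptide sequences with
#' at least one placement in each protein. A peptide placed at several
#' positions of one protein is counted once for that protein; a peptide
#' matching several proteins counts in each. Proteins with no mapped
#' peptide of the selector are absent from the result.
#'
#' @param db A `peptidome_db`.
#' @param class_selector One of `"I"`, `"II"`, `"I/II"`, `"I_short"`
#'   (class-I peptides shorter than 15 residues).
#' @return A tibble with columns `protein_id` and `n_peptides`.
#' @export
peptides_per_protein <- function(db, class_selector = "I") {
  check_db(db)
  seqs <- selector_sequences(db, class_selector)
  db$occurrences |>
    dplyr::filter(.data$sequence %in% seqs) |>
    dplyr::distinct(.data$protein_id, .data$sequence) |>
    dplyr::count(.data$protein_id, name = "n_peptides")
}

# unique sequences belonging to a class selector (membership, not mapping)
selector_sequences <- function(db, class_selector) {
  p <- db$peptides
  switch(class_selector,
    "I" = p$sequence[p$class1],
    "II" = p$sequence[p$class2],
    "I/II" = p$sequence[p$shared],
    "I_short" = p$sequence[p$class1 & p$length < 15L],
    stop(
      "unknown class selector '", class_selector,
      "'; use one of I, II, I/II, I_short",
      call. = FALSE
    )
  )
}

check_db <- function(db) {
  if (!inherits(db, "peptidome_db")) {
    stop("expected a 'peptidome_db' object (see build_db())", call. = FALSE)
  }
  invisible(db)
}

#' @export
print.peptidome_db <- function(x, ...) {
  s <- db_summary(x)
  cat("<peptidome_db>\n")
  cat("  proteins:        ", s$n_proteins,
      " (", s$n_proteins_mapped, " with mapped peptides)\n", sep = "")
  cat("  class I peptides: ", s$n_class1, "\n", sep = "")
  cat("  class II peptides:", s$n_class2, "\n")
  cat(sprintf("  shared (I/II):    %d (%.1f%%)\n", s$n_shared, s$shared_pct))
  cat("  occurrences:      ", nrow(x$occurrences), "\n")
  invisible(x)
}

#' @export
print.peptidome_db_summary <- function(x, ...) {
  cat("Peptide database summary\n")
  cat(sprintf(
    "  class I: %d  class II: %d  shared: %d (%.1f%%)\n",
    x$n_class1, x$n_class2, x$n_shared, x$shared_pct
  ))
  cat(sprintf(
    "  proteins: %d (%d with >=1 mapped peptide)\n",
    x$n_proteins, x$n_proteins_mapped
  ))
  invisible(x)
}

#' Glance at a peptide database
#'
#' @param x A `peptidome_db`.
#' @param ... Unused.
#' @return A one-row tibble with class counts, shared percentage and
#'   protein counts.
#' @export
glance.peptidome_db <- function(x, ...) {
  s <- db_summary(x)
  tibble::tibble(
    n_class1 = s$n_class1,
    n_class2 = s$n_class2,
    n_shared = s$n_shared,
    shared_pct = s$shared_pct,
    n_proteins = s$n_proteins,
    n_proteins_mapped = s$n_proteins_mapped
  )
}
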