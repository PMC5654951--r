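#' Number of database class-I peptides matching a protein
#'
#' Counts the unique class-I peptide sequences with at least one placement
#' in the given protein — the protein-level MS feature for neoantigen
#' prioritization (a protein that is highly presented in its wild-type
#' form has a better chance to present neoantigens).
#'
#' @param db A `peptidome_db`.
#' @param protein_id One or more protein identifiers.
#' @return An integer vector, one count per identifier; 0 for proteins
#'   absent from the database.
#' @export
nr_matching_peptides <- function(db, protein_id) {
  check_db(db)
  counts <- peptides_per_protein(db, "I")
  out <- counts$n_peptides[match(protein_id, counts$protein_id)]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Profile-sum match score of a wild-type peptide
#'
#' Sums the class-I density profile height over the span of every exact
#' placement of `wt_peptide` in the proteome and returns the highest sum
#' together with the placement achieving it (ties broken by protein
#' identifier, then start position). A peptide with no placement scores 0
#' with an absent placement.
#'
#' @param db A `peptidome_db`.
#' @param wt_peptide Wild-type peptide sequence (non-empty).
#' @param hla_class Profile class used for the sum; `"I"` (the default,
#'   giving `matchScore_I`) or `"II"`.
#' @param normalize Divide the score by the peptide length (off by
#'   default; the raw sum is the canonical score).
#' @param cache Optional environment memoizing per-protein profiles across
#'   calls.
#' @return A list with `match_score` and `best_placement` (a one-row
#'   tibble, or `NULL` when the peptide occurs nowhere).
#' @export
match_score <- function(db, wt_peptide, hla_class = "I", normalize = FALSE,
                        cache = NULL) {
  check_db(db)
  stopifnot(is.character(wt_peptide), length(wt_peptide) == 1L,
            nzchar(wt_peptide))
  plc <- locate_peptides(db$proteins, wt_peptide,
                         collapse_il = isTRUE(db$params$collapse_il))
  if (nrow(plc) == 0L) {
    return(list(match_score = 0, best_placement = NULL))
  }
  heights_of <- profile_getter(db, hla_class, cache)
  score <- vapply(seq_len(nrow(plc)), function(i) {
    sum(heights_of(plc$protein_id[i])[plc$start[i]:plc$end[i]])
  }, double(1))
  # highest score wins; ties by (protein_id, start): placements arrive
  # sorted that way, so the first maximum is the canonical one
  best <- which.max(score)
  out <- score[best]
  if (normalize) out <- out / nchar(wt_peptide)
  list(
    match_score = out,
    best_placement = tibble::new_tibble(
      list(
        protein_id = plc$protein_id[best],
        start = plc$start[best],
        end = plc$end[best]
      ),
      nrow = 1L
    )
  )
}

# memoized per-protein profile heights for a class selector
profile_getter <- function(db, class_selector, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  function(pid) {
    key <- paste0(class_selector, ":", pid)
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, density_profile(db, pid, class_selector)$height,
             envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
}

#' Exact-match gated score of a wild-type peptide
#'
#' Equal to the profile-sum match score when the peptide itself is a
#' class-I database peptide, and 0 otherwise.
#'
#' @inheritParams match_score
#' @return A number.
#' @export
exact_match_score <- function(db, wt_peptide, cache = NULL) {
  check_db(db)
  p <- db$peptides
  if (!wt_peptide %in% p$sequence[p$class1]) return(0)
  match_score(db, wt_peptide, cache = cache)$match_score
}

#' Classify how a wild-type peptide matches the database
#'
#' The match taxonomy, ordered from strongest to weakest evidence:
#'
#' * `exact` — the peptide itself was detected by MS (member of the
#'   class-I or class-II set);
#' * `included` — the peptide is a substring of a longer detected peptide;
#' * `partial` — at some placement of the peptide in the proteome, a
#'   detected peptide placement covers the absolute position of the
#'   mutation;
#' * `none` — no overlap at the mutation site.
#'
#' @param db A `peptidome_db`.
#' @param wt_peptide Wild-type peptide sequence.
#' @param mutation_pos 1-based position of the mutated residue within the
#'   peptide; out-of-range is an error.
#' @return One of `"exact"`, `"included"`, `"partial"`, `"none"`.
#' @export
classify_match <- function(db, wt_peptide, mutation_pos) {
  check_db(db)
  classify_match_impl(wt_peptide, mutation_pos, classify_context(db))
}

# precomputed lookups shared across many classify calls
classify_context <- function(db) {
  p <- db$peptides
  in_class <- p$class1 | p$class2
  list(
    db = db,
    member_set = p$sequence[in_class],
    detected = p$sequence[in_class],
    detected_len = p$length[in_class],
    occ = db$occurrences,
    collapse_il = isTRUE(db$params$collapse_il)
  )
}

classify_match_impl <- function(wt_peptide, mutation_pos, ctx) {
  len <- nchar(wt_peptide)
  if (mutation_pos < 1L || mutation_pos > len) {
    stop(
      "mutation_pos must be within 1..", len, " (got ", mutation_pos, ")",
      call. = FALSE
    )
  }
  if (wt_peptide %in% ctx$member_set) {
    return("exact")
  }
  longer <- ctx$detected[ctx$detected_len > len]
  if (length(longer) > 0L &&
      any(stringi::stri_detect_fixed(longer, wt_peptide))) {
    return("included")
  }
  plc <- locate_peptides(ctx$db$proteins, wt_peptide,
                         collapse_il = ctx$collapse_il)
  if (nrow(plc) > 0L) {
    occ <- ctx$occ
    for (i in seq_len(nrow(plc))) {
      abs_pos <- plc$start[i] + mutation_pos - 1L
      hit <- occ$protein_id == plc$protein_id[i] &
        occ$start <= abs_pos & occ$end >= abs_pos
      if (any(hit)) return("partial")
    }
  }
  "none"
}

#' Score a table of neoantigen candidates against the database
#'
#' Appends the match taxonomy class and the three MS-based prioritization
#' features (`nrMatchingPeptides_I`, `matchScore_I`, `exactMatchScore_I`)
#' plus the best placement of the wild-type peptide to each candidate row.
#' Rows whose mutated and wild-type peptides do not differ at exactly the
#' stated mutation position (or differ in length) are rejected with a
#' per-row report and the remainder is processed.
#'
#' @param db A `peptidome_db`.
#' @param candidates Tibble with at least `mut_peptide`, `wt_peptide`,
#'   `mutation_pos` (1-based) and `protein_id`; any further feature
#'   columns are carried through.
#' @return The candidate tibble with appended columns `match_type`,
#'   `nrMatchingPeptides_I`, `matchScore_I`, `exactMatchScore_I`,
#'   `best_protein_id`, `best_start`, `best_end`. Rejected rows are
#'   attached as attribute `"rejected"` (tibble with a `reason` column).
#' @export
score_candidates <- function(db, candidates) {
  check_db(db)
  need <- c("mut_peptide", "wt_peptide", "mutation_pos", "protein_id")
  missing <- setdiff(need, names(candidates))
  if (length(missing) > 0L) {
    stop(
      "candidates missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  candidates <- tibble::as_tibble(candidates)
  reason <- candidate_problems(candidates)
  rejected <- candidates[!is.na(reason), ]
  if (nrow(rejected) > 0L) {
    rejected$reason <- reason[!is.na(reason)]
    message(nrow(rejected), " candidate row(s) rejected (mut/wt mismatch)")
  }
  kept <- candidates[is.na(reason), ]
  if (nrow(kept) == 0L) {
    out <- kept |>
      dplyr::mutate(
        match_type = character(), nrMatchingPeptides_I = integer(),
        matchScore_I = double(), exactMatchScore_I = double(),
        best_protein_id = character(), best_start = integer(),
        best_end = integer()
      )
    return(structure(out, rejected = rejected))
  }
  cache <- new.env(parent = emptyenv())
  ctx <- classify_context(db)
  class1_set <- db$peptides$sequence[db$peptides$class1]
  scores <- purrr::pmap(
    list(kept$wt_peptide, kept$mutation_pos),
    function(wt, mpos) {
      ms <- match_score(db, wt, cache = cache)
      list(
        match_type = classify_match_impl(wt, mpos, ctx),
        matchScore_I = ms$match_score,
        exactMatchScore_I = if (wt %in% class1_set) ms$match_score else 0,
        best = ms$best_placement
      )
    }
  )
  best <- purrr::map(scores, "best")
  out <- kept |>
    dplyr::mutate(
      match_type = purrr::map_chr(scores, "match_type"),
      nrMatchingPeptides_I = nr_matching_peptides(db, .data$protein_id),
      matchScore_I = purrr::map_dbl(scores, "matchScore_I"),
      exactMatchScore_I = purrr::map_dbl(scores, "exactMatchScore_I"),
      best_protein_id = purrr::map_chr(
        best, ~ if (is.null(.x)) NA_character_ else .x$protein_id
      ),
      best_start = purrr::map_int(
        best, ~ if (is.null(.x)) NA_integer_ else .x$start
      ),
      best_end = purrr::map_int(
        best, ~ if (is.null(.x)) NA_integer_ else .x$end
      )
    )
  structure(out, rejected = rejected)
}

# NA for valid rows, otherwise a short description of the defect
candidate_problems <- function(candidates) {
  purrr::pmap_chr(
    list(candidates$mut_peptide, candidates$wt_peptide,
         candidates$mutation_pos),
    function(mut, wt, mpos) {
      if (is.na(mut) || is.na(wt) || is.na(mpos)) {
        return("missing peptide or mutation position")
      }
      if (nchar(mut) != nchar(wt)) {
        return("mut and wt peptides differ in length")
      }
      if (mpos < 1L || mpos > nchar(wt)) {
        return("mutation_pos out of range")
      }
      diff_at <- which(stringr::str_split_1(mut, "") !=
                         stringr::str_split_1(wt, ""))
      if (!identical(diff_at, as.integer(mpos))) {
        return("mut and wt must differ at exactly mutation_pos")
      }
      NA_character_
    }
  )
}

#' Immunogenic enrichment fraction
#'
#' The percentage of immunogenic candidates among a selected subset:
#' `100 * k / n`.
#'
#' @param k Immunogenic count within the subset.
#' @param n Subset size (> 0).
#' @return A percentage (report rounded to one decimal for display).
#' @examples
#' enrichment_fraction(16, 1034) # ~1.5
#' @export
enrichment_fraction <- function(k, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  100 * k / n
}

#' Probability of full database presence by chance
#'
#' If `m` of `n` candidates lie on database-covered proteins, the chance
#' that `k` independently drawn hits would all do so is `(m/n)^k` — used
#' to assess whether every immunogenic candidate lying on a database
#' protein could be coincidence.
#'
#' @param m Candidates on database proteins.
#' @param n Total candidates (> 0).
#' @param k Number of hits.
#' @return A probability.
#' @examples
#' presence_probability(872, 1034, 16) # ~0.065
#' @export
presence_probability <- function(m, n, k) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (m < 0 || m > n) stop("m must satisfy 0 <= m <= n", call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  (m / n)^k
}
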