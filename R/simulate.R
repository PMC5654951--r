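#' Simulate a proteome
#'
#' Draws protein sequences with residues i.i.d. from a background
#' composition (uniform over the 20 standard residues by default) and
#' lengths uniform within `length_range`.
#'
#' @param n_proteins Number of proteins (default 50).
#' @param length_range Inclusive bounds of protein length (default
#'   200-600 residues).
#' @param composition Optional named probability vector over the 20
#'   residues; normalized internally.
#' @param seed Integer seed (mandatory); identical seeds give identical
#'   proteomes.
#' @return A tibble with `protein_id`, `sequence`, `length`.
#' @export
simulate_proteome <- function(n_proteins = 50, length_range = c(200, 600),
                              composition = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (!setequal(names(composition), AA_ALPHABET)) {
    stop("composition must be named with the 20 standard residues",
         call. = FALSE)
  }
  composition <- composition[AA_ALPHABET] / sum(composition)
  withr::with_seed(as.integer(seed), {
    lens <- if (length_range[1] == length_range[2]) {
      rep(as.integer(length_range[1]), n_proteins)
    } else {
      sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    }
    seqs <- vapply(lens, function(l) {
      paste(sample(AA_ALPHABET, l, replace = TRUE, prob = composition),
            collapse = "")
    }, character(1))
    tibble::tibble(
      protein_id = sprintf("PROT%03d", seq_len(n_proteins)),
      sequence = seqs,
      length = lens
    )
  })
}

#' Simulate an immunopeptidome over a proteome
#'
#' Generates class-I and class-II peptide observations across samples,
#' emulating the statistical structure of a compiled ligandome database:
#'
#' * class-I peptide lengths over 8-14 with the mass concentrated on
#'   9-11-mers (about 5% at 14 or longer);
#' * class-II lengths over 12-20 centered on 15-mers;
#' * a small fraction of sequences detected in both classes (default
#'   3.4%), half re-emitted class-I sequences, half re-emitted class-II
#'   sequences, so the shared length distribution mixes both modes;
#' * planted class-I hotspots: in a fraction of proteins, an interval is
#'   tiled with overlapping peptides until every residue of the interval
#'   is covered at least `hotspot_depth` times, while background peptides
#'   are drawn uniformly across the proteome;
#' * a subset of samples lacking HLA-II expression (fewer than 100
#'   class-II peptides).
#'
#' Every generated peptide is an exact substring of its source protein.
#' The returned truth manifest records planted hotspots and all per-class
#' unique counts, making downstream recovery tests self-verifying.
#'
#' @param proteome Tibble from [simulate_proteome()].
#' @param n_samples_per_group Named integer vector of sample counts.
#' @param class1_per_sample,class2_per_sample Background peptide draws per
#'   sample and class. Defaults (`NULL`) scale with proteome size at a
#'   fixed coverage density and equal 60 and 120 at the reference scale of
#'   50 proteins averaging 400 residues.
#' @param class1_length_probs,class2_length_probs Named probability
#'   vectors over peptide lengths.
#' @param hla2_lacking_frac Fraction of samples lacking HLA-II expression.
#' @param shared_fraction Target fraction of unique sequences detected in
#'   both classes, relative to the summed class counts.
#' @param hotspot_fraction Fraction of proteins receiving a planted
#'   hotspot.
#' @param hotspot_length,hotspot_depth Planted interval length and target
#'   minimum coverage depth; an interval longer than its protein is an
#'   error. The depth cannot exceed the number of distinct class-I peptide
#'   lengths minus one, because the interval's first residue is only
#'   covered by windows starting there (one per length).
#' @param seed Integer seed (mandatory).
#' @return A list with `observations`, `samples` and `truth` (planted
#'   hotspots, per-class unique counts, parameters, seed).
#' @export
simulate_peptidome <- function(
    proteome,
    n_samples_per_group = c("B-cells" = 4, "T-cells" = 2,
                            "Melanoma" = 4, "other" = 2),
    class1_per_sample = NULL,
    class2_per_sample = NULL,
    class1_length_probs = c(
      "8" = 0.04, "9" = 0.33, "10" = 0.28, "11" = 0.16,
      "12" = 0.08, "13" = 0.06, "14" = 0.05
    ),
    class2_length_probs = c(
      "12" = 0.05, "13" = 0.12, "14" = 0.18, "15" = 0.25,
      "16" = 0.18, "17" = 0.12, "18" = 0.06, "19" = 0.03, "20" = 0.01
    ),
    hla2_lacking_frac = 0.25,
    shared_fraction = 0.034,
    hotspot_fraction = 0.3,
    hotspot_length = 40,
    hotspot_depth = 6,
    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  check_proteome(proteome)
  stopifnot(abs(sum(class1_length_probs) - 1) < 1e-6)
  stopifnot(abs(sum(class2_length_probs) - 1) < 1e-6)
  # the first residue of a planted interval can only be covered by windows
  # starting there, one per distinct peptide length, which bounds the
  # attainable minimum depth
  max_depth <- sum(class1_length_probs > 0) - 1L
  if (hotspot_depth > max_depth) {
    stop("hotspot_depth must be at most ", max_depth,
         " (one per distinct class-I peptide length, minus one)",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    n_samples <- sum(n_samples_per_group)
    samples <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      group = rep(names(n_samples_per_group), n_samples_per_group)
    )
    n_lacking <- max(1L, round(hla2_lacking_frac * n_samples))
    lacking <- sample(samples$sample_id, n_lacking)
    samples$hla2_expressing_planted <- !samples$sample_id %in% lacking

    # default yields target a fixed background coverage density so hotspots
    # stand out regardless of proteome size: class-I ~0.36x mean coverage
    # and class-II ~0.81x (60 and 120 peptides per sample at the reference
    # scale of 50 proteins averaging 400 residues)
    total_len <- sum(nchar(proteome$sequence))
    n_expressing <- n_samples - n_lacking
    if (is.null(class1_per_sample)) {
      class1_per_sample <- max(5L, round(0.36 * total_len / (10 * n_samples)))
    }
    if (is.null(class2_per_sample)) {
      class2_per_sample <- max(
        5L, round(0.81 * total_len / (15 * max(1L, n_expressing)))
      )
    }

    draw_len <- function(probs) {
      as.integer(sample(names(probs), 1L, prob = probs))
    }
    random_window <- function(len_probs) {
      repeat {
        l <- draw_len(len_probs)
        i <- sample.int(nrow(proteome), 1L, prob = proteome$length)
        if (proteome$length[i] >= l) {
          s <- sample.int(proteome$length[i] - l + 1L, 1L)
          return(list(
            protein_id = proteome$protein_id[i],
            sequence = substr(proteome$sequence[i], s, s + l - 1L)
          ))
        }
      }
    }

    # planted class-I hotspots: tile the interval with full-length peptides
    # (last one right-aligned) until min coverage reaches the target depth
    n_hot <- round(hotspot_fraction * nrow(proteome))
    hot_rows <- sample.int(nrow(proteome), n_hot)
    hotspots <- tibble::tibble(
      protein_id = proteome$protein_id[hot_rows],
      protein_length = proteome$length[hot_rows]
    )
    if (any(hotspots$protein_length < hotspot_length)) {
      stop("hotspot interval longer than protein", call. = FALSE)
    }
    hotspots$start <- vapply(hotspots$protein_length, function(L) {
      sample.int(L - hotspot_length + 1L, 1L)
    }, integer(1))
    hotspots$end <- hotspots$start + hotspot_length - 1L
    hotspots$depth <- hotspot_depth

    hot_peps <- purrr::pmap(
      list(hotspots$protein_id, hotspots$start, hotspots$end),
      function(pid, a, b) {
        pseq <- proteome$sequence[proteome$protein_id == pid]
        cov <- integer(b - a + 1L)
        peps <- character(0)
        seen <- character(0)
        passes <- 0L
        while (min(cov) < hotspot_depth) {
          passes <- passes + 1L
          if (passes > 1000L) {
            stop("hotspot tiling did not reach the target depth",
                 call. = FALSE)
          }
          pos <- a
          while (pos <= b) {
            l <- draw_len(class1_length_probs)
            s <- max(a, min(pos, b - l + 1L))
            e <- s + l - 1L
            key <- paste0(s, ":", e)
            if (!key %in% seen) {
              # profiles count unique sequences, so a window drawn twice
              # must not be tallied twice
              seen <- c(seen, key)
              peps <- c(peps, substr(pseq, s, e))
              cov[(s - a + 1L):(e - a + 1L)] <-
                cov[(s - a + 1L):(e - a + 1L)] + 1L
            }
            pos <- e + 1L
          }
        }
        tibble::tibble(sequence = peps, protein_id = pid)
      }
    ) |> dplyr::bind_rows()

    # background class-I peptides per sample
    bg1 <- purrr::map(samples$sample_id, function(sid) {
      w <- purrr::map(seq_len(class1_per_sample),
                      ~ random_window(class1_length_probs))
      tibble::tibble(
        sequence = purrr::map_chr(w, "sequence"),
        sample_id = sid, hla_class = "I"
      )
    }) |> dplyr::bind_rows()
    hot_obs <- hot_peps |>
      dplyr::mutate(
        sample_id = sample(samples$sample_id, dplyr::n(), replace = TRUE),
        hla_class = "I"
      ) |>
      dplyr::select("sequence", "sample_id", "hla_class")

    # class-II peptides: full yield for expressing samples, sparse
    # otherwise; sequences already detected as class I are redrawn so
    # sharing comes only from the planted re-emissions below
    uniq1 <- unique(c(bg1$sequence, hot_obs$sequence))
    bg2 <- purrr::map(seq_len(n_samples), function(i) {
      n2 <- if (samples$hla2_expressing_planted[i]) {
        class2_per_sample
      } else {
        sample.int(20L, 1L)
      }
      if (n2 == 0L) return(NULL)
      w <- purrr::map(seq_len(n2), function(k) {
        for (try in 1:100) {
          win <- random_window(class2_length_probs)
          if (!win$sequence %in% uniq1) return(win)
        }
        win
      })
      tibble::tibble(
        sequence = purrr::map_chr(w, "sequence"),
        sample_id = samples$sample_id[i], hla_class = "II"
      )
    }) |> dplyr::bind_rows()

    # shared (I/II) sequences: re-emit class-I sequences into class-II
    # samples and class-II sequences into class-I samples
    uniq2 <- unique(bg2$sequence)
    n_shared <- round(shared_fraction * (length(uniq1) + length(uniq2)))
    expressing <- samples$sample_id[samples$hla2_expressing_planted]
    n_from1 <- min(ceiling(n_shared / 2), length(uniq1))
    n_from2 <- min(n_shared - n_from1, length(uniq2))
    shared_obs <- dplyr::bind_rows(
      tibble::tibble(
        sequence = sample(uniq1, n_from1),
        sample_id = sample(expressing, n_from1, replace = TRUE),
        hla_class = "II"
      ),
      tibble::tibble(
        sequence = sample(uniq2, n_from2),
        sample_id = sample(samples$sample_id, n_from2, replace = TRUE),
        hla_class = "I"
      )
    )

    observations <- dplyr::bind_rows(bg1, hot_obs, bg2, shared_obs)
    class2_counts <- observations |>
      dplyr::filter(.data$hla_class == "II") |>
      dplyr::count(.data$sample_id)
    samples_out <- samples |>
      dplyr::left_join(class2_counts, by = "sample_id") |>
      dplyr::mutate(
        hla2_peptide_count = as.integer(dplyr::coalesce(.data$n, 0L)),
        hla2_expressing = .data$hla2_peptide_count >= HLA2_EXPRESSING_MIN_PEPTIDES
      ) |>
      dplyr::select("sample_id", "group", "hla2_peptide_count",
                    "hla2_expressing")

    seqs1 <- unique(observations$sequence[observations$hla_class == "I"])
    seqs2 <- unique(observations$sequence[observations$hla_class == "II"])
    truth <- list(
      hotspots = hotspots[, c("protein_id", "start", "end", "depth")],
      n_observations = nrow(observations),
      n_class1_unique = length(seqs1),
      n_class2_unique = length(seqs2),
      n_shared_unique = length(intersect(seqs1, seqs2)),
      class1_modal_length = as.integer(names(which.max(class1_length_probs))),
      class2_modal_length = as.integer(names(which.max(class2_length_probs))),
      params = list(
        class1_per_sample = class1_per_sample,
        class2_per_sample = class2_per_sample,
        shared_fraction = shared_fraction,
        hotspot_fraction = hotspot_fraction,
        hotspot_length = hotspot_length,
        hotspot_depth = hotspot_depth
      ),
      seed = as.integer(seed)
    )
    list(observations = observations, samples = samples_out, truth = truth)
  })
}

#' Simulate a neoantigen candidate table
#'
#' Builds a candidate table at the scale of a patient neoantigen screen
#' (default 1,034 candidates, 16 immunogenic) whose wild-type peptides
#' realize a controlled mix of database match classes:
#'
#' * `exact` — the wild-type peptide is itself a class-I database peptide;
#' * `included` — a sub-window of a longer database peptide, not itself
#'   detected;
#' * `partial` — overlaps a database peptide placement at the mutation
#'   position only;
#' * `none` — no database support at the mutation site; a fraction of
#'   these (default 15.7%) is placed on decoy proteins absent from the
#'   database, so the protein-presence filter has something to remove.
#'
#' With a positive `effect_size`, the immunogenic match composition is
#' itself planted: at the reference 16-label scale, 2 exact, 3 included
#' and 4 partial immunogenic candidates (scaled proportionally otherwise),
#' the rest unmatched but always on database-covered proteins. Matched
#' immunogenic candidates preferentially carry wild-type peptides from
#' recurrently presented (hotspot) regions, so their match scores are
#' high as well as positive. Affinity, stability, cleavage and expression
#' features receive planted log-scale shifts (strong binding, higher
#' stability and expression). With `effect_size = 0` labels are assigned
#' uniformly and no feature is shifted (a null table).
#'
#' @param db A `peptidome_db` built from a simulated peptidome.
#' @param n_total,n_immunogenic Table size and number of immunogenic
#'   labels.
#' @param match_mix Named counts for `exact`, `included` and `partial`
#'   planted classes; the remainder is `none`. The default scales with
#'   `n_total` and equals `c(exact = 7, included = 25, partial = 34)` at
#'   the reference scale of 1,034 candidates. Requesting more exact
#'   matches than there are eligible database peptides is an error.
#' @param decoy_fraction Fraction of all candidates placed on decoy
#'   proteins absent from the database.
#' @param effect_size Multiplier on all planted label-feature shifts.
#' @param seed Integer seed (mandatory).
#' @return A list with `candidates` (tibble with peptide columns, the
#'   nine candidate features, `immunogenic`) and `truth` (planted match
#'   class per candidate, counts, decoy proteins, parameters, seed).
#' @export
simulate_candidates <- function(
    db,
    n_total = 1034,
    n_immunogenic = 16,
    match_mix = NULL,
    decoy_fraction = 0.157,
    effect_size = 1,
    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  check_db(db)
  if (is.null(match_mix)) {
    # defaults scale with table size; at the reference scale of 1,034
    # candidates this gives 7 exact, 25 included and 34 partial matches
    match_mix <- c(
      exact = max(1L, round(n_total * 7 / 1034)),
      included = max(1L, round(n_total * 25 / 1034)),
      partial = max(1L, round(n_total * 34 / 1034))
    )
  }
  stopifnot(all(c("exact", "included", "partial") %in% names(match_mix)))
  n_none <- n_total - sum(match_mix)
  if (n_none < 0) stop("match_mix exceeds n_total", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    pep <- db$peptides
    occ <- db$occurrences
    prot <- db$proteins
    class_sets <- pep$sequence[pep$class1 | pep$class2]
    ctx <- classify_context(db)

    first_placement <- occ |>
      dplyr::group_by(.data$sequence) |>
      dplyr::slice_min(.data$start, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()

    # class-I coverage per protein: drives the hotspot preference of
    # immunogenic matched candidates and lets 'none' candidates be drawn
    # from windows without any database support (their matchScore is then
    # 0, keeping positive match scores confined to the planted classes)
    cov1 <- setNames(
      purrr::map(prot$protein_id, ~ density_profile(db, .x, "I")$height),
      prot$protein_id
    )
    place_sum <- function(protein_id, start, end) {
      sum(cov1[[protein_id]][start:end])
    }

    # immunogenic match composition is planted deterministically so the
    # MS-feature signal exists in every realization: at the reference
    # 16-label scale, 2 exact, 3 included, 4 partial, remainder none
    imm_mix <- if (effect_size > 0) {
      m <- round(n_immunogenic * c(exact = 2, included = 3, partial = 4) / 16)
      pmin(m, match_mix[c("exact", "included", "partial")])
    } else {
      c(exact = 0L, included = 0L, partial = 0L)
    }
    if (sum(imm_mix) > n_immunogenic) {
      stop("immunogenic match composition exceeds n_immunogenic",
           call. = FALSE)
    }

    exact_pool <- pep |>
      dplyr::filter(.data$class1, .data$mapped,
                    .data$length >= 9L, .data$length <= 11L)
    if (nrow(exact_pool) < match_mix[["exact"]]) {
      stop("requested exact-match count exceeds available database peptides",
           call. = FALSE)
    }
    exact_place <- first_placement[
      match(exact_pool$sequence, first_placement$sequence),
    ]
    # immunogenic exact matches prefer recurrently presented (hotspot)
    # peptides: weight by the profile sum over the peptide's placement
    w_exact <- purrr::pmap_dbl(
      exact_place[, c("protein_id", "start", "end")], place_sum
    )
    imm_exact_rows <- if (imm_mix[["exact"]] > 0L) {
      sample.int(nrow(exact_pool), imm_mix[["exact"]], prob = w_exact)
    } else {
      integer(0)
    }
    ctl_candidates_idx <- setdiff(seq_len(nrow(exact_pool)), imm_exact_rows)
    ctl_exact_rows <- ctl_candidates_idx[
      sample.int(length(ctl_candidates_idx),
                 match_mix[["exact"]] - imm_mix[["exact"]])
    ]
    exact_rows <- c(imm_exact_rows, ctl_exact_rows)
    exact_tbl <- tibble::tibble(
      wt_peptide = exact_pool$sequence[exact_rows],
      protein_id = exact_place$protein_id[exact_rows],
      planted_match = "exact",
      mutation_pos = vapply(
        exact_pool$length[exact_rows],
        function(l) sample.int(l, 1L), integer(1)
      ),
      immunogenic = seq_along(exact_rows) <= length(imm_exact_rows)
    )

    is_included <- function(wt) {
      longer <- pep$sequence[pep$length > nchar(wt)]
      length(longer) > 0L && any(stringi::stri_detect_fixed(longer, wt))
    }
    included_pool <- pep |>
      dplyr::filter(.data$mapped, .data$length >= 12L)
    included_place <- first_placement[
      match(included_pool$sequence, first_placement$sequence),
    ]
    w_included <- purrr::pmap_dbl(
      included_place[, c("protein_id", "start", "end")], place_sum
    )
    draw_included <- function(prefer_hotspot) {
      w <- if (prefer_hotspot) w_included else rep(1, nrow(included_pool))
      for (try in seq_len(500L)) {
        j <- sample.int(nrow(included_pool), 1L, prob = w)
        src <- included_pool[j, ]
        l <- sample(9:11, 1L)
        if (src$length <= l) next
        off <- sample.int(src$length - l + 1L, 1L)
        wt <- substr(src$sequence, off, off + l - 1L)
        if (wt %in% class_sets) next
        return(list(wt_peptide = wt,
                    protein_id = included_place$protein_id[j],
                    planted_match = "included",
                    mutation_pos = sample.int(l, 1L),
                    immunogenic = prefer_hotspot))
      }
      stop("could not construct an 'included' candidate", call. = FALSE)
    }
    w_occ <- purrr::pmap_dbl(occ[, c("protein_id", "start", "end")],
                             place_sum)
    draw_partial <- function(prefer_hotspot) {
      w <- if (prefer_hotspot) w_occ else rep(1, nrow(occ))
      for (try in seq_len(500L)) {
        o <- occ[sample.int(nrow(occ), 1L, prob = w), ]
        L <- prot$length[prot$protein_id == o$protein_id]
        pseq <- prot$sequence[prot$protein_id == o$protein_id]
        l <- sample(9:11, 1L)
        m <- sample.int(l, 1L)
        q <- sample(o$start:o$end, 1L)  # mutation site inside the db placement
        s <- q - m + 1L
        e <- s + l - 1L
        if (s < 1L || e > L) next
        wt <- substr(pseq, s, e)
        if (wt %in% class_sets || is_included(wt)) next
        return(list(wt_peptide = wt, protein_id = o$protein_id,
                    planted_match = "partial", mutation_pos = m,
                    immunogenic = prefer_hotspot))
      }
      stop("could not construct a 'partial' candidate", call. = FALSE)
    }
    n_decoy <- round(decoy_fraction * n_total)
    decoy_prot <- if (n_decoy > 0L) {
      simulate_proteome(
        n_proteins = max(3L, ceiling(n_decoy / 40)),
        length_range = c(150, 300),
        seed = as.integer(seed) + 104729L
      ) |>
        dplyr::mutate(protein_id = sub("^PROT", "DECOY", .data$protein_id))
    } else {
      NULL
    }
    covered_ids <- unique(occ$protein_id[
      occ$sequence %in% pep$sequence[pep$class1]
    ])
    draw_none <- function(on_decoy, want_imm = FALSE) {
      src <- if (on_decoy) decoy_prot else prot
      if (want_imm) {
        # immunogenic candidates always lie on database-covered proteins
        src <- src[src$protein_id %in% covered_ids, ]
      }
      for (try in seq_len(2000L)) {
        i <- sample.int(nrow(src), 1L)
        l <- sample(9:11, 1L)
        s <- sample.int(src$length[i] - l + 1L, 1L)
        if (!on_decoy && sum(cov1[[src$protein_id[i]]][s:(s + l - 1L)]) > 0L) {
          next
        }
        wt <- substr(src$sequence[i], s, s + l - 1L)
        m <- sample.int(l, 1L)
        if (wt %in% class_sets || is_included(wt)) next
        if (classify_match_impl(wt, m, ctx) != "none") next
        return(list(wt_peptide = wt, protein_id = src$protein_id[i],
                    planted_match = "none", mutation_pos = m,
                    immunogenic = want_imm))
      }
      stop("could not construct a 'none' candidate", call. = FALSE)
    }

    n_imm_none <- if (effect_size > 0) n_immunogenic - sum(imm_mix) else 0L
    n_ctl_none <- n_none - n_imm_none
    if (n_ctl_none < n_decoy) {
      stop("decoy_fraction leaves too few control 'none' candidates",
           call. = FALSE)
    }
    none_on_decoy <- c(rep(FALSE, n_imm_none), rep(TRUE, n_decoy),
                       rep(FALSE, n_ctl_none - n_decoy))
    none_want_imm <- c(rep(TRUE, n_imm_none), rep(FALSE, n_ctl_none))
    imm_flags <- function(n_class) {
      n_i <- imm_mix[[n_class]]
      n_c <- match_mix[[n_class]] - n_i
      rep(c(TRUE, FALSE), c(n_i, n_c))
    }
    drawn <- c(
      purrr::map(imm_flags("included"), draw_included),
      purrr::map(imm_flags("partial"), draw_partial),
      purrr::map2(none_on_decoy, none_want_imm, draw_none)
    )
    cand <- dplyr::bind_rows(
      exact_tbl,
      tibble::tibble(
        wt_peptide = purrr::map_chr(drawn, "wt_peptide"),
        protein_id = purrr::map_chr(drawn, "protein_id"),
        planted_match = purrr::map_chr(drawn, "planted_match"),
        mutation_pos = purrr::map_int(drawn, "mutation_pos"),
        immunogenic = purrr::map_lgl(drawn, "immunogenic")
      )
    )
    cand <- cand[sample.int(nrow(cand)), ]
    cand$candidate_id <- sprintf("cand%04d", seq_len(nrow(cand)))

    # point mutation at mutation_pos
    cand$mut_peptide <- purrr::pmap_chr(
      list(cand$wt_peptide, cand$mutation_pos),
      function(wt, m) {
        old <- substr(wt, m, m)
        new <- sample(setdiff(AA_ALPHABET, old), 1L)
        paste0(substr(wt, 1L, m - 1L), new, substr(wt, m + 1L, nchar(wt)))
      }
    )

    # null model: labels uniform over all candidates
    if (effect_size <= 0) {
      imm_rows <- sample.int(nrow(cand), n_immunogenic)
      cand$immunogenic <- seq_len(nrow(cand)) %in% imm_rows
    }
    covered <- nr_matching_peptides(db, cand$protein_id) > 0L

    n <- nrow(cand)
    imm <- cand$immunogenic
    ef <- effect_size
    ln <- function(meanlog, sdlog) rlnorm_vec(n, meanlog, sdlog)
    cand$mutAffinity <- ifelse(
      imm,
      rlnorm_vec(n, log(500) - ef * 1.6, 0.8),
      rlnorm_vec(n, log(500), 1.2)
    )
    cand$wtAffinity <- cand$mutAffinity * rlnorm_vec(n, 0, 0.4)
    cand$mutPeptideStability <- ifelse(
      imm,
      rlnorm_vec(n, log(1) + ef * 0.9, 0.8),
      rlnorm_vec(n, log(1), 0.8)
    )
    cand$wtPeptideStability <- cand$mutPeptideStability * rlnorm_vec(n, 0, 0.4)
    cand$mutCleavProb <- ifelse(
      imm,
      stats::rbeta(n, 2 + ef * 1.5, 2),
      stats::rbeta(n, 2, 2)
    )
    cand$wtCleavProb <- stats::rbeta(n, 2, 2)
    cand$mutReads <- stats::rnbinom(n, size = 2, mu = 60)
    cand$wtReads <- stats::rnbinom(n, size = 2, mu = 60)
    cand$rnaExpr <- ifelse(
      imm,
      rlnorm_vec(n, log(10) + ef * 0.7, 1),
      rlnorm_vec(n, log(10), 1)
    )

    candidates <- cand |>
      dplyr::select(
        "candidate_id", "mut_peptide", "wt_peptide", "mutation_pos",
        "protein_id", "mutAffinity", "wtAffinity", "mutPeptideStability",
        "wtPeptideStability", "mutCleavProb", "wtCleavProb", "mutReads",
        "wtReads", "rnaExpr", "immunogenic"
      )
    truth <- list(
      planted = cand[, c("candidate_id", "planted_match")],
      planted_counts = c(
        exact = unname(match_mix[["exact"]]),
        included = unname(match_mix[["included"]]),
        partial = unname(match_mix[["partial"]]),
        none = n_none
      ),
      immunogenic_ids = cand$candidate_id[imm],
      decoy_proteins = if (is.null(decoy_prot)) character(0) else decoy_prot$protein_id,
      n_on_db_proteins = sum(covered),
      params = list(
        n_total = n_total, n_immunogenic = n_immunogenic,
        decoy_fraction = decoy_fraction, effect_size = effect_size
      ),
      seed = as.integer(seed)
    )
    list(candidates = candidates, truth = truth)
  })
}

# lognormal draws; wrapper keeps the call sites compact
rlnorm_vec <- function(n, meanlog, sdlog) {
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Positional recovery of planted hotspots
#'
#' For every planted hotspot in a truth manifest, segments the class-I
#' density profile of its protein and reports the best positional Jaccard
#' index between the planted interval and any detected hotspot. The
#' default segmentation threshold is the planted depth itself: the
#' generator guarantees that minimum coverage across the interval, so the
#' full interval is always detected while background rarely reaches it.
#'
#' @param db A `peptidome_db` built from the generated peptidome.
#' @param truth_hotspots The `hotspots` tibble of a
#'   [simulate_peptidome()] truth manifest.
#' @param min_height Segmentation threshold; defaults to each hotspot's
#'   planted depth.
#' @return The truth tibble with an appended `jaccard` column.
#' @export
hotspot_recovery <- function(db, truth_hotspots, min_height = NULL) {
  check_db(db)
  truth_hotspots$jaccard <- purrr::pmap_dbl(
    truth_hotspots[, c("protein_id", "start", "end", "depth")],
    function(protein_id, start, end, depth) {
      prof <- density_profile(db, protein_id, "I")
      det <- segment_hotspots(
        prof, min_height = if (is.null(min_height)) depth else min_height
      )
      if (nrow(det) == 0L) return(0)
      planted <- start:end
      max(purrr::map2_dbl(det$start, det$end, function(s, e) {
        found <- s:e
        length(intersect(planted, found)) / length(union(planted, found))
      }))
    }
  )
  truth_hotspots
}

#' Simulate a full study: proteome, peptidome, database, candidates
#'
#' Convenience wrapper chaining [simulate_proteome()],
#' [simulate_peptidome()], [build_db()] and [simulate_candidates()] with
#' sub-seeds derived deterministically from one master seed.
#'
#' @param seed Master integer seed.
#' @param n_proteins Proteome size.
#' @param ... Passed to [simulate_candidates()] (`n_total`,
#'   `n_immunogenic`, `effect_size`, ...).
#' @return A list with `proteome`, `peptidome`, `db`, `candidates` and
#'   `truth` (candidate truth manifest).
#' @export
simulate_study <- function(seed, n_proteins = 50, ...) {
  seed <- as.integer(seed)
  proteome <- simulate_proteome(n_proteins = n_proteins, seed = seed)
  peptidome <- simulate_peptidome(proteome, seed = seed + 1L)
  db <- build_db(proteome, peptidome$observations, peptidome$samples)
  cand <- simulate_candidates(db, seed = seed + 2L, ...)
  list(
    proteome = proteome,
    peptidome = peptidome,
    db = db,
    candidates = cand$candidates,
    truth = cand$truth
  )
}
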