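#' Per-residue presentation density profile
#'
#' For one protein and one class selector, counts for every residue the
#' number of peptide placements covering it. Heights are computed from
#' unique peptide sequences: a sequence placed at two distinct positions of
#' the protein contributes to both placements (set
#' `count_once_per_protein = TRUE` to count each sequence at its first
#' placement only).
#'
#' @param db A `peptidome_db`.
#' @param protein_id Protein identifier; unknown protein is an error.
#' @param class_selector `"I"`, `"II"`, `"I/II"` or `"I_short"` (class-I
#'   peptides shorter than 15 residues).
#' @param count_once_per_protein Count a recurring sequence once per
#'   protein instead of once per placement.
#' @return A tibble of class `density_profile` with columns `position`
#'   (1-based), `residue` and `height`, one row per residue.
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", sequence = "ACDEFGHIKL")
#' obs <- tibble::tibble(
#'   sequence = c("ACDEF", "DEFGH", "GHIKL"),
#'   sample_id = "s1", hla_class = "I"
#' )
#' density_profile(build_db(prot, obs), "P1", "I")$height
#' @export
density_profile <- function(db, protein_id, class_selector = "I",
                            count_once_per_protein = FALSE) {
  check_db(db)
  row <- which(db$proteins$protein_id == protein_id)
  if (length(row) != 1L) {
    stop("unknown protein: ", protein_id, call. = FALSE)
  }
  seq <- db$proteins$sequence[row]
  len <- nchar(seq)
  seqs <- selector_sequences(db, class_selector)
  plc <- db$occurrences[
    db$occurrences$protein_id == protein_id &
      db$occurrences$sequence %in% seqs,
  ]
  if (count_once_per_protein && nrow(plc) > 0L) {
    plc <- plc |>
      dplyr::group_by(.data$sequence) |>
      dplyr::slice_min(.data$start, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  heights <- coverage_heights(len, plc$start, plc$end)
  out <- tibble::tibble(
    position = seq_len(len),
    residue = stringr::str_split_1(seq, ""),
    height = heights
  )
  structure(
    out,
    protein_id = protein_id,
    class_selector = class_selector,
    class = c("density_profile", class(out))
  )
}

# interval stabbing counts via a difference array; intervals 1-based inclusive
coverage_heights <- function(len, starts, ends) {
  delta <- integer(len + 1L)
  if (length(starts) > 0L) {
    add <- tabulate(starts, nbins = len)
    rem <- tabulate(ends + 1L, nbins = len + 1L)
    delta[seq_len(len)] <- add
    delta <- delta - rem
  }
  cumsum(delta)[seq_len(len)]
}

#' Segment a density profile into hotspots
#'
#' Hotspots are maximal runs of residues whose coverage height reaches the
#' threshold `t = max(min_height, ceiling(min_frac_of_max * max(height)))`.
#' Runs separated by fewer than `merge_gap` sub-threshold positions are
#' merged. An all-zero profile yields no hotspots.
#'
#' @param profile A `density_profile`.
#' @param min_height Absolute height threshold (default 2, enforcing
#'   recurrence across peptides).
#' @param min_frac_of_max Relative threshold as a fraction of the profile
#'   maximum (default 0).
#' @param merge_gap Merge runs separated by fewer than this many positions
#'   (default 0: no merging).
#' @return A tibble of class `hotspot_table` with columns `protein_id`,
#'   `start`, `end` (1-based inclusive), `peak_height` and `area`, sorted
#'   and disjoint.
#' @export
segment_hotspots <- function(profile, min_height = 2, min_frac_of_max = 0,
                             merge_gap = 0) {
  stopifnot(inherits(profile, "density_profile"))
  if (min_height < 0 || min_frac_of_max < 0 || merge_gap < 0) {
    stop("segmentation parameters must be non-negative", call. = FALSE)
  }
  h <- profile$height
  pid <- attr(profile, "protein_id")
  empty <- tibble::tibble(
    protein_id = character(), start = integer(), end = integer(),
    peak_height = integer(), area = integer()
  )
  if (length(h) == 0L || max(h) == 0L) {
    return(new_hotspot_table(empty, attr(profile, "class_selector")))
  }
  t <- max(min_height, ceiling(min_frac_of_max * max(h)))
  runs <- run_intervals(h >= t)
  if (nrow(runs) == 0L) {
    return(new_hotspot_table(empty, attr(profile, "class_selector")))
  }
  if (merge_gap > 0 && nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(0L, as.integer(gap >= merge_gap)))
    runs <- tibble::tibble(
      start = as.integer(unname(tapply(runs$start, grp, min))),
      end = as.integer(unname(tapply(runs$end, grp, max)))
    )
  }
  out <- tibble::tibble(
    protein_id = pid,
    start = as.integer(runs$start),
    end = as.integer(runs$end),
    peak_height = purrr::map2_int(runs$start, runs$end, ~ max(h[.x:.y])),
    area = purrr::map2_int(runs$start, runs$end, ~ as.integer(sum(h[.x:.y])))
  )
  new_hotspot_table(out, attr(profile, "class_selector"))
}

new_hotspot_table <- function(x, class_selector) {
  structure(
    x,
    class_selector = class_selector,
    class = c("hotspot_table", class(x))
  )
}

# maximal runs of TRUE, as 1-based inclusive intervals
run_intervals <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = start[keep], end = end[keep])
}

#' Main-peak similarity between two density profiles
#'
#' Binarizes each profile at `peak_frac` of its own maximum and returns the
#' Jaccard index of the two masks: the overlap of the main peaks, ignoring
#' smaller peaks. Zero when either mask is empty.
#'
#' @param profile_a,profile_b `density_profile`s of the same protein
#'   (equal length; a mismatch is an error).
#' @param peak_frac Fraction of each profile's maximum used for
#'   binarization (default 0.5).
#' @return A similarity in `[0, 1]`.
#' @export
main_peak_correlation <- function(profile_a, profile_b, peak_frac = 0.5) {
  stopifnot(inherits(profile_a, "density_profile"))
  stopifnot(inherits(profile_b, "density_profile"))
  a <- profile_a$height
  b <- profile_b$height
  if (length(a) != length(b)) {
    stop("profiles have different lengths; same protein required", call. = FALSE)
  }
  mask_a <- a > 0 & a >= peak_frac * max(a)
  mask_b <- b > 0 & b >= peak_frac * max(b)
  if (!any(mask_a) || !any(mask_b)) return(0)
  sum(mask_a & mask_b) / sum(mask_a | mask_b)
}

#' Hotspot overlap statistics across a database
#'
#' For every protein carrying at least one I/II hotspot, reports the
#' fraction of its I/II hotspots whose interval intersects at least one
#' class-II hotspot, and likewise for class-I hotspots, plus
#' database-wide means and a paired Wilcoxon signed-rank p-value across
#' proteins (testing whether I/II hotspots co-locate more with one class
#' than the other).
#'
#' @param db A `peptidome_db`.
#' @param min_height,min_frac_of_max,merge_gap Passed to
#'   [segment_hotspots()].
#' @return A list with `per_protein` (tibble), `mean_overlap_I`,
#'   `mean_overlap_II` and `p_value`. Empty `per_protein` if no protein
#'   has an I/II hotspot.
#' @export
hotspot_overlap_stats <- function(db, min_height = 2, min_frac_of_max = 0,
                                  merge_gap = 0) {
  check_db(db)
  shared <- selector_sequences(db, "I/II")
  pids <- unique(db$occurrences$protein_id[db$occurrences$sequence %in% shared])
  rows <- purrr::map(pids, function(pid) {
    hs_shared <- segment_hotspots(
      density_profile(db, pid, "I/II"),
      min_height, min_frac_of_max, merge_gap
    )
    if (nrow(hs_shared) == 0L) return(NULL)
    hs1 <- segment_hotspots(
      density_profile(db, pid, "I"),
      min_height, min_frac_of_max, merge_gap
    )
    hs2 <- segment_hotspots(
      density_profile(db, pid, "II"),
      min_height, min_frac_of_max, merge_gap
    )
    overlaps_any <- function(s, e, hs) {
      nrow(hs) > 0L && any(hs$start <= e & hs$end >= s)
    }
    tibble::tibble(
      protein_id = pid,
      n_hotspots = nrow(hs_shared),
      frac_overlap_I = mean(purrr::map2_lgl(
        hs_shared$start, hs_shared$end, overlaps_any, hs = hs1
      )),
      frac_overlap_II = mean(purrr::map2_lgl(
        hs_shared$start, hs_shared$end, overlaps_any, hs = hs2
      ))
    )
  })
  per_protein <- dplyr::bind_rows(rows)
  if (nrow(per_protein) == 0L) {
    return(list(
      per_protein = tibble::tibble(
        protein_id = character(), n_hotspots = integer(),
        frac_overlap_I = double(), frac_overlap_II = double()
      ),
      mean_overlap_I = NA_real_, mean_overlap_II = NA_real_,
      p_value = NA_real_
    ))
  }
  diffs <- per_protein$frac_overlap_II - per_protein$frac_overlap_I
  p <- if (nrow(per_protein) < 2L || all(diffs == 0)) {
    NA_real_
  } else {
    suppressWarnings(wilcox.test(
      per_protein$frac_overlap_II, per_protein$frac_overlap_I,
      paired = TRUE
    )$p.value)
  }
  list(
    per_protein = per_protein,
    mean_overlap_I = mean(per_protein$frac_overlap_I),
    mean_overlap_II = mean(per_protein$frac_overlap_II),
    p_value = p
  )
}

#' Peptide length distribution
#'
#' Counts unique peptide sequences of a class selector per length.
#'
#' @param db A `peptidome_db`.
#' @param class_selector `"I"`, `"II"`, `"I/II"` or `"I_short"`.
#' @return A tibble with columns `length` and `n`, carrying the modal
#'   length (smallest in case of ties) in attribute `modal_length`.
#' @export
length_distribution <- function(db, class_selector = "I") {
  check_db(db)
  seqs <- selector_sequences(db, class_selector)
  out <- tibble::tibble(length = nchar(seqs)) |>
    dplyr::count(.data$length)
  modal <- if (nrow(out) == 0L) NA_integer_ else out$length[which.max(out$n)]
  structure(out, modal_length = modal, class_selector = class_selector)
}

#' Long-peptide proportion by HLA-II expression group
#'
#' For every sample, the proportion of its unique class-I peptides with
#' length `>= min_len`; then mean and standard deviation within the
#' HLA-II-expressing group (at least 100 class-II peptides) and the
#' non-expressing group. A comparable proportion in both groups argues
#' against long class-I peptides being class-II purification carry-over.
#'
#' @param db A `peptidome_db`.
#' @param min_len Long-peptide cutoff (default 14: 14-mers and longer).
#' @return A list of class `long_peptide_comparison` with `per_sample`,
#'   `groups` (mean/sd/n per group; `NA` mean for an empty group) and
#'   `difference` (expressing minus non-expressing mean, `NA` if either
#'   group is empty).
#' @export
long_peptide_proportion <- function(db, min_len = 14) {
  check_db(db)
  per_sample <- db$observations |>
    dplyr::filter(.data$hla_class == "I") |>
    dplyr::distinct(.data$sample_id, .data$sequence) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      proportion_long = mean(nchar(.data$sequence) >= min_len),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      db$samples[, c("sample_id", "group", "hla2_expressing")],
      by = "sample_id"
    )
  groups <- per_sample |>
    dplyr::group_by(.data$hla2_expressing) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_proportion = mean(.data$proportion_long),
      sd_proportion = sd(.data$proportion_long),
      .groups = "drop"
    )
  for (flag in c(TRUE, FALSE)) {
    if (!flag %in% groups$hla2_expressing) {
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        hla2_expressing = flag, n_samples = 0L,
        mean_proportion = NA_real_, sd_proportion = NA_real_
      ))
    }
  }
  groups <- dplyr::arrange(groups, dplyr::desc(.data$hla2_expressing))
  m_expr <- groups$mean_proportion[groups$hla2_expressing]
  m_non <- groups$mean_proportion[!groups$hla2_expressing]
  structure(
    list(
      per_sample = per_sample,
      groups = groups,
      min_len = min_len,
      difference = m_expr - m_non
    ),
    class = "long_peptide_comparison"
  )
}

#' @export
print.long_peptide_comparison <- function(x, ...) {
  cat("Long-peptide proportion (length >=", x$min_len, ") by HLA-II expression\n")
  print(x$groups)
  cat(sprintf("difference (expressing - non-expressing): %s\n",
              format(x$difference)))
  invisible(x)
}

#' Export a density profile to TSV or bedGraph
#'
#' The TSV format has columns `position` (1-based), `residue` and
#' `height`. The bedGraph format emits 4-column intervals with the protein
#' identifier in the chromosome field, 0-based half-open coordinates and
#' runs of equal height merged; each protein is its own reference
#' sequence, so the file targets per-protein viewers rather than genome
#' browsers.
#'
#' @param profile A `density_profile`.
#' @param path Output file path.
#' @param format `"tsv"` or `"bedgraph"`.
#' @param skip_zero For bedGraph, omit zero-height runs instead of writing
#'   them.
#' @return `path`, invisibly.
#' @export
export_profile <- function(profile, path, format = c("tsv", "bedgraph"),
                           skip_zero = FALSE) {
  stopifnot(inherits(profile, "density_profile"))
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(
      tibble::tibble(
        position = profile$position,
        residue = profile$residue,
        height = profile$height
      ),
      path, progress = FALSE
    )
  } else {
    pid <- attr(profile, "protein_id")
    r <- rle(profile$height)
    end1 <- cumsum(r$lengths)
    start1 <- end1 - r$lengths + 1L
    keep <- if (skip_zero) r$values > 0 else rep(TRUE, length(r$values))
    lines <- sprintf("%s\t%d\t%d\t%d", pid, start1[keep] - 1L, end1[keep],
                     r$values[keep])
    writeLines(lines, path)
  }
  invisible(path)
}
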