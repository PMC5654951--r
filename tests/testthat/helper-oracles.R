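# Brute-force reference implementations, deliberately naive: every check is
# an explicit position-by-position loop, independent of the package's
# vectorized code paths.

# all exact placements of one peptide in one protein sequence (1-based)
oracle_locate_one <- function(protein_seq, peptide) {
  L <- nchar(protein_seq)
  l <- nchar(peptide)
  hits <- integer(0)
  if (l <= L) {
    for (s in 1:(L - l + 1)) {
      if (substr(protein_seq, s, s + l - 1) == peptide) hits <- c(hits, s)
    }
  }
  hits
}

# placement table of many peptides over a proteome tibble
oracle_locate <- function(proteome, peptides) {
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    for (p in peptides) {
      for (s in oracle_locate_one(proteome$sequence[i], p)) {
        rows[[length(rows) + 1]] <- data.frame(
          sequence = p, protein_id = proteome$protein_id[i],
          start = s, end = s + nchar(p) - 1
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), protein_id = character(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, rows)
}

# per-residue coverage of one protein by a set of peptide sequences,
# counting every placement
oracle_profile <- function(protein_seq, peptides) {
  L <- nchar(protein_seq)
  h <- integer(L)
  for (p in unique(peptides)) {
    for (s in oracle_locate_one(protein_seq, p)) {
      for (i in s:(s + nchar(p) - 1)) h[i] <- h[i] + 1L
    }
  }
  h
}

# count of unique class-I sequences with >=1 placement in the protein
oracle_nr_matching <- function(proteome, class1_peptides, protein_id) {
  seq <- proteome$sequence[proteome$protein_id == protein_id]
  if (length(seq) == 0) return(0L)
  n <- 0L
  for (p in unique(class1_peptides)) {
    if (length(oracle_locate_one(seq, p)) > 0) n <- n + 1L
  }
  n
}

# max over the query's placements of the summed overlap lengths with all
# class-I database placements (the profile-sum identity, computed the
# other way around)
oracle_match_score <- function(proteome, class1_peptides, wt) {
  best <- 0
  for (i in seq_len(nrow(proteome))) {
    for (s in oracle_locate_one(proteome$sequence[i], wt)) {
      e <- s + nchar(wt) - 1
      total <- 0
      for (p in unique(class1_peptides)) {
        for (s2 in oracle_locate_one(proteome$sequence[i], p)) {
          e2 <- s2 + nchar(p) - 1
          ov <- min(e, e2) - max(s, s2) + 1
          if (ov > 0) total <- total + ov
        }
      }
      if (total > best) best <- total
    }
  }
  best
}

# direct restatement of the match taxonomy
oracle_classify <- function(proteome, class1_peptides, class2_peptides,
                            wt, mutation_pos) {
  all_peps <- unique(c(class1_peptides, class2_peptides))
  if (wt %in% all_peps) return("exact")
  for (p in all_peps) {
    if (nchar(p) > nchar(wt) && grepl(wt, p, fixed = TRUE)) {
      return("included")
    }
  }
  for (i in seq_len(nrow(proteome))) {
    for (s in oracle_locate_one(proteome$sequence[i], wt)) {
      abs_pos <- s + mutation_pos - 1
      for (p in all_peps) {
        for (s2 in oracle_locate_one(proteome$sequence[i], p)) {
          e2 <- s2 + nchar(p) - 1
          if (s2 <= abs_pos && abs_pos <= e2) return("partial")
        }
      }
    }
  }
  "none"
}

# threshold-and-merge segmentation, one position at a time
oracle_hotspots <- function(heights, min_height = 2, min_frac_of_max = 0,
                            merge_gap = 0) {
  if (length(heights) == 0 || max(heights) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  t <- max(min_height, ceiling(min_frac_of_max * max(heights)))
  runs <- list()
  inside <- FALSE
  for (i in seq_along(heights)) {
    if (heights[i] >= t && !inside) {
      runs[[length(runs) + 1]] <- c(start = i, end = i)
      inside <- TRUE
    } else if (heights[i] >= t) {
      runs[[length(runs)]]["end"] <- i
    } else {
      inside <- FALSE
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r["start"] - last["end"] - 1 < merge_gap) {
      merged[[length(merged)]]["end"] <- r["end"]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  data.frame(
    start = vapply(merged, function(r) unname(r["start"]), numeric(1)),
    end = vapply(merged, function(r) unname(r["end"]), numeric(1))
  )
}

# expectation and sd of the hypergeometric draw underlying random ranking:
# k slots, K immunogenic among N test candidates
hypergeom_moments <- function(N, K, k) {
  mu <- k * K / N
  v <- k * (K / N) * (1 - K / N) * (N - k) / (N - 1)
  c(mean = mu, sd = sqrt(v))
}
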