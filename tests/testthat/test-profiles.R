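# build a density_profile object directly from a height vector
fake_profile <- function(heights, protein_id = "P1", class_selector = "I") {
  out <- tibble::tibble(
    position = seq_along(heights),
    residue = rep("A", length(heights)),
    height = as.integer(heights)
  )
  structure(out, protein_id = protein_id, class_selector = class_selector,
            class = c("density_profile", class(out)))
}

test_that("toy profile heights match per-position counting", {
  db <- toy_db()
  p <- density_profile(db, "P1", "I")
  expect_equal(p$height, c(1, 1, 2, 2, 2, 2, 2, 1, 1, 1))
  expect_equal(p$residue, strsplit("ACDEFGHIKL", "")[[1]])
  expect_error(density_profile(db, "NOPE", "I"), "unknown protein")
})

test_that("unmapped selectors give an all-zero profile of protein length", {
  db <- toy_db()
  p2 <- density_profile(db, "P1", "II")
  expect_equal(p2$height, rep(0, 10))
})

test_that("the shared selector profiles only peptides seen in both classes", {
  db <- toy_db(tibble::tibble(
    sequence = "DEFGH", sample_id = "s2", hla_class = "II"
  ))
  expect_equal(
    density_profile(db, "P1", "I/II")$height,
    c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0)
  )
})

test_that("a repeated placement counts twice unless counted once per protein", {
  prot <- tibble::tibble(protein_id = "P1", sequence = "ACDEFGACDEFG")
  obs <- tibble::tibble(sequence = "ACDEFG", sample_id = "s1",
                        hla_class = "I")
  db <- build_db(prot, obs)
  expect_equal(density_profile(db, "P1", "I")$height, rep(1, 12))
  once <- density_profile(db, "P1", "I", count_once_per_protein = TRUE)
  expect_equal(once$height, c(rep(1, 6), rep(0, 6)))
})

test_that("hotspot segmentation matches the run-length rule", {
  hs <- segment_hotspots(
    fake_profile(c(1, 1, 2, 2, 2, 2, 2, 1, 1, 1)),
    min_height = 2, min_frac_of_max = 0, merge_gap = 0
  )
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$start, 3L)
  expect_equal(hs$end, 7L)
  expect_equal(hs$peak_height, 2L)
  expect_equal(hs$area, 10L)
})

test_that("all-zero profiles yield no hotspots and bad parameters error", {
  expect_equal(nrow(segment_hotspots(fake_profile(rep(0, 8)))), 0L)
  expect_error(segment_hotspots(fake_profile(c(1, 2)), min_height = -1),
               "non-negative")
})

test_that("nearby runs merge when the gap is below merge_gap", {
  hs <- segment_hotspots(fake_profile(c(3, 0, 3)), min_height = 1,
                         merge_gap = 2)
  expect_equal(nrow(hs), 1L)
  expect_equal(c(hs$start, hs$end), c(1L, 3L))
  expect_equal(hs$area, 6L)
  # merge_gap 0 never merges
  hs0 <- segment_hotspots(fake_profile(c(3, 0, 3)), min_height = 1,
                          merge_gap = 0)
  expect_equal(nrow(hs0), 2L)
})

test_that("the relative threshold uses the ceiling of the fraction of max", {
  # max 5, frac 0.5 -> threshold 3
  hs <- segment_hotspots(fake_profile(c(1, 2, 3, 5, 3, 2, 1)),
                         min_height = 0, min_frac_of_max = 0.5)
  expect_equal(c(hs$start, hs$end), c(3L, 5L))
})

test_that("segmentation agrees with a brute-force oracle on random profiles", {
  withr::with_seed(99, {
    for (i in 1:25) {
      h <- rpois(sample(20:80, 1), lambda = runif(1, 0.3, 2))
      mh <- sample(1:3, 1)
      mf <- runif(1, 0, 0.8)
      mg <- sample(0:3, 1)
      got <- segment_hotspots(fake_profile(h), mh, mf, mg)
      want <- oracle_hotspots(h, mh, mf, mg)
      expect_equal(nrow(got), nrow(want))
      expect_equal(as.numeric(got$start), want$start)
      expect_equal(as.numeric(got$end), want$end)
    }
  })
})

test_that("main-peak similarity is a Jaccard index of binarized masks", {
  a <- fake_profile(c(0, 2, 2, 2, 2, 2, 2, 0, 0, 0))  # mask 2..7
  b <- fake_profile(c(0, 0, 2, 2, 2, 2, 2, 2, 2, 0))  # mask 3..9
  expect_equal(main_peak_correlation(a, b), 5 / 8)
  expect_equal(main_peak_correlation(a, a), 1.0)
  disjoint <- fake_profile(c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(main_peak_correlation(disjoint, b), 0.0)
  # empty masks and mismatched lengths
  expect_equal(main_peak_correlation(fake_profile(rep(0, 10)), b), 0)
  expect_error(main_peak_correlation(a, fake_profile(c(1, 1))), "length")
})

test_that("profile mass equals the summed placement lengths", {
  fx <- random_small_db(555, n_proteins = 8, n_peptides = 80)
  db <- fx$db
  for (sel in c("I", "II", "I/II", "I_short")) {
    seqs <- db$peptides$sequence[switch(sel,
      "I" = db$peptides$class1,
      "II" = db$peptides$class2,
      "I/II" = db$peptides$shared,
      "I_short" = db$peptides$class1 & db$peptides$length < 15
    )]
    occ <- db$occurrences[db$occurrences$sequence %in% seqs, ]
    for (pid in db$proteins$protein_id) {
      h <- density_profile(db, pid, sel)$height
      plc <- occ[occ$protein_id == pid, ]
      expect_equal(sum(h), sum(plc$end - plc$start + 1))
    }
  }
})

test_that("adding a placement never decreases heights and I_short <= I", {
  db_small <- toy_db()
  db_more <- toy_db(tibble::tibble(
    sequence = "CDEFGHI", sample_id = "s1", hla_class = "I"
  ))
  h1 <- density_profile(db_small, "P1", "I")$height
  h2 <- density_profile(db_more, "P1", "I")$height
  expect_true(all(h2 >= h1))
  fx <- random_small_db(21)
  for (pid in fx$db$proteins$protein_id) {
    expect_true(all(
      density_profile(fx$db, pid, "I_short")$height <=
        density_profile(fx$db, pid, "I")$height
    ))
  }
})

test_that("length distributions report counts and the modal length", {
  prot <- tibble::tibble(protein_id = "P1", sequence = "ACDEFGHIKLMN")
  obs <- tibble::tibble(sequence = "ACDEFGHIKLMN", sample_id = "s1",
                        hla_class = "I")
  ld <- length_distribution(build_db(prot, obs), "I")
  expect_equal(ld$length, 12L)
  expect_equal(ld$n, 1L)
  expect_equal(attr(ld, "modal_length"), 12L)
})

test_that("generated class-I lengths recover the generator's mode and the shared set is bimodal", {
  study <- study_fixture()
  ld1 <- length_distribution(study$db, "I")
  expect_equal(attr(ld1, "modal_length"),
               study$peptidome$truth$class1_modal_length)
  ld2 <- length_distribution(study$db, "II")
  expect_equal(attr(ld2, "modal_length"),
               study$peptidome$truth$class2_modal_length)
  # shared lengths mix re-emitted class-I and class-II sequences: local
  # maxima in both the short and the long length range
  lds <- length_distribution(study$db, "I/II")
  short_peak <- max(lds$n[lds$length <= 11])
  long_peak <- max(lds$n[lds$length >= 13])
  trough <- min(lds$n[lds$length %in% 11:13])
  expect_gt(short_peak, trough)
  expect_gt(long_peak, trough)
})

test_that("long-peptide proportions split by HLA-II expression", {
  prot <- tibble::tibble(protein_id = "P1",
                         sequence = "ACDEFGHIKLMNPQRSTVWY")
  # sample s1: unique class-I lengths 9, 9(dup), 10, 14 -> proportion 1/4
  obs <- tibble::tibble(
    sequence = c("ACDEFGHIK", "ACDEFGHIK", "CDEFGHIKL", "ACDEFGHIKL",
                 "ACDEFGHIKLMNPQ", "DEFGHIKLM"),
    sample_id = c("s1", "s1", "s1", "s1", "s1", "s2"),
    hla_class = "I"
  )
  samples <- tibble::tibble(
    sample_id = c("s1", "s2"),
    group = c("B-cells", "other"),
    hla2_peptide_count = c(150L, 0L),
    hla2_expressing = c(TRUE, FALSE)
  )
  lp <- long_peptide_proportion(build_db(prot, obs, samples))
  expect_equal(
    lp$per_sample$proportion_long[lp$per_sample$sample_id == "s1"], 0.25
  )
  expect_equal(
    lp$per_sample$proportion_long[lp$per_sample$sample_id == "s2"], 0
  )
  g <- lp$groups
  expect_equal(g$mean_proportion[g$hla2_expressing], 0.25)
  expect_equal(g$mean_proportion[!g$hla2_expressing], 0)
  expect_equal(lp$difference, 0.25)
})

test_that("an empty expression group reports a missing mean, not an error", {
  db <- toy_db()  # single sample, not HLA-II expressing
  lp <- long_peptide_proportion(db)
  g <- lp$groups
  expect_true(is.na(g$mean_proportion[g$hla2_expressing]))
  expect_true(is.na(lp$difference))
  # all long
  prot <- tibble::tibble(protein_id = "P1",
                         sequence = "ACDEFGHIKLMNPQRSTVWY")
  obs <- tibble::tibble(sequence = "ACDEFGHIKLMNPQ", sample_id = "s1",
                        hla_class = "I")
  lp2 <- long_peptide_proportion(build_db(prot, obs))
  expect_equal(lp2$per_sample$proportion_long, 1)
})

test_that("bedGraph export run-length encodes and TSV round-trips", {
  p <- fake_profile(c(1, 1, 2))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  export_profile(p, bg, format = "bedgraph")
  expect_equal(readLines(bg), c("P1\t0\t2\t1", "P1\t2\t3\t2"))
  zero <- fake_profile(c(0, 0, 0, 0))
  bg0 <- withr::local_tempfile(fileext = ".bedgraph")
  export_profile(zero, bg0, format = "bedgraph")
  expect_equal(readLines(bg0), "P1\t0\t4\t0")
  export_profile(zero, bg0, format = "bedgraph", skip_zero = TRUE)
  expect_equal(readLines(bg0), character(0))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_profile(p, tsv, format = "tsv")
  back <- readr::read_tsv(tsv, show_col_types = FALSE, progress = FALSE)
  expect_equal(back$height, p$height)
  expect_equal(back$position, p$position)
})

test_that("I/II hotspots co-locate with the planted class preferences", {
  # 20 proteins, each with one shared-peptide hotspot; a tall class-II
  # stack overlaps it in 14/20 proteins, a tall class-I stack in 6/20
  n <- 20
  withr::with_seed(31, {
    proteome <- simulate_proteome(n_proteins = n,
                                  length_range = c(100, 100), seed = 31)
  })
  obs <- list()
  add <- function(seqs, cls) {
    obs[[length(obs) + 1]] <<- tibble::tibble(
      sequence = seqs, sample_id = "s1", hla_class = cls
    )
  }
  ii_overlap <- rep(c(TRUE, FALSE), c(14, 6))
  for (i in seq_len(n)) {
    s <- proteome$sequence[i]
    shared1 <- substr(s, 41, 49)
    shared2 <- substr(s, 43, 51)
    add(c(shared1, shared2), "I")
    add(c(shared1, shared2), "II")
    # tall stacks (10 distinct peptides) overpower the relative threshold
    tall_at <- function(from) {
      vapply(0:9, function(k) substr(s, from + k, from + k + 8),
             character(1))
    }
    if (ii_overlap[i]) {
      add(tall_at(38), "II")   # class-II peak on the shared hotspot
      add(tall_at(5), "I")     # class-I peak elsewhere
    } else {
      add(tall_at(38), "I")
      add(tall_at(5), "II")
    }
  }
  db <- build_db(proteome, dplyr::bind_rows(obs))
  st <- hotspot_overlap_stats(db, min_height = 2, min_frac_of_max = 0.5)
  expect_equal(nrow(st$per_protein), n)
  expect_lt(abs(st$mean_overlap_II - 0.7), 0.1)
  expect_lt(abs(st$mean_overlap_I - 0.3), 0.1)
  expect_true(st$p_value >= 0 && st$p_value <= 1)
  expect_gt(st$mean_overlap_II, st$mean_overlap_I)
})

test_that("hotspot overlap fractions hit 1 and 0 in constructed extremes", {
  prot <- simulate_proteome(n_proteins = 1, length_range = c(60, 60),
                            seed = 77)[, c("protein_id", "sequence")]
  prot$protein_id <- "P1"
  s <- prot$sequence
  shared <- c(substr(s, 11, 19), substr(s, 13, 21))
  obs <- dplyr::bind_rows(
    tibble::tibble(sequence = shared, sample_id = "a", hla_class = "I"),
    tibble::tibble(sequence = shared, sample_id = "a", hla_class = "II")
  )
  st <- hotspot_overlap_stats(build_db(prot, obs))
  # the shared peptides themselves form the class-II hotspot
  expect_equal(st$per_protein$frac_overlap_II, 1)
  # a shared hotspot disjoint from all class-I hotspots scores 0: here the
  # only class-I coverage >=2 is the shared interval itself, so use a
  # relative threshold dominated by a distant class-I stack
  tall <- vapply(0:9, function(k) substr(s, 35 + k, 43 + k), character(1))
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(
    sequence = tall, sample_id = "a", hla_class = "I"
  ))
  st2 <- hotspot_overlap_stats(build_db(prot, obs2),
                               min_height = 2, min_frac_of_max = 0.5)
  expect_equal(st2$per_protein$frac_overlap_I, 0)
})
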