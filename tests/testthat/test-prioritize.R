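# minimal candidate table for harness tests: features are injected directly
make_candidates <- function(n_ctl, n_imm, features = list()) {
  n <- n_ctl + n_imm
  out <- tibble::tibble(
    candidate_id = sprintf("c%04d", seq_len(n)),
    immunogenic = rep(c(FALSE, TRUE), c(n_ctl, n_imm))
  )
  for (f in names(features)) out[[f]] <- features[[f]]
  out
}

test_that("feature groups resolve to the documented sets", {
  expect_setequal(feature_group(1),
                  c("mutAffinity", "mutPeptideStability", "rnaExpr"))
  expect_setequal(feature_group(2),
                  c(feature_group(1), "wtAffinity", "wtPeptideStability"))
  expect_setequal(feature_group(3),
                  c(feature_group(1), "diffAffinity", "diffPeptideStability"))
  expect_equal(feature_group(1, "matchScore_I"),
               c(feature_group(1), "matchScore_I"))
  expect_error(feature_group(1, "bogus"), "ms_features")
})

test_that("derived difference features follow their definitions", {
  cand <- tibble::tibble(
    mutAffinity = c(10, 20), wtAffinity = c(4, 30),
    mutPeptideStability = c(1, 2), wtPeptideStability = c(3, 1)
  )
  d <- add_derived_features(cand)
  expect_equal(d$diffAffinity, c(6, -10))
  expect_equal(d$diffPeptideStability, c(-2, 1))
})

test_that("the Wilcoxon scan reproduces the exact rank-sum p-value", {
  cand <- make_candidates(3, 3, list(x = c(1, 2, 3, 4, 5, 6)))
  scan <- wilcoxon_feature_scan(cand, "x")
  # complete separation of 3 vs 3: 2/choose(6,3) = 0.1 two-sided
  expect_equal(scan$p_value, 0.1)
  expect_equal(scan$neg_log10_p, 1)
})

test_that("a constant feature scores zero discriminability", {
  cand <- make_candidates(5, 5, list(x = rep(2, 10), y = 1:10))
  scan <- wilcoxon_feature_scan(cand, c("x", "y"))
  expect_equal(scan$neg_log10_p[scan$feature == "x"], 0)
  expect_gt(scan$neg_log10_p[scan$feature == "y"], 0)
  expect_error(wilcoxon_feature_scan(cand, "zz"), "missing")
  expect_error(
    wilcoxon_feature_scan(make_candidates(4, 0, list(x = 1:4)), "x"),
    "immunogenic"
  )
})

test_that("a planted shift out-discriminates pure noise across seeds", {
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    withr::with_seed(7000 + s, {
      n_ctl <- 60; n_imm <- 12
      cand <- make_candidates(n_ctl, n_imm, list(
        shifted = c(rnorm(n_ctl), rnorm(n_imm, mean = 1.5)),
        noise = rnorm(n_ctl + n_imm)
      ))
    })
    scan <- wilcoxon_feature_scan(cand, c("shifted", "noise"))
    if (scan$neg_log10_p[1] > scan$neg_log10_p[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("recovery curves count immunogenic candidates by rank", {
  cand <- tibble::tibble(
    candidate_id = sprintf("c%d", 1:5),
    immunogenic = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    aff = c(1, 2, 3, 4, 5)
  )
  curve <- rank_by_feature(cand, "aff", "asc")
  expect_equal(curve$recovered, c(1, 1, 2, 2, 2))
  # all immunogenic
  all_imm <- tibble::tibble(immunogenic = rep(TRUE, 4), aff = 4:1)
  expect_equal(rank_by_feature(all_imm, "aff", "asc")$recovered, 1:4)
  # ties keep input order (stable sort)
  tied <- tibble::tibble(immunogenic = c(TRUE, FALSE, TRUE),
                         aff = c(1, 1, 1))
  expect_equal(rank_by_feature(tied, "aff", "asc")$recovered, c(1, 1, 2))
  expect_error(rank_by_feature(cand, "nope"), "unknown feature")
  # curves are non-decreasing and end at the total count
  expect_true(all(diff(curve$recovered) >= 0))
  expect_equal(dplyr::last(curve$recovered), sum(cand$immunogenic))
})

test_that("the protein presence filter keeps only database-covered proteins", {
  db <- toy_db()
  cand <- tibble::tibble(
    candidate_id = c("a", "b", "c"),
    protein_id = c("P1", "P1", "P9"),
    immunogenic = c(TRUE, FALSE, FALSE)
  )
  expect_message(kept <- protein_presence_filter(cand, db), "retained 2 of 3")
  expect_equal(kept$candidate_id, c("a", "b"))
  empty_db <- build_db(
    tibble::tibble(protein_id = "PX", sequence = "ACDEFGHIKL"),
    tibble::tibble(sequence = "WWWWWWW", sample_id = "s", hla_class = "I")
  )
  suppressMessages(
    expect_equal(nrow(protein_presence_filter(cand, empty_db)), 0L)
  )
})

test_that("filtering sharpens the affinity-ranked recovery on generated data", {
  scored <- scored_fixture()
  db <- study_fixture()$db
  before <- rank_by_feature(scored, "mutAffinity", "asc")
  suppressMessages(filtered <- protein_presence_filter(scored, db))
  after <- rank_by_feature(filtered, "mutAffinity", "asc")
  total <- sum(scored$immunogenic)
  # all planted immunogenic candidates lie on database proteins, so the
  # filtered curve reaches the same total in no more ranks
  expect_equal(dplyr::last(after$recovered), total)
  rank_before <- min(before$rank[before$recovered == total])
  rank_after <- min(after$rank[after$recovered == total])
  expect_lte(rank_after, rank_before)
})

test_that("a perfect feature saturates the CV harness at the test-half bound", {
  cand <- make_candidates(1018, 16, list(
    oracle_feature = c(rep(0, 1018), rep(1, 16))
  ))
  res <- svm_cv_evaluate(cand, "oracle_feature", n_repeats = 40, top_k = 20,
                         seed = 5)
  expect_equal(res$mean_top_k, 8)
  expect_equal(res$sd_top_k, 0)
  expect_equal(res$n_immunogenic_test, 8L)
})

test_that("a constant feature ranks randomly (hypergeometric expectation)", {
  cand <- make_candidates(1018, 16, list(flat = rep(1, 1034)))
  n_rep <- 400
  res <- svm_cv_evaluate(cand, "flat", n_repeats = n_rep, top_k = 20,
                         seed = 12)
  hm <- hypergeom_moments(N = 509 + 8, K = 8, k = 20)
  se <- hm["sd"] / sqrt(n_rep)
  expect_lt(abs(res$mean_top_k - hm["mean"]), 3 * se)
})

test_that("the harness is reproducible and input-order invariant", {
  withr::with_seed(61, {
    cand <- make_candidates(120, 10, list(
      mutAffinity = rlnorm(130, log(300), 1),
      mutPeptideStability = rlnorm(130, 0, 1),
      rnaExpr = rlnorm(130, 2, 1)
    ))
    cand$mutAffinity[cand$immunogenic] <-
      cand$mutAffinity[cand$immunogenic] * 0.2
  })
  a <- svm_cv_evaluate(cand, feature_group(1), n_repeats = 30, top_k = 10,
                       seed = 3)
  b <- svm_cv_evaluate(cand, feature_group(1), n_repeats = 30, top_k = 10,
                       seed = 3)
  expect_identical(a$per_repeat, b$per_repeat)
  shuffled <- cand[sample(nrow(cand)), ]
  c_ <- svm_cv_evaluate(shuffled, feature_group(1), n_repeats = 30,
                        top_k = 10, seed = 3)
  expect_identical(a$per_repeat, c_$per_repeat)
  # different seed gives different splits
  d <- svm_cv_evaluate(cand, feature_group(1), n_repeats = 30, top_k = 10,
                       seed = 4)
  expect_false(identical(a$per_repeat, d$per_repeat))
})

test_that("the harness validates its inputs before training", {
  cand <- make_candidates(10, 4, list(x = rnorm(14)))
  expect_error(svm_cv_evaluate(cand, "missing_col", n_repeats = 2, seed = 1),
               "missing")
  expect_error(svm_cv_evaluate(cand, "x", n_repeats = 2),
               "seed")
  tiny <- make_candidates(10, 1, list(x = rnorm(11)))
  expect_error(svm_cv_evaluate(tiny, "x", n_repeats = 2, seed = 1),
               "at least 2")
})

test_that("label-permuted data shows no spurious lift from MS features", {
  # a single permutation can by chance place labels on match-supported
  # candidates, so the null is averaged over several permutations
  scored <- scored_fixture()
  n_perm <- 8
  diffs <- vapply(seq_len(n_perm), function(i) {
    permuted <- scored
    withr::with_seed(990 + i, {
      permuted$immunogenic <- sample(permuted$immunogenic)
    })
    cmp <- svm_cv_compare(
      permuted, base_features = 1,
      ms_features = c("exactMatchScore_I", "matchScore_I"),
      seed = 17, n_repeats = 60, top_k = 20
    )
    cmp$augmented$mean_top_k - cmp$base$mean_top_k
  }, double(1))
  se <- sd(diffs) / sqrt(n_perm)
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("improvement is the relative gain in mean top-k", {
  fake_cv <- function(mean) {
    structure(list(mean_top_k = mean, top_k = 20), class = "cv_result")
  }
  expect_equal(improvement(fake_cv(2), fake_cv(3)), 50)
  expect_equal(improvement(fake_cv(2.5), fake_cv(2.5)), 0)
  expect_equal(round(improvement(fake_cv(2.2), fake_cv(2.55)), 1), 15.9)
  expect_message(na <- improvement(fake_cv(0), fake_cv(1)), "undefined")
  expect_true(is.na(na))
})

test_that("tidy and glance summarise CV results", {
  cand <- make_candidates(30, 4, list(x = c(rep(0, 30), rep(1, 4))))
  res <- svm_cv_evaluate(cand, "x", n_repeats = 12, top_k = 5, seed = 2)
  td <- tidy(res)
  expect_equal(nrow(td), 12L)
  expect_equal(td$n_immunogenic_top_k, as.integer(res$per_repeat))
  gl <- glance(res)
  expect_equal(gl$mean_top_k, res$mean_top_k)
  expect_equal(gl$n_repeats, 12L)
})
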