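#' Resolve a feature-group specification
#'
#' The non-MS feature groups used to evaluate what the MS-based features
#' add on top of conventional predictors:
#'
#' * group `1`: `mutAffinity`, `mutPeptideStability`, `rnaExpr`;
#' * group `2`: group 1 plus `wtAffinity`, `wtPeptideStability`;
#' * group `3`: group 1 plus `diffAffinity`, `diffPeptideStability`
#'   (mutant minus wild-type differences).
#'
#' @param group `1`, `2` or `3` (number or string), or a character vector
#'   of feature names used as-is.
#' @param ms_features MS-based features to append, a subset of
#'   `exactMatchScore_I`, `matchScore_I`, `nrMatchingPeptides_I`.
#' @return A character vector of feature names.
#' @export
feature_group <- function(group = 1, ms_features = character()) {
  base1 <- c("mutAffinity", "mutPeptideStability", "rnaExpr")
  base <- if (is.character(group) && length(group) > 1L) {
    group
  } else {
    switch(as.character(group),
      "1" = base1,
      "2" = c(base1, "wtAffinity", "wtPeptideStability"),
      "3" = c(base1, "diffAffinity", "diffPeptideStability"),
      as.character(group)
    )
  }
  allowed_ms <- c("exactMatchScore_I", "matchScore_I", "nrMatchingPeptides_I")
  bad <- setdiff(ms_features, allowed_ms)
  if (length(bad) > 0L) {
    stop(
      "unknown ms_features: ", paste(bad, collapse = ", "),
      "; allowed: ", paste(allowed_ms, collapse = ", "),
      call. = FALSE
    )
  }
  unique(c(base, ms_features))
}

#' Add derived affinity/stability difference features
#'
#' Computes `diffAffinity = mutAffinity - wtAffinity` and
#' `diffPeptideStability = mutPeptideStability - wtPeptideStability` where
#' the source columns are present and the derived ones are not.
#'
#' @param candidates A candidate tibble.
#' @return The tibble with derived columns appended.
#' @export
add_derived_features <- function(candidates) {
  if (!"diffAffinity" %in% names(candidates) &&
      all(c("mutAffinity", "wtAffinity") %in% names(candidates))) {
    candidates$diffAffinity <- candidates$mutAffinity - candidates$wtAffinity
  }
  if (!"diffPeptideStability" %in% names(candidates) &&
      all(c("mutPeptideStability", "wtPeptideStability") %in% names(candidates))) {
    candidates$diffPeptideStability <-
      candidates$mutPeptideStability - candidates$wtPeptideStability
  }
  candidates
}

#' Wilcoxon rank-sum scan over candidate features
#'
#' Tests each feature's values in the immunogenic group against the
#' non-immunogenic group with a two-sided Wilcoxon rank-sum test and
#' reports `-log10(p)`; larger values mean a more discriminative feature.
#' A feature constant across all candidates yields `p = 1` (no
#' separation), not an error.
#'
#' @param candidates Tibble with the feature columns and a logical
#'   `immunogenic` column; both groups must be non-empty.
#' @param features Character vector of feature column names.
#' @return A tibble with columns `feature`, `p_value`, `neg_log10_p`.
#' @export
wilcoxon_feature_scan <- function(candidates, features) {
  candidates <- add_derived_features(candidates)
  missing <- setdiff(features, names(candidates))
  if (length(missing) > 0L) {
    stop(
      "feature column(s) missing: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  lab <- as.logical(candidates$immunogenic)
  if (sum(lab) < 1L || sum(!lab) < 1L) {
    stop("need at least one immunogenic and one control candidate",
         call. = FALSE)
  }
  p <- purrr::map_dbl(features, function(f) {
    x <- candidates[[f]][lab]
    y <- candidates[[f]][!lab]
    if (length(unique(c(x, y))) == 1L) return(1)
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  })
  tibble::tibble(
    feature = features,
    p_value = p,
    neg_log10_p = -log10(p)
  )
}

#' Recovery curve from ranking by a single feature
#'
#' Sorts candidates by a feature (stable sort: ties keep input order) and
#' reports, for every rank r, how many immunogenic candidates lie among
#' the first r. Use `direction = "asc"` for features where low values are
#' good (binding affinity in nM).
#'
#' @param candidates Tibble with the feature and a logical `immunogenic`
#'   column.
#' @param feature Feature column name; unknown name is an error.
#' @param direction `"asc"` or `"desc"`.
#' @return A tibble of class `recovery_curve` with columns `rank` and
#'   `recovered`; the final value equals the total immunogenic count.
#' @export
rank_by_feature <- function(candidates, feature, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  candidates <- add_derived_features(candidates)
  if (!feature %in% names(candidates)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  x <- candidates[[feature]]
  ord <- if (direction == "asc") order(x) else order(-x)
  lab <- as.logical(candidates$immunogenic)[ord]
  out <- tibble::tibble(
    rank = seq_along(lab),
    recovered = cumsum(lab)
  )
  structure(out, feature = feature, direction = direction,
            class = c("recovery_curve", class(out)))
}

#' Filter candidates to database-covered proteins
#'
#' Retains candidates whose source protein carries at least one mapped
#' class-I peptide in the database — the protein-presence filter that
#' sharpens affinity-ranked recovery.
#'
#' @param candidates Tibble with a `protein_id` column.
#' @param db A `peptidome_db`.
#' @return The retained rows, with attributes `n_total` and `n_retained`.
#' @export
protein_presence_filter <- function(candidates, db) {
  check_db(db)
  keep <- nr_matching_peptides(db, candidates$protein_id) > 0L
  out <- candidates[keep, ]
  message("protein presence filter: retained ", sum(keep), " of ",
          length(keep), " candidates")
  structure(out, n_total = length(keep), n_retained = sum(keep))
}

#' SVM-regression cross-validation of a feature set
#'
#' Evaluates how well a feature set prioritizes immunogenic candidates
#' with repeated half-split cross-validation. Per repeat, the control and
#' immunogenic lists are each split into random halves (an odd count sends
#' the extra candidate to training); a radial-basis-kernel SVM regressor
#' (cost 1, epsilon 0.1, gamma `1/n_features` — the backend defaults,
#' pinned) is trained on the training half with targets +1 (immunogenic)
#' and -1 (control); the held-out half is ranked by predicted value,
#' descending, and the number of immunogenic candidates among the `top_k`
#' highest-ranked is recorded. Features are standardized with
#' training-half mean and standard deviation (no leakage); the test half
#' is shuffled before ranking so that ties are resolved at random rather
#' than by table order. All splits are pre-generated from `seed`, so two
#' calls with the same seed — e.g. with and without MS features — share
#' their splits and are paired.
#'
#' @param candidates Tibble with feature columns and a logical
#'   `immunogenic` column; at least 2 candidates per group. Rows with
#'   missing feature values are dropped with a message. Candidates are
#'   canonically sorted internally, so results do not depend on input
#'   order.
#' @param features Character vector of feature column names (derived
#'   difference features are computed on the fly); a missing column is an
#'   error raised before any training.
#' @param n_repeats Number of random splits (default 2000).
#' @param top_k Size of the top-ranked window (default 20).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param standardize Standardize features by training-half statistics
#'   (default `TRUE`).
#' @return An object of class `cv_result` with `mean_top_k`, `sd_top_k`,
#'   the per-repeat counts and the run parameters.
#' @export
svm_cv_evaluate <- function(candidates, features, n_repeats = 2000,
                            top_k = 20, seed, standardize = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  candidates <- add_derived_features(tibble::as_tibble(candidates))
  missing_cols <- setdiff(features, names(candidates))
  if (length(missing_cols) > 0L) {
    stop(
      "feature column(s) missing: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  sort_cols <- intersect(
    c("candidate_id", "wt_peptide", "mut_peptide", "mutation_pos"),
    names(candidates)
  )
  if (length(sort_cols) > 0L) {
    candidates <- dplyr::arrange(
      candidates, dplyr::across(dplyr::all_of(sort_cols))
    )
  }
  X <- as.matrix(candidates[, features])
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X)
  if (any(!complete)) {
    message(sum(!complete), " candidate row(s) dropped: missing feature values")
    X <- X[complete, , drop = FALSE]
    candidates <- candidates[complete, ]
  }
  lab <- as.logical(candidates$immunogenic)
  imm_idx <- which(lab)
  ctl_idx <- which(!lab)
  if (length(imm_idx) < 2L || length(ctl_idx) < 2L) {
    stop("need at least 2 immunogenic and 2 control candidates",
         call. = FALSE)
  }
  # all randomness is consumed here, before any training, so paired runs
  # with the same seed see identical splits
  splits <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_repeats), function(i) {
      perm_i <- sample(imm_idx)
      perm_c <- sample(ctl_idx)
      n_train_i <- ceiling(length(perm_i) / 2)
      n_train_c <- ceiling(length(perm_c) / 2)
      train <- c(perm_i[seq_len(n_train_i)], perm_c[seq_len(n_train_c)])
      test <- sample(c(
        perm_i[-seq_len(n_train_i)], perm_c[-seq_len(n_train_c)]
      ))
      list(train = train, test = test)
    })
  })
  gamma <- 1 / length(features)
  counts <- purrr::map_int(splits, function(sp) {
    Xtr <- X[sp$train, , drop = FALSE]
    Xte <- X[sp$test, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2L, sd)
      sg[sg == 0 | is.na(sg)] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sg, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sg, "/")
    }
    y <- ifelse(lab[sp$train], 1, -1)
    fit <- e1071::svm(
      Xtr, y,
      type = "eps-regression", kernel = "radial",
      cost = 1, epsilon = 0.1, gamma = gamma, scale = FALSE
    )
    pred <- predict(fit, Xte)
    top <- head(order(-pred), top_k)
    sum(lab[sp$test][top])
  })
  structure(
    list(
      mean_top_k = mean(counts),
      sd_top_k = sd(counts),
      per_repeat = counts,
      n_repeats = n_repeats,
      top_k = top_k,
      seed = as.integer(seed),
      features = features,
      standardize = standardize,
      n_test = length(splits[[1L]]$test),
      n_immunogenic_test = length(imm_idx) - ceiling(length(imm_idx) / 2)
    ),
    class = "cv_result"
  )
}

#' Paired CV comparison with and without MS features
#'
#' Runs [svm_cv_evaluate()] on a base feature set and on the base set
#' augmented with MS features, using the same seed so both runs share
#' their splits, and reports the relative improvement.
#'
#' @param candidates Candidate tibble (see [svm_cv_evaluate()]).
#' @param base_features Character vector or a group id accepted by
#'   [feature_group()].
#' @param ms_features MS features to add.
#' @param ... Passed to [svm_cv_evaluate()] (`n_repeats`, `top_k`,
#'   `standardize`).
#' @param seed Integer seed shared by both runs.
#' @return A list with `base`, `augmented` (both `cv_result`) and
#'   `improvement_pct`.
#' @export
svm_cv_compare <- function(candidates, base_features, ms_features, seed, ...) {
  base_features <- feature_group(base_features)
  base <- svm_cv_evaluate(candidates, base_features, seed = seed, ...)
  augmented <- svm_cv_evaluate(
    candidates, unique(c(base_features, ms_features)), seed = seed, ...
  )
  list(
    base = base,
    augmented = augmented,
    improvement_pct = improvement(base, augmented)
  )
}

#' Relative improvement between two CV results
#'
#' `100 * (augmented - base) / base` on the mean top-k counts. Undefined
#' (`NA`) when the base mean is zero.
#'
#' @param base,augmented `cv_result` objects with the same `top_k`.
#' @return A percentage, or `NA`.
#' @export
improvement <- function(base, augmented) {
  stopifnot(inherits(base, "cv_result"), inherits(augmented, "cv_result"))
  if (base$top_k != augmented$top_k) {
    stop("cv results have different top_k", call. = FALSE)
  }
  if (base$mean_top_k == 0) {
    message("base mean_top_k is 0; improvement undefined")
    return(NA_real_)
  }
  100 * (augmented$mean_top_k - base$mean_top_k) / base$mean_top_k
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  cat("  features:  ", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  mean top-%d immunogenic: %.3f (sd %.3f) over %d repeats\n",
              x$top_k, x$mean_top_k, x$sd_top_k, x$n_repeats))
  cat("  seed:", x$seed, " standardized:", x$standardize, "\n")
  invisible(x)
}

#' Tidy a CV result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with one row per repeat (`repeat_id`,
#'   `n_immunogenic_top_k`).
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    repeat_id = seq_along(x$per_repeat),
    n_immunogenic_top_k = as.integer(x$per_repeat)
  )
}

#' Glance at a CV result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble of summary statistics and run parameters.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mean_top_k = x$mean_top_k,
    sd_top_k = x$sd_top_k,
    n_repeats = x$n_repeats,
    top_k = x$top_k,
    seed = x$seed,
    n_features = length(x$features),
    standardize = x$standardize
  )
}
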