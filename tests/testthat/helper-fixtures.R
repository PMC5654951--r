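# Shared in-code fixtures. Built once per test run.

# the 10-residue worked example used throughout: three class-I 5-mers
# tiling ACDEFGHIKL
toy_db <- function(extra_obs = NULL) {
  prot <- tibble::tibble(protein_id = "P1", sequence = "ACDEFGHIKL")
  obs <- tibble::tibble(
    sequence = c("ACDEF", "DEFGH", "GHIKL"),
    sample_id = "s1",
    hla_class = "I"
  )
  if (!is.null(extra_obs)) obs <- dplyr::bind_rows(obs, extra_obs)
  build_db(prot, obs)
}

# a small random database with known generation bookkeeping: peptides are
# random substrings (mapped) plus a few random sequences (mostly unmapped)
random_small_db <- function(seed, n_proteins = 6, n_peptides = 60) {
  withr::with_seed(seed, {
    proteome <- simulate_proteome(
      n_proteins = n_proteins, length_range = c(60, 150), seed = seed
    )
    draw_one <- function() {
      i <- sample.int(n_proteins, 1)
      l <- sample(8:15, 1)
      s <- sample.int(proteome$length[i] - l + 1, 1)
      substr(proteome$sequence[i], s, s + l - 1)
    }
    mapped <- replicate(n_peptides, draw_one())
    unmapped <- replicate(max(2, round(n_peptides * 0.05)), {
      paste(sample(c("W", "Y", "M", "H"), 9, replace = TRUE), collapse = "")
    })
    seqs <- c(mapped, unmapped)
    obs <- tibble::tibble(
      sequence = seqs,
      sample_id = sample(c("sA", "sB"), length(seqs), replace = TRUE),
      hla_class = sample(c("I", "II"), length(seqs), replace = TRUE,
                         prob = c(0.7, 0.3))
    )
    list(proteome = proteome, observations = obs,
         db = build_db(proteome, obs))
  })
}

# one moderately sized simulated study reused across test files
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- hlahotspots::simulate_study(424242)
    cache
  }
})

scored_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- hlahotspots::score_candidates(
        study_fixture()$db, study_fixture()$candidates
      )
    }
    cache
  }
})
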