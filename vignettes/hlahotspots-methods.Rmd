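---
title: "Presentation hotspots and MS-based neoantigen features: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presentation hotspots and MS-based neoantigen features: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlahotspots)
```

## The problem

HLA class I complexes present short peptides (mostly 9–11-mers) from
intracellular proteins to CD8+ T cells; class II complexes present longer
peptides (mostly 13–17-mers, centered on 15) from largely endosomal
sources to CD4+ T cells. Large immunopeptidomics compendia show two
regularities this package operationalizes: a small fraction of peptide
sequences (~3%) is eluted from both class I and class II complexes, and
detected peptides cluster in recurrent protein subsequences — hotspots —
rather than spreading uniformly. Because a hotspot aggregates evidence
across many donors and HLA allotypes, it estimates a protein region's
propensity to be processed and presented, information that binding-affinity
predictors do not carry. The package builds the database, computes the
profiles, and evaluates how much the database-derived features improve
ranking of candidate neoantigens.

## Database model

`build_db()` deduplicates observations to unique peptide sequences per
class and maps every sequence onto the proteome by exact substring search,
recording *all* placements. Key accounting rules:

* The deduplication unit is the unique sequence per class across all
  samples; per-sample observation lists are kept for group breakdowns
  (e.g. the long-peptide comparison) only.
* A peptide matching several proteins contributes to each of them.
  Razor-style single-protein assignment (most mapped peptides, ties by
  lexicographic identifier) is available via `razor = TRUE` for users who
  want MaxQuant-like protein inference.
* Isoleucine/leucine are distinct by default; `collapse_il = TRUE` merges
  them for matching, since MS cannot distinguish the isobaric pair.
  Reported coordinates always refer to the original sequences.
* Unmapped peptides (contaminants, variants) stay in the class sets — they
  affect class counts and exact-match membership — but never contribute to
  profiles or scores.
* Peptides shorter than 7 residues are rejected at load time as below any
  credible HLA ligand length.
* Modified peptide forms are not modeled; tables carry plain sequences.

The shared-peptide percentage uses the *sum* of the class counts as its
denominator, `100 * |I ∩ II| / (|I| + |II|)`, matching how the compiled
database's 3.4% figure is defined.

All coordinates in this package are 1-based inclusive, the natural R
convention; only bedGraph export converts to that format's 0-based
half-open intervals.

## Profiles and hotspots

A density profile counts, for each residue, the unique peptide placements
covering it. A sequence recurring at two positions of one protein counts
at both placements; `count_once_per_protein = TRUE` switches to
first-placement-only counting for users who prefer per-protein
multiplicity.

Hotspot boundaries have no canonical definition, so segmentation uses the
simplest rule consistent with "recurrently detected subsequence":
threshold-and-merge. The threshold is
`max(min_height, ceiling(min_frac_of_max * max(height)))` with defaults
`min_height = 2` (a single peptide is not recurrence), `min_frac_of_max =
0` and `merge_gap = 0`; all three are exposed. Profile similarity follows
the same philosophy: binarize each profile at half its own maximum
(`peak_frac = 0.5`) and take the Jaccard index of the masks — the overlap
of main peaks, ignoring minor ones.

The long-peptide statistic (fraction of unique class-I peptides of length
≥ 14 per sample, compared between samples with and without HLA-II
expression, the latter defined as fewer than 100 class-II peptides) probes
whether long class-I peptides are purification carry-over: comparable
proportions in both groups argue against it.

## MS-based candidate features

`matchScore_I` sums the class-I profile over the wild-type peptide's
placement and takes the maximum across placements (ties broken by protein
identifier and start for determinism). It is a raw sum, not
length-normalized; `normalize = TRUE` exposes the per-residue variant for
exploration. The score's profile includes the query itself when the query
is a database peptide — the database is treated as fixed; users running
leave-one-out experiments should account for this. `exactMatchScore_I`
gates the same value on class-I set membership, mirroring the `_I` suffix,
while the `exact` class of `classify_match()` accepts either class's
membership (a detected peptide is a detected peptide). `included` requires
a strictly longer detected superstring; `partial` requires a detected
placement covering the mutation position itself, not mere overlap.
Class-II variants of the scores are available via the `hla_class`
argument but are off by default, since candidate screens are class-I.

## The cross-validation harness

`svm_cv_evaluate()` reproduces the evaluation design: control and
immunogenic candidate lists are each split into random halves (odd counts
send the extra candidate to training, so a 16-candidate immunogenic list
yields exactly 8 test positives and the performance measure is bounded by
8); an epsilon-regression SVM with radial kernel is trained on targets +1
(immunogenic) and −1 (control); the held-out half is ranked by predicted
value and the immunogenic count among the top 20 recorded; the default is
2,000 repeats. Design choices worth stating explicitly:

* Hyperparameters are pinned at the backend defaults: `cost = 1`,
  `epsilon = 0.1`, `gamma = 1/n_features`, radial kernel. Any compliant
  re-implementation must report these.
* Features are standardized with training-half mean and standard
  deviation (never the full table — that would leak test information);
  `standardize = FALSE` disables it, and the result object records which
  mode was used. Zero-variance features are passed through unscaled.
* All split randomness is consumed up front from the user's seed, before
  any training. Two runs with the same seed therefore share their splits
  exactly, making with/without-MS comparisons paired by construction.
* The combined test half is shuffled once per repeat before ranking, so
  ties in predicted value resolve at random rather than by table order. A
  constant feature consequently ranks randomly and the top-20 immunogenic
  count follows the hypergeometric expectation — a calibration property
  the tests check. Candidates are canonically sorted internally, so
  results are invariant to input row order.
* Rows with missing feature values are dropped with a message; no
  imputation is attempted.

Feature groups follow the published design: group 1 is
{`mutAffinity`, `mutPeptideStability`, `rnaExpr`}; group 2 adds the
wild-type counterparts; group 3 adds the mutant-minus-wild-type
differences. `improvement()` reports the relative gain in mean top-20
count. The published absolute improvement percentages for these groups
depend on the original external screen table and the full compiled
database, neither of which ships here; the package's evaluation therefore
tests the *directional* property — adding MS features improves the mean
top-20 count on simulated screens with planted signal — rather than those
exact percentages.

## What the generator emulates — and what it does not

`simulate_proteome()`, `simulate_peptidome()` and `simulate_candidates()`
produce fully self-contained studies with truth manifests, sized so the
whole pipeline runs in seconds on one CPU:

* 50 proteins of 200–600 residues, i.i.d. uniform residue composition
  (overridable). Real proteomes have biased composition and repeats; none
  of the package's accounting depends on composition.
* Class-I peptide lengths over 8–14 with mass concentrated on 9–11 and
  P(length ≥ 14) = 0.05, matching the ~5% long-peptide proportions seen
  in real class-I eluates; class-II lengths 12–20 centered on 15.
* A shared fraction of 0.034 relative to the summed class counts, half
  re-emitted class-I sequences and half re-emitted class-II sequences, so
  the shared length distribution is bimodal like its real counterpart.
* Background peptides drawn uniformly at a fixed coverage density (~0.36×
  for class I; per-sample yields of 60/120 at the reference proteome
  size). In a fraction of proteins (30%) an interval of 40 residues is
  tiled with overlapping peptides until every residue is covered at least
  `hotspot_depth = 6` times. Because profiles count unique sequences, the
  interval's first residue can only be covered by distinct-length windows
  starting there, which caps attainable depth at the number of distinct
  class-I lengths minus one; 6 is the highest robust value. Planted
  recovery is checked by segmenting at the planted depth — the depth is
  guaranteed as minimum coverage, so the full interval is always detected
  while background almost never reaches it (`hotspot_recovery()`).
* Candidate tables default to the screen scale of 1,034 candidates with
  16 immunogenic. Match classes are planted (7 exact, 25 included, 34
  partial at that scale, scaled proportionally otherwise) and `none`
  candidates are drawn from zero-coverage windows, so positive match
  scores are confined to the planted classes (~66 positives at reference
  scale, mirroring the screen this emulates); 15.7% of candidates sit on
  decoy proteins absent from the database, reproducing the ~84% presence
  fraction. With planted signal, the immunogenic match composition is
  itself planted — 2 exact, 3 included, 4 partial and 7 unmatched at the
  16-label scale, the unmatched ones still on database-covered proteins —
  so the MS-feature signal exists in every realization rather than on
  average, and matched immunogenic candidates preferentially carry
  wild-type peptides from high-coverage (hotspot) regions; affinity
  shifts are log-scale toward strong binding (lower nM), with analogous
  shifts for stability, cleavage and expression. `effect_size = 0`
  yields a null table: uniform labels, no shifts.

The generator does not simulate spectra, identification error, HLA
binding motifs, allele-specific repertoires, tissue-specific expression,
or inter-sample correlation. Passing tests on this synthetic material
therefore demonstrate algorithmic correctness and calibration of the
package's accounting and evaluation machinery — not biological validity
of hotspot-based prioritization on any particular cohort.

## Numerical and degenerate-input choices

* Exact matching uses fixed-string search with overlapping self-matches
  reported; a naive positional scan serves as the test oracle.
* An all-zero profile yields no hotspots; an empty class set yields a
  shared percentage of 0; a Wilcoxon scan of a feature constant across
  all candidates reports p = 1 rather than erroring.
* An empty HLA-II expression group reports a missing mean, not an error.
* Candidate rows whose mutant/wild-type pair does not differ at exactly
  the stated mutation position are rejected row-wise with a report, and
  the remainder is processed.
* Sub-seeds for chained simulation stages are small fixed offsets from
  the master seed; every stochastic function requires an explicit seed
  and is byte-reproducible given one.

## Problem sizes used in the checks

The shipped tests run the oracle-equivalence sweep on 100 random
databases of 3–8 proteins and 30–86 peptides, the directional CV property
on 20 simulated screens at full 1,034-candidate scale with 200 repeats
per arm, harness calibration at 2,000 repeats, and the acceptance script
a 10-seed improvement fraction plus one 2,000-repeat paired comparison.
These sizes keep the full pipeline in the minutes range on a single CPU
while leaving the statistical conclusions stable across seeds.

## Known limitations

* Hotspot boundaries and the profile-similarity measure are pragmatic
  definitions; no ground-truth boundary concept exists to validate
  against.
* `matchScore_I` inherits the database's composition biases: proteins
  from well-sampled tissues accumulate higher profiles regardless of
  intrinsic presentability.
* The SVM harness evaluates ranking under the published design only; it
  is not a general immunogenicity predictor and performs no
  hyperparameter search.
* The razor option approximates, but does not reproduce, MaxQuant's
  razor-protein inference.
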