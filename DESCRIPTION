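Package: hlahotspots
Title: HLA Ligandome Hotspots and MS-Based Neoantigen Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a database of mass-spectrometry-observed HLA class I and
    class II peptides mapped exactly onto a proteome, computes per-residue
    presentation density profiles and antigen-presentation hotspots, derives
    MS-based neoantigen prioritization features (number of matching peptides
    per protein, profile-sum match scores and their exact-match gated
    variant), and evaluates neoantigen ranking with a support-vector-machine
    regression cross-validation harness. Includes a self-contained synthetic
    data generator emulating immunopeptidome length distributions, planted
    hotspots and candidate neoantigen tables, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
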