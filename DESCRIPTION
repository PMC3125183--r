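Package: cpgswarm
Title: CpG Island Prediction by Complementary Particle Swarm Search with
    Merge Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CpG islands in DNA sequences by running a particle
    swarm optimizer over windowed segments of the genome, encoding each
    candidate island as a (start, length) pair scored by GC content, CpG
    observed/expected ratio and length under the Gardiner-Garden and
    Frommer (or Takai-Jones) criteria.  A complementary (opposition-based)
    restart rescues stagnated swarms, and a reward-gated merge pass joins
    neighbouring islands separated by short gaps when the merged span still
    satisfies the criteria.  Includes per-nucleotide evaluation metrics
    (sensitivity, specificity, accuracy, performance and correlation
    coefficients), ROC sweeps, island summary reports (coverage, GC and
    O/E summaries, methylation density, TSS/promoter overlap), and a
    synthetic-sequence generator with planted islands for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
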