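Package: evoscales
Title: Comparing and Linking Micro- and Macroevolutionary Rates on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare rates of molecular and phenotypic evolution
    within and between species on time-calibrated phylogenies, and to predict
    species-level (macroevolutionary) rates from population-level
    (microevolutionary) parameters. Provides tree calibration, grafting of
    intraspecific trees into species phylogenies and random pairing of
    posterior tree distributions; maximum-likelihood branch-length estimation
    under JC and HKY substitution models with a Felsenstein pruning engine and
    rate estimation as branch-length ratios against dated trees; a
    haplotype-pruning procedure that predicts the species-level molecular rate
    from intraspecific data; a forward-time genetic-drift simulator of
    species-mean traits driven by intraspecific variance, effective population
    size and generation time, together with its Brownian-motion diffusion
    limit; ML fitting of Brownian-motion and Ornstein-Uhlenbeck trait models
    with AICc selection, prediction-probability and specificity tests, and a
    parametric-bootstrap power analysis; a McDonald-Kreitman test with
    codon-aware path counting and a genotype-depth association test; and a
    synthetic-data generator that emulates the full study design with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ggplot2,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
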