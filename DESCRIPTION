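Package: maccr
Title: Nucleosome Accessibility and Occupancy from MNase Titration Series
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates nucleosome accessibility from nucleosome occupancy in
    micrococcal nuclease (MNase) titration experiments. Fragment frequencies
    are binned per digestion level, library-normalized, and regressed across
    the titration series; the GC-corrected negative slope is the MACC
    accessibility score, while the titration-averaged frequency estimates
    occupancy. Includes fragment-level filtering (insert size, anomalous
    pileup positions), quantile-group scaling, gene-centric aggregation and
    rank-based comparisons, window Z-score enhancer calling and time-course
    classification from H3K27ac ChIP/input pairs, stable nucleosome position
    calling with positional-stability testing, a declarative pipeline runner,
    and a synthetic MNase digestion simulator that plants known occupancy,
    accessibility, enhancer and gene-class ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
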