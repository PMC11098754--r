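Package: clonetrace
Title: Whole-Tissue Lineage Tracing by DNA Barcoding: Simulation,
    Quantification and Optimal-Transport Comparison of Clone Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative clonal lineage tracing with genomic DNA
    barcodes in growing tissues such as cerebral organoids. Implements a
    stochastic model of clonal growth through symmetric divisions,
    symmetric-to-asymmetric transitions and asymmetric (neurogenic)
    divisions, simulated with a binomial tau-leaping scheme and validated
    against an exact stochastic simulation algorithm; a synthetic
    barcode-sequencing data generator (semi-random barcode libraries,
    multinomial read sampling, per-base substitution error, cross-sample
    contamination, chimeric two-genotype scenarios with chemical ablation);
    a barcode quantification pipeline (sample-index correction, directional
    Hamming-distance clustering of viral barcodes, cross-sample 20x
    contamination filtering, knee-point read thresholds, outlier-sample
    detection, reads-per-million normalization); summary statistics of
    lineage-size distributions (rank abundance, cumulative contribution,
    top-percentile shares, in-silico subsampling envelopes); and a
    one-dimensional optimal-transport framework for comparing lineage-size
    distributions between conditions via rank-wise mapping under an
    absolute log2 fold-change cost with lcm lineage weighting, LOWESS
    fold-change curves and fold-change densities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
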