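Package: ecoparallel
Title: Quantifying Parallel Ecotype Divergence Across Replicated Lake Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for quantifying parallel evolution across
    replicated sympatric ecotype pairs, as found in postglacial lake fishes.
    Provides allometric size correction of linear morphological traits,
    variance partitioning of parallel versus lake-specific divergence
    (partial eta-squared), phenotypic/genetic/expression trajectory analysis
    (divergence-vector lengths and angles with permutation tests),
    Weir-Cockerham Fst scans with empirical-quantile and permuted-panmixia
    outlier detection, resampling tests of outlier sharing, partial redundancy
    analysis for ecotype-associated loci and transcripts, co-expression module
    detection with module-trait correlations, cis-eQTL mapping, and Mantel and
    regression analyses linking divergence axes to ecosystem size. A synthetic
    study generator with planted ground truth supports calibration and
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
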