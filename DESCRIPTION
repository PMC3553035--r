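Package: gxe
Title: Genomic and Environmental Contributions to Bacterial Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative transcriptome toolkit for genome-reduced bacteria
    and their parent strains under normal and stress conditions. Provides
    chromosomal expression periodicity analysis (circular binning, moving
    average smoothing, Fourier periodograms with a chi-squared significance
    threshold, sinusoid fitting, and a random-deletion permutation null),
    rank-product differential expression with permutation-estimated false
    discovery proportions, preranked gene-set enrichment over regulon sets,
    one-tailed binomial category enrichment, scar-proximity and correlation
    statistics, and estimation of the epistasis coefficient relating additive
    and simultaneous transcriptional changes. Includes a synthetic-data
    generator with known ground truth for every stage and a config-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    withr
Config/testthat/edition: 3
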