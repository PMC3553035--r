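# gxe — genomic and environmental contributions to a bacterial transcriptome

Genome-reduced bacteria (a parent strain minus its dispensable segments —
insertion sequences, prophages, and the like) let one ask a clean question:
how much of transcriptome organisation is due to the genome itself, how
much to the environment, and what happens when both are perturbed at once?
`gxe` is an R toolkit for that comparative design: two strains (parent and
reduced), two conditions (normal growth and a stress such as heat shock),
replicated per-gene expression measured as log10 mRNA concentration
(log10 pM).

It provides, as tidyverse-style functions over tibbles:

* **Genome reconciliation** — classify every tagged parent gene as common,
  deleted, or mutated; derive deletion scars; compute circular
  gene-to-scar distances.
* **Chromosomal periodicity** — project expression onto 100-bp bins,
  smooth with a 50-kb circular moving average, compute the Fourier
  periodogram with a chi-squared (χ²₂) 95% significance threshold, fit the
  best sinusoid at the major peak, count chromosomal periods
  (`round(L / λ)`), and test whether a periodicity feature is specific to
  the real deletions via a random-deletion permutation null.
* **Rank-product differential expression** — per-gene rank product
  `RP_g = (∏_k r_{g,k})^{1/K}` over replicate-pair comparisons, with a
  permutation-estimated proportion of false positives (pfp) and separate
  up/down calls.
* **Enrichment** — preranked GSEA (running-sum ES, gene-set permutations,
  NES and FDR q) over regulon sets in GMT format, and one-tailed binomial
  enrichment of functional categories among DEGs.
* **Comparative statistics** — Wilcoxon–Mann–Whitney scar-distance tests,
  bootstrap comparison of subset-versus-universe Pearson correlations, and
  the per-gene changes ΔT_G (genome reduction), ΔT_E (environment), and
  ΔT_F (both at once).
* **Epistasis** — ordinary least squares of ΔT_F on ΔT_G + ΔT_E; with
  slope k the epistasis coefficient is α = k − 1, so α = 0 is additivity
  and α < 0 antagonistic (compressed) interaction, with a gene-bootstrap
  CI. Linear fold changes combine multiplicatively under additivity
  (`additive_prediction_fold(2.6, 30)` → 78).
* **A synthetic-data generator** (`synthetic_spec()`, `simulate_study()`)
  that emits every input format the readers consume, with ground truth for
  wavelength, spiked DEGs, and the planted α — plus `run_pipeline()`, a
  config-driven end-to-end runner.

Results come back as tibbles (or small S3 objects with `tidy()`,
`glance()`, and `autoplot()` methods), so everything chains with the pipe.

## Worked example

A full-scale synthetic study (4.64-Mb chromosome, 4406 genes, 40 deletion
segments, a 663-kb positional sinusoid, planted α = −0.29, small replicate
noise):

```r
library(gxe)
library(dplyr)

spec  <- synthetic_spec(sigma = 0.02, seed = 42)
study <- simulate_study(spec)
glance(study$comparison)
#>   n_parent n_common n_deleted n_mutated n_scars
#> 1     4406     3795       611         0      40

means   <- condition_means(study$expr)
profile <- condition_mean_vector(means, "parent", "normal") %>%
  bin_expression(study$parent) %>%
  smooth_profile(500)
pg <- periodogram(profile)
glance(pg)
#>   major_peak_wavelength major_peak_power major_peak_significant threshold
#> 1                663100           0.0232 TRUE                     0.00173
count_periods(attr(pg, "span"), attr(pg, "major_peak_wavelength"))
#> [1] 7

common <- filter(study$expr, locus_tag %in% study$comparison$common)
rp   <- rank_product(common, "parent:normal", "reduced:normal",
                     n_perm = 200, seed = 1)
degs <- call_degs(rp, 0.01)
count(degs, direction)
#>   direction     n
#> 1 down         50
#> 2 up           52

dt  <- delta_t(means)
fit <- estimate_alpha(dt$dt_genomic + dt$dt_environment,
                      dt$dt_simultaneous, n_boot = 500, seed = 2)
fit
#> <epistasis_fit> all common: n = 3795, slope k = 0.708,
#>   alpha = -0.292 [-0.294, -0.291] (90% CI), P = 0
```

Reading it: the 663-kb wavelength planted by the generator is recovered as
the major significant periodogram peak (663,100 bp, seven periods around
the chromosome); the rank product calls ~100 genes at pfp < 0.01, a mix of
the 50 spiked genes and background genes with genuinely large effects; and
the epistasis fit recovers the planted 29% compression of the simultaneous
response relative to the additive expectation, α̂ = −0.292.

`autoplot(pg)`, `autoplot(fit)`, and `autoplot(rp)` draw the periodogram
with its threshold, the additive-versus-simultaneous scatter with the
fitted slope, and a fold-change/pfp plot. For file-based runs,
`run_pipeline()` takes a YAML or list configuration naming the annotation,
expression, metadata, scar, and gene-set files and writes every stage's
TSV/JSON output plus a summary.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
defaults, and design choices in detail.

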