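---
title: "Methods: comparing genomic and environmental contributions to a bacterial transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing genomic and environmental contributions to a bacterial transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gxe analyses how two very different perturbations — engineered genome
reduction and an environmental stress such as heat shock — reorganize a
bacterial transcriptome, and how the two interact when applied together.
The package expects per-gene expression as log10 mRNA concentrations
(log10 pM) for two strains (a parent and a reduced-genome derivative) under
two conditions, with replicates. This vignette describes the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Genome reconciliation

The two strains are compared gene-by-gene on the parent's coordinate
system. Repeated locus tags in the parent annotation are resolved by
keeping the first occurrence in genome order; no biological rule selects
among repeats, so a deterministic positional rule is used and documented
rather than a heuristic. Each remaining parent gene is then *common*
(present in the reduced strain), *deleted* (absent), or *mutated*
(present but sequence-mismatched; the mutated list is an input, as
detecting mutations is an alignment problem outside this package's scope).
The three classes always partition the de-duplicated parent gene set. An
`oriC` record is excluded by default — the origin is a locus, not a gene —
with a flag to keep it.

Deletion scars are taken from a supplied segment table when available;
otherwise they are derived by merging runs of consecutive deleted genes.
Gene-to-scar distances are circular (both traversal directions around the
chromosome, never exceeding half the genome length) and are measured
between the nearer gene boundary and the nearer scar boundary; a gene
overlapping or touching a scar is at distance zero. Midpoint-based
distances differ by at most half a gene length and would not change the
rank-based tests downstream.

## Chromosomal periodicity

Expression is projected onto the chromosome in 100-bp bins: each gene's
value is assigned to every bin its coordinates overlap, bins covered by
several genes average their contributors, and uncovered bins are filled
with the genome-wide mean expression. Filling gaps with the mean (rather
than zero) avoids injecting step artefacts that would leak power into low
frequencies. The binned series is treated as circular throughout — binning,
smoothing, and the Fourier transform — because the chromosome is circular;
genes recorded with `start > end` wrap the origin and are split into two
arcs internally.

The profile is smoothed with a centred circular moving average of 500 bins
(50 kb; an even window is widened by one bin so it is symmetric). Smoothing
preserves the profile mean exactly and suppresses wavelengths comparable to
the window, which motivates the default analysis band of 100 kb up to half
the chromosome: below 100 kb the moving average has removed most signal,
above half the chromosome a "period" is indistinguishable from trend. The
periodogram is the discrete Fourier power spectrum of the mean-subtracted
series, scaled so that total power over positive frequencies equals the
series variance (a pure sinusoid of amplitude A contributes A²/2 at its
frequency). On a 4.64-Mb chromosome the band contains the wavelengths of
interest: the seventh harmonic is ~663 kb and the sixth ~774 kb, so a shift
between seven and six chromosomal periods is a shift between adjacent
Fourier frequencies.

Significance uses a chi-squared null: under white noise each periodogram
ordinate is exponentially distributed (chi-squared with 2 d.f. after
scaling), so the per-frequency threshold at confidence c is
`-mean(power) * log(1 - c)` with the mean taken over in-band ordinates.
No multiplicity correction is applied across frequencies — the threshold is
a per-ordinate confidence line of the kind drawn across a periodogram, and
the calibration tests confirm ~5% of white-noise ordinates exceed it. The
best-fitting sinusoid at a fixed wavelength is obtained by ordinary least
squares in the sine/cosine basis, which is exact (no iterative
optimisation, no starting values).

The period count is `round(genome_length / wavelength)`; it depends only on
the major peak's wavelength, not on amplitude or phase.

## The random-deletion null

To ask whether a periodicity feature of the reduced genome is specific to
the actual deletions, segments of the same lengths are placed uniformly at
random without overlap; genes they cover are dropped, coordinates are
compacted (deleted regions removed, not masked — the reduced chromosome is
a shorter circle, not a gapped one), and the profile, smoothing, and
periodogram are rebuilt. The default statistic is whether a placement
reproduces the observed period count of the major peak, and the empirical
P-value uses the add-one estimator so it is never exactly zero.

Two properties of this null are worth knowing. First, many small scattered
deletions of a fixed total length act on the signal like a near-uniform
compression of the chromosome: the parent's period count survives, while a
spatially concentrated excision of one full wavelength removes a period.
The period-count statistic therefore measures *placement*, which is exactly
the question. Second, with only a handful of large segments, chance
in-phase alignment of random placements blurs the distinction; a
phase-coherence statistic (`"peak_power"`, the major peak's power) is
available as an alternative. When no peak clears the significance
threshold the test falls back to the unrestricted in-band maximum and says
so in a message.

## Rank-product differential expression

Differential expression between two condition cells uses the rank product:
genes are ranked by the replicate difference within each of K replicate-pair
comparisons (average ranks on ties), separately for up- and downregulation
(two one-sided analyses, so each gene carries an up and a down statistic),
and the rank product is the geometric mean of a gene's ranks. The null is
Breitling-style: each permutation redraws every comparison's ranks uniformly
at random; the proportion of false positives (pfp) of a gene is the expected
count of null rank products at least as extreme divided by the gene's rank
position, made monotone along the ranking by a running maximum.

The default pairing is *disjoint*: replicate i of one condition is compared
with replicate i of the other, K = min(nA, nB). The classic layout using
all nA x nB cross-pairs is available (`pairing = "cross"`) and uses every
replicate of an unbalanced design, but its comparisons share replicates and
are therefore dependent, while the rank-redraw null assumes independence;
in null simulations (1000 genes, 3 vs 3, noise s.d. 0.1 log10) the
cross-pair layout called ~6% of genes at pfp < 0.05 where disjoint pairing
called almost none. Calibration was judged more important than squeezing
information out of extra replicates, hence the default. With the package's
defaults, spiked effects of 0.5 log10 against 0.1 replicate noise are
recovered with recall above 0.9 at pfp < 0.05.

A gene passing both directions at a cutoff keeps the smaller-pfp direction
(logged); lowering the cutoff never adds genes.

## Gene-set and category enrichment

Regulon enrichment is preranked GSEA: genes are ordered by the signed
difference of condition means (signed, not absolute, so a set's enrichment
direction — increased or decreased — is meaningful), and the classic
running sum rises by |score|^w (w = 1 by default) at set members and falls
uniformly otherwise; the enrichment score is the maximum deviation from
zero. Because the input is a single ranked list, significance uses gene-set
permutations: random sets of the same size drawn from the universe. The
normalized score divides by the mean absolute null score of matching sign,
and FDR q compares each score with the pooled null, as in the original
GSEA procedure. Sets smaller than 15 genes after restriction to the
analysis universe are skipped: smaller regulons make the running-sum
statistic unstable, and 15 matches the smallest regulon reported in the
kind of study this package targets.

Functional-category enrichment among DEGs is a one-tailed binomial test
per category and direction: with n DEGs of a direction and a category
occupying fraction p0 of the universe, P = P(X >= x), X ~ Binomial(n, p0).
With x = 0 the tail probability is 1 by definition. P-values are reported
raw; with 23 categories by 3 directions a reader can apply their preferred
multiplicity correction, and the package does not hide the choice.

## Scar distances, correlations, and epistasis

Scar-proximity contrasts (for instance DEGs versus genes of conserved
expression) use the Wilcoxon–Mann–Whitney rank-sum test on circular
distances: exact enumeration when both groups have at most 20 tie-free
values, the normal approximation with tie correction otherwise, two-sided
by default with a one-sided option. Correlation contrasts (a subset's
Pearson correlation across two conditions against the universe's) are
assessed by a gene bootstrap — resampling genes within subset and universe
and recomputing the difference of correlations — because no closed-form
test covers a subset nested in its reference set; 1000 resamples by
default.

The per-gene changes are defined on the common gene set, in log10 units:
the genomic contribution (reduced minus parent, normal condition), the
environmental contribution (parent heat shock minus parent normal), and the
simultaneous contribution (reduced heat shock minus parent normal). The
epistasis coefficient comes from ordinary least squares of the simultaneous
change on the additive expectation (the sum of the two separate changes):
with slope k, alpha = k - 1. Under this convention alpha = 0 is exact
additivity and alpha < 0 means the simultaneous response is compressed —
antagonistic epistasis; a ~30% suppression corresponds to alpha near
-0.3. The convention is chosen so that the sign agrees with the
"suppressive" reading of a slope below one; reports print both k and
alpha so no reader needs to guess the axis convention. The intercept is
fitted rather than forced through zero — a global offset between conditions
should not masquerade as epistasis. Uncertainty is a gene bootstrap
(percentile interval, default 90%) with a two-sided bootstrap P for
alpha != 0. Alpha is invariant to adding a constant to all condition means.

Because the additive predictor is itself estimated from replicate means,
measurement noise in the predictor attenuates the slope (classical
errors-in-variables). With replicate noise s.d. 0.1 and three replicates
the attenuation is a few percent of the slope; recovery experiments that
target the coefficient itself therefore use small replicate noise (0.02),
and analyses of real designs should note that a strongly noisy predictor
biases alpha downward in magnitude toward -0 and upward in magnitude of
compression. This is a limitation of the regression definition, not of the
implementation.

## The synthetic-data generator

The generator is first-class, tested code that produces every input the
pipeline consumes, with ground truth for every stage. Its defaults mirror
a genome-reduced *E. coli* study: a 4,641,652-bp circular chromosome,
4406 tagged genes tiled evenly (~900 bp each), 40 deletion segments with
log-normal lengths (median 15 kb, totalling ~0.7 Mb), a positional
sinusoid of wavelength one seventh of the chromosome (~663 kb) and
amplitude 0.2 log10 with uniformly drawn phase, baseline expression
1.0 ± 0.5 log10 pM between genes, per-gene genomic and environmental
effects drawn bivariate normal (s.d. 0.2 log10, correlation 0.6 — the two
contributions are positively correlated in this kind of data), 50 spiked
DEGs per perturbation at ±0.5 log10, an epistasis coefficient of -0.29
(optionally stronger on the spiked genes, to plant the
subset-versus-global contrast), replicate noise 0.1 log10, and three
replicates per condition. The simultaneous condition's mean is
`baseline + (1 + alpha) * (genomic + environmental effect)` per gene, so
the planted coefficient is exactly the quantity the epistasis fit
estimates. Everything is deterministic given the spec's seed.

What the generator does not emulate: probe-level microarray signal and
hybridization noise (expression is drawn directly on the log
concentration scale), operon and regulatory correlation structure between
neighbouring genes (effects are independent across genes apart from the
planted sinusoid), non-sinusoidal or multi-scale positional trends, and
condition-dependent variance. Passing the recovery tests therefore shows
the estimators are correct and calibrated under clean generative
conditions — it does not show that real microarray data satisfy those
conditions.

## Problem sizes and numerical choices in the test suite

The unit suite runs mostly on toy problems (tens to hundreds of genes,
sub-megabase chromosomes) where every statistic can be compared against an
independent oracle: per-base bookkeeping for binning, naive windowed sums
for smoothing, Parseval's identity for the spectrum, grid search for the
sinusoid fit, hand-computed geometric means for rank products, a hand
running sum (and an independent library implementation) for the enrichment
score, direct tail summation for the binomial, and full enumeration for
the rank-sum test. The study-scale checks use 20 seeded replicates for
wavelength recovery on the full 4.64-Mb genome, 1000 white-noise trials
for threshold calibration, 999 permutations for the deletion null (with
the planted excision split into 12 segments, where the period-count
statistic separates cleanly), 20 seeds by 1000 genes for rank-product
calibration and recall, and two full-scale generations for epistasis
recovery. These sizes were chosen so each property is measured with
comfortable margin at desk scale.

## Known limitations

* The pfp of the rank product is an expected-false-positive ratio, not a
  p-value; its calibration is exact only under the disjoint pairing.
* The GSEA FDR q is noisy when few sets are tested, as with any pooled
  permutation FDR.
* The random-deletion null assumes deletion segments could have fallen
  anywhere uniformly; real deletion placement is constrained by essential
  genes, which the test (and the generator) ignores.
* The epistasis regression treats genes as independent observations; genes
  in one operon share their response, so bootstrap intervals are somewhat
  narrow for real data.
* The peak-shift question (whether two periodograms' major peaks differ
  significantly) is deliberately not answered; the package provides the
  permutation machinery for deletion specificity only.
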