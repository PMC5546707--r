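---
title: "Methods: tissue-specific functional annotation and downstream GWAS analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific functional annotation and downstream GWAS analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `epifunc`, the conventions
and numerical choices behind them, what the synthetic-data generators do and
do not emulate, and the package's known limitations. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The annotation mixture model

For one tissue or cell type, the input is a fixed-order vector of ten binary
annotations per nucleotide: H3K4me1, H3K4me3, H3K36me3, H3K27me3, H3K9me3,
H3K27ac, H3K9ac, DNase I hypersensitivity, unmethylated CpG island, and
expressed RNA (see `annotation_names()`). The generative model is a
two-class latent mixture: a functionality indicator $Z \sim
\mathrm{Bernoulli}(\pi)$, and, conditionally on $Z = c$, independent
annotations $A_i \sim \mathrm{Bernoulli}(p_{ic})$. The conditional
independence given $Z$ is the model's central assumption; it is what lets
ten marginally correlated marks be combined without modeling their joint
distribution. The per-base score is the posterior $P(Z = 1 \mid A)$,
a number in $(0,1)$ that is piecewise constant wherever the annotation
pattern is constant.

The free parameters are $\pi$ and the $10 \times 2$ matrix $p_{ic}$ — 21 per
tissue track. `fit_functional_mixture()` estimates them by EM:

* **Observations.** Every base of the training regions is one observation.
  Identical annotation patterns are aggregated with base-pair counts before
  EM; this is an exact reformulation of the likelihood (there are at most
  $2^{10}$ distinct patterns), so EM cost is independent of genome size.
  Training regions themselves are built by `build_training_regions()` as
  1-kb intervals centered on index-SNP positions ($[\mathrm{bp}-500,
  \mathrm{bp}+500)$; the centering is our choice — only the total width is
  canonical) with overlaps merged and duplicates dropped.
* **Initialization.** $\pi_0 = 0.5$; $p_{i1}$ starts at the annotation
  frequency among pattern-positive observations and $p_{i0}$ at half the
  overall frequency (floored at 0.01), both with a seeded $\pm 10\%$
  jitter. The seed is recorded in the fit.
* **Convergence.** Relative log-likelihood change below `tol` (default
  `1e-6`) or 1000 iterations; hitting the cap warns but does not error. The
  log-likelihood is monotone by construction and asserted in tests.
* **Clamping.** Probabilities are confined to $[10^{-6}, 1-10^{-6}]$ with a
  warning when a boundary is hit, so posteriors never degenerate to 0/1.
* **Label switching.** A two-class mixture is identified only up to label
  permutation. After convergence, classes are relabeled so that the summed
  log odds ratios of H3K4me3, H3K9ac and DNase — the marks that should
  positively predict activity — are positive. Repressive marks (H3K9me3,
  H3K27me3) may legitimately show odds ratios below 1 under this labeling.

`posterior_score()` is plain Bayes arithmetic in log space; tests verify it
against an independently coded brute-force oracle on all 1,024 patterns to
$10^{-12}$. `score_genome()` applies it genome-wide by run-length encoding
the combined pattern id, computing each distinct pattern once.

## Track conventions

* **Coordinates.** Intervals are half-open 0-based at BED-style data-frame
  and file interfaces, converted to the 1-based closed convention of
  `GRanges` internally. All tracks are strandless.
* **Binarization rules.** Peaks pass at signal p-value $< 0.01$ (strict);
  CpG islands count as unmethylated at fraction $< 0.5$ (strict); RNA bins
  pass at rpkm $\ge 0.5$ on a 25-bp grid.
* **Ties at a dichotomization cutoff** go to the functional class
  (score $\ge$ cutoff) everywhere — `dichotomize()`,
  `functional_proportion()`, `quantile_binarize()`. One global convention
  avoids the inconsistency of mixing strict and non-strict comparisons
  across modules.
* **Smoothing.** `smooth_windows()` tiles each chromosome from position 1
  into fixed windows (default 10 kb, the smoothing used for the
  general-functionality tier); the last partial window is averaged over its
  actual length, which makes the genome-wide mean exactly invariant.
* **Multi-donor samples** are averaged per base (`combine_tracks(...,
  "mean")`) *before* any dichotomization; tissue clusters are unions of
  binary tracks.
* **Quantile dichotomization** uses the nearest-rank order statistic (no
  interpolation) of the scores at reference SNP positions; a degenerate
  all-equal reference set warns.

## Tissue specificity and element validation

`compute_tsi()` row-normalizes by the row *maximum* (not the sum) and
averages $1 - x$ over the remaining $N - 1$ tissues, so one-hot rows score
exactly 1 and uniform rows exactly 0; all-zero rows are an error, not a 0/0.
Element selection uses a strict threshold (default 0.75) and labels each
element by its maximally expressed tissue, breaking ties deterministically
toward the lowest-index tissue. `validate_elements()` is a thin matrix
wrapper over `functional_proportion()` — deliberately the same code path, so
validation numbers are definitionally consistent with the track algebra.

## Stratified heritability

`compute_ld_scores()` computes $\ell(j,c) = \sum_{k \in c,\ |cM_j - cM_k|
\le 1} \tilde r^2_{jk}$ with the small-sample adjustment $\tilde r^2 = r^2 -
(1-r^2)/(n-2)$. The adjustment makes an isolated SNP's base score exactly 1
and independent SNPs contribute zero in expectation; its price is that
individual adjusted terms can be negative, so the identity
$\ell(\mathrm{base}) \ge \ell(c)$ holds only up to an analytic slack of
(window SNP count)$/(n-2)$, which is how the tests phrase it.

`fit_stratified_regression()` is a deliberately lean single-pass
reimplementation of the stratified regression idea: weighted least squares
of $\chi^2_j$ on $N\,\ell(j,c)$ with a free intercept and fixed weights
$1/\max(\ell(j,\mathrm{base}), 1)$. The reference implementation iterates
its heteroskedasticity weights; we do not, trading a little efficiency for a
closed-form estimator that is easy to reason about and test (a noiseless
linear system is recovered to machine precision). SNPs with $\chi^2 > 80$
are excluded (configurable), mirroring standard quality control for
outlying effects. Uncertainty comes from a delete-one-block jackknife over
200 contiguous SNP blocks.

`enrichment()` attributes per-SNP heritability additively, $h^2_j = \sum_c
\tau_c a_{cj}$ — the natural convention for overlapping categories, adopted
explicitly because attribution is not uniquely defined — floors negative
values at zero before forming shares (negative per-SNP variances are
meaningless; the count floored is recorded), and reports
$\mathrm{enrichment} = \%h^2 / \%\mathrm{SNPs}$ with jackknife SE and a
two-sided normal p-value on $(\mathrm{enrichment}-1)/\mathrm{SE}$. The base
category has enrichment 1 by construction. With real annotation inputs a
full baseline model can be supplied simply as extra annotation columns; the
synthetic tests reduce the baseline to the base category.

On our synthetic fixtures the regression intercept sits above 1. That is
expected, not a defect: the simulated z-scores carry the *sample* LD of the
finite panel, whose $r^2$ exceeds adjusted $\tilde r^2$ by roughly
$m_{\mathrm{win}}/(n-2)$ in aggregate, and the free intercept absorbs
exactly this kind of bias — which is why it is free.

## The pleiotropy window test

`label_windows()` implements the two-condition labeling (a sub-threshold
SNP in the window, at least one of them inside the functional annotation)
over non-overlapping windows anchored at position 1 of each retained
chromosome (default 1 Mb; the last partial window is kept if it holds a
SNP; sex chromosomes and SNP-free windows are dropped). The hypergeometric
test takes all retained windows as the population — one reading of an
under-specified design, recorded as such and cross-checked by the
permutation test.

The permutation test shuffles the per-SNP annotation-membership indicator,
preserving the total annotated proportion and all per-window SNP counts,
and recomputes only condition 2. Association signals are never permuted, so
confounding shared by both studies (overlapping controls) inflates observed
and null counts alike. The add-one estimator $(1 + \#\{null \ge obs\}) /
(n_{perm}+1)$ never returns zero.

Two subtleties surfaced in testing and shaped the fixtures:

* The shuffle's null is *exchangeable SNP-level membership*. Annotations
  that come in contiguous blocks are a lumpier distribution than their
  shuffles; by Jensen's inequality the observed joint count then sits
  stochastically below the permutation null, i.e. the test is conservative
  for clumped annotations — the safe direction. Calibration fixtures
  therefore scatter membership i.i.d. (the exchangeable case), while power
  fixtures keep realistic blocks.
* The joint count is a small integer; a fixture with expected count near
  zero pins the p-value at 1 and cannot display a uniform null. The
  calibration fixture uses total heritability 0.4, 30% coverage and ~100
  windows so the count statistic has resolution. These are analytic
  requirements of the check, fixed once in the test code.

## SNP reprioritization

`genowap()` implements the three-case posterior: case 1 (tissue-functional
and trait-relevant) has $p \sim \mathrm{Beta}(\alpha, 1)$ with $\alpha \in
(0,1)$; case 2 (tissue-functional, trait-irrelevant) shares the p-value
distribution of generally non-functional SNPs; case 3 (not
tissue-functional) follows the low-tissue-score null. Priors come from the
fraction of SNPs at score $\ge 0.1$ (the partition threshold; results are
insensitive to it within reason, and both groups must be non-empty). Null
densities are 500-bin equal-width histograms floored at $10^{-8}$ and
renormalized, coarsened with a warning below 10 observations per bin. The
per-SNP tissue score is the annotation score at the SNP base and the general
score is conventionally a 10-kb-smoothed track; both are configurable by
passing per-SNP numeric vectors.

The signal mixture EM has the closed-form M-step $\alpha = -\sum w_j / \sum
w_j \log p_j$, projected into $[10^{-4}, 1-10^{-4}]$. One genuine
identifiability issue deserves record: as $\alpha \to 1$ the Beta component
becomes uniform and the likelihood goes flat in $w$, so under a no-signal
dataset EM stalls at an arbitrary weight whose likelihood gain over the
$w=0$ model is at the noise level of two free parameters. The fit therefore
applies a model-selection guard: if the mixture beats the $w=0$ model by
fewer than `lrt_min = 2` log-likelihood units (the AIC cost of its two
extra parameters), the no-signal fit $w = 0$ is reported and flagged. Real
signal clears this margin by orders of magnitude. Relatedly, when the null
density is itself a noisy histogram from a finite sample, a flat component
strictly improves fit on fresh data and biases $w$ upward for *any*
implementation of this model; tests that check $w$-recovery against planted
truth therefore supply the exact uniform null, while pipeline tests use the
estimated histograms.

For late-onset Alzheimer's-style analyses the APOE region
(chr19:45,147,340–45,594,595, hg19) is excluded before fitting via
`apoe_mask()`; the MHC (chr6:28,477,797–33,448,354, standard hg19 extended
boundaries, as the exact interval is conventional) is excluded from
heritability analyses via `mhc_mask()`. Both are configuration, not
hard-coded behavior.

## Meta-analysis z-score algebra

`meta_z()` is the sample-size-weighted combination $(z_1\sqrt{n_1} +
z_2\sqrt{n_2})/\sqrt{n_1+n_2}$; `infer_stage2_z()` is its exact algebraic
inverse, recovering replication-stage z-scores from discovery and combined
statistics. Note the model's own consequence: combining two studies that
both show $z$ yields *more* than $z$ — evidence accumulates. The pair is
tested as an exact round trip to $10^{-12}$.

## Synthetic data: what is and is not emulated

* `gen_annotation_tracks()` draws segments (default 10 bp over 1 Mb)
  i.i.d. from the mixture's own generative process, with planted defaults
  $\pi = 0.1$, $p_{i1} = 0.8$, $p_{i0} = 0.05$ — a sparse functional genome
  with strongly informative marks. Real annotation tracks have long-range
  autocorrelation and mark-specific frequencies; parameter-recovery results
  on these fixtures speak to the estimator, not to reference-epigenome-scale
  data.
* `gen_gwas_pair()` defaults to the heritability study scale: a 500-
  individual panel, 20,000 SNPs (20 chromosomes × 1,000 at 1-kb spacing),
  GWAS $N = 50{,}000$, total $h^2 = 0.5$, a "functional" category covering
  10% of SNPs at 5-fold enrichment. LD is first-order haplotype copying
  with copy probability $\sqrt{0.5}$, targeting adjacent-SNP $r^2 \approx
  0.5$ with geometric decay — sufficient for LD-score behavior, not a model
  of human haplotype structure (no recombination hotspots, no MAF/LD
  coupling, no population structure). Genetic positions are linear at
  1 cM/Mb. Marginal z-scores are drawn as $z = \sqrt{N} R\beta +
  \varepsilon$, $\varepsilon \sim N(0, R)$ with $R$ the panel LD realized
  through $X^\top u / \sqrt{n}$, so the stratified-regression expectation
  holds by construction and panel reuse across replicate traits
  (`panel_from`) mirrors how a fixed reference panel serves many GWAS.
* `gen_expression()` plants exactly one-hot rows (TSI = 1) among
  near-uniform noise rows and pairs each tissue with a binary track
  covering 80% of its own specific elements versus a 10% background
  sprinkle.
* Every generator is deterministic given its seed and can write its planted
  truth as a JSON sidecar next to the standard-format outputs; tests read
  planted truth only from the generators.

Problem sizes in the tests (1-Mb toy genomes, 100 windows, 20–50 replicate
traits, 199–499 permutations) are the package's chosen desk scale: large
enough that binomial noise sits well inside the asserted tolerances, small
enough to iterate on.

## Known limitations

* No continuous-emission or multi-class (>2 latent states) mixture; the
  model is faithful to the binary two-class design.
* The stratified regression has no constrained-intercept mode and no
  genetic-correlation machinery; it is not a drop-in replacement for the
  reference LD-score implementation on real data.
* The hypergeometric parameterization of window overlap is one reading of
  an under-specified test; the permutation test is the primary instrument.
* BigWig output, assembly liftover and peak calling are out of scope; text
  formats (BED, bedGraph, narrowPeak, tab-delimited tables, optionally
  gzipped) are the interchange surface.
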