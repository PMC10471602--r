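---
title: "Quantifying and classifying gene expression variability in reciprocal crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying gene expression variability in reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`canalex` analyses replicated RNA-seq count matrices from a two-morph
reciprocal-cross design: pure crosses PL×PL and SB×SB, reciprocal hybrids
PL×SB and SB×PL (maternal morph written first), each sampled at two
developmental time points with nine embryos (three families × three
embryos). The analysis group used throughout is the cross-type ×
time-point combination — eight groups — with families recorded in the
metadata but pooled, since the variability statistic needs all replicates
of a group on one footing.

This vignette explains the statistical machinery, the defaults and why
they are what they are, what the synthetic-data generator does and does
not emulate, and the numerical decisions a maintainer should know about.

## The LCV statistic

Expression variance rises and falls with expression level, so a raw CV
comparison between genes (or between groups whose expression shifted)
conflates level with noise. The Local Coefficient of Variation controls
for level by ranking locally: per group, genes are ordered by mean
normalized expression; for each focal gene, the window of `window_size`
genes centred on its rank is taken, and the focal CV's rank among the
window CVs is converted to the percentile

\[ \mathrm{LCV} = 100\,(r - 1)/(w - 1), \]

so 0 and 100 are attained exactly by the window minimum and maximum.

Numerical decisions:

- **Normalization** precedes CV: median-of-ratios size factors (the
  standard count-normalization family for DE analysis), falling back to
  library-size scaling when no gene is observed in every sample. CV on
  raw counts would conflate sequencing depth with biological variability.
- **Window edges are clamped**, not shrunk: the first and last
  `window_size` genes share the end windows, so every percentile is
  computed against exactly `w` competitors. A window is only shrunk (with
  a warning) when a group has fewer defined genes than `w`.
- **Ties**: equal mean expression is ordered by gene id for determinism;
  equal CVs share their mean rank, so duplicated genes always get equal
  scores. The exact percentile/tie convention of sliding-window CV
  ranking varies between implementations; this one is chosen to achieve
  the documented 0–100 endpoints and is locked in by an exhaustive
  brute-force oracle in the test suite.
- **Zero-mean genes** have no CV in that group; they are excluded from
  the group's ordering and reported `NA`.
- `window_size` defaults to **500 genes** — the production choice for
  transcriptome-scale matrices. For the few-thousand-gene simulations in
  the tests the same code is exercised at windows 50–500; the statistic
  only requires `w` to be large enough for a stable local CV distribution
  and small enough that the mean–variance trend is locally flat.

## Clustering variability profiles

Gene LCV profiles (rows = genes, columns = the 8 groups) are clustered
with Lloyd's k-means under Euclidean distance, k-means++ seeding and 10
restarts, keeping the best objective. Profiles are *not* row-standardized:
LCV is already a bounded, unitless 0–100 scale and standardizing would
erase overall-variability differences between clusters, which are part of
the phenotype. Labels are renumbered by descending cluster mean LCV so a
seed fully determines the output. `k` defaults to 10, with
`silhouette_scan()` always available to verify the choice (maximum mean
silhouette width; ties resolved to the smallest k; a degenerate fit
reports `NA` rather than failing).

For heatmap export, columns are ordered by average-linkage hierarchical
clustering of the group profiles and serialized as Newick. Average
linkage + Euclidean is the common heatmap default; the choice is recorded
in the run manifest because tip pairings (notably whether hybrids pair
with their maternal pure cross) are a headline readout.

## Per-cluster Bayesian inference

Each cluster's LCV scores are modelled as a one-way layout,
\(y_i = \mu_{g(i)} + \varepsilon_i\),
\(\varepsilon_i \sim N(0, \sigma^2)\), with conjugate priors: flat-ish
normal priors on the group means (variance 10^10) and
\(\sigma^2 \sim \mathrm{IG}(\nu/2, \nu V/2)\) with the weakly informative
V = 1, ν = 0.002. A Gibbs sampler alternates the two conjugate
full-conditionals; defaults are 13,000 iterations, thinning 10, burn-in
3,000, i.e. exactly 1,000 retained draws. For small datasets where the
retained-draw lag-1 autocorrelation exceeds 0.1 the summary warns and
recommends the long settings (130,000 / 1,000 / 3,000). In practice the
conjugate sampler for this model mixes essentially instantly; the gate is
kept because the convention of checking it is cheap and the settings are
user-configurable.

Summaries follow the posterior-mode-plus-HPD convention: the mode is the
argmax of a Gaussian KDE (Silverman bandwidth, 512-point grid over the
draw range), and the 95% credible interval is the *shortest* interval
containing ⌈0.95 n⌉ sorted draws (exhaustive sliding-window search over
order statistics — verified in tests against an independent
implementation). Two groups are called distinguishable when their HPD
intervals are disjoint; touching endpoints count as overlap, a
deliberately conservative closed-interval rule.

The model is fixed-effects only. Families are pooled (consistent with the
pooling used for LCV estimation); by default the response stacks both
time points and uses cross-type as the group factor, with a
`by = "group"` mode for per-time-point runs — the choice is exposed
because either convention is defensible.

## Inheritance classification

One deterministic rule cascade serves both levels, consuming (i)
pairwise distinguishability flags for all six cross-type pairs and (ii) a
per-cross-type location estimate (fitted mean or posterior mode):

1. over-/underdominant (mean level) or transgressive (variability level:
   a hybrid interval disjoint from and outside the span of both pure
   crosses, either direction);
2. maternal — each hybrid indistinguishable from its maternal pure cross
   and distinct from the other, pure crosses distinct;
3. PL-/SB-biased — both hybrids track one pure cross;
4. intermediate — hybrids distinct from both pures with estimates
   *strictly between* them (strict betweenness, the stricter of the two
   defensible readings);
5. conserved — no distinguishable pair at all; otherwise ambiguous.

The cascade is proven exhaustive and mutually exclusive by enumerating
all 2^6 flag configurations in the tests, and is equivariant under
relabelling the morphs (PL↔SB maps PL-biased to SB-biased and fixes the
symmetric patterns).

Mean-expression calls are gene-level, built on the six NB Wald contrasts
at one time point; variability calls are cluster-level, built on HPD
overlaps. An `AMBIGUOUS` call is a first-class outcome, not an error —
with narrow intervals (large clusters) small compositional differences
become distinguishable and the cascade refuses to force a pattern.

## Differential expression

The DE layer is a deliberately simplified NB GLM: per-gene log-link fit
with group (+ optional batch) design, log size-factor offsets, and a
gene-wise dispersion held fixed at a method-of-moments estimate shrunk
toward a fitted \(\phi = a_0/\mu + a_1\) trend (weight df/(df + 5),
floor 1e-8; the trend is skipped below 10 usable genes, where it cannot
be anchored). Wald z = log2FC/SE against the standard normal, BH
adjustment across converged genes only (non-converged fits are reported
`NA` and excluded from the BH denominator to avoid silently inflating m),
significance at adjusted P < 0.1. Genes with fewer than 10 reads in
total are filtered first.

This replaces the full empirical-Bayes machinery (trended dispersion
sharing, shrunk fold changes) of the established DE packages on purpose:
the downstream classifier consumes only significance flags, directions
and fitted means, and every piece of the simplified chain is specified
and unit-tested (type-I error on a 2,000-gene null, power and
effect-size recovery on planted fold changes). It is mildly
anticonservative relative to exact dispersion knowledge — the null
rejection rate at nominal 0.05 sits within the binomial 99% CI in the
acceptance checks — which is acceptable for a flag-consumer but would
matter for published single-gene inference.

Transcriptome-level dominance uses Yates-corrected 2×2 chi-squared tests
on DE-gene counts between contrasts (equal denominators: the shared
filtered gene set), with a Bonferroni threshold α/m reported exactly and
rounded half-away-from-zero to 3 decimals (0.05/4 → 0.013).

## The synthetic-data generator

`simulate_experiment()` draws NB counts with mean \(s_j \mu_{gk}\) and
variance \(\mu + \phi_{gk}\mu^2\) for sample j in group k:

- **Design**: 4 cross-types × 2 time points × 9 replicates = 72 samples,
  matching the study layout the pipeline targets.
- **Baseline means** log-normal (meanlog = log 100, sdlog = 1): a typical
  expressed-gene depth distribution after low-count filtering; nearly all
  genes have enough counts for a defined CV in every group.
- **Dispersion trend** \(\phi = 3/\mu + 0.05\), a standard bulk-RNA-seq
  mean–variance shape, so the LCV's level-control actually has a trend to
  remove.
- **Library sizes** log-uniform in [0.7, 1.4] to exercise normalization.
- **Mean patterns** planted as ±δ/2 log2 shifts of the pure crosses
  (δ = 2 by default) with hybrids placed per pattern; **variability
  patterns** planted as dispersion scaling by ρ (default 4) — never as
  mean shifts, so the statistic that should detect them is the
  level-controlled LCV, not a mean effect. The effect sizes present in
  real data are unknown; δ and ρ are harness choices.
- **Directions are balanced**: each planted gene randomly assigns which
  morph lineage is the high side (or whether transgressive hybrids lie
  above or below the pure-cross span). Because percentile scores are
  zero-sum within a group, piling all high-dispersion genes onto one
  morph would depress the scores of every unperturbed gene in those
  groups; balancing keeps the composition symmetric, as in real
  transcriptomes.
- **Pattern fractions** default to maternal-dominant variability (20%
  maternal, 6% + 6% biased, 8% transgressive): the qualitative regime the
  pipeline is designed around, in which maternal effects dominate
  variability inheritance and the group dendrogram pairs cross-types by
  maternal morph. With balanced fractions that pairing need not emerge —
  it is a property of the biology being emulated, not of the method.
- A configurable fraction of genes (default 30%) gets a global
  multiplicative shift at the later time point, mimicking a strong
  developmental signal.

The truth table records every planted label, direction, and the exact
per-group mean and dispersion used, making recovery measurable.

What the generator does **not** emulate: family-level random effects
(families exist in the metadata but contribute no variance component),
batch structure (the `batch` column is carried and usable in the DE
design but not simulated), count outliers and sample swaps,
gene–gene correlation, and miRNA-specific count structure. Passing
recovery tests on this generator therefore demonstrates the pipeline's
internal correctness and power under idealized NB noise — not robustness
to the full messiness of real data.

## Recovery evaluation and problem sizes

Recovery of planted *variability* patterns is evaluated on the
planted-pattern gene sets (`planted_variability_clusters()`): the gene
groups that covary by construction, i.e. the clusters an ideal profile
clustering would find. Gene-level LCV at n = 9 replicates is extremely
noisy (a conserved gene's score is nearly uniform on [0, 100]), so
k-means cannot reconstitute the planted sets gene-by-gene at desk scale —
that is a property of the noise level, not a pipeline defect — while the
cluster-level inference on the planted sets is a clean end-to-end test of
LCV → Gibbs → classifier. K-means itself is validated where its
guarantees live: exact recovery of separable archetype profiles,
objective-value verification, and silhouette selection of a planted
cluster count.

Default problem sizes in tests and the acceptance script — 2,000 genes
for the main recovery runs and the null type-I simulation, 500 genes for
oracle-equivalence checks, 13,000-iteration chains — were chosen so the
full suite completes in well under a minute of compute per component
while leaving every estimate comfortably inside its tolerance; they are
package choices, stated here so that users scaling up to real
transcriptomes (tens of thousands of genes) know the code paths are
identical, only larger.

## Known limitations

- The NB Wald test with plug-in dispersions is slightly liberal at small
  n; use it for pattern flags, not for publication-grade single-gene
  p-values.
- HPD non-overlap is a conservative pairwise rule; it has no global
  error-rate calibration across clusters.
- The LCV percentile is relative within a group: a group in which *all*
  genes double their noise is indistinguishable from one in which none
  did. Cross-group comparability rests on the assumption that most genes
  are unperturbed.
- `AMBIGUOUS` rates rise with cluster size (narrow intervals detect tiny
  compositional differences); interpreting them requires looking at the
  posterior geometry, which the classifier returns as evidence columns.
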