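---
title: "Modelling signal dilution in composite-structure RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling signal dilution in composite-structure RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compexr)
```

## The problem

Bulk RNA-seq is frequently performed on composite anatomical structures — a
whole insect abdomen, a whole head, sometimes a whole animal — because
micro-dissecting the organ of interest is laborious. The extracted RNA is
then a mixture of the transcriptomes of every organ inside the structure,
weighted by how much RNA mass each contributes. Two kinds of error follow
for a small organ nested inside a large structure:

* **False negatives.** A gene strongly differentially expressed between two
  conditions *within the organ* contributes only a small fraction of the
  composite signal. Its composite-level fold change may be intact (if the
  gene is organ-exclusive) but its absolute signal is diluted by roughly
  the inverse of the organ's mass fraction, often below the sensitivity of
  the test — or below the expressed-gene threshold entirely.
* **Opposite-direction calls.** A gene regulated one way in the focal organ
  and the other way in a heavier organ is called in the direction of the
  mass-weighted *net* effect, contradicting the focal biology.

compexr packages a generative model of this situation, the quantification
and differential-expression (DE) machinery needed to analyse it, and the
cross-extraction comparisons that quantify both error classes. The running
example throughout is a honey-bee-like design: two small organs (a venom
gland and a digestive tract) nested in one abdomen, two behavioural
conditions ("nurse" and "forager"), two biological replicates each.

## The generative mixture model

For gene $g$, tissue $t$ and condition $c$ the model stores an expected
relative abundance $\lambda_{g,t,c} \ge 0$ (transcripts per unit RNA mass),
a transcript length $L_g$ (bp), a per-tissue RNA mass fraction $w_t$
($\sum_t w_t = 1$) and a per-tissue negative-binomial dispersion $\phi_t$
(variance $\mu + \phi_t\mu^2$). A **tissue extraction** sequences tissue
$t$ alone; the **composite extraction** sequences the mixture
$\lambda^{mix}_{g,c} = \sum_t w_t\,\lambda_{g,t,c}$.

In a sequencing library the expected read share of a gene is proportional
to abundance × length, so for a library of depth $N$:

$$\mu_{g} = N\;\frac{\lambda_g L_g}{\sum_j \lambda_j L_j},$$

and counts are drawn per gene as NB$(\mu_g, \phi)$ (Poisson when
$\phi = 0$). The composite uses the mass-weighted mean dispersion
$\sum_t w_t \phi_t$ — a deliberately simple choice that is monotone in the
weights and reduces to the single-tissue dispersion when one tissue holds
all the mass; real mixtures of heterogeneous tissues can be more
overdispersed than this, which is out of scope here.

**Abundance normalization.** Abundances are rescaled once per tissue (one
factor per tissue, averaged over the two conditions) so that
$\sum_g \lambda_{g,t,c} L_g$ is a common constant. This gives $\lambda$ its
per-unit-mass interpretation and makes two useful identities exact:

* the expected composite RPKM of every gene equals
  $\sum_t w_t \times$ (expected RPKM in tissue $t$), and
* a gene exclusive to tissue $t$ has expected focal-to-composite RPKM
  ratio $1/w_t$ (the dilution factor).

A per-*condition* normalization would also be possible but would shift the
abundances of non-DE genes between conditions, breaking the guarantee that
a gene's ground-truth label matches the sign of
$\lambda_{g,t,1} - \lambda_{g,t,2}$; the per-tissue scheme preserves every
within-tissue fold change exactly. The small compositional difference
between conditions that DE genes induce (a fraction of a percent at the
default 10% DE rate) is retained, as it is in real libraries.

**Incomplete homogenization.** Grinding a composite structure to powder
before subsampling does not guarantee each organ is represented at its
true mass fraction: the grains are finite. `homogenization_spec(grains = G)`
models the subsample as $G$ grains falling into tissue $t$ with probability
$w_t$; each composite replicate draws its own realized fractions
$w'_t \sim \text{Multinomial}(G, w)/G$, so the realized fraction of a small
organ has variance $w_t(1-w_t)/G$. `grains = Inf` is perfect
homogenization. This reproduces the observation that even highly expressed
organ-exclusive genes can drop out of a composite library in some
replicates.

**Effect classes.** `effect_config()` controls the simulated gene classes:
a fraction of genes DE per tissue with $|\log_2 FC|$ drawn from a normal
distribution (default location 2, scale 0.5 — strong but realistic organ
effects); a fraction of those exclusive to their tissue (specialized genes,
default 20%); and a fraction with an equal-magnitude opposite-direction
effect in the largest-mass other tissue (default 5%), the class that
produces contradictory composite calls. Baseline abundances are log-normal
(meanlog $\log 50$, sdlog 1.5), giving the heavy-tailed expression
distribution typical of bulk libraries; transcript lengths are log-normal
around 1.5 kb, floored at 200 bp. Default demo tissues are a small gland
(2% of RNA mass), a digestive tract (30%) and a remainder (68%) — round
numbers chosen to span "tiny organ" and "sizeable organ" regimes, not
estimates of any particular species; every default is overridable.

**Seeding.** Each simulated sample draws from a stream derived by a stable
hash of (extraction, condition, replicate) folded with the master seed, so
adding a sample to an experiment never perturbs existing ones, and
identical seeds give bit-identical count matrices.

## Quantification

RPKM is computed as $10^9 c_{gs} / (N_s L_g)$ with $N_s$ the column sum of
the count matrix — the self-consistent library size at the count-matrix
boundary — and no effective-length correction. A gene belongs to the
transcriptome of an (extraction, condition) when its **replicate-mean**
RPKM is **strictly** greater than $\tau$ (default 10). The replicate-mean
rule is one concrete reading of an "expressed at RPKM > 10" convention;
per-replicate AND/OR rules would be stricter/looser and can be emulated by
calling `transcriptome_membership()` per replicate.

Depth is equalized by `downsample_counts()`: each sample is thinned without
replacement to the target total (a multivariate hypergeometric draw), the
in-silico analogue of comparing libraries at the same number of
quality-controlled reads (12 million in the motivating design).

## Differential expression

Two method families are implemented, deliberately different in spirit so
that conclusions can be checked for robustness across methods:

**Exact conditional NB test (`nb_exact`).** Replicate counts are scaled to
a common effective library size (geometric mean), summed within condition
and rounded. Conditional on the total $s = a + b$, the split follows a
negative hypergeometric law with sizes $n_1/\phi$ and $n_2/\phi$; the
two-sided p-value is the minimum-likelihood rule — the sum of point
probabilities of every split no more likely than the observed one, with
ties included within relative tolerance $10^{-7}$. Point probabilities are
computed in log space; below $\phi < 10^{-8}$ the law degenerates to
binomial$(s, n_1/(n_1+n_2))$ (the Poisson-conditional limit). Summing
scaled replicates keeps the conditional argument exact at the cost of
ignoring replicate-level shrinkage sophistication (pseudo-data,
empirical-Bayes moderation) found in mature DE packages; that divergence is
intentional and documented. P-values are BH-adjusted and genes called DE
at $q \le \alpha$ (inclusive; default $\alpha = 0.05$).

The common dispersion is estimated by method-of-moments per gene within
each condition on depth-normalized counts,
$\hat\phi_g = \max(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2)$, averaged over
conditions and summarized by the median over genes with mean normalized
count of at least 5 (floor and summary configurable). Averaging the two
per-condition estimates before the median halves the chi-square skew of
small-sample variances; at 5 replicates per condition the estimator
recovers $\phi = 0.1$ within a few percent of its value (the residual bias
is downward, from the median of a right-skewed estimator). With only 2
replicates the bias is larger; supplying a known dispersion via
`de_config(dispersion = )` is preferred in simulations.

**Nonparametric signal-vs-noise probability (`noiseq_like`).** On the RPKM
scale each gene's signal is $M_g = \log_2\frac{\bar x_1 + k}{\bar x_2 + k}$
and $D_g = |\bar x_1 - \bar x_2|$, with pseudo-count $k = 0.5$ RPKM keeping
$M$ finite. The noise distribution pools $(M^*, D^*)$ computed the same way
between every within-condition replicate pair, over **all** genes. The
probability $q_g$ is the fraction of noise points strictly dominated
($|M^*| < |M_g|$ and $D^* < D_g$); genes are called DE at $q_g > 0.8$
(strict, the conventional cutoff). Strict inequalities make $q_g = 0$
attainable for genes identical to their replicates and guarantee an
$M_g = 0$ gene can never be called. The noise pool uses biological
replicates directly (no technical-replicate simulation mode); with 2
replicates per condition the pool has $2 \times$ (number of genes) points.

Boundary conventions are asymmetric on purpose: $\alpha$ is inclusive and
$q$-cutoff exclusive, fixing semantics the conventions "FDR < 0.05" and
"0.8 probability cutoff" leave open; both are config-exposed.

## Cross-extraction analyses

* `classify_cross_extraction()` iterates over the focal extraction's DE
  genes and classifies each as `not_sig` (not DE in the composite, *or
  absent from the composite results* — a filtered gene is a false-negative
  candidate, not a contradiction), `same_direction` or
  `opposite_direction`. Comparisons across different methods or thresholds
  are refused.
* `presence_absence_table()` reports genes present (mean RPKM > τ) in
  exactly one of the two extractions, binned by expression in the
  extraction where they are present. Default bins (10,30], (30,100],
  (100,300], (300,∞) follow roughly logarithmic spacing with an explicit
  edge at 100 RPKM, above which "insufficient composite coverage" stops
  being a parsimonious explanation for absence.
* `dilution_ratios()` computes $r_g$ = focal RPKM / composite RPKM from
  replicate means; $r_g > 1$ (strict) counts as diluted; genes with
  composite RPKM 0 are tallied separately as undefined rather than
  entering the histogram.
* `fisher_exact_2x2()` / `compare_focal_tissues()` compare a property
  (not-significant fraction, dilution fraction) between two focal tissues
  by a two-sided Fisher's exact test (minimum-likelihood rule, tie
  tolerance $10^{-7}$), reporting the sample odds ratio $ad/bc$ with
  $\infty$ when $bc = 0$. Two-sided is the conservative choice when
  sidedness is unspecified.
* `subset_analysis()` restricts the classification to a user-supplied gene
  list (e.g. transcription factors); unresolvable ids warn rather than
  fail.

## What the simulator does and does not emulate

The generator reproduces the *structure* of a composite-extraction study:
nested extractions with known mass fractions, equalized depth, two
replicates, organ-exclusive and opposite-direction gene classes, and
count-level NB noise. It does not model read-level artefacts (mapping
bias, multi-mapping, GC effects), RNA degradation during dissection,
correlated gene modules, or tissue-dependent length effects — so passing
tests demonstrate that the *pipeline logic and statistics* behave as
designed under the stated model, not that any particular biological
dataset will show effects of a given size. The published contingency
tables are reproduced from their printed counts, not re-derived from raw
reads, which would require alignment and counting outside this package's
boundary (the count matrix).

## Numerical and scale choices

Simulation-backed checks use sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping each suite quick on a
laptop: 2000-gene experiments for the phenomenon and calibration suites
(20 seeds for the null false-positive fraction, 50 for dispersion
recovery), 500 replicate simulations for the $1/w$ dilution expectation,
and exhaustive enumeration for the oracle comparisons (all 2×2 tables with
margins ≤ 12; all exact-test totals ≤ 50). Degenerate inputs follow fixed
conventions: an all-zero gene is untestable and gets $p = 1$; a sample
with zero total counts is an error naming the sample; a focal gene with
composite RPKM 0 is "undefined" in the dilution analysis; `grains = 1`
puts the whole subsample in one tissue.

## Known limitations

* The composite dispersion model (mass-weighted mean) understates mixture
  overdispersion when tissues differ strongly in expression profile.
* The exact test's replicate pooling forfeits per-replicate information;
  with many replicates a GLM-based test would be more powerful.
* The nonparametric probability is not a posterior probability of DE; its
  0.8 cutoff is a convention, and with few genes the noise pool is small
  and $q_g$ granular.
* RPKM (rather than within-sample-free measures like TPM at the
  transcript level, or count-based normalization) is retained because the
  analyses the package reproduces are defined on RPKM.
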