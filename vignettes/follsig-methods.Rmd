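---
title: "Models and methods behind follsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind follsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follsig)
```

## The problem

Early ovarian folliculogenesis proceeds through four morphologically
defined stages — primordial (PD), primary (PM), secondary (SC) and
small antrum (SA) — in two interacting compartments, the oocyte (O)
and its surrounding granulosa cells (GC). Compartment-resolved
expression data from laser-capture microdissection come in small
numbers (three or four biological replicates per stage-compartment
cell, with a handful of multi-tissue pools as specificity background)
and in two complementary forms: genome-wide sequencing counts and a
qPCR biomarker panel in which a transcript can be *undetected* in some
wells and quantified in others.

`follsig` implements the complete analysis chain for such a design:

1. a synthetic-data module that generates study-shaped count matrices
   and biomarker panels with known ground truth;
2. efficiency-corrected qPCR quantification and reference
   normalization;
3. a negative-binomial differential-expression engine with the
   fold-change/FDR selection rules used for stage-regulated genes and
   compartment-specific biomarkers;
4. a two-part (hurdle) hierarchical mixed model of expression presence
   and level with correlated stage random effects;
5. empirical-Bayes posterior prediction of follicular stage from a new
   expression vector, validated by a resampling study;
6. a deterministic pipeline orchestrating all of the above.

## Synthetic data: what it emulates and what it does not

`generate_design()` reproduces the factorial backbone: 8
stage-by-compartment groups with 4 replicates (3 for PD oocytes, which
are hardest to capture), plus 3 multi-tissue pools — 31 LCM samples in
all.

`simulate_counts()` draws integer counts from a negative binomial with
`Var = mu + alpha * mu^2` (the parameterization of the count-based DE
packages; `alpha = 0` is the Poisson limit). A chosen fraction of
genes carries a signed log2 effect that switches on at a random onset
stage (PM, SC or SA) in one compartment and persists through later
stages, so consecutive transitions accumulate regulated genes the way
staged developmental programmes do. Marker genes can be planted in
exactly one stage-compartment group at a chosen fold. Multi-tissue
pools are simulated from the baseline with no stage structure. The
defaults (baseline mean 100, dispersion 0.2, log2 effect 2, 5% DE)
are typical of a moderately deep bulk experiment; the dispersion value
sits in the range commonly reported for biological replicates.

Deliberate simplifications: all genes share one baseline mean (so
moment checks against the specified means are exact), genes are
independent, there is no mean-dispersion trend and no library-size
variation beyond what the negative binomial induces. Passing tests on
these data therefore demonstrates correctness of the machinery, not
robustness to the full messiness of real libraries (GC content,
batch, correlated genes).

`simulate_hurdle_panel()` generates the biomarker panel: for each gene
a stage random 4-vector and a compartment random 2-vector are drawn
from user-specified covariances — independently for the binary
(detection) and quantitative parts, so that dropout is non-informative
for the level model and parameter recovery of each part can be judged
on its own. Detection is Bernoulli on the logit scale; detected levels
are Gaussian on the fourth-root scale and recorded as the fourth
power, undetected wells as absent (`NA`), mirroring qPCR wells that
never cross threshold. Fourth-root draws that would be non-positive
are truncated at a tiny positive value and counted in the truth object
(`n_truncated`); with the default means and spreads this is rare, and
configurations for recovery experiments are chosen so that it stays
rare. `stage_cov_onefactor()` builds valid stage covariances with a
prescribed first row via a one-factor structure, which is how we
encode the qualitative pattern seen in this system: behaviour at PD,
PM and SC strongly aligned and anti-correlated with SA.

## qPCR quantification

Amplification efficiency is fit by least squares of Ct on log10
relative input over a serial dilution (the assay's scheme is 1, 1:3,
1:3, 1:2, 1:2), with `E = 10^(-1/slope)`; a non-negative slope is a
quality failure, not a number. Quantities are efficiency-corrected
relative to a calibrator Ct (`E^(calibrator - ct)`); the calibrator
defaults to each gene's mean detected Ct because the original
protocol does not name one — any fixed choice only rescales a gene's
quantities by a constant, which reference normalization then cancels.
Normalization divides every quantity in a sample by the geometric mean
of the reference genes (three references in the original panel);
samples with an undetected reference cannot be normalized and are
excluded with a warning rather than imputed. Reference stability uses
the geNorm measure: M_j is the mean standard deviation across samples
of pairwise log2 ratios against the other candidates, computed on
complete cases, with iterative exclusion of the largest M. Detection
calling — never defined operationally in qPCR write-ups — is z = 1 iff
Ct is numeric, below 40 cycles, and at least 3 cycles below a matched
negative control; both numbers are arguments. Technical-replicate
averaging is outside the module: quantification operates on one Ct
per gene and sample.

## The negative-binomial DE engine

Size factors are median-of-ratios over genes nonzero in every sample
(with an optional positive-count pseudo-reference fallback).
Dispersions are per-gene pooled method of moments on normalized
counts; the `mu^2` term uses the unbiased estimate `m^2 - s^2/n`
because the naive `m^2` inflates the denominator and biases alpha
downward by ~10% at these replicate numbers — enough to make
downstream tests visibly anti-conservative. Per-gene estimates remain
noisy at 3-4 replicates, so `shrink = TRUE` moderates them toward the
across-gene median with a prior weight of 20 pseudo-degrees of
freedom by default; the pipeline uses a prior weight of 50, which on
panels with a stable dispersion-mean relationship trades a little
per-gene adaptivity for substantially better calibration of the
selection rules. The raw estimator remains the default at the module
surface.

The pairwise test is the exact conditional NB test: each group's total
is modelled as one negative binomial whose mean is the pooled per-unit
expression times the group's summed size factor and whose variance
matches the size-factor-adjusted convolution
(`Var = q S + alpha q^2 sum(s_j^2)`); conditioning on the grand total,
the two-sided p-value sums the probabilities of all partitions no more
probable than the observed one (mode-anchored, not tail-doubled), with
a relative tie tolerance of 1e-10. When `alpha ~ 0` the conditional
law is exactly binomial and that branch is used. The global stage test
fits NB log-link regressions (`count ~ stage` vs `count ~ 1`) by IRLS
with step-halving (max 50 iterations, deviance tolerance 1e-8) at
fixed dispersion, and refers twice the log-likelihood ratio to a
chi-square with (stages - 1) degrees of freedom, run per compartment —
the reading of "intra-compartment" stage effects; the pooled
alternative would share information across compartments but confound
compartment-specific dynamics.

Selection combines three gates: global FDR < 5% (Benjamini-Hochberg
across genes), at least one pairwise p < 1%, and fold change > 2 in
either direction. Biomarker selection tests one target group against
all remaining samples pooled — multi-tissue pools included, which is
what makes the rule tissue-specific — at BH FDR < 5% with fold change
above 3 (granulosa targets) or 10 (oocyte targets). A gene silent
everywhere except the target has infinite fold change and passes; 0/0
is excluded.

## The hurdle mixed model

For gene g, stage s, compartment c and replicate k, with z the
detection indicator and y the normalized relative expression:

* presence part: `logit P(z = 1) = beta[s,c] + b_g[s] + u_g[c]`,
  `b_g ~ MVN(0, Sigma_stage)` (4x4), `u_g ~ MVN(0, Sigma_cell)` (2x2);
* level part (detected records only, plus one zero record for every
  (g, s, c) cell with no detected replicate):
  `y^(1/4) = mu[s,c] + b'_g[s] + u'_g[c] + eps`,
  `eps ~ N(0, sigma^2)`.

The single-null-observation augmentation lets a silent cell inform the
level model without fabricating replicate-level values. The fourth
root is the variance-stabilizing scale on which the original analysis
modelled expression; the level part is equivariant to rescaling raw
expression (a factor kappa scales fitted means by kappa^(1/4)).

The additive (stage-vector plus compartment-vector) random-effect
architecture is the default because it reproduces both the marginal
stage correlations and the within-compartment view while remaining
estimable on a 24-gene panel; an unstructured 8-vector per gene over
the stage-compartment cells is available via
`hurdle_control(structure = "cell8")`.

Estimation is Laplace-approximated maximum likelihood: a penalized
joint Newton solve over fixed effects and per-gene conditional modes
(block elimination over genes, step-halving, gradient tolerance 1e-8),
alternating with EM updates of the covariances from conditional modes
plus conditional covariances taken from the gene-block Hessian
inverse. For the Gaussian level part the marginal likelihood is exact
and the EM trace is monotone; for the Bernoulli part the Laplace
objective is an approximation, accurate to a few percent on the
instances where we can compare it against two-dimensional numeric
quadrature. Covariance inversions carry a 1e-8 diagonal jitter; the
residual SD is floored at 1e-6. Complete separation (a cell all
detected or all undetected) engages a logistic ridge (1e-4) on the
fixed-effect logits and is flagged; fitted logits then sit at the
penalty ceiling rather than at infinity.

Known limitations, visible in the package's own recovery experiments:
binary-part stage correlations are attenuated by roughly 0.05-0.15 at
24 genes and 8 Bernoulli observations per gene-stage (a classic
Laplace/EM shrinkage effect), while the level part recovers its
correlations more closely; and under heavy dropout the augmented zero
records inflate the residual SD, since a single zero stands in for an
entire silent cell. Both effects shrink as panels grow.

## Stage prediction and the resampling study

The predictive equations are empirical-Bayes plug-ins: detection
probabilities and level means are evaluated at the fixed effects plus
each gene's conditional modes, and a new vector's posterior over the
four stages multiplies Bernoulli terms (all genes) and fourth-root
Gaussian terms (detected genes) with a prior (uniform by default,
configurable), in log space, normalized over stages. Integrating over
random-effect uncertainty instead of plugging in modes would widen
posteriors slightly but breaks the exact correspondence with
enumeration oracles; it is deliberately out of scope. The binary-only
variant simply drops the Gaussian terms.

The resampling study mirrors the original validation: for each
stage-compartment cell, each of (by default) 100 new vectors draws,
independently per gene, one replicate's (z, y) pair uniformly at
random — jointly, never mixing one replicate's detection call with
another's level. Reports aggregate posterior panels, the mean
posterior of the true stage, and an argmax confusion matrix with ties
broken toward the earlier stage and counted. Because vectors are
resampled from the same data the model was fitted to, this measures
in-sample predictive ability, as in the original study; independent
validation requires independent material.

## Problem sizes used in the validation suite

The test suite exercises the chain at the study's own scale: null
calibration and selection on 2,000-gene matrices over the 31-sample
(or 4-replicate) design; hurdle recovery on 24-gene panels over 20
simulated datasets; resampling studies with 100 vectors per cell;
enumeration oracles on totals up to 200 and panels up to 3 genes.
These sizes were chosen to match the study design while keeping each
check's Monte-Carlo error well below the tolerance it asserts.

## Numerical conventions

* Fold change x/0 is `Inf` (passes any gate), 0/0 is excluded.
* Undetected measurements are `NA`/absent markers, never numeric
  zeros; only the augmentation rule creates a zero, and exactly one
  per fully silent cell.
* All simulators and the pipeline are bit-reproducible under a seed;
  TSV writers serialize doubles at 17 significant digits and fit
  serialization goes through `%.17g`, so round trips are lossless.
* Correlations of zero-variance components are reported as `NA`
  (undefined), not 0.
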