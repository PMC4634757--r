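# follsig

Molecular signature discovery and stage prediction for early ovarian
folliculogenesis.

Early follicles pass through four stages — primordial (PD), primary
(PM), secondary (SC) and small antrum (SA) — in two compartments, the
oocyte (O) and the granulosa cells (GC). Laser-capture experiments
profile these cells with 3–4 biological replicates per
stage-compartment group, by RNA-seq counts genome-wide and by a qPCR
biomarker panel in which transcripts may be undetected in some wells.
`follsig` is for analysts of such compartment-resolved developmental
data: it finds stage-regulated genes and compartment-specific
biomarkers from counts, quantifies the qPCR panel, models the panel
with a two-part mixed model, and turns that model into predictive
equations for follicular stage.

## The models at the core

**Differential expression.** Counts are negative binomial,
`Var = μ + αμ²`, normalized by median-of-ratios size factors. The
global stage test compares `count ~ stage` with `count ~ 1` per
compartment by a likelihood-ratio chi-square; pairwise stages are
compared by an exact conditional NB test (the two-sided p sums all
partitions of the total no more probable than the observed one).
Stage-regulated genes require global FDR < 5 %, a pairwise p < 1 %
and fold change > 2; biomarkers of one group are tested against all
other samples pooled with multi-tissue background at FDR < 5 % and
fold change > 3 (GC) or > 10 (O).

**qPCR quantification.** Efficiency `E = 10^(−1/slope)` from a serial
dilution, Pfaffl relative quantities `E^(Ct_cal − Ct)`, normalization
by the geometric mean of reference genes, and geNorm stability
ranking of candidate references.

**Hurdle mixed model.** For gene *g*, stage *s*, compartment *c*:

    logit P(z = 1)  =  β_sc + b_g[s] + u_g[c],      b_g ~ N₄(0, Σ_stage)
    y^(1/4) | z = 1 =  μ_sc + b′_g[s] + u′_g[c] + ε, u_g ~ N₂(0, Σ_cell)

with one zero-level record added for every fully undetected cell.
Both parts are estimated by Laplace-approximated maximum likelihood
(joint Newton over fixed effects and conditional modes, EM updates of
the covariances). The correlated stage random effects are what carry
the developmental signal: a new observation vector's posterior over
{PD, PM, SC, SA} multiplies Bernoulli and fourth-root Gaussian
likelihoods at the empirical-Bayes plug-ins, and a resampling study
(100 vectors per stage and compartment) measures predictive ability.

## Worked example

```r
library(follsig)

design <- generate_design()                      # 31 LCM samples + 3 MT pools
panel  <- simulate_hurdle_panel(design, hurdle_sim_params(seed = 1))
fit    <- fit_hurdle(panel$det, panel$rel, panel$design)
fit
#> Two-part hurdle fit: 24 genes
#>   presence part: loglik -407.8957
#>   level part:    loglik -397.5193  resid_sd 0.4589634

vec <- resample_vectors(panel$rel, panel$det, panel$design,
                        stage = "SC", compartment = "O", n = 1, seed = 2)[[1]]
posterior_stage(fit, vec)
#> Stage posterior (full model, compartment O):
#> PD PM SC SA
#>  0  0  1  0

report <- resample_study(fit, panel$rel, panel$det, panel$design,
                         n = 100, seed = 3)
report$summary
#>   compartment stage   n mean_posterior_true n_ties
#> 1           O    PD 100           0.9999585      0
#> 2           O    PM 100           0.9998681      0
#> 3           O    SC 100           0.9999954      0
#> ...                                   (8 rows, one per stage x compartment)
```

The fit summary reports the Laplace log-likelihood of each part and
the residual SD of the fourth-root level model. The posterior places
essentially all mass on the true stage (SC) of the resampled vector,
and the resampling study shows the same for every stage and
compartment on this clearly structured panel. The estimated stage
correlations of the level part recover the simulated structure —
strong PD–PM alignment, anti-correlation with SA:

```r
round(stage_effect_correlations(fit)$level$model, 2)
#>       PD    PM    SC    SA
#> PD  1.00  0.99  0.78 -0.64
#> PM  0.99  1.00  0.76 -0.64
#> SC  0.78  0.76  1.00 -0.39
#> SA -0.64 -0.64 -0.39  1.00
```

For counts, `simulate_counts()` plants known stage effects,
`de_stage_analysis()` runs both DE designs per compartment,
`select_stage_de()` / `select_biomarkers()` apply the selection
rules, and `transition_summary()` counts up/down genes per
consecutive-stage transition. `run_pipeline()` chains everything
(simulate → qpcr → de → biomarkers → fit → predict) into a directory
of TSV artifacts with a YAML manifest, byte-reproducible under a
fixed config and seed.

## Package layout

- `R/` — modules: design/simulators (`design.R`, `sim-*.R`), qPCR
  (`qpcr.R`), NB engine (`nb-core.R`, `nb-glm.R`, `de-select.R`),
  hurdle model (`hurdle-fit.R`), prediction (`predict.R`), I/O
  (`io.R`), pipeline (`pipeline.R`).
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (enumeration, quadrature, brute-force Bayes).
- `vignettes/follsig-methods.Rmd` — the models, assumptions, tunable
  parameters, numerical choices and known limitations.
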