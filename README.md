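# polsmm

Pace-of-life syndromes (POLS) — the hypothesis that life-history speed,
physiology and behaviour covary consistently among individuals — are tested
by decomposing the phenotypic covariance of repeatedly measured traits into
an **among-individual** component $\Sigma_{ind}$ and a **within-individual
(residual)** component $\Sigma_{res}$. `polsmm` implements that analysis end
to end for a two-population, repeated-measures study design in fish, for
behavioural ecologists and ecophysiologists who need the full chain from raw
measurements to syndrome tests:

* **Standard metabolic rate (SMR) extraction** from overnight
  intermittent-flow respirometry traces: per-phase OLS slopes with 2-min end
  trims, an $R^2 \ge 0.95$ linearity filter, a 1-h acclimation cutoff, and a
  two-component normal mixture fitted by EM whose *lower* mean is the
  mass-specific SMR (the upper component absorbs spontaneous activity).
* **A REML engine for multi-trait mixed models** with individual random
  intercepts,

  $$y_{ito} = \mathbf{x}_{ito}'\boldsymbol\beta_t + u_{it} + e_{ito},\qquad
  \mathbf{u}_i \sim N(0, \Sigma_{ind}),\quad \mathbf{e}_{io} \sim N(0, \Sigma_{res}),$$

  residuals correlated across traits sharing a measurement occasion,
  unstructured / diagonal / element-wise-constrained covariance blocks, and
  population-specific structure in joint two-population fits.
* **Adjusted repeatability** $R = \sigma^2_{ind} / (\sigma^2_{ind} +
  \sigma^2_{res})$ with bootstrap or delta-method SEs, tested by
  likelihood-ratio against the boundary mixture
  $\frac12\chi^2_0 + \frac12\chi^2_1$.
* **Syndrome tests**: per-pair covariance LRTs ($\chi^2_1$), one trait's
  variance-plus-covariances ($\frac12\chi^2_k + \frac12\chi^2_{k+1}$), an
  overall test of all $\binom{T}{2}$ among-individual covariances, and a
  cross-population equality test of the pairwise covariances (pure $\chi^2$
  on the pair count — 6 df for four traits).
* **A synthetic-data generator** reproducing the study design (2 populations
  × 40 fish; behaviours twice per ontogenetic stage, SMR/size once; sex and
  stage coded ±0.5; post-stage-1 attrition) with known ground truth, so every
  stage has a parameter-recovery and calibration test surface.

## Worked example

```r
library(polsmm)

panel <- simulate_trait_panel(sim_config(seed = 1))
traits <- c("hiding_time", "distance_moved", "standard_size", "smr")

# repeatability per trait and population, with boundary-mixture LRT p-values
repeatability_table(panel, traits, nboot = 200)

# among- vs within-individual covariance decomposition in the SG population
dec <- pols_decompose(panel, traits, population = "SG", nboot = 200)
print(dec)

# overall syndrome test and cross-population comparison
test_overall_structure(panel, traits, population = "SG")
test_population_equality(panel, traits)
```

Output (abridged):

```
 population          trait sigma_ind sigma_res     R  se_R lrt_statistic   lrt_p
         SG    hiding_time     0.473     0.797 0.373 0.087         20.48 3.0e-06
         SG  standard_size     0.432     0.101 0.810 0.061         31.30 1.1e-08
         FG    hiding_time     0.145     0.728 0.166 0.082          5.38 1.0e-02
         FG  standard_size     0.014     0.096 0.126 0.188          0.59 2.2e-01
         ...

POLS covariance decomposition [SG], traits: hiding_time, distance_moved, standard_size, smr

Among-individual correlations (SE) [p from chi2_1 LRT]:
  hiding_time        ~ distance_moved      0.566 (0.242)  p = 0.01733 *
  hiding_time        ~ standard_size       0.659 (0.176)  p = 0.0007383 *
  distance_moved     ~ smr                -0.756 (0.174)  p = 0.0003994 *
  standard_size      ~ smr                -0.593 (0.198)  p = 0.002432 *
  ...

Likelihood-ratio test: chi2 = 36.837, chi2_6 (all among-individual covariances zero), p = 1.894e-06   # SG
Likelihood-ratio test: chi2 = 7.894,  chi2_6 (all among-individual covariances zero), p = 0.2459      # FG
Likelihood-ratio test: chi2 = 20.804, chi2_6 (pairwise among-individual covariances equal across populations), p = 0.00199
```

Reading it: `standard_size` is strongly repeatable in the slow-growing
population (R ≈ 0.81) and only weakly in the fast-growing one; the SG
among-individual correlations recover the syndrome pattern the generator
encodes (size and activity positive, mass-specific SMR negative, true
pairwise magnitude 0.6); the overall 6-df test rejects the no-covariance
model in SG but not in FG; and the cross-population equality test confirms
the two populations differ in covariance structure.

The pipeline — respirometry → preprocessing → repeatability gate →
decomposition → population comparison — runs from one config:

```r
report <- run_pols_pipeline(pipeline_config(simulation = sim_config(seed = 1)))
print(report)
```

or from the shell via `inst/scripts/pols-pipeline.R`
(`simulate | smr | fit | pols | compare | run-all`).

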