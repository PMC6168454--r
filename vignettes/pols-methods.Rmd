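---
title: "Decomposing pace-of-life syndromes: models, tests and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing pace-of-life syndromes: models, tests and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsmm)
```

## The scientific problem

The pace-of-life-syndrome (POLS) hypothesis predicts that life-history speed,
physiology and behaviour covary *among individuals*: within a population,
individuals with faster growth should also tend to be bolder, more active and
metabolically more expensive. Testing this requires more than phenotypic
correlations: a raw correlation between, say, activity and metabolic rate
mixes consistent differences between individuals with occasion-to-occasion
fluctuation within them. The syndrome lives in the among-individual
component, so the phenotypic covariance of repeatedly measured traits has to
be split into an among-individual matrix $\Sigma_{ind}$ and a residual
(within-individual) matrix $\Sigma_{res}$.

`polsmm` implements that decomposition end to end for a two-population,
repeated-measures fish study design: standard metabolic rate (SMR) extraction
from raw overnight respirometry traces, trait preprocessing, univariate
repeatability with boundary-corrected likelihood-ratio tests (LRTs), the
multivariate covariance decomposition with element-wise and global tests, and
cross-population tests of whether the syndrome structure differs.

## The mixed model

For trait $t$ of individual $i$ on occasion $o$,

$$y_{ito} = \mathbf{x}_{ito}'\boldsymbol\beta_t + u_{it} + e_{ito},
\qquad \mathbf{u}_i \sim N(0, \Sigma_{ind}), \qquad
\mathbf{e}_{io} \sim N(0, \Sigma_{res}),$$

with individual random intercepts correlated over traits and residuals
correlated over the traits measured on the same occasion, independent across
occasions. Fixed effects are per-trait: ontogenetic stage and sex (both coded
$-0.5/+0.5$ so intercepts sit at the design midpoint), and the within-stage
trial index for traits measured repeatedly within a stage. All models are
estimated by restricted maximum likelihood (REML), so variance components are
not biased by the estimated fixed effects; dependent variables are
mean-centred and variance-standardized before fitting so that components are
comparable across traits.

Occasion structure matters for what is estimable. Behavioural traits scored
from the same trial share an occasion; SMR and body size measured once per
stage at the same assay share another. A behavioural trait and SMR are never
observed on a common occasion, so their residual covariance is not estimable
from data; the engine detects such pairs, fixes the element to zero and says
so. The among-individual covariance of any trait pair is always estimable
because the random intercepts persist across occasions.

## Estimation

The engine (`mm_reml()`) maximizes the restricted log-likelihood

$$\ell_R = -\tfrac12\Big(\log|V| + \log|X'V^{-1}X| + r'V^{-1}r
 + (n - p)\log 2\pi\Big)$$

accumulated individual-by-individual (each individual's $V_i$ is a dense
matrix of at most a few dozen rows; a compiled kernel assembles the pieces).
Fixed effects are profiled out by generalized least squares at each parameter
value.

**Parameterization.** Variances enter as log standard deviations (hence
strictly positive, with a floor of $10^{-10}$; a fitted variance within ten
times the floor is reported as "at boundary"), covariances on their natural
scale, unbounded. This direct element-wise parameterization — rather than a
log-Cholesky factor — was chosen because the scientific constraints are
element-wise: a single covariance fixed to zero, a pair of covariances
equated across populations, one trait's variance and covariances removed.
Each such constraint removes or shares exactly one parameter, so likelihood-
ratio degrees of freedom can be read off the parameter map, and an unbounded
covariance matches the pure-$\chi^2$ reference used for covariance tests.
The price is that $\Sigma_{ind}$ is not forced positive definite elementwise;
the likelihood itself rejects parameter values for which some individual's
marginal covariance $V_i$ is not positive definite.

**Optimization.** Quasi-Newton (`nlminb`) with finite-difference gradients
from three dispersed starts: a moment-based start (between/within variance
split of individual means), a pooled-variance variant and an among-shrunken
variant. Convergence is taken from the optimizer status plus a
finite-difference gradient check at the optimum (infinity-norm below
$10^{-3}$ on the scaled criterion; parameters pinned at the variance floor
are exempt, since a positive gradient there is the boundary optimum).
Replicated simulation studies in the test suite run with a single start and a
relative tolerance of $10^{-8}$, which on these problem sizes reaches the
same optimum as the dispersed-start configuration.

Standard errors of variance parameters come from the finite-difference
Hessian of $-\ell_R$; standard errors of derived quantities (repeatability,
correlations) use a parametric bootstrap from the asymptotic distribution of
the variance parameters (the delta method is available for repeatability).
The bootstrap was preferred as the default because it is transparent about
the nonlinearity of ratios near the boundary; near $\hat\sigma^2_{ind}=0$ it
yields a one-sided spread.

**Fixed-effect tests.** Wald $F$ tests with containment-style denominator
degrees of freedom: terms constant within individuals (sex, population) get
$n - p - n_{ind} + 1$, within-individual terms $n - p$. This is a documented
approximation; specialized algebraic df algorithms in commercial REML
software can give slightly different fixed-effect p-values. Variance-
component inference, the package's focus, does not depend on these df.

## Likelihood-ratio tests with boundary mixtures

Twice the difference in restricted log-likelihood between nested covariance
structures (same fixed effects) is referred to:

* **one variance** (repeatability test): the null pins $\sigma^2_{ind}$ to the
  boundary, so the reference is the equal mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$;
* **one covariance**: unbounded parameter, pure $\chi^2_1$;
* **one trait's variance plus its $k$ covariances**: equal mixture
  $\tfrac12\chi^2_k + \tfrac12\chi^2_{k+1}$ (for two traits this is the
  familiar df-1/df-2 mixture);
* **all $\binom{T}{2}$ among-individual covariances zero** (overall syndrome
  test) and **covariances equated across populations** (syndrome-equality
  test): pure $\chi^2$ on the number of constrained pairs — six for four
  traits.

In the cross-population test, fixed effects are population-specific inside
the joint fit and both covariance matrices stay population-specific; only the
among-individual covariances are equated, so the nested pair differs by
exactly the pair count. Had variances been equated too, the df would change;
the pairwise-covariance-only reading is the one that matches a six-df test
for four traits. Test-suite calibration studies (2000 null replicates at the
study scale, 40 individuals with 4 occasions) confirm both the variance-LRT
mixture and the covariance $\chi^2_1$ hold their 5% level within binomial
tolerance.

## SMR extraction from respirometry traces

Intermittent-flow respirometry alternates open (flush) and closed phases;
during a closed phase the oxygen concentration declines linearly while the
fish respires quietly. Extraction proceeds as:

1. per closed phase, trim 120 s from each end (sealing and flushing
   transients), fit ordinary least squares of O$_2$ on time, and keep the
   slope (reported per minute) with its $R^2$;
2. retain phases with $R^2 \ge 0.95$ (linearity filter) that start after the
   1 h acclimation window;
3. convert to mass-specific rates,
   $\text{rate} = |\text{slope}| \times 60 \times V_{chamber} / m_{fish}$
   (mg O$_2$ kg$^{-1}$ h$^{-1}$);
4. fit a two-component normal mixture by EM; the **lower component mean is
   the SMR** — the resting state — while the upper component absorbs phases
   inflated by spontaneous activity.

The EM uses ten restarts from spread quantile pairs of the rates, asserts a
non-decreasing log-likelihood every iteration, floors component standard
deviations at $10^{-3}$ of the sample SD (restarting when a component still
collapses), and breaks exact likelihood ties toward the lower first
component mean. At least four retained phases are required — two parameters
per component plus a weight leaves no meaningful fit below that. Background
(microbial) respiration is not corrected for; if it matters it biases rates
additively and should be handled upstream.

## The synthetic-data generator

`simulate_trait_panel()` emulates the study design: two populations of 40
individuals; four behavioural traits measured twice per ontogenetic stage
(two stages, trials one week apart in the real design); SMR, standard size
and Fulton's condition factor once per stage; sex balanced and coded
$\pm0.5$; individual-level attrition after stage 1 at rates 0.2 and 0.025
(mirroring an overnight mortality event of 8/40 and 1/40 fish). Defaults for
the variance components and fixed effects are the reported univariate
estimates on the standardized scale; the slow-growing population's
among-individual correlation structure is a single-factor pace-of-life axis
with pairwise correlations of $\pm0.6$ over the four syndrome traits
(mass-specific SMR loading opposite to size and activity), the fast-growing
population's structure is diagonal, and the two non-repeatable behaviours are
generated with near-zero among-individual variance so the repeatability gate
has something to exclude. One residual correlation is built in: $-0.4$
between mass-specific SMR and size, the one robust within-individual
correlation reported.

Residual draws are joint across traits sharing an occasion and independent
across occasions — exactly the structure the estimator assumes. Behavioural
trials are conditionally independent given the individual effect; the
generator does not emulate serial correlation between trials, habituation
across repeated testing, non-Gaussian trait distributions, or record-level
missingness (attrition removes whole individuals after stage 1, matching the
mortality event, not random holes). Passing recovery tests on these panels
therefore demonstrates correctness of the estimator under its assumed model,
not robustness to violations of it.

`simulate_respirometry_trace()` generates overnight traces (default 12 h of
180 s open / 420 s closed cycles, 5 s sampling, saturation 8.6 mg L$^{-1}$,
a 20 mL chamber for a 0.5 g fish — roughly the 10–50× fish-volume ratio
used in practice — and 0.01 mg L$^{-1}$ optode noise, which puts closed-phase
$R^2$ near 0.99 for a resting slope of 0.125 mg L$^{-1}$ min$^{-1}$, i.e.
300 mg O$_2$ kg$^{-1}$ h$^{-1}$ mass-specific):
each closed phase is resting or active by a Bernoulli draw, declines linearly
at the corresponding slope plus Gaussian sample noise, and open phases relax
exponentially toward saturation. Ground-truth states and slopes ride along so
filters and the mixture can be scored exactly.

## Pipeline order and the repeatability gate

`run_pols_pipeline()` follows the analysis order of the study design: mean
comparisons first (life-history traits by linear models at the latest stage
measured; behaviour and SMR by mixed models with size and condition as
covariates, reported as estimated marginal means at the covariate reference
grid — centred covariates at their mean, coded factors at 0); then
per-population repeatability; then the multivariate stage restricted to
traits whose repeatability LRT is significant at the gate level (default
$\alpha = 0.05$) in *every* population; then element-wise, overall and
cross-population covariance tests. Every exclusion and boundary event is
logged in the report, all randomness derives from the single config seed, and
every reported p-value can be regenerated from its stored statistic and
mixture specification alone.

Element-wise covariance p-values are reported unadjusted — each pair is a
separate biological hypothesis in this design — and the global structure test
is the protection against over-interpreting any single pair.

## Worked example

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
panel <- simulate_trait_panel(cfg)
tr <- c("hiding_time", "distance_moved", "standard_size", "smr")

rep_tab <- repeatability_table(panel, tr)
dec <- pols_decompose(panel, tr, population = "SG")
test_overall_structure(panel, tr, population = "SG")
test_population_equality(panel, tr)
```

## Problem sizes and known limitations

Replicated studies in the test suite use the study scale (40 individuals per
population, 4/2/2 measures) with 100 replicates for correlation recovery and
2000 null replicates for each LRT calibration; single fits of the four-trait
model take a couple of seconds on one core. Limitations worth knowing:

* no pedigree or relatedness structure: "among-individual" conflates genetic
  and permanent-environment variance;
* no temporal autocorrelation or random slopes; ontogenetic stage enters the
  mean only;
* asymptotic and bootstrap SEs for correlations are rough near $\pm1$ or near
  boundary variances;
* fixed-effect denominator df are a containment approximation;
* the EM mixture assumes exactly two metabolic states; strongly trimodal
  activity patterns would inflate the lower mean;
* background respiration in the chambers is not modelled.
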