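---
title: "Comparing multiple-imputation methods for incomplete longitudinal covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multiple-imputation methods for incomplete longitudinal covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmi)
```

## The problem

Longitudinal cohort studies routinely lose covariate measurements wave by
wave, and the analyst must choose among a dozen multiple-imputation (MI)
strategies whose assumptions about the repeated-measures structure differ
substantially: wide-format joint models that treat each wave as a distinct
variable, chained equations conditioning on all (or only neighbouring)
waves, and multilevel samplers that model the within-subject correlation
explicitly. **longmi** provides a controlled environment for comparing
these strategies: a synthetic six-wave child cohort with known generating
parameters, a calibrated missing-at-random (MAR) amputation mechanism,
eight from-scratch MI engines, two analysis models, Rubin's-rules pooling,
and a replicated evaluation harness reporting bias, empirical and
model-based standard errors, and coverage.

## The synthetic cohort

`generate_cohort()` simulates subjects sequentially, mimicking the
structure of a six-wave national child cohort with two-year spacing:

1. baseline binaries — sex, English as the main home language, and
   mother's completion of year 12 — from Bernoulli(0.5), (0.9), (0.6);
2. age in months at wave $j$:
   $\mathrm{age}_{ij} = 48 + 24(j-1) + u_i + v_{ij}$, with
   $u_i \sim N(11, 1.5)$ the recruitment-age intercept and
   $v_{ij} \sim N(0, 2)$ interview-timing noise from wave 2 on; ages are
   divided by 12 and never rounded;
3. a single-parent indicator from a logistic mixed model,
   $\mathrm{logit}\,P(\mathrm{FamStruc}_{ij}=1) = -6.9 + 0.15\,
   \mathrm{ageyr}_{ij} + 0.62\,\mathrm{language}_i - 1.9\,\mathrm{moedu}_i
   + \xi_{0i}$, $\xi_{0i} \sim N(0, 5.5)$;
4. baseline socio-economic position
   $\mathrm{SEP}_{i} = -0.5 + 0.94\,\mathrm{moedu}_i -
   0.45\,\mathrm{FamStruc}_{i1} + \tau_i$, $\tau_i \sim N(0, 1.2)$;
5. the BMI z-score exposure from a random-intercept linear mixed model
   (intercept 0.53; slopes $-0.012$ on age, $-0.008$ on sex, $0.07$ on
   family structure; between-subject variance 0.9, residual 0.6);
6. the QoL z-score outcome from a random-intercept linear mixed model
   (intercept $-0.04$; slopes $0.05$ sex, $-0.02$ age, $-0.12$ BMIz,
   $-0.2$ FamStruc, $0.20$ language, $0.09$ SEP; between-subject variance
   0.7, residual 0.7).

All second distribution arguments are interpreted as **variances**. Because
the notation $N(a, b)$ is ambiguous in parts of the methodological
literature, `gen_params(second_param_is_sd = TRUE)` switches every
dispersion argument to a standard deviation; the variance reading is the
default because it makes the implied intra-cluster correlations (0.5 for
QoL, 0.6 for BMI) plausible for child-cohort z-scores.

The generator's closed-form moments are available from
`analytic_moments()` and anchor the Monte-Carlo tests:

```{r moments}
analytic_moments(gen_params())$qolz
```

What the generator deliberately does *not* emulate: survey sampling
weights, re-contact of dropouts, multi-category family structures, or
secular trends in adiposity. Passing tests therefore demonstrate correct
behaviour under a clean random-intercept data-generating process, not
robustness to the messier features of real cohort data.

## The missingness mechanism

`calibrate_intercepts()` + `apply_mar()` mask the BMI z-score at all waves
and the family-structure indicator at waves 2–6, each cell independently,
with logistic probabilities driven by always-observed quantities: age and
the same-wave QoL z-score for BMI, baseline family structure and the
same-wave QoL z-score for the single-parent indicator. The mechanism is
MAR by construction. Per-wave target proportions (defaults
0.01/0.06/0.10/0.15/0.19/0.28 for BMI and 0/0.06/0.08/0.10/0.15/0.24 for
family structure) are hit by solving for each intercept with monotone
root-finding so that the mean logistic probability over a calibration
cohort equals the target to $10^{-6}$.

The slope defaults ($0.1$ per year of age, $-0.4$ per QoL z-score unit,
$0.5$ on baseline single-parenthood) are package choices: signs were fixed
once so that poorer quality of life predicts more missingness, emulating
health-related dropout, and magnitudes were set to moderate values on the
z-score scale. They are configurable via `mar_model()`. A consequence
worth knowing: at this signal strength, complete-case ("available data")
estimates of the model-2 slopes for the incomplete predictors are only
very mildly biased — the selection mostly distorts the intercept and the
age coefficient — so contrasts between complete-case analysis and MI are
correspondingly subtle at this calibration. Stronger outcome-dependence
(e.g. slope $-2$) produces the textbook complete-case bias and can be
requested through `mar_model()`.

Cell-level independent masking matches the per-wave logistic models; a
`monotone_dropout` option instead propagates a mask to all later waves,
emulating attrition.

## The imputation engines

All engines impute the BMI z-score (all waves) and family structure
(waves 2–6), conditioning on age at wave 1, sex, SEP, home language,
wave-1 family structure, and the QoL z-score at all six waves. Each
returns `m` completed datasets; observed cells are preserved bit-exactly.

* **JM-MVN** — data augmentation under an unstructured multivariate
  normal on the wide matrix. I-step: missing cells drawn per missingness
  pattern from their conditional normal; P-step: $(\mu, \Sigma)$ from the
  normal–inverse-Wishart posterior under a Jeffreys-type prior. A single
  chain; imputations kept every `between_draws` iterations after
  `burn_in`. Binary variables are imputed as continuous.
* **FCS-Standard** — chained equations on the wide matrix; continuous
  targets by Bayesian linear-regression draws, binary targets by logistic
  regression with an approximate normal posterior draw; each imputation is
  an independent chain initialised from the observed marginals.
* **FCS-MTW / FCS-Twofold** — as FCS-Standard but univariate models at
  wave $t$ condition only on wave-varying measurements within `window`
  waves of $t$ (default 1) plus baseline covariates; the twofold variant
  nests `within_time_iters` iterations per time block inside each sweep.
* **JM-MLMM** — a joint bivariate linear mixed model on the long data:
  Gibbs cycles over the fixed-effect matrix, per-subject bivariate random
  intercepts, inverse-Wishart draws of the random-effect and residual
  covariances, and conditional-normal draws of missing responses.
* **FCS-LMM** (+ `-het`, `-PMM`) — chained equations whose univariate
  models are two-level samplers with a subject random intercept. The
  heteroscedastic variant adds random slopes for all predictors and
  per-subject residual variances drawn from scaled inverse-$\chi^2$ full
  conditionals (Kasim–Raudenbush); the PMM variant copies, for each
  missing row, the observed value of one of the `pmm_donors` donors with
  nearest model-predicted mean.

Two engines described in the comparative literature — chained equations
with logistic GLMMs and the FCS-embedded latent-normal multivariate
sampler — are excluded: both cost roughly two orders of magnitude more
compute per imputation than the engines above, which makes them
impractical in the replicated design this package targets. Latent-normal
probit variants of the multilevel engines are a possible extension but are
not implemented.

### Numerical choices

* Priors: Jeffreys for JM-MVN; inverse-Wishart with df = dimension and
  identity scale for the multilevel covariances (`prior_df`,
  `prior_scale`).
* The logistic "posterior draw" is the standard chained-equations device
  (penalised MLE plus an asymptotic-normal perturbation) with a ridge
  $\lambda = 10^{-4}$ guarding perfect separation; the linear draws add a
  relative ridge $10^{-5}$ against collinearity, and JM-MVN falls back to
  a ridged covariance with a logged message if a pattern's observed block
  is singular.
* Visit order for chained equations is fixed and documented: waves
  ascending, BMI before family structure within a wave.
* Iteration defaults: `burn_in = 200`, `between_draws = 100` for the JM
  chains; `fcs_cycles = 10` independent cycles per FCS imputation;
  `within_time_iters = 2` for the twofold variant;
  `gibbs_iters_per_visit = 10` for the two-level univariate samplers.
  These are conventional magnitudes, configurable in `mi_config()`, and
  recorded in the imputation-set manifest.
* Parameter traces are stored in `imputation_set$diagnostics`; no
  automatic convergence test is applied.
* Degenerate inputs: a cohort with no missing cells short-circuits to `m`
  identical copies; a subject with fewer than two observations falls back
  to the pooled residual variance in the heteroscedastic sampler (logged).

## Analysis models and pooling

Model 1 (`fit_model1()`) regresses the wave-6 QoL z-score on
cumulative-exposure categories — the number of waves 1–5 with BMI z-score
at or above `zcut`, and with single-parenthood, each categorised as
none/1/2/3–4/5 — plus age at wave 6, sex, SEP and language. The default
`zcut = 1.04` ($\approx$ the 85th percentile of a standard normal) stands
in for age-and-sex-specific overweight cut-offs, which require external
reference tables; the same threshold is used for truth computation and
every analysis, so comparisons are internally consistent. Where an engine
imputes the binary indicator on the continuous scale, values are converted
by **adaptive rounding** (cutoff
$\bar\omega - \Phi^{-1}(\bar\omega)\sqrt{\bar\omega(1-\bar\omega)}$) on
this path only; model 2 uses the unrounded values, since rounding can bias
mixed-model coefficients.

Model 2 (`fit_model2()`) is a random-intercept linear mixed model of the
QoL z-score on BMI z-score, age, sex, SEP, language and family structure,
fitted by REML via `lme4`. Because it coincides with the
outcome-generating model, its true coefficients are known exactly; model-1
truth is instead computed by `compute_truth_model1()` from a large
generated population (default $10^6$ subjects, chunked; $10^7$ at full
scale). One printed formulation of model 1 lists the sex term twice and
omits SEP from the formula while naming SEP in the adjustment set; the
package fits a single sex coefficient plus SEP.

`pool_rubin()` implements the classic combining rules
($\bar Q$, $W$, $B$, $T = W + (1 + 1/m)B$,
$\nu = (m-1)(1 + W/((1+1/m)B))^2$) with the Barnard–Rubin small-sample df
available via `dfcom` — the classic formula is the default because the
reference analyses do not state which was used. Intervals for unpooled
(complete/available) fits are t-based on the residual df.

## The evaluation harness

`run_study()` runs the full replicated design: per replicate, generate →
ampute (with intercepts calibrated once, on a separate 10 000-subject
calibration cohort, so the mechanism is fixed across replicates) → impute
with each requested engine → fit both models on every completed dataset →
pool → also fit the complete-data and available-data comparators.
`performance()` turns the tidy estimates into bias, empirical SE, average
model SE, coverage and Monte-Carlo errors; `report()` writes the
bias-distribution boxplots and coverage dot-plots (with the 0.95 reference
line) plus CSV tables. Engine failures are caught, flagged, and do not
halt the study; metrics are invariant to replicate order; per-replicate
caching makes long runs resumable.

Scale defaults are desk-sized — `K = 200` replicates, `n = 1000` subjects,
`m = 10` imputations, model-1 truth at $N = 10^6$ — chosen so a full
single-method study runs on one CPU in minutes. `study_config(full_scale
= TRUE)` switches to the headline design (`K = 1000`, `n = 5000`,
`m = 40`, truth at $10^7$), which across eight engines is a cluster-sized
computation. The package's own verification (tests and the acceptance
script) uses the desk scale: cohort-moment checks at $n = 10^5$,
parameter-recovery averages over 100 cohorts of $n = 2000$, coverage runs
at $K \le 200$, and directional method comparisons at $K = 40$–200 with
explicitly computed Monte-Carlo error bands.

## Reproducibility

Every randomised function takes a `seed` and restores the caller's RNG
state. One master seed spawns labelled substreams
(`derive_seed(seed, "stage", r)`) so that adding a method or replicate
never perturbs the draws of another — a property the determinism tests
assert directly.

## Known limitations

* The generator and engines handle exactly the variable roles above;
  arbitrary user-specified imputation models, interactions, survey weights
  and multi-category variables are out of scope.
* The binary indicator is modelled as continuous inside the JM and LMM
  engines (as their reference implementations do); only the chained
  logistic engine and PMM produce natively binary imputations.
* Missingness in the outcome is deliberately excluded to keep the
  mechanism MAR; MNAR sensitivity analysis is not provided.
* At the default MAR signal strength the complete-case bias on incomplete
  predictors' model-2 slopes is small (see above), so method contrasts on
  those terms require large `K` to resolve.

```{r example, eval = FALSE}
# a small end-to-end study
cfg <- study_config(methods = c("complete", "available", "FCS-Standard",
                                "JM-MVN"),
                    K = 50, n = 1000, m = 10, seed = 2024)
st <- run_study(cfg, progress = TRUE)
report(st, dir = "longmi-report")
subset(st$summary, model == 2 & term == "BMIz")
```
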