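---
title: "Methods: counterfactual mediation of APOE e4 effects through brain-MRI markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual mediation of APOE e4 effects through brain-MRI markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the estimand

Carriers of the APOE e4 allele decline cognitively faster and develop
dementia more often than non-carriers. A natural mechanistic question is how
much of that effect travels through measurable brain pathology — hippocampal
atrophy, cortical thinning in the Alzheimer-signature regions, white matter
hyperintensities (WMH), cerebral microbleeds — and how much takes other
paths. `apoemed` answers this with a counterfactual mediation decomposition.

With exposure $A$ (e4 carrier, 1 vs 0), mediator $M$, outcome $Y$ and
confounders $C$, the total effect of the contrast $a = 1$ vs $a^\* = 0$
splits into two non-overlapping components,

$$\mathrm{TE} = \underbrace{E[Y(a, M(a^\*))] - E[Y(a^\*, M(a^\*))]}_{\text{natural direct effect (NDE)}}
 + \underbrace{E[Y(a, M(a))] - E[Y(a, M(a^\*))]}_{\text{natural indirect effect (NIE)}},$$

and the proportion mediated is $\mathrm{PM} = \mathrm{NIE}/\mathrm{TE}$ on
the difference scale. For a rare binary outcome the same decomposition is
multiplicative on the odds-ratio scale,
$\mathrm{OR_{TE}} = \mathrm{OR_{NDE}} \times \mathrm{OR_{NIE}}$, and PM uses
the excess-odds-ratio form
$\mathrm{OR_{NDE}}(\mathrm{OR_{NIE}}-1)/(\mathrm{OR_{NDE}}\,\mathrm{OR_{NIE}}-1)$.
These require the usual mediation identification assumptions: no unmeasured
exposure–outcome, mediator–outcome, or exposure–mediator confounding given
$C$, and no mediator–outcome confounder itself affected by exposure.

## The regression-based estimator

Two regressions are fitted on the analysis sample:

* mediator model: $M$ on $A$ and $C$ (linear for continuous markers,
  logistic for the binary microbleed-burden indicator), coefficients
  $(\beta_0, \beta_1, \beta_2)$ and residual SD $\sigma$;
* outcome model: $Y$ on $A$, $M$, $A \times M$ and $C$ (linear or
  logistic), coefficients $(\theta_0, \ldots, \theta_4)$. The
  exposure–mediator interaction $\theta_3$ is always estimated, never
  assumed away.

Closed-form natural effects are then assembled for the four link
combinations. For instance, with both models linear,
$\mathrm{NDE} = (\theta_1 + \theta_3(\beta_0 + \beta_1 a^\* + \beta_2^\top c))(a - a^\*)$
and $\mathrm{NIE} = (\theta_2\beta_1 + \theta_3\beta_1 a)(a - a^\*)$; with a
binary mediator the mediator mean $\mathrm{expit}(\beta_0 + \beta_1 x +
\beta_2^\top c)$ replaces the linear predictor; with a rare binary outcome
the same ingredients produce log-odds-ratio analogues, including the
Gaussian-mediator correction terms $\theta_2\sigma^2$ and
$\tfrac12\theta_3^2\sigma^2(a^2 - a^{*2})$. Per-subject conditional effects
are averaged over the empirical confounder distribution of the analysis
sample (evaluation at confounder means is available via
`confounder_reference = "means"`; the averaged version is the default
because it targets a population-averaged estimand and requires no choice of
reference covariate values). On the odds-ratio scale the *log* odds ratios
are averaged, which preserves the multiplicative decomposition identity
exactly.

The rare-outcome approximation is what turns logistic-regression odds
ratios into the natural-effect odds ratios; it degrades as the outcome gets
common. The package enforces a hard guard at 10% outcome prevalence
(override with `rare_ok = TRUE`, which downgrades the rejection to a
warning). A dementia cumulative incidence near 6% is comfortably inside the
valid regime.

## Multiple mediators

For mediator sets (e.g. WMH + microbleeds) no closed form is attempted.
Instead `joint_natural_effects()` uses Monte-Carlo g-computation: for every
subject's confounder row, the mediator vector is drawn from its fitted
conditional distribution under $a$ and under $a^\*$, pushed through the
fitted outcome model (with all mediators and all exposure–mediator
interactions), and the three counterfactual means are averaged. Mediators
are modelled conditionally independent given exposure and confounders: no
causal ordering among the imaging markers is assumed, and the joint
estimand only needs the joint mediator law, which this factorisation fixes.
Common random numbers across the two exposure levels remove mediator noise
from every contrast in which it cancels (for continuous mediators the
$k = 1$ joint decomposition therefore equals the closed form to machine
precision). The default of `mc_draws = 5` per subject is deliberate: with
the per-subject average taken over the whole sample, the residual
Monte-Carlo standard error is orders of magnitude below sampling error.
Binary-outcome joint effects are computed on risks and converted to odds
ratios directly — the rare-outcome shortcut is not needed in this engine.

## Inference

Confidence intervals are percentile bootstrap over subjects (default
$B = 1000$): both model stages are refitted on every resample, so the CI
reflects the full estimation pipeline. Percentiles use inverse-ECDF
(type-1) quantiles — the one choice under which pooling $m$ identical
replicate sets across imputations leaves the interval exactly unchanged,
which makes the imputation-no-op invariant hold to machine precision. Two-sided p-values come from the
bootstrap distribution, $p = 2\min(\#\{\hat\theta^\*_b \le 0\} + 1,
\#\{\hat\theta^\*_b \ge 0\} + 1)/(B+1)$, with the null at 0 on the
difference scale and at $\log = 0$ on the odds-ratio scale. The p-value
reported for PM is the p-value of the NIE — PM is a ratio whose sign-based
test is meaningless when the TE is near zero. Replicates on which a model
fails (e.g. a quasi-separated logistic fit in a small stratum) are dropped;
more than 1% failures rejects the whole run rather than silently averaging
over a biased subset. PM is reported even when NDE and NIE have opposite
signs — the value can then fall outside [0, 1] and is flagged via the
`opposite_signs` attribute rather than suppressed.

Missing covariables (never exposure, mediators, or outcomes) are completed
by fivefold chained-equations imputation: 10 cycles of conditional linear /
logistic models with predictive draws. Ten cycles is far past practical
convergence for the ~1% missingness rates this package targets. Pooling
follows a draws-pooling rule: point estimates are averaged across the $m$
imputations (log scale for odds ratios, so the multiplicative identity
survives pooling) and the bootstrap replicate draws are concatenated across
imputations before taking percentiles, so between-imputation variability
widens the interval. Whether the bootstrap should be nested within or
across imputations is not prescribed by the method literature for this
design; pooling draws across imputations is one defensible choice and is
applied uniformly. On complete data the whole imputation layer is exactly a
no-op (a tested invariant).

## Preprocessing conventions

* WMH volumes are strictly positive by construction and are
  log-transformed (`ln_transform_wmh()` rejects non-positive values rather
  than applying a silent offset — a zero indicates an upstream
  segmentation failure).
* ln-WMH, hippocampal volume, and Alzheimer-signature cortical thickness
  are Z-standardised (denominator $n-1$) on the analysis sample after
  exclusions; standardised mediators are never missing, so the
  standardise-then-impute order is immaterial. The full analysis sample is
  used (whether the source study standardised on the MRI sample or the
  cognition subsample is unstated; the full sample is the more stable
  choice).
* Microbleeds enter as the indicator of $\ge 2$ bleeds; a lobar-only
  variant is available as a sensitivity analysis.
* Global cognition is the g-factor: the first unrotated principal
  component of the Z-standardised test battery (Stroop, word fluency,
  letter-digit substitution, 15-word verbal learning, Purdue pegboard).
  Standardising before extraction stops high-variance tests from dominating
  the component. Reverse-coded tests (Stroop completion time: higher =
  worse) are negated first so loadings are interpretable; the component
  sign is anchored by a positive loading on the memory test (15-WLT), so a
  higher g-factor always means better cognition. Subjects with an
  incomplete battery are excluded from cognition analyses, not imputed,
  mirroring a complete-assessment subsample design; dementia analyses use
  the full sample. Test scores are not age/sex-residualised before
  extraction (the source design does not state such a step; confounders
  enter the mediation models instead).
* The age-equivalent conversion divides the exposure coefficient on
  cognition by the per-year age coefficient and multiplies by 12, giving
  "months of cognitive ageing".

## The synthetic cohort and the truth oracle

No subject-level data from the motivating cohort are distributable, so the
package carries its own stated world. `default_dgp_config()` encodes a
Rotterdam-like population: carrier prevalence 28.3%; age $N(65.0,
10.9^2)$; 55% women; four-level education; three-level smoking; BMI, SBP,
non-HDL cholesterol, medication, diabetes, atrial fibrillation, stroke and
intracranial volume with published-table marginals; hippocampal volume
$7.8 \pm 0.9$ ml; cortical thickness $2.5 \pm 0.1$ mm; WMH lognormal with
median 3.1 ml ($\sigma_{\log} = 0.6$, a free parameter since a printed IQR
under-determines a lognormal); microbleed burden ($\ge 2$) at 7.4% vs 10.2%
by carriership. Effect sizes are calibrated so that the carrier total
effect on the cognition Z-score is about $-0.02$ with roughly 25% mediated
by microbleeds and 12% by WMH, and the dementia odds ratio about 2.3 at ~6%
cumulative incidence. Deliberate simplifications, hence what a green test
does *not* establish: confounders are mutually independent (no joint
distribution is published; correlation is not emulated), dementia is a
logistic event with a uniform event time rather than a hazard process
(matching the odds-ratio analysis framing — the source reports the same
contrast as both HR and OR, and the logistic framing is followed), and
missingness is MCAR at the published covariable rates (the true mechanism
is unstated). Microbleed counts are zero-inflated counts consistent with
the calibrated $\ge 2$ prevalence; only the dichotomy is scientifically
load-bearing.

Columns are drawn in causal order, each from a named RNG substream hashed
from the single global seed, so extending a config never perturbs
previously generated columns — a property the determinism tests pin down.

`counterfactual_oracle()` is the package's independent validation
standard: it simulates $Y(a, M(a))$, $Y(a, M(a^\*))$, $Y(a^\*, M(a^\*))$
directly from the structural equations (fresh confounder and mediator
noise, conditional outcome means rather than outcome noise) and reports
difference-scale and odds-ratio-scale truths with batch-based Monte-Carlo
standard errors (20 batches). It shares no code path with the
regression-based estimator. Mediators outside the analysed set are held at
the exposure level of the outcome's own argument, i.e. counted as part of
the direct path; the validation DGPs only declare the analysed mediators,
so nothing in the test surface depends on this convention.

## Calibrated acceptance worlds

`calibration_dgp()` ships four fixed DGPs whose truths are hand-computable
(documented on its help page): a binary-mediator cognition world
(TE $-0.020$, PM 25%), a rare-outcome dementia world (marginal OR 2.345,
OR$_{\mathrm{NIE}}$ 1.030, PM 5.07%), a two-mediator world (joint PM 27%)
and a continuous-mediator world (PM 12%). Parameter recovery on these at
$n = 4{,}000{,}000$ is the acceptance surface; `scripts/acceptance.R`
recomputes all of it from scratch.

## Numerical choices and degenerate inputs

* Decomposition identities (TE = NDE + NIE; OR: TE = NDE × NIE) hold to
  machine precision by construction and are asserted to $10^{-10}$.
* PM with a numerically null TE ($|$TE$| < 10^{-8}$, or $|\log$ TE$|$ on
  the OR scale) is returned with a warning and an `unstable` flag, not
  rejected.
* Model fits reject rank-deficient designs by name and logistic fits that
  fail to converge or diverge ($|\hat\beta| > 100$); quasi-separated but
  converged fits are allowed — they occur legitimately in bootstrap
  resamples of small strata and are handled by the bootstrap's failure
  accounting instead.
* Joint mediator sets are rejected when the mediator correlation matrix
  has condition number above $10^6$ (catches duplicated markers).
* Sensitivity strata below 100 subjects or 10 events (configurable) are
  marked `underpowered` and skipped rather than estimated noisily.
* Bootstrap seeds, imputation seeds and g-computation seeds all derive
  from one study seed via named substreams; rerunning any pipeline with
  the same seed is byte-identical, and report files contain no timestamps
  for the same reason.

## Known limitations

The estimator inherits the identification assumptions of natural effects;
unmeasured mediator–outcome confounding inflates PM. The rare-outcome OR
decomposition is an approximation (the multi-mediator engine avoids it by
working on risks). The synthetic world is a marginal-distribution emulator:
it validates estimator correctness and pipeline plumbing, not findings
about any real population. Survival/hazard mediation, exposure–confounder
interaction, and path-specific effects among mediators are out of scope.
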