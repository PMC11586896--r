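---
title: "Subgroup-specific optimal biological dose finding: models, priors and design"
author: "obdsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgroup-specific optimal biological dose finding: models, priors and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phase I/II trials of immunotherapies and targeted agents aim for the
*optimal biological dose* (OBD) — the dose with the best trade-off between
a binary efficacy response and a binary dose-limiting toxicity (DLT) —
rather than the classical maximum tolerated dose, because efficacy can
plateau while toxicity keeps rising.  When two prespecified patient
subgroups (for instance, large versus small tumors) may differ in their
dose-toxicity or dose-efficacy curves, an investigator must otherwise
choose between running one pooled trial (efficient, but mis-doses one
subgroup if the curves differ) or two independent trials (robust, but
wasteful if the curves coincide).  `obdsub` implements a Bayesian
adaptive design that makes this choice from the data, using
spike-and-slab priors on all subgroup effects.

## Dose-outcome models

Raw doses $\delta_1 < \dots < \delta_J$ are standardized to centered
natural-log doses $d_j = \log\delta_j - J^{-1}\sum_q \log\delta_q$.  The
natural log is used (the base is not identified by anything else in the
model; a different base only rescales the slope coefficients).  The
binary subgroup label $k \in \{0,1\}$ enters through the contrast code
$x_k = 2k - 1 \in \{-1, +1\}$, which makes subgroup effects symmetric
deviations and mixes better than 0/1 coding.

With $\pi_{kE}(d)$ and $\pi_{kT}(d)$ the efficacy and toxicity
probabilities,

$$\mathrm{logit}\,\pi_{kE}(d) = \beta_{E,0} + \beta_{E,1} d +
\beta_{E,2} d^2 + x_k(\beta_{E,3} + \beta_{E,4} d + \beta_{E,5} d^2),$$

$$\mathrm{logit}\,\pi_{kT}(d) = \beta_{T,0} + \beta_{T,1} d +
x_k(\beta_{T,2} + \beta_{T,3} d).$$

Efficacy is quadratic in dose so non-monotone and plateauing curves are
expressible; toxicity is linear, reflecting the monotonicity expected of
DLT rates.  The five subgroup coefficients ($\beta_{E,3..5}$,
$\beta_{T,2..3}$) carry spike-and-slab priors
$\beta \mid \gamma \sim \gamma\,N(0, 2.5^2) + (1-\gamma)\,\delta_0$,
$\gamma \sim \mathrm{Bernoulli}(0.5)$: when the data look homogeneous
the indicators switch the subgroup terms off and both subgroups' data
estimate one shared curve; when they do not, subgroup-specific curves
emerge.  Inverse logits clip the linear predictor at $\pm 35$, since
MCMC can visit extreme coefficients.

## Prior calibration

Non-subgroup coefficients get weakly informative priors calibrated to an
elicited schedule of mean outcome probabilities and a target prior
effective sample size (ESS):

1. prior means solve a least-squares fit of the linear predictor (at
   $x=0$) to the logit of the elicited probabilities over the dose grid;
2. a single shared prior sd for the non-subgroup coefficients is found
   by bisection so that the Monte-Carlo prior ESS hits the target.  The
   ESS is computed by drawing coefficients from the prior, evaluating
   $\pi$ at every dose (at $x=0$), moment-matching each $\pi$'s prior to
   a Beta$(a,b)$, and averaging $a+b$ over doses and both outcomes.
   Common random numbers across candidate sds make the ESS exactly
   monotone in the sd, so the bisection is well posed;
3. because the mean of a logit-normal distribution drifts toward 0.5 as
   its spread grows, a raw logit-scale fit misses the elicited *means*
   at a very diffuse target such as ESS 0.9.  `calibrate_prior`
   therefore runs a few mean-correction sweeps: it measures the drift,
   shifts the logit targets by it, refits the means and re-bisects the
   sd (4 sweeps by default; the fixed-point is reached in 2-3).

With the default elicitation ($\pi_E = (0.3, 0.5, 0.6, 0.65, 0.7)$,
$\pi_T = (0.05, 0.1, 0.15, 0.2, 0.25)$ on the $\{0.2,\dots,1\}$ grid,
ESS 0.9) the calibrated prior reproduces every elicited mean within
$\pm 0.05$ and the ESS within $\pm 0.01$.  Subgroup coefficients always
use mean 0, sd 2.5 and inclusion probability 0.5 — the published
recommendation for all five, including the $x d^2$ efficacy interaction.

## Posterior computation

`sample_posterior` runs a single-chain Gibbs sampler with Pólya-Gamma
data augmentation: given $\omega_i \sim \mathrm{PG}(1, x_i'\beta)$ the
Bernoulli-logit likelihood is conditionally Gaussian in $\beta$.  Each
inclusion indicator is updated from its exact conditional with the slab
integrated out against the PG-augmented Gaussian form, and excluded
coefficients are held at exactly zero (point-mass spike).  The PG(1, z)
variates come from the alternating-series rejection sampler of Devroye,
which is exact (no truncation approximation); its per-z setup is shared
across observations with the same dose and subgroup.  With zero
observations the function returns draws from the prior, which is also
how the first cohort's decisions are regularized.  Defaults are 5000
burn-in and 15 000 kept draws, no thinning; both are configurable and
the simulation harness uses much shorter chains (below).

## Utility, admissibility and dose selection

The four joint outcomes are scored by a utility table with anchors
$\nu_{1,0} = 100$ (efficacy without toxicity) and $\nu_{0,1} = 0$; the
default free values are $\nu_{0,0} = 40$ and $\nu_{1,1} = 60$, encoding
that response matters more than avoiding a DLT.  Expected utility uses
the independence working model
$U = \sum_{a,b} \nu_{a,b}\,\pi_E^a(1-\pi_E)^{1-a}\pi_T^b(1-\pi_T)^{1-b}$;
per-dose probabilities are point-estimated by the MAP of the per-draw
probability cloud (Gaussian KDE, Silverman bandwidth, 512-point lattice
on $[0,1]$ with boundary reflection, clamped to the draw range).  A
posterior-mean plug-in is available (`estimator = "mean"`), but the MAP
variant selects markedly better in simulation and is the default.

Dose $j$ is *admissible* for subgroup $k$ when it passes

* Condition 1 (safety): $P(\pi_{kT}(d_j) < \bar\pi_T) > p_T$;
* and either Condition 2a (efficacy): $P(\pi_{kE}(d_j) > \underline\pi_E)
  > p_E$ with $j$ already tried, or Condition 2b (escalation): $j$ is
  exactly one level above the highest tried dose.

Defaults $\bar\pi_T = 0.35$, $\underline\pi_E = 0.3$, $p_T = p_E = 0.1$.
Inequalities are strict, as printed.  At the final analysis only
Conditions 1 and 2a count, so an untried dose cannot be declared the
OBD.  Each open subgroup is assigned the admissible dose maximizing
estimated utility, ties broken toward the lower dose (conservative
dosing; the choice is otherwise arbitrary).  The tried set is kept per
subgroup — admissibility is subgroup-indexed, so escalation bookkeeping
follows the subgroup once model-based assignment begins — with a pooled
option (`pool_tried`) for sensitivity analyses.

## Trial structure

Participants enroll in cohorts of two, one per subgroup (an unrestricted
composition mode draws labels i.i.d. Bernoulli(0.5)).  A rule-based
run-in mimics 3+3 escalation while the model would still be unstable:
the first cohort gets the lowest dose, both subgroups share a dose, and
the dose escalates exactly one level after a cohort only when no DLT has
occurred at the current dose, or at least six have been treated there
with at most one DLT.  The run-in lasts a fixed, configurable number of
cohorts (default 3).  The published flow diagram for the run-in is only
available graphically; a fixed-length run-in with the textual
escalation rule is the cleanest codification consistent with every
stated constraint, and the length is exposed in the configuration.  With
the run-in disabled entirely, the empty tried set means Condition 2b
admits only the lowest dose, so a cold-started trial still begins at the
bottom of the grid.

Model-based assignment then refits both posteriors on all accumulated
data before every cohort, computes utilities and admissible sets, and
assigns each subgroup its admissible utility maximizer.  A subgroup with
an empty admissible set closes (no enrollment) and is re-evaluated
before every subsequent cohort; while one subgroup is closed, cohorts of
size one come from the open subgroup.  If both admissible sets are
empty the trial stops and no dose is acceptable for either subgroup.
Enrollment is capped at 30 per subgroup (60 total).  At the end, each
subgroup's OBD is its admissible (final rule) utility maximizer, or
none.

## Comparison designs and scenarios

The pooled design fits the same models without subgroup terms to the
combined data and selects one common OBD; the independent design runs
two disjoint single-subgroup trials (30 each, cohorts of two from the
same subgroup, reduced models, separate random streams).  Both reuse
the run-in, admissibility and utility machinery.

`build_scenario_suite()` provides eight synthetic truths on the
five-dose grid spanning the classes that matter for the comparison:
identical curves in both subgroups (1, 5, 6 — OBD at the top, a low
dose, and a mid-grid plateau respectively); subgroup-specific curves
with different OBDs (2, 3, 7 — scenario 3 places one subgroup just
outside the acceptability thresholds so *no* dose is acceptable there,
and scenario 7 is tabulated without any model form); and
subgroup-specific curves with a common OBD (4, 8), scenario 8 adding
positive efficacy-toxicity correlation through conditional efficacy
curves given DLT status (the marginals then satisfy
$\pi_E = \pi_{E|1}\pi_T + \pi_{E|0}(1-\pi_T)$ exactly).  The published
scenario curves exist only as figures, so these are analogues matching
each scenario's qualitative description, with anchor probabilities
chosen once for clear class margins; outcomes are Bernoulli draws from
the tabulated truths.  What the generator does *not* emulate: accrual
over time, partial follow-up, non-binary endpoints, or drift in
outcome probabilities — conclusions from these simulations speak to
design behavior under clean binary outcomes, not to those
complications.

## Study sizes and numerical choices

The operating-characteristics harness (`run_study`) derives one seed per
scenario-replicate pair and shares it across designs (common random
numbers), so design contrasts are paired; every proportion carries a
binomial standard error.  The packaged studies use 200-500 replicates
per scenario and design with 100 burn-in / 250 kept draws per refit —
about 55 refits per simulated trial — which keeps a full comparison on
one core in the tens of minutes while leaving Monte-Carlo error well
below the contrasts of interest; single-fit analyses (parameter
recovery, calibration checks) use full-length chains.  Other numerical
choices: KDE MAP on a 512-point lattice with reflection; utility ties
broken to the lower dose; trial and study results are exactly
reproducible from their seeds.

## Known limitations

* Two subgroups only; a continuous covariate would need a different
  interface and larger samples.
* The independence working model for the joint outcome is deliberate
  (parsimony); scenario 8 probes its robustness but the package never
  fits a correlated-outcome model.
* Posterior inclusion probabilities are strongly prior-driven at trial
  sample sizes and should not be read as a subgroup-effect test.
* Grouped spike-and-slab priors (one indicator per model) are not
  implemented.
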