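# obdsub: subgroup-specific optimal biological dose finding

`obdsub` implements a Bayesian adaptive phase I/II dose-finding design for
trials with **two prespecified patient subgroups** in which the optimal
biological dose (OBD) — the dose with the best efficacy–toxicity trade-off —
may or may not differ between subgroups.  It is aimed at trial
statisticians designing dose-finding studies for immunotherapies and
targeted agents, where efficacy can plateau below the maximum tolerated
dose and a patient characteristic (e.g. large vs small tumors) is suspected,
but not known, to shift the dose–toxicity or dose–efficacy curve.

## The model

Doses are standardized to centered log doses
d_j = log δ_j − J⁻¹ Σ_q log δ_q, and the subgroup k ∈ {0,1} enters through
the contrast x_k = 2k − 1.  Two Bernoulli-logit working models drive all
decisions:

    logit π_kE(d) = β_E0 + β_E1 d + β_E2 d² + x_k (β_E3 + β_E4 d + β_E5 d²)
    logit π_kT(d) = β_T0 + β_T1 d + x_k (β_T2 + β_T3 d)

The five subgroup coefficients carry **spike-and-slab priors**
β | γ ~ γ·N(0, 2.5²) + (1−γ)·δ₀ with γ ~ Bernoulli(0.5), so the design
pools the subgroups when the accumulating data look homogeneous and
separates the curves when they do not.  Non-subgroup coefficients get
weakly informative normal priors calibrated to elicited mean outcome
probabilities and a target prior effective sample size (ESS, via Beta
moment matching).  Posteriors are sampled by Gibbs with Pólya-Gamma data
augmentation (exact Devroye sampler, compiled).

Dose assignment maximizes the expected utility
U = Σ_ab ν_ab π_E^a(1−π_E)^(1−a) π_T^b(1−π_T)^(1−b)
(anchors ν₁₀ = 100, ν₀₁ = 0; defaults ν₀₀ = 40, ν₁₁ = 60) over the
**admissible set**: doses with posterior evidence of safety
(P(π_T < 0.35) > 0.1), and either evidence of efficacy at a tried dose
(P(π_E > 0.3) > 0.1) or being the next escalation level.  A rule-based
run-in mimicking 3+3 escalation precedes model-based assignment; subgroups
with no admissible dose close (and can reopen), and the trial stops early
if no dose is acceptable for anyone.  The package also ships the pooled
and independent comparison designs, an eight-scenario synthetic truth
suite, and a simulation harness for operating characteristics.

## Worked example

```r
library(obdsub)

grid   <- dose_grid(c(0.2, 0.4, 0.6, 0.8, 1))
target <- elicitation_target(pi_E = c(0.3, 0.5, 0.6, 0.65, 0.7),
                             pi_T = c(0.05, 0.1, 0.15, 0.2, 0.25),
                             ess  = 0.9)
prior  <- calibrate_prior(target, grid, seed = 1)
prior
#> Prior specification
#>   efficacy model:
#>   coef       b  sigma p_incl
#>      1  0.5451 2.8304    1.0
#>      d  2.3125 2.8304    1.0
#>    d^2 -0.5691 2.8304    1.0
#>      x  0.0000 2.5000    0.5
#>    x:d  0.0000 2.5000    0.5
#>  x:d^2  0.0000 2.5000    0.5
#>   toxicity model:
#>  coef       b  sigma p_incl
#>     1 -3.8759 2.8304    1.0
#>     d  2.6266 2.8304    1.0
#>     x  0.0000 2.5000    0.5
#>   x:d  0.0000 2.5000    0.5
attr(prior, "ess")   # 0.894 — the elicited target was 0.9
```

The calibrated prior means trace the elicited probability schedule on the
logit scale; the shared sd 2.83 is what makes the prior worth about 0.9
observations.  Now run one trial against a truth where subgroup 1 is much
more toxic (true OBDs: dose 5 for subgroup 0, dose 1 for subgroup 1):

```r
suite <- build_scenario_suite(grid)
cfg   <- trial_config(grid, prior, n_burn = 1000, n_keep = 3000)
run_trial(cfg, suite$s2, seed = 17)
#> Trial result (proposed design, scenario 2)
#>   enrolled: 60 (k0: 30, k1: 30)
#>   selected OBD: k0 = 5 , k1 = 2
#>   stop reason: max-enrollment
```

The design split the subgroups: the tolerant subgroup is pushed to the top
dose while the toxicity-prone subgroup ends one level above its true OBD —
a typical near-miss at n = 30/subgroup.  Operating characteristics over
many replicates come from the harness:

```r
st <- run_study(suite[c("s1", "s2")], n_reps = 300, base_seed = 2024,
                grid = grid, prior = prior,
                config_args = list(n_burn = 100, n_keep = 250))
tabulate_oc(st)$summary
```

In that study the subgroup-aware design's percent-correct-selection sits
between the pooled and independent comparators in both regimes
(homogeneous truth: pooled 50%, proposed 45%, independent 37%;
subgroup-specific OBDs: independent 41%, proposed 33%, pooled 11%) — the
design behaves like whichever comparator you would have chosen with
foreknowledge.

A thin CLI wraps the same functions
(`exec/obdsub-design run|simulate|scenarios`, configs in YAML).

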