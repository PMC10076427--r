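# ivasa

An in-silico laboratory for **progressive-ratio intravenous alcohol
self-administration** experiments.

Human laboratory paradigms of this kind let a participant earn small
intravenous ethanol infusions as rewards for work on an attention task,
under exposure dynamics enforced by a computer-controlled infusion pump:
every alcohol reward raises breath alcohol concentration (BrAC) by
13 mg/dL within 3.0 min, between rewards BrAC is driven down at
0.8 mg/dL/min, and a 180 mg% safety gate blocks work-sets that could
overshoot. Because the number of correct trials per work-set grows
geometrically (≈4 trials for the first set, 189 for the fifteenth), the
reward contingency shifts over the 150-min session from cheap,
positively-reinforced drinking-like behavior to a "futile" phase in which
BrAC falls no matter how hard one works. Such paradigms are used to screen
medications (e.g. opioid antagonists) for their ability to reduce the
willingness to work for alcohol (cWFA, cumulative work for alcohol).

`ivasa` rebuilds the whole apparatus at desk scale, for method developers
and trialists who want to probe "what would this design detect?" before
running humans:

* **Pharmacokinetics** — two-compartment Michaelis–Menten ethanol
  disposition; distribution volume from Watson total body water;
  `simulate_pk()`, `step_pk()`.
* **Clamp controller** — model-inversion feedforward + proportional
  feedback tracking the prescribed BrAC trajectory within the 1998 ml/h
  pump limit, with 20-min breathalyzer recalibration; `simulate_clamp()`.
* **Session engine** — priming, waiting period, voluntary work phase,
  adaptive constant-attention task, independent alcohol/saline
  progressive-ratio progressions; `run_session()`.
* **Behavioral agent** — softmax choice among work-for-alcohol,
  work-for-water and rest, with positive-reinforcement, overshoot-aversion
  and desire (negative-reinforcement) channels, and a drug parameter that
  attenuates positive reinforcement in proportion to blood level;
  `agent_params()`, `scripted_agent()`.
* **Trial machinery** — genotype-enriched cohorts (OPRM1 A118G block-of-six
  rule), sex × carrier stratified permuted-block randomization, two-session
  trials, and the endpoint statistics: pooled-variance t, Cohen's
  *d* = (x̄₁ − x̄₂)/s<sub>pooled</sub> with normal-approximation CI,
  correlations, subjective slopes, intention-to-treat imputation;
  `simulate_trial()`, `analyze_endpoints()`, `cohens_d_ci()`.

## Worked example

Simulate one laboratory session for a default subject and summarise it:

```r
library(ivasa)
prof <- subject_profile("s001", "male", age = 30, height = 180, weight = 80)
s <- run_session(prof, seed = 42)
summary(s)
#> Session 1 of subject s001
#>   cWFA 370 (ascending 137, plateau 233), cWFS 74
#>   completed work-sets: 12 alcohol, 7 saline
#>   peak BrAC 136.5 mg/dL, mean BrAC 114.0 mg/dL
```

The subject completed 12 alcohol work-sets (reaching the steep end of the
progression — the futility point sits at set 14), performed 370 correct
trials for alcohol versus 74 for saline (alcohol is clearly the operative
reward), and peaked at 136.5 mg/dL, under the 180 mg% gate.
`plot(s)` shows the BrAC trace against the prescribed target.

Trial statistics work straight from printed group summaries
(n, mean, SD of the change in cWFA; control group first):

```r
d <- cohens_d_ci(group_summary(24, -39, 166.7), group_summary(22, -76, 174.5))
tt <- two_sample_t(group_summary(24, -39, 166.7), group_summary(22, -76, 174.5))
#> d = 0.217 (95% CI -0.363 to 0.797), t(44) = 0.735, p = 0.466
```

i.e. a small standardized effect whose confidence interval spans zero —
the drug arm reduced its work for alcohol more than placebo, but not
significantly over the full session.

A complete in-silico trial (two arms, two sessions each):

```r
tr <- simulate_trial(cohort_config(n_per_arm = 23, delta = 0.005, seed = 1))
tr$stats       # d, CI, t per phase; blood-level correlation
tr$endpoints   # per-subject endpoint table
```

A thin command-line front end over the same functions is installed at
`inst/scripts/ivasa-cli.R` (`simulate`, `analyze`, `trial` subcommands,
YAML/JSON configuration via `read_config()`).

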