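---
title: "Models and methods behind ivasa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ivasa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivasa)
```

`ivasa` is a virtual laboratory for progressive-ratio intravenous alcohol
self-administration experiments. A session couples four models: ethanol
pharmacokinetics, a BrAC clamp controller, an operant work schedule with an
adaptive attention task, and a behavioral agent standing in for the
participant. On top of the session engine sits the clinical-trial machinery:
genotype-enriched cohorts, stratified randomization, two sessions per
subject, and the endpoint statistics. This vignette explains each model, its
assumptions, the defaults, and what the simulations can and cannot say about
real data.

## Pharmacokinetics

Ethanol disposition is a two-compartment model with Michaelis-Menten
elimination from the central (arterial/breath-equivalent) pool:

$$\frac{dC_c}{dt} = \frac{u(t)}{v_d (1-f)} - \frac{k\,(C_c-C_p)}{1-f}
  - \frac{v_{max} C_c}{(k_m + C_c)\, v_d (1-f)}, \qquad
\frac{dC_p}{dt} = \frac{k\,(C_c-C_p)}{f},$$

with BrAC (mg/dL) $= 100\,C_c$ and $u(t)$ the ethanol mass input (g/min)
from the 6.0 % (v/v) infusate (pump-limited at 1998 ml/h, i.e. 1.577 g
ethanol/min). The distribution volume is Watson total body water, the
standard choice in intravenous clamp work because it needs only screening
anthropometrics.

Defaults: $v_{max} = 0.003\,v_d$ g/min (zero-infusion whole-body decline of
about 15 mg/dL/h near 50 mg/dL, a typical human value), $k_m = 0.1$ g/L,
$k = 0.10$ /min, $f = 0.70$. The small central fraction (30 % of $v_d$) is
deliberate: the paradigm prescribes inter-reward BrAC declines of
0.8 mg/dL/min, nearly four times the elimination-limited rate, and such
declines are only possible while arterial ethanol redistributes into a
large, still-unsaturated peripheral pool. With these defaults the decline is
sustainable for roughly 6-7 minutes after a reward, which reproduces the
behavior of real clamp systems (and the published priming-interval decline
of about -0.76 mg/dL/min over 7 min); over longer reward-free spans the
decline necessarily relaxes toward the elimination limit, "as long as is
pharmacokinetically possible". A configuration with $f = 0$, $k = 0$
degenerates to one well-mixed compartment, which the tests use for
closed-form checks.

Integration is classical fixed-step RK4 at $dt = 0.05$ min. The system is
non-stiff; halving the step changes end-of-session BrAC by well under
0.1 mg/dL, and the cumulative infused/eliminated tallies are co-integrated
so that mass balance holds to integrator precision (a linear invariant,
preserved exactly by Runge-Kutta schemes).

## Clamp controller

The prescribed target trajectory is piecewise linear: each alcohol reward
ramps the target up 13 mg/dL over 3.0 min; otherwise it falls at
0.8 mg/dL/min, clamped at zero. Saline rewards (15 ml over 3 min) leave the
target untouched.

The controller is model-inversion feedforward plus proportional feedback:
at each step it solves its own model for the pump rate that lands model
BrAC on the target one step ahead, adds $0.5\,(\text{target} -
\text{model BrAC})$, and saturates into $[0, 1998]$ ml/h. It tracks a
private model state; every 20 min a (noisy, zero-truncated) breathalyzer
reading resets the model BrAC and rescales the $v_{max}$ estimate by the
prediction/measurement ratio, bounded to $\pm 30\,\%$ per update. Only
$v_{max}$ is adapted because a single reading cannot separate volume from
elimination errors. With true parameters and no noise, tracking error on a
dynamically feasible target stays in the hundredths of a mg/dL; the paired
simulation tests show recalibration shrinking end-of-session error when the
subject's true $v_{max}$ is mis-estimated by 35 %.

The 180 mg% safety gate is inclusive and evaluated at work-set start: a set
may begin only if the ensuing +13 mg/dL cannot exceed the limit, so
simulated BrAC can never cross 180.

## Work schedule and attention task

The progressive-ratio requirement is geometric,
$n_k = \mathrm{round}(n_1 r^{k-1})$, calibrated to the two public anchor
durations: about 30 s for the first work-set and about 23 min for the
fifteenth at 7.3 s per trial, giving $n_1 = 4$, $r = (189/4)^{1/14} \approx
1.317$. Both are configuration fields, so an exact progression table can be
dropped in if available. Alcohol and saline progressions are identical but
advance independently. The futility index - the first set whose expected
work time costs more BrAC than a reward restores - is 14 under these
defaults.

The constant attention task draws trial durations (truncated normal, mean
7.3 s) and lognormal reaction times; success requires the reaction time to
fall inside an adaptive window multiplied by 1.06 on failure and 0.98 on
success, a weighted up-down staircase whose equilibrium success probability
solves $p\log 0.98 + (1-p)\log 1.06 = 0$, i.e. about 0.74. An impairment
factor ($1 + 0.002\,\mathrm{BrAC}$) slows reaction times; the staircase
widens until the success rate recovers, mimicking the task's automatic
compensation.

## Behavioral agent

The participant is a softmax decision maker choosing among working for
alcohol, working for water, and resting (2-min bouts), with utility

$$u_{alc} = wp + w_+\,(1-\delta L) - w_{av}\,\frac{(\mathrm{BrAC}-c)_+}{100}
          + w_-\,\frac{desire}{100} - \text{fatigue} \cdot t,$$

four channels with distinct roles: a drug-attenuated anticipation of the
next reward's pleasure ($w_+ = 1.5$; $\delta$ is the attenuation per ng/ml
of drug blood level $L$), an unattenuated aversion to exceeding a comfort
ceiling ($w_{av} = 3$ above $c = 85$ mg/dL, encoding the instruction to
seek pleasant and avoid unpleasant effects), a desire term ($w_- = 4$, the
negative-reinforcement channel), and fatigue. Because the drug acts only on
the anticipation term, its behavioral effect concentrates where that term
drives work - the low-demand ascending phase - while plateau work, carried
by desire, is relatively spared. That asymmetry is the contingency
hypothesis the paradigm was designed to probe, and it emerges here from the
utility structure rather than being imposed per phase.

Subjective visual-analog scales (0-100) follow linear-gain dynamics with
exponential return to baseline. Stimulation and wellbeing rise with BrAC
level and rising BrAC, both gains scaled by $1-\delta L$. Desire rises
while BrAC falls, driven mainly by a saturating "unintended drop" signal:
the gap between the (slowly forgotten) session-peak BrAC and the current
value, capped at 15 mg/dL. The saturation matters: without it, subjects who
work hard enough to slow their own decline would systematically feel less
desire, an artifact that inverts the observed desire-work association.
Sedation and drunkenness track BrAC level. All scales clip to [0, 100].

## Sessions and cohorts

A session runs on the analytical time axis: priming from $T = -25$ min
(two prompted saline then four alcohol work-sets of 4 trials, excluded from
the progression and from cumulative work), a waiting period, then 150 min
of voluntary work. Discrete events (trials, work-sets, rewards, rests,
decisions) carry exact times; only the pharmacokinetic/control layer lives
on the 0.05-min grid, so event arithmetic can be checked against closed
forms. Assessments are taken at $T = -25, 15, 75, 150$ min, and phase
windows are $[0, 75)$ and $[75, 150)$. Sessions replay bit-identically
from a seed.

Cohorts draw Hardy-Weinberg genotypes at a 15 % G-allele frequency,
enriched by the block-of-six rule (all GG first, then AG, then AA, by
consent order), 87 % male, age uniform 25-55, sex-specific anthropometrics
truncated at the 130 kg bound. Persistent (cross-session) random effects
give each subject a work propensity (SD 0.45), a comfort ceiling shift
(SD 5 mg/dL), a desire-responsiveness multiplier (lognormal, sdlog 1.2) and
lognormal pharmacokinetic perturbations (CV 0.15) on $v_{max}$ and $v_d$;
the controller starts from the unperturbed population model and relies on
recalibration. These variances were set so that placebo-arm session-1 vs
session-2 cumulative work correlates at about 0.7, bracketing the
published test-retest estimates. Randomization is permuted-block (size 4)
within sex x G-carrier strata; treated-arm blood levels are normal
(55.4 +/- 27.6 ng/ml, truncated at 0) and enter the agent as $\delta L$
with $\delta = 0.005$ per ng/ml by default.

## Trial statistics

The analysis layer works from group summaries (n, mean, SD) exactly as a
trial report prints them: pooled-variance Student t
($df = n_a + n_b - 2$; the published degrees of freedom identify this,
not Welch, as the test used), Cohen's
$d = (\bar x_a - \bar x_b)/s_{pooled}$ with the normal-approximation
confidence interval $d \pm z_{1-\alpha/2}\sqrt{(n_a+n_b)/(n_a n_b) +
d^2/(2(n_a+n_b))}$ (the noncentral-t inversion reproduces published
intervals less closely for these inputs), Pearson and Spearman correlations
through `stats::cor.test`, slopes of subjective responses between
assessment pairs 2-3 and 3-4, and the intention-to-treat imputation that
sets a missing subject's change score to the mean change of the rest of the
arm. Where the imputation sentence's sign is ambiguous for negative mean
changes, the implemented convention (baseline plus mean change) is the one
that leaves the group mean change unchanged. When raw vectors are supplied
instead of summaries the same code paths apply after summarising, and the
tests verify them against per-observation computation.

## Problem sizes and reproducibility

All desk-scale worked examples run in well under a second. The cohort-level
properties are established at 200 subjects per arm (800 simulated sessions,
a few minutes on one CPU); dose-response monotonicity uses 200 matched-seed
sessions per attenuation level; staircase and randomization Monte Carlo
checks use 10,000 and 1,000 draws. Every stochastic path flows from one
user seed; per-session seeds inside a trial are drawn once from that seed
and stay below $2^{31}$.

## What passing tests do and do not show

The generator emulates the *structure* of the paradigm - exposure dynamics,
schedule arithmetic, contingency shift, between-subject stability - not any
particular human sample. Quantities that depend on the sample are checked
only as signs, orderings or ranges: a positive drug effect concentrated in
the ascending phase, a negative blood-level correlation, test-retest
stability between 0.5 and 0.9, positive work-stimulation association early
and work-desire association late. Known deviations from the published
cohort, accepted as calibration compromises: simulated exposure runs warm
(mean peak BrAC around 140 mg/dL versus 117 +/- 23; session mean around 118
versus 91-96), cumulative work for saline is low (about 30 versus 60-150),
and the *cross-window comparison* of the desire-slope correlation
(ascending vs plateau) sits at the noise floor of this generator - the
within-window directions are robust, the between-window ordering is not,
because working suppresses one's own BrAC decline and thereby one's own
desire signal. Real-data features deliberately not modelled: oral-route
pharmacokinetics, venous-arterial lag, learning or tolerance across
sessions, craving instruments, and any neurobiological detail of the
genotype (it enters screening and stratification only).
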