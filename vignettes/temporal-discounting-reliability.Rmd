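---
title: "Models and methods: temporal discounting reliability with diffusion choice rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temporal discounting reliability with diffusion choice rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`discountDDM` implements a complete, simulation-first replica of a
test-retest reliability study of intertemporal choice: a task generator, a
generative model of choices and response times, hierarchical Bayesian
estimation under softmax and drift-diffusion choice rules, model comparison,
model-free discounting summaries, reliability statistics, Bayesian session
contrasts, and electrodermal phase summaries. Everything runs end-to-end on
synthetic cohorts with known ground truth, so every downstream statistic can
be checked against the parameters that generated the data.

# The decision models

## Hyperbolic valuation

A delayed reward of amount $A$ (Euros) at delay $D$ (days) is valued
hyperbolically,

$$\mathrm{SV}(A, D) = \frac{A}{1 + \exp(\log k)\, D},$$

with the discount rate carried in log-space throughout: discount rates are
severely right-skewed across people and log-scaling removes the numerical
instability of rates near zero. Larger $\log k$ means steeper devaluation.
The smaller-sooner (SS) option is a fixed immediate 20 Euros, so its value
is its amount.

## Softmax choice rule

Choice of the larger-later (LL) option follows

$$P(\mathrm{LL}) = \frac{e^{\beta\,\mathrm{SV_{LL}}}}
{e^{\beta\,\mathrm{SV_{SS}}} + e^{\beta\,\mathrm{SV_{LL}}}},$$

where the inverse temperature $\beta \ge 0$ measures choice consistency;
$\beta = 0$ is coin-flipping. The implementation works on the log-odds
scale, so extreme value differences cannot overflow.

## Drift-diffusion choice rules

The diffusion variants model each trial as noisy evidence accumulation with
unit diffusion coefficient between two boundaries separated by $\alpha$,
starting at relative point $z$ (fraction of $\alpha$, 0.5 = unbiased),
with non-decision time $\tau$ absorbing perception and motor components.
The upper boundary codes LL choices; response times of SS choices are
sign-flipped so one signed number carries both choice and latency. Three
drift specifications are nested:

* **DDM0** — a constant drift $v$; values play no role.
* **DDM_L** — $v_t = v_\mathrm{coeff}\,(\mathrm{SV_{LL}} -
  \mathrm{SV_{SS}})$, linear in the trial's value difference.
* **DDM_S** — the linear term is passed through
  $S(m) = \frac{2 v_\mathrm{max}}{1 + e^{-m}} - v_\mathrm{max}$,
  a sigmoid saturating at $\pm v_\mathrm{max}$, which prevents the
  unboundedly fast predicted responses the linear mapping implies for
  large value differences. Note $S(m) = v_\mathrm{max} \tanh(m/2)$, so for
  small $|m|$ the model behaves like DDM_L with effective coefficient
  $v_\mathrm{coeff} v_\mathrm{max} / 2$ — the two drift parameters trade
  off, which is visible in their joint posteriors and in their lower
  individual reliabilities.

The signed-RT likelihood is the Wiener first-passage-time density. The
implementation evaluates the standard small-time and large-time series
expansions of the density and selects, per evaluation, the expansion whose
truncation meets the requested absolute tolerance (default $10^{-9}$) with
fewer terms. The upper-boundary density is the lower-boundary kernel after
the reflection $v \to -v$, $z \to 1 - z$; this identity is exact and is
asserted in the test suite. Any response at or before $\tau$ has zero
density ($-\infty$ log-likelihood), which is what rules out $\tau$ values
above a subject's fastest retained trial during sampling.

# Preprocessing

Per subject and session, the 2.5% fastest and 2.5% slowest trials are
removed before fitting, computed on raw unsigned RTs *before* sign-coding
(trimming signed values would conflate choice with speed). The count per
tail is $\lfloor f n \rfloor$ — conservative: never more than the requested
fraction. Ties at a trim boundary keep the earlier trial. Trimming is per
subject-session because each session is fit separately. RTs are in seconds.

One knock-on effect worth knowing: on perfectly clean simulated data,
trimming removes genuine distribution tails and biases boundary-separation
estimates slightly downward. We keep the step in all pipelines anyway —
it is part of the procedure being replicated, and on real data it guards
against contaminant RTs; the recovery tests simply inherit the small bias,
which stays inside the posterior uncertainty at the study's scale.

# Task generator

The design crosses 6 delays (1-122 days) with 16 LL multiples
(1.025-3.85 of the 20 Euro SS) into 96 trials per set, with three sets
matched exactly on mean delay and mean LL amount. The constructor lays an
18-value integer delay grid and a 48-value arithmetic multiple grid over
the stated ranges, pairs values symmetrically around each grid's midpoint
(every delay pair sums to 123, every multiple pair to 4.875), and deals
whole pairs to sets — 3 delay pairs and 8 multiple pairs per set — so the
set means are equal *by construction*, not by numerical search. Dealing is
stratified: pairs are ordered outermost to innermost and each set receives
one pair per stratum of three, so every set's delays and amounts stay
spread over the full range (an unstratified deal can hand one set three
adjacent delay pairs, leaving a three-month gap no indifference analysis
could bridge). The seed permutes assignments within strata only. Sets are assigned to sessions by a
Latin square over subjects, and trial order within a session is a seeded
permutation.

# Hierarchical estimation

Subject-level parameters are drawn from group-level Gaussians truncated to
each parameter's support; supports double as the uniform priors on group
means ($\log k \in (-20, 3)$, $\beta \in (0, 10)$, $v \in (-100, 100)$,
$\tau \in (0.1, 6)$, $\alpha \in (0.01, 5)$, $z \in (0.1, 0.9)$,
$v_\mathrm{coeff} \in (-100, 100)$, $v_\mathrm{max} \in (0, 100)$), and
group precisions carry Gamma(0.001, 0.001) priors. Truncation is our
choice where the hierarchy is otherwise silent: untruncated Gaussians
would propose invalid $\tau$, $z$ or $\alpha$ for some subjects. Sessions
are always fit independently — the reliability question requires
independent per-session estimates.

Sampling is adaptive Metropolis-within-Gibbs: random-walk updates for each
subject-level parameter (vectorized across subjects), each group mean and
each group log-precision, with per-quantity proposal scales tuned toward a
0.44 acceptance rate during warmup and frozen afterwards. No gradients are
needed, which keeps the wfpt kernel free of derivative bookkeeping. Two
extra moves matter in practice:

* an *independence refresh* from the truncated group prior (every 5th
  iteration), which lets subjects whose likelihood is flat in a parameter
  (e.g. an all-SS responder's $\log k$) traverse the whole plausible range;
* a *joint refresh* of $(\log k, v_\mathrm{coeff})$, because for
  near-deterministic responders these two parameters form two modes
  (steep discounting with positive drift scaling vs. the mirrored
  solution) that single-coordinate moves essentially never cross. Without
  this move, chains starting in different modes report split-chain R-hat
  values near 1.8 for the affected subjects; with it, the same fits
  converge to R-hat ≤ ~1.04.

Starting values are data-informed for $\log k$ (bisection on each
subject's observed LL fraction through a moderate softmax), mid-support
and chain-staggered otherwise, and $\tau$ starts safely below each
subject's fastest trial. Convergence is summarized by rank-normalized
split-chain R-hat for every sampled quantity; any value above 1.01 flags
the whole fit as non-converged (a warning, not an error — flagged fits
are still inspectable). Model comparison uses the DIC with the plug-in
deviance at the posterior means of the subject-level parameters
($p_D = \bar D - D(\bar\theta)$); only DIC *orderings* are interpreted,
never absolute values, which depend on sampler conventions.

Default sampler settings are 4 chains, 1000 warmup, 4000 retained draws
per chain. The test suite and the acceptance script use smaller,
explicitly stated settings per fit (typically 2-4 chains and a few
thousand total iterations); the recovery studies run at 34 subjects
(softmax) and 20 subjects (DDM_S) with 96 trials per subject.

# Synthetic cohorts

A cohort is 34 subjects x 3 sessions x 96 trials by default. Each
subject's session-specific parameter is group mean + trait + state, with
trait drawn once per subject and state per session; the implied
test-retest reliability of a parameter is
$\rho = \sigma^2_\mathrm{trait} / (\sigma^2_\mathrm{trait} +
\sigma^2_\mathrm{state})$. Softmax defaults give $\rho(\log k) = 0.9$ and
$\rho(\beta) \approx 0.34$, matching the qualitative pattern the task is
known for (discount rates reliable, consistency parameters much less so).
Bounded parameters are clipped to their supports after perturbation (clip
events are counted in the ground truth). Clipping is not the same as the
truncated-Gaussian population the fitting model assumes; near a bound
(notably $\beta \ge 0$) this mismatch makes the fitted group mean sit
below the naive sample mean of the generating values. That is expected
behavior of a truncated-normal model, not an estimation defect, and it is
why recovery checks target parameters away from their bounds.

DDM generative defaults ($v_\mathrm{coeff} = 0.3$, $v_\mathrm{max} = 2.5$,
$\alpha = 2$, $\tau = 0.8$ s lab, $+0.4$ s in VR sessions for the motor
overhead of controller responses, $z = 0.55$) were chosen once to place
simulated RTs on the 1-3 s scale such a task produces; they are stated
here because nothing in the printed record pins them down. Diffusion
trials are simulated by Euler-Maruyama with $dt = 10^{-4}$ s from $z
\alpha$ until absorption; paths not absorbed within 60 s are resampled and
counted (their rate is enforced below 0.1%). Euler first-passage
simulation carries a known small-$dt$ discretization bias (missed
within-step crossings act like a boundary widened by about
$0.583\sqrt{dt}$ per side), which is why the density-vs-simulation
agreement is asserted at the 2% level at the histogram mode rather than
exactly. RTs in the softmax-only mode are log-normal nuisance draws so
files stay schema-complete.

The EDA generator emulates the three 5-minute phases (baseline, first and
second exploration) at 1 Hz: a tonic level with a multiplicative step at
VR entry, slow drift, Gaussian noise, and Poisson phasic events. It makes
no attempt to model SCR shapes, habituation, or movement artifacts — it
exists so the binning, normalization and contrast machinery can be tested
against a known step size, not as a model of skin conductance.

# Model-free discounting summary

Per delay, a logistic in LL amount is fit to the subject's choices and the
indifference point read off as $A^* = -b_0 / b_1$, clamped to the offer
range [20, 77]. Perfect separation (common for consistent responders on a
16-point amount grid) uses the midpoint between the largest always-SS and
smallest always-LL amounts; all-LL and all-SS responders clamp to 20 and
77. Because indifference here is an LL *magnitude* with a fixed SS, the
area under the curve normalizes as $y = 20 / A^*$ against $x =
\mathrm{delay}/122$, anchored at $(0, 1)$, trapezoid-integrated and
divided by the covered $x$-range: 1 = no discounting. This is the standard
normalized-AUC construction adapted to magnitude-valued indifference
points. AUC session effects use a tie-corrected Friedman test (an
all-equal-rows matrix is reported as statistic 0, p = 1).

# Reliability and contrasts

Test-retest reliability is the intraclass correlation for a two-way model
with absolute agreement on the average of the $k = 3$ sessions — ICC(A,k)
in McGraw-Wong terms, $(\mathrm{MSR} - \mathrm{MSE}) / (\mathrm{MSR} +
(\mathrm{MSC} - \mathrm{MSE})/n)$ — with the F-based confidence interval
and p-value. The conventional label "two-way mixed, absolute agreement,
mean of 3 raters" maps onto this form; the mixed/random distinction does
not change the computed value. Categories use half-open bands fixed here
once: [0, 0.5) poor, [0.5, 0.75) moderate, [0.75, 0.9) good, [0.9, 1]
excellent. Point estimates entering ICCs are subject-level posterior
means. Split-half reliability splits trials by index parity within
session, refits each half independently with the session's settings, and
reports per-parameter Pearson r and ICC(A,2) between halves.

Session contrasts work on group-mean posteriors of independently fit
sessions: draws are thinned to a common length and paired by a seeded
random permutation (any exchangeable pairing gives the same marginal
difference distribution), summarized by the mean, the 95% highest-density
interval (narrowest sorted window), and the directional Bayes factor
dBF = (mass above 0)/(mass below 0), with an empty side floored at one
sample and flagged as a bound. Bands: dBF ≥ 3 moderate, ≥ 12 strong,
> 100 extreme (reciprocals for negative shifts). Cohen's d between
sessions uses subject-level posterior means with the root-mean pooled SD;
the between-session correlation is reported alongside d rather than folded
into it, since the d-for-paired-designs variants disagree on that role and
reporting both keeps the quantity interpretable.

# Electrodermal summaries

Each 5-minute phase is cut into five 1-minute bins; per bin the tonic
measure is mean SCL and the phasic measure the count of spontaneous SCRs;
both become percent change from the mean of the five baseline bins, making
them invariant to amplifier scale. The planned contrasts are B5 vs F1
(does VR entry raise arousal) and F5 vs S1 (does entering the experimental
area raise it further) within each VR session, plus the across-session
comparison of per-subject F5-S1 difference scores. Tests are Wilcoxon
signed-rank: zero differences dropped (and counted), midranks with tie
correction in the normal approximation, exact enumeration below 12
non-zero tie-free pairs. The effect size is $r = |Z|/\sqrt{N}$ with $N$
the pairs supplied before zero-removal — the convention that reproduces
the worked examples this package tests against (small < 0.3, medium
0.3-0.5, large > 0.5). Decomposition of raw EDA into tonic and phasic
components is out of scope: the package consumes already-decomposed
series, real or synthetic.

# What the synthetic studies do and do not show

Passing recovery and reliability checks on these cohorts shows the
estimation machinery is consistent with its own generative assumptions at
realistic scale — it does not certify the substantive conclusions on human
data, where RT contaminants, non-hyperbolic discounters, session-order
effects and EDA artifacts exist. The trait/state decomposition is additive
Gaussian on the estimation scale — a deliberately simple stand-in for
whatever produces between-day parameter drift in people. Known
limitations: DIC values depend on the plug-in convention (orderings only);
the Euler oracle has the discretization bias noted above; the clip-vs-
truncate mismatch at support bounds affects parameters living near a
bound; and the softmax-mode RTs are pure nuisance, so nothing about RTs
should be inferred from softmax-only cohorts.
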