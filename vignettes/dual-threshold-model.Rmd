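---
title: "The dual-process treatment threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-process treatment threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmm)
```

## The decision problem

A clinician must decide whether to treat a patient who has a disease with
probability $p$. Classic threshold analysis, grounded in expected utility
theory (EUT), prescribes treatment whenever $p$ exceeds
$p_t^{EUT} = H/(B+H)$, where $B$ is the net benefit of treating the diseased
and $H$ the net harm of treating the non-diseased. Observed practice often
departs sharply from this prescription in both directions. This package
implements a *descriptive* model of that departure: decisions emerge from a
weighted combination of a deliberative valuation (system II, which follows
EUT) and an intuitive one (system I, which is probability-insensitive and
driven here by anticipated regret).

## The valuation model

A risky choice with outcomes $x_i > 0$ and probabilities $p_i$ is valued as

$$V(C) \;=\; \gamma \,\frac{1}{n}\sum_i x_i^{m_I} \;+\; (1-\gamma)\,k \sum_i p_i x_i .$$

The model's assumptions, and what each parameter does:

* **$\gamma \in [0,1]$** — relative involvement of system I
  (dimensionless). $\gamma = 0$ is a pure EUT decision-maker, $\gamma = 1$ a
  pure intuitive one. The package treats $\gamma$ as an input; estimating it
  from behavior is out of scope.
* **$k > 0$** — scaling constant on the system-II term (default 1, the
  value used in all worked examples; it rescales magnitudes but, as shown
  below, cannot change which side of the EUT threshold the dual threshold
  falls on).
* **$m_I \in (0,1]$** — curvature of the system-I power value function
  $x^{m_I}$ (risk aversion for gains). At $m_I = 1$ system-I and system-II
  magnitudes coincide.

Two structural assumptions matter. Outcome utilities are strictly positive —
zero is rejected, since $x^{m_I}$ at $x=0$ with fractional exponent is a
boundary the model never uses. And system I weighs outcomes *as listed*,
each at $1/n$: duplicate outcomes are not coalesced, so splitting an event
changes the system-I value. That event-splitting sensitivity is a feature of
the underlying cognitive model, not an implementation accident.

## Specialization to treat/no-treat

The dilemma has four outcomes: treat/disease ($x_1$), treat/no-disease
($x_2$), no-treat/disease ($x_3$), no-treat/no-disease ($x_4$); in the
standard configuration $x_1 > x_3$ and $x_4 > x_2$. System I values each
outcome by its **regret** — the loss against the retrospectively correct
action — so the two "right" cells carry zero and the others carry the regret
of omission ($x_3^{m_I}-x_1^{m_I}$) and of commission
($x_2^{m_I}-x_4^{m_I}$). Writing $B_{II}=x_1-x_3$, $H_{II}=x_4-x_2$ for the
system-II net benefit and harm and $B_I = x_1^{m_I}-x_3^{m_I}$,
$H_I = x_4^{m_I}-x_2^{m_I}$ for their system-I counterparts, equating the
two action valuations gives the dual threshold

$$p_t \;=\; \frac{(1-\gamma)k H_{II} - \frac{\gamma}{2}(B_I - H_I)}
               {(1-\gamma)k (B_{II}+H_{II})}.$$

Profiles may be supplied directly (`benefit_harm_profile()`) — as in the
worked examples, where $B_I, H_I$ are subjective gist quantities — or
derived from utilities (`profile_from_outcomes()`); the two construction
paths are never mixed silently.

Properties the test suite verifies:

* $\gamma = 0$ recovers the EUT threshold exactly.
* $B_I = H_I$ makes system I irrelevant: $p_t = p_t^{EUT}$ for every
  $\gamma < 1$.
* The *side* of the EUT threshold is decided by $\mathrm{sign}(B_I-H_I)$
  alone — benefit-dominant intuition lowers the threshold, harm-dominant
  raises it — and neither $\gamma$, nor $k$, nor $H_I/H_{II}$ can flip it;
  they only set the magnitude of the shift.
* $p_t$ is monotone in $\gamma$, increasing when $H_I > B_I$.

### Regimes, clamping, and the $\gamma = 1$ singularity

The raw threshold can leave $[0,1]$: at or below 0 the decision-maker treats
at any disease probability (`always_treat`), at or above 1 only with
certainty (`never_treat`). Both the raw and the clamped value are always
reported — the raw value is what critical-involvement analysis needs, the
clamped one carries the decision semantics. At $\gamma = 1$ the formula
divides by zero; rather than evaluating it, `dual_threshold()` returns a
dedicated `system1_only` regime in which `decide()` ignores probability and
compares $B_I$ with $H_I$ categorically — the "toggle" reading of a pure
system-I decision-maker. Ties at the threshold are reported as
`indifferent`, not as treatment: only strictly exceeding the threshold
favors treating.

The boundary involvement levels solve $p_t = 1$ and $p_t = 0$ in closed
form:

$$\gamma^{never} = \frac{B_{II}}{B_{II} + (H_I-B_I)/2k}, \qquad
  \gamma^{always} = \frac{H_{II}}{H_{II} + (B_I-H_I)/2k},$$

each returned by `critical_gamma()` only when it falls in $(0,1)$ —
the never-treat boundary requires harm-dominant intuition, the always-treat
boundary benefit-dominant intuition, and a neutral system I reaches neither.

```{r}
aml <- benefit_harm_profile(b2 = 0.12, h2 = 0.16, b1 = 0.12, h1 = 0.32)
eut_threshold(aml)
critical_gamma(aml, boundary = "never_treat")
```

## Sensitivity analysis and the gist heuristic

`gamma_sweep()`, `ratio_sweep()` and `behavior_grid()` tabulate the
threshold over the involvement weight, the benefit/harm ratio and a grid of
risk-perception distortions; every row is an isolated `dual_threshold()`
call, so sweeps carry no state. Gamma grids stop at $1 - 10^{-6}$ by default
to stay clear of the singularity. For the ratio sweep the published account
fixes neither the involvement weight nor the harm scale, so the package
defaults to $\gamma = 0.5$ — the focal mixed-processing case, in which both
systems are active players — and $H_{II} = 0.05$; the four bundled
gamma-sweep panels (`threshold_gamma_panels()`) likewise use $H_{II} = 0.05$
with a $\pm 0.05$ system-I imbalance, magnitudes that are illustrative
rather than canonical except for the pulmonary-embolism ratios 60.8 and 3.5.

`gist_round()` implements the prominent-number heuristic by which intuition
is thought to assess magnitudes: values are mapped to the nearest member of
$\{1,2,5\}\times 10^n$. The rounding metric is not pinned down by the theory;
the package uses log-space distance (so the decision is scale-covariant
under powers of ten) with exact ties going to the larger prominent number.
Constraining user inputs to prominent numbers is deliberately *not* imposed:
the scenario format accepts any value, and gist rounding is available as an
explicit preprocessing step.

## Numerical choices

* All computation is in fractions; percent appears only at the I/O boundary
  (one decimal in human-readable output, full precision in JSON/CSV).
* Indifference and decision ties use an absolute tolerance of $10^{-12}$:
  every quantity is closed-form double-precision arithmetic, so a tighter
  band would only chase rounding noise.
* The independent oracle `numeric_indifference()` locates the indifference
  probability by root-bracketing the difference of the two action
  valuations (which is linear in $p$) over the extended interval
  $[-10, 10]$, tolerance $10^{-12}$, using Brent's method. It never touches
  the closed form, so agreement between the two routes — which the tests
  check to $10^{-9}$ across 1000 generated scenarios — is evidence about
  both. Roots beyond the bracket correspond to raw thresholds of magnitude
  above 10; there the oracle reports non-existence, and the tests verify the
  two routes agree on existence as well.

## What the scenario generator emulates

`random_scenarios()` draws outcome quadruples in $(0,1]$ with $x_1 > x_3$
and $x_4 > x_2$ — treatments that help the diseased and harm the healthy,
the regime the model addresses — with $m_I$ uniform on $(0,1]$, $k$ from
$\{0.5, 1, 2\}$, and $\gamma$ uniform on $[0, 0.99]$ plus a 5% admixture of
pure system-I decision-makers ($\gamma = 1$), so that large draws exercise
all four decision regimes including the categorical one. The CLI's `check`
subcommand defaults to seed 20120903; any seed reproduces its collection
exactly, and generation leaves the caller's RNG stream untouched.

These scenarios are mathematical stress tests, not simulated clinicians:
they contain no behavioral noise, no correlation between $\gamma$ and case
severity, and utilities drawn uniformly rather than from elicited
distributions. Passing tests therefore establishes that the closed form,
its limits and its regime classification are internally correct — not that
the model describes real decision-makers, which is an empirical question
outside the package's scope.

## Limitations

* The model is descriptive; the package makes no claim that the dual
  threshold is the threshold clinicians *should* use.
* $\gamma$, $m_I$ and the system-I benefit/harm gist values are inputs, not
  estimates; eliciting them from behavior (e.g. by fuzzy-logic methods) is
  future work upstream of this implementation.
* Regret is modeled at the system-I level only, and system II is assumed
  strictly linear in probability.
* The two-way risk-perception table is reproduced in structure only; its
  published cell values are not available in the main text, so
  `behavior_grid()` output is checked against the closed form, not against
  printed numbers.
* Worked-example problem sizes are desk-scale by nature (single closed-form
  evaluations, 100-point $\gamma$ grids, 1000 random scenarios for the
  oracle comparison).
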