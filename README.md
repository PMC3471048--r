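# dsmm — dual-process threshold model for treat/no-treat decisions

`dsmm` implements a descriptive model of how clinicians decide whether to
treat a patient who may or may not have a disease, when the decision is
shaped by both deliberative, evidence-based reasoning (**system II**) and
fast, intuitive, affect-driven reasoning (**system I**). It is aimed at
medical decision-making and health-outcomes researchers who want to explore
how intuition shifts the classic therapeutic threshold — for instance to
explain why clinicians demand near-certainty before anticoagulating for
pulmonary embolism when expected-utility theory says to treat at a 22%
probability of disease.

## The model

A risky choice *C* with outcomes *x<sub>i</sub>* (utilities, > 0) and
probabilities *p<sub>i</sub>* is valued as a mixture of the two systems:

> V(C) = γ · (1/n) Σ<sub>i</sub> x<sub>i</sub><sup>m<sub>I</sub></sup> + (1 − γ) · k Σ<sub>i</sub> p<sub>i</sub> x<sub>i</sub>

System I gives every possible outcome equal weight (it senses presence, not
probability) through a power value function x^m<sub>I</sub>; system II is
linear expected utility. γ ∈ [0, 1] is the relative involvement of system I.

Specialized to the treat/no-treat dilemma, system I values outcomes by
anticipated **regret** (the loss relative to the action that would have been
right in retrospect), and the indifference probability — the **dual decision
threshold** — has the closed form

> p<sub>t</sub> = [ (1 − γ) k H<sub>II</sub> − (γ/2)(B<sub>I</sub> − H<sub>I</sub>) ] / [ (1 − γ) k (B<sub>II</sub> + H<sub>II</sub>) ]

where B<sub>II</sub>, H<sub>II</sub> are the evidence-based net benefit and
harm of treatment and B<sub>I</sub>, H<sub>I</sub> their subjective,
system-I counterparts. At γ = 0 this is the classic expected-utility
threshold H/(B+H); when system I feels harm exceeding benefit the threshold
rises above it (under-treatment), in the opposite case it falls below
(over-treatment), and it can escape [0, 1] entirely — the always-treat /
never-treat regimes, reached at a computable critical γ.

## Worked example

The pulmonary-embolism worst case: evidence gives net benefit 17.5% and net
harm 5% (benefit/harm ratio 3.5), but a physician primed by a recent
bleeding complication feels harm exceeding benefit by 10 percentage points
and decides mostly intuitively (γ = 0.77):

```r
library(dsmm)
pe  <- benefit_harm_profile(b2 = 0.175, h2 = 0.05, b1 = 0.175, h1 = 0.275)
res <- dual_threshold(pe, dual_weights(gamma = 0.77))
res
#> <threshold_result>
#>   EUT threshold:  22.2%
#>   dual threshold: 96.6% (raw 0.966184)
#>   regime: interior   (gamma = 0.77, k = 1)
decide(0.95, res, pe)
#> [1] "no_treat"
```

Pure evidence says treat above a 22.2% probability of embolism; the dual
threshold is 96.6%, so even a 95% probability leaves this decision-maker
withholding anticoagulants — matching guideline-style behavior. One notch
more intuition (γ = 0.78) pushes the threshold past 1 (`never_treat`
regime), and `critical_gamma()` returns such boundaries in closed form.

Sensitivity sweeps (`gamma_sweep()`, `ratio_sweep()`, `behavior_grid()`)
tabulate the threshold over the involvement weight, the benefit/harm ratio,
and individual risk perception; `gist_round()` maps magnitudes onto the
prominent-number scale {1, 2, 5}×10ⁿ that intuitive assessment is thought to
use. `numeric_indifference()` is an independent bisection oracle that finds
the indifference probability from the two action valuations without the
closed form. A command-line interface (`run_cli()`, or `exec/dsmm`) computes
thresholds, decisions and sweeps from JSON/YAML scenario files; bundled
worked examples are listed by `dsm_examples()`.

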