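Package: dsmm
Title: Dual-Process Threshold Model for Treat/No-Treat Decisions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dual-processing (system I / system II) valuation
    model of medical decision-making and its specialization to the
    treat/no-treat dilemma. Combines an intuitive, probability-insensitive
    system-I valuation (with decision regret as its affective driver) and a
    deliberative expected-utility system-II valuation into a single value,
    and derives the closed-form dual decision threshold: the probability of
    disease at which treating and not treating are equally attractive.
    Provides one-way sensitivity sweeps over the system-I involvement weight
    and over benefit/harm ratios, critical-involvement boundaries for the
    always-treat and never-treat regimes, a prominent-number ("gist")
    rounding heuristic, an independent bisection oracle for the indifference
    point, bundled worked-example scenarios, and a command-line interface
    over JSON/YAML scenario files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
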