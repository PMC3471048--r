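#' Indifference probability by bracketing, without the closed form
#'
#' Finds the disease probability at which the dual-system valuations of
#' treating and not treating are equal, by root-bracketing on the valuation
#' difference built directly from the two action valuations — never from the
#' closed-form threshold. Disagreement between this oracle and
#' [dual_threshold()] is therefore diagnostic of a defect in one of them.
#'
#' The difference is linear in `p`; the search runs over an extended interval
#' (default \[-10, 10\]) so that indifference points outside \[0, 1\] — the
#' always-treat / never-treat regimes — are still located.
#'
#' @param quad An [outcome_quadruple()].
#' @param weights A [dual_weights()] with `gamma < 1`.
#' @param lower,upper Bracketing interval in extended probability space.
#' @param tol Convergence tolerance on the root.
#' @return The indifference probability (possibly outside \[0, 1\]), or
#'   `NA_real_` if the valuation difference has no sign change over the
#'   interval.
#' @export
numeric_indifference <- function(quad, weights, lower = -10, upper = 10,
                                 tol = 1e-12) {
  stopifnot(inherits(quad, "outcome_quadruple"),
            inherits(weights, "dual_weights"))
  if (weights$gamma >= 1) {
    stop("indifference point undefined at gamma = 1 ",
         "(probability plays no role)", call. = FALSE)
  }
  f <- function(p) {
    valuation_treat(p, quad, weights, extended = TRUE) -
      valuation_notreat(p, quad, weights, extended = TRUE)
  }
  fl <- f(lower)
  fu <- f(upper)
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) == sign(fu)) return(NA_real_)
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Generate random treat/no-treat scenarios
#'
#' Reproducible scenario generator for property testing: outcome quadruples
#' are drawn in (0, 1\] with `x1 > x3` and `x4 > x2` (so the derived profile
#' always has positive system-II benefit and harm), `m_I` uniform on (0, 1\],
#' `k` from \{0.5, 1, 2\}, and `gamma` uniform on \[0, 0.99\] except for a 5%
#' admixture of pure system-I decision-makers (`gamma = 1`) so that all four
#' decision regimes, including the categorical one, occur in large draws.
#'
#' @param seed Integer seed; the same seed reproduces the same collection.
#' @param count Number of scenarios (>= 1).
#' @return A list of scenarios, each a list with elements `name`, `quad`
#'   ([outcome_quadruple()]), `weights` ([dual_weights()]), and `profile`
#'   (derived via [profile_from_outcomes()]).
#' @examples
#' sc <- random_scenarios(seed = 1, count = 3)
#' sc[[1]]$profile
#' @export
random_scenarios <- function(seed, count) {
  check_number(seed, "seed")
  check_number(count, "count")
  if (count < 1) stop("`count` must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  lapply(seq_len(count), function(i) {
    u <- sort(stats::runif(2, min = 0.01, max = 1))
    v <- sort(stats::runif(2, min = 0.01, max = 1))
    quad <- outcome_quadruple(x1 = u[2], x2 = v[1], x3 = u[1], x4 = v[2])
    gamma <- if (stats::runif(1) < 0.05) 1 else stats::runif(1, 0, 0.99)
    m_I <- stats::runif(1, .Machine$double.eps, 1)
    k <- sample(c(0.5, 1, 2), 1)
    w <- dual_weights(gamma = gamma, k = k, m_I = m_I)
    list(name = sprintf("random-%d", i), quad = quad, weights = w,
         profile = profile_from_outcomes(quad, w))
  })
}

#' Bundled worked-example scenarios
#'
#' Loads the scenarios shipped with the package: the pulmonary-embolism
#' best/worst cases and the acute-myeloid-leukemia transplant dilemma with
#' pessimistic and optimistic system-I harm perception. Each carries its
#' benefit/harm profile, model parameters, and (where present) expected
#' threshold values with provenance notes. Where a scenario includes an
#' `outcomes` block it is a synthetic quadruple constructed to realize the
#' published profile (so the bisection oracle can run on it), not a set of
#' published utilities.
#'
#' @param name Optional scenario name; omit to get all of them.
#' @return A named list of parsed scenarios (see [parse_scenario()]), or a
#'   single scenario if `name` is given.
#' @examples
#' names(dsm_examples())
#' dsm_examples("aml-pessimistic")$profile
#' @export
dsm_examples <- function(name = NULL) {
  path <- system.file("extdata", "examples.json", package = "dsmm",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  scenarios <- lapply(raw, validate_scenario, source = path)
  names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  if (is.null(name)) return(scenarios)
  if (!name %in% names(scenarios)) {
    stop("no bundled scenario named '", name, "'; available: ",
         paste(names(scenarios), collapse = ", "), call. = FALSE)
  }
  scenarios[[name]]
}
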