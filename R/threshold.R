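#' Utilities of the four treat/disease outcomes
#'
#' The treat/no-treat dilemma has four terminal outcomes: treating a diseased
#' patient (`x1`), treating a non-diseased patient (`x2`), not treating a
#' diseased patient (`x3`), and not treating a non-diseased patient (`x4`).
#' All utilities are strictly positive. In the standard configuration
#' treatment benefits the diseased (`x1 > x3`) and harms the non-diseased
#' (`x4 > x2`); set `standard = FALSE` to describe a treatment that violates
#' either assumption.
#'
#' @param x1 Utility of (treat, disease present).
#' @param x2 Utility of (treat, disease absent).
#' @param x3 Utility of (no treat, disease present).
#' @param x4 Utility of (no treat, disease absent).
#' @param standard Enforce `x1 > x3` and `x4 > x2`? Default `TRUE`.
#' @return An object of class `outcome_quadruple`.
#' @examples
#' outcome_quadruple(x1 = 0.9, x2 = 0.7, x3 = 0.4, x4 = 0.95)
#' @export
outcome_quadruple <- function(x1, x2, x3, x4, standard = TRUE) {
  for (nm in c("x1", "x2", "x3", "x4")) check_number(get(nm), nm)
  if (any(c(x1, x2, x3, x4) <= 0)) {
    stop("all four outcome utilities must be strictly positive",
         call. = FALSE)
  }
  if (standard && !(x1 > x3 && x4 > x2)) {
    stop("standard profile requires x1 > x3 (treatment benefits the ",
         "diseased) and x4 > x2 (treatment harms the non-diseased); ",
         "use standard = FALSE to allow a non-standard quadruple",
         call. = FALSE)
  }
  structure(list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, standard = standard),
            class = "outcome_quadruple")
}

#' System-I regret values for the four outcomes
#'
#' Regret is the loss between the outcome of the action taken and that of the
#' action that, in retrospect, should have been taken; it operates at the
#' system-I level only. Actions that turn out right carry no regret, so the
#' (treat, D+) and (no treat, D-) cells are always zero. The other two cells
#' carry the regret of omission and of commission, in system-I (power-curved)
#' units.
#'
#' @param quad An [outcome_quadruple()].
#' @param weights A [dual_weights()]; only `m_I` is used.
#' @return A list of class `regret_table` with fields `rg_rx_dpos`,
#'   `rg_norx_dpos`, `rg_rx_dneg`, `rg_norx_dneg`.
#' @export
regret_values <- function(quad, weights) {
  stopifnot(inherits(quad, "outcome_quadruple"),
            inherits(weights, "dual_weights"))
  m <- weights$m_I
  structure(
    list(
      rg_rx_dpos   = 0,
      rg_norx_dpos = quad$x3^m - quad$x1^m,
      rg_rx_dneg   = quad$x2^m - quad$x4^m,
      rg_norx_dneg = 0
    ),
    class = "regret_table"
  )
}

#' Benefit/harm profile as seen by the two systems
#'
#' Net benefit is the utility gain from treating a diseased patient versus
#' not; net harm the utility loss from treating a non-diseased patient versus
#' not. `b2`/`h2` are the evidence-based (system-II) quantities that enter the
#' expected-utility threshold; `b1`/`h1` are their subjective, system-I
#' counterparts (gist magnitudes, possibly distorted by affect, memory or
#' recent experience). When the system-I values are not supplied they default
#' to the system-II ones, i.e. a system I that mirrors the evidence.
#'
#' Profiles can also be derived from an [outcome_quadruple()] via
#' [profile_from_outcomes()]; the two construction paths are never mixed.
#'
#' @param b2 System-II net benefit (> 0); utility difference or absolute risk
#'   difference, as a fraction.
#' @param h2 System-II net harm (> 0), same units.
#' @param b1 System-I net benefit (>= 0 in standard mode). Default `b2`.
#' @param h1 System-I net harm (>= 0 in standard mode). Default `h2`.
#' @param standard Enforce `b1 >= 0` and `h1 >= 0`? Default `TRUE`.
#' @return An object of class `benefit_harm_profile`.
#' @examples
#' # pulmonary-embolism worst case: system-I harm exceeds benefit by 0.10
#' benefit_harm_profile(b2 = 0.175, h2 = 0.05, b1 = 0.175, h1 = 0.275)
#' @export
benefit_harm_profile <- function(b2, h2, b1 = b2, h1 = h2, standard = TRUE) {
  for (nm in c("b2", "h2", "b1", "h1")) check_number(get(nm), nm)
  if (b2 <= 0 || h2 <= 0) {
    stop("`b2` and `h2` must be strictly positive ",
         "(the expected-utility threshold requires both)", call. = FALSE)
  }
  if (standard && (b1 < 0 || h1 < 0)) {
    stop("standard profile requires b1 >= 0 and h1 >= 0; ",
         "use standard = FALSE to allow signed system-I values",
         call. = FALSE)
  }
  structure(list(b2 = b2, h2 = h2, b1 = b1, h1 = h1),
            class = "benefit_harm_profile")
}

#' @export
print.benefit_harm_profile <- function(x, ...) {
  cat(sprintf(
    "<benefit_harm_profile> system II: B = %s, H = %s (ratio %.3g); system I: B = %s, H = %s\n",
    format(x$b2), format(x$h2), x$b2 / x$h2, format(x$b1), format(x$h1)
  ))
  invisible(x)
}

#' Derive a benefit/harm profile from outcome utilities
#'
#' System-II net benefit and harm are the plain utility differences
#' `b2 = x1 - x3`, `h2 = x4 - x2`; the system-I counterparts apply the power
#' value function first: `b1 = x1^m - x3^m`, `h1 = x4^m - x2^m` (m = `m_I`).
#' With `m_I = 1` the two systems' magnitudes coincide.
#'
#' @inheritParams regret_values
#' @return A [benefit_harm_profile()].
#' @examples
#' q <- outcome_quadruple(0.9, 0.7, 0.4, 0.95)
#' profile_from_outcomes(q, dual_weights(0.5)) # b2 = 0.5, h2 = 0.25
#' @export
profile_from_outcomes <- function(quad, weights) {
  stopifnot(inherits(quad, "outcome_quadruple"),
            inherits(weights, "dual_weights"))
  m <- weights$m_I
  b2 <- quad$x1 - quad$x3
  h2 <- quad$x4 - quad$x2
  if (b2 <= 0 || h2 <= 0) {
    stop("non-standard profile: derived b2 = ", format(b2), ", h2 = ",
         format(h2), "; the dual threshold requires both positive",
         call. = FALSE)
  }
  benefit_harm_profile(
    b2 = b2, h2 = h2,
    b1 = quad$x1^m - quad$x3^m,
    h1 = quad$x4^m - quad$x2^m
  )
}

#' Dual-system valuation of treating / not treating
#'
#' The value of each action combines the system-I regret values of its two
#' possible outcomes (equal 1/2 weights, probability-insensitive) and the
#' system-II expected utility at disease probability `p`:
#' \deqn{V(Rx) = \frac{\gamma}{2}(x_2^m - x_4^m) + (1-\gamma)k\,(p x_1 + (1-p) x_2)}
#' \deqn{V(NoRx) = \frac{\gamma}{2}(x_3^m - x_1^m) + (1-\gamma)k\,(p x_3 + (1-p) x_4)}
#'
#' @param p Probability of disease, in \[0, 1\] (unless `extended = TRUE`).
#' @param quad An [outcome_quadruple()].
#' @param weights A [dual_weights()].
#' @param extended Allow `p` outside \[0, 1\]? Used by the indifference
#'   oracle to bracket roots that fall outside the probability interval.
#' @return The valuation (a utility).
#' @seealso [dual_threshold()], [numeric_indifference()]
#' @export
valuation_treat <- function(p, quad, weights, extended = FALSE) {
  check_prob(p, extended)
  stopifnot(inherits(quad, "outcome_quadruple"),
            inherits(weights, "dual_weights"))
  g <- weights$gamma
  m <- weights$m_I
  g / 2 * (quad$x2^m - quad$x4^m) +
    (1 - g) * weights$k * (p * quad$x1 + (1 - p) * quad$x2)
}

#' @rdname valuation_treat
#' @export
valuation_notreat <- function(p, quad, weights, extended = FALSE) {
  check_prob(p, extended)
  stopifnot(inherits(quad, "outcome_quadruple"),
            inherits(weights, "dual_weights"))
  g <- weights$gamma
  m <- weights$m_I
  g / 2 * (quad$x3^m - quad$x1^m) +
    (1 - g) * weights$k * (p * quad$x3 + (1 - p) * quad$x4)
}

#' Expected-utility (system-II) treatment threshold
#'
#' The classic therapeutic threshold under pure expected-utility reasoning:
#' the probability of disease at which treating and not treating have equal
#' expected utility, \eqn{p_t = H/(B+H) = 1/(1 + B/H)}.
#'
#' @param profile A [benefit_harm_profile()]; only `b2` and `h2` are used.
#' @return The threshold probability, strictly inside (0, 1).
#' @examples
#' eut_threshold(benefit_harm_profile(b2 = 0.12, h2 = 0.16)) # 0.571
#' @export
eut_threshold <- function(profile) {
  stopifnot(inherits(profile, "benefit_harm_profile"))
  profile$h2 / (profile$b2 + profile$h2)
}

#' Dual-process treatment threshold
#'
#' The probability of disease at which the combined dual-system valuations of
#' treating and not treating are equal:
#' \deqn{p_t = \frac{(1-\gamma) k H_{II} - \frac{\gamma}{2}(B_I - H_I)}
#'                  {(1-\gamma) k (B_{II} + H_{II})}}
#' At `gamma = 0` this reduces to the expected-utility threshold exactly.
#' The raw value can fall outside \[0, 1\]: at or below 0 the decision-maker
#' treats at any disease probability (`always_treat`), at or above 1 only
#' with certainty (`never_treat`). At `gamma = 1` the formula is singular and
#' the decision is purely categorical (`system1_only`): treat iff the
#' system-I benefit exceeds the system-I harm (see [decide()]).
#'
#' @param profile A [benefit_harm_profile()].
#' @param weights A [dual_weights()]; `m_I` plays no role once the profile is
#'   fixed.
#' @return An object of class `threshold_result` with fields `p_eut`,
#'   `p_dual_raw` (may lie outside \[0, 1\]; `NA` when `gamma = 1`), `p_dual`
#'   (clamped to \[0, 1\]), `regime` (one of `"interior"`, `"always_treat"`,
#'   `"never_treat"`, `"system1_only"`), and the `gamma` and `k` used.
#' @examples
#' pe <- benefit_harm_profile(b2 = 0.175, h2 = 0.05, b1 = 0.175, h1 = 0.275)
#' dual_threshold(pe, dual_weights(gamma = 0.77)) # raw threshold 0.966
#' @export
dual_threshold <- function(profile, weights) {
  stopifnot(inherits(profile, "benefit_harm_profile"),
            inherits(weights, "dual_weights"))
  g <- weights$gamma
  k <- weights$k
  p_eut <- eut_threshold(profile)
  if (g == 1) {
    return(new_threshold_result(p_eut, NA_real_, NA_real_, "system1_only",
                                g, k))
  }
  raw <- ((1 - g) * k * profile$h2 - g / 2 * (profile$b1 - profile$h1)) /
    ((1 - g) * k * (profile$b2 + profile$h2))
  regime <- if (raw <= 0) "always_treat" else if (raw >= 1) "never_treat"
            else "interior"
  new_threshold_result(p_eut, raw, min(1, max(0, raw)), regime, g, k)
}

new_threshold_result <- function(p_eut, raw, clamped, regime, gamma, k) {
  structure(
    list(p_eut = p_eut, p_dual_raw = raw, p_dual = clamped,
         regime = regime, gamma = gamma, k = k),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result>\n")
  cat(sprintf("  EUT threshold:  %s\n", format_percent(x$p_eut)))
  if (x$regime == "system1_only") {
    cat("  dual threshold: undefined (gamma = 1, pure system-I decision)\n")
  } else {
    cat(sprintf("  dual threshold: %s (raw %.6g)\n",
                format_percent(x$p_dual), x$p_dual_raw))
  }
  cat(sprintf("  regime: %s   (gamma = %s, k = %s)\n",
              x$regime, format(x$gamma), format(x$k)))
  invisible(x)
}

#' Treat or not, given a disease probability and a threshold
#'
#' Treatment is favored strictly above the threshold and withheld strictly
#' below it; at the threshold (within `tol`) the decision-maker is
#' indifferent. In the `system1_only` regime (`gamma = 1`) the probability
#' plays no role and the decision is the categorical comparison of the
#' system-I benefit and harm.
#'
#' @param p Probability of disease, in \[0, 1\].
#' @param result A `threshold_result` from [dual_threshold()].
#' @param profile The [benefit_harm_profile()] the result was computed from
#'   (consulted only in the `system1_only` regime).
#' @param tol Absolute tolerance for indifference.
#' @return `"treat"`, `"no_treat"`, or `"indifferent"`.
#' @export
decide <- function(p, result, profile, tol = 1e-12) {
  check_prob(p, extended = FALSE)
  stopifnot(inherits(result, "threshold_result"),
            inherits(profile, "benefit_harm_profile"))
  if (result$regime == "system1_only") {
    d <- profile$b1 - profile$h1
    return(if (abs(d) <= tol) "indifferent" else if (d > 0) "treat"
           else "no_treat")
  }
  d <- p - result$p_dual_raw
  if (abs(d) <= tol) "indifferent" else if (d > 0) "treat" else "no_treat"
}

#' Critical system-I involvement for the always/never-treat boundaries
#'
#' Solves the raw dual threshold for the boundary value of `gamma` at which
#' it reaches 1 (`never_treat`: treatment requires diagnostic certainty) or 0
#' (`always_treat`: treatment at any disease probability). Closed forms:
#' \deqn{\gamma^{never} = \frac{B_{II}}{B_{II} + (H_I - B_I)/2k}, \qquad
#'       \gamma^{always} = \frac{H_{II}}{H_{II} + (B_I - H_I)/2k}.}
#' The never-treat boundary is reachable only when the system-I harm exceeds
#' the system-I benefit (the threshold then increases with `gamma`); the
#' always-treat boundary only in the opposite case. When unreachable —
#' including the neutral case `b1 = h1`, where the threshold equals the EUT
#' threshold for every `gamma` — the function returns `NA`.
#'
#' @param profile A [benefit_harm_profile()].
#' @param k System-II scaling constant.
#' @param boundary `"never_treat"` or `"always_treat"`.
#' @return The critical gamma in (0, 1), or `NA_real_` if that boundary is
#'   unreachable.
#' @examples
#' aml <- benefit_harm_profile(b2 = 0.12, h2 = 0.16, b1 = 0.12, h1 = 0.32)
#' critical_gamma(aml, boundary = "never_treat") # 0.5454...
#' @export
critical_gamma <- function(profile, k = 1,
                           boundary = c("never_treat", "always_treat")) {
  stopifnot(inherits(profile, "benefit_harm_profile"))
  check_number(k, "k")
  if (k <= 0) stop("`k` must be strictly positive", call. = FALSE)
  boundary <- match.arg(boundary)
  d <- profile$b1 - profile$h1
  g <- switch(boundary,
    never_treat  = profile$b2 / (profile$b2 + (-d) / (2 * k)),
    always_treat = profile$h2 / (profile$h2 + d / (2 * k))
  )
  if (!is.finite(g) || g <= 0 || g >= 1) NA_real_ else g
}

# p must be a probability unless the caller explicitly works on the
# extended real line (indifference oracle)
check_prob <- function(p, extended) {
  check_number(p, "p")
  if (!extended && (p < 0 || p > 1)) {
    stop("`p` must lie in [0, 1], got ", format(p), call. = FALSE)
  }
  invisible(p)
}

#' Format a fraction as a percent string
#'
#' All internal computation is in fractions; percent appears only at the I/O
#' boundary, formatted to one decimal place.
#'
#' @param x Numeric fraction(s).
#' @param digits Decimal places, default 1.
#' @return Character vector like `"96.6%"`.
#' @export
format_percent <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f%%"), 100 * x))
}
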