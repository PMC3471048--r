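#' Dual-system model parameters
#'
#' Bundles the three parameters of the dual-system valuation: the relative
#' involvement of system I (`gamma`), the scaling constant on the system-II
#' (expected-utility) term (`k`), and the curvature exponent of the system-I
#' power value function (`m_I`).
#'
#' @param gamma Weight of system I in the combined valuation, in \[0, 1\].
#'   `gamma = 0` is a pure expected-utility decision-maker; `gamma = 1` a pure
#'   system-I (intuitive) one.
#' @param k Positive scaling constant on the system-II term. Defaults to 1,
#'   the value used throughout the worked examples.
#' @param m_I Exponent of the system-I value function \eqn{x^{m_I}}, in
#'   (0, 1\]. Values below 1 give risk aversion for gains; `m_I = 1` makes the
#'   system-I value function linear so system-I and system-II magnitudes
#'   coincide.
#'
#' @return An object of class `dual_weights`.
#' @examples
#' dual_weights(gamma = 0.5)
#' dual_weights(gamma = 0.77, k = 1, m_I = 1)
#' @export
dual_weights <- function(gamma, k = 1, m_I = 1) {
  check_number(gamma, "gamma")
  check_number(k, "k")
  check_number(m_I, "m_I")
  if (gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1], got ", format(gamma), call. = FALSE)
  }
  if (k <= 0) {
    stop("`k` must be strictly positive, got ", format(k), call. = FALSE)
  }
  if (m_I <= 0 || m_I > 1) {
    stop("`m_I` must lie in (0, 1], got ", format(m_I), call. = FALSE)
  }
  structure(list(gamma = gamma, k = k, m_I = m_I), class = "dual_weights")
}

#' @export
print.dual_weights <- function(x, ...) {
  cat(sprintf(
    "<dual_weights> gamma = %s, k = %s, m_I = %s\n",
    format(x$gamma), format(x$k), format(x$m_I)
  ))
  invisible(x)
}

#' A risky choice: outcomes with values and probabilities
#'
#' A decision-making situation described by `n` outcomes, each with a strictly
#' positive utility and a probability. Probabilities must sum to one.
#' Duplicate outcome values are kept as listed: the system-I valuation
#' averages over outcomes as enumerated, so splitting an event into two
#' identical outcomes changes the system-I value (event-splitting sensitivity
#' is a property of the model, not an accident of implementation).
#'
#' @param values Numeric vector of outcome utilities, all > 0.
#' @param probabilities Numeric vector of the same length, each in \[0, 1\],
#'   summing to 1 within 1e-9.
#' @param label Optional text label for the choice.
#'
#' @return An object of class `risky_choice`.
#' @examples
#' risky_choice(c(4, 9), c(0.2, 0.8), label = "gamble")
#' @export
risky_choice <- function(values, probabilities, label = "") {
  if (!is.numeric(values) || length(values) < 1 || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("all outcome values must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(probabilities) || length(probabilities) != length(values) ||
      anyNA(probabilities)) {
    stop("`probabilities` must be numeric, without NA, one per outcome",
         call. = FALSE)
  }
  if (any(probabilities < 0) || any(probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (tolerance 1e-9); got ",
         format(sum(probabilities), digits = 12), call. = FALSE)
  }
  structure(
    list(values = as.numeric(values),
         probabilities = as.numeric(probabilities),
         label = as.character(label)[1]),
    class = "risky_choice"
  )
}

#' @export
print.risky_choice <- function(x, ...) {
  lbl <- if (nzchar(x$label)) paste0(" '", x$label, "'") else ""
  cat(sprintf("<risky_choice>%s %d outcome(s)\n", lbl, length(x$values)))
  print(data.frame(value = x$values, probability = x$probabilities))
  invisible(x)
}

#' System-I (intuitive) valuation of a risky choice
#'
#' System I is sensitive only to the presence or absence of outcomes, not to
#' their probabilities: every outcome under consideration gets equal weight
#' 1/n, and values enter through the power function \eqn{x^{m_I}}. The result
#' is therefore invariant under any change of the probabilities.
#'
#' @param choice A [risky_choice()].
#' @param weights A [dual_weights()]; only `m_I` is used.
#' @return The system-I value, \eqn{(1/n) \sum_i x_i^{m_I}}.
#' @examples
#' value_system1(risky_choice(c(4, 9), c(0.2, 0.8)), dual_weights(0.5, m_I = 0.5))
#' @export
value_system1 <- function(choice, weights) {
  stopifnot(inherits(choice, "risky_choice"), inherits(weights, "dual_weights"))
  mean(choice$values ^ weights$m_I)
}

#' System-II (deliberative) valuation of a risky choice
#'
#' System II values the choice linearly in probability, as in expected utility
#' theory, scaled by the constant `k`.
#'
#' @inheritParams value_system1
#' @return The system-II value, \eqn{k \sum_i p_i x_i}.
#' @examples
#' value_system2(risky_choice(c(1, 3), c(0.5, 0.5)), dual_weights(0.5, k = 2))
#' @export
value_system2 <- function(choice, weights) {
  stopifnot(inherits(choice, "risky_choice"), inherits(weights, "dual_weights"))
  weights$k * sum(choice$probabilities * choice$values)
}

#' Combined dual-system valuation
#'
#' The overall value of a risky choice is the convex combination of the
#' system-I and system-II valuations with weight `gamma` on system I:
#' \deqn{V(C) = \gamma \frac{1}{n}\sum_i x_i^{m_I} + (1-\gamma)\, k \sum_i p_i x_i.}
#'
#' @inheritParams value_system1
#' @return The combined value.
#' @examples
#' ch <- risky_choice(c(2, 4), c(0.1, 0.9))
#' dsm_value(ch, dual_weights(gamma = 0.5)) # 0.5*3 + 0.5*3.8 = 3.4
#' @export
dsm_value <- function(choice, weights) {
  g <- weights$gamma
  g * value_system1(choice, weights) + (1 - g) * value_system2(choice, weights)
}

#' Compare two risky choices by dual-system value
#'
#' @param a,b [risky_choice()] objects.
#' @param weights A [dual_weights()].
#' @param tol Absolute indifference tolerance on the value difference.
#' @return `"a"`, `"b"`, or `"indifferent"`.
#' @export
compare_choices <- function(a, b, weights, tol = 1e-12) {
  d <- dsm_value(a, weights) - dsm_value(b, weights)
  if (abs(d) <= tol) "indifferent" else if (d > 0) "a" else "b"
}

# shared scalar check
check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
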