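test_that("regret vanishes for retrospectively correct actions only", {
  w <- dual_weights(0.5, m_I = 1)
  q <- outcome_quadruple(x1 = 0.9, x2 = 0.7, x3 = 0.4, x4 = 0.95)
  rg <- regret_values(q, w)
  expect_equal(rg$rg_rx_dpos, 0)
  expect_equal(rg$rg_norx_dneg, 0)
  expect_equal(rg$rg_norx_dpos, -0.5)   # x3 - x1 at m_I = 1
  expect_equal(rg$rg_rx_dneg, 0.7 - 0.95)

  # no benefit -> no regret of omission; no harm -> no regret of commission
  q_eq_b <- outcome_quadruple(0.4, 0.7, 0.4, 0.95, standard = FALSE)
  expect_equal(regret_values(q_eq_b, w)$rg_norx_dpos, 0)
  q_eq_h <- outcome_quadruple(0.9, 0.95, 0.4, 0.95, standard = FALSE)
  expect_equal(regret_values(q_eq_h, w)$rg_rx_dneg, 0)
})

test_that("profile derivation applies the system-I power curve", {
  q <- outcome_quadruple(0.9, 0.7, 0.4, 0.95)
  pr <- profile_from_outcomes(q, dual_weights(0.5, m_I = 1))
  expect_equal(pr$b2, 0.5)
  expect_equal(pr$h2, 0.25)
  # with m_I = 1 the two systems' magnitudes coincide
  expect_equal(pr$b1, pr$b2)
  expect_equal(pr$h1, pr$h2)

  q2 <- outcome_quadruple(0.81, 0.49, 0.36, 1.0)
  pr2 <- profile_from_outcomes(q2, dual_weights(0.5, m_I = 0.5))
  expect_equal(pr2$b1, 0.3)   # 0.9 - 0.6
  expect_equal(pr2$h1, 0.3)   # 1.0 - 0.7

  # treatment that does not benefit the diseased is a non-standard profile
  q_bad <- outcome_quadruple(0.4, 0.7, 0.9, 0.95, standard = FALSE)
  expect_error(profile_from_outcomes(q_bad, dual_weights(0.5)),
               "non-standard")
  expect_error(outcome_quadruple(0.4, 0.7, 0.9, 0.95), "standard profile")
})

test_that("action valuations reduce to expected utility at gamma 0 and match the dual-system value", {
  q <- outcome_quadruple(0.9, 0.7, 0.4, 0.95)
  w0 <- dual_weights(0, k = 1)
  p <- 0.3
  expect_equal(valuation_treat(p, q, w0), p * 0.9 + (1 - p) * 0.7)
  expect_equal(valuation_notreat(p, q, w0), p * 0.4 + (1 - p) * 0.95)
  expect_equal(valuation_notreat(0, q, w0), 0.95)

  # gamma = 1: probability drops out entirely
  w1 <- dual_weights(1)
  expect_equal(valuation_treat(0.1, q, w1), valuation_treat(0.9, q, w1))

  # cross-module oracle: each action valuation equals the combined
  # dual-system value of its branch, with system-I values from the regret
  # table and system-II from the linear expected-utility term
  set.seed(11)
  for (i in 1:100) {
    u <- sort(runif(2, 0.01, 1)); v <- sort(runif(2, 0.01, 1))
    q <- outcome_quadruple(u[2], v[1], u[1], v[2])
    w <- dual_weights(gamma = runif(1), k = sample(c(0.5, 1, 2), 1),
                      m_I = runif(1, 0.1, 1))
    p <- runif(1)
    rg <- regret_values(q, w)
    treat_branch <- risky_choice(c(q$x1, q$x2), c(p, 1 - p))
    expect_equal(
      valuation_treat(p, q, w),
      w$gamma * mean(c(rg$rg_rx_dpos, rg$rg_rx_dneg)) +
        (1 - w$gamma) * value_system2(treat_branch, w),
      tolerance = 1e-12
    )
    notreat_branch <- risky_choice(c(q$x3, q$x4), c(p, 1 - p))
    expect_equal(
      valuation_notreat(p, q, w),
      w$gamma * mean(c(rg$rg_norx_dpos, rg$rg_norx_dneg)) +
        (1 - w$gamma) * value_system2(notreat_branch, w),
      tolerance = 1e-12
    )
  }
})

test_that("expected-utility threshold is H/(B+H)", {
  expect_equal(round(100 * eut_threshold(benefit_harm_profile(60.8, 1)), 1),
               1.6)
  expect_equal(eut_threshold(benefit_harm_profile(0.3, 0.3)), 0.5)
  expect_equal(round(eut_threshold(aml_profile()), 3), 0.571)
  expect_error(benefit_harm_profile(0, 0.1), "strictly positive")
  expect_error(benefit_harm_profile(0.1, -1), "strictly positive")
})

test_that("dual threshold reproduces the pulmonary-embolism worked case", {
  res <- dual_threshold(pe_worst_profile(), dual_weights(gamma = 0.77))
  expect_equal(res$p_dual_raw, 0.96618357487922713, tolerance = 1e-12)
  expect_identical(res$regime, "interior")
  expect_equal(res$p_eut, 1 / (1 + 3.5))

  # a slightly more intuition-driven decision-maker requires certainty
  res78 <- dual_threshold(pe_worst_profile(), dual_weights(gamma = 0.78))
  expect_gte(res78$p_dual_raw, 1)
  expect_identical(res78$regime, "never_treat")
  expect_equal(res78$p_dual, 1)
})

test_that("dual threshold limits, neutrality, direction and regime labels", {
  set.seed(23)
  for (i in 1:200) {
    prof <- benefit_harm_profile(b2 = runif(1, 0.01, 1),
                                 h2 = runif(1, 0.01, 1),
                                 b1 = runif(1, 0, 1), h1 = runif(1, 0, 1))
    g <- runif(1, 0, 0.99)
    k <- sample(c(0.5, 1, 2), 1)
    res <- dual_threshold(prof, dual_weights(g, k = k))

    # clamping and regime classification
    expect_equal(res$p_dual, min(1, max(0, res$p_dual_raw)))
    expect_identical(res$regime,
                     if (res$p_dual_raw <= 0) "always_treat"
                     else if (res$p_dual_raw >= 1) "never_treat"
                     else "interior")

    # gamma = 0 recovers expected utility exactly
    res0 <- dual_threshold(prof, dual_weights(0, k = k))
    expect_identical(res0$p_dual_raw, res0$p_eut)

    # side of the EUT threshold is set by sign(b1 - h1) alone
    d <- prof$b1 - prof$h1
    if (g > 0) {
      if (d > 0) expect_lt(res$p_dual_raw, res$p_eut)
      if (d < 0) expect_gt(res$p_dual_raw, res$p_eut)
    }
    # ... and k cannot flip it
    res_k <- dual_threshold(prof, dual_weights(g, k = 5 * k))
    expect_identical(sign(res$p_dual_raw - res$p_eut) * (g > 0),
                     sign(res_k$p_dual_raw - res_k$p_eut) * (g > 0))
  }

  # neutral system I: threshold equals EUT threshold for every gamma
  prof_n <- benefit_harm_profile(0.3, 0.1, b1 = 0.2, h1 = 0.2)
  for (g in seq(0, 0.98, by = 0.07)) {
    res <- dual_threshold(prof_n, dual_weights(g))
    expect_equal(res$p_dual_raw, res$p_eut, tolerance = 1e-15)
  }

  # monotonicity in gamma per sign(h1 - b1)
  gs <- seq(0, 0.99, by = 0.01)
  up <- vapply(gs, function(g)
    dual_threshold(aml_profile(h1 = 0.32), dual_weights(g))$p_dual_raw,
    numeric(1))
  expect_true(all(diff(up) > 0))
  down <- vapply(gs, function(g)
    dual_threshold(aml_profile(h1 = 0.08), dual_weights(g))$p_dual_raw,
    numeric(1))
  expect_true(all(diff(down) < 0))
})

test_that("pure system-I decisions are categorical in b1 vs h1", {
  prof <- aml_profile(h1 = 0.32)
  res <- dual_threshold(prof, dual_weights(gamma = 1))
  expect_identical(res$regime, "system1_only")
  expect_true(is.na(res$p_dual_raw))
  # harm felt larger than benefit: never treat, at any probability
  for (p in c(0, 0.5, 1)) {
    expect_identical(decide(p, res, prof), "no_treat")
  }
  prof_b <- aml_profile(h1 = 0.08)
  res_b <- dual_threshold(prof_b, dual_weights(gamma = 1))
  expect_identical(decide(0.01, res_b, prof_b), "treat")
  prof_eq <- aml_profile(h1 = 0.12)
  res_eq <- dual_threshold(prof_eq, dual_weights(gamma = 1))
  expect_identical(decide(0.5, res_eq, prof_eq), "indifferent")
})

test_that("treat above the threshold, withhold below, indifferent at it", {
  prof <- aml_profile()
  res <- dual_threshold(prof, dual_weights(gamma = 0))
  expect_identical(decide(0.5, res, prof), "no_treat")   # 0.5 < 0.571
  expect_identical(decide(0.6, res, prof), "treat")
  expect_identical(decide(res$p_dual_raw, res, prof), "indifferent")
})

test_that("critical gamma closed forms match the transplant worked case", {
  # doubled perceived harm: transplant refused for gamma above ~55%
  g_never <- critical_gamma(aml_profile(h1 = 0.32), boundary = "never_treat")
  expect_equal(g_never, 0.12 / 0.22, tolerance = 1e-12)
  expect_equal(round(100 * g_never), 55)
  # halved perceived harm: transplant for everyone above ~89%
  g_always <- critical_gamma(aml_profile(h1 = 0.08),
                             boundary = "always_treat")
  expect_equal(g_always, 0.16 / 0.18, tolerance = 1e-12)
  expect_equal(round(100 * g_always), 89)

  # the returned gamma brackets the boundary
  eps <- 1e-6
  raw_at <- function(prof, g) dual_threshold(prof, dual_weights(g))$p_dual_raw
  expect_lt(raw_at(aml_profile(h1 = 0.32), g_never - eps), 1)
  expect_gt(raw_at(aml_profile(h1 = 0.32), g_never + eps), 1)
  expect_gt(raw_at(aml_profile(h1 = 0.08), g_always - eps), 0)
  expect_lt(raw_at(aml_profile(h1 = 0.08), g_always + eps), 0)

  # unreachable boundaries: neutral system I, or imbalance of the wrong sign
  expect_true(is.na(critical_gamma(aml_profile(h1 = 0.12),
                                   boundary = "never_treat")))
  expect_true(is.na(critical_gamma(aml_profile(h1 = 0.12),
                                   boundary = "always_treat")))
  expect_true(is.na(critical_gamma(aml_profile(h1 = 0.32),
                                   boundary = "always_treat")))
  expect_true(is.na(critical_gamma(aml_profile(h1 = 0.08),
                                   boundary = "never_treat")))
})
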