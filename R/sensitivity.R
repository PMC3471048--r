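#' Sweep the dual threshold over system-I involvement
#'
#' One-way sensitivity analysis of the dual threshold in `gamma`, holding the
#' benefit/harm profile fixed. The curve is flat at the expected-utility
#' threshold when the system-I benefit and harm are equal, rises with `gamma`
#' when harm dominates, and falls when benefit dominates. The grid stops just
#' short of 1 by default: at `gamma = 1` the threshold formula is singular
#' and the decision is purely categorical.
#'
#' @param profile A [benefit_harm_profile()].
#' @param gammas Strictly increasing grid of `gamma` values in \[0, 1).
#' @param k System-II scaling constant.
#' @return A tibble with one row per grid point: `gamma`, `p_eut`,
#'   `p_dual_raw`, `p_dual`, `regime`.
#' @examples
#' pe <- benefit_harm_profile(0.175, 0.05, b1 = 0.175, h1 = 0.275)
#' gamma_sweep(pe, gammas = seq(0, 0.9, by = 0.1))
#' @export
gamma_sweep <- function(profile,
                        gammas = seq(0, 1 - 1e-6, length.out = 100),
                        k = 1) {
  check_grid(gammas, "gammas")
  if (any(gammas < 0) || any(gammas >= 1)) {
    stop("`gammas` must lie in [0, 1)", call. = FALSE)
  }
  rows <- lapply(gammas, function(g) {
    r <- dual_threshold(profile, dual_weights(gamma = g, k = k))
    tibble::tibble(gamma = g, p_eut = r$p_eut, p_dual_raw = r$p_dual_raw,
                   p_dual = r$p_dual, regime = r$regime)
  })
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- list(profile = profile, k = k, grid_var = "gamma")
  out
}

#' Sweep the threshold over the benefit/harm ratio
#'
#' Traces the threshold as a function of the system-II benefit/harm ratio
#' (`h2` held fixed, `b2 = ratio * h2`), with three curves per grid point:
#' the expected-utility threshold `1/(1 + ratio)`, a system-I
#' benefit-dominant curve (`b1 - h1 = +shift`, always below the EUT curve),
#' and a harm-dominant curve (`b1 - h1 = -shift`, always above it).
#'
#' @param ratios Strictly increasing grid of positive `b2/h2` ratios.
#' @param h2 Fixed system-II net harm defining the scale.
#' @param shift Magnitude of the system-I benefit-harm imbalance per curve.
#' @param gamma System-I involvement for the two dual curves.
#' @param k System-II scaling constant.
#' @return A tibble with columns `ratio`, `curve` (`"eut"`,
#'   `"system1_benefit"`, `"system1_harm"`), `p_eut`, `p_dual_raw`, `p_dual`,
#'   `regime`.
#' @export
ratio_sweep <- function(ratios, h2 = 0.05, shift = 0.05, gamma = 0.5, k = 1) {
  check_grid(ratios, "ratios")
  if (any(ratios <= 0)) stop("`ratios` must be positive", call. = FALSE)
  check_number(shift, "shift")
  if (shift < 0) stop("`shift` must be non-negative", call. = FALSE)
  w <- dual_weights(gamma = gamma, k = k)
  curves <- list(
    eut             = c(b1 = 0, h1 = 0),
    system1_benefit = c(b1 = shift, h1 = 0),
    system1_harm    = c(b1 = 0, h1 = shift)
  )
  rows <- lapply(ratios, function(r) {
    do.call(rbind, lapply(names(curves), function(nm) {
      s <- curves[[nm]]
      prof <- benefit_harm_profile(b2 = r * h2, h2 = h2,
                                   b1 = s[["b1"]], h1 = s[["h1"]])
      res <- dual_threshold(prof, w)
      tibble::tibble(ratio = r, curve = nm, p_eut = res$p_eut,
                     p_dual_raw = res$p_dual_raw, p_dual = res$p_dual,
                     regime = res$regime)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- list(h2 = h2, shift = shift, gamma = gamma, k = k,
                             grid_var = "ratio")
  out
}

#' Threshold grid over individual risk perception
#'
#' Reproduces the structure of a two-way behavior table: with `gamma` and the
#' objective benefit/harm ratio fixed, the threshold is tabulated over how
#' strongly system I feels the harm relative to the evidence (`h1/h2`) and
#' how it weighs benefit against harm internally (`b1/h1`). Cells whose raw
#' threshold escapes \[0, 1\] are labeled with the `always_treat` /
#' `never_treat` regime: such a decision-maker accepts or rejects treatment
#' regardless of the disease probability.
#'
#' @param gamma System-I involvement weight.
#' @param ratio Objective (system-II) benefit/harm ratio `b2/h2`.
#' @param h1_over_h2_grid Positive grid of perceived-to-evidence harm ratios.
#' @param b1_over_h1_grid Positive grid of system-I benefit-to-harm ratios.
#' @param h2 System-II net harm fixing the scale.
#' @param k System-II scaling constant.
#' @return A tibble with one row per cell: `h1_over_h2`, `b1_over_h1`, the
#'   implied `b1` and `h1`, `p_eut`, `p_dual_raw`, `p_dual`, `regime`.
#' @export
behavior_grid <- function(gamma = 0.5, ratio = 10,
                          h1_over_h2_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                          b1_over_h1_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                          h2 = 0.05, k = 1) {
  check_grid(h1_over_h2_grid, "h1_over_h2_grid")
  check_grid(b1_over_h1_grid, "b1_over_h1_grid")
  if (any(h1_over_h2_grid <= 0) || any(b1_over_h1_grid <= 0)) {
    stop("grids must be positive", call. = FALSE)
  }
  w <- dual_weights(gamma = gamma, k = k)
  cells <- expand.grid(h1_over_h2 = h1_over_h2_grid,
                       b1_over_h1 = b1_over_h1_grid)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    h1 <- cells$h1_over_h2[i] * h2
    b1 <- cells$b1_over_h1[i] * h1
    prof <- benefit_harm_profile(b2 = ratio * h2, h2 = h2, b1 = b1, h1 = h1)
    res <- dual_threshold(prof, w)
    tibble::tibble(h1_over_h2 = cells$h1_over_h2[i],
                   b1_over_h1 = cells$b1_over_h1[i],
                   b1 = b1, h1 = h1, p_eut = res$p_eut,
                   p_dual_raw = res$p_dual_raw, p_dual = res$p_dual,
                   regime = res$regime)
  })
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- list(gamma = gamma, ratio = ratio, h2 = h2, k = k,
                             grid_var = c("h1_over_h2", "b1_over_h1"))
  out
}

#' Four-panel gamma sweep across benefit/harm regimes
#'
#' Bundled presets covering the qualitative regimes of the objective
#' evidence: benefit vastly exceeding harm (ratio 60.8, the best-case
#' pulmonary-embolism figure), moderately exceeding it (3.5, the worst case),
#' equal, and harm exceeding benefit. Each panel carries a benefit-dominant
#' and a harm-dominant system-I curve (`b1 - h1 = +/- shift`). The `h2`
#' magnitudes for the non-PE panels are illustrative, not canonical.
#'
#' @param ratios Named or unnamed vector of `b2/h2` ratios, one per panel.
#' @param h2 Fixed system-II net harm.
#' @param shift System-I benefit/harm imbalance (default 0.05, i.e. 5%).
#' @param gammas Gamma grid, in \[0, 1).
#' @param k System-II scaling constant.
#' @return A tibble with columns `panel`, `ratio`, `curve`
#'   (`"system1_benefit"` / `"system1_harm"`), `gamma`, `p_eut`,
#'   `p_dual_raw`, `p_dual`, `regime`.
#' @export
threshold_gamma_panels <- function(ratios = c(60.8, 3.5, 1, 0.5),
                                   h2 = 0.05, shift = 0.05,
                                   gammas = seq(0, 1 - 1e-6,
                                                length.out = 100),
                                   k = 1) {
  shifts <- c(system1_benefit = shift, system1_harm = -shift)
  panels <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    do.call(rbind, lapply(names(shifts), function(nm) {
      s <- shifts[[nm]]
      prof <- benefit_harm_profile(b2 = r * h2, h2 = h2,
                                   b1 = max(s, 0), h1 = max(-s, 0))
      sw <- gamma_sweep(prof, gammas = gammas, k = k)
      tibble::tibble(panel = i, ratio = r, curve = nm, sw)
    }))
  })
  do.call(rbind, panels)
}

#' Round to the nearest prominent number
#'
#' The "gist" heuristic: system I assesses magnitudes not exactly but on the
#' prominent-number scale \{1, 2, 5\} x 10^n (1, 2, 5, 10, 20, 50, ...).
#' Rounds each value to the nearest prominent number in log10 distance; exact
#' ties go to the larger prominent number. Idempotent, and covariant under
#' multiplication by powers of 10.
#'
#' @param x Positive numeric vector.
#' @return Vector of prominent numbers, same length as `x`.
#' @examples
#' gist_round(c(60.8, 3.5, 10)) # 50, 5, 10
#' @export
gist_round <- function(x) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x)) {
    stop("`x` must be numeric without NA", call. = FALSE)
  }
  if (any(x <= 0)) stop("`x` must be strictly positive", call. = FALSE)
  vapply(x, function(xi) {
    lx <- log10(xi)
    n <- floor(lx)
    cand <- c(1, 2, 5, 10) * 10^n          # brackets xi within one decade
    d <- abs(log10(cand) - lx)
    # ties-to-larger: among minimal distances take the largest candidate
    max(cand[d <= min(d) + 1e-15])
  }, numeric(1))
}

#' Write a sweep result to CSV
#'
#' One header row, one data row per grid point; full precision, no
#' timestamps, so repeated runs produce byte-identical output.
#'
#' @param result A tibble from [gamma_sweep()], [ratio_sweep()] or
#'   [behavior_grid()].
#' @param path File path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path = "") {
  stopifnot(is.data.frame(result))
  utils::write.csv(as.data.frame(result), file = path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot a sweep through a caller-supplied callback
#'
#' The package does not bit-specify figures; instead the sweep rows are
#' handed to `callback` (default: a ggplot2 line plot of the clamped
#' threshold against the grid variable, if ggplot2 is available).
#'
#' @param result A sweep tibble.
#' @param callback A function of one argument (the sweep tibble); its return
#'   value is passed through.
#' @return Whatever `callback` returns.
#' @export
plot_sweep <- function(result, callback = NULL) {
  stopifnot(is.data.frame(result))
  if (!is.null(callback)) return(callback(result))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("supply `callback` or install ggplot2", call. = FALSE)
  }
  xvar <- if ("gamma" %in% names(result)) "gamma" else "ratio"
  aes <- if ("curve" %in% names(result)) {
    ggplot2::aes(x = .data[[xvar]], y = .data[["p_dual"]],
                 colour = .data[["curve"]])
  } else {
    ggplot2::aes(x = .data[[xvar]], y = .data[["p_dual"]])
  }
  ggplot2::ggplot(result, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "dual decision threshold")
}

check_grid <- function(g, name) {
  if (!is.numeric(g) || length(g) < 1 || anyNA(g)) {
    stop("`", name, "` must be a non-empty numeric grid", call. = FALSE)
  }
  if (length(g) > 1 && any(diff(g) <= 0)) {
    stop("`", name, "` must be strictly increasing", call. = FALSE)
  }
  invisible(g)
}
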