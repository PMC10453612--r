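#' Normalize raw cell counts to percent growth of control
#'
#' Growth under treatment is expressed relative to the untreated control after
#' subtracting the background cell number present when treatment started:
#' \deqn{growth\% = 100 (n_{treated} - n_{background}) /
#'                  (n_{control} - n_{background}).}
#' The result can be negative (net cell loss below the starting number) or
#' exceed 100 (treatment outgrew the control).
#'
#' @param n_treated Cell count in the treated well at endpoint.
#' @param n_control Cell count in the untreated control well at endpoint.
#' @param n_background Cell count at the start of treatment.
#' @return Growth as a percentage of control (numeric, vectorised).
#' @examples
#' normalize_growth(16500, 27500, 5500) # 50
#' @export
normalize_growth <- function(n_treated, n_control, n_background) {
  if (any(n_control <= n_background)) {
    stop_rescuekit(
      "Control wells did not grow beyond background: cannot normalize.",
      "rescuekit_degenerate_control_error"
    )
  }
  100 * (n_treated - n_background) / (n_control - n_background)
}

#' Fit the median-effect model to a dose-response table
#'
#' Fits the median-effect law \eqn{f_a/f_u = (D/D_m)^m}, where \eqn{f_a} is
#' the fraction affected (1 - growth/100), \eqn{f_u = 1 - f_a}, \eqn{D_m}
#' the median-effect dose (the IC50 of the fit) and \eqn{m} the shape
#' coefficient. Fitting is by least squares on the linearized form
#' \eqn{\log_{10}(f_a/f_u) = m \log_{10} D - m \log_{10} D_m}.
#'
#' Points with growth at or outside (0, 100) carry no information on the
#' log-odds scale and are dropped (their count is reported via a message and
#' kept in the returned object). Duplicate doses are averaged before fitting.
#'
#' @param data Data frame with columns `dose` and `growth_pct` (percent of
#'   no-drug control). Extra columns are ignored.
#' @return An object of class `medfit` with elements `m`, `dm`, `r`
#'   (correlation of the linearized fit), `n_points`, `n_dropped` and the
#'   fitted points. Supports [tidy()], [glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @seealso [ic50()], [combination_index()]
#' @examples
#' d <- sim_dose_response(m = 1, Dm = 100, doses = c(25, 50, 100, 200, 400),
#'                        noise_sd = 0)
#' fit_median_effect(d)
#' @export
fit_median_effect <- function(data) {
  stopifnot(is.data.frame(data), all(c("dose", "growth_pct") %in% names(data)))
  pts <- tibble(dose = as.numeric(data$dose),
                growth_pct = as.numeric(data$growth_pct))
  if (any(pts$dose < 0) || any(!is.finite(pts$growth_pct))) {
    stop_rescuekit("Doses must be >= 0 and growth values finite.",
                   "rescuekit_parameter_error")
  }
  pts <- dplyr::filter(pts, .data$dose > 0)
  # average replicate/duplicate doses before assessing usability
  pts <- pts |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(growth_pct = mean(.data$growth_pct), .groups = "drop")
  usable <- pts$growth_pct > 0 & pts$growth_pct < 100
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    inform(sprintf(
      "fit_median_effect: dropped %d point(s) with growth outside (0, 100).",
      n_dropped))
  }
  pts <- pts[usable, ]
  if (nrow(pts) < 3L) {
    stop_rescuekit(
      "Need at least 3 distinct positive doses with growth strictly inside (0, 100).",
      "rescuekit_insufficient_data_error"
    )
  }
  fa <- 1 - pts$growth_pct / 100
  x <- log10(pts$dose)
  y <- log10(fa / (1 - fa))
  if (sd(y) == 0) {
    stop_rescuekit(
      "All usable points have the same effect level; median-effect slope is undefined.",
      "rescuekit_unfittable_error"
    )
  }
  ls <- stats::lm(y ~ x)
  m <- unname(stats::coef(ls)[2])
  if (!is.finite(m) || m == 0) {
    stop_rescuekit("Median-effect slope is zero or undefined; Dm is unfittable.",
                   "rescuekit_unfittable_error")
  }
  dm <- 10^(-unname(stats::coef(ls)[1]) / m)
  r <- stats::cor(x, y)
  structure(
    list(m = m, dm = dm, r = r, n_points = nrow(pts), n_dropped = n_dropped,
         points = tibble(dose = pts$dose, growth_pct = pts$growth_pct,
                         log10_dose = x, log10_fa_fu = y)),
    class = "medfit"
  )
}

#' @export
print.medfit <- function(x, ...) {
  cat("Median-effect fit\n")
  cat(sprintf("  m (shape): %.4f\n  Dm (IC50): %.4g\n  r: %.4f\n  points: %d (%d dropped)\n",
              x$m, x$dm, x$r, x$n_points, x$n_dropped))
  invisible(x)
}

#' @export
predict.medfit <- function(object, dose, ...) {
  fa <- 1 / (1 + (object$dm / dose)^object$m)
  fa[dose == 0] <- 0
  100 * (1 - fa)
}

#' @rdname fit_median_effect
#' @param x,object A `medfit` object.
#' @param ... Unused.
#' @export
tidy.medfit <- function(x, ...) {
  tibble(term = c("m", "dm"),
         estimate = c(x$m, x$dm),
         description = c("dose-effect shape coefficient",
                         "median-effect dose (IC50)"))
}

#' @rdname fit_median_effect
#' @export
glance.medfit <- function(x, ...) {
  tibble(m = x$m, dm = x$dm, r = x$r, r.squared = x$r^2,
         n_points = x$n_points, n_dropped = x$n_dropped)
}

#' IC50 from a single dose-growth observation
#'
#' Computes the dose producing 50% growth inhibition from one observed
#' (dose, growth) pair under the median-effect law with shape `m`:
#' \deqn{IC_{50} = D / (100/y - 1)^{1/m}.}
#'
#' @param dose Observed dose (> 0).
#' @param growth_pct Observed growth as percent of control, strictly inside
#'   (0, 100).
#' @param m Shape coefficient of the dose-effect relationship (> 0).
#' @return The IC50, in the units of `dose`.
#' @examples
#' ic50(100, 20, 1) # 25
#' ic50(100, 80, 2) # 200
#' @export
ic50 <- function(dose, growth_pct, m) {
  assert_scalar_number(dose, "dose", lower = 0, strict_lower = TRUE)
  assert_scalar_number(m, "m", lower = 0, strict_lower = TRUE)
  if (!is.numeric(growth_pct) || any(growth_pct <= 0 | growth_pct >= 100)) {
    stop_rescuekit("`growth_pct` must lie strictly inside (0, 100).",
                   "rescuekit_domain_error")
  }
  dose / (100 / growth_pct - 1)^(1 / m)
}

#' Loewe combination index for a two-agent combination
#'
#' The combination index at a chosen effect level \eqn{f_a} is
#' \deqn{CI = d_1/D_{x,1} + d_2/D_{x,2}, \quad
#'       D_{x,i} = D_{m,i} (f_a/(1-f_a))^{1/m_i},}
#' where \eqn{D_{x,i}} is the dose of agent i alone producing that effect
#' under its median-effect fit, and \eqn{d_1, d_2} the doses actually used in
#' combination. CI near 1 indicates Loewe additivity, below 1 synergy, above
#' 1 antagonism.
#'
#' When a fixed-level modulator (serum, a growth factor) is the second
#' "agent", fit its own titration with [fit_median_effect()] and pass that
#' fit here with the modulator level as `d2`; the effect level should be the
#' observed combined effect.
#'
#' @param fit1,fit2 `medfit` objects for the two agents.
#' @param d1,d2 Doses of each agent used in the combination.
#' @param effect_level Percent inhibition at which CI is evaluated (0-100,
#'   exclusive).
#' @param bands Numeric breaks classifying CI: below `bands[1]` synergy,
#'   between `bands[1]` and `bands[2]` additive, between `bands[2]` and
#'   `bands[3]` moderate antagonism, above strong antagonism.
#' @return An object of class `ci_result`: a one-row tibble with columns
#'   `ci`, `effect_level`, `d1`, `d2`, `dx1`, `dx2`, `classification`.
#' @examples
#' f <- fit_median_effect(
#'   sim_dose_response(m = 1, Dm = 100, doses = c(25, 50, 100, 200, 400),
#'                     noise_sd = 0))
#' combination_index(f, f, d1 = 50, d2 = 50, effect_level = 50) # CI = 1
#' @export
combination_index <- function(fit1, fit2, d1, d2, effect_level,
                              bands = c(0.9, 1.1, 3.3)) {
  stopifnot(inherits(fit1, "medfit"), inherits(fit2, "medfit"))
  assert_scalar_number(effect_level, "effect_level", lower = 0, upper = 100,
                       strict_lower = TRUE)
  if (effect_level >= 100) {
    stop_rescuekit("`effect_level` must be below 100.",
                   "rescuekit_parameter_error")
  }
  fa <- effect_level / 100
  dx <- function(fit) fit$dm * (fa / (1 - fa))^(1 / fit$m)
  dx1 <- dx(fit1)
  dx2 <- dx(fit2)
  for (fit in list(fit1, fit2)) {
    rng <- range(fit$points$growth_pct)
    inhib <- 100 - rng  # inhibition range covered by the fitted points
    if (effect_level < min(inhib) || effect_level > max(inhib)) {
      warn(sprintf(
        "effect level %.1f%% lies outside the fitted inhibition range [%.1f, %.1f]%%; CI is an extrapolation.",
        effect_level, min(inhib), max(inhib)))
    }
  }
  ci <- d1 / dx1 + d2 / dx2
  cls <- classify_ci(ci, bands)
  out <- tibble(ci = ci, effect_level = effect_level, d1 = d1, d2 = d2,
                dx1 = dx1, dx2 = dx2, classification = cls)
  class(out) <- c("ci_result", class(out))
  out
}

classify_ci <- function(ci, bands = c(0.9, 1.1, 3.3)) {
  stopifnot(length(bands) == 3L, !is.unsorted(bands))
  cut(ci, breaks = c(0, bands, Inf),
      labels = c("synergy", "additive", "moderate antagonism",
                 "strong antagonism"),
      right = FALSE) |> as.character()
}

#' @rdname fit_median_effect
#' @export
autoplot.medfit <- function(object, ...) {
  doses <- exp(seq(log(min(object$points$dose) / 2),
                   log(max(object$points$dose) * 2), length.out = 200))
  curve <- tibble(dose = doses, growth_pct = predict(object, doses))
  ggplot2::ggplot(object$points, ggplot2::aes(.data$dose, .data$growth_pct)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose", y = "Growth (% of control)",
                  title = sprintf("Median-effect fit: m = %.2f, IC50 = %.3g",
                                  object$m, object$dm)) +
    ggplot2::theme_minimal()
}
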