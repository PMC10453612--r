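test_that("growth normalization matches the background-subtracted ratio", {
  expect_equal(normalize_growth(16500, 27500, 5500), 50)
  expect_equal(normalize_growth(27500, 27500, 5500), 100)
  expect_equal(normalize_growth(5500, 27500, 5500), 0)
  # net cell loss gives negative growth; outgrowing control exceeds 100
  expect_lt(normalize_growth(4000, 27500, 5500), 0)
  expect_gt(normalize_growth(30000, 27500, 5500), 100)
  expect_error(normalize_growth(100, 500, 500),
               class = "rescuekit_degenerate_control_error")
})

test_that("noise-free median-effect data are recovered to numerical precision", {
  for (params in list(c(1, 100), c(2, 300), c(0.7, 42))) {
    tab <- exact_dose_table(params[1], params[2],
                            doses = params[2] * c(0.25, 0.5, 1, 2, 4))
    fit <- fit_median_effect(tab)
    expect_equal(fit$m, params[1], tolerance = 1e-9)
    expect_equal(fit$dm, params[2], tolerance = 1e-9)
    expect_equal(fit$r, 1, tolerance = 1e-12)
  }
})

test_that("median-effect fit recovers generator parameters under noise", {
  tab <- sim_dose_response(m = 2, Dm = 300, doses = 50 * 2^(0:7),
                           noise_sd = 0.02, seed = 1)
  fit <- fit_median_effect(tab)
  expect_lt(abs(fit$m - 2), 0.2)
  expect_lt(abs(fit$dm - 300) / 300, 0.10)
})

test_that("degenerate dose tables are rejected with informative classes", {
  flat <- tibble::tibble(dose = c(10, 20, 40, 80), growth_pct = rep(50, 4))
  expect_error(fit_median_effect(flat), class = "rescuekit_unfittable_error")
  few <- tibble::tibble(dose = c(10, 20), growth_pct = c(60, 40))
  expect_error(fit_median_effect(few),
               class = "rescuekit_insufficient_data_error")
  # saturated points (0% / 100%) are dropped before the count check
  saturated <- tibble::tibble(dose = c(1, 10, 20, 40),
                              growth_pct = c(100, 60, 50, 0))
  expect_message(expect_error(fit_median_effect(saturated),
                              class = "rescuekit_insufficient_data_error"),
                 "dropped 2")
})

test_that("replicate doses are averaged before fitting", {
  tab <- exact_dose_table(1, 100, c(50, 100, 200))
  dup <- dplyr::bind_rows(
    tab,
    tibble::tibble(dose = 100, growth_pct = tab$growth_pct[2]))
  fit <- fit_median_effect(dup)
  expect_equal(fit$n_points, 3)
  expect_equal(fit$dm, 100, tolerance = 1e-9)
})

test_that("ic50 identities hold", {
  expect_equal(ic50(400, 50, 2), 400)
  expect_equal(ic50(100, 20, 1), 25)
  expect_equal(ic50(100, 80, 2), 200)
  # y = 50 is a fixed point for every shape
  for (m in c(0.3, 1, 2.5, 7)) expect_equal(ic50(123, 50, m), 123)
  # strictly increasing in growth for fixed dose and shape
  ys <- seq(5, 95, by = 5)
  vals <- vapply(ys, function(y) ic50(100, y, 1.7), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(ic50(100, 100, 1), class = "rescuekit_domain_error")
  expect_error(ic50(100, 0, 1), class = "rescuekit_domain_error")
})

test_that("an agent combined with itself is Loewe-additive at every effect level", {
  fit <- fit_median_effect(exact_dose_table(1.6, 150,
                                            150 * c(0.1, 0.5, 1, 2, 10)))
  for (eff in seq(10, 90, by = 10)) {
    dx <- fit$dm * (eff / (100 - eff))^(1 / fit$m)
    res <- combination_index(fit, fit, d1 = dx / 2, d2 = dx / 2,
                             effect_level = eff)
    expect_equal(res$ci, 1, tolerance = 1e-6)
  }
})

test_that("full single-agent doses sum to CI = 2 and bands classify", {
  fit <- fit_median_effect(exact_dose_table(2, 100, c(25, 50, 100, 200, 400)))
  dx <- fit$dm
  res <- combination_index(fit, fit, d1 = dx, d2 = dx, effect_level = 50)
  expect_equal(res$ci, 2, tolerance = 1e-9)
  expect_equal(res$classification, "moderate antagonism")
  syn <- combination_index(fit, fit, d1 = dx / 4, d2 = dx / 4,
                           effect_level = 50)
  expect_equal(syn$classification, "synergy")
})

test_that("a rescuing modulator produces an antagonistic combination index", {
  drug_fit <- fit_median_effect(
    sim_dose_response(m = 2, Dm = 300, doses = 50 * 2^(0:7), noise_sd = 0,
                      seed = 1))
  mod_fit <- fit_median_effect(
    sim_dose_response(m = 1.5, Dm = 2, doses = c(0.25, 0.5, 1, 2, 4, 8),
                      noise_sd = 0, seed = 2))
  combo <- sim_dose_response(m = 2, Dm = 300, doses = 600,
                             modulator_levels = 1, rescue_strength = 0.5,
                             noise_sd = 0)
  effect <- 100 - combo$growth_pct[1]
  res <- combination_index(drug_fit, mod_fit, d1 = 600, d2 = 1,
                           effect_level = effect)
  expect_gt(res$ci, 1)
  # hand computation from the two fits
  fa <- effect / 100
  dx1 <- drug_fit$dm * (fa / (1 - fa))^(1 / drug_fit$m)
  dx2 <- mod_fit$dm * (fa / (1 - fa))^(1 / mod_fit$m)
  expect_equal(res$ci, 600 / dx1 + 1 / dx2, tolerance = 1e-12)
})

test_that("extrapolated effect levels warn rather than error", {
  fit <- fit_median_effect(exact_dose_table(2, 100, c(80, 100, 125)))
  w <- testthat::capture_warnings(
    combination_index(fit, fit, 10, 10, effect_level = 99))
  expect_length(w, 2)  # one per single-agent fit
  expect_match(w, "extrapolation", all = TRUE)
})

test_that("medfit supports tidy, glance, predict and autoplot", {
  fit <- fit_median_effect(exact_dose_table(2, 100, c(25, 50, 100, 200)))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "dm"], 100, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 4)
  expect_equal(predict(fit, 100), 50, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
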