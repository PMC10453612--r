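#' Simulate a dose-response table from the median-effect model
#'
#' Draws growth percentages from the median-effect law
#' \eqn{f_a = 1/(1 + (D_m/D)^m)} with optional multiplicative Gaussian noise
#' and an optional rescuing modulator. Rescue is modelled as effective-dose
#' attenuation: at modulator level \eqn{L}, the drug acts at
#' \eqn{D_{eff} = D (1 - \rho L)} with rescue strength \eqn{\rho \in [0,1]}.
#' This is a deliberately simple monotone model, sufficient to generate the
#' antagonistic combinations (CI > 1) that the analysis side must detect.
#'
#' @param m Shape coefficient of the dose-effect relationship.
#' @param Dm Median-effect dose (> 0), in drug units.
#' @param doses Vector of doses (>= 0).
#' @param modulator_levels Levels of the rescuing modulator at which each dose
#'   series is generated (0 = drug alone). Levels are on a 0-1 scale
#'   (e.g. fraction of full serum supplement).
#' @param noise_sd Fractional (multiplicative) Gaussian noise on growth
#'   percent; 0 gives noise-free model values.
#' @param rescue_strength Attenuation factor in `[0, 1]` applied per unit of
#'   modulator level.
#' @param n_reps Replicate series per (dose, level) pair.
#' @param seed Integer seed; fixing it reproduces the table bit-identically.
#' @return A tibble with columns `dose`, `modulator_level`, `replicate`,
#'   `growth_pct`, carrying the ground truth (`m`, `Dm`, `rescue_strength`)
#'   in attribute `"truth"`.
#' @examples
#' sim_dose_response(m = 2, Dm = 300, doses = c(0, 100, 300, 900),
#'                   noise_sd = 0)
#' @export
sim_dose_response <- function(m, Dm, doses, modulator_levels = 0,
                              noise_sd = 0.02, rescue_strength = 0,
                              n_reps = 1, seed = NULL) {
  assert_scalar_number(Dm, "Dm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(m, "m", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rescue_strength, "rescue_strength", lower = 0, upper = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (any(doses < 0)) {
    stop_rescuekit("All doses must be >= 0.", "rescuekit_parameter_error")
  }
  grid <- tidyr::expand_grid(modulator_level = modulator_levels,
                             dose = as.numeric(doses),
                             replicate = seq_len(n_reps))
  with_seed(seed, {
    d_eff <- grid$dose * (1 - rescue_strength * grid$modulator_level)
    fa <- ifelse(d_eff > 0, 1 / (1 + (Dm / d_eff)^m), 0)
    growth <- 100 * (1 - fa)
    if (noise_sd > 0) {
      growth <- growth * (1 + rnorm(nrow(grid), sd = noise_sd))
    }
    out <- tibble(dose = grid$dose,
                  modulator_level = grid$modulator_level,
                  replicate = grid$replicate,
                  growth_pct = growth)
    attr(out, "truth") <- list(m = m, Dm = Dm,
                               rescue_strength = rescue_strength,
                               noise_sd = noise_sd)
    out
  })
}

#' Simulate a DNA-content event list with known phase fractions
#'
#' Events are drawn from a G1 Gaussian (mean `g1_mean`, sd `cv * g1_mean`), a
#' G2/M Gaussian at exactly twice the G1 mean (sd `cv * 2 g1_mean`), and an
#' S-phase component modelled as a uniform spread between the two peak means
#' convolved with the G1-width Gaussian (a Dean-Jett-Fox-style broadened
#' plateau). Optional sub-G1 debris is added uniformly below half the G1
#' mean, on top of the `n_events` cycle events.
#'
#' @param n_events Number of in-cycle events to draw.
#' @param f_g1,f_s,f_g2m Phase fractions; must sum to 1.
#' @param g1_mean Mean DNA-content channel value of the G1 peak.
#' @param cv Coefficient of variation of the G1 peak.
#' @param debris_frac Debris events as a fraction of `n_events`.
#' @param seed Integer seed.
#' @return A numeric vector of event intensities with attribute `"truth"`
#'   (the planted fractions and peak parameters).
#' @examples
#' x <- sim_dna_histogram(1000, f_g1 = 0.6, f_s = 0.25, f_g2m = 0.15, seed = 1)
#' attr(x, "truth")$f_g1
#' @export
sim_dna_histogram <- function(n_events, f_g1, f_s, f_g2m, g1_mean = 200,
                              cv = 0.05, debris_frac = 0, seed = NULL) {
  if (abs(f_g1 + f_s + f_g2m - 1) > 1e-9 ||
      any(c(f_g1, f_s, f_g2m) < 0)) {
    stop_rescuekit("Phase fractions must be non-negative and sum to 1.",
                   "rescuekit_parameter_error")
  }
  assert_scalar_number(g1_mean, "g1_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(debris_frac, "debris_frac", lower = 0, upper = 1)
  truth <- list(f_g1 = f_g1, f_s = f_s, f_g2m = f_g2m, g1_mean = g1_mean,
                g2m_mean = 2 * g1_mean, cv = cv, debris_frac = debris_frac)
  if (n_events == 0 && debris_frac == 0) {
    return(structure(numeric(0), truth = truth))
  }
  with_seed(seed, {
    phase <- sample(c("g1", "s", "g2m"), n_events, replace = TRUE,
                    prob = c(f_g1, f_s, f_g2m))
    sdev <- cv * g1_mean
    x <- numeric(n_events)
    x[phase == "g1"] <- rnorm(sum(phase == "g1"), g1_mean, sdev)
    x[phase == "g2m"] <- rnorm(sum(phase == "g2m"), 2 * g1_mean, 2 * sdev)
    ns <- sum(phase == "s")
    x[phase == "s"] <- runif(ns, g1_mean, 2 * g1_mean) + rnorm(ns, 0, sdev)
    n_debris <- round(debris_frac * n_events)
    debris <- runif(n_debris, 0.05 * g1_mean, 0.45 * g1_mean)
    out <- pmax(c(x, debris), 0)
    structure(out, truth = truth)
  })
}
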