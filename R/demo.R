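#' Run the end-to-end synthetic rescue-experiment demonstration
#'
#' Generates a complete synthetic experiment — dose-response tables, KTR
#' reporter fields, DNA-content histograms, an RNA-seq count matrix with
#' planted drug-responsive and rescued genes, and pathway definitions built
#' from the planted classes — then runs all five analysis stages and
#' returns a report comparing every recovered quantity to its planted
#' truth. All randomness flows from the single `seed` (stage seeds are
#' derived by fixed offsets), so a rerun with the same seed reproduces the
#' report bit-identically.
#'
#' Stage scales are chosen to finish in well under a minute while leaving
#' each estimator enough data to demonstrate recovery; they are not meant
#' as power analyses (the test suite covers those at larger sizes).
#'
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, the report is written to
#'   `report.json` (and key tables as TSV) inside it.
#' @param skip Stages to omit: any of `"dose"`, `"imaging"`, `"cycle"`,
#'   `"degs"`, `"pal"`.
#' @param thresholds Named list overriding analysis thresholds (`alpha`,
#'   `lfc_threshold`, `n_iter`, `ring_width`, `min_pathway_genes`).
#' @return A list of class `rescue_demo` with one element per executed
#'   stage, each containing recovered values, planted truth and stage
#'   counters; plus `seed` and `thresholds`.
#' @examples
#' \donttest{
#' demo <- run_demo(seed = 1, skip = c("imaging"))
#' demo$degs$restored_pct_serum
#' }
#' @export
run_demo <- function(seed = 1, out_dir = NULL, skip = character(),
                     thresholds = list()) {
  th <- utils::modifyList(
    list(alpha = 0.05, lfc_threshold = 1, n_iter = 1000, ring_width = 10,
         min_pathway_genes = 10),
    thresholds)
  bad <- setdiff(skip, c("dose", "imaging", "cycle", "degs", "pal"))
  if (length(bad) > 0) {
    stop_rescuekit(paste("Unknown stage(s) in `skip`:",
                         paste(bad, collapse = ", ")),
                   "rescuekit_parameter_error")
  }
  report <- list(seed = seed, thresholds = th)

  run_stage <- function(name, fun) {
    if (name %in% skip) return(NULL)
    inform(sprintf("demo: running %s stage", name))
    tryCatch(fun(), error = function(e) {
      stop_rescuekit(sprintf("Stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "rescuekit_stage_error")
    })
  }

  report$dose <- run_stage("dose", function() demo_dose(seed, th))
  report$ktr <- run_stage("imaging", function() demo_ktr(seed, th))
  report$cycle <- run_stage("cycle", function() demo_cycle(seed))
  degs_pal_sim <- if (!all(c("degs", "pal") %in% skip)) {
    sim_counts(n_genes = 1500, n_drug_down = 75, n_drug_up = 75,
               effect_log2fc = 2, rescued_fraction_serum = 0.75,
               rescued_fraction_egf = 1, seed = seed + 4)
  }
  report$degs <- run_stage("degs", function() demo_degs(degs_pal_sim, th,
                                                        seed))
  report$pal <- run_stage("pal", function() demo_pal(degs_pal_sim, th))
  report <- report[!vapply(report, is.null, logical(1))]
  class(report) <- "rescue_demo"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(demo_report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

demo_dose <- function(seed, th) {
  doses <- 50 * 2^(0:7)
  drug_tab <- sim_dose_response(m = 2, Dm = 300, doses = doses,
                                noise_sd = 0.02, seed = seed + 1)
  fit_drug <- fit_median_effect(drug_tab)
  # the modulator's own titration acts as agent 2 of the combination
  mod_tab <- sim_dose_response(m = 1.5, Dm = 2, doses = c(0.25, 0.5, 1, 2,
                                                          4, 8),
                               noise_sd = 0.02, seed = seed + 2)
  fit_mod <- fit_median_effect(mod_tab)
  combo <- sim_dose_response(m = 2, Dm = 300, doses = 600,
                             modulator_levels = 1, rescue_strength = 0.5,
                             noise_sd = 0, seed = seed + 3)
  effect <- 100 - combo$growth_pct[1]
  ci <- combination_index(fit_drug, fit_mod, d1 = 600, d2 = 1,
                          effect_level = effect)
  list(truth = list(m = 2, Dm = 300),
       fit = list(m = fit_drug$m, dm = fit_drug$dm, r = fit_drug$r),
       ic50_drug = fit_drug$dm,
       combination = list(effect_level = effect, ci = ci$ci,
                          classification = ci$classification))
}

demo_ktr <- function(seed, th) {
  conds <- list(control = 2.5, drug = 1.0)
  meas <- purrr::imap(conds, function(ratio, cond) {
    purrr::map(1:2, function(rep_i) {
      f <- sim_ktr_field(field_size = c(192, 192), n_cells = 15,
                         true_cn_ratio = ratio,
                         illumination_gradient = 0.2, noise_sd = 0.02,
                         n_artifacts = 1,
                         seed = seed + 10 * rep_i +
                           100 * match(cond, names(conds)))
      m <- ktr_pipeline(f$nuclear, f$reporter, ring_width = th$ring_width)
      m$condition <- cond
      m$replicate <- rep_i
      m
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summ <- summarize_condition(meas, reference = "control")
  list(truth = conds,
       conditions = as.list(stats::setNames(summ$conditions$mean_cn,
                                            summ$conditions$condition)),
       relative_drug_activity =
         summ$conditions$relative_activity[summ$conditions$condition ==
                                             "drug"],
       n_cells_measured = nrow(meas))
}

demo_cycle <- function(seed) {
  arms <- list(control = c(0.6, 0.25, 0.15), drug = c(0.8, 0.1, 0.1))
  fits <- purrr::imap(arms, function(f, arm) {
    purrr::map(1:3, function(rep_i) {
      x <- sim_dna_histogram(4000, f_g1 = f[1], f_s = f[2], f_g2m = f[3],
                             seed = seed + 20 * rep_i +
                               200 * match(arm, names(arms)))
      estimate_fractions(x)
    })
  })
  cmp <- compare_fractions(fits$control, fits$drug)
  list(truth = arms,
       estimated = purrr::map(fits, function(fl) {
         purrr::map_dbl(c(pct_g1 = "pct_g1", pct_s = "pct_s",
                          pct_g2m = "pct_g2m"),
                        function(col) mean(purrr::map_dbl(fl, col)))
       }),
       g1_shift = cmp$shift[cmp$phase == "g1"],
       g1_shift_p = cmp$p_value[cmp$phase == "g1"])
}

demo_degs <- function(sim, th, seed) {
  call <- function(cond) {
    suppressMessages(call_degs(sim$counts, sim$design,
                               contrast = c(cond, "control"),
                               alpha = th$alpha,
                               lfc_threshold = th$lfc_threshold))
  }
  deg_drug <- call("drug")
  deg_serum <- call("drug_serum")
  deg_egf <- call("drug_egf")
  core_serum <- core_gene_set(deg_drug, deg_serum, "drug", "serum")
  core_egf <- core_gene_set(deg_drug, deg_egf, "drug", "egf")
  planted <- intersect(sim$truth$gene[sim$truth$class != "baseline"],
                       deg_drug$gene)
  ov <- permutation_overlap_test(
    list(deg_drug$gene[deg_drug$is_deg], planted),
    deg_drug$gene, n_iter = th$n_iter, seed = seed + 5)
  list(truth = list(n_planted = sum(sim$truth$class != "baseline"),
                    rescued_fraction_serum = 0.75,
                    rescued_fraction_egf = 1),
       n_degs_drug = sum(deg_drug$is_deg),
       n_degs_drug_serum = sum(deg_serum$is_deg),
       n_degs_drug_egf = sum(deg_egf$is_deg),
       restored_pct_serum = core_serum$restored_pct,
       restored_pct_egf = core_egf$restored_pct,
       overlap_with_planted = list(observed = ov$observed,
                                   p_value = ov$p_value, note = ov$note),
       n_genes_filtered = attr(deg_drug, "n_filtered"),
       n_permutations = th$n_iter)
}

demo_pal <- function(sim, th) {
  down <- sim$truth$gene[sim$truth$class == "drug_down"]
  up <- sim$truth$gene[sim$truth$class == "drug_up"]
  baseline <- sim$truth$gene[sim$truth$class == "baseline"]
  pathways <- dplyr::bind_rows(
    tibble(pathway = "planted_drug_suppressed", gene = down, weight = 1),
    tibble(pathway = "planted_drug_induced", gene = up, weight = 1),
    tibble(pathway = "unrelated_background", gene = head(baseline, 50),
           weight = 1)
  )
  sel <- sim$design$sample[sim$design$condition %in% c("control", "drug")]
  profiles <- suppressMessages(
    geometric_mean_normalize(sim$counts[, sel, drop = FALSE]))
  scores <- suppressMessages(
    pal_score(profiles, pathways, min_genes = th$min_pathway_genes))
  groups <- stats::setNames(
    sim$design$condition[match(sel, sim$design$sample)], sel)
  cmp <- compare_pal_groups(scores, groups, alpha = th$alpha)
  list(pathways_scored = length(unique(scores$pathway)),
       top_pathway = cmp$pathway[1],
       delta_pal = stats::setNames(cmp$delta_pal, cmp$pathway) |> as.list(),
       significant = stats::setNames(cmp$significant, cmp$pathway) |>
         as.list())
}

demo_report_json <- function(report) {
  unclass(report)
}

#' @export
print.rescue_demo <- function(x, ...) {
  cat("Synthetic rescue-experiment demo (seed", x$seed, ")\n")
  if (!is.null(x$dose)) {
    cat(sprintf("  dose: m %.2f (true %.1f), IC50 %.1f (true %.0f), CI %.2f (%s)\n",
                x$dose$fit$m, x$dose$truth$m, x$dose$ic50_drug,
                x$dose$truth$Dm, x$dose$combination$ci,
                x$dose$combination$classification))
  }
  if (!is.null(x$ktr)) {
    cat(sprintf("  ktr: control C/N %.2f (true %.1f), drug relative activity %.2f\n",
                x$ktr$conditions$control, x$ktr$truth$control,
                x$ktr$relative_drug_activity))
  }
  if (!is.null(x$cycle)) {
    cat(sprintf("  cycle: G1 shift %+.1f points (p = %.3g)\n",
                x$cycle$g1_shift, x$cycle$g1_shift_p))
  }
  if (!is.null(x$degs)) {
    cat(sprintf("  degs: %d drug DEGs; restored %.1f%% (serum), %.1f%% (EGF)\n",
                x$degs$n_degs_drug, x$degs$restored_pct_serum,
                x$degs$restored_pct_egf))
  }
  if (!is.null(x$pal)) {
    cat(sprintf("  pal: top changed pathway '%s'\n", x$pal$top_pathway))
  }
  invisible(x)
}
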