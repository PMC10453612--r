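#' Simulate an RNA-seq count matrix with planted drug-responsive genes
#'
#' Emulates the transcriptomic design of a drug-rescue experiment: six
#' conditions (no-drug control, serum alone, EGF alone, drug alone, drug plus
#' serum, drug plus EGF) in `n_reps` replicates each. Counts are negative
#' binomial around gene baseline means drawn log-uniformly from `mean_range`.
#' Under the drug, `n_drug_down` planted genes shift down and `n_drug_up`
#' shift up by `effect_log2fc` on the log2 scale. Under each combined
#' condition, a designated fraction of the planted genes (chosen at random,
#' recorded in the truth table) returns exactly to the control mean — these
#' are the "rescued" genes whose recovery downstream analysis must measure.
#' Serum alone and EGF alone leave all means at baseline, so those arms act
#' as negative controls for the differential-expression caller.
#'
#' @param n_genes Total genes.
#' @param n_reps Replicates per condition (>= 2).
#' @param mean_range Bounds for log-uniform baseline means.
#' @param dispersion Global negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_drug_down,n_drug_up Planted drug-responsive gene counts.
#' @param effect_log2fc Planted absolute log2 fold change (> 1 so planted
#'   genes sit strictly above the conventional calling threshold).
#' @param rescued_fraction_serum,rescued_fraction_egf Fractions of planted
#'   genes rescued under drug+serum and drug+EGF. Defaults mirror a drug
#'   whose expression signature is 75% restored by serum and fully restored
#'   by EGF.
#' @param seed Integer seed.
#' @return A list of class `counts_sim`: `counts` (integer matrix, genes x
#'   samples), `design` (tibble: `sample`, `condition`, `replicate`) and
#'   `truth` (tibble: `gene`, `class` in `baseline`/`drug_down`/`drug_up`,
#'   `rescued_serum`, `rescued_egf`).
#' @examples
#' sim <- sim_counts(n_genes = 200, n_drug_down = 10, n_drug_up = 10, seed = 1)
#' table(sim$truth$class)
#' @export
sim_counts <- function(n_genes = 2000, n_reps = 3,
                       mean_range = c(20, 2000), dispersion = 0.05,
                       n_drug_down = 100, n_drug_up = 100,
                       effect_log2fc = 2,
                       rescued_fraction_serum = 0.75,
                       rescued_fraction_egf = 1,
                       seed = NULL) {
  if (n_reps < 2) {
    stop_rescuekit("Need at least 2 replicates per condition.",
                   "rescuekit_parameter_error")
  }
  if (n_drug_down + n_drug_up > n_genes) {
    stop_rescuekit("Planted gene classes exceed the number of genes.",
                   "rescuekit_parameter_error")
  }
  if (effect_log2fc <= 1 && (n_drug_down + n_drug_up) > 0) {
    stop_rescuekit(
      "Planted |log2FC| must exceed 1 so planted genes sit above the calling threshold.",
      "rescuekit_parameter_error"
    )
  }
  assert_scalar_number(rescued_fraction_serum, "rescued_fraction_serum",
                       lower = 0, upper = 1)
  assert_scalar_number(rescued_fraction_egf, "rescued_fraction_egf",
                       lower = 0, upper = 1)
  conditions <- c("control", "serum", "egf", "drug", "drug_serum", "drug_egf")

  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    base_mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))

    planted <- sample(n_genes, n_drug_down + n_drug_up)
    down <- planted[seq_len(n_drug_down)]
    up <- setdiff(planted, down)
    class <- rep("baseline", n_genes)
    class[down] <- "drug_down"
    class[up] <- "drug_up"

    pick_rescued <- function(frac) {
      res <- logical(n_genes)
      for (idx in list(down, up)) {
        if (length(idx) > 0) {
          res[sample(idx, round(frac * length(idx)))] <- TRUE
        }
      }
      res
    }
    rescued_serum <- pick_rescued(rescued_fraction_serum)
    rescued_egf <- pick_rescued(rescued_fraction_egf)

    drug_mu <- base_mu
    drug_mu[down] <- base_mu[down] * 2^(-effect_log2fc)
    drug_mu[up] <- base_mu[up] * 2^(effect_log2fc)
    mu_for <- function(cond) {
      switch(cond,
        control = , serum = , egf = base_mu,
        drug = drug_mu,
        drug_serum = ifelse(rescued_serum, base_mu, drug_mu),
        drug_egf = ifelse(rescued_egf, base_mu, drug_mu)
      )
    }

    design <- tidyr::expand_grid(condition = factor(conditions, conditions),
                                 replicate = seq_len(n_reps)) |>
      dplyr::mutate(sample = sprintf("%s_r%d", .data$condition,
                                     .data$replicate),
                    condition = as.character(.data$condition)) |>
      dplyr::select("sample", "condition", "replicate")

    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(genes, design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- mu_for(design$condition[j])
      counts[, j] <- as.integer(rnbinom(n_genes, mu = mu,
                                        size = 1 / dispersion))
    }

    truth <- tibble(gene = genes, class = class, base_mean = base_mu,
                    rescued_serum = rescued_serum, rescued_egf = rescued_egf)
    structure(list(counts = counts, design = design, truth = truth,
                   dispersion = dispersion, effect_log2fc = effect_log2fc),
              class = "counts_sim")
  })
}

#' @export
print.counts_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated counts: %d genes x %d samples (%d planted down, %d up)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$truth$class == "drug_down"), sum(x$truth$class == "drug_up")))
  invisible(x)
}
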