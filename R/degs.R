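#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median across genes of
#' the ratio of each sample's count to the gene's geometric mean over all
#' samples; genes with a zero anywhere are excluded from the median. This is
#' the standard library-size estimator for RNA-seq count comparisons.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of size factors (geometric mean 1-ish).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  log_geo <- rowMeans(log(counts))
  sf <- apply(counts, 2, function(cnt) {
    finite <- is.finite(log_geo) & cnt > 0
    if (!any(finite)) {
      stop_rescuekit("A sample shares no positive genes with the geometric mean.",
                     "rescuekit_degenerate_design_error")
    }
    exp(median(log(cnt[finite]) - log_geo[finite]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin, name-stable wrapper over [stats::p.adjust()] with `method = "BH"`:
#' the step-up adjustment with monotonicity enforcement, preserving input
#' order.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes with a negative-binomial Wald test
#'
#' A self-contained two-group NB test: counts are normalised with
#' median-of-ratios size factors; a per-gene dispersion is estimated by
#' method of moments from within-group variability and moderated towards the
#' experiment-wide typical dispersion (weights `residual df : prior_df`),
#' with a floor; group means are quasi-likelihood estimates
#' \eqn{\hat\mu_g = \sum_j K_{gj} / \sum_j s_j}; and the Wald statistic on
#' the log fold change uses
#' \eqn{Var(\log\hat\mu_g) = 1/(\hat\mu_g \sum s_j) +
#'      \alpha \sum s_j^2 / (\sum s_j)^2}.
#' Because the dispersion is estimated from few replicates, the statistic is
#' referred to a t distribution with residual-plus-prior degrees of freedom
#' (a moderated-t reference); with a user-supplied known dispersion the
#' normal reference is used. P-values are BH-adjusted and a gene is flagged as differential when the
#' adjusted p-value is below `alpha` and |log2FC| exceeds `lfc_threshold`
#' (the conventional adjusted p < 0.05, fold change > 2 rule by default).
#'
#' Genes with total count below `min_total` across the contrasted samples
#' are excluded before testing (their number is reported via a message).
#' This caller is deliberately pluggable: downstream core-set and overlap
#' functions accept any table with `gene`, `log2fc`, `padj`/`is_deg`
#' columns, so an externally produced DEG table can be substituted.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param design Data frame with columns `sample` and `condition` matching
#'   `colnames(counts)`.
#' @param contrast Character pair `c(condition, reference)`.
#' @param alpha Adjusted-significance threshold.
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param min_total Minimum total count across contrasted samples.
#' @param dispersion Optional known dispersion (scalar or per-gene vector);
#'   skips estimation when supplied.
#' @param prior_df Prior degrees of freedom for dispersion moderation.
#' @return A tibble (one row per tested gene): `gene`, `base_mean`,
#'   `log2fc`, `lfc_se`, `stat`, `pvalue`, `padj`, `is_deg`, `direction`
#'   (`"up"`, `"down"` or `"none"`), with attributes `contrast` and
#'   `n_filtered`.
#' @export
call_degs <- function(counts, design, contrast, alpha = 0.05,
                      lfc_threshold = 1, min_total = 10, dispersion = NULL,
                      prior_df = 10) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            all(c("sample", "condition") %in% names(design)),
            length(contrast) == 2L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_rescuekit("Counts must be non-negative integers.",
                   "rescuekit_parameter_error")
  }
  design <- as_tibble(design)
  if (!all(design$sample %in% colnames(counts))) {
    stop_rescuekit("Design samples missing from the count matrix.",
                   "rescuekit_degenerate_design_error")
  }
  sel <- design[design$condition %in% contrast, ]
  n_per <- table(factor(sel$condition, levels = contrast))
  if (any(n_per < 2)) {
    stop_rescuekit(
      "Each contrasted condition needs at least 2 replicates.",
      "rescuekit_degenerate_design_error"
    )
  }
  mat <- counts[, sel$sample, drop = FALSE]
  keep <- rowSums(mat) >= min_total
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    inform(sprintf(
      "call_degs: excluded %d gene(s) with total count < %d.", n_filtered,
      min_total))
  }
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0) {
    stop_rescuekit("No genes pass the expression filter.",
                   "rescuekit_insufficient_data_error")
  }

  sf <- size_factors(mat)
  grp_cond <- sel$sample[sel$condition == contrast[1]]
  grp_ref <- sel$sample[sel$condition == contrast[2]]

  if (is.null(dispersion)) {
    alpha_hat <- estimate_dispersion(mat, sf, list(grp_cond, grp_ref),
                                     prior_df)
    # moderated-t reference: estimated dispersions leave the Wald statistic
    # with finite effective degrees of freedom (residual df + prior df)
    test_df <- (length(grp_cond) + length(grp_ref) - 2) + prior_df
  } else {
    alpha_hat <- rep_len(dispersion, nrow(mat))
    test_df <- Inf
  }

  group_stats <- function(samples) {
    k <- mat[, samples, drop = FALSE]
    s <- sf[samples]
    tot <- rowSums(k)
    mu <- tot / sum(s)
    mu_safe <- (tot + 0.5 * (tot == 0)) / sum(s)  # guard zero groups
    var_log <- 1 / (mu_safe * sum(s)) + alpha_hat * sum(s^2) / sum(s)^2
    list(mu = mu_safe, var_log = var_log)
  }
  g1 <- group_stats(grp_cond)
  g0 <- group_stats(grp_ref)

  beta <- unname(log(g1$mu / g0$mu))
  se <- unname(sqrt(g1$var_log + g0$var_log))
  z <- beta / se
  pval <- 2 * stats::pt(-abs(z), df = test_df)
  padj <- bh_adjust(pval)
  log2fc <- beta / log(2)

  norm_all <- sweep(mat, 2, sf, `/`)
  out <- tibble(
    gene = rownames(mat),
    base_mean = unname(rowMeans(norm_all)),
    log2fc = log2fc,
    lfc_se = se / log(2),
    stat = z,
    pvalue = pval,
    padj = padj,
    is_deg = padj < alpha & abs(log2fc) > lfc_threshold,
    direction = dplyr::case_when(
      padj < alpha & log2fc > lfc_threshold ~ "up",
      padj < alpha & log2fc < -lfc_threshold ~ "down",
      .default = "none"
    )
  )
  attr(out, "contrast") <- contrast
  attr(out, "n_filtered") <- n_filtered
  out
}

# Method-of-moments NB dispersion from within-group variability of
# normalised counts, moderated towards the experiment-typical value.
estimate_dispersion <- function(mat, sf, groups, prior_df,
                                floor = 1e-4, ceiling = 10) {
  z <- sweep(mat, 2, sf, `/`)
  n <- ncol(mat)
  ss <- 0
  for (g in groups) {
    zg <- z[, g, drop = FALSE]
    ss <- ss + rowSums((zg - rowMeans(zg))^2)
  }
  s2 <- ss / (n - length(groups))
  m <- rowMeans(z)
  c1 <- mean(1 / sf)
  raw <- pmax((s2 - m * c1) / m^2, 0)
  prior <- median(raw[m > 5])
  if (!is.finite(prior)) prior <- 0.01
  d <- n - length(groups)
  mod <- (d * raw + prior_df * prior) / (d + prior_df)
  pmin(pmax(mod, floor), ceiling)
}

#' Build a drug core gene group from two DEG tables
#'
#' The core gene group of a drug, relative to a rescuing modulator, is the
#' set of genes differential under the drug alone whose expression returns
#' to non-differential status when the modulator is co-applied: members are
#' the drug DEGs not flagged in the drug-plus-modulator contrast. The
#' restored fraction — the share of drug DEGs so rescued — is the headline
#' statistic of a rescue experiment.
#'
#' @param deg_drug DEG table for drug vs control (from [call_degs()] or any
#'   table with `gene`, `is_deg`, `direction`).
#' @param deg_combo DEG table for drug + modulator vs control, over the same
#'   gene universe.
#' @param drug,modulator Labels stored in the result.
#' @return An object of class `core_gene_set`: tibble `members` (gene,
#'   direction), counts `n_up`/`n_down`, `n_drug_degs`, and `restored_pct`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' # a drug table with 4 DEGs of which only g2 stays differential:
#' drug <- tibble::tibble(gene = paste0("g", 1:6),
#'                        is_deg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'                        direction = c("up", "up", "down", "down",
#'                                      "none", "none"))
#' combo <- dplyr::mutate(drug, is_deg = gene == "g2",
#'                        direction = ifelse(gene == "g2", "up", "none"))
#' core_gene_set(drug, combo)$restored_pct # 75
#' @export
core_gene_set <- function(deg_drug, deg_combo, drug = "drug",
                          modulator = "modulator") {
  if (!setequal(deg_drug$gene, deg_combo$gene) ||
      nrow(deg_drug) != nrow(deg_combo)) {
    stop_rescuekit(
      "DEG tables cover different gene universes; core set is undefined.",
      "rescuekit_universe_mismatch_error"
    )
  }
  combo_deg <- deg_combo$gene[deg_combo$is_deg]
  drug_degs <- deg_drug[deg_drug$is_deg, c("gene", "direction")]
  members <- drug_degs[!drug_degs$gene %in% combo_deg, ]
  structure(
    list(drug = drug, modulator = modulator,
         members = as_tibble(members),
         n_up = sum(members$direction == "up"),
         n_down = sum(members$direction == "down"),
         n_drug_degs = nrow(drug_degs),
         restored_pct = if (nrow(drug_degs) == 0) NA_real_
                        else 100 * nrow(members) / nrow(drug_degs)),
    class = "core_gene_set"
  )
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat(sprintf(
    "%s core gene group (vs %s): %d genes (%d up, %d down) of %d drug DEGs; restored %.1f%%\n",
    x$drug, x$modulator, nrow(x$members), x$n_up, x$n_down, x$n_drug_degs,
    x$restored_pct))
  invisible(x)
}

#' @rdname core_gene_set
#' @param x,object A `core_gene_set`.
#' @param ... Unused.
#' @export
tidy.core_gene_set <- function(x, ...) x$members

#' @rdname core_gene_set
#' @export
glance.core_gene_set <- function(x, ...) {
  tibble(drug = x$drug, modulator = x$modulator, n_members = nrow(x$members),
         n_up = x$n_up, n_down = x$n_down, n_drug_degs = x$n_drug_degs,
         restored_pct = x$restored_pct)
}

#' Permutation test for the overlap of two or three gene sets
#'
#' Tests whether the observed intersection of gene sets is larger than
#' expected by chance: in each of `n_iter` iterations a random set of the
#' same size is drawn uniformly without replacement from each set's
#' universe, and the size of the random intersection recorded. The p-value
#' is the fraction of iterations whose random overlap is at least the
#' observed one (no +1 correction; an exact zero is annotated as below the
#' Monte-Carlo resolution `1/n_iter`).
#'
#' @param sets List of 2 or 3 character vectors (the observed gene sets).
#' @param universes A single character vector (shared universe) or a list of
#'   universes matching `sets`; each set must be contained in its universe.
#' @param n_iter Number of random intersections.
#' @param seed Integer seed for the draws.
#' @return An object of class `overlap_test`: `observed`, `p_value`, `note`,
#'   `null` (the n_iter random overlap sizes), `n_iter`, `seed`.
#' @examples
#' u <- paste0("g", 1:20)
#' permutation_overlap_test(list(u[1:5], u[1:5]), u, n_iter = 200, seed = 1)
#' @export
permutation_overlap_test <- function(sets, universes, n_iter = 1000,
                                     seed = NULL) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  if (!is.list(universes)) universes <- rep(list(universes), length(sets))
  stopifnot(length(universes) == length(sets))
  purrr::walk2(sets, universes, function(s, u) {
    if (!all(s %in% u)) {
      stop_rescuekit("Every set must be contained in its universe.",
                     "rescuekit_universe_mismatch_error")
    }
  })
  sizes <- lengths(sets)
  observed <- length(Reduce(intersect, sets))
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      draws <- purrr::map2(universes, sizes, ~ sample(.x, .y))
      length(Reduce(intersect, draws))
    }, integer(1))
  })
  p <- mean(null >= observed)
  structure(
    list(observed = observed, p_value = p,
         note = if (p == 0) sprintf("< %g", 1 / n_iter) else NA_character_,
         null = null, n_iter = n_iter, seed = seed),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Permutation overlap test: observed %d, null mean %.2f, p = %s (%d iterations)\n",
    x$observed, mean(x$null),
    if (!is.na(x$note)) x$note else format(x$p_value), x$n_iter))
  invisible(x)
}

#' Directional overlap between two DEG tables
#'
#' For each direction (up, down), reports the share of table A's DEGs also
#' called in the same direction in table B, with a permutation p-value for
#' the overlap (universes are each table's tested genes).
#'
#' @param deg_a,deg_b DEG tables with `gene`, `is_deg`, `direction`.
#' @param n_iter,seed Passed to [permutation_overlap_test()].
#' @return Tibble: `direction`, `n_a`, `n_b`, `n_overlap`, `overlap_pct`
#'   (of A), `p_value`.
#' @export
deg_overlap_summary <- function(deg_a, deg_b, n_iter = 1000, seed = NULL) {
  purrr::map_dfr(c("up", "down"), function(dir) {
    a <- deg_a$gene[deg_a$direction == dir]
    b <- deg_b$gene[deg_b$direction == dir]
    n_ov <- length(intersect(a, b))
    p <- if (length(a) > 0 && length(b) > 0) {
      permutation_overlap_test(list(a, b),
                               list(deg_a$gene, deg_b$gene),
                               n_iter = n_iter, seed = seed)$p_value
    } else {
      NA_real_
    }
    tibble(direction = dir, n_a = length(a), n_b = length(b),
           n_overlap = n_ov,
           overlap_pct = if (length(a) > 0) 100 * n_ov / length(a)
                         else NA_real_,
           p_value = p)
  })
}

#' Volcano-style plot of a DEG table
#'
#' @param deg_table Output of [call_degs()].
#' @return A ggplot object: log2FC vs -log10 adjusted p, DEGs highlighted.
#' @export
plot_volcano <- function(deg_table) {
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(.data$log2fc, -log10(.data$padj),
                               colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
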