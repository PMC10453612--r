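#' Case-to-normal ratios by geometric-mean normalisation
#'
#' Normalises each gene's expression in each sample against that gene's
#' geometric mean across all samples in the dataset, yielding the
#' case-to-normal ratio (CNR) used for pathway activation scoring. Genes
#' that are zero in every sample are excluded; genes with some zeros get a
#' pseudocount added (to every sample of that gene, keeping per-gene scale
#' invariance), and the number of affected genes is reported via a message.
#'
#' @param mat Non-negative expression matrix, genes x samples, with
#'   dimnames.
#' @param pseudocount Value added to all entries of genes containing zeros.
#' @return A tibble in long form: `gene`, `sample`, `cnr` (> 0).
#' @examples
#' m <- matrix(c(1, 10, 100), 1, 3,
#'             dimnames = list("g1", c("a", "b", "c")))
#' geometric_mean_normalize(m) # CNR 0.1, 1, 10
#' @export
geometric_mean_normalize <- function(mat, pseudocount = 0.5) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            all(mat >= 0))
  all_zero <- rowSums(mat) == 0
  if (any(all_zero)) {
    inform(sprintf(
      "geometric_mean_normalize: excluded %d gene(s) that are zero in all samples.",
      sum(all_zero)))
    mat <- mat[!all_zero, , drop = FALSE]
  }
  has_zero <- apply(mat == 0, 1, any)
  if (any(has_zero)) {
    inform(sprintf(
      "geometric_mean_normalize: added pseudocount %g to %d gene(s) containing zeros.",
      pseudocount, sum(has_zero)))
    mat[has_zero, ] <- mat[has_zero, , drop = FALSE] + pseudocount
  }
  geo <- exp(rowMeans(log(mat)))
  cnr <- mat / geo
  as_tibble(cnr, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "cnr")
}

#' Pathway activation level of one pathway in one sample
#'
#' The pathway activation level (PAL) aggregates member genes' log
#' expression ratios, weighted by each gene's activator/repressor role
#' (ARR weight: positive for activators, negative for repressors, zero for
#' neutral members):
#' \deqn{PAL = K \frac{\sum_g ARR_g \log_{10} CNR_g}{\sum_g |ARR_g|}}
#' with K = 100 by convention. Positive PAL means net pathway activation in
#' this sample relative to the dataset average, negative means inhibition.
#' Pathways with fewer than `min_genes` members present in the profile are
#' ineligible and refuse to score.
#'
#' @param pathway A list or one-pathway tibble with `gene` and `weight`
#'   (named numeric vectors also accepted: names are genes, values ARR
#'   weights in `[-1, 1]`).
#' @param profile Named numeric vector of CNR values (> 0), or a two-column
#'   data frame `gene`, `cnr`.
#' @param k Scaling constant (100 by convention).
#' @param log_base Base of the logarithm (10 by convention).
#' @param min_genes Eligibility threshold on members present.
#' @return A list of class `pal_result`: `pal`, `n_members`, and
#'   `contributions` (tibble: gene, weight, cnr, contribution).
#' @examples
#' pw <- c(g1 = 1, g2 = 1)
#' pal(pw, c(g1 = 10, g2 = 10), min_genes = 2) # PAL = 100
#' @export
pal <- function(pathway, profile, k = 100, log_base = 10, min_genes = 10) {
  pw <- as_pathway_weights(pathway)
  pr <- as_cnr_vector(profile)
  present <- intersect(names(pw), names(pr))
  if (length(present) < min_genes) {
    stop_rescuekit(sprintf(
      "Pathway has %d member(s) present; %d required for scoring.",
      length(present), min_genes), "rescuekit_ineligible_pathway_error")
  }
  w <- pw[present]
  cnr <- pr[present]
  if (any(cnr <= 0)) {
    stop_rescuekit("CNR values must be strictly positive.",
                   "rescuekit_parameter_error")
  }
  if (sum(abs(w)) == 0) {
    stop_rescuekit("Pathway has no members with nonzero role weight.",
                   "rescuekit_parameter_error")
  }
  contrib <- w * log(cnr, base = log_base)
  value <- k * sum(contrib) / sum(abs(w))
  structure(
    list(pal = value, n_members = length(present),
         contributions = tibble(gene = present, weight = unname(w),
                                cnr = unname(cnr),
                                contribution = unname(contrib))),
    class = "pal_result"
  )
}

#' @export
print.pal_result <- function(x, ...) {
  cat(sprintf("PAL = %.2f over %d member genes\n", x$pal, x$n_members))
  invisible(x)
}

as_pathway_weights <- function(pathway) {
  if (is.numeric(pathway) && !is.null(names(pathway))) return(pathway)
  if (is.data.frame(pathway)) {
    stopifnot(all(c("gene", "weight") %in% names(pathway)))
    return(stats::setNames(pathway$weight, pathway$gene))
  }
  if (is.list(pathway) && !is.null(pathway$gene)) {
    return(stats::setNames(pathway$weight, pathway$gene))
  }
  stop_rescuekit("Cannot interpret `pathway` as gene/weight pairs.",
                 "rescuekit_parameter_error")
}

as_cnr_vector <- function(profile) {
  if (is.numeric(profile) && !is.null(names(profile))) return(profile)
  if (is.data.frame(profile)) {
    stopifnot(all(c("gene", "cnr") %in% names(profile)))
    return(stats::setNames(profile$cnr, profile$gene))
  }
  stop_rescuekit("Cannot interpret `profile` as named CNR values.",
                 "rescuekit_parameter_error")
}

#' Score every pathway in every sample
#'
#' Vectorised PAL scoring: takes the long CNR tibble from
#' [geometric_mean_normalize()] and a pathway table, returns one PAL per
#' eligible pathway per sample. Ineligible pathways (fewer than `min_genes`
#' members present) are skipped with a message.
#'
#' @param profiles Long tibble `gene`, `sample`, `cnr`.
#' @param pathways Tibble `pathway`, `gene`, `weight` (e.g. from
#'   [read_gmt()]).
#' @inheritParams pal
#' @return Tibble: `pathway`, `sample`, `pal`, `n_members`.
#' @export
pal_score <- function(profiles, pathways, k = 100, log_base = 10,
                      min_genes = 10) {
  stopifnot(all(c("gene", "sample", "cnr") %in% names(profiles)),
            all(c("pathway", "gene", "weight") %in% names(pathways)))
  samples <- unique(profiles$sample)
  by_pathway <- split(pathways, pathways$pathway)
  skipped <- character(0)
  out <- purrr::map(names(by_pathway), function(pname) {
    pw <- stats::setNames(by_pathway[[pname]]$weight,
                          by_pathway[[pname]]$gene)
    rows <- purrr::map(samples, function(s) {
      pr <- profiles[profiles$sample == s, ]
      res <- tryCatch(
        pal(pw, stats::setNames(pr$cnr, pr$gene), k = k,
            log_base = log_base, min_genes = min_genes),
        rescuekit_ineligible_pathway_error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble(pathway = pname, sample = s, pal = res$pal,
             n_members = res$n_members)
    })
    bound <- dplyr::bind_rows(rows)
    if (nrow(bound) == 0) skipped <<- c(skipped, pname)
    bound
  }) |> dplyr::bind_rows()
  if (length(skipped) > 0) {
    inform(sprintf(
      "pal_score: skipped %d ineligible pathway(s) with < %d members present.",
      length(skipped), min_genes))
  }
  if (nrow(out) == 0) {
    out <- tibble(pathway = character(0), sample = character(0),
                  pal = numeric(0), n_members = integer(0))
  }
  out
}

#' Compare pathway activation between two sample groups
#'
#' Per pathway: the difference in mean PAL between groups, a two-sample
#' t-test across per-sample PAL values, and BH adjustment across pathways;
#' results are ranked by absolute difference. Pathways without variation in
#' either group get no p-value.
#'
#' @param pal_table Tibble from [pal_score()].
#' @param groups Named character/factor vector mapping sample -> group (two
#'   groups), or a data frame with `sample` and `group`.
#' @param alpha Significance level applied to adjusted p-values.
#' @param top_n Optional: keep only the `top_n` most changed pathways.
#' @return Tibble: `pathway`, `mean_a`, `mean_b`, `delta_pal`, `p_value`,
#'   `padj`, `significant`, ordered by decreasing |delta_pal|.
#' @export
compare_pal_groups <- function(pal_table, groups, alpha = 0.05,
                               top_n = NULL) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  lev <- unique(groups)
  if (length(lev) != 2) {
    stop_rescuekit("Exactly two groups are required.",
                   "rescuekit_parameter_error")
  }
  tab <- pal_table |>
    dplyr::mutate(group = unname(groups[.data$sample])) |>
    dplyr::filter(!is.na(.data$group))
  out <- tab |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      mean_a = mean(.data$pal[.data$group == lev[1]]),
      mean_b = mean(.data$pal[.data$group == lev[2]]),
      p_value = {
        xa <- .data$pal[.data$group == lev[1]]
        xb <- .data$pal[.data$group == lev[2]]
        if (length(xa) >= 2 && length(xb) >= 2 &&
            (sd(xa) > 0 || sd(xb) > 0)) {
          t.test(xb, xa)$p.value
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_pal = .data$mean_b - .data$mean_a,
                  padj = bh_adjust(.data$p_value),
                  significant = !is.na(.data$padj) & .data$padj < alpha) |>
    dplyr::select("pathway", "mean_a", "mean_b", "delta_pal", "p_value",
                  "padj", "significant") |>
    dplyr::arrange(dplyr::desc(abs(.data$delta_pal)))
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Plot top activated and inhibited pathways
#'
#' @param comparison Tibble from [compare_pal_groups()].
#' @param top_n Pathways shown from each end.
#' @return A ggplot horizontal bar chart of delta PAL.
#' @export
plot_pal_top <- function(comparison, top_n = 10) {
  picked <- dplyr::bind_rows(
    dplyr::slice_max(comparison, .data$delta_pal, n = top_n),
    dplyr::slice_min(comparison, .data$delta_pal, n = top_n)
  ) |> dplyr::distinct(.data$pathway, .keep_all = TRUE)
  ggplot2::ggplot(picked,
                  ggplot2::aes(.data$delta_pal,
                               stats::reorder(.data$pathway,
                                              .data$delta_pal),
                               fill = .data$delta_pal > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "Pathway activation change (PAL units)", y = NULL) +
    ggplot2::theme_minimal()
}
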