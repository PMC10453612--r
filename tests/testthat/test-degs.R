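test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.5, 0.02, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("size factors recover planted library-size multipliers", {
  set.seed(1)
  base <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500, 4)
  scaled <- sweep(base, 2, c(1, 2, 0.5, 1), `*`)
  dimnames(scaled) <- list(paste0("g", 1:500), paste0("s", 1:4))
  sf <- size_factors(round(scaled))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.1)
  expect_equal(unname(sf[3] / sf[1]), 0.5, tolerance = 0.1)
})

test_that("identical replicate groups yield zero fold change and no DEGs", {
  set.seed(2)
  half <- matrix(rnbinom(300 * 3, mu = 200, size = 20), 300, 3)
  counts <- cbind(half, half)
  dimnames(counts) <- list(paste0("g", 1:300),
                           c(paste0("a_", 1:3), paste0("b_", 1:3)))
  design <- tibble::tibble(sample = colnames(counts),
                           condition = rep(c("a", "b"), each = 3))
  res <- suppressMessages(call_degs(counts, design, c("b", "a")))
  expect_equal(res$log2fc, rep(0, nrow(res)))
  expect_equal(sum(res$is_deg), 0)
  expect_true(all(res$pvalue == 1))
})

test_that("planted high-count effects are detected with correct direction", {
  n <- 500
  mu1 <- rep(500, n)
  mu2 <- mu1
  mu2[1:50] <- mu1[1:50] * 4      # up in condition b
  mu2[51:100] <- mu1[51:100] / 4  # down in condition b
  d <- two_group_counts(n, mu1, mu2, seed = 3)
  res <- suppressMessages(call_degs(d$counts, d$design, c("b", "a")))
  planted_up <- res$gene %in% sprintf("g%04d", 1:50)
  planted_down <- res$gene %in% sprintf("g%04d", 51:100)
  expect_gt(mean(res$is_deg[planted_up]), 0.9)
  expect_gt(mean(res$is_deg[planted_down]), 0.9)
  expect_true(all(res$direction[planted_up & res$is_deg] == "up"))
  expect_true(all(res$direction[planted_down & res$is_deg] == "down"))
  # few false calls among null genes
  expect_lt(mean(res$is_deg[!planted_up & !planted_down]), 0.01)
})

test_that("DEG flagging follows both thresholds and is monotone in alpha", {
  d <- two_group_counts(300, rep(100, 300),
                        c(rep(400, 30), rep(100, 270)), seed = 4)
  strict <- suppressMessages(call_degs(d$counts, d$design, c("b", "a"),
                                       alpha = 0.01))
  loose <- suppressMessages(call_degs(d$counts, d$design, c("b", "a"),
                                      alpha = 0.1))
  expect_true(all(strict$gene[strict$is_deg] %in% loose$gene[loose$is_deg]))
  expect_true(all(strict$padj >= strict$pvalue))
  expect_true(all(strict$is_deg ==
                    (strict$padj < 0.01 & abs(strict$log2fc) > 1)))
})

test_that("low-count genes are filtered and degenerate designs rejected", {
  d <- two_group_counts(100, c(rep(0, 10), rep(100, 90)),
                        c(rep(0, 10), rep(100, 90)), seed = 5)
  d$counts[1:10, ] <- 0L
  expect_message(res <- call_degs(d$counts, d$design, c("b", "a")),
                 "excluded 10")
  expect_equal(nrow(res), 90)
  one_rep <- d$design[c(1, 4), ]
  expect_error(suppressMessages(
    call_degs(d$counts, one_rep, c("b", "a"))),
    class = "rescuekit_degenerate_design_error")
})

test_that("null simulations keep the false-discovery proportion controlled", {
  # complete null: any flagged gene is a false discovery
  fdp <- vapply(1:5, function(s) {
    d <- two_group_counts(1000, rep(150, 1000), rep(150, 1000), seed = s)
    res <- suppressMessages(call_degs(d$counts, d$design, c("b", "a")))
    n_disc <- sum(res$is_deg)
    if (n_disc == 0) 0 else 1
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 5))
})

test_that("core gene sets are the set difference of drug and combo DEGs", {
  drug <- tibble::tibble(gene = paste0("g", 1:6),
                         is_deg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                         direction = c("up", "up", "down", "down",
                                       "none", "none"))
  combo <- dplyr::mutate(drug, is_deg = gene == "g2",
                         direction = ifelse(gene == "g2", "up", "none"))
  core <- core_gene_set(drug, combo)
  expect_setequal(core$members$gene, c("g1", "g3", "g4"))
  expect_equal(core$restored_pct, 75)
  expect_equal(core$n_up, 1)
  expect_equal(core$n_down, 2)
  # combined DEGs identical to drug DEGs: nothing restored
  all_same <- core_gene_set(drug, drug)
  expect_equal(nrow(all_same$members), 0)
  expect_equal(all_same$restored_pct, 0)
  # members never intersect the combined DEG set
  expect_length(intersect(core$members$gene, combo$gene[combo$is_deg]), 0)
})

test_that("core sets require matching gene universes", {
  drug <- tibble::tibble(gene = paste0("g", 1:5), is_deg = TRUE,
                         direction = "up")
  combo <- tibble::tibble(gene = paste0("h", 1:5), is_deg = FALSE,
                          direction = "none")
  expect_error(core_gene_set(drug, combo),
               class = "rescuekit_universe_mismatch_error")
})

test_that("round-trip through call_degs recovers the planted rescue fraction", {
  sim <- sim_counts(n_genes = 800, n_drug_down = 60, n_drug_up = 60,
                    rescued_fraction_serum = 0.8, seed = 6)
  deg_drug <- suppressMessages(
    call_degs(sim$counts, sim$design, c("drug", "control")))
  deg_serum <- suppressMessages(
    call_degs(sim$counts, sim$design, c("drug_serum", "control")))
  core <- core_gene_set(deg_drug, deg_serum, "drug", "serum")
  expect_lt(abs(core$restored_pct - 80), 5)
})

test_that("full-universe sets give permutation p = 1", {
  u <- paste0("g", 1:15)
  res <- permutation_overlap_test(list(u, u), u, n_iter = 100, seed = 1)
  expect_equal(res$p_value, 1)
  expect_true(all(res$null == 15))
})

test_that("permutation p matches the exact hypergeometric tail", {
  u <- paste0("g", 1:20)
  res <- permutation_overlap_test(list(u[1:6], u[4:9]), u,
                                  n_iter = 10000, seed = 2)
  # exact tail: P(overlap >= observed) with |A| = |B| = 6 from 20
  expect_equal(res$observed, 3)
  p_exact <- sum(dhyper(3:6, 6, 14, 6))
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 1e-12)
})

test_that("a perfect overlap of 5 in 20 is essentially never matched by chance", {
  u <- paste0("g", 1:20)
  res <- permutation_overlap_test(list(u[1:5], u[1:5]), u,
                                  n_iter = 1000, seed = 3)
  expect_equal(res$observed, 5)
  # exact tail is 1/choose(20,5) ~ 6.45e-5; 3 MC SE at n = 1000 is ~0.0076
  expect_lte(res$p_value, 0.008)
  if (res$p_value == 0) expect_match(res$note, "< 0.001")
})

test_that("three-set intersections and degenerate observations behave", {
  u <- paste0("g", 1:12)
  res <- permutation_overlap_test(list(u[1:4], u[5:8], u[9:12]), u,
                                  n_iter = 200, seed = 4)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)  # every null >= 0
  expect_error(
    permutation_overlap_test(list(c("x", "y"), u[1:2]), u, n_iter = 10),
    class = "rescuekit_universe_mismatch_error")
})

test_that("directional DEG overlap percentages are computed per direction", {
  a <- tibble::tibble(gene = paste0("g", 1:10),
                      is_deg = c(rep(TRUE, 6), rep(FALSE, 4)),
                      direction = c(rep("up", 3), rep("down", 3),
                                    rep("none", 4)))
  self <- deg_overlap_summary(a, a, n_iter = 100, seed = 5)
  expect_equal(self$overlap_pct, c(100, 100))
  b <- dplyr::mutate(a, is_deg = FALSE, direction = "none")
  none <- deg_overlap_summary(a, b, n_iter = 100, seed = 5)
  expect_true(all(is.na(none$p_value)))
  expect_equal(none$n_overlap, c(0, 0))
})

test_that("the NB Wald caller agrees with an independent DE implementation", {
  skip_if_not_installed("DESeq2")
  sim <- sim_counts(n_genes = 400, n_drug_down = 25, n_drug_up = 25,
                    seed = 9)
  mine <- suppressMessages(
    call_degs(sim$counts, sim$design, c("drug", "control")))
  sel <- sim$design$condition %in% c("drug", "control")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    sim$counts[, sim$design$sample[sel]],
    data.frame(condition = factor(sim$design$condition[sel],
                                  c("control", "drug"))),
    ~ condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  common <- intersect(mine$gene, rownames(res))
  lfc_mine <- mine$log2fc[match(common, mine$gene)]
  lfc_ref <- res$log2FoldChange[match(common, rownames(res))]
  expect_gt(cor(lfc_mine, lfc_ref), 0.99)
  ref_deg <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                             abs(res$log2FoldChange) > 1]
  my_deg <- mine$gene[mine$is_deg]
  jaccard <- length(intersect(ref_deg, my_deg)) /
    length(union(ref_deg, my_deg))
  expect_gt(jaccard, 0.9)
})
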