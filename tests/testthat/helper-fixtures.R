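# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures are stored.

# Exact (noise-free) median-effect table: growth from fa = 1/(1+(Dm/D)^m).
exact_dose_table <- function(m, dm, doses) {
  fa <- 1 / (1 + (dm / doses)^m)
  tibble::tibble(dose = doses, growth_pct = 100 * (1 - fa))
}

# Rasterized disk mask on an h x w grid (same convention as the simulator:
# pixel (i, j) is inside when (i - r0)^2 + (j - c0)^2 <= radius^2).
disk_mask <- function(h, w, r0, c0, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - r0)^2 + (cols - c0)^2 <= radius^2
}

# Brute-force Euclidean distance from every pixel to the nearest TRUE pixel
# of `mask` (quadratic; use on small images only). Independent oracle for
# the distance-transform based ring assignment.
brute_force_distance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2))
    }
  }
  out
}

# Deterministic two-group count matrix with means mu1 (group A) and mu2
# (group B), NB noise, for DEG caller tests.
two_group_counts <- function(n_genes, mu1, mu2, n_reps = 3,
                             dispersion = 0.05, seed = 1) {
  set.seed(seed)
  samples <- c(paste0("a_r", seq_len(n_reps)), paste0("b_r", seq_len(n_reps)))
  counts <- cbind(
    matrix(rnbinom(n_genes * n_reps, mu = mu1, size = 1 / dispersion),
           n_genes, n_reps),
    matrix(rnbinom(n_genes * n_reps, mu = mu2, size = 1 / dispersion),
           n_genes, n_reps)
  )
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)), samples)
  design <- tibble::tibble(
    sample = samples,
    condition = rep(c("a", "b"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2))
  list(counts = counts, design = design)
}
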