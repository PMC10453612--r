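#' Simulate a two-channel KTR reporter field with known C/N ratios
#'
#' Generates a nuclear-stain channel (bright disks on background) and a
#' reporter channel in which each cell's nucleus has intensity `nuc_level`
#' and its surrounding cytoplasm `nuc_level * true_cn_ratio`, so the planted
#' cytoplasm/nucleus ratio is known exactly. Optional features emulate real
#' acquisitions: a linear illumination gradient across the field,
#' multiplicative shot-like noise, and saturated artifact blobs planted on
#' top of randomly chosen cells (the affected cells are recorded in the
#' ground truth so artifact removal can be verified exactly).
#'
#' Cells are placed on a jittered grid whose spacing guarantees centre
#' separation of at least `2 * (nucleus_radius + ring_width + 2)` plus a
#' margin, so measured cytoplasm rings (and the painted cytoplasm behind
#' them) never touch; asking for more cells than the grid can hold is a
#' generation error.
#'
#' @param field_size Integer `(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius Nucleus disk radius, px.
#' @param true_cn_ratio Planted cytoplasm/nucleus reporter intensity ratio.
#' @param ring_width Width of the downstream measurement ring, px; controls
#'   placement margins and the extent of the painted cytoplasm (which is
#'   `ring_width + 2` px so the measured ring sits fully inside it).
#' @param background Additive background intensity in both channels.
#' @param nuc_level Reporter intensity inside the nucleus.
#' @param stain_level Nuclear-stain intensity inside the nucleus.
#' @param illumination_gradient Fractional slope of a left-to-right linear
#'   illumination multiplier `1 + g * (2 x / (w - 1) - 1)`; 0.3 means the
#'   field spans 0.7x to 1.3x.
#' @param noise_sd Multiplicative Gaussian noise fraction on both channels.
#' @param n_artifacts Number of saturated blobs, each centred on a distinct
#'   cell.
#' @param bit_depth Bit depth; intensities are clamped to
#'   `[0, 2^bit_depth - 1]` and rounded to integers.
#' @param seed Integer seed.
#' @return A list of class `ktr_field`: `nuclear` and `reporter` integer
#'   matrices, and `truth`, a tibble with one row per cell (`cell`, `row`,
#'   `col`, `true_cn_ratio`, `artifact` flag).
#' @examples
#' f <- sim_ktr_field(field_size = c(96, 96), n_cells = 4, seed = 1)
#' dim(f$reporter)
#' @export
sim_ktr_field <- function(field_size = c(384, 384), n_cells = 50,
                          nucleus_radius = 8, true_cn_ratio = 2.5,
                          ring_width = 10, background = 100,
                          nuc_level = 2000, stain_level = 3000,
                          illumination_gradient = 0, noise_sd = 0,
                          n_artifacts = 0, bit_depth = 16, seed = NULL) {
  stopifnot(length(field_size) == 2L, all(field_size >= 16))
  assert_scalar_number(true_cn_ratio, "true_cn_ratio", lower = 0)
  assert_scalar_number(nucleus_radius, "nucleus_radius", lower = 1)
  if (n_artifacts > n_cells) {
    stop_rescuekit("Cannot plant more artifacts than cells.",
                   "rescuekit_parameter_error")
  }
  h <- field_size[1]; w <- field_size[2]
  cyto_extent <- ring_width + 2
  margin <- nucleus_radius + cyto_extent + 1
  min_sep <- 2 * (nucleus_radius + cyto_extent) + 2
  max_int <- 2^bit_depth - 1

  jitter_px <- 2
  spacing <- min_sep + 2 * jitter_px
  grid_r <- seq(margin, h - margin, by = spacing)
  grid_c <- seq(margin, w - margin, by = spacing)
  capacity <- length(grid_r) * length(grid_c)
  if (n_cells > capacity) {
    stop_rescuekit(sprintf(
      "Cannot place %d non-overlapping cells on a %dx%d field (capacity %d); reduce n_cells or enlarge the field.",
      n_cells, h, w, capacity), "rescuekit_generation_error")
  }

  with_seed(seed, {
    nodes <- as.matrix(expand.grid(grid_r, grid_c))
    picked <- nodes[sample(capacity, n_cells), , drop = FALSE]
    centers <- picked + matrix(runif(2 * n_cells, -jitter_px, jitter_px),
                               ncol = 2)

    nuclear <- matrix(background, h, w)
    reporter <- matrix(background, h, w)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (k in seq_len(n_cells)) {
      d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
      nuc <- d2 <= nucleus_radius^2
      cyt <- d2 <= (nucleus_radius + cyto_extent)^2 & !nuc
      nuclear[nuc] <- stain_level
      reporter[nuc] <- nuc_level
      reporter[cyt] <- nuc_level * true_cn_ratio
    }

    if (illumination_gradient != 0) {
      illum <- 1 + illumination_gradient * (2 * (cols - 1) / (w - 1) - 1)
      nuclear <- nuclear * illum
      reporter <- reporter * illum
    }
    if (noise_sd > 0) {
      nuclear <- nuclear * (1 + rnorm(h * w, sd = noise_sd))
      reporter <- reporter * (1 + rnorm(h * w, sd = noise_sd))
    }
    nuclear <- matrix(pmin(pmax(round(nuclear), 0), max_int), h, w)
    reporter <- matrix(pmin(pmax(round(reporter), 0), max_int), h, w)

    # saturated artifact blobs are a detector effect: painted at full scale
    # after gradient, noise and clamping, centred on randomly chosen cells
    artifact_cells <- integer(0)
    if (n_artifacts > 0) {
      artifact_cells <- sort(sample(n_cells, n_artifacts))
      for (k in artifact_cells) {
        d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
        reporter[d2 <= (nucleus_radius * 0.8)^2] <- max_int
      }
    }

    truth <- tibble(cell = seq_len(n_cells),
                    row = centers[, 1][seq_len(n_cells)],
                    col = centers[, 2][seq_len(n_cells)],
                    true_cn_ratio = true_cn_ratio,
                    artifact = seq_len(n_cells) %in% artifact_cells)
    if (n_cells == 0) {
      truth <- tibble(cell = integer(0), row = numeric(0), col = numeric(0),
                      true_cn_ratio = numeric(0), artifact = logical(0))
    }
    structure(list(nuclear = nuclear, reporter = reporter, truth = truth,
                   bit_depth = bit_depth),
              class = "ktr_field")
  })
}

#' @export
print.ktr_field <- function(x, ...) {
  cat(sprintf("KTR field: %d x %d px, %d cells (%d with planted artifacts)\n",
              nrow(x$nuclear), ncol(x$nuclear), nrow(x$truth),
              sum(x$truth$artifact)))
  invisible(x)
}

#' Write / read a simulated field as 16-bit TIFF pairs
#'
#' Convenience I/O for interoperating with external image tools: the two
#' channels are written as separate single-channel TIFFs named
#' `<stem>_nuclear.tif` and `<stem>_reporter.tif`. Requires the tiff package.
#'
#' @param field A `ktr_field` object.
#' @param stem Path stem for the two files.
#' @return `write_ktr_field()` returns the two paths invisibly;
#'   `read_ktr_field()` returns a list with `nuclear` and `reporter`
#'   matrices.
#' @export
write_ktr_field <- function(field, stem) {
  rlang::check_installed("tiff")
  max_int <- 2^field$bit_depth - 1
  paths <- paste0(stem, c("_nuclear.tif", "_reporter.tif"))
  tiff::writeTIFF(field$nuclear / max_int, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(field$reporter / max_int, paths[2], bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname write_ktr_field
#' @param bit_depth Bit depth used to rescale intensities back to integers.
#' @export
read_ktr_field <- function(stem, bit_depth = 16) {
  rlang::check_installed("tiff")
  max_int <- 2^bit_depth - 1
  nuc <- tiff::readTIFF(paste0(stem, "_nuclear.tif"))
  rep_ <- tiff::readTIFF(paste0(stem, "_reporter.tif"))
  list(nuclear = round(nuc * max_int), reporter = round(rep_ * max_int))
}
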