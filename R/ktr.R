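#' Correct uneven illumination in a fluorescence field
#'
#' Estimates the illumination profile by heavy Gaussian smoothing of the
#' image (kernel sigma defaulting to 1/8 of the smaller image dimension),
#' divides it out, and rescales so the global median intensity is preserved.
#' If the smoothed estimate touches zero anywhere the image is returned
#' uncorrected with a warning, since division would be undefined.
#'
#' @param image Numeric matrix of intensities (>= 0).
#' @param sigma Smoothing sigma in pixels; default `min(dim(image)) / 8`.
#' @return Corrected matrix of the same dimensions.
#' @export
correct_illumination <- function(image, sigma = NULL) {
  stopifnot(is.matrix(image))
  sigma <- sigma %||% (min(dim(image)) / 8)
  est <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigma))
  if (any(est <= 0)) {
    warn("Illumination estimate reaches zero; returning the image uncorrected.")
    return(image)
  }
  corrected <- image / est
  med <- median(corrected)
  if (med > 0) corrected <- corrected * median(image) / med
  corrected
}

#' Segment nuclei by global Otsu thresholding
#'
#' Applies a two-class Otsu threshold to the nuclear channel, labels
#' connected foreground components (8-connectivity), and removes components
#' outside an area gate and, optionally, components touching the image
#' border. A uniform image has no Otsu threshold; an empty mask is returned
#' with a warning.
#'
#' @param image Nuclear-channel matrix (ideally illumination-corrected).
#' @param min_area,max_area Area gate in pixels; components outside are
#'   dropped.
#' @param exclude_border Drop components touching the field edge.
#' @return Integer label matrix: 0 background, k > 0 for nucleus k. Labels
#'   are consecutive from 1.
#' @export
segment_nuclei <- function(image, min_area = 50, max_area = 5000,
                           exclude_border = FALSE) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) == 0) {
    warn("Uniform image: Otsu threshold undefined; returning an empty mask.")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  scaled <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < min_area | areas > max_area)
  if (exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border[border > 0])
  }
  labels[labels %in% drop] <- 0L
  relabel_consecutive(labels)
}

# 8-connectivity labelling: EBImage::bwlabel is 4-connective, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label_components <- function(mask) {
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  n <- max(labels)
  if (n < 2) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-h, -w]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-1, -w]), as.vector(labels[-h, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels[labels > 0] <- root[labels[labels > 0]]
  relabel_consecutive(labels)
}

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  labels[labels > 0] <- map[labels[labels > 0]]
  labels
}

#' Extend cytoplasm rings outward from segmented nuclei
#'
#' Defines each cell's cytoplasm as the set of background pixels within
#' `width` pixels (Euclidean distance) of that cell's nucleus, excluding all
#' nucleus pixels. Pixels within reach of several nuclei are assigned to the
#' nearest one (distance-transform assignment), so rings never overlap each
#' other or any nucleus.
#'
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @param width Ring width in pixels (> 0); the conventional reporter
#'   measurement uses 10.
#' @return Integer label matrix of cytoplasm rings, labels matching `nuclei`.
#' @export
extend_cytoplasm <- function(nuclei, width = 10) {
  stopifnot(is.matrix(nuclei))
  if (width <= 0) {
    stop_rescuekit("`width` must be a positive number of pixels.",
                   "rescuekit_parameter_error")
  }
  ids <- sort(unique(nuclei[nuclei > 0]))
  rings <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (length(ids) == 0) return(rings)
  # per-nucleus Euclidean distance maps; the per-pixel argmin both assigns
  # contested pixels to the nearest nucleus and realises the disk dilation
  min_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  nearest <- matrix(0L, nrow(nuclei), ncol(nuclei))
  for (k in ids) {
    d <- as.matrix(EBImage::distmap(EBImage::Image((nuclei != k) * 1)))
    closer <- d < min_d
    min_d[closer] <- d[closer]
    nearest[closer] <- k
  }
  in_ring <- min_d > 0 & min_d <= width & nuclei == 0
  rings[in_ring] <- nearest[in_ring]
  rings
}

#' Measure per-cell reporter C/N ratios
#'
#' For each labelled cell, takes the median reporter intensity over its
#' nucleus pixels and over its cytoplasm-ring pixels and reports their ratio
#' (cytoplasm / nucleus), the per-cell kinase-activity statistic of
#' translocation reporters. Cells whose nuclear median is zero get an
#' undefined ratio and a QC flag; cells containing saturated pixels beyond
#' `saturation_frac` of their area are flagged for artifact removal.
#'
#' @param nuclei,rings Matching label matrices.
#' @param reporter Reporter-channel matrix.
#' @param bit_depth Bit depth defining the saturation level
#'   (`2^bit_depth - 1`).
#' @param saturation_frac Flag a cell when more than this fraction of its
#'   nucleus + ring pixels are saturated.
#' @return A tibble with one row per cell: `cell`, `nuc_area`, `ring_area`,
#'   `median_nuc`, `median_cyt`, `cn_ratio`, `saturated_frac`,
#'   `flag_saturated`, `flag_zero_nucleus`.
#' @export
measure_ktr <- function(nuclei, rings, reporter, bit_depth = 16,
                        saturation_frac = 0.01) {
  stopifnot(all(dim(nuclei) == dim(reporter)),
            all(dim(rings) == dim(reporter)))
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (length(ids) == 0) return(empty_measurements())
  sat_level <- 2^bit_depth - 1
  rows <- purrr::map(ids, function(k) {
    nuc_px <- reporter[nuclei == k]
    ring_px <- reporter[rings == k]
    med_n <- median(nuc_px)
    med_c <- if (length(ring_px) > 0) median(ring_px) else NA_real_
    sat <- mean(c(nuc_px, ring_px) >= sat_level)
    tibble(cell = k,
           nuc_area = length(nuc_px), ring_area = length(ring_px),
           median_nuc = med_n, median_cyt = med_c,
           cn_ratio = if (is.na(med_c) || med_n <= 0) NA_real_
                      else med_c / med_n,
           saturated_frac = sat,
           flag_saturated = sat > saturation_frac,
           flag_zero_nucleus = med_n <= 0)
  })
  dplyr::bind_rows(rows)
}

empty_measurements <- function() {
  tibble(cell = integer(0), nuc_area = integer(0), ring_area = integer(0),
         median_nuc = numeric(0), median_cyt = numeric(0),
         cn_ratio = numeric(0), saturated_frac = numeric(0),
         flag_saturated = logical(0), flag_zero_nucleus = logical(0))
}

#' Drop artifactual cell measurements
#'
#' Removes cells flagged for saturation, with a nuclear area outside
#' `area_bounds`, with an undefined ratio, or with a ratio outside
#' `ratio_bounds`. The number removed per reason is reported via a message;
#' removing every cell additionally raises a warning.
#'
#' @param measurements Tibble from [measure_ktr()].
#' @param area_bounds Allowed nucleus area range, px.
#' @param ratio_bounds Allowed C/N ratio range.
#' @return The filtered measurement tibble.
#' @export
remove_artifacts <- function(measurements, area_bounds = c(50, 5000),
                             ratio_bounds = c(0.05, 20)) {
  if (nrow(measurements) == 0) return(measurements)
  bad_sat <- measurements$flag_saturated
  bad_area <- measurements$nuc_area < area_bounds[1] |
    measurements$nuc_area > area_bounds[2]
  bad_ratio <- is.na(measurements$cn_ratio) |
    measurements$cn_ratio < ratio_bounds[1] |
    measurements$cn_ratio > ratio_bounds[2] |
    measurements$flag_zero_nucleus
  drop <- bad_sat | bad_area | bad_ratio
  if (any(drop)) {
    inform(sprintf(
      "remove_artifacts: dropped %d of %d cells (%d saturated, %d area, %d ratio/undefined).",
      sum(drop), length(drop), sum(bad_sat), sum(bad_area & !bad_sat),
      sum(bad_ratio & !bad_sat & !bad_area)))
  }
  if (all(drop) && length(drop) > 0) {
    warn("All cells were flagged as artifactual; no measurements remain.")
  }
  measurements[!drop, ]
}

#' Run the full KTR quantification pipeline on one field
#'
#' Chains illumination correction (both channels), nuclei segmentation,
#' cytoplasm-ring extension, per-cell measurement and artifact removal.
#'
#' @param nuclear,reporter Channel matrices of equal size.
#' @param ring_width Ring width in pixels.
#' @param correct Logical; apply illumination correction first.
#' @param bit_depth Bit depth for saturation flagging.
#' @param ... Passed to [segment_nuclei()] and [remove_artifacts()] where
#'   named arguments match.
#' @return Per-cell measurement tibble (artifact-filtered).
#' @examples
#' f <- sim_ktr_field(field_size = c(128, 128), n_cells = 5,
#'                    true_cn_ratio = 2, seed = 1)
#' m <- ktr_pipeline(f$nuclear, f$reporter)
#' median(m$cn_ratio)
#' @export
ktr_pipeline <- function(nuclear, reporter, ring_width = 10, correct = TRUE,
                         bit_depth = 16, min_area = 50, max_area = 5000,
                         area_bounds = c(50, 5000), ratio_bounds = c(0.05, 20),
                         saturation_frac = 0.01) {
  # saturation must be judged on raw intensities, before correction rescales
  sat_level <- 2^bit_depth - 1
  raw_reporter <- reporter
  if (correct) {
    nuclear <- correct_illumination(nuclear)
    reporter <- correct_illumination(reporter)
  }
  nuclei <- segment_nuclei(nuclear, min_area = min_area, max_area = max_area)
  rings <- extend_cytoplasm(nuclei, width = ring_width)
  meas <- measure_ktr(nuclei, rings, reporter, bit_depth = bit_depth,
                      saturation_frac = saturation_frac)
  if (nrow(meas) > 0) {
    # recompute saturation flags on the raw channel
    meas$saturated_frac <- vapply(meas$cell, function(k) {
      mean(raw_reporter[nuclei == k | rings == k] >= sat_level)
    }, numeric(1))
    meas$flag_saturated <- meas$saturated_frac > saturation_frac
  }
  remove_artifacts(meas, area_bounds = area_bounds,
                   ratio_bounds = ratio_bounds)
}

#' Summarise C/N ratios per replicate and condition
#'
#' Per biological replicate: the median and interquartile range of per-cell
#' ratios. Per condition: the mean of replicate medians with their SD (0 when
#' only one replicate exists). Optionally normalises condition summaries to a
#' reference condition's mean.
#'
#' @param measurements Tibble of per-cell measurements with added `condition`
#'   and `replicate` columns.
#' @param reference Optional condition name; if given, a
#'   `relative_activity` column reports each condition's mean divided by the
#'   reference mean.
#' @return A list with tibbles `replicates` (condition, replicate,
#'   median_cn, iqr_cn, n_cells) and `conditions` (condition, mean_cn,
#'   sd_cn, n_reps, and optionally relative_activity).
#' @export
summarize_condition <- function(measurements, reference = NULL) {
  stopifnot(all(c("condition", "replicate", "cn_ratio") %in%
                  names(measurements)))
  reps <- measurements |>
    dplyr::filter(!is.na(.data$cn_ratio)) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(median_cn = median(.data$cn_ratio),
                     iqr_cn = stats::IQR(.data$cn_ratio),
                     n_cells = dplyr::n(), .groups = "drop")
  conds <- reps |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_cn = mean(.data$median_cn),
                     sd_cn = ifelse(dplyr::n() > 1, sd(.data$median_cn), 0),
                     n_reps = dplyr::n(), .groups = "drop")
  if (!is.null(reference)) {
    if (!reference %in% conds$condition) {
      stop_rescuekit("Reference condition not present in the data.",
                     "rescuekit_parameter_error")
    }
    ref <- conds$mean_cn[conds$condition == reference]
    conds$relative_activity <- conds$mean_cn / ref
  }
  list(replicates = reps, conditions = conds)
}

#' Plot per-cell C/N ratio distributions by condition
#'
#' @param measurements Per-cell tibble with `condition` and `cn_ratio`.
#' @return A ggplot object (boxplots over jittered cells).
#' @export
plot_ktr_ratios <- function(measurements) {
  ggplot2::ggplot(measurements,
                  ggplot2::aes(.data$condition, .data$cn_ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "C/N reporter ratio") +
    ggplot2::theme_minimal()
}
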