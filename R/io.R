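#' Read and write the package's tabular formats
#'
#' Thin readr-based wrappers fixing the column contracts used throughout:
#' dose-response tables (CSV: `dose`, `modulator_level`, `growth_pct`,
#' optional `replicate`), DNA-content event lists (CSV: one `intensity` per
#' row), count matrices (TSV: first column `gene`, remaining columns
#' samples) and sample designs (TSV: `sample`, `condition`, optional
#' `replicate`).
#'
#' @param path File path.
#' @name rescuekit-io
NULL

#' @rdname rescuekit-io
#' @export
read_dose_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("dose", "growth_pct")
  if (!all(need %in% names(tab))) {
    stop_rescuekit("Dose table needs columns `dose` and `growth_pct`.",
                   "rescuekit_format_error")
  }
  if (!"modulator_level" %in% names(tab)) tab$modulator_level <- 0
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  tab
}

#' @rdname rescuekit-io
#' @param table Tibble to write.
#' @export
write_dose_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname rescuekit-io
#' @export
read_events <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  col <- if ("intensity" %in% names(tab)) "intensity" else names(tab)[1]
  as.numeric(tab[[col]])
}

#' @rdname rescuekit-io
#' @param events Numeric vector of event intensities.
#' @export
write_events <- function(events, path) {
  readr::write_csv(tibble(intensity = as.numeric(events)), path)
  invisible(path)
}

#' @rdname rescuekit-io
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- tab[[1]]
  mat <- as.matrix(tab[, -1])
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  mat
}

#' @rdname rescuekit-io
#' @param counts Integer matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(as_tibble(counts, rownames = "gene"), path)
  invisible(path)
}

#' @rdname rescuekit-io
#' @export
read_design <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample", "condition") %in% names(tab))) {
    stop_rescuekit("Design needs columns `sample` and `condition`.",
                   "rescuekit_format_error")
  }
  tab
}

#' @rdname rescuekit-io
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Read a GMT gene-set file, optionally with role weights
#'
#' Standard GMT: one tab-separated line per set — name, description, then
#' member genes. This reader additionally understands a weighted dialect in
#' which each member is written `gene|weight`, encoding activator/repressor
#' roles (positive/negative, magnitude at most 1). In plain GMT mode every
#' member gets weight +1 (all-activator).
#'
#' @param path GMT file path.
#' @param weighted Parse `gene|weight` members; plain genes still default
#'   to +1.
#' @return Tibble: `pathway`, `description`, `gene`, `weight`.
#' @examples
#' gmt <- system.file("extdata", "example_pathways.gmt",
#'                    package = "rescuekit")
#' read_gmt(gmt)
#' @export
read_gmt <- function(path, weighted = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_rescuekit("GMT lines need name, description and >= 1 gene.",
                     "rescuekit_format_error")
    }
    members <- parts[-(1:2)]
    if (weighted) {
      split_members <- strsplit(members, "|", fixed = TRUE)
      genes <- vapply(split_members, `[`, character(1), 1)
      weights <- vapply(split_members, function(m) {
        if (length(m) > 1) as.numeric(m[2]) else 1
      }, numeric(1))
    } else {
      genes <- members
      weights <- rep(1, length(members))
    }
    if (any(!is.finite(weights)) || any(abs(weights) > 1)) {
      stop_rescuekit("Role weights must be finite with magnitude <= 1.",
                     "rescuekit_format_error")
    }
    tibble(pathway = parts[1], description = parts[2], gene = genes,
           weight = weights)
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_gmt
#' @param pathways Tibble `pathway`, `gene`, `weight` (and optionally
#'   `description`).
#' @export
write_gmt <- function(pathways, path) {
  lines <- pathways |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      line = paste(c(.data$pathway[1],
                     if ("description" %in% names(pathways))
                       .data$description[1] else "na",
                     sprintf("%s|%g", .data$gene, .data$weight)),
                   collapse = "\t"),
      .groups = "drop")
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Configuration files hold paths, seeds and analysis thresholds. Missing
#' thresholds default to the conventional values used throughout the
#' package: significance alpha 0.05, |log2FC| threshold 1, 1000 permutation
#' iterations, 10 px cytoplasm ring, minimum pathway size 10.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list with a `thresholds` sub-list fully populated.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(alpha = 0.05, lfc_threshold = 1, n_iter = 1000,
                   ring_width = 10, min_pathway_genes = 10)
  cfg$thresholds <- utils::modifyList(defaults,
                                      as.list(cfg$thresholds %||% list()))
  cfg
}
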