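#' Default run configuration
#'
#' The full parameter set of the pipeline stages, used by the command
#' line interface and embedded as provenance in every output file.
#' Unknown keys are rejected by [validate_run_config()].
#'
#' @return nested named list of stage parameters.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(n_per_group = 10L, mode = "rigid", spec = list()),
    detector = list(base_sigma_mm = 1.6, levels_per_octave = 3L,
                    n_octaves = NULL, contrast_min = 0.08,
                    edge_ratio_max = 10, max_features = Inf),
    descriptor = list(support_factor = 2, grid_n = 16L,
                      orientation_mode = "upright"),
    matching = list(bandwidth = NULL, geometry = TRUE, loc_sigma_mm = 10,
                    logscale_sigma = log(1.5)),
    classify = list(threshold = 0, orientation = "female_positive")
  )
}

#' Validate a run configuration against the schema
#'
#' Checks (recursively) that every key exists in [default_run_config()];
#' unknown keys raise an error naming the offending path. Returns the
#' default configuration with the given values merged in.
#'
#' @param config nested list (e.g. parsed from JSON).
#' @return merged, validated configuration list.
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  merge_validate <- function(def, cfg, path) {
    if (!is.list(cfg)) return(cfg)
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown) > 0) {
      stop("unknown configuration key: ",
           paste0(path, unknown, collapse = ", "))
    }
    for (k in names(cfg)) {
      def[[k]] <- if (is.list(def[[k]]) && k != "spec") {
        merge_validate(def[[k]], cfg[[k]], paste0(path, k, "."))
      } else cfg[[k]]
    }
    def
  }
  merge_validate(defaults, config, "")
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

config_json <- function(config) {
  jsonlite::toJSON(config, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Write a feature set to a keypoint TSV
#'
#' One row per keypoint; `#`-prefixed header lines carry the extraction
#' parameters and grid metadata as JSON (provenance). Floating point
#' fields are written at full precision so the round trip is lossless.
#'
#' @param features feature tibble (see [extract_features()]).
#' @param path output path.
#' @param header named list recorded in the `#` header (e.g. the run
#'   configuration); the tibble's own `params` attribute is included
#'   automatically.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(features, path, header = list()) {
  cols <- keypoint_cols()
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature tibble lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  meta <- c(header, list(params = attr(features, "params")))
  lines <- c(
    "# voxsift keypoints v1",
    paste0("# ", config_json(meta)),
    paste(cols, collapse = "\t"))
  df <- features[, cols]
  fmt <- vapply(seq_len(nrow(df)), function(r) {
    paste(vapply(cols, function(cn) {
      v <- df[[cn]][r]
      if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
      else as.character(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(lines, fmt), path)
  invisible(path)
}

keypoint_cols <- function() {
  c("subject_id", "label", "x_mm", "y_mm", "z_mm", "sigma_mm", "response",
    "sign", rotation_cols(), descriptor_cols())
}

#' Read a keypoint TSV
#'
#' Validates the schema: the expected 81 columns, and unit descriptor
#' norms (deviation greater than 1e-6 raises an error naming the row).
#'
#' @param path path to a TSV written by [write_keypoints()].
#' @return feature tibble with attribute `header` (parsed `#` metadata).
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop("keypoint file not found: ", path)
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  body <- raw[!startsWith(raw, "#")]
  if (length(body) == 0L) stop("keypoint file has no column header: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols, keypoint_cols())) {
    stop("unexpected keypoint columns in ", path, " (got ", length(cols),
         ", expected ", length(keypoint_cols()), ")")
  }
  out <- empty_features()
  if (length(body) > 1L) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(cols))
    if (length(bad) > 0) {
      stop("row ", bad[1], " of ", path, " has ", lengths(parts)[bad[1]],
           " fields, expected ", length(cols))
    }
    m <- do.call(rbind, parts)
    out <- tibble::tibble(subject_id = m[, 1], label = m[, 2])
    for (ci in 3:length(cols)) {
      out[[cols[ci]]] <- as.numeric(m[, ci])
    }
    out$sign <- as.integer(out$sign)
    norms <- sqrt(rowSums(descriptor_matrix(out)^2))
    bad <- which(abs(norms - 1) > 1e-6)
    if (length(bad) > 0) {
      stop("row ", bad[1], " of ", path, ": descriptor norm ",
           format(norms[bad[1]]), " is not unit")
    }
  }
  meta <- NULL
  json_lines <- hdr[grepl("^# \\{", hdr)]
  if (length(json_lines) > 0) {
    meta <- tryCatch(
      jsonlite::fromJSON(sub("^# ", "", json_lines[1]),
                         simplifyVector = TRUE),
      error = function(e) NULL)
  }
  attr(out, "header") <- meta
  out
}

#' Published per-label feature counts of the reference study
#'
#' Mean (and sd) of features extracted per image by label and
#' registration mode, as published in the 422-subject brain MRI sex
#' classification study this package's analysis design mirrors. The
#' male excess under rigid registration (fine-scale features visible only
#' in larger brains) is the quantity examined by
#' [trim_smallest_features()].
#'
#' @return A tibble: `registration`, `label`, `mean_features`,
#'   `sd_features`.
#' @export
reference_feature_counts <- function() {
  tibble::tibble(
    registration = rep(c("rigid", "nonlinear"), each = 2),
    label = rep(c("F", "M"), 2),
    mean_features = c(252, 292, 315, 314),
    sd_features = c(42, 42, 33, 33))
}
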