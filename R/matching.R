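#' Nearest-neighbour feature matching between two feature sets
#'
#' For each keypoint of `A`, finds the single nearest keypoint of `B` by
#' Euclidean distance between descriptors, optionally excluding one
#' subject's keypoints from `B` (leave-one-out hygiene). The search is
#' exact; ties are broken by the smallest row index of `B`.
#'
#' @param A,B feature tibbles (see [extract_features()]). `A` is the
#'   query set, `B` the target (memory) set.
#' @param exclude_subject subject id whose keypoints are removed from `B`
#'   before matching, or `NULL`.
#' @return A tibble with one row per keypoint of `A`: `query_index`,
#'   `query_subject`, `target_index` (row in `B`), `target_subject`,
#'   `distance`.
#' @export
nn_match <- function(A, B, exclude_subject = NULL) {
  keep <- rep(TRUE, nrow(B))
  if (!is.null(exclude_subject)) keep <- B$subject_id != exclude_subject
  if (!any(keep)) {
    stop("memory is unusable: no target keypoints remain after excluding ",
         "subject '", exclude_subject, "'")
  }
  Bk <- B[keep, , drop = FALSE]
  rows_b <- which(keep)
  da <- descriptor_matrix(A)
  db <- descriptor_matrix(Bk)
  # squared distances via the polarization identity (BLAS-backed)
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * tcrossprod(da, db)
  d2 <- pmax(d2, 0)
  j <- max.col(-d2, ties.method = "first")
  tibble::tibble(
    query_index = seq_len(nrow(A)),
    query_subject = A$subject_id,
    target_index = rows_b[j],
    target_subject = Bk$subject_id[j],
    distance = sqrt(d2[cbind(seq_len(nrow(A)), j)]))
}

#' Soft feature-equivalence weight
#'
#' Maps a descriptor distance to a soft equivalence weight
#' `exp(-d^2 / bandwidth^2)` in `[0, 1]`; `bandwidth = 1` reproduces the
#' literal `exp(-d^2)` form.
#'
#' @param d non-negative descriptor distance(s).
#' @param bandwidth positive kernel bandwidth.
#' @return weight(s) in `[0, 1]`.
#' @export
equivalence_weight <- function(d, bandwidth = 1) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive")
  }
  stopifnot(all(d >= 0))
  exp(-d^2 / bandwidth^2)
}

#' Geometric-consistency weight for a feature match
#'
#' Down-weights matches whose world locations or scales disagree:
#' `exp(-||xa - xb||^2 / (2 loc_sigma^2)) * exp(-(ln sa - ln sb)^2 /
#' (2 logscale_sigma^2))`. With `geometry = FALSE` the weight is 1
#' regardless of the inputs.
#'
#' @param a,b data frames (equal rows) with `x_mm, y_mm, z_mm, sigma_mm`.
#' @param loc_sigma_mm location tolerance (mm).
#' @param logscale_sigma log-scale tolerance.
#' @param geometry logical; `FALSE` disables geometric weighting.
#' @return weight(s) in `[0, 1]`.
#' @export
geometry_weight <- function(a, b, loc_sigma_mm = 10,
                            logscale_sigma = log(1.5), geometry = TRUE) {
  if (!geometry) return(rep(1, max(nrow(a), 1L)))
  if (loc_sigma_mm <= 0 || logscale_sigma <= 0) {
    stop("loc_sigma_mm and logscale_sigma must be positive")
  }
  if (any(a$sigma_mm <= 0) || any(b$sigma_mm <= 0)) {
    stop("keypoint scales must be positive")
  }
  d2 <- (a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2 + (a$z_mm - b$z_mm)^2
  ds <- log(a$sigma_mm) - log(b$sigma_mm)
  exp(-d2 / (2 * loc_sigma_mm^2)) * exp(-ds^2 / (2 * logscale_sigma^2))
}

#' Soft intersection of two feature sets
#'
#' The directed soft intersection |A (intersect) B|: the sum over query
#' features of the combined (equivalence x geometry) weight of each
#' feature's nearest-neighbour match in `B`. Bounded above by |A|.
#'
#' @inheritParams nn_match
#' @param bandwidth equivalence-kernel bandwidth.
#' @param geometry logical; include geometric-consistency weighting.
#' @param loc_sigma_mm,logscale_sigma see [geometry_weight()].
#' @return non-negative scalar.
#' @export
soft_intersection <- function(A, B, bandwidth = 1, geometry = FALSE,
                              exclude_subject = NULL, loc_sigma_mm = 10,
                              logscale_sigma = log(1.5)) {
  if (nrow(A) == 0L) return(0)
  m <- nn_match(A, B, exclude_subject = exclude_subject)
  w <- equivalence_weight(m$distance, bandwidth)
  if (geometry) {
    w <- w * geometry_weight(A[m$query_index, ], B[m$target_index, ],
                             loc_sigma_mm, logscale_sigma)
  }
  sum(w)
}

#' Soft Jaccard overlap between two feature sets
#'
#' `J(A, B) = |A n B| / (|A| + |B| - |A n B|)` with the soft directed
#' intersection of [soft_intersection()] and hard cardinalities |A|, |B|.
#' Lies in `[0, 1]`; 1 indicates perfect overlap.
#'
#' @inheritParams soft_intersection
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(A, B, bandwidth = 1, geometry = FALSE,
                    exclude_subject = NULL, loc_sigma_mm = 10,
                    logscale_sigma = log(1.5)) {
  nb <- if (is.null(exclude_subject)) nrow(B) else
    sum(B$subject_id != exclude_subject)
  if (nrow(A) + nb == 0L) stop("both feature sets are empty")
  s <- soft_intersection(A, B, bandwidth = bandwidth, geometry = geometry,
                         exclude_subject = exclude_subject,
                         loc_sigma_mm = loc_sigma_mm,
                         logscale_sigma = logscale_sigma)
  j <- s / (nrow(A) + nb - s)
  if (j < 0 || j > 1) {
    if (j < -1e-9 || j > 1 + 1e-9) {
      warning("Jaccard value ", j, " clipped to [0, 1]")
    }
    j <- min(max(j, 0), 1)
  }
  j
}

#' Calibrate the equivalence-kernel bandwidth from a memory
#'
#' Sets the bandwidth to the median nearest-neighbour descriptor distance
#' over a sample of cross-subject matches, so that a typical match
#' receives weight `exp(-1)`. Unit-norm rank descriptors concentrate
#' distances, making a fixed bandwidth of 1 arbitrary; this data-driven
#' scale adapts to the cohort. Deterministic given the memory and seed.
#'
#' @param memory a [group_memory()] or a feature tibble with >= 2
#'   subjects.
#' @param max_queries at most this many query keypoints are sampled.
#' @param seed integer seed for the query sample.
#' @return positive bandwidth; falls back to 1 with a warning when the
#'   memory is degenerate (all nearest-neighbour distances zero).
#' @export
calibrate_bandwidth <- function(memory, max_queries = 2000L, seed = 1L) {
  feats <- memory_features(memory)
  if (length(unique(feats$subject_id)) < 2L) {
    stop("bandwidth calibration needs at least 2 subjects")
  }
  idx <- seq_len(nrow(feats))
  if (nrow(feats) > max_queries) {
    idx <- with_local_seed(seed, sort(sample(idx, max_queries)))
  }
  dmin <- cross_subject_nn_distances(feats, idx)
  med <- stats::median(dmin)
  if (med <= 0) {
    warning("degenerate memory (median NN distance 0); bandwidth fallback 1")
    return(1)
  }
  med
}

# Nearest cross-subject descriptor distance for the selected query rows.
cross_subject_nn_distances <- function(feats, idx = seq_len(nrow(feats))) {
  dm <- descriptor_matrix(feats)
  q <- dm[idx, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(dm^2), "+") - 2 * tcrossprod(q, dm)
  same <- outer(feats$subject_id[idx], feats$subject_id, "==")
  d2[same] <- Inf
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Write a match table to TSV
#'
#' @param matches a [nn_match()] result (optionally with weight columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
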