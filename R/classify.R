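#' Build a labelled group memory from pooled feature sets
#'
#' The memory is the classifier's training state: all labelled subjects'
#' keypoints pooled, with per-label cardinalities. No fitting is
#' involved — classification is pure feature matching against this
#' memory.
#'
#' @param features feature tibble with columns `subject_id`, `label`
#'   (values `"M"`/`"F"`) and the keypoint schema of
#'   [extract_features()].
#' @return An object of class `group_memory`.
#' @export
group_memory <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  if (!all(features$label %in% c("M", "F"))) {
    stop("memory features must be labelled 'M' or 'F'")
  }
  subjects <- unique(features$subject_id)
  labels <- vapply(subjects, function(s) {
    l <- unique(features$label[features$subject_id == s])
    if (length(l) != 1L) stop("subject ", s, " has inconsistent labels")
    l
  }, character(1))
  structure(
    list(features = tibble::as_tibble(features), subjects = subjects,
         labels = labels,
         cardinality = c(F = sum(features$label == "F"),
                         M = sum(features$label == "M"))),
    class = "group_memory")
}

#' @export
print.group_memory <- function(x, ...) {
  cat(sprintf("<group_memory> %d subjects (%d F, %d M), |Female| = %d, |Male| = %d keypoints\n",
              length(x$subjects), sum(x$labels == "F"), sum(x$labels == "M"),
              x$cardinality[["F"]], x$cardinality[["M"]]))
  invisible(x)
}

memory_features <- function(memory) {
  if (inherits(memory, "group_memory")) memory$features
  else tibble::as_tibble(memory)
}

#' Remove the smallest-scale features from one label's sets
#'
#' Removes the `k` smallest-sigma keypoints from each feature set of the
#' given label (e.g. to test whether excess fine-scale features in the
#' larger-brained group affect classification).
#'
#' @param memory a [group_memory()] or feature tibble.
#' @param label `"M"` or `"F"`.
#' @param k number of keypoints to drop per subject of that label.
#' @return A [group_memory()] with the trimmed feature sets.
#' @export
trim_smallest_features <- function(memory, label, k) {
  stopifnot(label %in% c("M", "F"), k >= 0)
  feats <- memory_features(memory)
  if (k == 0) return(group_memory(feats))
  out <- feats |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      if (df$label[1] != label) return(df)
      if (k > nrow(df)) {
        stop("k = ", k, " exceeds the feature count of subject ",
             key$subject_id)
      }
      df[rank(df$sigma_mm, ties.method = "first") > k, , drop = FALSE]
    }) |>
    dplyr::ungroup()
  group_memory(out)
}

# Per-(query keypoint, target subject) best-match table for a cohort:
# list(dmin = n_kp x n_subj matrix of NN descriptor distances,
#      wg = matching geometry weights, feats, subjects).
# This is the O(n^2) precompute that makes leave-one-out scoring and
# label permutations cheap: the NN within any subject pool is the
# minimum over that pool's columns.
cross_match_table <- function(feats, loc_sigma_mm = 10,
                              logscale_sigma = log(1.5)) {
  subjects <- unique(feats$subject_id)
  dm <- descriptor_matrix(feats)
  nq <- nrow(feats)
  q2 <- rowSums(dm^2)
  dmin <- matrix(Inf, nq, length(subjects),
                 dimnames = list(NULL, subjects))
  wg <- matrix(1, nq, length(subjects), dimnames = list(NULL, subjects))
  for (si in seq_along(subjects)) {
    rows_t <- which(feats$subject_id == subjects[si])
    dt <- dm[rows_t, , drop = FALSE]
    d2 <- outer(q2, rowSums(dt^2), "+") - 2 * tcrossprod(dm, dt)
    j <- max.col(-d2, ties.method = "first")
    dmin[, si] <- sqrt(pmax(d2[cbind(seq_len(nq), j)], 0))
    tgt <- feats[rows_t[j], ]
    wg[, si] <- geometry_weight(feats, tgt,
                                loc_sigma_mm = loc_sigma_mm,
                                logscale_sigma = logscale_sigma)
  }
  list(dmin = dmin, wg = wg, feats = feats, subjects = subjects)
}

# Directed soft intersection of subject q against the pool of subjects
# `pool` (character), from a cross_match_table.
soft_intersection_from_table <- function(tab, q_rows, pool, bandwidth,
                                         geometry) {
  cols <- match(pool, tab$subjects)
  sub <- tab$dmin[q_rows, cols, drop = FALSE]
  j <- max.col(-sub, ties.method = "first")
  d <- sub[cbind(seq_along(q_rows), j)]
  w <- exp(-d^2 / bandwidth^2)
  if (geometry) {
    w <- w * tab$wg[q_rows, cols, drop = FALSE][cbind(seq_along(q_rows), j)]
  }
  sum(w[is.finite(d)])
}

#' Score one subject against a labelled group memory
#'
#' Computes the subject's soft-Jaccard overlap to the Female and Male
#' pooled memories (always excluding the subject's own features,
#' leave-one-out) and the prediction score
#' `score = log J(A, Female) - log J(A, Male)`.
#' Under the default `"female_positive"` orientation a higher score means
#' more Female-typical; `"male_positive"` negates the score (some
#' presentations plot male on the positive side).
#'
#' @param A one subject's feature tibble.
#' @param memory a [group_memory()] containing both labels.
#' @param bandwidth equivalence-kernel bandwidth.
#' @param geometry logical; geometric-consistency weighting.
#' @param threshold decision threshold on the score.
#' @param orientation `"female_positive"` (literal score) or
#'   `"male_positive"` (negated).
#' @param loc_sigma_mm,logscale_sigma see [geometry_weight()].
#' @param balance_pools logical; with plain leave-one-out the query's own
#'   label pool is one subject smaller than the other, which biases every
#'   subject towards its own label (a set-size effect on the Jaccard
#'   denominator). When `TRUE` (default) one deterministically chosen
#'   subject (the last of the opposite label in memory order) is also
#'   excluded, so both pools shrink by exactly one subject and a
#'   label-shuffled cohort scores at chance.
#' @return One-row tibble: `subject_id, label, j_female, j_male, score,
#'   predicted, threshold, degenerate` (TRUE when an overlap is exactly 0
#'   and the score is an infinite sentinel).
#' @export
score_subject <- function(A, memory, bandwidth = 1, geometry = FALSE,
                          threshold = 0,
                          orientation = c("female_positive", "male_positive"),
                          loc_sigma_mm = 10, logscale_sigma = log(1.5),
                          balance_pools = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(memory, "group_memory"))
  if (!all(c("F", "M") %in% memory$labels)) {
    stop("memory must contain both labels")
  }
  sid <- unique(A$subject_id)
  stopifnot(length(sid) == 1L)
  # balancing only matters when the query itself sits in the memory:
  # an external query leaves both pools at full size already
  own_label <- if (sid %in% names(memory$labels)) memory$labels[[sid]]
               else NA_character_
  feats <- memory$features
  j_for <- function(lab) {
    pool <- feats[feats$label == lab, , drop = FALSE]
    excl <- sid
    if (balance_pools && !is.na(own_label) && lab != own_label) {
      excl <- balancer_subject(memory, lab, sid)
    }
    jaccard(A, pool, bandwidth = bandwidth, geometry = geometry,
            exclude_subject = excl, loc_sigma_mm = loc_sigma_mm,
            logscale_sigma = logscale_sigma)
  }
  finish_prediction(sid, if ("label" %in% names(A)) A$label[1] else NA,
                    j_for("F"), j_for("M"), threshold, orientation)
}

# The subject removed from the opposite-label pool to balance plain
# leave-one-out: the last subject of that label in memory order (never
# the query). Returns NULL (no exclusion) when the pool has < 2 subjects.
balancer_subject <- function(memory, lab, sid) {
  pool_subjects <- setdiff(memory$subjects[memory$labels == lab], sid)
  if (length(pool_subjects) < 2L) return(sid)
  pool_subjects[length(pool_subjects)]
}

finish_prediction <- function(sid, true_label, jf, jm, threshold,
                              orientation) {
  degenerate <- (jf == 0 || jm == 0)
  score <- log(jf) - log(jm)
  if (orientation == "male_positive") score <- -score
  predicted <- if (is.nan(score)) NA_character_
               else if (orientation == "female_positive") {
                 if (score > threshold) "F" else "M"
               } else {
                 if (score > threshold) "M" else "F"
               }
  tibble::tibble(subject_id = sid, label = true_label, j_female = jf,
                 j_male = jm, score = score, predicted = predicted,
                 threshold = threshold, degenerate = degenerate)
}

#' Leave-one-out classification of a whole cohort
#'
#' Scores every subject against the memory formed by all *other*
#' subjects (a subject's own features never appear in its memory) and
#' predicts labels by thresholding the score. Equivalent to calling
#' [score_subject()] per subject, but uses a shared cross-match
#' precompute.
#'
#' @param features cohort feature tibble (labelled).
#' @param bandwidth kernel bandwidth, or `NULL` to calibrate with
#'   [calibrate_bandwidth()].
#' @param geometry logical; geometric-consistency weighting.
#' @param threshold decision threshold.
#' @param orientation score orientation, see [score_subject()].
#' @param loc_sigma_mm,logscale_sigma see [geometry_weight()].
#' @param labels optional named character vector (subject_id -> label)
#'   overriding the labels in `features` (used for permutation nulls);
#'   matching is unaffected, only pool membership changes.
#' @param match_table optional precomputed internal cross-match table
#'   (reused across label permutations).
#' @param balance_pools see [score_subject()]; keeps both label pools the
#'   same number of subjects smaller under leave-one-out.
#' @return A tibble of per-subject predictions (class
#'   `sift_predictions`), one row per subject, with attributes
#'   `bandwidth`, `geometry`, `orientation`, `match_table`.
#' @export
classify_cohort <- function(features, bandwidth = NULL, geometry = TRUE,
                            threshold = 0,
                            orientation = c("female_positive", "male_positive"),
                            loc_sigma_mm = 10, logscale_sigma = log(1.5),
                            labels = NULL, match_table = NULL,
                            balance_pools = TRUE) {
  orientation <- match.arg(orientation)
  memory <- group_memory(features)
  if (is.null(bandwidth)) bandwidth <- calibrate_bandwidth(memory)
  tab <- match_table
  if (is.null(tab)) {
    tab <- cross_match_table(memory$features, loc_sigma_mm = loc_sigma_mm,
                             logscale_sigma = logscale_sigma)
  }
  subj_labels <- memory$labels
  if (!is.null(labels)) {
    stopifnot(all(names(subj_labels) %in% names(labels)))
    subj_labels <- labels[names(subj_labels)]
  }
  feats <- tab$feats
  counts <- table(factor(feats$subject_id, levels = tab$subjects))
  out <- purrr::map(tab$subjects, function(sid) {
    q_rows <- which(feats$subject_id == sid)
    own_label <- subj_labels[[sid]]
    res <- purrr::map_dbl(c("F", "M"), function(lab) {
      pool <- tab$subjects[subj_labels[tab$subjects] == lab &
                             tab$subjects != sid]
      if (balance_pools && lab != own_label && length(pool) >= 2L) {
        pool <- pool[-length(pool)]   # balanced leave-one-out
      }
      if (length(pool) == 0L) {
        stop("memory is unusable: no '", lab, "' subjects besides ", sid)
      }
      s <- soft_intersection_from_table(tab, q_rows, pool, bandwidth,
                                        geometry)
      nb <- sum(counts[pool])
      min(max(s / (length(q_rows) + nb - s), 0), 1)
    })
    finish_prediction(sid, subj_labels[[sid]], res[1], res[2], threshold,
                      orientation)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("sift_predictions", class(out))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "geometry") <- geometry
  attr(out, "orientation") <- orientation
  attr(out, "match_table") <- tab
  out
}

#' Per-feature group affinity (log likelihood ratio)
#'
#' Estimates `log p(f | Male) - log p(f | Female)` for each query feature
#' by kernel density on descriptors over the label pools:
#' `p(f | label) = (1/|label|) * sum_i exp(-d(f, b_i)^2 / bandwidth^2)`
#' (times the geometry kernel when enabled), floored at 1e-12. The
#' `1/|label|` normalization is kept so that unequal pooled set sizes
#' shift affinities, mirroring their effect on the Jaccard overlap.
#' Positive affinity means more Male-typical. The query subject's own
#' features are always excluded from the pools.
#'
#' @param f feature tibble (one or more query keypoints).
#' @param memory a [group_memory()].
#' @param bandwidth kernel bandwidth.
#' @param geometry logical; multiply by the geometry kernel.
#' @param loc_sigma_mm,logscale_sigma see [geometry_weight()].
#' @return numeric vector of affinities, one per row of `f`.
#' @export
feature_affinity <- function(f, memory, bandwidth = 1, geometry = FALSE,
                             loc_sigma_mm = 10, logscale_sigma = log(1.5)) {
  stopifnot(inherits(memory, "group_memory"))
  if (!all(c("F", "M") %in% memory$labels)) {
    stop("memory must contain both labels")
  }
  feats <- memory$features
  eps <- 1e-12
  qd <- descriptor_matrix(f)
  out <- numeric(nrow(f))
  for (sid in unique(f$subject_id)) {
    rows_q <- which(f$subject_id == sid)
    q <- qd[rows_q, , drop = FALSE]
    for (lab in c("M", "F")) {
      pool <- feats[feats$label == lab & feats$subject_id != sid, ,
                    drop = FALSE]
      if (nrow(pool) == 0L) stop("empty '", lab, "' pool")
      pd <- descriptor_matrix(pool)
      d2 <- pmax(outer(rowSums(q^2), rowSums(pd^2), "+") -
                   2 * tcrossprod(q, pd), 0)
      w <- exp(-d2 / bandwidth^2)
      if (geometry) {
        wg <- vapply(seq_len(nrow(pool)), function(pi) {
          geometry_weight(f[rows_q, , drop = FALSE],
                          pool[rep(pi, length(rows_q)), , drop = FALSE],
                          loc_sigma_mm, logscale_sigma)
        }, numeric(length(rows_q)))
        w <- w * matrix(wg, nrow = length(rows_q))
      }
      phat <- pmax(rowMeans(w), eps)
      out[rows_q] <- out[rows_q] + if (lab == "M") log(phat) else -log(phat)
    }
  }
  out
}
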