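#' Sorted score continuum and linearity of fit
#'
#' Sorts the scores ascending and regresses them on rank 1..n by ordinary
#' least squares; `r_squared` is the squared Pearson correlation. A value
#' near 1 indicates a near-linear continuum of prediction scores rather
#' than two discrete clusters; a balanced binary step vector gives
#' r_squared near 3/4 (exactly 3/4 * n^2 / (n^2 - 1)).
#'
#' @param scores numeric vector (>= 3 finite values).
#' @return A list: `sorted` (ascending scores), `r_squared`, `slope`,
#'   `intercept`, `degenerate` (TRUE for constant scores, where
#'   `r_squared` is reported as 0).
#' @export
score_continuum <- function(scores) {
  s <- scores[is.finite(scores)]
  if (length(s) < 3L) stop("need at least 3 finite scores")
  s <- sort(s)
  n <- length(s)
  if (stats::sd(s) == 0) {
    return(list(sorted = s, r_squared = 0, slope = 0, intercept = s[1],
                degenerate = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, seq_len(n)), s)
  list(sorted = s, r_squared = stats::cor(s, seq_len(n))^2,
       slope = fit$coefficients[2], intercept = fit$coefficients[1],
       degenerate = FALSE)
}

#' Reference continuum linearity of a balanced binary step
#'
#' The r-squared obtained when `n` subjects split into two equal groups
#' at two distinct score values are regressed on rank — the discontinuous
#' step reference against which a near-linear continuum is judged.
#'
#' @param n total (even) number of subjects.
#' @return scalar r-squared (approaches 3/4 as n grows).
#' @export
step_reference_r2 <- function(n) {
  stopifnot(n >= 4L, n %% 2L == 0L)
  score_continuum(rep(c(0, 1), each = n / 2))$r_squared
}

#' Conditional score-distribution overlap and crossing threshold
#'
#' Estimates kernel densities of `p(score | label)` on a common grid
#' (Gaussian kernel, Silverman's bandwidth, 512 points), locates the
#' crossing threshold — the grid point between the two label means where
#' the densities intersect — and the overlap range: scores between the
#' lowest score of the higher-mean label and the highest score of the
#' lower-mean label. The overlap fraction is the fraction of subjects
#' inside that closed interval.
#'
#' @param scores numeric scores (finite).
#' @param labels parallel labels (`"M"`/`"F"`).
#' @return A list: `overlap_fraction`, `crossing_threshold`,
#'   `overlap_range` (length 2), `separable` (TRUE when the label
#'   supports do not overlap, in which case the crossing threshold is the
#'   midpoint between the two extreme scores and the overlap is 0).
#' @export
distribution_overlap <- function(scores, labels) {
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  stopifnot(all(c("M", "F") %in% labels))
  mu <- tapply(scores, labels, mean)
  hi <- names(which.max(mu))  # higher-mean label
  lo <- setdiff(c("M", "F"), hi)
  s_hi <- scores[labels == hi]
  s_lo <- scores[labels == lo]
  lower <- min(s_hi)
  upper <- max(s_lo)
  if (lower > upper) {
    return(list(overlap_fraction = 0,
                crossing_threshold = (upper + lower) / 2,
                overlap_range = c(NA_real_, NA_real_), separable = TRUE))
  }
  rng <- range(scores)
  grid <- seq(rng[1], rng[2], length.out = 512L)
  d_hi <- stats::density(s_hi, bw = "nrd0", from = rng[1], to = rng[2],
                         n = 512L)$y
  d_lo <- stats::density(s_lo, bw = "nrd0", from = rng[1], to = rng[2],
                         n = 512L)$y
  between <- grid >= min(mu) & grid <= max(mu)
  if (!any(between)) between <- rep(TRUE, length(grid))
  diff_abs <- abs(d_hi - d_lo)
  diff_abs[!between] <- Inf
  crossing <- grid[which.min(diff_abs)]
  inside <- scores >= lower & scores <= upper
  list(overlap_fraction = mean(inside), crossing_threshold = crossing,
       overlap_range = c(lower, upper), separable = FALSE)
}

#' Bootstrap standard deviation of classification accuracy
#'
#' Subject-level bootstrap: resamples subjects with replacement and
#' recomputes the accuracy of the (fixed) leave-one-out predictions.
#'
#' @param predictions a [classify_cohort()] result (or tibble with
#'   `label`, `predicted`).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return A list: `accuracy`, `sd`, `ci` (2.5/97.5 percentiles).
#' @export
bootstrap_accuracy <- function(predictions, n_boot = 1000L, seed = 1L) {
  correct <- predictions$predicted == predictions$label
  n <- length(correct)
  if (n < 2L) stop("bootstrap undefined for fewer than 2 subjects")
  accs <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(correct[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  list(accuracy = mean(correct), sd = stats::sd(accs),
       ci = stats::quantile(accs, c(0.025, 0.975), names = FALSE))
}

#' Evaluation grid over registration mode and geometry weighting
#'
#' Runs leave-one-out classification for each provided cohort
#' (registration mode) with and without geometric-consistency weighting,
#' and summarizes each condition: accuracy with bootstrap sd, mean
#' features per image per label, score-continuum linearity, the
#' balanced-step reference r-squared, conditional-distribution overlap
#' and crossing threshold.
#'
#' @param cohorts named list of labelled feature tibbles, e.g.
#'   `list(rigid = , nonlinear = )`.
#' @param geometry logical vector of geometry settings to evaluate.
#' @param bandwidth kernel bandwidth or `NULL` to calibrate per cohort.
#' @param n_boot bootstrap resamples for the accuracy sd.
#' @param seed integer seed (bootstrap).
#' @param ... further arguments passed to [classify_cohort()].
#' @return A tibble (class `sift_eval_grid`) with one row per condition:
#'   `mode, geometry, n_subjects, accuracy, accuracy_sd, mean_features_F,
#'   mean_features_M, r2_continuum, r2_step_reference, overlap_fraction,
#'   crossing_threshold, bandwidth`. Attribute `predictions` holds the
#'   per-condition prediction tibbles.
#' @export
run_grid <- function(cohorts, geometry = c(TRUE, FALSE), bandwidth = NULL,
                     n_boot = 1000L, seed = 1L, ...) {
  stopifnot(is.list(cohorts), length(names(cohorts)) == length(cohorts))
  rows <- list()
  preds <- list()
  for (mode in names(cohorts)) {
    feats <- cohorts[[mode]]
    n_subj <- length(unique(feats$subject_id))
    if (min(table(dplyr::distinct(feats, .data$subject_id,
                                  .data$label)$label)) < 2L) {
      stop("bootstrap undefined: need at least 2 subjects per label in '",
           mode, "'")
    }
    tab <- NULL
    for (g in geometry) {
      pr <- classify_cohort(feats, bandwidth = bandwidth, geometry = g,
                            match_table = tab, ...)
      tab <- attr(pr, "match_table")
      bt <- bootstrap_accuracy(pr, n_boot = n_boot, seed = seed)
      cont <- score_continuum(pr$score)
      ov <- distribution_overlap(pr$score[is.finite(pr$score)],
                                 pr$label[is.finite(pr$score)])
      nf <- feats |>
        dplyr::count(.data$subject_id, .data$label) |>
        dplyr::group_by(.data$label) |>
        dplyr::summarise(mean_n = mean(.data$n))
      get_mean <- function(l) {
        v <- nf$mean_n[nf$label == l]
        if (length(v)) v else NA_real_
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = mode, geometry = g, n_subjects = n_subj,
        accuracy = bt$accuracy, accuracy_sd = bt$sd,
        mean_features_F = get_mean("F"), mean_features_M = get_mean("M"),
        r2_continuum = cont$r_squared,
        r2_step_reference = step_reference_r2(
          if (n_subj %% 2L == 0L) n_subj else n_subj + 1L),
        overlap_fraction = ov$overlap_fraction,
        crossing_threshold = ov$crossing_threshold,
        bandwidth = attr(pr, "bandwidth"))
      preds[[paste(mode, g, sep = "_")]] <- pr
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sift_eval_grid", class(out))
  attr(out, "predictions") <- preds
  out
}
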