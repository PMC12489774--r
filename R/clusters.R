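#' Greedy cross-subject feature clustering
#'
#' Identifies recurring anatomical features across subjects by greedy
#' exemplar clustering: candidate exemplars are visited in descending
#' |response|; each subject contributes at most its best keypoint within
#' `match_radius_mm` of the exemplar's location and within
#' `descriptor_radius` in descriptor space; member keypoints are consumed
#' (a keypoint joins at most one cluster). The occurrence rate is the
#' fraction of subjects contributing a member. Deterministic given the
#' visiting order.
#'
#' @param memory a [group_memory()] or labelled feature tibble.
#' @param match_radius_mm spatial radius around the exemplar (mm).
#' @param descriptor_radius maximum descriptor distance to the exemplar.
#' @param min_occurrence clusters below this occurrence are dropped.
#' @return A tibble of clusters (class `sift_clusters`), sorted by
#'   occurrence then exemplar |response| descending: `cluster_id`,
#'   `occurrence`, `n_members`, `x_mm, y_mm, z_mm` (mean member
#'   location), `sigma_mean_F`, `sigma_mean_M` (per-label mean member
#'   scale, `NA` when a label is absent), `exemplar_response`, and a
#'   list-column `members` (tibble of member keypoints per cluster).
#' @export
cluster_features <- function(memory, match_radius_mm = 8,
                             descriptor_radius = 1.0,
                             min_occurrence = 0) {
  feats <- memory_features(memory)
  stopifnot(nrow(feats) > 0)
  subjects <- unique(feats$subject_id)
  n_subj <- length(subjects)
  ord <- order(-abs(feats$response), feats$x_mm, feats$y_mm, feats$z_mm)
  dm <- descriptor_matrix(feats)
  dm2 <- rowSums(dm^2)
  loc <- t(cbind(feats$x_mm, feats$y_mm, feats$z_mm))
  rows_by_subject <- split(seq_len(nrow(feats)), feats$subject_id)[subjects]
  assigned <- rep(FALSE, nrow(feats))
  clusters <- list()
  for (ei in ord) {
    if (assigned[ei]) next
    d_loc <- sqrt(colSums((loc - loc[, ei])^2))
    d_desc <- sqrt(pmax(dm2 + dm2[ei] - 2 * dm %*% dm[ei, ], 0))
    ok <- !assigned & d_loc <= match_radius_mm & d_desc <= descriptor_radius
    ok[ei] <- TRUE
    members <- integer(0)
    for (rows_s in rows_by_subject) {
      rows <- rows_s[ok[rows_s]]
      if (length(rows) == 0L) next
      members <- c(members, rows[which.min(d_desc[rows])])
    }
    if (length(members) == 0L) next
    assigned[members] <- TRUE
    mem <- feats[members, , drop = FALSE]
    sf <- mem$sigma_mm[mem$label == "F"]
    sm <- mem$sigma_mm[mem$label == "M"]
    clusters[[length(clusters) + 1L]] <- tibble::tibble(
      cluster_id = NA_integer_,
      occurrence = length(members) / n_subj,
      n_members = length(members),
      x_mm = mean(mem$x_mm), y_mm = mean(mem$y_mm), z_mm = mean(mem$z_mm),
      sigma_mean_F = if (length(sf)) mean(sf) else NA_real_,
      sigma_mean_M = if (length(sm)) mean(sm) else NA_real_,
      exemplar_response = feats$response[ei],
      members = list(mem))
  }
  out <- dplyr::bind_rows(clusters)
  if (nrow(out) > 0) {
    out <- out[out$occurrence >= min_occurrence, , drop = FALSE]
    out <- out[order(-out$occurrence, -abs(out$exemplar_response)), ]
    out$cluster_id <- seq_len(nrow(out))
  }
  class(out) <- c("sift_clusters", class(out))
  out
}

#' Leave-one-out classifier from a pair of feature clusters
#'
#' Classifies each subject from the group affinities of its member
#' keypoints in two clusters (e.g. the bilateral informative pair). The
#' pair rule sums the two member affinities (a missing member contributes
#' 0); positive affinity predicts Male. Subjects missing both members are
#' classified by the training-set majority (ties broken towards
#' `tie_default`, recorded in the output). Affinities are leave-one-out:
#' a subject's own features are excluded from the pools.
#'
#' @param clusters a two-row subset of a [cluster_features()] result.
#' @param memory a [group_memory()].
#' @param bandwidth kernel bandwidth for [feature_affinity()].
#' @param geometry logical; see [feature_affinity()].
#' @param tie_default label predicted when a subject is missing both
#'   members and the labels are balanced.
#' @return A list: `accuracy_individual` (length 2), `accuracy_pair`,
#'   `per_subject` tibble (subject, label, affinity_1, affinity_2, sum,
#'   predicted).
#' @export
cluster_pair_classifier <- function(clusters, memory, bandwidth = 1,
                                    geometry = FALSE, tie_default = "F") {
  stopifnot(nrow(clusters) == 2L, inherits(memory, "group_memory"))
  if (any(clusters$n_members == 0)) stop("both clusters need members")
  feats <- memory$features
  subjects <- memory$subjects
  labels <- memory$labels
  aff <- matrix(NA_real_, length(subjects), 2L,
                dimnames = list(subjects, NULL))
  for (ci in 1:2) {
    mem <- clusters$members[[ci]]
    a <- feature_affinity(mem, memory, bandwidth = bandwidth,
                          geometry = geometry)
    aff[mem$subject_id, ci] <- a
  }
  aff0 <- aff
  aff0[is.na(aff0)] <- 0
  majority <- function(exclude) {
    tl <- table(labels[subjects != exclude])
    if (tl[["F"]] == tl[["M"]]) tie_default
    else names(tl)[which.max(tl)]
  }
  pred_from <- function(v) {
    vapply(seq_along(subjects), function(i) {
      if (v[i] > 0) "M"
      else if (v[i] < 0) "F"
      else majority(subjects[i])   # missing member(s) / exact tie -> prior
    }, character(1))
  }
  pred1 <- pred_from(aff0[, 1])
  pred2 <- pred_from(aff0[, 2])
  predp <- pred_from(rowSums(aff0))
  acc <- function(p) mean(p == labels)
  list(accuracy_individual = c(acc(pred1), acc(pred2)),
       accuracy_pair = acc(predp),
       per_subject = tibble::tibble(
         subject_id = subjects, label = unname(labels),
         affinity_1 = aff[, 1], affinity_2 = aff[, 2],
         affinity_sum = rowSums(aff0),
         predicted = predp))
}

#' Leave-one-out single-threshold classifier on a scalar attribute
#'
#' For each held-out subject, fits the optimal single threshold (and
#' direction) on the remaining subjects and predicts the held-out label.
#' Used to quantify how much group information a single geometric
#' attribute (e.g. a feature's z coordinate or scale) carries.
#'
#' @param data data frame with one row per subject.
#' @param value column with the scalar attribute.
#' @param label column with labels (`"M"`/`"F"`).
#' @return A list: `accuracy`, `per_subject` tibble, `flagged` (TRUE when
#'   the attribute is constant and the majority rate is returned).
#' @export
attribute_classifier <- function(data, value = "value", label = "label") {
  v <- data[[value]]
  l <- data[[label]]
  stopifnot(length(v) == length(l), all(l %in% c("M", "F")))
  if (min(table(l)) < 2L) stop("need at least 2 subjects per label")
  if (length(unique(v)) == 1L) {
    maj <- names(which.max(table(l)))
    return(list(accuracy = mean(l == maj),
                per_subject = tibble::tibble(value = v, label = l,
                                             predicted = maj),
                flagged = TRUE))
  }
  fit_threshold <- function(vt, lt) {
    o <- order(vt)
    vs <- vt[o]; ls <- lt[o]
    cuts <- (vs[-1] + vs[-length(vs)]) / 2
    best <- c(acc = -1, thr = NA, dir = 1)
    for (thr in unique(cuts)) {
      for (dir in c(1, -1)) {
        p <- ifelse(dir * vt > dir * thr, "M", "F")
        a <- mean(p == lt)
        if (a > best[["acc"]]) best <- c(acc = a, thr = thr, dir = dir)
      }
    }
    best
  }
  pred <- character(length(v))
  for (i in seq_along(v)) {
    b <- fit_threshold(v[-i], l[-i])
    pred[i] <- if (b[["dir"]] * v[i] > b[["dir"]] * b[["thr"]]) "M" else "F"
  }
  list(accuracy = mean(pred == l),
       per_subject = tibble::tibble(value = v, label = l, predicted = pred),
       flagged = FALSE)
}

#' Female/male scale ratio of a feature cluster
#'
#' Ratio of mean member scale (Female over Male) with a Welch two-sample
#' two-sided t-test on the member sigma values. The means entering the
#' ratio are lightly trimmed (`trim`, default 5% per tail): greedy
#' cluster membership occasionally admits a mismatched keypoint whose
#' scale is an outlier, and the trim keeps the ratio robust to those.
#'
#' @param cluster one row of a [cluster_features()] result, or a member
#'   tibble with `sigma_mm` and `label`.
#' @param trim trimming fraction per tail for the label means.
#' @return A list: `ratio`, `p_value`, `mean_F`, `mean_M` (trimmed),
#'   `sd_F`, `sd_M`, `n_F`, `n_M`.
#' @export
scale_ratio <- function(cluster, trim = 0.05) {
  mem <- if (is.data.frame(cluster) && "members" %in% names(cluster)) {
    stopifnot(nrow(cluster) == 1L)
    cluster$members[[1]]
  } else cluster
  sf <- mem$sigma_mm[mem$label == "F"]
  sm <- mem$sigma_mm[mem$label == "M"]
  if (length(sf) == 0L || length(sm) == 0L) {
    stop("both labels must be represented in the cluster")
  }
  p <- if (length(sf) > 1L && length(sm) > 1L) {
    tryCatch(stats::t.test(sf, sm)$p.value,
             error = function(e) NA_real_)  # e.g. zero-variance members
  } else NA_real_
  mf <- mean(sf, trim = trim)
  mm <- mean(sm, trim = trim)
  list(ratio = mf / mm, p_value = p, mean_F = mf, mean_M = mm,
       sd_F = stats::sd(sf), sd_M = stats::sd(sm),
       n_F = length(sf), n_M = length(sm))
}
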