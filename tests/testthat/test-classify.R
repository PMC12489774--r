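# Synthetic descriptor-level cohort: each subject carries one feature per
# "informative site" drawn near a label-specific prototype, plus shared
# uninformative features. Exercises the classifier without the image
# pipeline.
make_descriptor_cohort <- function(n_per_group = 10, n_sites = 2,
                                   n_noise = 4, sd_desc = 0.15, seed = 1,
                                   informative = TRUE) {
  set.seed(seed)
  protos_f <- random_unit_descriptors(n_sites, seed + 100)
  protos_m <- if (informative) random_unit_descriptors(n_sites, seed + 200)
              else protos_f
  protos_n <- random_unit_descriptors(n_noise, seed + 300)
  rows <- list()
  for (lab in c("F", "M")) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s%02d", lab, i)
      pro <- rbind(if (lab == "F") protos_f else protos_m, protos_n)
      d <- pro + matrix(rnorm(nrow(pro) * 64, 0, sd_desc), nrow(pro))
      d <- d / sqrt(rowSums(d^2))
      rows[[sid]] <- synthetic_features(
        d, sid, lab,
        x = c(seq(-20, 20, length.out = n_sites), rep(0, n_noise)))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("score is antisymmetric under label swap and zero under symmetry", {
  feats <- make_descriptor_cohort(n_per_group = 5, seed = 2)
  mem <- group_memory(feats)
  A <- feats[feats$subject_id == "F01", ]
  r1 <- score_subject(A, mem, bandwidth = 0.5)
  swapped <- feats
  swapped$label <- ifelse(feats$label == "F", "M", "F")
  r2 <- score_subject(A, group_memory(swapped), bandwidth = 0.5)
  expect_equal(r1$score, -r2$score, tolerance = 1e-12)
  expect_equal(r1$j_female, r2$j_male, tolerance = 1e-12)

  # orientation flag negates the reported score
  r3 <- score_subject(A, mem, bandwidth = 0.5, orientation = "male_positive")
  expect_equal(r3$score, -r1$score, tolerance = 1e-12)

  # a memory that is symmetric between labels scores zero
  base <- random_unit_descriptors(3, 42)
  symf <- dplyr::bind_rows(
    synthetic_features(base, "sf", "F"),
    synthetic_features(base, "sm", "M"))
  q <- synthetic_features(random_unit_descriptors(3, 43), "q", "F")
  r0 <- score_subject(q, group_memory(symf), bandwidth = 1)
  expect_equal(r0$score, 0, tolerance = 1e-12)
})

test_that("a subject's own features never influence its score", {
  feats <- make_descriptor_cohort(n_per_group = 5, seed = 3)
  A <- feats[feats$subject_id == "F01", ]
  # plain leave-one-out (no pool balancing): removing the subject from
  # the memory entirely must change nothing
  with_own <- score_subject(A, group_memory(feats), bandwidth = 0.5,
                            balance_pools = FALSE)
  without <- score_subject(A, group_memory(
    feats[feats$subject_id != "F01", ]), bandwidth = 0.5,
    balance_pools = FALSE)
  expect_equal(with_own$j_female, without$j_female, tolerance = 1e-12)
  expect_equal(with_own$score, without$score, tolerance = 1e-12)
})

test_that("the cohort fast path reproduces per-subject scoring", {
  feats <- make_descriptor_cohort(n_per_group = 6, seed = 4)
  mem <- group_memory(feats)
  pr <- classify_cohort(feats, bandwidth = 0.5, geometry = FALSE)
  for (sid in c("F01", "M03", "M06")) {
    single <- score_subject(feats[feats$subject_id == sid, ], mem,
                            bandwidth = 0.5)
    row <- pr[pr$subject_id == sid, ]
    expect_equal(row$j_female, single$j_female, tolerance = 1e-10)
    expect_equal(row$j_male, single$j_male, tolerance = 1e-10)
    expect_equal(row$score, single$score, tolerance = 1e-10)
  }
  # with geometry weighting as well
  prg <- classify_cohort(feats, bandwidth = 0.5, geometry = TRUE)
  sg <- score_subject(feats[feats$subject_id == "F02", ], mem,
                      bandwidth = 0.5, geometry = TRUE)
  expect_equal(prg$score[prg$subject_id == "F02"], sg$score,
               tolerance = 1e-10)
})

test_that("an informative cohort classifies well; a shuffled one does not", {
  feats <- make_descriptor_cohort(n_per_group = 15, sd_desc = 0.25, seed = 5)
  pr <- classify_cohort(feats, geometry = FALSE)
  expect_gte(mean(pr$predicted == pr$label), 0.85)

  # permutation null: accuracies stay inside the 95% binomial band
  tab <- attr(pr, "match_table")
  sids <- unique(feats$subject_id)
  true_labels <- setNames(substr(sids, 1, 1), sids)
  accs <- vapply(1:10, function(b) {
    set.seed(b)
    shuffled <- setNames(sample(true_labels), sids)
    p <- classify_cohort(feats, bandwidth = attr(pr, "bandwidth"),
                         geometry = FALSE, labels = shuffled,
                         match_table = tab)
    mean(p$predicted == p$label)
  }, numeric(1))
  half_width <- 1.96 * sqrt(0.25 / length(sids))
  expect_gte(mean(accs), 0.5 - half_width)
  expect_lte(mean(accs), 0.5 + half_width)
})

test_that("feature affinity follows the kernel-density estimator", {
  # 2 vs 2 toy with hand-set distances (male 0.5, 1.0; female 1.0, 1.0)
  f <- synthetic_features(basis_descriptors(1), "q", "F")
  mem <- dplyr::bind_rows(
    synthetic_features(rbind(descriptor_at_distance(0.5, 1, 2),
                             descriptor_at_distance(1.0, 1, 3)), "m1", "M"),
    synthetic_features(rbind(descriptor_at_distance(1.0, 1, 4),
                             descriptor_at_distance(1.0, 1, 5)), "f1", "F"))
  a <- feature_affinity(f, group_memory(mem), bandwidth = 1)
  expected <- log((exp(-0.25) + exp(-1)) / 2) - log(exp(-1))
  expect_equal(a, expected, tolerance = 1e-9)

  # equidistant pools of equal size -> zero affinity
  mem2 <- dplyr::bind_rows(
    synthetic_features(rbind(descriptor_at_distance(0.8, 1, 2),
                             descriptor_at_distance(0.8, 1, 3)), "m1", "M"),
    synthetic_features(rbind(descriptor_at_distance(0.8, 1, 4),
                             descriptor_at_distance(0.8, 1, 5)), "f1", "F"))
  expect_equal(feature_affinity(f, group_memory(mem2), bandwidth = 1), 0,
               tolerance = 1e-12)

  # density floor: at a tiny bandwidth the empty-side density floors at
  # 1e-12 while an exact copy keeps the matching side finite
  mem3 <- dplyr::bind_rows(
    synthetic_features(basis_descriptors(1), "m1", "M"),   # exact copy
    synthetic_features(basis_descriptors(9), "f1", "F"))   # far
  a3 <- feature_affinity(f, group_memory(mem3), bandwidth = 0.05)
  expect_true(is.finite(a3))
  expect_equal(a3, log(1) - log(1e-12), tolerance = 1e-6)
})

test_that("greedy clustering recovers planted structure", {
  # single-subject memory: every cluster has occurrence 1
  one <- synthetic_features(random_unit_descriptors(5, 21), "s1", "F")
  cl <- cluster_features(one, match_radius_mm = 5, descriptor_radius = 0.5)
  expect_true(all(cl$occurrence == 1))

  # planted bilateral pair on a small image cohort
  feats <- small_features()
  spec <- phantom_spec()
  mem <- group_memory(feats)
  cl <- cluster_features(mem, match_radius_mm = 8, descriptor_radius = 1.0)
  pair_lay <- small_cohort()$registry |>
    dplyr::filter(provenance %in% c("pair_left", "pair_right")) |>
    dplyr::group_by(provenance) |>
    dplyr::summarise(x = mean(x_mm), y = mean(y_mm), z = mean(z_mm))
  for (i in seq_len(nrow(pair_lay))) {
    dists <- sqrt((cl$x_mm - pair_lay$x[i])^2 + (cl$y_mm - pair_lay$y[i])^2 +
                    (cl$z_mm - pair_lay$z[i])^2)
    best <- which.min(dists)
    expect_lt(dists[best], 4)
    expect_gte(cl$occurrence[best], 0.9)
  }
})

test_that("cluster occurrence tracks planted presence probability", {
  spec <- phantom_spec(grid_shape = 40L, voxel_size_mm = 3,
                       head_semiaxes_mm = c(48, 40, 44),
                       pair_separation_mm = c(F = 12, M = 16),
                       n_shared_pool = 6L, p_shared = 0.5,
                       shared_amp_bias = 1, n_private = 0L, noise_sd = 0.5)
  coh <- make_cohort(spec, n_per_group = 8, mode = "nonlinear", seed = 77)
  feats <- extract_cohort_features(coh$volumes)
  cl <- cluster_features(group_memory(feats), match_radius_mm = 8,
                         descriptor_radius = 1.0)
  reg <- coh$registry
  pool_ids <- unique(reg$blob_id[reg$provenance == "shared_pool"])
  n_subj <- length(unique(reg$subject_id))
  checked <- 0L
  for (bid in pool_ids) {
    rows <- reg[reg$blob_id == bid, ]
    planted_rate <- nrow(rows) / n_subj
    dists <- sqrt((cl$x_mm - mean(rows$x_mm))^2 +
                    (cl$y_mm - mean(rows$y_mm))^2 +
                    (cl$z_mm - mean(rows$z_mm))^2)
    if (min(dists) < 4) {
      got <- cl$occurrence[which.min(dists)]
      expect_lt(abs(got - planted_rate), 0.3)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)
})

test_that("the pair classifier combines member affinities sensibly", {
  # descriptor-level simulation: only the two sites carry label signal;
  # combining the pair beats each site alone on average
  acc_ind <- matrix(NA_real_, 20, 2)
  acc_pair <- numeric(20)
  for (r in 1:20) {
    feats <- make_descriptor_cohort(n_per_group = 12, n_sites = 2,
                                    n_noise = 3, sd_desc = 0.55,
                                    seed = 400 + r)
    mem <- group_memory(feats)
    cl <- cluster_features(mem, match_radius_mm = 6, descriptor_radius = 2)
    # the two informative sites are at distinct x positions
    cl2 <- cl[order(-cl$occurrence), ][1:2, ]
    res <- cluster_pair_classifier(cl2, mem, bandwidth = 0.7)
    acc_ind[r, ] <- res$accuracy_individual
    acc_pair[r] <- res$accuracy_pair
  }
  expect_gt(mean(acc_pair), mean(acc_ind) - 0.01)
  expect_gt(mean(acc_pair), 0.6)

  # degenerate: perfectly separated affinities classify perfectly
  feats <- make_descriptor_cohort(n_per_group = 8, n_sites = 2,
                                  n_noise = 0, sd_desc = 0.05, seed = 900)
  mem <- group_memory(feats)
  cl <- cluster_features(mem, match_radius_mm = 6, descriptor_radius = 2)
  res <- cluster_pair_classifier(cl[1:2, ], mem, bandwidth = 0.5)
  expect_equal(res$accuracy_pair, 1.0)
})

test_that("the attribute classifier handles separation, nulls and constants", {
  d <- tibble::tibble(value = c(1:8, 11:18),
                      label = rep(c("F", "M"), each = 8))
  expect_equal(attribute_classifier(d)$accuracy, 1.0)

  d2 <- tibble::tibble(value = rep(4, 16), label = rep(c("F", "M"), 8))
  r2 <- attribute_classifier(d2)
  expect_true(r2$flagged)
  expect_equal(r2$accuracy, 0.5)

  set.seed(10)
  accs <- vapply(1:10, function(i) {
    dn <- tibble::tibble(value = rnorm(40), label = rep(c("F", "M"), 20))
    attribute_classifier(dn)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 1.96 * sqrt(0.25 / 40))
})

test_that("scale ratio recovers constructed and null ratios", {
  mem <- tibble::tibble(sigma_mm = c(rep(4 * 0.97, 6), rep(4, 6)),
                        label = rep(c("F", "M"), each = 6))
  r <- scale_ratio(mem)
  expect_equal(r$ratio, 0.97, tolerance = 1e-12)

  set.seed(11)
  ratios <- vapply(1:20, function(i) {
    m <- tibble::tibble(sigma_mm = rnorm(40, 5, 0.2),
                        label = rep(c("F", "M"), 20))
    scale_ratio(m)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)

  expect_error(scale_ratio(tibble::tibble(sigma_mm = 1:3,
                                          label = rep("F", 3))),
               "both labels")
})

test_that("trimming the smallest-scale features behaves as specified", {
  feats <- make_descriptor_cohort(n_per_group = 3, seed = 12)
  feats$sigma_mm <- seq_len(nrow(feats))  # unique sigmas
  mem <- group_memory(feats)
  expect_identical(trim_smallest_features(mem, "M", 0)$features,
                   mem$features)
  t1 <- trim_smallest_features(mem, "M", 1)
  for (sid in unique(feats$subject_id[feats$label == "M"])) {
    before <- feats$sigma_mm[feats$subject_id == sid]
    after <- t1$features$sigma_mm[t1$features$subject_id == sid]
    expect_equal(sort(after), sort(before)[-1])
  }
  # female sets untouched
  expect_equal(sum(t1$features$label == "F"), sum(feats$label == "F"))
  expect_error(trim_smallest_features(mem, "M", 1000), "exceeds")
})

test_that("mean feature affinity tracks the subject-level score", {
  feats <- null_cohort_features()
  pr <- classify_cohort(feats, geometry = FALSE)
  bw <- attr(pr, "bandwidth")
  mem <- group_memory(feats)
  aff <- feature_affinity(feats, mem, bandwidth = bw)
  by_subj <- tapply(aff, feats$subject_id, mean)
  rho <- cor(by_subj[pr$subject_id], pr$score, method = "spearman")
  # affinity is positive-Male, the default score is positive-Female
  expect_lte(rho, -0.5)
})
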