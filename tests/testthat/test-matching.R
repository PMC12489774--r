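test_that("nearest-neighbour matching: exact copies, exclusion, oracle", {
  A <- synthetic_features(basis_descriptors(1:3), "qa")
  B <- dplyr::bind_rows(
    synthetic_features(basis_descriptors(c(2, 7)), "tb"),
    synthetic_features(basis_descriptors(9:12), "tc"))
  m <- nn_match(A, B)
  expect_equal(m$distance[2], 0)          # exact copy of e2 lives in B
  expect_equal(m$target_subject[2], "tb")

  expect_error(nn_match(A, B[B$subject_id == "tb", ], exclude_subject = "tb"),
               "unusable")

  # brute-force double-loop oracle on random sets
  set.seed(99)
  for (rep in 1:5) {
    na <- sample(5:20, 1); nb <- sample(5:50, 1)
    A <- synthetic_features(random_unit_descriptors(na, seed = rep), "qa")
    B <- synthetic_features(random_unit_descriptors(nb, seed = 100 + rep), "tb")
    m <- nn_match(A, B)
    da <- as.matrix(A[, sprintf("d%d", 1:64)])
    db <- as.matrix(B[, sprintf("d%d", 1:64)])
    for (i in seq_len(na)) {
      best_j <- 0; best_d <- Inf
      for (j in seq_len(nb)) {
        dd <- sqrt(sum((da[i, ] - db[j, ])^2))
        if (dd < best_d - 1e-15) { best_d <- dd; best_j <- j }
      }
      expect_equal(m$target_index[i], best_j)
      expect_equal(m$distance[i], best_d, tolerance = 1e-9)
    }
  }
})

test_that("equivalence weight has the prescribed closed form", {
  expect_equal(equivalence_weight(0, 1), 1)
  expect_equal(equivalence_weight(1, 1), exp(-1))
  expect_equal(equivalence_weight(0.7, 0.7), exp(-1))
  expect_lt(equivalence_weight(10, 1), 1e-43)
  expect_error(equivalence_weight(1, 0), "positive")
  expect_error(equivalence_weight(1, -2), "positive")
})

test_that("geometry weight has the prescribed closed form and off-mode", {
  a <- tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 0, sigma_mm = 3)
  b_same <- a
  expect_equal(geometry_weight(a, b_same), 1)
  b_loc <- tibble::tibble(x_mm = 10, y_mm = 0, z_mm = 0, sigma_mm = 3)
  expect_equal(geometry_weight(a, b_loc, loc_sigma_mm = 10), exp(-1 / 2))
  b_sc <- tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 0, sigma_mm = 3 * 1.5)
  expect_equal(geometry_weight(a, b_sc, logscale_sigma = log(1.5)),
               exp(-1 / 2))
  expect_equal(geometry_weight(a, b_loc, geometry = FALSE), 1)
  expect_error(geometry_weight(a, b_loc, loc_sigma_mm = -1))
})

test_that("soft intersection follows the defined sum", {
  A <- synthetic_features(basis_descriptors(1:4), "qa")
  # identical copy: all distances zero
  B <- synthetic_features(basis_descriptors(1:4), "tb")
  expect_equal(soft_intersection(A, B), 4, tolerance = 1e-12)

  # all cross distances sqrt(2) (disjoint basis vectors)
  B2 <- synthetic_features(basis_descriptors(5:8), "tb")
  expect_equal(soft_intersection(A, B2, bandwidth = 1),
               4 * exp(-2), tolerance = 1e-12)

  # hand-set distances 0.5 and 1.0 at bandwidth 1
  A3 <- synthetic_features(basis_descriptors(c(1, 3)), "qa")
  B3 <- synthetic_features(rbind(descriptor_at_distance(0.5, 1, 2),
                                 descriptor_at_distance(1.0, 3, 4)), "tb")
  expect_equal(soft_intersection(A3, B3, bandwidth = 1),
               exp(-0.25) + exp(-1), tolerance = 1e-9)
})

test_that("the soft Jaccard overlap satisfies its identities and bounds", {
  A <- synthetic_features(basis_descriptors(1:5), "qa")
  expect_equal(jaccard(A, A), 1)

  # no effective matches: far descriptors at a small bandwidth
  B <- synthetic_features(basis_descriptors(6:10), "tb")
  expect_equal(jaccard(A, B, bandwidth = 0.1), 0, tolerance = 1e-12)

  # |A| = |B| = 2 with soft intersection 1 -> 1/3
  d_half <- sqrt(log(2))  # exp(-d^2) = 1/2
  A2 <- synthetic_features(basis_descriptors(c(1, 3)), "qa")
  B2 <- synthetic_features(rbind(descriptor_at_distance(d_half, 1, 2),
                                 descriptor_at_distance(d_half, 3, 4)), "tb")
  expect_equal(jaccard(A2, B2, bandwidth = 1), 1 / 3, tolerance = 1e-9)

  expect_error(jaccard(A[0, ], B[0, ]), "empty")

  # bounds and padding property on random sets
  set.seed(5)
  A <- synthetic_features(random_unit_descriptors(15, 1), "qa")
  B <- synthetic_features(random_unit_descriptors(30, 2), "tb")
  j0 <- jaccard(A, B, bandwidth = 0.8)
  expect_gte(j0, 0); expect_lte(j0, 1)
  expect_lte(soft_intersection(A, B, bandwidth = 0.8), nrow(A))
  # appending non-matching keypoints to B strictly decreases the overlap
  pad <- synthetic_features(-random_unit_descriptors(10, 3), "tb")
  j1 <- jaccard(A, dplyr::bind_rows(B, pad), bandwidth = 0.8)
  expect_lt(j1, j0)
})

test_that("decreasing a match distance never decreases the overlap", {
  A <- synthetic_features(basis_descriptors(c(1, 3)), "qa")
  dists <- seq(1.2, 0.1, by = -0.1)
  j <- vapply(dists, function(dd) {
    B <- synthetic_features(rbind(descriptor_at_distance(dd, 1, 2),
                                  descriptor_at_distance(0.9, 3, 4)), "tb")
    jaccard(A, B, bandwidth = 1)
  }, numeric(1))
  expect_true(all(diff(j) >= -1e-12))
})

test_that("bandwidth calibration: degenerate fallback, constants, oracle", {
  mem <- dplyr::bind_rows(
    synthetic_features(basis_descriptors(1:3), "s1", "F"),
    synthetic_features(basis_descriptors(1:3), "s2", "M"))
  expect_warning(bw <- calibrate_bandwidth(mem), "degenerate")
  expect_equal(bw, 1)

  # all cross-subject NN distances equal 0.7
  mem2 <- dplyr::bind_rows(
    synthetic_features(basis_descriptors(c(1, 3)), "s1", "F"),
    synthetic_features(rbind(descriptor_at_distance(0.7, 1, 2),
                             descriptor_at_distance(0.7, 3, 4)), "s2", "M"))
  expect_equal(calibrate_bandwidth(mem2), 0.7, tolerance = 1e-9)

  expect_error(calibrate_bandwidth(
    synthetic_features(basis_descriptors(1:3), "only")), "2 subjects")

  # oracle: median of brute-force cross-subject NN distances
  set.seed(8)
  mem3 <- dplyr::bind_rows(
    synthetic_features(random_unit_descriptors(10, 11), "s1", "F"),
    synthetic_features(random_unit_descriptors(12, 12), "s2", "M"),
    synthetic_features(random_unit_descriptors(9, 13), "s3", "F"))
  dm <- as.matrix(mem3[, sprintf("d%d", 1:64)])
  nn <- vapply(seq_len(nrow(mem3)), function(i) {
    other <- which(mem3$subject_id != mem3$subject_id[i])
    min(sqrt(colSums((t(dm[other, , drop = FALSE]) - dm[i, ])^2)))
  }, numeric(1))
  expect_equal(calibrate_bandwidth(mem3), median(nn), tolerance = 1e-9)
})
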