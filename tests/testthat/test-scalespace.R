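test_that("the scale ladder follows the geometric formula", {
  vol <- gaussian_blob_volume(n = 32, sigma_mm = 4)
  pyr <- build_pyramid(vol, base_sigma_mm = 1.6, levels_per_octave = 3)
  expect_equal(pyr$octaves[[1]]$sigmas_mm[1:3],
               1.6 * 2^((0:2) / 3), tolerance = 1e-12)
  expect_equal(pyr$octaves[[1]]$sigmas_mm[2] / pyr$octaves[[1]]$sigmas_mm[1],
               2^(1 / 3), tolerance = 1e-12)
})

test_that("smoothing preserves constants and the Gaussian semigroup holds", {
  const <- vox_volume(array(7, dim = c(24, 24, 24)), 1)
  pyr <- build_pyramid(const, base_sigma_mm = 1.6)
  for (img in pyr$octaves[[1]]$images) {
    expect_equal(max(abs(img - 7)), 0, tolerance = 1e-9)
  }
  # sequential smoothing sigma_a then sigma_b equals direct smoothing to
  # sqrt(sigma_a^2 + sigma_b^2), checked away from the boundary
  set.seed(42)
  x <- array(rnorm(32^3), dim = c(32, 32, 32))
  x <- gaussian_smooth(x, 1, 1.0)   # make it smooth-ish first
  seq_s <- gaussian_smooth(gaussian_smooth(x, 1, 2.0), 1, 1.5)
  dir_s <- gaussian_smooth(x, 1, sqrt(2.0^2 + 1.5^2))
  core <- 9:24
  rel <- max(abs(seq_s[core, core, core] - dir_s[core, core, core])) /
    max(abs(dir_s[core, core, core]))
  expect_lt(rel, 1e-3)
})

test_that("responses are zero for flat input and linear in the image", {
  zero <- vox_volume(array(0, dim = c(24, 24, 24)), 1)
  r0 <- log_response(build_pyramid(zero, 1.6))
  for (oc in r0$octaves) for (s in oc$stacks) expect_equal(max(abs(s)), 0)

  v1 <- gaussian_blob_volume(n = 24, sigma_mm = 3, centre_vox = c(9, 9, 9))
  v2 <- gaussian_blob_volume(n = 24, sigma_mm = 5, centre_vox = c(15, 15, 15),
                             amplitude = -30)
  vsum <- vox_volume(v1$data + v2$data, 1)
  r1 <- log_response(build_pyramid(v1, 1.6))
  r2 <- log_response(build_pyramid(v2, 1.6))
  rs <- log_response(build_pyramid(vsum, 1.6))
  for (o in seq_along(rs$octaves)) {
    for (t in seq_along(rs$octaves[[o]]$stacks)) {
      a <- r1$octaves[[o]]$stacks[[t]] + r2$octaves[[o]]$stacks[[t]]
      b <- rs$octaves[[o]]$stacks[[t]]
      expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
    }
  }
})

test_that("a planted blob yields one candidate at the oracle scale", {
  for (sigma_b in c(3, 5)) {
    vol <- gaussian_blob_volume(n = 48, sigma_mm = sigma_b, amplitude = 50)
    resp <- log_response(build_pyramid(vol, base_sigma_mm = 1.6))
    kp <- detect_extrema(resp)
    expect_equal(nrow(kp), 1L)
    ctr <- rep(24, 3)
    expect_lt(max(abs(c(kp$x_mm, kp$y_mm, kp$z_mm) - ctr)), 1)
    s_star <- oracle_sigma_star(sigma_b)
    step <- 2^(1 / 3)
    expect_gt(kp$sigma_mm, s_star / step)
    expect_lt(kp$sigma_mm, s_star * step)
    # bright blob: scale-normalized Laplacian is negative at the centre
    expect_lt(kp$response, 0)
  }
})

test_that("uniform input produces no candidates", {
  vol <- vox_volume(array(3, dim = c(24, 24, 24)), 1)
  kp <- detect_extrema(log_response(build_pyramid(vol, 1.6)))
  expect_equal(nrow(kp), 0L)
})

test_that("discrete extrema equal a brute-force scan on a small grid", {
  set.seed(7)
  x <- gaussian_smooth(array(rnorm(16^3), dim = c(16, 16, 16)), 1, 1.2)
  vol <- vox_volume(x, 1)
  resp <- log_response(build_pyramid(vol, base_sigma_mm = 1.4, n_octaves = 1))
  got <- detect_extrema(resp, refine = FALSE)
  got <- got[order(got$level, got$vi, got$vj, got$vk), ]

  stacks <- resp$octaves[[1]]$stacks
  d <- dim(stacks[[1]])
  oracle <- list()
  for (t in 2:(length(stacks) - 1)) {
    for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
      v <- stacks[[t]][i, j, k]
      nb <- c(stacks[[t - 1]][(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)],
              stacks[[t]][(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)][-14],
              stacks[[t + 1]][(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
      if (all(v > nb) || all(v < nb)) {
        oracle[[length(oracle) + 1]] <-
          c(t, i - 1, j - 1, k - 1, if (all(v > nb)) 1L else -1L)
      }
    }
  }
  om <- do.call(rbind, oracle)
  om <- om[order(om[, 1], om[, 2], om[, 3], om[, 4]), , drop = FALSE]
  expect_equal(nrow(got), nrow(om))
  expect_equal(as.matrix(got[, c("level", "vi", "vj", "vk", "sign")]),
               om, ignore_attr = TRUE)
})

test_that("detected scale is covariant with content scaling", {
  kp_of <- function(sigma_b, n) {
    vol <- gaussian_blob_volume(n = n, sigma_mm = sigma_b, amplitude = 50)
    detect_extrema(log_response(build_pyramid(vol, 1.2)))
  }
  k1 <- kp_of(4, 48)
  step <- 2^(1 / 3)
  for (s in c(0.5, 2)) {
    k2 <- kp_of(4 * s, if (s > 1) 80 else 48)
    ratio <- k2$sigma_mm[1] / k1$sigma_mm[1]
    expect_gt(ratio, s / step)
    expect_lt(ratio, s * step)
  }
})

test_that("world-unit scale is invariant to voxel resampling", {
  k1 <- detect_extrema(log_response(build_pyramid(
    gaussian_blob_volume(n = 32, voxel_mm = 1, sigma_mm = 4,
                         centre_vox = c(16, 16, 16)), 1.6)))
  k2 <- detect_extrema(log_response(build_pyramid(
    gaussian_blob_volume(n = 64, voxel_mm = 0.5, sigma_mm = 4,
                         centre_vox = c(32, 32, 32)), 1.6)))
  expect_equal(k1$sigma_mm[1], k2$sigma_mm[1], tolerance = 0.1)
  expect_lt(max(abs(c(k1$x_mm[1] - k2$x_mm[1], k1$y_mm[1] - k2$y_mm[1],
                      k1$z_mm[1] - k2$z_mm[1]))), 1)
})

test_that("octave generation stops with a warning on small volumes", {
  vol <- gaussian_blob_volume(n = 20, sigma_mm = 3, centre_vox = c(10, 10, 10))
  expect_warning(build_pyramid(vol, 1.6, n_octaves = 3), "octave")
})
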