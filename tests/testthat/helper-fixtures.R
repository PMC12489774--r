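# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A single isotropic Gaussian blob on a constant background, centred on a
# voxel so that discrete extrema are unambiguous.
gaussian_blob_volume <- function(n = 48, voxel_mm = 1, sigma_mm = 4,
                                 amplitude = 50, centre_vox = NULL,
                                 background = 0, subject_id = "blob") {
  if (is.null(centre_vox)) centre_vox <- rep(floor(n / 2), 3)
  ax <- (0:(n - 1)) * voxel_mm
  ctr <- centre_vox * voxel_mm
  g <- lapply(1:3, function(a) {
    exp(-((ax - ctr[a])^2) / (2 * sigma_mm^2))
  })
  vol <- background + amplitude * outer(outer(g[[1]], g[[2]]), g[[3]])
  vox_volume(vol, voxel_mm, subject_id = subject_id)
}

# Closed-form magnitude of the scale-normalized LoG centre response of a
# Gaussian blob of width sigma_b: |sigma^2 Lap(G(sigma) * I)(0)| =
# 3 A sigma^2 sigma_b^3 / (sigma^2 + sigma_b^2)^(5/2).
log_centre_response <- function(sigma, sigma_b, amplitude = 1) {
  3 * amplitude * sigma^2 * sigma_b^3 / (sigma^2 + sigma_b^2)^2.5
}

# Brute-force 1-D oracle for the response-maximizing scale.
oracle_sigma_star <- function(sigma_b) {
  stats::optimize(function(s) log_centre_response(s, sigma_b),
                  interval = c(0.3, 4 * sigma_b), maximum = TRUE)$maximum
}

# Synthetic feature rows with prescribed unit-norm descriptors (for
# matching/classification algebra tests without running the detector).
synthetic_features <- function(descriptors, subject_id = "s1", label = "F",
                               x = 0, y = 0, z = 0, sigma = 3,
                               response = 1) {
  n <- nrow(descriptors)
  out <- tibble::tibble(
    subject_id = rep_len(subject_id, n), label = rep_len(label, n),
    x_mm = rep_len(x, n), y_mm = rep_len(y, n), z_mm = rep_len(z, n),
    sigma_mm = rep_len(sigma, n), response = rep_len(response, n),
    sign = rep(1L, n))
  rot <- matrix(rep(as.numeric(diag(3)), each = n), nrow = n)
  colnames(rot) <- as.vector(t(outer(1:3, 1:3,
                                     function(i, j) sprintf("r%d%d", i, j))))
  colnames(descriptors) <- sprintf("d%d", 1:64)
  dplyr::bind_cols(out, tibble::as_tibble(rot),
                   tibble::as_tibble(descriptors))
}

# Unit basis descriptor matrix rows e_{i1}, e_{i2}, ...
basis_descriptors <- function(idx) {
  m <- matrix(0, length(idx), 64)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# A unit descriptor at prescribed Euclidean (chordal) distance d from the
# basis vector e_axis, rotated into the e_axis/e_aux plane.
descriptor_at_distance <- function(d, axis, aux) {
  stopifnot(d >= 0, d <= 2)
  cth <- 1 - d^2 / 2
  v <- numeric(64)
  v[axis] <- cth
  v[aux] <- sqrt(max(1 - cth^2, 0))
  v
}

random_unit_descriptors <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * 64), n, 64)
  m / sqrt(rowSums(m^2))
}

# --- cached phantom cohorts used across test files -----------------------

small_cohort <- function() {
  cached("small_cohort", {
    spec <- phantom_spec()
    make_cohort(spec, n_per_group = 8, mode = "rigid", seed = 11)
  })
}

small_features <- function() {
  cached("small_features", extract_cohort_features(small_cohort()$volumes))
}

null_cohort_features <- function() {
  # n = 30 / group, rigid: used for null-calibration, affinity and
  # padding tests
  cached("null_cohort_features", {
    spec <- phantom_spec()
    coh <- make_cohort(spec, n_per_group = 30, mode = "rigid", seed = 601)
    extract_cohort_features(coh$volumes)
  })
}
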