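#' Gaussian smoothing of a 3D array (separable, world-unit sigma)
#'
#' Smooths with an isotropic Gaussian of standard deviation `sigma_mm`
#' (world units), implemented as one dense kernel-matrix product per axis
#' (BLAS-backed; exact discrete Gaussian with renormalized rows, which
#' gives Neumann-like boundary handling). Constants are preserved exactly.
#'
#' @param x 3D numeric array.
#' @param voxel_size_mm voxel size (scalar or per-axis).
#' @param sigma_mm Gaussian sd in mm (0 returns `x` unchanged).
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth <- function(x, voxel_size_mm, sigma_mm) {
  stopifnot(is.array(x), length(dim(x)) == 3L, sigma_mm >= 0)
  if (sigma_mm == 0) return(x)
  vs <- rep_len(voxel_size_mm, 3L)
  for (ax in 1:3) {
    K <- gauss_kernel_matrix(dim(x)[ax], vs[ax], sigma_mm)
    x <- apply_along_axis1(x, K, ax)
  }
  x
}

gauss_kernel_matrix <- function(n, h, sigma_mm) {
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * h)
  K <- exp(-d^2 / (2 * sigma_mm^2))
  K[abs(d) > 4.5 * sigma_mm + h] <- 0
  K / rowSums(K)
}

# Multiply kernel matrix K along axis `ax` of 3D array x.
apply_along_axis1 <- function(x, K, ax) {
  d <- dim(x)
  if (ax == 1L) {
    array(K %*% matrix(x, d[1], d[2] * d[3]), dim = d)
  } else if (ax == 2L) {
    y <- aperm(x, c(2, 1, 3))
    y <- array(K %*% matrix(y, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    aperm(y, c(2, 1, 3))
  } else {
    y <- aperm(x, c(3, 1, 2))
    y <- array(K %*% matrix(y, d[3], d[1] * d[2]), dim = c(d[3], d[1], d[2]))
    aperm(y, c(2, 3, 1))
  }
}

#' Build a Gaussian scale-space pyramid
#'
#' Constructs the geometric scale ladder sigma_k = base * 2^(k / levels)
#' over `n_octaves` octaves, downsampling the grid by 2 at each octave.
#' Each octave holds `levels_per_octave + 3` Gaussian images so that
#' difference-of-Gaussians extrema can be localized at
#' `levels_per_octave` scales per octave. The input is assumed to carry a
#' native blur of half a voxel; all recorded scales are world mm.
#'
#' @param volume a [vox_volume()].
#' @param base_sigma_mm scale of the first ladder rung (mm).
#' @param n_octaves number of octaves, or `NULL` to continue until the
#'   smallest grid dimension falls below 16 voxels.
#' @param levels_per_octave scales sampled per octave doubling (>= 3).
#' @return A `sift_pyramid`: list of octaves, each with `images` (list of
#'   3D arrays), `sigmas_mm`, `voxel_size_mm`, `step` (downsampling factor
#'   relative to the input grid) and `octave` index.
#' @export
build_pyramid <- function(volume, base_sigma_mm = 1.6, n_octaves = NULL,
                          levels_per_octave = 3L) {
  stopifnot(inherits(volume, "vox_volume"), base_sigma_mm > 0,
            levels_per_octave >= 3L)
  s <- as.integer(levels_per_octave)
  vs <- volume$voxel_size_mm
  native_blur <- 0.5 * min(vs)
  if (base_sigma_mm <= native_blur) {
    stop("base_sigma_mm must exceed the assumed native blur of half a voxel")
  }
  requested <- n_octaves
  if (is.null(n_octaves)) n_octaves <- 99L
  octaves <- list()
  img <- volume$data
  cur_sigma <- native_blur
  cur_vs <- vs
  step <- 1L
  for (o in seq_len(n_octaves) - 1L) {
    if (min(dim(img)) < 16L) {
      if (!is.null(requested) && o < requested) {
        warning("stopping octave generation at octave ", o,
                ": grid smaller than the minimal octave size")
      }
      break
    }
    sigmas <- base_sigma_mm * 2^(o + (0:(s + 2)) / s)
    images <- vector("list", s + 3L)
    for (k in seq_along(sigmas)) {
      inc <- sqrt(max(sigmas[k]^2 - cur_sigma^2, 0))
      img <- gaussian_smooth(img, cur_vs, inc)
      cur_sigma <- sigmas[k]
      images[[k]] <- img
    }
    octaves[[length(octaves) + 1L]] <- list(
      images = images, sigmas_mm = sigmas, voxel_size_mm = cur_vs,
      step = step, octave = o)
    # seed the next octave from the image at sigma = base * 2^(o+1)
    seed_img <- images[[s + 1L]]
    d <- dim(seed_img)
    img <- seed_img[seq(1, d[1], by = 2), seq(1, d[2], by = 2),
                    seq(1, d[3], by = 2), drop = FALSE]
    cur_sigma <- sigmas[s + 1L]
    cur_vs <- cur_vs * 2
    step <- step * 2L
  }
  structure(list(octaves = octaves, base_sigma_mm = base_sigma_mm,
                 levels_per_octave = s, affine = volume$affine,
                 voxel_size_mm = vs, subject_id = volume$subject_id),
            class = "sift_pyramid")
}

#' @export
print.sift_pyramid <- function(x, ...) {
  cat(sprintf("<sift_pyramid> %d octaves x %d levels, base sigma %.2f mm\n",
              length(x$octaves), x$levels_per_octave, x$base_sigma_mm))
  invisible(x)
}

#' Scale-normalized Laplacian-of-Gaussian responses (DoG approximation)
#'
#' Approximates the scale-normalized Laplacian sigma^2 * Laplacian(G(sigma) * I)
#' by differences of adjacent Gaussian pyramid levels divided by
#' (2^(1/levels) - 1), the standard DoG-to-normalized-LoG proportionality.
#' The sign is preserved: bright blobs give negative responses, dark blobs
#' positive. Each response stack is attributed the geometric-mean scale of
#' the two levels it differences.
#'
#' @param pyramid a [build_pyramid()] result.
#' @return A `sift_responses`: per octave, `stacks` (list of 3D arrays),
#'   `sigmas_mm` (attributed scales), plus grid metadata.
#' @export
log_response <- function(pyramid) {
  stopifnot(inherits(pyramid, "sift_pyramid"))
  s <- pyramid$levels_per_octave
  norm <- 2^(1 / s) - 1
  octaves <- purrr::map(pyramid$octaves, function(oc) {
    n <- length(oc$images)
    stacks <- purrr::map(seq_len(n - 1L), function(k) {
      (oc$images[[k + 1L]] - oc$images[[k]]) / norm
    })
    sig <- sqrt(oc$sigmas_mm[-n] * oc$sigmas_mm[-1])
    list(stacks = stacks, sigmas_mm = sig, gaussians = oc$images,
         gauss_sigmas_mm = oc$sigmas_mm,
         voxel_size_mm = oc$voxel_size_mm, step = oc$step, octave = oc$octave)
  })
  structure(list(octaves = octaves, levels_per_octave = s,
                 affine = pyramid$affine, voxel_size_mm = pyramid$voxel_size_mm,
                 subject_id = pyramid$subject_id),
            class = "sift_responses")
}

# Strict local extrema of the middle stack against its 3x3x3(x3)
# neighbourhood (80 neighbours). Candidate voxels below `pre_thr` in
# magnitude are skipped (pass 0 to scan every interior voxel, as the
# brute-force comparison path does). Returns a data.frame of 1-based
# voxel indices and a sign column (+1 max, -1 min).
discrete_extrema <- function(stacks, t, pre_thr = 0, mask = NULL) {
  cur <- stacks[[t]]
  d <- dim(cur)
  if (any(d < 3L)) return(NULL)
  keep <- abs(cur) >= pre_thr
  if (!is.null(mask)) keep <- keep & mask
  keep[c(1L, d[1]), , ] <- FALSE
  keep[, c(1L, d[2]), ] <- FALSE
  keep[, , c(1L, d[3])] <- FALSE
  idx <- which(keep)
  if (length(idx) == 0L) return(NULL)
  v <- cur[idx]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lin <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  # compare against same-level neighbours first and progressively drop
  # settled voxels: most candidates are eliminated within a comparison
  # or two, keeping the gather cost near-linear in the few survivors
  plan <- c(purrr::map(lin[lin != 0], function(o) list(2L, o)),
            purrr::map(lin, function(o) list(1L, o)),
            purrr::map(lin, function(o) list(3L, o)))
  is_max <- rep(TRUE, length(idx))
  is_min <- rep(TRUE, length(idx))
  for (p in plan) {
    A <- stacks[[t + p[[1]] - 2L]]
    nb <- A[idx + p[[2]]]
    is_max <- is_max & (v > nb)
    is_min <- is_min & (v < nb)
    alive <- is_max | is_min
    if (!all(alive)) {
      if (!any(alive)) return(NULL)
      idx <- idx[alive]; v <- v[alive]
      is_max <- is_max[alive]; is_min <- is_min[alive]
    }
  }
  n_hit <- sum(is_max) + sum(is_min)
  if (n_hit == 0L) return(NULL)
  arr_ind <- function(ii) {
    ii0 <- ii - 1L
    cbind(ii0 %% d[1], (ii0 %/% d[1]) %% d[2], ii0 %/% (d[1] * d[2])) + 1L
  }
  out <- rbind(arr_ind(idx[is_max]), arr_ind(idx[is_min]))
  data.frame(i = out[, 1], j = out[, 2], k = out[, 3],
             sign = rep(c(1L, -1L), c(sum(is_max), sum(is_min))))
}

# Quadratic sub-voxel / sub-scale refinement of one candidate.
# stacks: list of 3D arrays; t: stack index; v: 1-based voxel triple.
refine_candidate <- function(stacks, t, v, max_moves = 5L) {
  d <- dim(stacks[[t]])
  for (move in seq_len(max_moves)) {
    if (t < 2L || t > length(stacks) - 1L) return(NULL)
    if (any(v < 2L) || any(v > d - 1L)) return(NULL)
    Dm <- stacks[[t - 1L]]; Dc <- stacks[[t]]; Dp <- stacks[[t + 1L]]
    i <- v[1]; j <- v[2]; k <- v[3]
    val <- Dc[i, j, k]
    g <- c((Dc[i + 1, j, k] - Dc[i - 1, j, k]) / 2,
           (Dc[i, j + 1, k] - Dc[i, j - 1, k]) / 2,
           (Dc[i, j, k + 1] - Dc[i, j, k - 1]) / 2,
           (Dp[i, j, k] - Dm[i, j, k]) / 2)
    H <- matrix(0, 4, 4)
    H[1, 1] <- Dc[i + 1, j, k] + Dc[i - 1, j, k] - 2 * val
    H[2, 2] <- Dc[i, j + 1, k] + Dc[i, j - 1, k] - 2 * val
    H[3, 3] <- Dc[i, j, k + 1] + Dc[i, j, k - 1] - 2 * val
    H[4, 4] <- Dp[i, j, k] + Dm[i, j, k] - 2 * val
    H[1, 2] <- H[2, 1] <- (Dc[i + 1, j + 1, k] - Dc[i + 1, j - 1, k] -
                           Dc[i - 1, j + 1, k] + Dc[i - 1, j - 1, k]) / 4
    H[1, 3] <- H[3, 1] <- (Dc[i + 1, j, k + 1] - Dc[i + 1, j, k - 1] -
                           Dc[i - 1, j, k + 1] + Dc[i - 1, j, k - 1]) / 4
    H[2, 3] <- H[3, 2] <- (Dc[i, j + 1, k + 1] - Dc[i, j + 1, k - 1] -
                           Dc[i, j - 1, k + 1] + Dc[i, j - 1, k - 1]) / 4
    H[1, 4] <- H[4, 1] <- (Dp[i + 1, j, k] - Dp[i - 1, j, k] -
                           Dm[i + 1, j, k] + Dm[i - 1, j, k]) / 4
    H[2, 4] <- H[4, 2] <- (Dp[i, j + 1, k] - Dp[i, j - 1, k] -
                           Dm[i, j + 1, k] + Dm[i, j - 1, k]) / 4
    H[3, 4] <- H[4, 3] <- (Dp[i, j, k + 1] - Dp[i, j, k - 1] -
                           Dm[i, j, k + 1] + Dm[i, j, k - 1]) / 4
    off <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(NULL)
    if (all(abs(off[1:3]) <= 0.5)) {
      if (abs(off[4]) > 1) return(NULL)
      spatial_H <- H[1:3, 1:3]
      return(list(v = v, t = t, offset = off,
                  response = val + 0.5 * sum(g * off),
                  spatial_hessian = spatial_H))
    }
    shift <- as.integer(round(pmax(pmin(off[1:3], 1), -1)))
    v <- v + shift
  }
  NULL
}

# 3D blob/edge test on the spatial Hessian: discard saddle-like points
# (mixed eigenvalue signs) and elongated ridge/plate responses
# (largest-to-smallest absolute eigenvalue ratio above edge_ratio_max).
edge_test_ok <- function(H, edge_ratio_max) {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  a <- sort(abs(ev), decreasing = TRUE)
  if (a[3] <= 0) return(FALSE)
  if (a[1] / a[3] > edge_ratio_max) return(FALSE)
  all(ev > 0) || all(ev < 0)
}

#' Detect scale-space extrema
#'
#' Finds candidate keypoints as strict local extrema (maxima and minima)
#' of the scale-normalized LoG responses over the 3x3x3 spatial
#' neighbourhood and adjacent scales (80 neighbours), refines them to
#' sub-voxel/sub-scale precision by a quadratic fit, and filters by
#' contrast and a 3D Hessian eigenvalue-ratio edge test. Candidates within
#' one voxel of any grid border are discarded.
#'
#' @param responses a [log_response()] result.
#' @param contrast_min minimum |response| as a fraction of the maximum
#'   response magnitude over all levels (the DoG smoothing already
#'   suppresses isolated hot voxels, so the maximum is a stable
#'   reference). The default rejects the weak ring lobe that surrounds
#'   every blob response.
#' @param edge_ratio_max maximum ratio between the largest and smallest
#'   absolute eigenvalues of the spatial Hessian; mixed-sign (saddle)
#'   Hessians are always discarded.
#' @param refine logical; if `FALSE`, discrete extrema are returned
#'   without sub-voxel refinement or contrast/edge filtering (used by the
#'   brute-force oracle tests).
#' @param mask optional logical 3D array on the input grid (e.g. an
#'   eroded brain mask); candidates whose voxel centre falls outside it
#'   are discarded. Boundary-of-support responses (skull edge, phantom
#'   envelope rim) are removed this way.
#' @return A tibble of candidates, sorted by |response| descending (ties
#'   by lexicographic voxel order): columns `x_mm, y_mm, z_mm, sigma_mm,
#'   response, sign, octave, level, vi, vj, vk` (0-based voxel indices in
#'   the octave grid).
#' @export
detect_extrema <- function(responses, contrast_min = 0.08,
                           edge_ratio_max = 10, refine = TRUE, mask = NULL) {
  stopifnot(inherits(responses, "sift_responses"))
  robust <- max(abs(unlist(purrr::map(responses$octaves,
                                      function(oc) purrr::map(oc$stacks,
                                                              as.numeric)))))
  # numerical floor: an exactly flat input yields response arrays that are
  # zero up to rounding; never treat that rounding noise as structure
  gmax <- max(abs(responses$octaves[[1]]$gaussians[[1]]))
  thr <- max(contrast_min * robust, 1e-9 * gmax)
  rows <- list()
  emit <- function(octave, level, v, off, response, sign, sigma) {
    rows[[length(rows) + 1L]] <<- c(octave, level, v - 1L, off, response,
                                    sign, sigma)
  }
  for (oc in responses$octaves) {
    stacks <- oc$stacks
    nt <- length(stacks)
    mask_oc <- NULL
    if (!is.null(mask)) {
      d0 <- dim(mask)
      mask_oc <- mask[seq(1, d0[1], by = oc$step),
                      seq(1, d0[2], by = oc$step),
                      seq(1, d0[3], by = oc$step), drop = FALSE]
    }
    for (t in 2:(nt - 1L)) {
      hits <- discrete_extrema(stacks, t,
                               pre_thr = if (refine) 0.5 * thr else 0,
                               mask = mask_oc)
      if (is.null(hits)) next
      for (r in seq_len(nrow(hits))) {
        v <- c(hits$i[r], hits$j[r], hits$k[r])
        if (!refine) {
          emit(oc$octave, t, v, c(0, 0, 0, 0),
               stacks[[t]][v[1], v[2], v[3]], hits$sign[r], oc$sigmas_mm[t])
          next
        }
        ref <- refine_candidate(stacks, t, v)
        if (is.null(ref)) next
        if (abs(ref$response) < thr) next
        if (!edge_test_ok(ref$spatial_hessian, edge_ratio_max)) next
        emit(oc$octave, ref$t, ref$v, ref$offset, ref$response, hits$sign[r],
             oc$sigmas_mm[ref$t] *
               2^(ref$offset[4] / responses$levels_per_octave))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
      sigma_mm = numeric(), response = numeric(), sign = integer(),
      octave = integer(), level = integer(),
      vi = integer(), vj = integer(), vk = integer()))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(
    octave = as.integer(m[, 1]), level = as.integer(m[, 2]),
    vi = as.integer(m[, 3]), vj = as.integer(m[, 4]), vk = as.integer(m[, 5]),
    di = m[, 6], dj = m[, 7], dk = m[, 8], ds = m[, 9],
    response = m[, 10], sign = as.integer(m[, 11]), sigma_mm = m[, 12])
  steps <- purrr::map_int(responses$octaves, function(oc) as.integer(oc$step))
  names(steps) <- as.character(purrr::map_int(responses$octaves,
                                              function(oc) as.integer(oc$octave)))
  step <- steps[as.character(out$octave)]
  vox0 <- cbind((out$vi + out$di) * step, (out$vj + out$dj) * step,
                (out$vk + out$dk) * step)
  world <- cbind(vox0, 1) %*% t(responses$affine)
  out$x_mm <- world[, 1]; out$y_mm <- world[, 2]; out$z_mm <- world[, 3]
  out <- out[order(-abs(out$response), out$vi, out$vj, out$vk), ]
  dplyr::select(out, "x_mm", "y_mm", "z_mm", "sigma_mm", "response", "sign",
                "octave", "level", "vi", "vj", "vk")
}
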