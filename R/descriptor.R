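#' Trilinear interpolation on a 3D grid
#'
#' @param image 3D numeric array.
#' @param coords n x 3 matrix of 0-based fractional voxel coordinates.
#' @return numeric vector of interpolated values; `NA` where a coordinate
#'   falls outside the grid.
#' @keywords internal
interp_trilinear <- function(image, coords) {
  d <- dim(image)
  out <- rep(NA_real_, nrow(coords))
  ok <- coords[, 1] >= 0 & coords[, 1] <= d[1] - 1 &
        coords[, 2] >= 0 & coords[, 2] <= d[2] - 1 &
        coords[, 3] >= 0 & coords[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- coords[ok, , drop = FALSE]
  i0 <- floor(p)
  for (k in 1:3) i0[, k] <- pmin(i0[, k], d[k] - 2)
  f <- p - i0
  lin <- function(dx, dy, dz) {
    1 + (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz))
  }
  v <- image[lin(0, 0, 0)] * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
       image[lin(1, 0, 0)] * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
       image[lin(0, 1, 0)] * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
       image[lin(1, 1, 0)] * f[, 1] * f[, 2] * (1 - f[, 3]) +
       image[lin(0, 0, 1)] * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
       image[lin(1, 0, 1)] * f[, 1] * (1 - f[, 2]) * f[, 3] +
       image[lin(0, 1, 1)] * (1 - f[, 1]) * f[, 2] * f[, 3] +
       image[lin(1, 1, 1)] * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- v
  out
}

#' Extract a scale-normalized cubic patch around a keypoint
#'
#' Resamples a cubic window of half-width `support_factor * sigma` (world
#' mm) centred on the keypoint to a fixed `grid_n`^3 grid by trilinear
#' interpolation, optionally rotated by an orientation frame. Sampling
#' from a window proportional to the detected scale is what makes the
#' descriptor scale-invariant: the same structure rendered twice as large
#' yields the same patch.
#'
#' @param volume a [vox_volume()].
#' @param candidate one-row data frame (or list) with `x_mm, y_mm, z_mm,
#'   sigma_mm` (e.g. a [detect_extrema()] row).
#' @param support_factor window half-width in units of sigma.
#' @param grid_n patch grid size per axis.
#' @param rotation 3x3 rotation applied to the sampling offsets (columns =
#'   patch axes in world space); `NULL` for the upright identity frame.
#' @param image optional 3D array to sample instead of `volume$data`
#'   (e.g. the Gaussian pyramid level the keypoint was detected in), with
#'   `step` giving its downsampling factor relative to the volume grid.
#' @param step downsampling factor of `image` (1 for the native grid).
#' @return `grid_n`^3 numeric array, or `NULL` when the sampling window
#'   leaves the grid (the keypoint is rejected).
#' @export
extract_patch <- function(volume, candidate, support_factor = 2,
                          grid_n = 16L, rotation = NULL,
                          image = NULL, step = 1) {
  stopifnot(inherits(volume, "vox_volume"), support_factor > 0, grid_n >= 4L)
  if (is.null(image)) image <- volume$data
  ctr <- c(candidate$x_mm, candidate$y_mm, candidate$z_mm)
  hw <- support_factor * candidate$sigma_mm
  u <- seq(-hw, hw, length.out = grid_n)
  offs <- as.matrix(expand.grid(x = u, y = u, z = u))
  if (!is.null(rotation)) {
    stopifnot(all(dim(rotation) == c(3L, 3L)))
    offs <- offs %*% t(rotation)
  }
  world <- sweep(offs, 2L, ctr, "+")
  vox <- world_to_voxel(volume, world) / step
  vals <- interp_trilinear(image, vox)
  if (anyNA(vals)) return(NULL)
  array(vals, dim = rep(grid_n, 3L))
}

# Central-difference gradients of a cubic patch; returns a list with
# n x 3 gradient matrix `g`, magnitudes `m`, and the interior 0-based
# voxel positions `pos` (one row per interior voxel).
patch_gradients <- function(patch) {
  n <- dim(patch)[1]
  ii <- 2:(n - 1)
  gx <- (patch[ii + 1, ii, ii] - patch[ii - 1, ii, ii]) / 2
  gy <- (patch[ii, ii + 1, ii] - patch[ii, ii - 1, ii]) / 2
  gz <- (patch[ii, ii, ii + 1] - patch[ii, ii, ii - 1]) / 2
  pos <- as.matrix(expand.grid(x = ii - 1, y = ii - 1, z = ii - 1))
  g <- cbind(as.numeric(gx), as.numeric(gy), as.numeric(gz))
  list(g = g, m = sqrt(rowSums(g^2)), pos = pos, n = n)
}

# The 26 neighbour directions (faces, edges, corners), unit-normalized.
# Closed under the 24 proper grid rotations, so assigned frames are
# exactly equivariant under 90-degree patch rotations.
grid_directions <- function() {
  d <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

#' Assign a local orientation frame from patch gradients
#'
#' Builds a gradient-direction histogram over the 26 grid directions on
#' the sphere (Gaussian-windowed magnitude voting, hard assignment to the
#' nearest direction). The primary axis is the dominant direction; the
#' secondary axis is the dominant direction among those exactly
#' orthogonal to the primary; the third completes a right-handed frame.
#' Ties are broken by lexicographic comparison of the candidate axes. In
#' `"upright"` mode (the default used on registered images) the identity
#' is returned for any patch.
#'
#' @param patch cubic patch array (see [extract_patch()]).
#' @param mode `"upright"` (identity) or `"local"` (data-driven frame).
#' @return 3x3 rotation matrix (det +1) with attribute `degenerate = TRUE`
#'   when gradient energy is near zero (or no valid secondary direction
#'   exists) and the identity is returned as a fallback.
#' @export
assign_orientation <- function(patch, mode = c("upright", "local")) {
  mode <- match.arg(mode)
  ident <- diag(3)
  if (mode == "upright") return(ident)
  pg <- patch_gradients(patch)
  energy <- sum(pg$m^2)
  patch_energy <- sum(patch^2)
  if (energy < 1e-8 * max(patch_energy, .Machine$double.eps)) {
    attr(ident, "degenerate") <- TRUE
    warning("near-zero gradient energy: returning identity orientation")
    return(ident)
  }
  ctr <- (pg$n - 1) / 2
  gw <- exp(-rowSums(sweep(pg$pos, 2L, rep(ctr, 3L), "-")^2) /
              (2 * (pg$n / 4)^2))
  dirs <- grid_directions()
  unit_g <- pg$g / pmax(pg$m, .Machine$double.eps)
  # hard-assign each gradient to its nearest direction bin
  dots <- unit_g %*% t(dirs)
  bin <- max.col(dots, ties.method = "first")
  w <- numeric(nrow(dirs))
  rs <- rowsum(pg$m * gw, bin)
  w[as.integer(rownames(rs))] <- rs[, 1]
  pick_dominant <- function(weights, allowed) {
    idx <- which(allowed)
    if (length(idx) == 0L) return(NA_integer_)
    best <- max(weights[idx])
    cand <- idx[weights[idx] == best]
    if (length(cand) > 1L) {
      # lexicographic tie-break on the direction vectors
      ord <- do.call(order, as.data.frame(dirs[cand, , drop = FALSE]))
      cand <- cand[ord]
    }
    cand[1]
  }
  # an exactly tied dominant direction (spherically symmetric content) has
  # no rotation-equivariant tie-break, so the frame is flagged degenerate
  # and the identity returned; any real asymmetry — even noise, which
  # rotates with the content — defines an equivariant frame and is kept
  ambiguous <- function(weights, allowed, pick) {
    rivals <- allowed & (abs(weights - weights[pick]) <=
                           1e-9 * max(weights))
    sum(rivals) > 1L
  }
  all_bins <- rep(TRUE, nrow(dirs))
  p1 <- pick_dominant(w, all_bins)
  if (ambiguous(w, all_bins, p1)) {
    attr(ident, "degenerate") <- TRUE
    return(ident)
  }
  e1 <- dirs[p1, ]
  orth <- as.logical(abs(dirs %*% e1) < 1e-9)
  # secondary axis: dominant direction among the bins orthogonal to the
  # primary, voted by the gradients projected onto that orthogonal plane
  # (a smooth patch concentrates raw gradients near the primary axis, so
  # the raw histogram is empty off-axis)
  proj <- pg$g - (pg$g %*% e1) %*% t(e1)
  pm <- sqrt(rowSums(proj^2))
  unit_p <- proj / pmax(pm, .Machine$double.eps)
  dots2 <- unit_p %*% t(dirs)
  dots2[, !orth] <- -Inf
  bin2 <- max.col(dots2, ties.method = "first")
  w2 <- numeric(nrow(dirs))
  rs2 <- rowsum(pm * gw, bin2)
  w2[as.integer(rownames(rs2))] <- rs2[, 1]
  w2[!orth] <- 0
  p2 <- pick_dominant(w2, orth)
  if (is.na(p2) || ambiguous(w2, orth, p2)) {
    attr(ident, "degenerate") <- TRUE
    return(ident)
  }
  e2 <- dirs[p2, ]
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3, deparse.level = 0)
  R
}

# Snap values that agree within `tol * max(|x|)` (chained along the
# sorted order) to their group mean, so that symmetry-induced ties are
# exact ties for the rank transform. Without this, bins that are equal by
# construction (e.g. the octants of a rotationally symmetric blob) but
# differ by interpolation noise would receive arbitrary distinct ranks,
# destabilizing the descriptor.
snap_ties <- function(x, tol = 1e-3) {
  s <- tol * max(abs(x))
  if (s <= 0) return(x)
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(c(1, diff(xs) > s))
  x[o] <- stats::ave(xs, grp, FUN = mean)
  x
}

#' Rank-normalize a descriptor bin vector
#'
#' Replaces each element by its ascending rank (ties averaged) and scales
#' the rank vector to unit Euclidean norm. The result is invariant to any
#' strictly monotone transform of the input — the defining trait of the
#' rank descriptor, conferring robustness to intensity nonlinearities.
#'
#' @param raw_bins numeric vector of raw bin values.
#' @return unit-norm rank vector of the same length.
#' @export
rank_normalize <- function(raw_bins) {
  r <- rank(raw_bins, ties.method = "average")
  r / sqrt(sum(r^2))
}

#' Compute the 64-element rank-ordered gradient-orientation descriptor
#'
#' Gradients of the scale-normalized patch are quantized into 8
#' orientation octants (the sign pattern of the three gradient
#' components) and their magnitudes accumulated into 2x2x2 spatial
#' subregions with trilinear spatial weighting under a Gaussian window
#' (sd = half the patch half-width), giving 2x2x2x8 = 64 bins. The bins
#' are then rank-transformed and unit-normalized ([rank_normalize()]).
#'
#' @param patch cubic patch array (see [extract_patch()]).
#' @param orientation ignored here (the patch is assumed already sampled
#'   in its orientation frame); kept for interface clarity.
#' @return unit-norm numeric vector of length 64, with attribute
#'   `degenerate = TRUE` (uniform descriptor) when the patch has all-zero
#'   gradients.
#' @export
compute_descriptor <- function(patch, orientation = NULL) {
  pg <- patch_gradients(patch)
  if (all(pg$m == 0)) {
    out <- rep(1 / 8, 64L)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n <- pg$n
  ctr <- (n - 1) / 2
  gw <- exp(-rowSums(sweep(pg$pos, 2L, rep(ctr, 3L), "-")^2) /
              (2 * (n / 4)^2))
  # octant = sign pattern of (gx, gy, gz); zero counts as positive
  oct <- 1L + (pg$g[, 1] < 0) + 2L * (pg$g[, 2] < 0) + 4L * (pg$g[, 3] < 0)
  # trilinear weights over the 2x2x2 spatial subregions: cell coordinate
  # c in [-0.5, 1.5] per axis, weight max(0, 1 - |c - j|) for cell j
  cc <- (pg$pos + 0.5) / n * 2 - 0.5
  w0 <- pmax(1 - abs(cc), 0)       # weight to cell 0 per axis
  w1 <- pmax(1 - abs(cc - 1), 0)   # weight to cell 1 per axis
  bins <- numeric(64L)
  base <- pg$m * gw
  for (a in 0:1) for (b in 0:1) for (c3 in 0:1) {
    wx <- if (a == 0) w0[, 1] else w1[, 1]
    wy <- if (b == 0) w0[, 2] else w1[, 2]
    wz <- if (c3 == 0) w0[, 3] else w1[, 3]
    rs <- rowsum(base * wx * wy * wz, oct)
    cell <- a + 2L * b + 4L * c3     # 0..7
    idx <- cell * 8L + as.integer(rownames(rs))
    bins[idx] <- bins[idx] + rs[, 1]
  }
  rank_normalize(snap_ties(bins))
}
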