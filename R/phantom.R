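#' Specification of a synthetic phantom cohort
#'
#' Defines the generative model for synthetic 3D "head" volumes with
#' planted, ground-truth-known group structure. Each phantom is a smooth
#' ellipsoidal envelope plus a sum of isotropic Gaussian intensity blobs:
#'
#' * `common` blobs at canonical locations in every subject (uninformative
#'   shared anatomy);
#' * a bilateral informative `pair` whose centre-to-centre separation and
#'   scale differ by group — the synthetic analogue of a bilateral
#'   structure (e.g. thalamic features flanking an interthalamic adhesion)
#'   that sits closer together and slightly smaller in one group;
#' * `shared_pool` blobs, each present in a random subset of subjects with
#'   a label-conditional amplitude bias — weakly informative features
#'   shared by small, apparently random subject subsets;
#' * `private` blobs unique to each subject;
#' * a global isotropic size factor per subject whose mean differs by
#'   group (one group's anatomy is on average larger), applied by scaling
#'   blob geometry about the head centroid in `"rigid"` mode and forced
#'   to 1 in `"nonlinear"` mode (emulating size-removing registration).
#'
#' The canonical blob layout (locations, scales, base amplitudes, favoured
#' labels of pool blobs) is drawn once from `seed` and stored in the spec,
#' so all subjects of a cohort share the same canonical anatomy.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm positive scalar voxel edge (mm).
#' @param n_common_blobs number of blobs planted in all subjects.
#' @param pair_separation_mm named numeric `c(F = , M = )`: centre-to-centre
#'   distance of the bilateral pair per group (mm).
#' @param pair_scale_mm named numeric `c(F = , M = )`: sigma of the pair
#'   blobs per group (mm).
#' @param pair_amplitude intensity amplitude of the pair blobs.
#' @param group_size_factor list with elements `F` and `M`, each
#'   `c(mean = , sd = )`: global isotropic size scaling per group.
#' @param n_shared_pool size of the canonical pool of weakly-informative
#'   blobs.
#' @param p_shared probability that a pool blob is present in a subject.
#' @param shared_amp_bias amplitude multiplier applied to a pool blob in
#'   subjects of its unfavoured label (1 = no bias; negative values invert
#'   contrast). Half the pool favours each label.
#' @param n_private subject-private random blobs per subject.
#' @param location_jitter_mm sd of per-subject blob-centre jitter (mm).
#' @param noise_sd sd of additive Gaussian voxel noise.
#' @param amplitude_range range of base blob amplitudes (uniform draw).
#' @param blob_sigma_range range of sigmas for common/pool/private blobs (mm).
#' @param min_site_separation_mm minimum distance between canonical blob
#'   sites (and their clearance from the bilateral pair's endpoints);
#'   keeps planted features from merging into compound structures.
#' @param head_semiaxes_mm ellipsoid semi-axes of the head envelope (mm).
#' @param head_amplitude envelope peak intensity (0 disables the envelope).
#' @param head_edge_mm width of the smooth envelope falloff (mm).
#' @param seed integer seed fixing the canonical layout.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size_mm = 2.5,
                         n_common_blobs = 6L,
                         pair_separation_mm = c(F = 16, M = 22),
                         pair_scale_mm = c(F = 3.88, M = 4.0),
                         pair_amplitude = 45,
                         group_size_factor = list(F = c(mean = 1.00, sd = 0.02),
                                                  M = c(mean = 1.06, sd = 0.02)),
                         n_shared_pool = 24L,
                         p_shared = 0.6,
                         shared_amp_bias = -0.6,
                         n_private = 4L,
                         location_jitter_mm = 1.5,
                         noise_sd = 2.0,
                         amplitude_range = c(25, 45),
                         blob_sigma_range = c(3.5, 5.5),
                         min_site_separation_mm = 12,
                         head_semiaxes_mm = c(50, 42, 46),
                         head_amplitude = 100,
                         head_edge_mm = 4,
                         seed = 20260101L) {
  # accept JSON-parsed lists (e.g. from the CLI config) as well as
  # vectors; JSON serialization drops names, so unnamed length-2 values
  # are interpreted positionally as (F, M) / (mean, sd)
  named2 <- function(x, nms) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == length(nms)) names(x) <- nms
    x
  }
  grid_shape <- unlist(grid_shape)
  pair_separation_mm <- named2(pair_separation_mm, c("F", "M"))
  pair_scale_mm <- named2(pair_scale_mm, c("F", "M"))
  group_size_factor <- lapply(group_size_factor, named2,
                              nms = c("mean", "sd"))
  amplitude_range <- unlist(amplitude_range)
  blob_sigma_range <- unlist(blob_sigma_range)
  head_semiaxes_mm <- unlist(head_semiaxes_mm)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  stopifnot(all(grid_shape >= 8L), voxel_size_mm > 0,
            all(pair_separation_mm > 0), all(pair_scale_mm > 0),
            p_shared >= 0, p_shared <= 1,
            location_jitter_mm >= 0, noise_sd >= 0,
            all(amplitude_range > 0), all(blob_sigma_range > 0),
            all(head_semiaxes_mm > 0), head_edge_mm > 0,
            min_site_separation_mm >= 0)
  for (g in c("F", "M")) {
    gs <- group_size_factor[[g]]
    if (is.null(gs) || gs[["mean"]] <= 0 || gs[["sd"]] < 0) {
      stop("group_size_factor must give positive mean and non-negative sd for both groups")
    }
  }
  spec <- list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    n_common_blobs = as.integer(n_common_blobs),
    pair_separation_mm = pair_separation_mm,
    pair_scale_mm = pair_scale_mm, pair_amplitude = pair_amplitude,
    group_size_factor = group_size_factor,
    n_shared_pool = as.integer(n_shared_pool), p_shared = p_shared,
    shared_amp_bias = shared_amp_bias, n_private = as.integer(n_private),
    location_jitter_mm = location_jitter_mm, noise_sd = noise_sd,
    amplitude_range = amplitude_range, blob_sigma_range = blob_sigma_range,
    head_semiaxes_mm = rep_len(head_semiaxes_mm, 3L),
    head_amplitude = head_amplitude, head_edge_mm = head_edge_mm,
    min_site_separation_mm = min_site_separation_mm,
    seed = as.integer(seed)
  )
  spec$head_centre_mm <- (grid_shape - 1) / 2 * voxel_size_mm
  spec$layout <- phantom_layout(spec)
  check_layout_fits(spec)
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> %dx%dx%d @ %.2f mm; pair sep F/M %.1f/%.1f mm, ",
    "scale F/M %.2f/%.2f mm; %d common, %d pool (p=%.2f), %d private\n"),
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$voxel_size_mm,
    x$pair_separation_mm[["F"]], x$pair_separation_mm[["M"]],
    x$pair_scale_mm[["F"]], x$pair_scale_mm[["M"]],
    x$n_common_blobs, x$n_shared_pool, x$p_shared, x$n_private))
  invisible(x)
}

# Evaluate code with a locally-scoped RNG seed, restoring global RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Draw a point uniformly inside the head ellipsoid shrunk by `margin_mm`
# along every semi-axis (rejection sampling).
sample_in_head <- function(spec, margin_mm, n = 1L) {
  ax <- pmax(spec$head_semiaxes_mm - margin_mm, 1)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    out[i, ] <- spec$head_centre_mm + u * ax
  }
  out
}

# Canonical (subject-independent) blob layout drawn from the spec seed.
# Sites keep a minimum mutual separation (and clearance from the
# bilateral pair's endpoints) so that planted features remain distinct
# clusters rather than merged structures.
phantom_layout <- function(spec) {
  min_sep_mm <- spec$min_site_separation_mm
  with_local_seed(spec$seed, {
    mid <- spec$head_centre_mm + c(0, 6, 4)
    max_half_sep <- max(spec$pair_separation_mm) / 2
    protected <- rbind(mid, mid + c(max_half_sep, 0, 0),
                       mid - c(max_half_sep, 0, 0))
    taken <- protected
    sample_sites <- function(n, margin_mm) {
      margin_mm <- rep_len(margin_mm, n)
      out <- matrix(NA_real_, n, 3L)
      for (i in seq_len(n)) {
        for (try in 1:500) {
          cand <- sample_in_head(spec, margin_mm[i])[1, ]
          if (nrow(taken) == 0L ||
                min(sqrt(rowSums((taken - rep(cand, each = nrow(taken)))^2))) >=
                  min_sep_mm) {
            out[i, ] <- cand
            taken <<- rbind(taken, cand)
            break
          }
        }
        if (anyNA(out[i, ])) {
          stop("could not place ", n, " canonical blobs with ", min_sep_mm,
               " mm separation; enlarge the grid or reduce blob counts")
        }
      }
      out
    }
    rows <- list()
    if (spec$n_common_blobs > 0) {
      sig <- stats::runif(spec$n_common_blobs, spec$blob_sigma_range[1],
                          spec$blob_sigma_range[2])
      amp <- stats::runif(spec$n_common_blobs, spec$amplitude_range[1],
                          spec$amplitude_range[2]) *
        sample(c(-1, 1), spec$n_common_blobs, replace = TRUE)
      loc <- sample_sites(spec$n_common_blobs,
                          margin_mm = 3 * sig + spec$head_edge_mm)
      rows$common <- tibble::tibble(
        blob_id = sprintf("common_%02d", seq_len(spec$n_common_blobs)),
        provenance = "common",
        x_mm = loc[, 1], y_mm = loc[, 2], z_mm = loc[, 3],
        sigma_mm = sig, amplitude = amp, favoured = NA_character_)
    }
    # bilateral pair: canonical midpoint above/behind head centre; actual
    # separation and sigma are filled in per subject by label
    rows$pair <- tibble::tibble(
      blob_id = c("pair_left", "pair_right"),
      provenance = c("pair_left", "pair_right"),
      x_mm = mid[1], y_mm = mid[2], z_mm = mid[3],
      sigma_mm = NA_real_, amplitude = spec$pair_amplitude,
      favoured = NA_character_)
    if (spec$n_shared_pool > 0) {
      sig <- stats::runif(spec$n_shared_pool, spec$blob_sigma_range[1],
                          spec$blob_sigma_range[2])
      amp <- stats::runif(spec$n_shared_pool, spec$amplitude_range[1],
                          spec$amplitude_range[2])
      loc <- sample_sites(spec$n_shared_pool,
                          margin_mm = 3 * sig + spec$head_edge_mm)
      fav <- rep(c("F", "M"), length.out = spec$n_shared_pool)
      rows$pool <- tibble::tibble(
        blob_id = sprintf("pool_%02d", seq_len(spec$n_shared_pool)),
        provenance = "shared_pool",
        x_mm = loc[, 1], y_mm = loc[, 2], z_mm = loc[, 3],
        sigma_mm = sig, amplitude = amp, favoured = fav)
    }
    dplyr::bind_rows(rows)
  })
}

check_layout_fits <- function(spec) {
  lay <- spec$layout
  sig <- ifelse(is.na(lay$sigma_mm), max(spec$pair_scale_mm), lay$sigma_mm)
  ctr <- cbind(lay$x_mm, lay$y_mm, lay$z_mm)
  half <- (spec$grid_shape - 1) / 2 * spec$voxel_size_mm
  for (i in seq_len(nrow(lay))) {
    if (any(abs(ctr[i, ] - spec$head_centre_mm) + 3 * sig[i] > half)) {
      stop("phantom grid too small: blob ", lay$blob_id[i],
           " does not fit with a 3-sigma margin")
    }
  }
  invisible(TRUE)
}

# TRUE if `xyz` (after scaling) lies inside the head with 3*sigma margin.
inside_head <- function(spec, xyz, sigma, size_factor = 1) {
  ax <- pmax(spec$head_semiaxes_mm * size_factor - 3 * sigma, 1)
  u <- (xyz - spec$head_centre_mm) / ax
  sum(u^2) <= 1
}

#' Generate one synthetic phantom volume
#'
#' Renders a subject volume from a [phantom_spec()]: ellipsoidal head
#' envelope + planted Gaussian blobs + additive noise, together with the
#' ground-truth blob registry for oracle testing. Deterministic given
#' `(spec, subject_id, label, mode, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier string.
#' @param label `"M"` or `"F"`.
#' @param seed integer seed for subject-level draws (presence, jitter,
#'   size factor, noise).
#' @param mode `"rigid"` (size factor applied to blob geometry and head
#'   envelope) or `"nonlinear"` (size factor forced to 1).
#' @return A list with elements `volume` (a [vox_volume()]) and
#'   `registry` (tibble of [planted blobs][make_cohort()]).
#' @export
make_phantom <- function(spec, subject_id, label, seed, mode = c("rigid", "nonlinear")) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label, c("M", "F"))
  mode <- match.arg(mode)
  with_local_seed(seed, {
    gs <- spec$group_size_factor[[label]]
    f <- if (mode == "rigid") {
      max(stats::rnorm(1, gs[["mean"]], gs[["sd"]]), 0.5)
    } else 1.0
    reg <- subject_registry(spec, subject_id, label, size_factor = f)
    vol <- render_phantom(spec, reg, size_factor = f,
                          subject_id = subject_id, label = label)
    list(volume = vol, registry = reg)
  })
}

# Build the per-subject blob registry (jitter, presence draws, label
# conditioning, size-factor scaling about the head centroid).
subject_registry <- function(spec, subject_id, label, size_factor) {
  lay <- spec$layout
  rows <- list()

  jitter <- function(xyz) xyz + stats::rnorm(3, 0, spec$location_jitter_mm)
  place <- function(xyz, sigma) {
    # retry jitter when a blob lands outside the head mask margin
    for (try in 1:25) {
      cand <- jitter(xyz)
      if (inside_head(spec, cand, sigma)) return(cand)
    }
    stop("blob could not be placed inside the head mask after 25 jitter retries")
  }

  common <- lay[lay$provenance == "common", ]
  for (i in seq_len(nrow(common))) {
    xyz <- place(c(common$x_mm[i], common$y_mm[i], common$z_mm[i]),
                 common$sigma_mm[i])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      blob_id = common$blob_id[i], provenance = "common",
      x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
      sigma_mm = common$sigma_mm[i], amplitude = common$amplitude[i])
  }

  # bilateral pair: separation and scale by label
  sep <- spec$pair_separation_mm[[label]]
  psig <- spec$pair_scale_mm[[label]]
  pair <- lay[lay$provenance %in% c("pair_left", "pair_right"), ]
  mid <- c(pair$x_mm[1], pair$y_mm[1], pair$z_mm[1])
  for (side in c(-1, 1)) {
    xyz <- place(mid + c(side * sep / 2, 0, 0), psig)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      blob_id = if (side < 0) "pair_left" else "pair_right",
      provenance = if (side < 0) "pair_left" else "pair_right",
      x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
      sigma_mm = psig, amplitude = spec$pair_amplitude)
  }

  pool <- lay[lay$provenance == "shared_pool", ]
  for (i in seq_len(nrow(pool))) {
    present <- stats::runif(1) < spec$p_shared
    if (!present) next
    mult <- if (identical(pool$favoured[i], label)) 1 else spec$shared_amp_bias
    xyz <- place(c(pool$x_mm[i], pool$y_mm[i], pool$z_mm[i]), pool$sigma_mm[i])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      blob_id = pool$blob_id[i], provenance = "shared_pool",
      x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
      sigma_mm = pool$sigma_mm[i], amplitude = pool$amplitude[i] * mult)
  }

  if (spec$n_private > 0) {
    sig <- stats::runif(spec$n_private, spec$blob_sigma_range[1],
                        spec$blob_sigma_range[2])
    amp <- stats::runif(spec$n_private, spec$amplitude_range[1],
                        spec$amplitude_range[2]) *
      sample(c(-1, 1), spec$n_private, replace = TRUE)
    for (i in seq_len(spec$n_private)) {
      xyz <- sample_in_head(spec, 3 * sig[i] + spec$head_edge_mm)[1, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        blob_id = sprintf("%s_private_%02d", subject_id, i),
        provenance = "private",
        x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
        sigma_mm = sig[i], amplitude = amp[i])
    }
  }

  reg <- dplyr::bind_rows(rows)
  # global isotropic size confound: scale geometry about the head centroid
  if (size_factor != 1) {
    for (ax in 1:3) {
      col <- c("x_mm", "y_mm", "z_mm")[ax]
      reg[[col]] <- spec$head_centre_mm[ax] +
        (reg[[col]] - spec$head_centre_mm[ax]) * size_factor
    }
    reg$sigma_mm <- reg$sigma_mm * size_factor
  }
  reg$subject_id <- subject_id
  reg$label <- label
  reg$size_factor <- size_factor
  dplyr::select(reg, "subject_id", "blob_id", "x_mm", "y_mm", "z_mm",
                "sigma_mm", "amplitude", "provenance", "label", "size_factor")
}

# Render envelope + blob sum + noise on the voxel grid.
render_phantom <- function(spec, registry, size_factor, subject_id, label) {
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  axes <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * vs)
  vol <- array(0, dim = d)

  if (spec$head_amplitude > 0) {
    ax <- spec$head_semiaxes_mm * size_factor
    e <- lapply(1:3, function(a) ((axes[[a]] - spec$head_centre_mm[a]) / ax[a])^2)
    r2 <- outer(outer(e[[1]], e[[2]], "+"), e[[3]], "+")
    k <- min(ax) / spec$head_edge_mm
    vol <- vol + spec$head_amplitude * stats::plogis((1 - sqrt(r2)) * k)
  }

  for (i in seq_len(nrow(registry))) {
    ctr <- c(registry$x_mm[i], registry$y_mm[i], registry$z_mm[i])
    sg <- registry$sigma_mm[i]
    idx <- lapply(1:3, function(a) {
      which(abs(axes[[a]] - ctr[a]) <= 4 * sg)
    })
    if (any(lengths(idx) == 0)) next
    g <- lapply(1:3, function(a) {
      exp(-((axes[[a]][idx[[a]]] - ctr[a])^2) / (2 * sg^2))
    })
    bump <- registry$amplitude[i] * outer(outer(g[[1]], g[[2]]), g[[3]])
    vol[idx[[1]], idx[[2]], idx[[3]]] <-
      vol[idx[[1]], idx[[2]], idx[[3]]] + bump
  }

  if (spec$noise_sd > 0) {
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }
  # analytic head mask (eroded: 80% of the scaled envelope radius) so that
  # envelope-rim detector responses can be discarded, as with a brain mask
  mask <- NULL
  if (spec$head_amplitude > 0) {
    ax <- spec$head_semiaxes_mm * size_factor
    e <- lapply(1:3, function(a) ((axes[[a]] - spec$head_centre_mm[a]) / ax[a])^2)
    r2 <- outer(outer(e[[1]], e[[2]], "+"), e[[3]], "+")
    mask <- r2 <= 0.8^2
  }
  vox_volume(vol, voxel_size_mm = vs, subject_id = subject_id, label = label,
             mask = mask)
}

#' Generate a balanced synthetic cohort
#'
#' Generates `n_per_group` phantoms per label with per-subject seeds
#' derived deterministically from the master seed.
#'
#' @inheritParams make_phantom
#' @param n_per_group subjects per label (>= 1).
#' @param seed master integer seed.
#' @return A list with `volumes` (list of [vox_volume()]) and `registry`
#'   (tibble: one row per planted blob across all subjects, with columns
#'   subject_id, blob_id, x_mm, y_mm, z_mm, sigma_mm, amplitude,
#'   provenance, label, size_factor).
#' @export
make_cohort <- function(spec, n_per_group, mode = c("rigid", "nonlinear"), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), n_per_group >= 1)
  mode <- match.arg(mode)
  ids <- c(sprintf("F%03d", seq_len(n_per_group)),
           sprintf("M%03d", seq_len(n_per_group)))
  labels <- rep(c("F", "M"), each = n_per_group)
  sub_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(ids)))
  out <- purrr::map(seq_along(ids), function(i) {
    make_phantom(spec, ids[i], labels[i], seed = sub_seeds[i], mode = mode)
  })
  list(volumes = purrr::map(out, "volume"),
       registry = dplyr::bind_rows(purrr::map(out, "registry")))
}

#' Write a cohort's volumes and registry to disk
#'
#' Volumes are written as NIfTI (`<subject_id>.nii.gz`) and the blob
#' registry as a TSV.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in cohort$volumes) {
    write_volume(v, file.path(dir, paste0(v$subject_id, ".nii.gz")))
    if (!is.null(v$mask)) {
      mv <- vox_volume(array(as.numeric(v$mask), dim = dim(v$mask)),
                       v$voxel_size_mm, v$affine,
                       subject_id = paste0(v$subject_id, "_mask"))
      write_volume(mv, file.path(dir, paste0(v$subject_id, "_mask.nii.gz")))
    }
  }
  utils::write.table(cohort$registry, file.path(dir, "registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
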