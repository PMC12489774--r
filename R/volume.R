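#' Construct a 3D volume object
#'
#' A `vox_volume` is the package's in-memory representation of a 3D scalar
#' image: an intensity array together with its voxel size and a 0-based
#' voxel-to-world affine (world coordinates in mm). All detector and
#' descriptor geometry is expressed in world mm so results are comparable
#' across grids of different resolution.
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param voxel_size_mm voxel edge length(s) in mm; scalar or length 3.
#' @param affine 4x4 voxel-to-world affine applied to 0-based voxel indices.
#'   Default: diagonal scaling by `voxel_size_mm` (origin at voxel 0,0,0).
#' @param subject_id character subject identifier.
#' @param label group label, one of `"M"`, `"F"`, `"unknown"`.
#' @param mask optional logical array of the same dimensions marking the
#'   region of interest (e.g. an eroded brain mask); keypoint candidates
#'   outside it are discarded during extraction.
#' @return An object of class `vox_volume`.
#' @export
vox_volume <- function(data, voxel_size_mm, affine = NULL,
                       subject_id = "subject", label = "unknown",
                       mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(data)))
  }
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("voxel-to-world affine must be invertible")
  }
  label <- match.arg(label, c("M", "F", "unknown"))
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, affine = affine,
         subject_id = as.character(subject_id), label = label, mask = mask),
    class = "vox_volume"
  )
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vox_volume> %s (label %s): %dx%dx%d voxels @ %.3g mm\n",
              x$subject_id, x$label, d[1], d[2], d[3], x$voxel_size_mm[1]))
  invisible(x)
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

#' Convert 0-based voxel indices to world mm
#'
#' @param volume a [vox_volume()].
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(volume$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world mm to 0-based (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(volume$affine))
  out[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI image into a [vox_volume()]. World coordinates follow
#' the file's xform affine applied to 0-based voxel indices.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,label optional metadata attached to the volume; by
#'   default the subject id is the file name without extension.
#' @return A [vox_volume()].
#' @export
read_volume <- function(path, subject_id = NULL, label = "unknown") {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D image: ", path)
  }
  aff <- structure(RNifti::xform(img), class = NULL)
  attributes(aff) <- list(dim = dim(aff))
  # voxel size from the affine column norms (the header pixdim does not
  # always reflect an assigned xform)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  vox_volume(array(as.numeric(img), dim = d), voxel_size_mm = vs,
             affine = aff, subject_id = subject_id, label = label)
}

#' Write a volume to NIfTI
#'
#' @param volume a [vox_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
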