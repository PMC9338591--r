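#' Binary voxel mask with world geometry
#'
#' The sole imaging input of the measurement pipeline: a 3D binary occupancy
#' grid with voxel spacing and origin in mm. Index-to-world follows
#' `world = origin + (index - 1) * spacing` (0-based index times spacing plus
#' origin; R indices are 1-based), i.e. `origin` is the world position of the
#' centre of the first voxel and each voxel's world position is its centre.
#'
#' @param occupancy 3D array; any nonzero entry is foreground.
#' @param spacing_mm numeric length 3, positive voxel edge lengths in mm.
#' @param origin_mm numeric length 3, world position (mm) of voxel (1,1,1).
#' @return An object of class `voxel_mask`: list with `occupancy` (integer
#'   0/1 array), `spacing_mm`, `origin_mm`.
#' @examples
#' m <- voxel_mask(array(1L, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0))
#' dim(m$occupancy)
#' @export
voxel_mask <- function(occupancy, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3)
    abort_camangle("occupancy must be a 3D array", "validation_error")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    abort_camangle("spacing_mm must be 3 positive lengths", "validation_error")
  if (length(origin_mm) != 3 || any(!is.finite(origin_mm)))
    abort_camangle("origin_mm must be a finite 3-vector", "validation_error")
  occ <- array(as.integer(occupancy != 0), dim(occupancy))
  structure(list(occupancy = occ, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("voxel_mask: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              sum(x$occupancy)))
  invisible(x)
}

#' Convert voxel indices to world coordinates (and back)
#'
#' @param mask a [voxel_mask()].
#' @param index integer matrix (n x 3) of 1-based voxel indices.
#' @return `mask_index_to_world`: n x 3 matrix of world mm coordinates
#'   (voxel centres); `mask_world_to_index`: n x 3 integer matrix of nearest
#'   voxel indices.
#' @export
mask_index_to_world <- function(mask, index) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, mask$spacing_mm, "*"), 2, mask$origin_mm, "+")
}

#' @rdname mask_index_to_world
#' @param world numeric matrix (n x 3) of world mm coordinates.
#' @export
mask_world_to_index <- function(mask, world) {
  world <- rbind(world)
  round(sweep(sweep(world, 2, mask$origin_mm), 2, mask$spacing_mm, "/")) + 1
}

# world coordinates of all foreground voxel centres
mask_foreground_world <- function(mask) {
  idx <- which(mask$occupancy != 0L)
  ai <- arrayInd(idx, dim(mask$occupancy))
  mask_index_to_world(mask, ai)
}

#' Read a segmentation mask from a NIfTI file
#'
#' Any nonzero voxel becomes foreground (a warning is issued when more than
#' one nonzero label is present). The affine must be axis-aligned (a permuted,
#' possibly flipped, scaled identity within tolerance 1e-3); the volume is
#' canonicalised to a right-handed +x/+y/+z frame by permuting and flipping
#' axes, so downstream code sees a single coordinate convention. Oblique
#' affines are rejected, not resampled.
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3D integer/float data.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    abort_camangle(sprintf("file not found: %s", path), "io_error")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    abort_camangle(sprintf("mask must be 3D, got %dD", length(dim(arr))), "dimension_error")
  aff <- RNifti::xform(img)
  R <- aff[1:3, 1:3]
  origin <- aff[1:3, 4]
  # each voxel axis must map to exactly one world axis
  perm <- integer(3); sgn <- numeric(3); spac <- numeric(3)
  for (ax in 1:3) {
    col <- R[, ax]
    w <- which.max(abs(col))
    if (sum(abs(col[-w])) > 1e-3 * max(abs(col[w]), 1e-6))
      abort_camangle("oblique (non axis-aligned) affine; resample the mask first",
                     "orientation_error")
    perm[ax] <- w
    sgn[ax] <- sign(col[w])
    spac[ax] <- abs(col[w])
  }
  if (any(duplicated(perm)))
    abort_camangle("degenerate affine: two voxel axes map to one world axis",
                   "orientation_error")
  # canonicalise: world axis w is served by voxel axis ord[w]
  ord <- order(perm)
  arr <- aperm(arr, ord)
  sgn <- sgn[ord]; spac <- spac[ord]
  org <- origin  # translation is already in world coordinates
  # after aperm, voxel axis i corresponds to world axis i with sign sgn[i]
  d <- dim(arr)
  for (ax in 1:3) {
    if (sgn[ax] < 0) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[ax]] <- rev(idx[[ax]])
      arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      org[ax] <- org[ax] - (d[ax] - 1) * spac[ax]
    }
  }
  labs <- unique(as.vector(arr))
  labs <- labs[labs != 0]
  if (length(labs) > 1)
    warning(sprintf("mask has %d nonzero labels; treating all as foreground",
                    length(labs)))
  if (length(labs) == 0)
    abort_camangle("empty mask: no foreground voxels", "empty_mask_error")
  voxel_mask(arr, spac, org)
}

#' Write a segmentation mask to a NIfTI file
#'
#' Lossless inverse of [read_mask()] for binary data; spacing and origin are
#' encoded in the qform/sform affine.
#'
#' @param mask a [voxel_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param overwrite overwrite an existing file? Default `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, overwrite = TRUE) {
  if (!inherits(mask, "voxel_mask"))
    abort_camangle("mask must be a voxel_mask", "validation_error")
  if (!overwrite && file.exists(path))
    abort_camangle(sprintf("file exists and overwrite = FALSE: %s", path), "io_error")
  if (!dir.exists(dirname(path)))
    abort_camangle(sprintf("directory does not exist: %s", dirname(path)), "io_error")
  aff <- diag(4)
  diag(aff)[1:3] <- mask$spacing_mm
  aff[1:3, 4] <- mask$origin_mm
  img <- RNifti::asNifti(mask$occupancy)
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
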