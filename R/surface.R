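#' Extract a triangle surface from a binary mask
#'
#' Iso-surfaces the occupancy field at level 0.5 (marching-tetrahedra style,
#' vertices in world mm coordinates). The binary grid is first smoothed with
#' a small Gaussian (`smooth_sigma_vox` voxels) so the level-0.5 surface
#' interpolates the voxel staircase instead of reproducing it; only the
#' largest connected surface component is retained and zero-area triangles
#' are dropped.
#'
#' @param mask a [voxel_mask()] with at least one foreground voxel.
#' @param smooth_sigma_vox Gaussian pre-smoothing sigma in voxels (0 = none).
#' @param min_vertices minimum vertex count for a usable surface.
#' @return An object of class `triangle_mesh`: list with `vertices`
#'   (n x 3 mm), `triangles` (m x 3, 1-based).
#' @export
extract_surface <- function(mask, smooth_sigma_vox = 1, min_vertices = 100) {
  if (!inherits(mask, "voxel_mask"))
    abort_camangle("mask must be a voxel_mask", "validation_error")
  if (sum(mask$occupancy) == 0)
    abort_camangle("empty mask: no foreground voxels", "empty_mask_error")
  field <- smooth_field3d(mask$occupancy, smooth_sigma_vox)
  iso <- .mt_isosurface(as.numeric(field), dim(mask$occupancy),
                        mask$spacing_mm, mask$origin_mm, 0.5)
  V <- iso$vertices
  F <- iso$triangles
  if (nrow(V) < min_vertices)
    abort_camangle(sprintf("degenerate surface: %d vertices (< %d)",
                           nrow(V), min_vertices), "degenerate_surface_error")
  # drop zero-area triangles
  a <- V[F[, 2], ] - V[F[, 1], ]
  b <- V[F[, 3], ] - V[F[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- sqrt(cx^2 + cy^2 + cz^2) / 2
  F <- F[area2 > 1e-9, , drop = FALSE]
  # keep the largest connected component (vertex connectivity via edges)
  g <- igraph::graph_from_edgelist(
    rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(1, 3)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(V) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < nrow(V)) {
    remap <- rep(NA_integer_, nrow(V))
    remap[keep] <- seq_along(keep)
    F <- F[F[, 1] %in% keep & F[, 2] %in% keep & F[, 3] %in% keep, , drop = FALSE]
    F <- cbind(remap[F[, 1]], remap[F[, 2]], remap[F[, 3]])
    V <- V[keep, , drop = FALSE]
  }
  if (nrow(V) < min_vertices)
    abort_camangle(sprintf("degenerate surface: %d vertices (< %d)",
                           nrow(V), min_vertices), "degenerate_surface_error")
  structure(list(vertices = V, triangles = F), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 2], ] - V[F[, 1], ]
  b <- V[F[, 3], ] - V[F[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Initial landmarks: approximate head centre, radius and neck axis
#'
#' The femoral head hosts the largest inscribed sphere of the bone, so the
#' head centre is taken as the global maximum of the Euclidean distance
#' transform of the foreground (ties broken toward the lowest (x, y, z)
#' index) and the head radius as the distance value there. The approximate
#' neck axis is the principal direction of the foreground voxels in a
#' spherical shell at `shell` times the head radius from the centre (the
#' neck and proximal shaft dominate that shell), signed to point away from
#' the head apex, i.e. toward the shell's centre of mass. These landmarks
#' are deliberately rough; the sphere fit and the minimal-circumference neck
#' search refine them.
#'
#' @param mask a [voxel_mask()].
#' @param shell inner/outer shell radii as multiples of the head radius.
#' @return An object of class `initial_landmarks`: `head_center_mm`,
#'   `head_radius_mm`, `neck_axis` (unit, head toward neck).
#' @export
initial_landmarks <- function(mask, shell = c(1.1, 2.0)) {
  if (!inherits(mask, "voxel_mask"))
    abort_camangle("mask must be a voxel_mask", "validation_error")
  occ <- mask$occupancy
  if (sum(occ) == 0)
    abort_camangle("empty mask: no foreground voxels", "empty_mask_error")
  d <- .edt3d(as.integer(occ), dim(occ), mask$spacing_mm)
  imax <- which.max(d)  # first maximum = lowest (x, y, z) index in column-major order
  ctr <- as.numeric(mask_index_to_world(mask, arrayInd(imax, dim(occ))))
  hr <- d[imax]
  fg <- mask_foreground_world(mask)
  rel <- sweep(fg, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  in_shell <- r >= shell[1] * hr & r <= shell[2] * hr
  if (sum(in_shell) < 10)
    abort_camangle("landmark failure: shell around the head is (nearly) empty",
                   "landmark_error")
  sh <- rel[in_shell, , drop = FALSE]
  # principal direction of the shell about the head centre (uncentred second
  # moment): the neck/shaft offset from the centre dominates, so this is
  # robust even when the neck is short and thick
  ev <- eigen(crossprod(sh) / nrow(sh), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (sum(ax * colMeans(sh)) < 0) ax <- -ax
  structure(list(head_center_mm = ctr, head_radius_mm = hr,
                 neck_axis = unitv(ax)),
            class = "initial_landmarks")
}

#' @export
print.initial_landmarks <- function(x, ...) {
  cat(sprintf("initial_landmarks: head centre (%.1f, %.1f, %.1f) mm, radius %.1f mm\n",
              x$head_center_mm[1], x$head_center_mm[2], x$head_center_mm[3],
              x$head_radius_mm))
  cat(sprintf("  neck axis (%.3f, %.3f, %.3f)\n",
              x$neck_axis[1], x$neck_axis[2], x$neck_axis[3]))
  invisible(x)
}

#' Partition mesh vertices into head, neck and other
#'
#' Labels each vertex by its position relative to the initial landmarks:
#' head = within `head_margin` times the head radius of the head centre;
#' neck = remaining vertices whose projection t onto the neck axis lies in
#' `neck_band` times the head radius and whose distance to the axis is at
#' most `neck_radial_margin` times the head radius; everything else = other.
#'
#' @param mesh a `triangle_mesh`.
#' @param landmarks an `initial_landmarks`.
#' @param head_margin head radius multiplier (default 1.10).
#' @param neck_band axial band as head-radius multiples (default c(0.8, 2.2)).
#' @param neck_radial_margin radial cut-off as head-radius multiple (1.2).
#' @return character vector (length = vertex count) with values
#'   `"head"`, `"neck"`, `"other"`.
#' @export
partition_head_neck <- function(mesh, landmarks, head_margin = 1.10,
                                neck_band = c(0.8, 2.2),
                                neck_radial_margin = 1.2) {
  V <- mesh$vertices
  rel <- sweep(V, 2, landmarks$head_center_mm)
  r <- sqrt(rowSums(rel^2))
  hr <- landmarks$head_radius_mm
  t_ax <- rel %*% landmarks$neck_axis
  d_ax <- sqrt(pmax(0, r^2 - t_ax^2))
  lab <- rep("other", nrow(V))
  lab[r <= head_margin * hr] <- "head"
  is_neck <- lab == "other" &
    t_ax >= neck_band[1] * hr & t_ax <= neck_band[2] * hr &
    d_ax <= neck_radial_margin * hr
  lab[is_neck] <- "neck"
  if (!any(lab == "head") || !any(lab == "neck"))
    abort_camangle("partition failure: empty head or neck vertex set",
                   "partition_error")
  lab
}
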