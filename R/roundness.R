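#' Spherical roundness map of the femoral head
#'
#' Casts rays from the fitted sphere centre over a grid of (azimuth phi,
#' polar angle theta) directions - theta measured from the neck-axis
#' direction, so the head apex is at theta = 180 - and records, per cell,
#' the distance to the first mesh intersection divided by the fitted head
#' radius. Cells whose ray misses the mesh are marked missing. A perfectly
#' spherical head gives rho = 1 on the head region; cam-type bone excess
#' shows as rho > 1 at polar angles above the neck cone.
#'
#' @param mesh a `triangle_mesh` of the femur surface.
#' @param sphere a `sphere_fit` (ray origin and radius normalisation).
#' @param slice_group a `radial_slice_group` (azimuth bins and axis frame).
#' @param theta_step_deg polar resolution (default 0.5, range (0, 175]).
#' @param theta_max_deg top of the polar range (default 175).
#' @param max_missing_fraction map failure threshold: more than this
#'   fraction of missing cells in theta [20, 120] aborts (geometry likely
#'   wrong).
#' @return An object of class `roundness_map`: `rho` (n_theta x n_phi),
#'   `missing` (logical same shape), `theta_deg`, `phi_deg`, `sphere`,
#'   `slice_group`.
#' @export
build_roundness_map <- function(mesh, sphere, slice_group,
                                theta_step_deg = 0.5, theta_max_deg = 175,
                                max_missing_fraction = 0.3) {
  theta <- seq(theta_step_deg, theta_max_deg, by = theta_step_deg)
  phi <- slice_group$azimuths_deg
  ax <- slice_group$axis
  dist <- .raycast_map(mesh$vertices, mesh$triangles,
                       sphere$center_mm,
                       slice_group$e1, slice_group$e2, ax$direction,
                       deg2rad(theta), deg2rad(phi))
  rho <- dist / sphere$radius_mm
  missing <- is.na(rho)
  band <- theta >= 20 & theta <= 120
  miss_frac <- mean(missing[band, ])
  if (miss_frac > max_missing_fraction)
    abort_camangle(sprintf(
      "map failure: %.0f%% of cells missing in theta [20, 120] (geometry likely wrong)",
      100 * miss_frac), "map_error")
  structure(list(rho = rho, missing = missing, theta_deg = theta,
                 phi_deg = phi, sphere = sphere, slice_group = slice_group),
            class = "roundness_map")
}

#' @export
print.roundness_map <- function(x, ...) {
  cat(sprintf("roundness_map: %d theta x %d phi cells, %.1f%% missing\n",
              length(x$theta_deg), length(x$phi_deg), 100 * mean(x$missing)))
  invisible(x)
}

#' Build a roundness map directly from an analytic radius function
#'
#' Constructs a `roundness_map` from a closed-form surface radius
#' `radius_fun(theta_deg, phi_deg)` (mm) instead of ray casting a mesh -
#' the noise-free substrate used to validate the optimal cut against closed
#' forms.
#'
#' @param radius_fun vectorised function of (theta_deg, phi_deg) returning
#'   surface radius in mm (NA = missing cell).
#' @param head_radius_mm normalising head radius.
#' @param phi_deg azimuth grid (degrees).
#' @param theta_step_deg,theta_max_deg polar grid as in
#'   [build_roundness_map()].
#' @return A `roundness_map` (with `sphere` and `slice_group` set to NULL).
#' @export
roundness_map_from_function <- function(radius_fun, head_radius_mm,
                                        phi_deg = seq(0, 357, by = 3),
                                        theta_step_deg = 0.5,
                                        theta_max_deg = 175) {
  theta <- seq(theta_step_deg, theta_max_deg, by = theta_step_deg)
  grid_t <- matrix(theta, length(theta), length(phi_deg))
  grid_p <- matrix(phi_deg, length(theta), length(phi_deg), byrow = TRUE)
  r <- radius_fun(as.vector(grid_t), as.vector(grid_p))
  rho <- matrix(r / head_radius_mm, length(theta), length(phi_deg))
  structure(list(rho = rho, missing = is.na(rho), theta_deg = theta,
                 phi_deg = phi_deg, sphere = list(radius_mm = head_radius_mm),
                 slice_group = NULL),
            class = "roundness_map")
}

# analytic surface radius of a phantom in spherical coordinates about the
# head centre (theta from the neck axis); mirrors the solid used by
# generate_phantom, ignoring the shaft
phantom_radius_function <- function(spec) {
  Tn <- phantom_neck_extent(spec)
  function(theta_deg, phi_deg) {
    rh <- phantom_head_radius(theta_deg, phi_deg, spec)
    st <- sin(deg2rad(theta_deg)); ct <- cos(deg2rad(theta_deg))
    rn <- ifelse(st > 1e-9, spec$neck_radius_mm / st, Inf)
    ok <- is.finite(rn) & rn * ct >= 0 & rn * ct <= Tn
    # rays down the axis exit through the flat neck end cap
    rcap <- ifelse(ct > 1e-9 & st * Tn / pmax(ct, 1e-9) <= spec$neck_radius_mm,
                   Tn / pmax(ct, 1e-9), -Inf)
    pmax(rh, ifelse(ok, rn, -Inf), rcap)
  }
}
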