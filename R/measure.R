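#' Pipeline configuration
#'
#' Collects every tunable of the measurement chain with its default. All
#' thresholds are expressed relative to the (initial or fitted) head radius
#' unless a unit says otherwise.
#'
#' @param head_margin head partition: vertices within this multiple of the
#'   initial head radius are "head" (default 1.10).
#' @param neck_band axial band (head-radius multiples) of the neck partition.
#' @param neck_radial_margin radial cut-off (head-radius multiple) of the
#'   neck partition.
#' @param smooth_sigma_vox Gaussian pre-smoothing of the occupancy grid
#'   (voxels) before iso-surfacing.
#' @param ransac_iters RANSAC hypothesis count.
#' @param ransac_thresh_mm RANSAC inlier threshold; `NULL` =
#'   `max(0.75, 0.02 * radius)`.
#' @param station_step_mm neck-slicing station spacing (mm).
#' @param axis_tol_deg convergence tolerance of the axis iteration (degrees).
#' @param axis_max_iter maximum axis iterations.
#' @param theta_step_deg polar resolution of the roundness map (degrees).
#' @param tau_mm asphericity tolerance in mm of radial excess; `NULL` =
#'   `max(0.6, half voxel diagonal)` - the floor guards against voxelisation
#'   noise triggering false exceedance at sub-mm imaging resolution.
#' @param w_head,w_neck misclassification weights of the cut data term.
#' @param lambda_smooth smoothness penalty per polar bin of cut change.
#' @param reference anterior reference direction (world 3-vector) anchoring
#'   azimuth 0.
#' @param span_deg azimuth span of the slice group (360 or 180).
#' @return named list of class `alpha_control`.
#' @export
alpha_control <- function(head_margin = 1.10, neck_band = c(0.8, 2.2),
                          neck_radial_margin = 1.2, smooth_sigma_vox = 1,
                          ransac_iters = 2000, ransac_thresh_mm = NULL,
                          station_step_mm = 1, axis_tol_deg = 0.5,
                          axis_max_iter = 10, theta_step_deg = 0.5,
                          tau_mm = NULL, w_head = 10, w_neck = 1,
                          lambda_smooth = 2, reference = c(1, 0, 0),
                          span_deg = 360) {
  ctl <- list(head_margin = head_margin, neck_band = neck_band,
              neck_radial_margin = neck_radial_margin,
              smooth_sigma_vox = smooth_sigma_vox,
              ransac_iters = ransac_iters, ransac_thresh_mm = ransac_thresh_mm,
              station_step_mm = station_step_mm, axis_tol_deg = axis_tol_deg,
              axis_max_iter = axis_max_iter, theta_step_deg = theta_step_deg,
              tau_mm = tau_mm, w_head = w_head, w_neck = w_neck,
              lambda_smooth = lambda_smooth, reference = reference,
              span_deg = span_deg)
  structure(ctl, class = "alpha_control")
}

#' Automated alpha-angle measurement from a segmentation mask
#'
#' Runs the full measurement chain on a binary proximal-femur mask:
#' surface extraction, initial landmarks (distance-transform head centre +
#' shell principal direction), head/neck partition, RANSAC sphere refinement
#' of the head, minimal-circumference refinement of the neck axis, radial
#' slice group, spherical roundness map, and the smoothness-regularised
#' optimal cut that yields one alpha angle per radial half-plane. The seven
#' named clinical planes are read off the profile at their nearest azimuths.
#'
#' @param mask a [voxel_mask()] (or a path to a NIfTI file).
#' @param n_slices number of radial half-plane slices (default 120, i.e.
#'   3-degree azimuth steps).
#' @param seed integer seed for the RANSAC sampler.
#' @param control an [alpha_control()] configuration.
#' @param hip_id identifier carried into the output tables.
#' @return An object of class `alpha_fit` with components `profile`
#'   (per-azimuth alpha), `planes` (seven named planes), `sphere`, `axis`,
#'   `landmarks`, `map`, `slice_group`, `control`, `seed`, `timings_s`,
#'   `version`. Methods: `print`, `summary`, `coef` (named-plane alphas),
#'   `plot` (roundness map with the cut overlaid).
#' @examples
#' \donttest{
#' m <- generate_phantom(femur_phantom())
#' fit <- measure_alpha(m, seed = 1)
#' coef(fit)
#' }
#' @export
measure_alpha <- function(mask, n_slices = 120, seed = 1L,
                          control = alpha_control(), hip_id = "hip") {
  if (is.character(mask)) mask <- read_mask(mask)
  if (!inherits(mask, "voxel_mask"))
    abort_camangle("mask must be a voxel_mask or a NIfTI path", "validation_error")
  if (sum(mask$occupancy) == 0)
    abort_camangle("empty mask: no foreground voxels", "empty_mask_error")
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  mesh <- extract_surface(mask, smooth_sigma_vox = control$smooth_sigma_vox)
  timings["surface"] <- tic() - t0

  t0 <- tic()
  lm <- initial_landmarks(mask)
  labels <- partition_head_neck(mesh, lm, head_margin = control$head_margin,
                                neck_band = control$neck_band,
                                neck_radial_margin = control$neck_radial_margin)
  timings["landmarks"] <- tic() - t0

  t0 <- tic()
  sphere <- ransac_sphere(mesh$vertices[labels == "head", , drop = FALSE],
                          seed = seed, iters = control$ransac_iters,
                          thresh_mm = control$ransac_thresh_mm)
  axis <- min_circumference_neck(mesh, labels, sphere, axis0 = lm$neck_axis,
                                 station_step_mm = control$station_step_mm,
                                 tol_deg = control$axis_tol_deg,
                                 max_iter = control$axis_max_iter)
  timings["geometry"] <- tic() - t0

  t0 <- tic()
  slices <- build_slice_group(sphere, axis, n_slices = n_slices,
                              reference = control$reference,
                              span_deg = control$span_deg)
  map <- build_roundness_map(mesh, sphere, slices,
                             theta_step_deg = control$theta_step_deg)
  timings["roundness"] <- tic() - t0

  t0 <- tic()
  tau_mm <- if (is.null(control$tau_mm)) {
    max(0.6, 0.5 * vnorm(mask$spacing_mm))
  } else control$tau_mm
  profile <- alpha_by_optimal_cut(map, tau = tau_mm / sphere$radius_mm,
                                  lambda_smooth = control$lambda_smooth,
                                  w_head = control$w_head,
                                  w_neck = control$w_neck)
  planes <- select_named_planes(profile, hip_id = hip_id)
  timings["cut"] <- tic() - t0

  structure(list(profile = profile, planes = planes, sphere = sphere,
                 axis = axis, landmarks = lm, map = map, slice_group = slices,
                 mesh = mesh, labels = labels, control = control,
                 tau_mm = tau_mm, seed = as.integer(seed), hip_id = hip_id,
                 timings_s = timings,
                 version = as.character(utils::packageVersion("camangle"))),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_fit (hip '%s'): %d radial slices\n", x$hip_id,
              nrow(x$profile)))
  cat(sprintf("  head: radius %.1f mm (%.0f%% RANSAC inliers); neck circumference %.1f mm\n",
              x$sphere$radius_mm, 100 * x$sphere$inlier_fraction,
              x$axis$neck_min_circumference_mm))
  cat(sprintf("  alpha: %.1f-%.1f deg (median %.1f)\n",
              min(x$profile$alpha_deg), max(x$profile$alpha_deg),
              stats::median(x$profile$alpha_deg)))
  invisible(x)
}

#' @export
summary.alpha_fit <- function(object, ...) {
  s <- list(hip_id = object$hip_id,
            sphere = object$sphere, axis = object$axis,
            alpha_summary = summary(object$profile$alpha_deg),
            planes = object$planes[, c("plane", "alpha_deg", "matched_azimuth_deg")],
            n_extrapolated = sum(object$profile$quality != "ok"),
            timings_s = object$timings_s)
  class(s) <- "summary.alpha_fit"
  s
}

#' @export
print.summary.alpha_fit <- function(x, ...) {
  cat(sprintf("Automated alpha-angle measurement, hip '%s'\n", x$hip_id))
  print(x$sphere)
  print(x$axis)
  cat("Per-azimuth alpha (deg):\n")
  print(x$alpha_summary)
  cat("Named clinical planes:\n")
  print(x$planes, row.names = FALSE)
  if (x$n_extrapolated > 0)
    cat(sprintf("%d azimuth(s) extrapolated\n", x$n_extrapolated))
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) {
  stats::setNames(object$planes$alpha_deg, object$planes$plane)
}

#' @export
plot.alpha_fit <- function(x, ...) {
  map <- x$map
  rho <- map$rho
  rho[map$missing] <- NA
  graphics::image(map$phi_deg, map$theta_deg, t(rho),
                  xlab = "azimuth (deg)", ylab = "polar angle (deg)",
                  main = sprintf("roundness map + optimal cut (hip '%s')", x$hip_id),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::lines(x$profile$azimuth_deg, x$profile$alpha_deg, lwd = 2)
  invisible(x)
}
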