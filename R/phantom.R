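#' Parametric proximal-femur phantom specification
#'
#' Describes the anatomy the measurement pipeline assumes: a quasi-spherical
#' femoral head, a narrower neck joining it along an oblique axis, a shaft
#' continuing at the neck-shaft angle, and an optional cam deformity (bone
#' excess) at the head-neck junction. The cam raises the surface radius to
#' `head_radius * (1 + cam_height_frac * w(theta, phi))` inside the cam
#' region, where `w` is a smooth plateaued bump window (raised-cosine tapers,
#' exactly 0 on the region boundary, 1 on the central plateau). Polar angle
#' theta is measured from the neck-axis direction (0 = down the neck,
#' 180 = head apex); azimuth phi is measured around the axis from the
#' anterior reference (the world +x direction projected orthogonal to the
#' axis), positive toward superior.
#'
#' Defaults describe an adult-scale hip: 24 mm head radius, 16 mm neck
#' radius (baseline alpha angle asin(16/24) = 41.8 degrees), 30 mm neck,
#' 130 degree neck-shaft angle.
#'
#' @param head_radius_mm femoral head radius (mm).
#' @param neck_radius_mm femoral neck radius (mm); must not exceed the head
#'   radius.
#' @param neck_length_mm neck length beyond the head-neck junction (mm).
#' @param shaft_radius_mm shaft/metaphysis radius (mm); default
#'   `min(0.95 * head_radius_mm, max(0.75 * head_radius_mm,
#'   1.2 * neck_radius_mm))` so the intertrochanteric region is broader than
#'   the neck but narrower than the head, as in real anatomy.
#' @param shaft_length_mm shaft length (mm).
#' @param neck_shaft_angle_deg angle between shaft axis and neck axis
#'   (pointing toward the head); 130 degrees is typical adult anatomy.
#' @param neck_axis_direction unit 3-vector, head centre toward neck.
#' @param head_center_mm world position of the head centre (mm).
#' @param cam_present logical; add a cam bump?
#' @param cam_theta_min_deg,cam_theta_max_deg polar-angle interval of the cam
#'   (degrees from the neck-axis direction), 0 < min < max <= 170.
#' @param cam_phi_min_deg,cam_phi_max_deg azimuth interval of the cam
#'   (degrees); may wrap through 360.
#' @param cam_height_frac fractional radial protrusion of the cam (>= 0).
#' @param cam_taper_theta,cam_taper_phi taper fractions of the bump window in
#'   polar angle and azimuth (plateau covers `1 - taper` of each interval).
#' @param noise_sd_mm optional Gaussian radial surface jitter (mm); 0 = off.
#' @param rng_seed integer seed used only when `noise_sd_mm > 0`.
#' @return An object of class `femur_phantom` (validated list of the above).
#' @examples
#' spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
#'                       cam_theta_max_deg = 70, cam_phi_min_deg = 0,
#'                       cam_phi_max_deg = 60, cam_height_frac = 0.15)
#' attr(analytic_alpha(spec), "baseline_alpha_deg")
#' @export
femur_phantom <- function(head_radius_mm = 24,
                          neck_radius_mm = 16,
                          neck_length_mm = 30,
                          shaft_radius_mm = NULL,
                          shaft_length_mm = 40,
                          neck_shaft_angle_deg = 130,
                          neck_axis_direction = c(0.55, 0.3, 0.78),
                          head_center_mm = c(0, 0, 0),
                          cam_present = FALSE,
                          cam_theta_min_deg = 50,
                          cam_theta_max_deg = 70,
                          cam_phi_min_deg = 0,
                          cam_phi_max_deg = 60,
                          cam_height_frac = 0,
                          cam_taper_theta = 0.5,
                          cam_taper_phi = 0.2,
                          noise_sd_mm = 0,
                          rng_seed = 1L) {
  # the intertrochanteric region is broader than the neck but narrower than
  # the head (otherwise the largest inscribed sphere would not sit in the head)
  if (is.null(shaft_radius_mm))
    shaft_radius_mm <- min(0.95 * head_radius_mm,
                           max(0.75 * head_radius_mm, 1.2 * neck_radius_mm))
  spec <- list(head_radius_mm = head_radius_mm, neck_radius_mm = neck_radius_mm,
               neck_length_mm = neck_length_mm, shaft_radius_mm = shaft_radius_mm,
               shaft_length_mm = shaft_length_mm,
               neck_shaft_angle_deg = neck_shaft_angle_deg,
               neck_axis_direction = as.numeric(neck_axis_direction) /
                 vnorm(as.numeric(neck_axis_direction)),
               head_center_mm = as.numeric(head_center_mm),
               cam_present = isTRUE(cam_present),
               cam_theta_min_deg = cam_theta_min_deg,
               cam_theta_max_deg = cam_theta_max_deg,
               cam_phi_min_deg = cam_phi_min_deg, cam_phi_max_deg = cam_phi_max_deg,
               cam_height_frac = cam_height_frac,
               cam_taper_theta = cam_taper_theta, cam_taper_phi = cam_taper_phi,
               noise_sd_mm = noise_sd_mm, rng_seed = as.integer(rng_seed))
  validate_phantom(spec)
  structure(spec, class = "femur_phantom")
}

validate_phantom <- function(spec) {
  pos <- c("head_radius_mm", "neck_radius_mm", "neck_length_mm",
           "shaft_radius_mm", "shaft_length_mm")
  for (f in pos)
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1 || !is.finite(spec[[f]]) ||
        spec[[f]] <= 0)
      abort_camangle(sprintf("%s must be a positive length", f), "validation_error")
  if (spec$neck_radius_mm > spec$head_radius_mm)
    abort_camangle("neck_radius_mm must not exceed head_radius_mm", "validation_error")
  if (spec$shaft_radius_mm >= spec$head_radius_mm)
    abort_camangle("shaft_radius_mm must be smaller than head_radius_mm",
                   "validation_error")
  if (abs(vnorm(spec$neck_axis_direction) - 1) > 1e-9)
    abort_camangle("neck_axis_direction must have unit norm", "validation_error")
  if (spec$cam_present) {
    if (!(spec$cam_theta_min_deg > 0 && spec$cam_theta_min_deg < spec$cam_theta_max_deg &&
          spec$cam_theta_max_deg <= 170))
      abort_camangle("cam polar interval must satisfy 0 < min < max <= 170",
                     "validation_error")
    if (spec$cam_height_frac < 0)
      abort_camangle("cam_height_frac must be >= 0", "validation_error")
  }
  if (spec$noise_sd_mm < 0)
    abort_camangle("noise_sd_mm must be >= 0", "validation_error")
  invisible(spec)
}

#' @export
print.femur_phantom <- function(x, ...) {
  cat(sprintf("femur_phantom: head R = %.1f mm, neck r = %.1f mm (baseline alpha %.1f deg)\n",
              x$head_radius_mm, x$neck_radius_mm,
              rad2deg(asin(min(1, x$neck_radius_mm / x$head_radius_mm)))))
  if (x$cam_present && x$cam_height_frac > 0)
    cat(sprintf("  cam: theta [%g, %g] deg, phi [%g, %g] deg, height %.2f\n",
                x$cam_theta_min_deg, x$cam_theta_max_deg,
                x$cam_phi_min_deg, x$cam_phi_max_deg, x$cam_height_frac))
  invisible(x)
}

# in-plane basis orthogonal to the phantom's neck axis; e1 is the azimuth
# reference (world +x projected orthogonal to the axis, +z fallback)
phantom_basis <- function(spec) {
  a <- spec$neck_axis_direction
  ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  if (vnorm(e1) < 1e-6) {
    ref <- c(0, 0, 1)
    e1 <- ref - sum(ref * a) * a
  }
  e1 <- unitv(e1)
  list(e1 = e1, e2 = cross3(a, e1), e3 = a)
}

# azimuth distance into the cam interval, as fraction of its span; NA outside
cam_phi_fraction <- function(phi_deg, spec) {
  span <- (spec$cam_phi_max_deg - spec$cam_phi_min_deg) %% 360
  if (span == 0) span <- 360
  u <- ((phi_deg - spec$cam_phi_min_deg) %% 360) / span
  u[u > 1] <- NA_real_
  u
}

# bump window w(theta, phi) in [0, 1] (1 on the plateau, 0 outside the region)
cam_window <- function(theta_deg, phi_deg, spec) {
  if (!spec$cam_present || spec$cam_height_frac <= 0)
    return(numeric(length(theta_deg)))
  ut <- (theta_deg - spec$cam_theta_min_deg) /
    (spec$cam_theta_max_deg - spec$cam_theta_min_deg)
  up <- cam_phi_fraction(phi_deg, spec)
  w <- tukey_window(ut, spec$cam_taper_theta) *
    ifelse(is.na(up), 0, tukey_window(ifelse(is.na(up), 0, up), spec$cam_taper_phi))
  w
}

# surface radius (mm) of the head + cam in direction (theta, phi)
phantom_head_radius <- function(theta_deg, phi_deg, spec) {
  spec$head_radius_mm * (1 + spec$cam_height_frac *
                           cam_window(theta_deg, phi_deg, spec))
}

# axial extent of the neck cylinder measured from the head centre
phantom_neck_extent <- function(spec) {
  sqrt(max(0, spec$head_radius_mm^2 - spec$neck_radius_mm^2)) + spec$neck_length_mm
}

phantom_shaft_direction <- function(spec, basis = phantom_basis(spec)) {
  # angle between the shaft and the head-pointing neck axis is the neck-shaft
  # angle, so the shaft makes (180 - nsa) with the neck-pointing axis; the
  # shaft bends toward inferior (azimuth 270, i.e. -e2)
  bend <- deg2rad(180 - spec$neck_shaft_angle_deg)
  unitv(cos(bend) * basis$e3 - sin(bend) * basis$e2)
}

#' Voxelize a femur phantom
#'
#' Produces the binary segmentation mask the measurement pipeline consumes,
#' by a voxel-centre-in-solid test against the union of the head (plus cam
#' bump), the neck cylinder and the tilted shaft cylinder. The grid is sized
#' to enclose the phantom plus `padding_mm` on all sides and aligned so the
#' head centre falls exactly on a voxel centre. Two calls with the same spec
#' and spacing are bit-identical; `rng_seed` only matters when
#' `noise_sd_mm > 0` (voxel-level Gaussian radial jitter of the head surface
#' for robustness experiments).
#'
#' @param spec a [femur_phantom()].
#' @param spacing_mm voxel spacing, scalar or length 3, components in
#'   (0.2, 2] mm.
#' @param padding_mm padding (mm) around the phantom.
#' @return A [voxel_mask()]; the mask is a single 26-connected component.
#' @examples
#' m <- generate_phantom(femur_phantom(head_radius_mm = 10, neck_radius_mm = 7,
#'                                     neck_length_mm = 10, shaft_length_mm = 10,
#'                                     shaft_radius_mm = 6), spacing_mm = 1)
#' print(m)
#' @export
generate_phantom <- function(spec, spacing_mm = c(1, 1, 1), padding_mm = 8) {
  validate_phantom(spec)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0.2) || any(spacing_mm > 2))
    abort_camangle("spacing components must lie in (0.2, 2] mm", "validation_error")
  if (padding_mm < 0)
    abort_camangle("padding_mm must be >= 0", "validation_error")

  B <- phantom_basis(spec)
  C <- spec$head_center_mm
  Rh <- spec$head_radius_mm * (1 + max(0, spec$cam_height_frac))
  Tn <- phantom_neck_extent(spec)
  sdir <- phantom_shaft_direction(spec, B)
  Pn <- C + Tn * B$e3
  Ps <- Pn + (spec$shaft_length_mm + 0.5 * spec$shaft_radius_mm) * sdir
  lo <- pmin(C - Rh, Pn - spec$neck_radius_mm - 1, Ps - spec$shaft_radius_mm - 1) - padding_mm
  hi <- pmax(C + Rh, Pn + spec$neck_radius_mm + 1, Ps + spec$shaft_radius_mm + 1) + padding_mm

  # align the grid so the head centre is a voxel centre
  n_lo <- ceiling((C - lo) / spacing_mm)
  origin <- C - n_lo * spacing_mm
  dims <- as.integer(n_lo + ceiling((hi - C) / spacing_mm) + 1)
  if (any(dims < 8))
    abort_camangle("grid too small for the phantom", "dimension_error")
  if (prod(dims) > 6e7)
    abort_camangle("grid too large; increase spacing or reduce padding",
                   "dimension_error")

  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing_mm[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing_mm[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing_mm[3]

  n <- prod(dims)
  px <- rep(gx, times = dims[2] * dims[3]) - C[1]
  py <- rep(rep(gy, each = dims[1]), times = dims[3]) - C[2]
  pz <- rep(gz, each = dims[1] * dims[2]) - C[3]

  t_ax <- px * B$e3[1] + py * B$e3[2] + pz * B$e3[3]
  r2 <- px^2 + py^2 + pz^2
  r <- sqrt(r2)
  d2_ax <- pmax(0, r2 - t_ax^2)

  # head (+ cam): compare r against the direction-dependent surface radius
  if (spec$cam_present && spec$cam_height_frac > 0) {
    theta <- rad2deg(acos(clamp(ifelse(r > 0, t_ax / r, 1), -1, 1)))
    u1 <- px * B$e1[1] + py * B$e1[2] + pz * B$e1[3]
    u2 <- px * B$e2[1] + py * B$e2[2] + pz * B$e2[3]
    phi <- rad2deg(atan2(u2, u1)) %% 360
    rlim <- phantom_head_radius(theta, phi, spec)
  } else {
    rlim <- spec$head_radius_mm
  }
  if (spec$noise_sd_mm > 0) {
    jitter <- with_seed(spec$rng_seed, stats::rnorm(n, sd = spec$noise_sd_mm))
    rlim <- rlim + jitter
  }
  head_in <- r <= rlim

  neck_in <- t_ax >= 0 & t_ax <= Tn & d2_ax <= spec$neck_radius_mm^2

  # the shaft starts slightly proximal of the neck end so the metaphysis
  # swallows the neck's end disk (no exposed flat cap, as in real anatomy)
  ov <- 0.5 * spec$shaft_radius_mm
  S0 <- Tn * B$e3 - ov * sdir
  qx <- px - S0[1]; qy <- py - S0[2]; qz <- pz - S0[3]
  t_s <- qx * sdir[1] + qy * sdir[2] + qz * sdir[3]
  d2_s <- pmax(0, qx^2 + qy^2 + qz^2 - t_s^2)
  shaft_in <- t_s >= 0 & t_s <= spec$shaft_length_mm + ov & d2_s <= spec$shaft_radius_mm^2

  occ <- array(as.integer(head_in | neck_in | shaft_in), dims)
  comp <- .label_components3d(as.integer(occ), dims)
  if (length(comp$sizes) != 1) {
    # jitter can detach fragments; keep the main bone
    keep <- which.max(comp$sizes)
    occ <- array(as.integer(comp$labels == keep), dims)
  }
  voxel_mask(occ, spacing_mm, origin)
}

#' Analytic ground-truth alpha profile of a phantom
#'
#' Closed-form counterpart of the alpha-angle definition: for each azimuth,
#' the first polar angle (sweeping from the head apex, theta = 180, toward
#' the neck-axis direction, theta = 0) at which the phantom surface radius
#' exceeds `head_radius * (1 + tol_mm / head_radius)`. With the default
#' `tol_mm = 0` the profile equals `cam_theta_max_deg` at every azimuth
#' strictly inside the cam span (where the bump window is positive) and the
#' baseline `asin(neck_radius / head_radius)` elsewhere. A positive `tol_mm`
#' reproduces the finite detection tolerance a measurement at finite
#' resolution must use, moving the exceedance slightly down the bump taper.
#'
#' @param spec a [femur_phantom()].
#' @param tol_mm detection tolerance in mm of radial excess (default 0:
#'   ideal continuum truth).
#' @param step_deg azimuth step of the table (default 1 degree).
#' @return data.frame with `phi_deg`, `alpha_deg`, of class
#'   `ground_truth_alpha`, with attribute `baseline_alpha_deg`.
#' @export
analytic_alpha <- function(spec, tol_mm = 0, step_deg = 1) {
  validate_phantom(spec)
  baseline <- rad2deg(asin(min(1, spec$neck_radius_mm / spec$head_radius_mm)))
  phi <- seq(0, 360 - step_deg, by = step_deg)
  alpha <- rep(baseline, length(phi))
  if (spec$cam_present && spec$cam_height_frac > 0) {
    up <- cam_phi_fraction(phi, spec)
    bphi <- ifelse(is.na(up), 0, tukey_window(ifelse(is.na(up), 0, up),
                                              spec$cam_taper_phi))
    h_eff <- spec$cam_height_frac * bphi
    tol_frac <- tol_mm / spec$head_radius_mm
    span_t <- spec$cam_theta_max_deg - spec$cam_theta_min_deg
    for (i in seq_along(phi)) {
      if (h_eff[i] <= tol_frac || h_eff[i] <= 0) next
      cv <- if (h_eff[i] > 0) tol_frac / h_eff[i] else Inf
      ufrac <- tukey_upper_exceedance(cv, spec$cam_taper_theta)
      if (is.na(ufrac)) next
      th <- spec$cam_theta_min_deg + ufrac * span_t
      alpha[i] <- max(baseline, th)
    }
  }
  structure(data.frame(phi_deg = phi, alpha_deg = alpha),
            baseline_alpha_deg = baseline,
            class = c("ground_truth_alpha", "data.frame"))
}

#' Exact 2D contour of a phantom radial slice
#'
#' Returns the analytic bone outline in the full radial plane at azimuth
#' `phi_deg`: the half-plane at `phi_deg` maps to in-plane x > 0 and the
#' opposite half-plane (`phi_deg + 180`) to x < 0; y runs along the neck axis
#' (positive toward the neck, head apex at y = -head_radius). Points are
#' ordered from the neck end of the opposite side, over the head apex, down
#' to the neck end of the `phi_deg` side, so traversal "from the head apex
#' toward the neck" in sequence order measures the `phi_deg` side - the
#' convention [notzli_alpha_2d()] expects.
#'
#' @param spec a [femur_phantom()].
#' @param phi_deg azimuth of the slice half-plane (degrees).
#' @param step_deg polar sampling step along the contour (degrees).
#' @return n x 2 matrix of (x, y) points in mm.
#' @export
phantom_slice_contour <- function(spec, phi_deg, step_deg = 0.25) {
  validate_phantom(spec)
  Tn <- phantom_neck_extent(spec)
  theta_end <- rad2deg(atan2(spec$neck_radius_mm, Tn))
  theta <- seq(180 - step_deg / 2, theta_end, by = -step_deg)
  side <- function(phi) {
    rh <- phantom_head_radius(theta, rep(phi %% 360, length(theta)), spec)
    st <- sin(deg2rad(theta)); ct <- cos(deg2rad(theta))
    rn <- ifelse(st > 1e-9, spec$neck_radius_mm / st, Inf)
    t_on_cyl <- rn * ct
    rn[t_on_cyl < 0 | t_on_cyl > Tn] <- -Inf
    r <- pmax(rh, rn)
    cbind(x = r * st, y = r * ct)
  }
  s1 <- side(phi_deg)
  s2 <- side(phi_deg + 180)
  s2[, 1] <- -s2[, 1]
  out <- rbind(s2[rev(seq_len(nrow(s2))), ], s1)
  unname(out)
}
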