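# Kasa algebraic circle fit (least squares on x^2 + y^2 = 2 a x + 2 b y + c)
fit_circle_lsq <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  coef <- qr.coef(qr(A), b)
  ctr <- coef[1:2]
  r <- sqrt(max(0, coef[3] + sum(ctr^2)))
  list(center = unname(ctr), radius = unname(r))
}

#' Manual alpha-angle construction on a 2D radial slice
#'
#' Implements the classical circle construction used for manual alpha
#' measurements on a single radial image: fit a "circle of best fit" to the
#' femoral head contour (robust least squares: one trimming pass removing
#' points farther than twice the median absolute residual of an initial
#' algebraic fit), identify the neck centre `nc` as the midpoint of the
#' narrowest contour cross-section along the neck direction (ties resolved
#' toward the head), find the first-exceedance point `A` - the first contour
#' point, traversing from the head apex toward the neck, farther than
#' `r + tol_mm` from the head centre `hc` - and report the angle between
#' rays `hc -> A` and `hc -> nc`.
#'
#' The contour must be an ordered 2D point sequence. Open head-spanning
#' contours (as produced by [phantom_slice_contour()]) are traversed from
#' the apex toward the sequence end; closed contours are traversed from the
#' apex in the direction indicated by `side_hint`. If no exceedance occurs
#' before the traversal leaves the slice, alpha is undefined and the result
#' is flagged `failed`.
#'
#' @param contour n x 2 matrix of ordered points (mm), n >= 50.
#' @param head_side_hint unit 2-vector pointing from the bone centre toward
#'   the head apex; default: direction from the contour centroid to the
#'   middle point of the sequence (the apex of an open head-spanning
#'   contour ordered neck end -> apex -> neck end).
#' @param side_hint for closed contours, a 2-vector indicating the half of
#'   the plane whose head-neck junction is measured; default: `head_side_hint`
#'   rotated +90 degrees.
#' @param tol_mm exceedance tolerance added to the fitted radius (mm).
#' @param n_stations number of cross-section stations in the neck search.
#' @param t_max_factor neck search is confined to axial distances within
#'   this multiple of the fitted head radius (keeps the distal shaft, which
#'   can present a narrower oblique cross-section, out of the neck search).
#' @return An object of class `notzli_alpha`: `hc`, `r`, `nc`, `A`,
#'   `alpha_deg`, `failed`.
#' @examples
#' spec <- femur_phantom()
#' cont <- phantom_slice_contour(spec, 0)
#' notzli_alpha_2d(cont)$alpha_deg  # asin(16/24) up to the tolerance
#' @export
notzli_alpha_2d <- function(contour, head_side_hint = NULL, side_hint = NULL,
                            tol_mm = 0.6, n_stations = 300,
                            t_max_factor = 2.0) {
  contour <- unname(as.matrix(contour))
  if (ncol(contour) != 2 || nrow(contour) < 50)
    abort_camangle("contour must be an n x 2 matrix with n >= 50", "validation_error")
  n <- nrow(contour)
  closed <- sqrt(sum((contour[1, ] - contour[n, ])^2)) <
    1e-6 * max(1, max(abs(contour)))
  if (closed) {
    contour <- contour[-n, , drop = FALSE]
    n <- nrow(contour)
  }
  centroid <- colMeans(contour)
  hint <- if (is.null(head_side_hint)) unitv(contour[n %/% 2, ] - centroid)
          else unitv(head_side_hint)

  apex_i <- which.max((contour[, 1] - centroid[1]) * hint[1] +
                      (contour[, 2] - centroid[2]) * hint[2])
  # traversal order: apex -> neck on the measured side. For closed loops the
  # direction comes from side_hint; open contours default to sequence order
  # (the phantom_slice_contour convention) unless side_hint says otherwise.
  if (closed) {
    sh <- if (is.null(side_hint)) c(-hint[2], hint[1]) else unitv(side_hint)
    probe <- max(2L, n %/% 8L)
    fwd_i <- (apex_i - 1 + probe) %% n + 1
    bwd_i <- (apex_i - 1 - probe) %% n + 1
    fwd_score <- sum((contour[fwd_i, ] - centroid) * sh)
    bwd_score <- sum((contour[bwd_i, ] - centroid) * sh)
    ord <- if (fwd_score >= bwd_score) {
      ((apex_i - 1 + 0:(n - 1)) %% n) + 1
    } else {
      ((apex_i - 1 - 0:(n - 1)) %% n) + 1
    }
    path <- contour[ord, , drop = FALSE]
  } else if (!is.null(side_hint)) {
    sh <- unitv(side_hint)
    probe <- max(2L, n %/% 8L)
    fwd_i <- min(n, apex_i + probe)
    bwd_i <- max(1L, apex_i - probe)
    fwd_score <- sum((contour[fwd_i, ] - centroid) * sh)
    bwd_score <- sum((contour[bwd_i, ] - centroid) * sh)
    path <- if (fwd_score >= bwd_score) contour[apex_i:n, , drop = FALSE]
            else contour[apex_i:1, , drop = FALSE]
  } else {
    path <- contour[apex_i:n, , drop = FALSE]
  }

  # robust best-fit circle on the head arc (apex-side half of the contour)
  head_arc <- contour[((contour[, 1] - centroid[1]) * hint[1] +
                       (contour[, 2] - centroid[2]) * hint[2]) > 0, , drop = FALSE]
  if (nrow(head_arc) < 10)
    abort_camangle("too few head-arc points for a circle fit", "validation_error")
  fit <- fit_circle_lsq(head_arc)
  res <- abs(sqrt(rowSums(sweep(head_arc, 2, fit$center)^2)) - fit$radius)
  thr <- max(2 * stats::median(res), 1e-6 * fit$radius)
  keep <- res <= thr
  if (sum(keep) >= 10) fit <- fit_circle_lsq(head_arc[keep, , drop = FALSE])
  hc <- fit$center
  r <- fit$radius

  # neck centre: narrowest cross-section along the neck direction
  neck_dir <- -hint
  perp <- c(-neck_dir[2], neck_dir[1])
  t_all <- (contour[, 1] - hc[1]) * neck_dir[1] + (contour[, 2] - hc[2]) * neck_dir[2]
  q_all <- (contour[, 1] - hc[1]) * perp[1] + (contour[, 2] - hc[2]) * perp[2]
  t_hi <- min(max(t_all), t_max_factor * r)
  stations <- seq(0, t_hi, length.out = n_stations + 1)[-1]
  # consecutive contour segments (closed: wrap)
  i1 <- seq_len(n)
  i2 <- c(2:n, if (closed) 1L else NA_integer_)
  if (!closed) { i1 <- i1[-n]; i2 <- i2[-n] }
  best_w <- Inf; best_t <- NA_real_; best_mid <- NA_real_
  for (ts in stations) {
    da <- t_all[i1] - ts; db <- t_all[i2] - ts
    m <- da * db < 0
    if (sum(m) < 2) next
    w <- da[m] / (da[m] - db[m])
    qc <- q_all[i1[m]] + w * (q_all[i2[m]] - q_all[i1[m]])
    width <- max(qc) - min(qc)
    if (width < best_w - 1e-9) {  # strict improvement: ties stay nearer the head
      best_w <- width; best_t <- ts; best_mid <- (max(qc) + min(qc)) / 2
    }
  }
  if (!is.finite(best_w))
    abort_camangle("no neck cross-section found along the neck direction",
                   "validation_error")
  nc <- hc + best_t * neck_dir + best_mid * perp

  # first exceedance from the apex toward the neck
  dpath <- sqrt((path[, 1] - hc[1])^2 + (path[, 2] - hc[2])^2)
  exceed <- which(dpath > r + tol_mm)
  if (length(exceed) == 0) {
    return(structure(list(hc = hc, r = r, nc = nc, A = c(NA_real_, NA_real_),
                          alpha_deg = NA_real_, failed = TRUE),
                     class = "notzli_alpha"))
  }
  A <- path[exceed[1], ]
  alpha <- angle_between_deg(c(A - hc, 0), c(nc - hc, 0))
  structure(list(hc = hc, r = r, nc = nc, A = A, alpha_deg = alpha,
                 failed = FALSE),
            class = "notzli_alpha")
}

#' @export
print.notzli_alpha <- function(x, ...) {
  if (x$failed) {
    cat("notzli_alpha: no exceedance point found (alpha undefined)\n")
  } else {
    cat(sprintf("notzli_alpha: alpha = %.1f deg (hc (%.1f, %.1f), r %.1f mm)\n",
                x$alpha_deg, x$hc[1], x$hc[2], x$r))
  }
  invisible(x)
}

#' Extract a 2D slice contour of a mask in a radial plane
#'
#' Samples the smoothed occupancy field of `mask` on a regular 2D grid in
#' the full radial plane at azimuth `phi_deg` (in-plane x along the azimuth
#' direction, negative x = the opposite half-plane; y along the neck axis,
#' positive toward the neck) and extracts the 0.5 iso-contour enclosing the
#' head. This is the voxel-resolution counterpart of
#' [phantom_slice_contour()], used to feed the manual construction with the
#' same data the automated pipeline sees.
#'
#' @param mask a [voxel_mask()].
#' @param center_mm world point on the plane (head centre).
#' @param axis_dir unit 3-vector along the neck axis (head toward neck).
#' @param e1,e2 in-plane azimuth basis (from a `radial_slice_group`).
#' @param phi_deg azimuth of the half-plane.
#' @param extent_mm half-size of the sampled window (mm).
#' @param res_mm sampling step (mm).
#' @param smooth_sigma_vox Gaussian smoothing applied to the occupancy grid.
#' @return n x 2 matrix of (x, y) contour points (closed, ordered), in mm
#'   relative to `center_mm`.
#' @export
mask_slice_contour <- function(mask, center_mm, axis_dir, e1, e2, phi_deg,
                               extent_mm = 60, res_mm = 0.5,
                               smooth_sigma_vox = 1) {
  u <- cos(deg2rad(phi_deg)) * e1 + sin(deg2rad(phi_deg)) * e2
  gx <- seq(-extent_mm, extent_mm, by = res_mm)
  gy <- seq(-extent_mm, extent_mm, by = res_mm)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  world <- matrix(center_mm, nrow(pts), 3, byrow = TRUE) +
    pts[, 1, drop = FALSE] %*% rbind(u) + pts[, 2, drop = FALSE] %*% rbind(axis_dir)
  field <- smooth_field3d(mask$occupancy, smooth_sigma_vox)
  vals <- interp_trilinear(field, mask$spacing_mm, mask$origin_mm, world)
  z <- matrix(vals, length(gx), length(gy))
  cl <- grDevices::contourLines(gx, gy, z, levels = 0.5)
  if (length(cl) == 0)
    abort_camangle("no slice contour found at this azimuth", "validation_error")
  # pick the contour whose points get closest to the head centre (the bone
  # outline around the origin), preferring the longest such loop
  score <- vapply(cl, function(cc) {
    d2 <- cc$x^2 + cc$y^2
    -min(d2) * 1e6 + length(cc$x)
  }, numeric(1))
  best <- cl[[which.max(score)]]
  cbind(best$x, best$y)
}
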