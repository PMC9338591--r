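#' Refine the femoral neck axis via the minimal-circumference cross-section
#'
#' Planar cross-sections of the neck surface are taken at stations every
#' `station_step_mm` along the current axis; a section's circumference is the
#' total length of the mesh-plane intersection segments restricted to
#' neck-labelled triangles. The station with minimal circumference defines
#' the neck plane; the refined axis direction is the unit vector from the
#' fitted sphere centre to that section's (length-weighted) centroid. The
#' procedure iterates, re-slicing normal to the refined axis, until the
#' direction changes by less than `tol_deg` or `max_iter` iterations (the
#' last iterate is returned with `converged = FALSE` if the loop does not
#' settle).
#'
#' @param mesh a `triangle_mesh`.
#' @param labels per-vertex labels from [partition_head_neck()].
#' @param sphere a `sphere_fit` of the femoral head.
#' @param axis0 initial axis direction (unit 3-vector, head toward neck).
#' @param station_step_mm spacing of slicing stations along the axis (mm).
#' @param tol_deg convergence tolerance on the axis direction (degrees).
#' @param max_iter maximum number of re-slicing iterations.
#' @return An object of class `neck_axis`: `anchor_mm` (sphere centre),
#'   `direction` (unit, head toward neck), `neck_plane_center_mm`,
#'   `neck_min_circumference_mm`, `iterations`, `converged`.
#' @export
min_circumference_neck <- function(mesh, labels, sphere, axis0,
                                   station_step_mm = 1, tol_deg = 0.5,
                                   max_iter = 10) {
  V <- mesh$vertices
  F <- mesh$triangles
  neck_v <- labels == "neck"
  tri_neck <- (neck_v[F[, 1]] + neck_v[F[, 2]] + neck_v[F[, 3]]) >= 2
  if (!any(tri_neck))
    abort_camangle("axis failure: no neck-labelled triangles", "axis_error")
  Fn <- F[tri_neck, , drop = FALSE]
  ctr <- sphere$center_mm

  P1 <- V[Fn[, 1], , drop = FALSE]
  P2 <- V[Fn[, 2], , drop = FALSE]
  P3 <- V[Fn[, 3], , drop = FALSE]

  axis <- unitv(axis0)
  best <- NULL
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    t1 <- (P1 - matrix(ctr, nrow(P1), 3, byrow = TRUE)) %*% axis
    t2 <- (P2 - matrix(ctr, nrow(P2), 3, byrow = TRUE)) %*% axis
    t3 <- (P3 - matrix(ctr, nrow(P3), 3, byrow = TRUE)) %*% axis
    tmin <- min(t1, t2, t3); tmax <- max(t1, t2, t3)
    stations <- seq(tmin + station_step_mm / 2, tmax - station_step_mm / 2,
                    by = station_step_mm)
    if (length(stations) == 0)
      abort_camangle("axis failure: no station intersects the neck surface",
                     "axis_error")
    cand <- list()
    for (ts in stations) {
      s1 <- t1 - ts; s2 <- t2 - ts; s3 <- t3 - ts
      lo <- pmin(s1, s2, s3); hi <- pmax(s1, s2, s3)
      crossing <- lo < 0 & hi > 0
      if (!any(crossing)) next
      # interpolated crossing points on each edge
      edge_pt <- function(sa, sb, Pa, Pb) {
        m <- crossing & (sa * sb < 0)
        w <- sa[m] / (sa[m] - sb[m])
        list(m = m, p = Pa[m, , drop = FALSE] +
               w * (Pb[m, , drop = FALSE] - Pa[m, , drop = FALSE]))
      }
      e12 <- edge_pt(s1, s2, P1, P2)
      e13 <- edge_pt(s1, s3, P1, P3)
      e23 <- edge_pt(s2, s3, P2, P3)
      seg_len <- 0; seg_mid_sum <- c(0, 0, 0); mids <- NULL; lens <- NULL
      pair <- function(ea, eb) {
        m <- ea$m & eb$m
        if (!any(m)) return(NULL)
        pa <- ea$p[m[ea$m], , drop = FALSE]
        pb <- eb$p[m[eb$m], , drop = FALSE]
        len <- sqrt(rowSums((pa - pb)^2))
        list(len = sum(len), mid = colSums((pa + pb) / 2 * len),
             mids = (pa + pb) / 2, lens = len)
      }
      for (pp in list(pair(e12, e13), pair(e12, e23), pair(e13, e23))) {
        if (is.null(pp)) next
        seg_len <- seg_len + pp$len
        seg_mid_sum <- seg_mid_sum + pp$mid
        mids <- rbind(mids, pp$mids)
        lens <- c(lens, pp$lens)
      }
      if (seg_len <= 0) next
      centroid <- seg_mid_sum / seg_len
      relm <- sweep(mids, 2, centroid)
      b1 <- perp_basis(axis)
      ang <- atan2(relm %*% b1$v2, relm %*% b1$v1)
      cover <- length(unique(floor((ang + pi) / (2 * pi) * 24))) / 24
      radd <- sqrt(rowSums(relm^2))
      cand[[length(cand) + 1]] <- list(
        circ = seg_len, centroid = centroid, t = ts, cover = cover,
        ecc = stats::sd(radd) / mean(radd),
        completeness = seg_len / (2 * pi * mean(radd)))
    }
    if (length(cand) == 0)
      abort_camangle("axis failure: no station intersects the neck surface",
                     "axis_error")
    # The sought section is a closed circle on the neck surface. Prefer
    # near-complete, near-circular rings (ragged rings at the label boundary
    # and oblique clips of the flare/shaft fake small circumferences);
    # progressively relax if the mesh never yields a clean ring.
    best <- NULL
    for (tier in list(c(completeness = 0.97, ecc = 0.15, cover = 0.9),
                      c(completeness = 0.90, ecc = 0.25, cover = 0.9),
                      c(completeness = 0, ecc = Inf, cover = 0))) {
      ok <- Filter(function(cc) cc$completeness >= tier[["completeness"]] &&
                     cc$ecc <= tier[["ecc"]] && cc$cover >= tier[["cover"]], cand)
      if (length(ok)) {
        best <- ok[[which.min(vapply(ok, `[[`, numeric(1), "circ"))]]
        break
      }
    }
    new_axis <- unitv(best$centroid - ctr)
    delta <- angle_between_deg(new_axis, axis)
    axis <- new_axis
    if (delta < tol_deg) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("neck axis refinement did not converge in %d iterations", max_iter))
  structure(list(anchor_mm = ctr, direction = axis,
                 neck_plane_center_mm = best$centroid,
                 neck_min_circumference_mm = best$circ,
                 iterations = iterations, converged = converged),
            class = "neck_axis")
}

#' @export
print.neck_axis <- function(x, ...) {
  cat(sprintf("neck_axis: direction (%.3f, %.3f, %.3f), min circumference %.1f mm (%d iterations%s)\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$neck_min_circumference_mm, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Radial slice group around the neck axis
#'
#' Builds the family of half-planes bounded by the neck axis on which alpha
#' is measured slice by slice. Azimuths are evenly spaced; in the default
#' 360-degree mode they cover `[0, 360)` so asphericity anywhere on the
#' head-neck circumference is sampled, and a clinical "radial image" (a full
#' plane) corresponds to the pair phi and phi + 180. The 180-degree legacy
#' mode spans `[0, 180]` inclusive (7 slices reproduce the seven named
#' planes at 30-degree steps). Azimuth 0 is anchored to the `reference`
#' direction (anterior) projected orthogonal to the axis; 90 = superior,
#' 180 = posterior, 270 = inferior, viewed along the axis from head to neck.
#'
#' @param sphere a `sphere_fit` (slice planes contain its centre).
#' @param axis a `neck_axis`.
#' @param n_slices number of half-plane slices (7 to `max_slices`).
#' @param reference anterior reference direction (world 3-vector).
#' @param span_deg 360 (full circle, default) or 180 (legacy half span).
#' @param max_slices upper bound on `n_slices` (default 120).
#' @return An object of class `radial_slice_group`: `center_mm`, `axis`,
#'   `azimuths_deg`, `e1`, `e2` (in-plane basis with `e1` the azimuth-0
#'   direction), `span_deg`.
#' @export
build_slice_group <- function(sphere, axis, n_slices = 120,
                              reference = c(1, 0, 0), span_deg = 360,
                              max_slices = 120) {
  if (n_slices < 7)
    abort_camangle("n_slices must be >= 7", "validation_error")
  if (n_slices > max_slices)
    abort_camangle(sprintf("n_slices must be <= %d", max_slices), "validation_error")
  if (!span_deg %in% c(180, 360))
    abort_camangle("span_deg must be 180 or 360", "validation_error")
  e3 <- unitv(axis$direction)
  e1 <- reference - sum(reference * e3) * e3
  if (vnorm(e1) < 1e-6)
    abort_camangle("anchor error: reference direction is parallel to the axis",
                   "anchor_error")
  e1 <- unitv(e1)
  e2 <- cross3(e3, e1)
  az <- if (span_deg == 360) {
    seq(0, 360 - 360 / n_slices, by = 360 / n_slices)
  } else {
    seq(0, 180, length.out = n_slices)
  }
  structure(list(center_mm = sphere$center_mm, axis = axis,
                 azimuths_deg = az, e1 = e1, e2 = e2, span_deg = span_deg),
            class = "radial_slice_group")
}
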