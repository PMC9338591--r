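#' Least-squares sphere fit
#'
#' Linear algebraic fit (the sphere equation \eqn{|p|^2 = 2 c \cdot p + d}
#' solved by least squares), used to polish RANSAC hypotheses and as a
#' building block for tests.
#'
#' @param points n x 3 matrix.
#' @return list with `center`, `radius`, `rms` (RMS radial residual, mm).
#' @export
fit_sphere_lsq <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 4)
    abort_camangle("need at least 4 points for a sphere fit", "validation_error")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  coef <- qr.coef(qr(A), b)
  ctr <- coef[1:3]
  r <- sqrt(max(0, coef[4] + sum(ctr^2)))
  res <- sqrt(rowSums(sweep(points, 2, ctr)^2)) - r
  list(center = unname(ctr), radius = unname(r), rms = sqrt(mean(res^2)))
}

# exact sphere through 4 points (circumsphere); NULL for near-coplanar quads
circumsphere <- function(p) {
  A <- 2 * (p[2:4, , drop = FALSE] - matrix(p[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  det_a <- det(A)
  scale <- prod(sqrt(rowSums(A^2)))
  if (!is.finite(det_a) || scale < 1e-12 || abs(det_a) < 1e-6 * scale) return(NULL)
  ctr <- solve(A, b)
  list(center = as.numeric(ctr), radius = sqrt(sum((p[1, ] - ctr)^2)))
}

#' Robust femoral head sphere fit (RANSAC)
#'
#' Draws `iters` random 4-point hypotheses, solves each exactly via the
#' circumsphere linear system (near-coplanar quadruples rejected), counts
#' inliers within `thresh_mm` of the hypothesis surface, and polishes the
#' best hypothesis by least squares on its inlier set (one re-selection +
#' refit round). Deterministic for a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param points n x 3 matrix of head-surface points (mm); n >= 50.
#' @param seed integer seed for the hypothesis sampler.
#' @param iters number of RANSAC hypotheses (default 2000).
#' @param thresh_mm inlier distance threshold; default
#'   `max(0.75, 0.02 * radius)` evaluated per hypothesis.
#' @param min_inlier_fraction fit is rejected below this fraction (0.5).
#' @param score_max_points hypotheses are scored on at most this many points
#'   (a fixed random subset) for speed; the final fit uses all points.
#' @return An object of class `sphere_fit`: `center_mm`, `radius_mm`,
#'   `inlier_fraction`, `rms_residual_mm`, `n_points`, `seed`.
#' @export
ransac_sphere <- function(points, seed = 1L, iters = 2000,
                          thresh_mm = NULL, min_inlier_fraction = 0.5,
                          score_max_points = 4000) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 50)
    abort_camangle(sprintf("need >= 50 points for RANSAC sphere fit, got %d", n),
                   "validation_error")
  res <- with_seed(seed, {
    score_idx <- if (n > score_max_points) sample.int(n, score_max_points) else seq_len(n)
    sp <- points[score_idx, , drop = FALSE]
    best <- NULL
    best_count <- -1L
    for (it in seq_len(iters)) {
      cand <- circumsphere(points[sample.int(n, 4), , drop = FALSE])
      if (is.null(cand)) next
      th <- if (is.null(thresh_mm)) max(0.75, 0.02 * cand$radius) else thresh_mm
      dd <- abs(sqrt((sp[, 1] - cand$center[1])^2 +
                     (sp[, 2] - cand$center[2])^2 +
                     (sp[, 3] - cand$center[3])^2) - cand$radius)
      cnt <- sum(dd <= th)
      if (cnt > best_count) {
        best_count <- cnt
        best <- cand
      }
    }
    best
  })
  if (is.null(res))
    abort_camangle("RANSAC failed: no valid sphere hypothesis", "fit_failure_error")
  # polish: least squares on inliers of the full set, one re-selection round
  ctr <- res$center; rad <- res$radius
  for (round in 1:2) {
    th <- if (is.null(thresh_mm)) max(0.75, 0.02 * rad) else thresh_mm
    dd <- abs(sqrt(rowSums(sweep(points, 2, ctr)^2)) - rad)
    inl <- dd <= th
    if (sum(inl) < 4) break
    ls <- fit_sphere_lsq(points[inl, , drop = FALSE])
    ctr <- ls$center; rad <- ls$radius
  }
  th <- if (is.null(thresh_mm)) max(0.75, 0.02 * rad) else thresh_mm
  dd <- abs(sqrt(rowSums(sweep(points, 2, ctr)^2)) - rad)
  inl <- dd <= th
  frac <- mean(inl)
  if (frac < min_inlier_fraction)
    abort_camangle(sprintf("RANSAC fit failure: inlier fraction %.2f < %.2f",
                           frac, min_inlier_fraction), "fit_failure_error")
  structure(list(center_mm = ctr, radius_mm = rad,
                 inlier_fraction = frac,
                 rms_residual_mm = sqrt(mean(dd[inl]^2)),
                 n_points = n, seed = as.integer(seed)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: centre (%.2f, %.2f, %.2f) mm, radius %.2f mm, %.0f%% inliers, rms %.3f mm\n",
              x$center_mm[1], x$center_mm[2], x$center_mm[3], x$radius_mm,
              100 * x$inlier_fraction, x$rms_residual_mm))
  invisible(x)
}
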