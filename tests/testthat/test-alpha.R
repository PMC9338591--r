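# analytic sphere + cylinder roundness map (no mesh, no voxels)
analytic_map <- function(spec, ...) {
  roundness_map_from_function(camangle:::phantom_radius_function(spec),
                              spec$head_radius_mm, ...)
}

test_that("roundness map of a digital sphere is 1 within 2%", {
  R <- 20
  g <- seq(-24, 24, by = 1)
  occ <- array(0L, c(length(g), length(g), length(g)))
  for (k in seq_along(g)) occ[, , k] <- (outer(g^2, g^2, "+") + g[k]^2 <= R^2) * 1L
  mesh <- extract_surface(voxel_mask(occ, c(1, 1, 1), c(-24, -24, -24)))
  sphere <- structure(list(center_mm = c(0, 0, 0), radius_mm = R,
                           inlier_fraction = 1, rms_residual_mm = 0),
                      class = "sphere_fit")
  axis <- structure(list(anchor_mm = c(0, 0, 0), direction = c(0, 0, 1)),
                    class = "neck_axis")
  sg <- build_slice_group(sphere, axis, n_slices = 60)
  map <- build_roundness_map(mesh, sphere, sg)
  sel <- map$theta_deg > 30
  expect_lt(mean(abs(map$rho[sel, ] - 1), na.rm = TRUE), 0.02)
  expect_lt(mean(map$missing[sel, ]), 0.01)
})

test_that("roundness map sees the neck cylinder at the closed-form rho", {
  d <- default_fit()
  map <- d$fit$map
  base <- asin(2 / 3) * 180 / pi
  # inside the neck cone, proximal of the metaphysis (the ray must cross the
  # cylindrical neck wall, not the broader intertrochanteric region)
  th <- 0.7 * base
  i <- which.min(abs(map$theta_deg - th))
  expected <- (d$spec$neck_radius_mm / sin(th * pi / 180)) /
    d$spec$head_radius_mm
  vals <- map$rho[i, ]
  expect_gt(min(vals, na.rm = TRUE), 1)
  expect_lt(max(abs(vals - expected), na.rm = TRUE), 0.1 * expected)
})

test_that("roundness map failure triggers on wrong geometry", {
  d <- default_fit()
  bad_sphere <- d$fit$sphere
  bad_sphere$center_mm <- bad_sphere$center_mm + c(0, 0, 120)  # outside bone
  sg <- build_slice_group(bad_sphere, d$fit$axis, n_slices = 24)
  expect_error(build_roundness_map(d$fit$mesh, bad_sphere, sg),
               class = "map_error")
})

test_that("optimal cut on the analytic sphere+cylinder map hits the tolerance-adjusted baseline", {
  spec <- femur_phantom()
  map <- analytic_map(spec)
  tau <- 0.6 / 24
  prof <- alpha_by_optimal_cut(map, tau = tau, lambda_smooth = 0)
  expected <- asin((2 / 3) / (1 + tau)) * 180 / pi
  expect_true(all(abs(prof$alpha_deg - expected) <= 0.5 + 1e-9))
})

test_that("DP cut with lambda = 0 equals exhaustive per-column minimisation", {
  set.seed(99)
  for (rep in 1:10) {
    nt <- sample(20:60, 1); np <- sample(8:30, 1)
    D <- matrix(runif(nt * np), nt, np)
    sol <- camangle:::.dp_cut(D, 0)
    brute <- apply(D, 2, which.min)
    expect_identical(as.integer(sol$path), as.integer(brute))
    expect_equal(sol$cost, sum(apply(D, 2, min)), tolerance = 1e-12)
  }
})

test_that("large lambda forces the best constant cut", {
  set.seed(100)
  D <- matrix(runif(40 * 12), 40, 12)
  sol <- camangle:::.dp_cut(D, 1e9)
  expect_equal(length(unique(sol$path)), 1)
  expect_equal(unique(sol$path), which.min(rowSums(D)))
})

test_that("DP respects the circular azimuth closure", {
  # cheap-at-the-seam configuration: a path ignoring the wrap-around jump
  # would pay lambda * |end - start|
  nt <- 11; np <- 6
  D <- matrix(1, nt, np)
  D[1, c(1, 2, 6)] <- 0   # low near theta bin 1 at the seam
  D[11, 3:5] <- 0         # low at bin 11 mid-sequence
  lam <- 0.6
  sol <- camangle:::.dp_cut(D, lam)
  # brute force over all 11^6 paths is too big; use DP vs randomised check
  cost <- function(path) sum(D[cbind(path, 1:np)]) +
    lam * sum(abs(diff(c(path, path[1]))))
  expect_equal(sol$cost, cost(sol$path), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:500) {
    cand <- sample(nt, np, replace = TRUE)
    expect_gte(cost(cand), sol$cost - 1e-12)
  }
})

test_that("cam maps give the cam angle inside the span and baseline opposite", {
  spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
                        cam_theta_max_deg = 70, cam_phi_min_deg = 0,
                        cam_phi_max_deg = 60, cam_height_frac = 0.15)
  map <- analytic_map(spec)
  tau <- 0.6 / 24
  prof <- alpha_by_optimal_cut(map, tau = tau)
  gt <- analytic_alpha(spec, tol_mm = 0.6)
  on_plateau <- prof$azimuth_deg >= 6 & prof$azimuth_deg <= 54
  gt_match <- gt$alpha_deg[match(prof$azimuth_deg, gt$phi_deg)]
  expect_true(all(abs(prof$alpha_deg[on_plateau] - gt_match[on_plateau]) <= 0.5 + 1e-9))
  i180 <- which(prof$azimuth_deg == 180)
  expect_lt(abs(prof$alpha_deg[i180] - asin((2/3) / (1 + tau)) * 180 / pi), 0.51)
})

test_that("recovered cam angle is monotone in cam_theta_max", {
  vals <- vapply(c(55, 65, 75), function(tm) {
    spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = tm - 20,
                          cam_theta_max_deg = tm, cam_phi_min_deg = 0,
                          cam_phi_max_deg = 60, cam_height_frac = 0.15)
    prof <- alpha_by_optimal_cut(analytic_map(spec), tau = 0.6 / 24)
    mean(prof$alpha_deg[prof$azimuth_deg >= 12 & prof$azimuth_deg <= 48])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("all-missing azimuth columns are interpolated and flagged", {
  spec <- femur_phantom()
  map <- analytic_map(spec)
  kill <- map$phi_deg >= 90 & map$phi_deg < 105
  map$rho[, kill] <- NA
  map$missing[, kill] <- TRUE
  prof <- alpha_by_optimal_cut(map, tau = 0.6 / 24)
  expect_true(all(prof$quality[kill] == "extrapolated"))
  expect_true(all(prof$quality[!kill] == "ok"))
  # interpolated cut stays near the neighbouring baseline cut
  expect_lt(max(abs(prof$alpha_deg[kill] - median(prof$alpha_deg[!kill]))), 2)
})

test_that("profiles on rotationally symmetric maps are constant", {
  spec <- femur_phantom()
  prof <- alpha_by_optimal_cut(analytic_map(spec), tau = 0.6 / 24)
  expect_lte(diff(range(prof$alpha_deg)), 0.5 + 1e-9)
})

test_that("2D construction details: robust fit, tie-break, failure flag", {
  spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
                        cam_theta_max_deg = 70, cam_phi_min_deg = 0,
                        cam_phi_max_deg = 60, cam_height_frac = 0.15)
  cont <- phantom_slice_contour(spec, 30, step_deg = 0.1)
  nz <- notzli_alpha_2d(cont)
  # the cam bump must not inflate the fitted head circle
  expect_lt(abs(nz$r / 24 - 1), 0.005)
  expect_false(nz$failed)
  expect_gt(camangle:::vnorm(nz$A - nz$hc), nz$r)
  # nc sits on the neck axis (x ~ 0) nearer the head on the tie run
  expect_lt(abs(nz$nc[1]), 1)
  # a pure circle has no exceedance point
  th <- seq(0, 2 * pi, length.out = 400)[-1]
  circ <- cbind(24 * cos(th), 24 * sin(th))
  expect_true(notzli_alpha_2d(circ, head_side_hint = c(0, -1))$failed)
  # short contours are rejected
  expect_error(notzli_alpha_2d(cont[1:20, ]), class = "validation_error")
})

test_that("named planes map onto the nearest computed azimuths", {
  d <- default_fit()
  planes <- select_named_planes(d$fit$profile, hip_id = "p1")
  expect_equal(nrow(planes), 7)
  expect_equal(planes$matched_azimuth_deg, planes$plane_azimuth_deg)  # 3-deg grid
  expect_equal(planes$alpha_deg[planes$plane == "superior"],
               d$fit$profile$alpha_deg[d$fit$profile$azimuth_deg == 90])
  # 7-slice legacy profile maps one-to-one
  prof7 <- structure(data.frame(azimuth_deg = seq(0, 180, by = 30),
                                alpha_deg = 41:47,
                                quality = "ok"),
                     class = c("alpha_profile", "data.frame"))
  p7 <- select_named_planes(prof7)
  expect_equal(p7$alpha_deg, 41:47)
  # constant profiles give identical named values
  prof7$alpha_deg <- rep(50, 7)
  expect_true(all(select_named_planes(prof7)$alpha_deg == 50))
  # sparse profiles warn when the match is farther than one step
  prof_sparse <- structure(data.frame(azimuth_deg = c(0, 10, 180, 190),
                                      alpha_deg = rep(45, 4),
                                      quality = "ok"),
                           class = c("alpha_profile", "data.frame"))
  w <- testthat::capture_warnings(select_named_planes(prof_sparse))
  expect_true(any(grepl("away", w)))
})

test_that("half-plane pair folding takes the per-plane maximum", {
  prof <- structure(data.frame(azimuth_deg = seq(0, 330, by = 30),
                               alpha_deg = c(40, 41, 42, 43, 44, 45,
                                             50, 39, 39, 39, 39, 39),
                               quality = "ok"),
                    class = c("alpha_profile", "data.frame"))
  pairs <- alpha_profile_pairs(prof)
  expect_equal(nrow(pairs), 6)
  expect_equal(pairs$alpha_deg[pairs$azimuth_deg == 0], 50)
  expect_equal(pairs$alpha_deg[pairs$azimuth_deg == 30], 41)
})
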