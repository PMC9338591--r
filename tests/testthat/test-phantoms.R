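test_that("phantom spec validation enforces the anatomical invariants", {
  expect_error(femur_phantom(head_radius_mm = -1), class = "validation_error")
  expect_error(femur_phantom(neck_radius_mm = 30), class = "validation_error")
  expect_error(femur_phantom(cam_present = TRUE, cam_theta_min_deg = 0),
               class = "validation_error")
  expect_error(femur_phantom(cam_present = TRUE, cam_theta_min_deg = 80,
                             cam_theta_max_deg = 60), class = "validation_error")
  expect_error(femur_phantom(cam_present = TRUE, cam_theta_max_deg = 175),
               class = "validation_error")
  expect_error(femur_phantom(cam_present = TRUE, cam_height_frac = -0.1),
               class = "validation_error")
  # degenerate hemispherical junction is representable
  expect_silent(femur_phantom(neck_radius_mm = 24))
  expect_error(generate_phantom(small_spec(), spacing_mm = 0.1),
               class = "validation_error")
  expect_error(generate_phantom(small_spec(), spacing_mm = 3),
               class = "validation_error")
})

test_that("voxelisation matches the analytic head volume within 2%", {
  spec <- femur_phantom()  # R = 24, r_neck = 16
  m <- generate_phantom(spec, spacing_mm = 1)
  # count foreground voxel centres inside the analytic head sphere
  fg <- camangle:::mask_foreground_world(m)
  r <- sqrt(rowSums(sweep(fg, 2, spec$head_center_mm)^2))
  vol_vox <- sum(r <= spec$head_radius_mm) * prod(m$spacing_mm)
  vol_true <- 4 / 3 * pi * spec$head_radius_mm^3
  expect_lt(abs(vol_vox / vol_true - 1), 0.02)
})

test_that("phantom generation is deterministic and single-component", {
  m1 <- generate_phantom(small_spec())
  m2 <- generate_phantom(small_spec())
  expect_identical(m1$occupancy, m2$occupancy)
  comp <- camangle:::.label_components3d(as.integer(m1$occupancy),
                                         dim(m1$occupancy))
  expect_length(comp$sizes, 1)
})

test_that("cam-free phantom is rotationally symmetric about a grid-aligned axis", {
  spec <- femur_phantom(head_radius_mm = 12, neck_radius_mm = 8,
                        neck_length_mm = 15, shaft_length_mm = 10,
                        neck_axis_direction = c(0, 0, 1))
  m <- generate_phantom(spec)
  occ <- m$occupancy
  d <- dim(occ)
  # head centre voxel index
  ci <- camangle:::mask_world_to_index(m, rbind(spec$head_center_mm))
  # restrict to the symmetric head+neck part: everything below the lowest
  # point of the (tilted, asymmetric) shaft cylinder
  Tn <- camangle:::phantom_neck_extent(spec)
  bend <- (180 - spec$neck_shaft_angle_deg) * pi / 180
  ov <- 0.5 * spec$shaft_radius_mm
  z_shaft_min <- (Tn - ov * cos(bend)) - spec$shaft_radius_mm * sin(bend)
  kmax <- ci[3] + floor(z_shaft_min - 2)
  sub <- occ[, , 1:kmax]
  # rotate 90 deg about the axis through the head-centre column
  nx <- dim(sub)[1]; ny <- dim(sub)[2]
  # symmetric crop so the centre voxel is the pivot
  hw <- min(ci[1] - 1, nx - ci[1], ci[2] - 1, ny - ci[2])
  sq <- sub[(ci[1] - hw):(ci[1] + hw), (ci[2] - hw):(ci[2] + hw), , drop = FALSE]
  rot <- aperm(sq, c(2, 1, 3))[dim(sq)[2]:1, , , drop = FALSE]
  expect_identical(sq, rot)
})

test_that("analytic alpha reproduces the closed-form baseline", {
  # hemispherical junction: arcsin(1)
  gt <- analytic_alpha(femur_phantom(neck_radius_mm = 24))
  expect_equal(attr(gt, "baseline_alpha_deg"), 90)
  # R = 24, r = 16: arcsin(2/3)
  gt <- analytic_alpha(femur_phantom())
  expect_equal(attr(gt, "baseline_alpha_deg"), asin(2 / 3) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(nrow(gt), 360)
  expect_true(all(gt$alpha_deg == attr(gt, "baseline_alpha_deg")))
})

test_that("analytic alpha of a cam phantom is cam_theta_max inside the span", {
  spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
                        cam_theta_max_deg = 70, cam_phi_min_deg = 0,
                        cam_phi_max_deg = 60, cam_height_frac = 0.15)
  gt <- analytic_alpha(spec)
  base <- attr(gt, "baseline_alpha_deg")
  inside <- gt$phi_deg > 0 & gt$phi_deg < 60
  expect_true(all(abs(gt$alpha_deg[inside] - 70) < 1e-9))
  expect_equal(gt$alpha_deg[gt$phi_deg == 180], base)
  expect_true(all(gt$alpha_deg >= base - 1e-12))
  # a finite detection tolerance moves the exceedance down the bump taper
  gt_tol <- analytic_alpha(spec, tol_mm = 0.6)
  expect_true(all(gt_tol$alpha_deg <= gt$alpha_deg + 1e-12))
  expect_lt(gt_tol$alpha_deg[gt_tol$phi_deg == 30], 70)
  expect_gt(gt_tol$alpha_deg[gt_tol$phi_deg == 30], 66)
})

test_that("2D construction on the exact analytic contour reproduces analytic alpha", {
  # voxelisation-free oracle agreement, < 0.1 degree at fine contour sampling
  spec0 <- femur_phantom()
  cont <- phantom_slice_contour(spec0, 0, step_deg = 0.05)
  nz <- notzli_alpha_2d(cont, tol_mm = 1e-4)
  expect_lt(abs(nz$alpha_deg - attr(analytic_alpha(spec0), "baseline_alpha_deg")),
            0.1)
  spec1 <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
                         cam_theta_max_deg = 70, cam_phi_min_deg = 0,
                         cam_phi_max_deg = 60, cam_height_frac = 0.15)
  for (phi in c(30, 180)) {
    gt <- analytic_alpha(spec1)
    cont <- phantom_slice_contour(spec1, phi, step_deg = 0.05)
    nz <- notzli_alpha_2d(cont, tol_mm = 1e-4)
    expect_lt(abs(nz$alpha_deg - gt$alpha_deg[gt$phi_deg == phi]), 0.1)
  }
})

test_that("surface jitter is seeded and off by default", {
  s1 <- small_spec(noise_sd_mm = 0.3, rng_seed = 7)
  m1 <- generate_phantom(s1)
  m2 <- generate_phantom(s1)
  expect_identical(m1$occupancy, m2$occupancy)
  m3 <- generate_phantom(small_spec(noise_sd_mm = 0.3, rng_seed = 8))
  expect_false(identical(m1$occupancy, m3$occupancy))
})
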