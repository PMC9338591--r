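test_that("iso-surface of a digital sphere has the analytic area within 3%", {
  R <- 20
  g <- seq(-24, 24, by = 1)
  occ <- array(0L, c(length(g), length(g), length(g)))
  pts2 <- outer(g^2, g^2, "+")
  for (k in seq_along(g)) occ[, , k] <- (pts2 + g[k]^2 <= R^2) * 1L
  mask <- voxel_mask(occ, c(1, 1, 1), c(-24, -24, -24))
  mesh <- extract_surface(mask)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * R^2) - 1), 0.03)
})

test_that("only the largest of two disjoint blobs contributes vertices", {
  occ <- array(0L, c(40, 20, 20))
  occ[4:16, 4:16, 4:16] <- 1L   # 13^3 cube
  occ[30:35, 4:9, 4:9] <- 1L    # smaller cube
  mesh <- extract_surface(voxel_mask(occ, c(1, 1, 1)), smooth_sigma_vox = 0.8)
  expect_true(all(mesh$vertices[, 1] < 25))
})

test_that("mesh vertices lie near a foreground/background interface", {
  m <- small_mask()
  mesh <- extract_surface(m)
  # boundary voxels: foreground with at least one background 6-neighbour
  occ <- m$occupancy
  d <- dim(occ)
  pad <- array(0L, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  bnd <- which(occ == 1L & nb < 6L)
  bw <- camangle:::mask_index_to_world(m, arrayInd(bnd, d))
  # nearest boundary voxel centre within one voxel diagonal, checked on a
  # deterministic vertex subsample
  V <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 7), , drop = FALSE]
  d2 <- outer(rowSums(V^2), rowSums(bw^2), "+") - 2 * V %*% t(bw)
  worst <- sqrt(max(apply(d2, 1, min)))
  expect_lt(worst, sqrt(3) * max(m$spacing_mm))
})

test_that("degenerate inputs give typed surface errors", {
  empty <- voxel_mask(array(0L, c(6, 6, 6)), c(1, 1, 1))
  expect_error(extract_surface(empty), class = "empty_mask_error")
  tiny <- array(0L, c(6, 6, 6)); tiny[3:4, 3:4, 3:4] <- 1L
  expect_error(extract_surface(voxel_mask(tiny, c(1, 1, 1))),
               class = "degenerate_surface_error")
})

test_that("initial landmarks recover the phantom head and axis", {
  d <- default_fit()
  lm <- initial_landmarks(d$mask)
  expect_lt(camangle:::vnorm(lm$head_center_mm - d$spec$head_center_mm),
            sqrt(3) * max(d$mask$spacing_mm))
  expect_lt(abs(lm$head_radius_mm / d$spec$head_radius_mm - 1), 0.05)
  expect_lt(camangle:::angle_between_deg(lm$neck_axis,
                                         d$spec$neck_axis_direction), 10)
})

test_that("a neckless sphere triggers a landmark failure", {
  R <- 12
  g <- seq(-16, 16, by = 1)
  occ <- array(0L, c(length(g), length(g), length(g)))
  for (k in seq_along(g)) occ[, , k] <- (outer(g^2, g^2, "+") + g[k]^2 <= R^2) * 1L
  expect_error(initial_landmarks(voxel_mask(occ, c(1, 1, 1))),
               class = "landmark_error")
})

test_that("head/neck partition matches the analytic membership", {
  d <- default_fit()
  mesh <- d$fit$mesh
  lm <- d$fit$landmarks
  labels <- partition_head_neck(mesh, lm)
  # vertices analytically on the spherical cap (radius within 2% of R, polar
  # angle above the junction cone)
  rel <- sweep(mesh$vertices, 2, d$spec$head_center_mm)
  r <- sqrt(rowSums(rel^2))
  theta <- acos(pmin(1, pmax(-1, rel %*% d$spec$neck_axis_direction / r))) * 180 / pi
  on_cap <- abs(r - d$spec$head_radius_mm) < 0.02 * d$spec$head_radius_mm &
    theta > asin(d$spec$neck_radius_mm / d$spec$head_radius_mm) * 180 / pi + 5
  expect_gt(mean(labels[on_cap] == "head"), 0.95)
  # neck centroid projection within [R, 2R]
  neckc <- colMeans(mesh$vertices[labels == "neck", , drop = FALSE])
  t_ax <- sum((neckc - lm$head_center_mm) * lm$neck_axis)
  expect_gt(t_ax, lm$head_radius_mm)
  expect_lt(t_ax, 2 * lm$head_radius_mm)
  # landmarks bigger than the whole bone leave no neck
  lm_bad <- lm
  lm_bad$head_radius_mm <- 200
  expect_error(partition_head_neck(mesh, lm_bad), class = "partition_error")
})

test_that("landmarks are covariant under 90-degree grid rotations", {
  m <- small_mask()
  lm <- initial_landmarks(m)
  mr <- rotate_mask_z90(m)
  lmr <- initial_landmarks(mr)
  expect_lt(camangle:::angle_between_deg(lmr$neck_axis, rot_z90(lm$neck_axis)), 2)
  expect_lt(abs(lmr$head_radius_mm - lm$head_radius_mm), 1e-9)
})
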