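# Shared fixtures, memoised so expensive phantoms/pipelines are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small, fast phantom for unit tests (same neck/head ratio as the default)
small_spec <- function(...) {
  femur_phantom(head_radius_mm = 12, neck_radius_mm = 8, neck_length_mm = 15,
                shaft_length_mm = 15, ...)
}

small_mask <- function() fixture("small_mask", generate_phantom(small_spec()))

default_fit <- function() {
  fixture("default_fit", {
    spec <- femur_phantom()
    list(spec = spec, mask = generate_phantom(spec),
         fit = measure_alpha(generate_phantom(spec), seed = 1))
  })
}

# study-condition phantoms of the validation grid (adult scale, 1 mm voxels)
baseline_fit <- function(ratio) {
  fixture(sprintf("baseline_%g", ratio), {
    spec <- femur_phantom(neck_radius_mm = ratio * 24)
    mask <- generate_phantom(spec)
    t0 <- proc.time()[["elapsed"]]
    fit <- measure_alpha(mask, seed = 1)
    list(spec = spec, mask = mask, fit = fit,
         elapsed_s = proc.time()[["elapsed"]] - t0)
  })
}

cam_fit <- function(theta_max) {
  fixture(sprintf("cam_%g", theta_max), {
    spec <- femur_phantom(cam_present = TRUE,
                          cam_theta_min_deg = theta_max - 20,
                          cam_theta_max_deg = theta_max,
                          cam_phi_min_deg = 0, cam_phi_max_deg = 60,
                          cam_height_frac = 0.15)
    mask <- generate_phantom(spec)
    t0 <- proc.time()[["elapsed"]]
    fit <- measure_alpha(mask, seed = 1)
    list(spec = spec, mask = mask, fit = fit,
         elapsed_s = proc.time()[["elapsed"]] - t0)
  })
}

# points on a sphere (deterministic), optionally contaminated with uniform
# box outliers
sphere_points <- function(n, center = c(10, -5, 3), radius = 24, seed = 42) {
  set.seed(seed)
  z <- stats::rnorm(n * 3)
  dim(z) <- c(n, 3)
  z <- z / sqrt(rowSums(z^2))
  sweep(z * radius, 2, center, "+")
}

with_outliers <- function(pts, frac = 0.2, seed = 43) {
  set.seed(seed)
  n_out <- round(nrow(pts) * frac)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  out <- cbind(stats::runif(n_out, lo[1], hi[1]),
               stats::runif(n_out, lo[2], hi[2]),
               stats::runif(n_out, lo[3], hi[3]))
  rbind(pts, out)
}

# independent from-scratch ICC(A,1) oracle: raw sums of squares, no aov
icc_oracle_a1 <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  gm <- mean(wide)
  rowm <- rowMeans(wide); colm <- colMeans(wide)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sse <- sum(wide^2) - n * k * gm^2 - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# 90-degree rotation of a mask about the z grid axis (indices (x, y) -> grid
# rotation); world directions map as (vx, vy, vz) -> (-vy, vx, vz)
rotate_mask_z90 <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  new <- aperm(occ, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  voxel_mask(new, mask$spacing_mm[c(2, 1, 3)], c(0, 0, 0))
}

rot_z90 <- function(v) c(-v[2], v[1], v[3])
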