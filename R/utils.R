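# Internal helpers shared across the pipeline.

# Typed errors so callers can distinguish failure modes.
abort_camangle <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "camangle_error", "error"),
                      call = call))
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort_camangle("cannot normalise a zero vector", "validation_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any orthonormal pair perpendicular to a unit vector
perp_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- unitv(ref - sum(ref * a) * a)
  list(v1 = v1, v2 = cross3(a, v1))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# angle between two vectors in degrees
angle_between_deg <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a temporary RNG seed, restoring global RNG state afterwards,
# so seeded components do not disturb the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Separable Gaussian smoothing of a 3D array (zero-padded borders); sigma in
# voxels. Used to regularise binary occupancy before iso-surfacing so the
# level-0.5 surface interpolates the voxel staircase.
smooth_field3d <- function(arr, sigma_vox = 1) {
  if (sigma_vox <= 0) return(arr)
  rad <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    n <- d[ax]
    for (m in seq_along(k)) {
      off <- m - rad - 1L
      src_lo <- max(1L, 1L - off); src_hi <- min(n, n - off)
      if (src_lo > src_hi) next
      dst <- (src_lo + off):(src_hi + off)
      src <- src_lo:src_hi
      idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx_src <- idx_dst
      idx_dst[[ax]] <- dst
      idx_src[[ax]] <- src
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
        k[m] * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    }
    arr <- out
  }
  arr
}

# Trilinear interpolation of a 3D array at world points (n x 3), given
# spacing/origin of the grid (voxel centres at origin + (index-1)*spacing).
# Points outside the grid get `outside`.
interp_trilinear <- function(arr, spacing, origin, pts, outside = 0) {
  d <- dim(arr)
  g <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1  # fractional 1-based index
  i0 <- floor(g)
  fr <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  val <- rep(outside, nrow(pts))
  if (!any(ok)) return(val)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  at <- function(dx, dy, dz) {
    arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v <- at(0, 0, 0) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
       at(1, 0, 0) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
       at(0, 1, 0) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
       at(1, 1, 0) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
       at(0, 0, 1) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
       at(1, 0, 1) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
       at(0, 1, 1) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
       at(1, 1, 1) * fr[, 1] * fr[, 2] * fr[, 3]
  val[ok] <- v
  val
}

# Tukey (raised-cosine-tapered) window on [0, 1]: 0 outside, 1 on the central
# plateau, cosine taper of total fraction `taper` (taper/2 each side).
tukey_window <- function(u, taper) {
  w <- numeric(length(u))
  inside <- u > 0 & u < 1
  if (taper <= 0) {
    w[inside] <- 1
    return(w)
  }
  a <- taper / 2
  lo <- inside & u < a
  hi <- inside & u > 1 - a
  mid <- inside & !lo & !hi
  w[mid] <- 1
  w[lo] <- 0.5 * (1 - cos(pi * u[lo] / a))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / a))
  w
}

# Largest theta (as fraction u of the window) at which tukey_window exceeds c;
# inverse of the upper taper. c in (0, 1]; returns NA if never exceeded.
tukey_upper_exceedance <- function(c_val, taper) {
  if (c_val >= 1) return(NA_real_)
  if (c_val <= 0) return(1)
  a <- taper / 2
  if (a <= 0) return(1)
  1 - a * acos(1 - 2 * c_val) / pi
}
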