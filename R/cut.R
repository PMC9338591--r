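#' Per-azimuth alpha angles as an optimal cut through the roundness map
#'
#' Determines the head-neck boundary on the roundness map as a per-azimuth
#' polar angle `theta_c(phi)` minimising
#' \deqn{\sum_\phi D(\phi, \theta_c(\phi)) +
#'       \lambda \sum_\phi |\theta_c(\phi+1) - \theta_c(\phi)|}
#' over the circular azimuth domain (solved exactly by dynamic programming
#' over the discretised polar bins, run over every possible starting state to
#' honour the circular closure). The data term is an asymmetric
#' misclassification count:
#' `D(phi, theta) = w_head * #\{theta' > theta : rho > 1 + tau\} +
#'  w_neck * #\{theta' <= theta : rho <= 1 + tau\}`
#' over sampled cells only - aspherical cells left on the head side of the
#' cut are heavily penalised, spherical cells on the neck side lightly. The
#' alpha angle at each azimuth is the cut angle itself (theta is measured
#' from the neck axis, so no offset convention is needed).
#'
#' Azimuth columns with no sampled cells contribute no data cost; their cut
#' is interpolated by the smoothness term and flagged `"extrapolated"`.
#'
#' @param map a `roundness_map`.
#' @param tau asphericity tolerance as a fraction of the head radius; the
#'   cell threshold is `rho > 1 + tau`. Default
#'   `max(0.6 mm, half voxel diagonal) / head_radius`; pass `tau_mm` via
#'   [measure_alpha()] or give the fraction here.
#' @param lambda_smooth smoothness penalty per polar bin of cut change
#'   between adjacent azimuths (default 2).
#' @param w_head,w_neck misclassification weights (default 10 : 1).
#' @return An object of class `alpha_profile`: data.frame with
#'   `azimuth_deg`, `alpha_deg`, `quality` (`"ok"` / `"extrapolated"`),
#'   attributes `cut_bins`, `cost`, `tau`.
#' @export
alpha_by_optimal_cut <- function(map, tau = 0.025, lambda_smooth = 2,
                                 w_head = 10, w_neck = 1) {
  rho <- map$rho
  nt <- nrow(rho); np <- ncol(rho)
  sampled <- !map$missing
  supra <- sampled & !is.na(rho) & rho > 1 + tau
  sub <- sampled & !supra

  # D(theta_c, phi): supra cells strictly above the cut + sub cells at/below
  supra_above <- apply(supra, 2, function(col) rev(cumsum(rev(col))) - col)
  sub_below <- apply(sub, 2, function(col) cumsum(col))
  D <- w_head * supra_above + w_neck * sub_below
  empty_col <- colSums(sampled) == 0
  D[, empty_col] <- 0

  sol <- .dp_cut(D, lambda_smooth)
  bins <- sol$path
  alpha <- map$theta_deg[bins]
  quality <- ifelse(empty_col, "extrapolated", "ok")
  structure(data.frame(azimuth_deg = map$phi_deg, alpha_deg = alpha,
                       quality = quality),
            cut_bins = bins, cost = sol$cost, tau = tau,
            class = c("alpha_profile", "data.frame"))
}

#' @export
print.alpha_profile <- function(x, ...) {
  cat(sprintf("alpha_profile: %d azimuths, alpha %.1f-%.1f deg (median %.1f)\n",
              nrow(x), min(x$alpha_deg), max(x$alpha_deg),
              stats::median(x$alpha_deg)))
  if (any(x$quality != "ok"))
    cat(sprintf("  %d azimuth(s) extrapolated\n", sum(x$quality != "ok")))
  invisible(x)
}
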