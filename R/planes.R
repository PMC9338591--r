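#' The seven named clinical radial planes
#'
#' Radial planes are named anterior (0), anterior-superior (30),
#' superior-anterior (60), superior (90), superior-posterior (120),
#' posterior-superior (150) and posterior (180 degrees), running from
#' anterior to posterior through superior.
#'
#' @return named numeric vector of azimuths in degrees.
#' @export
named_plane_azimuths <- function() {
  c(anterior = 0, `anterior-superior` = 30, `superior-anterior` = 60,
    superior = 90, `superior-posterior` = 120, `posterior-superior` = 150,
    posterior = 180)
}

#' Map an alpha profile onto the seven named clinical planes
#'
#' Each named plane takes the profile value at the nearest computed azimuth
#' (circular distance); the chosen azimuth is recorded. A warning is issued
#' when the nearest azimuth is farther away than one azimuth step.
#'
#' @param profile an `alpha_profile` (from [alpha_by_optimal_cut()]).
#' @param hip_id identifier written into the output rows.
#' @param rater rater label (default `"software"`).
#' @return data.frame with columns `hip_id`, `plane`, `rater`, `alpha_deg`,
#'   plus `plane_azimuth_deg` (nominal) and `matched_azimuth_deg` (used).
#' @export
select_named_planes <- function(profile, hip_id = "hip", rater = "software") {
  az <- profile$azimuth_deg
  step <- if (length(az) > 1) min(diff(sort(az))) else 360
  planes <- named_plane_azimuths()
  out <- lapply(names(planes), function(nm) {
    target <- planes[[nm]]
    d <- abs((az - target + 180) %% 360 - 180)
    i <- which.min(d)
    if (d[i] > step + 1e-9)
      warning(sprintf("plane '%s': nearest computed azimuth %.1f deg is %.1f deg away",
                      nm, az[i], d[i]))
    data.frame(hip_id = hip_id, plane = nm, rater = rater,
               alpha_deg = profile$alpha_deg[i],
               plane_azimuth_deg = target, matched_azimuth_deg = az[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold an alpha profile into full planes (max of the half-plane pair)
#'
#' A clinical radial image is a full plane; its two half-planes phi and
#' phi + 180 are measured separately by the pipeline. This convenience view
#' reports, for each azimuth in `[0, 180)`, the larger of the two half-plane
#' values - the reading a worst-case clinical assessment would take.
#'
#' @param profile an `alpha_profile` covering `[0, 360)`.
#' @return data.frame with `azimuth_deg` in `[0, 180)` and `alpha_deg`.
#' @export
alpha_profile_pairs <- function(profile) {
  az <- profile$azimuth_deg
  half <- az[az < 180]
  opp <- (half + 180) %% 360
  idx_opp <- match(opp, az)
  a1 <- profile$alpha_deg[az < 180]
  a2 <- profile$alpha_deg[idx_opp]
  data.frame(azimuth_deg = half,
             alpha_deg = pmax(a1, ifelse(is.na(a2), a1, a2)))
}
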