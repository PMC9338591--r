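#' Read and write long-format alpha-angle measurement tables
#'
#' A measurement table holds one row per (hip, plane, rater) with the measured
#' alpha angle in degrees: columns `hip_id`, `plane`, `rater`, `alpha_deg`.
#' `plane` is either one of the seven named clinical planes (see
#' [select_named_planes()]) or an azimuth in degrees. Alpha values must lie
#' strictly between 0 and 180 degrees and (hip_id, plane, rater) must be
#' unique; offending rows are reported by row number.
#'
#' @param path CSV file with header `hip_id,plane,rater,alpha_deg`.
#' @return `read_measurements` returns a `data.frame` with the four columns;
#'   `write_measurements` invisibly returns `path`.
#' @examples
#' tab <- data.frame(hip_id = "h1", plane = "superior",
#'                   rater = c("obs1", "software"), alpha_deg = c(57, 55))
#' f <- tempfile(fileext = ".csv")
#' write_measurements(tab, f)
#' read_measurements(f)
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    abort_camangle(sprintf("file not found: %s", path), "io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hip_id", "plane", "rater", "alpha_deg")
  if (!all(need %in% names(tab)))
    abort_camangle(sprintf("missing columns: %s",
                           paste(setdiff(need, names(tab)), collapse = ", ")),
                   "validation_error")
  tab <- tab[, need, drop = FALSE]
  validate_measurements(tab)
  tab
}

#' @rdname read_measurements
#' @param table data.frame with columns `hip_id`, `plane`, `rater`, `alpha_deg`.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_measurements <- function(table) {
  if (nrow(table) == 0) return(invisible(table))
  alpha <- suppressWarnings(as.numeric(table$alpha_deg))
  bad <- which(!is.finite(alpha) | alpha <= 0 | alpha >= 180)
  if (length(bad))
    abort_camangle(sprintf("alpha_deg outside (0, 180) or non-numeric at row(s): %s",
                           paste(bad, collapse = ", ")),
                   "validation_error")
  key <- paste(table$hip_id, table$plane, table$rater, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    abort_camangle(sprintf("duplicate (hip_id, plane, rater) at row(s): %s",
                           paste(dup, collapse = ", ")),
                   "validation_error")
  invisible(table)
}
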