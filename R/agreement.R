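#' Intraclass correlation for absolute agreement (two-way random, single)
#'
#' Computes the single-measure, absolute-agreement ICC under the two-way
#' random-effects model (ICC(A,1) in the McGraw-Wong taxonomy): the standard
#' choice when the same raters rate every unit and systematic offsets
#' between raters should count against agreement. Mean squares come from the
#' two-way ANOVA decomposition (between subjects, between raters, residual);
#' the 95% confidence interval uses the standard F-based interval and the
#' p-value the F test of the between-subjects effect.
#'
#' Units of analysis are (hip, plane) combinations by default - pooling all
#' planes of all hips into one column per rater - with `unit = "hip"`
#' aggregating to per-hip means first.
#'
#' @param table measurement table (columns `hip_id`, `plane`, `rater`,
#'   `alpha_deg`), complete in the two chosen raters.
#' @param raters character vector of exactly two rater labels to compare.
#' @param unit `"plane"` (default: hip x plane units) or `"hip"`.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_agreement`: `icc`, `ci95` (low, high),
#'   `p_value`, `reliability_band`, `n_subjects`, `n_raters`, `ms`
#'   (mean squares), `model`.
#' @examples
#' tab <- simulate_rating_table(icc = 0.9, seed = 1)
#' icc_absolute(tab, raters = c("rater1", "rater2"))
#' @export
icc_absolute <- function(table, raters, unit = c("plane", "hip"),
                         conf_level = 0.95) {
  unit <- match.arg(unit)
  if (length(raters) != 2)
    abort_camangle("exactly two raters must be named", "validation_error")
  tab <- table[table$rater %in% raters, , drop = FALSE]
  if (unit == "hip") {
    agg <- stats::aggregate(alpha_deg ~ hip_id + rater, data = tab, FUN = mean)
    agg$plane <- "all"
    tab <- agg
  }
  tab$unit_id <- paste(tab$hip_id, tab$plane, sep = "\r")
  units <- unique(tab$unit_id)
  n <- length(units)
  if (n < 5)
    abort_camangle(sprintf("need at least 5 units, got %d", n), "sample_size_error")
  wide <- matrix(NA_real_, n, 2, dimnames = list(units, raters))
  for (j in 1:2) {
    sub <- tab[tab$rater == raters[j], ]
    if (anyDuplicated(sub$unit_id))
      abort_camangle("duplicate ratings for a unit/rater", "validation_error")
    wide[match(sub$unit_id, units), j] <- sub$alpha_deg
  }
  if (anyNA(wide))
    abort_camangle("incomplete two-way layout: every unit must be rated by both raters (no imputation)",
                   "missing_data_error")
  k <- 2
  long <- data.frame(y = as.vector(wide),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used, so anova's F-test caveat on perfect
  # fits (identical raters) is irrelevant here
  aov_tab <- withCallingHandlers(
    stats::anova(stats::aov(y ~ subject + rater, data = long)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  msr <- aov_tab["subject", "Mean Sq"]
  msc <- aov_tab["rater", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  eps <- 1e-12 * max(msr, 1)
  perfect <- mse < eps && msc < eps
  icc <- if (perfect || denom == 0) 1 else (msr - mse) / denom

  alpha <- 1 - conf_level
  if (perfect) {
    ci <- c(1, 1)
    p <- 0
  } else {
    # Satterthwaite df of the denominator combination (standard A,1 interval)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
    p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci95 = ci, p_value = p,
                 reliability_band = classify_reliability(icc),
                 n_subjects = n, n_raters = k,
                 ms = c(subjects = msr, raters = msc, residual = mse),
                 model = "two-way random effects, absolute agreement, single measures"),
            class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("ICC (absolute agreement, single measures): %.3f [%.3f-%.3f], p %s\n",
              x$icc, x$ci95[1], x$ci95[2],
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  cat(sprintf("  %s reliability; %d units x %d raters (%s)\n",
              x$reliability_band, x$n_subjects, x$n_raters, x$model))
  invisible(x)
}

#' Reliability band of an ICC value
#'
#' Classifies an ICC into the conventional reliability bands: above 0.9
#' excellent, 0.75 up to 0.9 good, 0.5 up to 0.75 moderate, below 0.5 poor.
#'
#' @param icc numeric vector of ICC values in `[-1, 1]`.
#' @return character vector: `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @examples
#' classify_reliability(c(0.93, 0.77, 0.45))
#' @export
classify_reliability <- function(icc) {
  if (any(icc < -1 | icc > 1, na.rm = TRUE))
    abort_camangle("icc must lie in [-1, 1]", "validation_error")
  ifelse(icc > 0.9, "excellent",
         ifelse(icc >= 0.75, "good",
                ifelse(icc >= 0.5, "moderate", "poor")))
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 95% limits of agreement
#' (bias +/- 1.96 * SD of differences, sample SD with n - 1) of two paired
#' measurement series, plus the plotting coordinates (pair means vs
#' differences).
#'
#' @param x,y paired numeric vectors, equal length >= 3, no missing pairs.
#' @return An object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`, `means`, `diffs`. A `plot` method draws the classic
#'   three-dashed-line display.
#' @examples
#' ba <- bland_altman(c(55, 60, 62, 58), c(54, 63, 60, 59))
#' ba$bias
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    abort_camangle("x and y must have equal length", "validation_error")
  if (length(x) < 3)
    abort_camangle("need at least 3 pairs", "validation_error")
  if (anyNA(x) || anyNA(y))
    abort_camangle("missing pairs are not allowed", "validation_error")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * sdd,
                 loa_high = bias + 1.96 * sdd, sd_diff = sdd,
                 n = length(x), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f, limits of agreement [%.2f, %.2f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference of methods", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Paired t-test of two measurement series
#'
#' Thin wrapper around the standard paired t-test returning the quantities
#' the comparison workflow reports; zero-variance differences are flagged as
#' degenerate instead of erroring.
#'
#' @param x,y paired numeric vectors, equal length >= 3.
#' @return list of class `paired_t`: `t`, `p_value`, `mean_diff`, `df`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    abort_camangle("x and y must have equal length", "validation_error")
  if (length(x) < 3)
    abort_camangle("need at least 3 pairs", "validation_error")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, p_value = NA_real_,
                          mean_diff = mean(d), df = length(x) - 1,
                          degenerate = TRUE),
                     class = "paired_t"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(t = unname(tt$statistic), p_value = tt$p.value,
                 mean_diff = unname(tt$estimate), df = unname(tt$parameter),
                 degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired t: degenerate (zero-variance differences), mean diff %.3f\n",
                x$mean_diff))
  } else {
    cat(sprintf("paired t: t = %.3f (df %d), p = %.4g, mean diff %.3f\n",
                x$t, x$df, x$p_value, x$mean_diff))
  }
  invisible(x)
}

#' Per-rater summary of a measurement table
#'
#' Mean, SD, minimum, maximum and quartiles (linear interpolation between
#' order statistics) of alpha angles per rater - the layout of the usual
#' per-method summary table.
#'
#' @param table measurement table (columns `hip_id`, `plane`, `rater`,
#'   `alpha_deg`).
#' @return data.frame with one row per rater: `rater`, `n`, `mean`, `sd`,
#'   `min`, `max`, `p25`, `p50`, `p75`.
#' @export
summarize_measurements <- function(table) {
  if (nrow(table) == 0)
    abort_camangle("empty measurement table", "validation_error")
  out <- lapply(split(table$alpha_deg, table$rater), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), p25 = q[1], p50 = q[2], p75 = q[3])
  })
  res <- do.call(rbind, out)
  res <- cbind(rater = names(out), res)
  rownames(res) <- NULL
  res
}

#' Simulate a two-rater measurement table with known intraclass correlation
#'
#' Generates `n_subjects` x `n_planes` units whose true alpha angles are
#' i.i.d. Normal(`mean_deg`, `sd_deg`); each rater observes the truth plus
#' independent Normal noise whose SD is set so the generating intraclass
#' correlation equals `icc`
#' (`sigma_rater = sd_deg * sqrt(1 / icc - 1)`).
#'
#' @param n_subjects number of hips (default 19).
#' @param n_planes planes per hip (default 7).
#' @param icc generating intraclass correlation in (0, 1].
#' @param mean_deg,sd_deg distribution of true alpha angles (57 and 6 by
#'   default: adult cohort scale).
#' @param raters two rater labels.
#' @param seed RNG seed.
#' @return measurement table data.frame (`hip_id`, `plane`, `rater`,
#'   `alpha_deg`).
#' @export
simulate_rating_table <- function(n_subjects = 19, n_planes = 7, icc = 0.8,
                                  mean_deg = 57, sd_deg = 6,
                                  raters = c("rater1", "rater2"), seed = 1L) {
  if (icc <= 0 || icc > 1)
    abort_camangle("icc must lie in (0, 1]", "validation_error")
  sig <- sd_deg * sqrt(1 / icc - 1)
  with_seed(seed, {
    nu <- n_subjects * n_planes
    truth <- stats::rnorm(nu, mean_deg, sd_deg)
    hips <- rep(sprintf("hip%02d", seq_len(n_subjects)), each = n_planes)
    planes <- rep(sprintf("plane%d", seq_len(n_planes)), times = n_subjects)
    do.call(rbind, lapply(seq_along(raters), function(j) {
      data.frame(hip_id = hips, plane = planes, rater = raters[j],
                 alpha_deg = truth + stats::rnorm(nu, 0, sig),
                 stringsAsFactors = FALSE)
    }))
  })
}
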