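toy_table <- function(a, b, raters = c("r1", "r2")) {
  n <- length(a)
  rbind(data.frame(hip_id = sprintf("h%d", 1:n), plane = "anterior",
                   rater = raters[1], alpha_deg = a),
        data.frame(hip_id = sprintf("h%d", 1:n), plane = "anterior",
                   rater = raters[2], alpha_deg = b))
}

test_that("identical rating columns give ICC exactly 1", {
  a <- c(50, 55, 60, 65, 70, 75)
  res <- icc_absolute(toy_table(a, a), raters = c("r1", "r2"))
  expect_identical(res$icc, 1)
  expect_equal(res$ci95, c(1, 1))
  expect_equal(res$reliability_band, "excellent")
})

test_that("ICC matches an independent mean-squares oracle to 1e-10", {
  a <- c(51.2, 63.7, 47.9, 58.4, 72.1, 55.0)
  b <- c(54.0, 60.1, 50.3, 61.8, 69.5, 57.7)
  res <- icc_absolute(toy_table(a, b), raters = c("r1", "r2"))
  expect_equal(res$icc, icc_oracle_a1(cbind(a, b)), tolerance = 1e-10)
  expect_lte(res$ci95[1], res$icc)
  expect_gte(res$ci95[2], res$icc)
  # and on a larger simulated table
  tab <- simulate_rating_table(icc = 0.7, seed = 4)
  res2 <- icc_absolute(tab, raters = c("rater1", "rater2"))
  w <- matrix(tab$alpha_deg, ncol = 2)
  expect_equal(res2$icc, icc_oracle_a1(w), tolerance = 1e-10)
})

test_that("absolute agreement penalises systematic offset while Pearson does not", {
  a <- c(50, 55, 60, 65, 70, 75)
  res <- icc_absolute(toy_table(a, a + 10), raters = c("r1", "r2"))
  expect_lt(res$icc, 1)
  expect_equal(stats::cor(a, a + 10), 1)
})

test_that("ICC is invariant to common shifts and subject relabelling", {
  a <- c(51.2, 63.7, 47.9, 58.4, 72.1, 55.0)
  b <- c(54.0, 60.1, 50.3, 61.8, 69.5, 57.7)
  r1 <- icc_absolute(toy_table(a, b), raters = c("r1", "r2"))
  r2 <- icc_absolute(toy_table(a + 25, b + 25), raters = c("r1", "r2"))
  expect_equal(r1$icc, r2$icc, tolerance = 1e-12)
  perm <- c(3, 1, 6, 2, 5, 4)
  r3 <- icc_absolute(toy_table(a[perm], b[perm]), raters = c("r1", "r2"))
  expect_equal(r1$icc, r3$icc, tolerance = 1e-12)
})

test_that("incomplete layouts and tiny samples are refused", {
  tab <- toy_table(c(50, 55, 60, 65, 70, 75), c(51, 56, 61, 66, 71, 76))
  expect_error(icc_absolute(tab[-1, ], raters = c("r1", "r2")),
               class = "missing_data_error")
  small <- toy_table(c(50, 55, 60), c(51, 56, 61))
  expect_error(icc_absolute(small, raters = c("r1", "r2")),
               class = "sample_size_error")
  expect_error(icc_absolute(tab, raters = "r1"), class = "validation_error")
})

test_that("reliability banding follows the conventional rule", {
  expect_equal(classify_reliability(0.77), "good")
  expect_equal(classify_reliability(0.93), "excellent")
  expect_equal(classify_reliability(0.45), "poor")
  expect_equal(classify_reliability(0.56), "moderate")
  # boundaries: 0.9 is good (excellent needs > 0.9), 0.75 good, 0.5 moderate
  expect_equal(classify_reliability(c(0.9, 0.75, 0.5, 0.4999)),
               c("good", "good", "moderate", "poor"))
  expect_error(classify_reliability(1.2), class = "validation_error")
})

test_that("Bland-Altman closed forms", {
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))  # differences -1, 0, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  x <- c(55, 60, 62, 58)
  same <- bland_altman(x, x)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  y <- c(54, 63, 60, 59)
  f <- bland_altman(x, y); g <- bland_altman(y, x)
  expect_equal(f$bias, -g$bias)
  expect_equal(f$loa_low, -g$loa_high)
  expect_error(bland_altman(1:4, 1:5), class = "validation_error")
  expect_error(bland_altman(1:2, 1:2), class = "validation_error")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  x <- c(61, 58, 66, 54)
  y <- c(57, 55, 60, 53)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (stats::sd(d) / sqrt(4))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 3)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_equal(res$mean_diff, mean(d))
  swapped <- paired_t(y, x)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  deg <- paired_t(x, x)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("per-rater summaries match a sort-based quantile oracle", {
  tab <- data.frame(hip_id = "h", plane = as.character(1:100), rater = "r",
                    alpha_deg = 1:100)
  s <- summarize_measurements(tab)
  expect_equal(s$p50, 50.5)
  expect_equal(s$min, 1); expect_equal(s$max, 100)
  const <- data.frame(hip_id = "h", plane = as.character(1:5), rater = "r",
                      alpha_deg = rep(57, 5))
  sc <- summarize_measurements(const)
  expect_equal(sc$sd, 0)
  expect_equal(unlist(sc[c("p25", "p50", "p75")], use.names = FALSE),
               rep(57, 3))
  set.seed(8)
  v <- stats::rnorm(37, 60, 10)
  sv <- summarize_measurements(data.frame(hip_id = "h",
                                          plane = as.character(1:37),
                                          rater = "r", alpha_deg = v))
  # oracle: linear interpolation between order statistics
  oracle_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(sv$p25, oracle_q(v, 0.25), tolerance = 1e-12)
  expect_equal(sv$p75, oracle_q(v, 0.75), tolerance = 1e-12)
})

test_that("estimated ICC approaches 1 as rater noise vanishes and decreases with noise", {
  iccs <- vapply(c(0.999, 0.9, 0.6), function(rho) {
    vals <- vapply(1:20, function(s)
      icc_absolute(simulate_rating_table(icc = rho, seed = s),
                   raters = c("rater1", "rater2"))$icc, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(iccs[1], 0.99)
  expect_true(all(diff(iccs) < 0))
})
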