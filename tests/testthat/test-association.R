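test_that("bonferroni threshold is alpha over n_tests", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 0.05), 5e-4)
  expect_error(bonferroni_threshold(0), "n_tests")
  expect_error(bonferroni_threshold(10, 1.5), "alpha")
})

test_that("per-site fit recovers exact linear signal and handles degeneracy", {
  cov <- toy_covariates(50)
  y_lin <- 0.2 + 0.005 * cov$age
  y_const <- rep(0.4, 50)
  m <- row_matrix(list(y_lin, y_const), cov)
  res <- fit_all_sites(m, cov)
  expect_lt(res$p_age[1], 1e-12)
  expect_equal(res$correlation[1], 1)
  expect_equal(res$slope_age[1], 0.005, tolerance = 1e-9)

  expect_equal(res$correlation[2], 0)
  expect_true(is.na(res$p_age[2]))
  cls <- classify_sites(res)
  expect_equal(cls$class[2], "uncorrelated")

  # single-site wrapper agrees with the matrix path
  one <- fit_site(setNames(y_lin, cov$sample_id), cov)
  expect_equal(one$slope_age, res$slope_age[1])
  expect_equal(one$p_age, res$p_age[1])
})

test_that("fit reduces to simple regression when sex and bmi are constant", {
  cov <- toy_covariates(30)
  cov$sex <- 0
  cov$bmi <- 25
  set.seed(3)
  y <- 0.3 + 0.002 * cov$age + rnorm(30, 0, 0.01)
  res <- fit_all_sites(row_matrix(list(y), cov), cov)
  closed_form <- sum((cov$age - mean(cov$age)) * (y - mean(y))) /
    sum((cov$age - mean(cov$age))^2)
  expect_equal(res$slope_age, closed_form, tolerance = 1e-12)
})

test_that("age p-values are uniform under the null", {
  cov <- toy_covariates(60, seed = 12)
  set.seed(13)
  m <- matrix(runif(2000 * 60, 0.2, 0.8), 2000, 60,
              dimnames = list(sprintf("cg%04d", 1:2000), cov$sample_id))
  res <- fit_all_sites(m, cov)
  rate <- mean(res$p_age < 0.05)
  # binomial CI around 0.05 at n = 2000
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # missing values: the complete-case fallback agrees with a complete fit
  # restricted to the same samples
  m2 <- m[1:5, , drop = FALSE]
  m2[, 1:10] <- NA
  res_na <- fit_all_sites(m2, cov)
  res_cc <- fit_all_sites(m[1:5, -(1:10), drop = FALSE], cov[-(1:10), ])
  expect_equal(res_na$slope_age, res_cc$slope_age, tolerance = 1e-12)
  expect_equal(res_na$p_age, res_cc$p_age, tolerance = 1e-10)
  expect_equal(res_na$n_used, rep(50L, 5))
})

test_that("classification partitions sites into the four classes", {
  res <- data.frame(probe_id = c("a", "b", "c"),
                    n_used = 400L, slope_age = c(0.001, -0.001, 0),
                    correlation = c(0.5, -0.5, 0.1),
                    p_age = c(1e-9, 0.5, 1e-3), stringsAsFactors = FALSE)
  cls <- classify_sites(res, n_tests = 476366, alpha = 0.05)
  expect_equal(cls$class, c("hyper", "uncorrelated", "suggestive"))
  expect_equal(attr(cls, "threshold"), 0.05 / 476366)

  set.seed(14)
  rnd <- data.frame(probe_id = sprintf("cg%04d", 1:500), n_used = 100L,
                    slope_age = rnorm(500),
                    correlation = runif(500, -1, 1),
                    p_age = runif(500)^3, stringsAsFactors = FALSE)
  rnd$p_age[sample(500, 5)] <- NA
  cls <- classify_sites(rnd, n_tests = 500)
  expect_true(all(cls$class %in% c("hyper", "hypo", "suggestive", "uncorrelated")))
  expect_equal(sum(table(cls$class)), 500)
  expect_true(all(cls$class[!is.na(cls$p_age) & cls$p_age > 0.05] == "uncorrelated"))
  expect_true(all(is.na(cls$p_age[cls$class == "uncorrelated"]) |
                  cls$p_age[cls$class == "uncorrelated"] > 0.05))
})

test_that("interaction scan detects a planted sex-by-age slope and little else", {
  set.seed(15)
  n <- 400
  cov <- data.frame(sample_id = sprintf("S%04d", 1:n),
                    age = runif(n, 14, 94), sex = rep(c(0, 1), n / 2),
                    bmi = rnorm(n, 26, 3), stringsAsFactors = FALSE)
  y_int <- 0.2 + 0.005 * cov$age * cov$sex + rnorm(n, 0, 0.02)
  null_rows <- lapply(1:200, function(i) 0.5 + rnorm(n, 0, 0.05))
  m <- row_matrix(c(list(y_int), null_rows), cov)
  scan <- interaction_scan(m, cov, n_tests = 5000)
  expect_true(scan$significant[1])
  expect_lte(sum(scan$significant[-1]), 1)

  cov1 <- cov; cov1$sex <- 0
  expect_error(interaction_scan(m, cov1), "both sexes")
})

test_that("x-linked sites dominate the significant interaction list", {
  ds <- small_dataset()
  scan <- interaction_scan(ds$beta, ds$cohort,
                           n_tests = nrow(ds$beta$values))
  sig <- scan$probe_id[scan$significant]
  expect_gt(length(sig), 0)
  chroms <- ds$catalog$manifest$chrom[match(sig, ds$catalog$manifest$probe_id)]
  expect_gt(mean(chroms == "chrX"), 0.8)
})

test_that("cohort quantile trends match a sort-based oracle and detect drift", {
  cov <- toy_covariates(30)
  set.seed(16)
  m <- matrix(runif(200 * 30), 200, 30,
              dimnames = list(sprintf("cg%03d", 1:200), cov$sample_id))
  # sort-based type-7 quantile oracle for one sample
  q_oracle <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p
    lo <- floor(h) + 1
    x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
  }
  med <- apply(m, 2, q_oracle, p = 0.5)
  y <- apply(m, 2, stats::median)
  expect_equal(unname(y), unname(med))

  tr <- cohort_trends(m, cov)
  expect_setequal(tr$statistic, c("mean", "q1", "median", "q3"))
  expect_true(all(abs(tr$correlation_with_age) <
                  3 / sqrt(nrow(cov))))  # null data: near zero

  ds <- small_dataset()
  auto <- ds$catalog$manifest$probe_id[ds$catalog$manifest$chrom != "chrX"]
  tr2 <- cohort_trends(ds$beta, ds$cohort, sites = auto)
  expect_gt(tr2$correlation_with_age[tr2$statistic == "q1"], 0)
  expect_lt(tr2$correlation_with_age[tr2$statistic == "q3"], 0)
})

test_that("sex median test equals the exhaustive rank statistic on a toy", {
  med_m <- c(0.50, 0.52, 0.48, 0.51, 0.49)
  med_f <- c(0.55, 0.56, 0.54, 0.53, 0.57)
  n <- 5
  # build a 1-site matrix whose per-sample median IS the value
  m <- matrix(c(med_m, med_f), 1, 10,
              dimnames = list("cg1", sprintf("S%02d", 1:10)))
  cov <- data.frame(sample_id = sprintf("S%02d", 1:10),
                    age = 30, sex = rep(c(1, 0), each = 5), bmi = 25,
                    stringsAsFactors = FALSE)
  res <- sex_median_test(m, cov)
  ranks <- rank(c(med_m, med_f))
  w_oracle <- sum(ranks[1:5]) - n * (n + 1) / 2
  expect_equal(unname(res$statistic), w_oracle)

  # location-shifted male medians are detected with n = 200 + 200
  set.seed(17)
  big <- matrix(c(runif(200, 0.4, 0.6) - 0.02, runif(200, 0.4, 0.6)), 1, 400,
                dimnames = list("cg1", sprintf("S%04d", 1:400)))
  cov2 <- data.frame(sample_id = sprintf("S%04d", 1:400), age = 30,
                     sex = rep(c(1, 0), each = 200), bmi = 25,
                     stringsAsFactors = FALSE)
  expect_lt(sex_median_test(big, cov2)$p.value, 0.05)
  expect_error(sex_median_test(m, within(cov, sex <- c(1, rep(0, 9)))),
               "at least 2")
})
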