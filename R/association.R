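# Per-site linear modelling of beta values on chronological age with sex and
# BMI as covariates. Significance of the age term comes from the adjusted
# model; the per-site "correlation" reported alongside is the marginal Pearson
# r of beta vs age (the quantity the figure/selection language refers to).
# Classification uses a Bonferroni threshold over the number of tested sites.

#' Bonferroni-adjusted significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate, in (0, 1) (default 0.05).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(476366, 0.05)  # 1.049613e-07
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a single integer >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

# Build the (intercept, covariates...) design from a covariate table,
# restricted to samples with complete covariates. Constant covariate columns
# are dropped so e.g. a single-sex cohort reduces cleanly to fewer terms.
build_design <- function(covariates, covariate_cols = c("age", "sex", "bmi"),
                         interaction = FALSE) {
  stopifnot("age" %in% covariate_cols)
  cols <- intersect(covariate_cols, colnames(covariates))
  M <- as.matrix(covariates[, cols, drop = FALSE])
  used <- which(stats::complete.cases(M))
  M <- M[used, , drop = FALSE]
  keep <- apply(M, 2, function(v) stats::sd(v) > 0)
  keep["age"] <- TRUE
  M <- M[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, M)
  if (interaction) {
    if (!"sex" %in% colnames(M)) stop("both sexes must be present for an interaction scan")
    X <- cbind(X, `age:sex` = M[, "age"] * M[, "sex"])
  }
  list(X = X, used = used)
}

# OLS of each matrix row on design X; returns the estimate, two-sided t-test
# p-value and n for the requested term. Rows with missing values fall back to
# a per-row complete-case fit; rank-deficient per-row designs (e.g. constant
# age among the used samples) yield NA p-values.
ols_term_stats <- function(values, X, term) {
  n <- nrow(X); p <- ncol(X); m <- nrow(values)
  ti <- match(term, colnames(X))
  est <- rep(NA_real_, m); pv <- rep(NA_real_, m); nu <- rep(0L, m)
  complete <- rowSums(is.na(values)) == 0
  if (any(complete) && n > p) {
    Y <- t(values[complete, , drop = FALSE])
    fit <- stats::lm.fit(X, Y)
    coefs <- fit$coefficients
    if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
    res <- as.matrix(fit$residuals)
    df <- n - p
    s2 <- colSums(res^2) / df
    R <- qr.R(fit$qr)
    xtx_inv <- chol2inv(R)
    se <- sqrt(pmax(s2 * xtx_inv[ti, ti], 0))
    tt <- coefs[ti, ] / se
    pvals <- 2 * stats::pt(-abs(tt), df)
    pvals[!is.finite(coefs[ti, ])] <- NA_real_
    # degenerate rows (constant beta): zero residuals and zero slope
    pvals[is.nan(tt) | (s2 <= 1e-24 & abs(coefs[ti, ]) <= 1e-10)] <- NA_real_
    est[complete] <- coefs[ti, ]
    pv[complete] <- pvals
    nu[complete] <- n
  }
  for (i in which(!complete)) {
    ok <- !is.na(values[i, ])
    nu[i] <- sum(ok)
    if (sum(ok) < p + 2) next
    Xi <- X[ok, , drop = FALSE]
    qri <- qr(Xi)
    if (qri$rank < p) next  # rank-deficient: flagged via NA p
    fi <- stats::lm.fit(Xi, values[i, ok])
    df <- sum(ok) - p
    s2 <- sum(fi$residuals^2) / df
    se <- sqrt(max(s2 * chol2inv(qr.R(fi$qr))[ti, ti], 0))
    tt <- fi$coefficients[ti] / se
    est[i] <- fi$coefficients[ti]
    pv[i] <- if (is.nan(tt) ||
                 (s2 <= 1e-24 && abs(fi$coefficients[ti]) <= 1e-10))
      NA_real_ else 2 * stats::pt(-abs(tt), df)
  }
  data.frame(n_used = nu, estimate = est, p = pv)
}

#' Fit the age model at every site
#'
#' Ordinary least squares of beta on age, sex and BMI (complete cases per
#' site), with the two-sided t-test p-value of the age coefficient, plus the
#' marginal Pearson correlation of beta with age. Constant-beta or
#' rank-deficient sites get a zero correlation and missing p-value (and are
#' classified uncorrelated downstream).
#'
#' @param x a [beta_matrix()] or numeric sites-x-samples matrix.
#' @param covariates covariates data.frame with `sample_id` matching the
#'   matrix columns.
#' @param covariate_cols covariates entering the model (must include "age").
#' @return data.frame: probe_id, n_used, slope_age, correlation, p_age.
#' @export
fit_all_sites <- function(x, covariates, covariate_cols = c("age", "sex", "bmi")) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  if (any(is.na(covariates$sample_id)))
    stop("covariates missing for some samples in the beta matrix")
  d <- build_design(covariates, covariate_cols)
  st <- ols_term_stats(values[, d$used, drop = FALSE], d$X, "age")
  age <- covariates$age[d$used]
  r <- suppressWarnings(
    as.vector(stats::cor(t(values[, d$used, drop = FALSE]), age,
                         use = "pairwise.complete.obs")))
  r[is.na(r)] <- 0
  data.frame(probe_id = rownames(values), n_used = st$n_used,
             slope_age = st$estimate, correlation = r, p_age = st$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the age model at a single site
#'
#' @param beta_row named numeric vector of betas (names = sample ids).
#' @param covariates covariates data.frame.
#' @param covariate_cols covariates entering the model.
#' @return one-row data.frame as in [fit_all_sites()].
#' @export
fit_site <- function(beta_row, covariates, covariate_cols = c("age", "sex", "bmi")) {
  m <- matrix(beta_row, nrow = 1,
              dimnames = list("site", names(beta_row)))
  fit_all_sites(m, covariates, covariate_cols)
}

#' Classify sites as hyper/hypo/suggestive/uncorrelated
#'
#' Hyper: Bonferroni-significant age term with positive age correlation;
#' hypo: significant with negative correlation; uncorrelated: nominal
#' p > 0.05 (or no valid p); suggestive: the remainder (nominally but not
#' Bonferroni significant). The four classes partition the tested sites.
#'
#' @param results output of [fit_all_sites()].
#' @param n_tests Bonferroni denominator (default: number of rows, i.e. the
#'   number of probes actually tested).
#' @param alpha family-wise alpha (default 0.05).
#' @return `results` with `class` and `adjusted_p` columns; the threshold is
#'   attached as attributes `n_tests` and `threshold`.
#' @export
classify_sites <- function(results, n_tests = nrow(results), alpha = 0.05) {
  thr <- bonferroni_threshold(n_tests, alpha)
  p <- results$p_age
  r <- results$correlation
  cls <- rep("suggestive", nrow(results))
  cls[is.na(p) | p > 0.05] <- "uncorrelated"
  sig <- !is.na(p) & p < thr
  cls[sig & r > 0] <- "hyper"
  cls[sig & r < 0] <- "hypo"
  results$adjusted_p <- pmin(1, p * n_tests)
  results$class <- cls
  attr(results, "n_tests") <- n_tests
  attr(results, "threshold") <- thr
  results
}

#' Scan for sex-by-age interactions
#'
#' Fits beta ~ age + sex + bmi + sex:age at every site and reports the
#' interaction p-value; sites Bonferroni-significant at `alpha / n_tests`
#' are flagged.
#'
#' @param x a [beta_matrix()] or matrix.
#' @param covariates covariates data.frame (both sexes required).
#' @param n_tests Bonferroni denominator (default: number of sites).
#' @param alpha family-wise alpha.
#' @return data.frame: probe_id, n_used, interaction_estimate,
#'   p_interaction, significant.
#' @export
interaction_scan <- function(x, covariates, n_tests = NULL, alpha = 0.05) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  if (length(unique(stats::na.omit(covariates$sex))) < 2)
    stop("interaction scan requires both sexes in the cohort")
  d <- build_design(covariates, interaction = TRUE)
  st <- ols_term_stats(values[, d$used, drop = FALSE], d$X, "age:sex")
  if (is.null(n_tests)) n_tests <- nrow(values)
  thr <- bonferroni_threshold(n_tests, alpha)
  data.frame(probe_id = rownames(values), n_used = st$n_used,
             interaction_estimate = st$estimate, p_interaction = st$p,
             significant = !is.na(st$p) & st$p < thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort-level distributional trends with age
#'
#' Computes each sample's mean, first quartile, median and third quartile of
#' beta over the supplied (typically autosomal) sites and correlates each
#' statistic with age (Pearson). A cohort drifting toward hemimethylation
#' shows a rising Q1 and falling median/Q3.
#'
#' @param x a [beta_matrix()] or matrix.
#' @param covariates covariates data.frame.
#' @param sites optional site ids (or indices) to restrict to, e.g. autosomal
#'   probes.
#' @return data.frame: statistic, correlation_with_age, p.
#' @export
cohort_trends <- function(x, covariates, sites = NULL) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  if (!is.null(sites)) values <- values[sites, , drop = FALSE]
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  if (ncol(values) < 3) stop("at least 3 samples required")
  qs <- apply(values, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              na.rm = TRUE)
  stat_vals <- rbind(mean = colMeans(values, na.rm = TRUE),
                     q1 = qs[1, ], median = qs[2, ], q3 = qs[3, ])
  out <- lapply(rownames(stat_vals), function(s) {
    ct <- stats::cor.test(stat_vals[s, ], covariates$age)
    data.frame(statistic = s, correlation_with_age = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare median methylation between sexes
#'
#' Wilcoxon rank-sum test of the per-sample median beta (over the supplied
#' sites) between males and females.
#'
#' @param x a [beta_matrix()] or matrix.
#' @param covariates covariates data.frame.
#' @param sites optional site restriction (e.g. autosomal probes).
#' @return an `htest` object from [stats::wilcox.test()].
#' @export
sex_median_test <- function(x, covariates, sites = NULL) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  if (!is.null(sites)) values <- values[sites, , drop = FALSE]
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  med <- apply(values, 2, stats::median, na.rm = TRUE)
  male <- med[covariates$sex == 1]
  female <- med[covariates$sex == 0]
  if (length(male) < 2 || length(female) < 2)
    stop("each sex needs at least 2 samples")
  stats::wilcox.test(male, female)
}
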