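# PCA of the beta matrix with samples as observations and sites as variables
# (site-wise mean centering, no scaling: betas share a natural [0,1] scale),
# followed by attribution of methylation variance to age: for each component,
# the squared Spearman correlation of its scores with age times the
# component's variance proportion, summed over components.

#' Principal component analysis of a beta matrix
#'
#' Missing betas are mean-imputed per site before decomposition. The SVD of
#' the column-centered samples-x-sites matrix gives sample scores and variance
#' proportions (squared singular values over their total).
#'
#' @param x a [beta_matrix()] or sites-x-samples matrix.
#' @return list with `scores` (samples x components), `prop_var`, and
#'   `sdev`.
#' @export
run_pca <- function(x) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  if (ncol(values) < 3) stop("PCA requires at least 3 samples")
  if (anyNA(values)) {
    mu <- rowMeans(values, na.rm = TRUE)
    mu[is.nan(mu)] <- 0.5
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- mu[idx[, 1]]
  }
  X <- t(values)                              # samples x sites
  Xc <- sweep(X, 2, colMeans(X), "-")
  s <- svd(Xc)
  ev <- s$d^2
  scores <- s$u %*% diag(s$d, nrow = length(s$d))
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_along(s$d))
  list(scores = scores, prop_var = ev / sum(ev),
       sdev = s$d / sqrt(max(1, nrow(X) - 1)))
}

#' Spearman correlation of PC scores with age
#'
#' @param scores samples x components score matrix from [run_pca()].
#' @param ages numeric vector aligned with the score rows.
#' @param n_components number of leading components to test (default 10).
#' @return data.frame: pc, rho, p_rho.
#' @export
pc_age_correlation <- function(scores, ages, n_components = 10) {
  k <- min(n_components, ncol(scores))
  out <- lapply(seq_len(k), function(i) {
    if (stats::sd(scores[, i]) == 0) stop("constant scores for component ", i)
    ct <- suppressWarnings(
      stats::cor.test(scores[, i], ages, method = "spearman", exact = FALSE))
    data.frame(pc = i, rho = unname(ct$estimate), p_rho = ct$p.value)
  })
  do.call(rbind, out)
}

#' Attribute methylation variance to age per principal component
#'
#' For component i, `attributed_i = rho_i^2 * prop_var_i`; cumulative columns
#' are prefix sums. Attribution is invariant to PC sign flips and bounded by
#' the component's variance proportion.
#'
#' @param prop_var variance proportions (non-increasing), one per component.
#' @param rho Spearman correlations with age for the leading components
#'   (the table covers `length(rho)` components).
#' @param p_rho optional p-values to carry through.
#' @return data.frame: pc, prop_var, cum_prop, rho, p_rho, attributed,
#'   cum_attributed.
#' @export
attribute_variance <- function(prop_var, rho, p_rho = NULL) {
  k <- length(rho)
  if (length(prop_var) < k) stop("prop_var shorter than rho")
  prop_var <- prop_var[seq_len(k)]
  if (any(abs(rho) > 1 + 1e-12)) stop("|rho| must not exceed 1")
  attributed <- rho^2 * prop_var
  data.frame(pc = seq_len(k), prop_var = prop_var,
             cum_prop = cumsum(prop_var), rho = rho,
             p_rho = if (is.null(p_rho)) NA_real_ else p_rho[seq_len(k)],
             attributed = attributed, cum_attributed = cumsum(attributed))
}

#' Full PCA-based variance attribution for a cohort
#'
#' Convenience wrapper: [run_pca()], [pc_age_correlation()] and
#' [attribute_variance()] in sequence.
#'
#' @param x a [beta_matrix()] or matrix.
#' @param covariates covariates data.frame aligned by sample_id.
#' @param n_components leading components to report (default 10).
#' @return the attribution data.frame (see [attribute_variance()]).
#' @export
variance_attribution <- function(x, covariates, n_components = 10) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  pca <- run_pca(values)
  corr <- pc_age_correlation(pca$scores, covariates$age, n_components)
  attribute_variance(pca$prop_var, corr$rho, corr$p_rho)
}
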