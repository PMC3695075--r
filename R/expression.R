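# Age trends in gene expression and their integration with the methylation
# results: per-probe OLS of expression on age and sex, direction calls at
# nominal p < 0.05, chi-square enrichment of direction classes within the
# hyper-/hypomethylated gene lists, and one-tailed Fisher tests for gene-set
# overlaps.

#' Fit age trends for every expression probe
#'
#' OLS of expression on age and sex per probe (complete cases). Direction:
#' `decrease` iff p < 0.05 and slope < 0, `increase` iff p < 0.05 and
#' slope > 0, otherwise `flat` (constant probes get a missing p and are flat).
#'
#' @param expr probes x samples expression matrix.
#' @param covariates covariates data.frame with sample_id, age, sex.
#' @param p_cutoff nominal direction cutoff (default 0.05).
#' @return data.frame: probe_id, n_used, slope_age, p, direction.
#' @export
fit_all_expression <- function(expr, covariates, p_cutoff = 0.05) {
  covariates <- covariates[match(colnames(expr), covariates$sample_id), ]
  if (any(is.na(covariates$sample_id)))
    stop("covariates missing for some samples in the expression matrix")
  d <- build_design(covariates, covariate_cols = c("age", "sex"))
  st <- ols_term_stats(expr[, d$used, drop = FALSE], d$X, "age")
  direction <- rep("flat", nrow(expr))
  ok <- !is.na(st$p) & st$p < p_cutoff
  direction[ok & st$estimate < 0] <- "decrease"
  direction[ok & st$estimate > 0] <- "increase"
  data.frame(probe_id = rownames(expr), n_used = st$n_used,
             slope_age = st$estimate, p = st$p, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the age trend for one expression probe
#' @param expr_row named numeric vector (names = sample ids).
#' @param covariates covariates data.frame.
#' @param p_cutoff nominal direction cutoff.
#' @return one-row data.frame as in [fit_all_expression()].
#' @export
fit_expression <- function(expr_row, covariates, p_cutoff = 0.05) {
  if (sum(!is.na(expr_row)) < 4) stop("at least 4 complete cases required")
  m <- matrix(expr_row, nrow = 1, dimnames = list("probe", names(expr_row)))
  fit_all_expression(m, covariates, p_cutoff)
}

# Collapse probe-level trends to gene level: each gene takes the direction of
# its most significant probe (ties by probe order).
gene_directions <- function(trends, gene_map) {
  d <- merge(trends, gene_map, by = "probe_id")
  d <- d[order(d$gene, d$p), ]
  d[!duplicated(d$gene), c("gene", "direction", "p", "slope_age")]
}

#' Enrichment of expression direction in a gene set
#'
#' For each direction (decrease, increase), builds the 2x2 table of gene-set
#' membership against having that direction and applies a chi-square test
#' without continuity correction. Gene-level direction is that of the gene's
#' most significant probe.
#'
#' @param trends probe-level trends from [fit_all_expression()].
#' @param gene_map data.frame probe_id, gene.
#' @param gene_set character vector of genes (must be a subset of the mapped
#'   genes).
#' @return data.frame: direction, in_set_frac, background_frac, statistic, p.
#' @export
direction_enrichment <- function(trends, gene_map, gene_set) {
  if (length(gene_set) == 0) stop("empty gene set")
  gd <- gene_directions(trends, gene_map)
  in_set <- gd$gene %in% gene_set
  if (!any(in_set)) stop("no gene-set members among the mapped genes")
  out <- lapply(c("decrease", "increase"), function(dir) {
    hit <- gd$direction == dir
    tab <- table(factor(in_set, c(TRUE, FALSE)), factor(hit, c(TRUE, FALSE)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(direction = dir,
               in_set_frac = mean(hit[in_set]),
               background_frac = mean(hit[!in_set]),
               statistic = unname(ct$statistic), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-tailed Fisher test for gene-set overlap
#'
#' Tests over-enrichment of the overlap between two gene sets within a
#' universe, via the one-tailed (greater) Fisher exact test on the 2x2
#' membership table.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
set_overlap_fisher <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
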