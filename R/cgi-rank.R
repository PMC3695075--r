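# Ranking CpG islands by the fraction of member sites whose methylation is
# significantly positively (hyper) or negatively (hypo) correlated with age.
# Only islands with more than `min_sites` measured sites (strictly, default 3)
# are scored, and one gene per island is drawn at random for downstream gene
# lists to avoid clusters of co-located, functionally similar genes biasing
# set-level analyses.

#' Score CpG islands by fraction of age-associated sites
#'
#' @param results classified association results (probe_id, class).
#' @param site_cgi named character vector (names = probe ids) giving each
#'   site's island id (`NA` for sites outside islands).
#' @param min_sites islands need strictly more than this many measured sites
#'   to be scored (default 3).
#' @param island_genes optional named character vector (names = cgi ids) of
#'   semicolon-joined gene symbols, carried into the output.
#' @return data.frame: cgi_id, n_sites, n_hyper, n_hypo, frac_hyper,
#'   frac_hypo, genes.
#' @export
score_cgis <- function(results, site_cgi, min_sites = 3, island_genes = NULL) {
  cgi <- site_cgi[results$probe_id]
  keep <- !is.na(cgi)
  cgi <- cgi[keep]
  cls <- results$class[keep]
  n_sites <- tapply(cls, cgi, length)
  n_hyper <- tapply(cls == "hyper", cgi, sum)
  n_hypo <- tapply(cls == "hypo", cgi, sum)
  ids <- names(n_sites)
  out <- data.frame(cgi_id = ids, n_sites = as.integer(n_sites),
                    n_hyper = as.integer(n_hyper), n_hypo = as.integer(n_hypo),
                    frac_hyper = as.numeric(n_hyper / n_sites),
                    frac_hypo = as.numeric(n_hypo / n_sites),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$genes <- if (is.null(island_genes)) NA_character_ else
    unname(island_genes[out$cgi_id])
  out <- out[out$n_sites > min_sites, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k islands in one direction
#'
#' Descending by the chosen fraction; ties broken by the number of
#' significant sites in that direction (descending), then island id
#' (ascending), so the ranking is total and deterministic.
#'
#' @param scores output of [score_cgis()].
#' @param direction `"hyper"` or `"hypo"`.
#' @param k number of islands to return.
#' @return the first `k` rows of the ranked score table (all rows, with a
#'   warning, if `k` exceeds the number of scored islands).
#' @export
top_k_cgis <- function(scores, direction = c("hyper", "hypo"), k = 500) {
  direction <- match.arg(direction)
  if (k < 0) stop("k must be non-negative")
  frac <- scores[[paste0("frac_", direction)]]
  nsig <- scores[[paste0("n_", direction)]]
  o <- order(-frac, -nsig, scores$cgi_id)
  ranked <- scores[o, , drop = FALSE]
  if (k > nrow(ranked)) {
    warning("k exceeds the number of scored islands; returning all ",
            nrow(ranked))
    k <- nrow(ranked)
  }
  out <- ranked[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One random gene per island
#'
#' For each ranked island with at least one annotated gene, one gene is drawn
#' uniformly at random (islands without genes are skipped); the resulting
#' list is de-duplicated keeping first occurrences. Deterministic under the
#' seed.
#'
#' @param ranked ranked score table with a `genes` column of semicolon-joined
#'   symbols.
#' @param seed integer RNG seed.
#' @return character vector of gene symbols; duplicates dropped after the
#'   first occurrence are reported in the `"duplicates"` attribute.
#' @export
one_gene_per_cgi <- function(ranked, seed = 1L) {
  with_seed(seed, {
    picks <- character(0)
    for (i in seq_len(nrow(ranked))) {
      g <- ranked$genes[i]
      if (is.na(g) || g == "") next
      opts <- strsplit(g, ";", fixed = TRUE)[[1]]
      picks <- c(picks, if (length(opts) == 1) opts else sample(opts, 1))
    }
    dup <- unique(picks[duplicated(picks)])
    out <- picks[!duplicated(picks)]
    attr(out, "duplicates") <- dup
    out
  })
}
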