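# Pipeline driver and command-line entry point. Subcommands bind the stages
# in dependency order (simulate -> qc -> associate/modes/pca -> annotate ->
# rank -> integrate); every output TSV carries a provenance header (package
# version, config hash, seed) so identical config + seed gives byte-identical
# outputs.

AUTOSOMES <- function(chrom) !(chrom %in% c("chrX", "chrY", "X", "Y"))

# FNV-1a hash of a string, as 8 hex digits; used for the config fingerprint
# in provenance headers.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s) %% 256) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply by the FNV prime mod 2^32 in two 16-bit halves to stay exact
    h0 <- h %% 65536; h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Default pipeline configuration
#'
#' @return named list: alpha (family-wise error rate), n_bins (correlation
#'   bins), smoothing (KDE bandwidth), min_cgi_sites (strict island-size
#'   floor), k_top (ranked islands per direction), snp_window (bp),
#'   n_samples / m_sites (simulation sizes), seed.
#' @export
default_config <- function() {
  list(alpha = 0.05, n_bins = 100, smoothing = 0.05, min_cgi_sites = 3,
       k_top = 500, snp_window = 50, n_samples = 421, m_sites = 10000,
       seed = 1L)
}

provenance <- function(config) {
  cfg <- config[order(names(config))]
  hash <- fnv1a(paste(names(cfg), unlist(cfg), sep = "=", collapse = ";"))
  c(paste0("agewas_version: ", as.character(utils::packageVersion("agewas"))),
    paste0("config_hash: ", hash),
    paste0("seed: ", config$seed))
}

read_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(beta = read_beta_matrix(p("beta.tsv"), p("detection.tsv")),
       covariates = read_covariates(p("covariates.tsv")),
       manifest = read_manifest(p("manifest.csv")),
       segments = read_bed_states(p("segments.bed")),
       snps = read_snp_table(p("snps.tsv")),
       islands = read_tsv_raw(p("islands.tsv")))
}

#' Run pipeline stages on a dataset directory
#'
#' `stage = "all"` runs everything in dependency order. Inputs are read from
#' `dir` (the layout written by [simulate_dataset()]); outputs are written
#' next to them. Returns a named list of per-stage summary counts.
#'
#' @param dir dataset directory.
#' @param stage one of simulate, qc, associate, modes, pca, annotate, rank,
#'   integrate, all.
#' @param config configuration list (see [default_config()]).
#' @return (invisibly) named list of stage summaries.
#' @export
run_pipeline <- function(dir, stage = "all", config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  hdr <- provenance(cfg)
  p <- function(f) file.path(dir, f)
  stages <- if (stage == "all")
    c("simulate", "qc", "associate", "modes", "pca", "annotate", "rank",
      "integrate") else stage
  log <- list()

  if ("simulate" %in% stages) {
    simulate_dataset(dir, n_samples = cfg$n_samples, m_sites = cfg$m_sites,
                     seed = cfg$seed, header_lines = hdr)
    log$simulate <- c(n_samples = cfg$n_samples, m_sites = cfg$m_sites)
  }

  qc_beta <- function() {
    if (file.exists(p("beta_qc.tsv")))
      read_beta_matrix(p("beta_qc.tsv"))
    else read_beta_matrix(p("beta.tsv"))
  }

  if ("qc" %in% stages) {
    inp <- read_beta_matrix(p("beta.tsv"), p("detection.tsv"))
    flt <- filter_probes(inp)
    write_beta_matrix(flt$matrix, p("beta_qc.tsv"), header_lines = hdr)
    write_table_tsv(flt$report, p("qc_report.tsv"), hdr)
    write_table_tsv(sample_call_rates(inp), p("sample_call_rates.tsv"), hdr)
    log$qc <- c(kept = sum(!flt$report$removed),
                removed = sum(flt$report$removed))
  }

  if ("associate" %in% stages) {
    beta <- qc_beta()
    cov <- read_covariates(p("covariates.tsv"))
    man <- read_manifest(p("manifest.csv"))
    res <- fit_all_sites(beta, cov)
    res <- classify_sites(res, n_tests = nrow(res), alpha = cfg$alpha)
    write_association_table(res, p("association.tsv"), hdr)
    inter <- interaction_scan(beta, cov, n_tests = nrow(res), alpha = cfg$alpha)
    write_table_tsv(inter, p("interactions.tsv"), hdr)
    auto <- man$probe_id[AUTOSOMES(man$chrom)]
    auto <- intersect(auto, rownames(beta$values))
    trends <- cohort_trends(beta, cov, sites = auto)
    write_table_tsv(trends, p("cohort_trends.tsv"), hdr)
    sx <- sex_median_test(beta, cov, sites = auto)
    write_table_tsv(data.frame(statistic = unname(sx$statistic),
                               p = sx$p.value), p("sex_median_test.tsv"), hdr)
    log$associate <- table(res$class)
  }

  if ("modes" %in% stages) {
    beta <- qc_beta()
    man <- read_manifest(p("manifest.csv"))
    prof <- count_modes_matrix(beta, smoothing = cfg$smoothing)
    write_table_tsv(prof, p("modes.tsv"), hdr)
    write_table_tsv(modality_table(prof), p("modality_table.tsv"), hdr)
    snps <- read_snp_table(p("snps.tsv"))
    prox <- snp_distance(man[man$probe_id %in% prof$probe_id, ], snps,
                         window = cfg$snp_window)
    ms <- modality_by_snp(prof, prox)
    frac <- as.data.frame.matrix(ms$fractions)
    frac <- cbind(modality = rownames(frac), frac)
    write_table_tsv(frac, p("snp_modality.tsv"),
                    c(hdr, sprintf("chisq_p: %g", ms$p_value)))
    log$modes <- table(prof$n_modes)
  }

  if ("pca" %in% stages) {
    beta <- qc_beta()
    cov <- read_covariates(p("covariates.tsv"))
    man <- read_manifest(p("manifest.csv"))
    auto <- intersect(man$probe_id[AUTOSOMES(man$chrom)], rownames(beta$values))
    att <- variance_attribution(subset_beta(beta, sites = auto), cov)
    write_table_tsv(att, p("attribution.tsv"), hdr)
    log$pca <- c(cum_attributed = att$cum_attributed[nrow(att)])
  }

  if ("annotate" %in% stages) {
    res <- read_association_table(p("association.tsv"))
    man <- read_manifest(p("manifest.csv"))
    seg <- read_bed_states(p("segments.bed"))
    auto_ids <- man$probe_id[AUTOSOMES(man$chrom)]
    res_a <- res[res$probe_id %in% auto_ids, ]
    bins <- bin_by_correlation(res_a, n_bins = min(cfg$n_bins, nrow(res_a)))
    rel <- stats::setNames(man$relation, man$probe_id)
    write_table_tsv(bin_fractions(bins, rel, RELATION_LEVELS),
                    p("bins_relation.tsv"), hdr)
    fg <- man$feature_group
    fg[is.na(fg)] <- "intergenic"
    write_table_tsv(bin_fractions(bins, stats::setNames(fg, man$probe_id),
                                  FEATURE_LEVELS),
                    p("bins_feature.tsv"), hdr)
    states <- map_chromatin_states(man, seg)
    st <- ifelse(is.na(states), "none", as.character(states))
    write_table_tsv(bin_fractions(bins, stats::setNames(st, man$probe_id),
                                  c(as.character(1:15), "none")),
                    p("bins_chromatin.tsv"), hdr)
    islands <- read_tsv_raw(p("islands.tsv"))
    cgi <- stats::setNames(man$cgi_id, man$probe_id)
    island_only <- cgi
    island_only[man$relation != "island"] <- NA
    write_table_tsv(bin_cgi_stats(bins, islands, island_only),
                    p("bins_cgi_stats.tsv"), hdr)
    log$annotate <- c(n_bins = max(bins$bin))
  }

  if ("rank" %in% stages) {
    res <- read_association_table(p("association.tsv"))
    man <- read_manifest(p("manifest.csv"))
    islands <- read_tsv_raw(p("islands.tsv"))
    cgi <- stats::setNames(man$cgi_id, man$probe_id)
    cgi[man$relation != "island"] <- NA  # rank by sites inside the island
    genes <- stats::setNames(islands$genes, islands$cgi_id)
    scores <- score_cgis(res, cgi, min_sites = cfg$min_cgi_sites,
                         island_genes = genes)
    for (dir_ in c("hyper", "hypo")) {
      top <- top_k_cgis(scores, dir_, k = min(cfg$k_top, nrow(scores)))
      write_table_tsv(top, p(sprintf("ranked_%s.tsv", dir_)), hdr)
      gl <- one_gene_per_cgi(top, seed = cfg$seed)
      writeLines(gl, p(sprintf("genes_%s.txt", dir_)))
    }
    log$rank <- c(n_scored = nrow(scores))
  }

  if ("integrate" %in% stages) {
    cov <- read_covariates(p("covariates.tsv"))
    edf <- read_tsv_raw(p("expression.tsv"))
    expr <- as.matrix(edf[, -1, drop = FALSE])
    rownames(expr) <- edf[[1]]
    gene_map <- read_tsv_raw(p("gene_map.tsv"))
    trends <- fit_all_expression(expr, cov)
    write_table_tsv(trends, p("expression_trends.tsv"), hdr)
    enr <- list()
    for (dir_ in c("hyper", "hypo")) {
      gl_path <- p(sprintf("genes_%s.txt", dir_))
      if (!file.exists(gl_path)) next
      gl <- intersect(readLines(gl_path), gene_map$gene)
      if (length(gl) == 0) next
      e <- direction_enrichment(trends, gene_map, gl)
      e$gene_list <- dir_
      enr[[dir_]] <- e
    }
    if (length(enr) > 0)
      write_table_tsv(do.call(rbind, enr), p("expression_enrichment.tsv"), hdr)
    log$integrate <- table(trends$direction)
  }

  invisible(log)
}

pipeline_usage <- function() {
  paste(
    "usage: agewas <subcommand> [--out-dir DIR] [--config FILE] [--seed INT]",
    "              [--alpha X] [--n-bins N] [--smoothing X] [--k-top N]",
    "              [--min-cgi-sites N] [--n-samples N] [--m-sites N]",
    "subcommands: simulate qc associate modes pca annotate rank integrate all",
    "Flags override --config (YAML key: value); --version prints the version.",
    sep = "\n")
}

#' Command-line entry point
#'
#' Parses `argv` (a character vector, excluding the program name), runs the
#' requested pipeline stage and returns an exit code: 0 on success, 1 on a
#' data error, 2 on a usage error.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
agewas_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { message(pipeline_usage()); return(2L) }
  if (argv[1] == "--version") {
    message("agewas ", as.character(utils::packageVersion("agewas")))
    return(0L)
  }
  sub <- argv[1]
  valid <- c("simulate", "qc", "associate", "modes", "pca", "annotate",
             "rank", "integrate", "all")
  if (!sub %in% valid) {
    message("unknown subcommand: ", sub, "\n", pipeline_usage())
    return(2L)
  }
  flags <- list(`--out-dir` = "out_dir", `--config` = "config_file",
                `--seed` = "seed", `--alpha` = "alpha", `--n-bins` = "n_bins",
                `--smoothing` = "smoothing", `--k-top` = "k_top",
                `--min-cgi-sites` = "min_cgi_sites",
                `--n-samples` = "n_samples", `--m-sites` = "m_sites",
                `--snp-window` = "snp_window")
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!key %in% names(flags) || i == length(argv)) {
      message("unknown or incomplete flag: ", key, "\n", pipeline_usage())
      return(2L)
    }
    opts[[flags[[key]]]] <- argv[i + 1]
    i <- i + 2
  }
  cfg <- default_config()
  if (!is.null(opts$config_file)) {
    if (!file.exists(opts$config_file)) {
      message("config file not found: ", opts$config_file)
      return(2L)
    }
    cfg <- utils::modifyList(cfg, yaml::read_yaml(opts$config_file))
  }
  num_keys <- c("alpha", "n_bins", "smoothing", "k_top", "min_cgi_sites",
                "n_samples", "m_sites", "seed", "snp_window")
  for (k in num_keys)
    if (!is.null(opts[[k]])) cfg[[k]] <- as.numeric(opts[[k]])
  cfg$seed <- as.integer(cfg$seed)
  out_dir <- if (is.null(opts$out_dir)) "." else opts$out_dir
  status <- tryCatch({
    log <- run_pipeline(out_dir, stage = sub, config = cfg)
    for (nm in names(log))
      message(nm, ": ", paste(names(log[[nm]]), unlist(log[[nm]]),
                              sep = "=", collapse = " "))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
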