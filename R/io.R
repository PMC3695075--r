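# Readers/writers for every external file the pipeline touches. All TSVs are
# tab-delimited UTF-8 with "NA" for missing; lines starting with '#' are
# provenance headers and skipped on read. Floats are written with %.17g so
# write -> read round-trips are exact at double precision.

RELATION_LEVELS <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf", "open_sea")
FEATURE_LEVELS  <- c("tss200", "tss1500", "utr5", "first_exon", "body", "utr3", "intergenic")
CLASS_LEVELS    <- c("hyper", "hypo", "suggestive", "uncorrelated")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

read_tsv_raw <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_raw <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0)
    writeLines(paste0("#", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids with the first column holding site ids.
#' Cells are beta values in `[0, 1]`; `"NA"` marks a missing call. An optional
#' companion TSV of identical layout provides per-call detection p-values.
#'
#' @param path TSV of beta values.
#' @param detection_path optional TSV of detection p-values, same layout.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  values <- read_numeric_grid(path, what = "beta value", lower = 0, upper = 1)
  dp <- NULL
  if (!is.null(detection_path)) {
    dp <- read_numeric_grid(detection_path, what = "detection p-value",
                            lower = 0, upper = 1)
    if (!identical(dimnames(dp), dimnames(values)))
      stop("detection p-value table ids do not match the beta matrix")
  }
  beta_matrix(values, dp)
}

read_numeric_grid <- function(path, what, lower, upper) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("expected a site-id column plus at least one sample column in ", path)
  site_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(site_ids)) stop("duplicate site ids in ", path)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !(raw == "NA" | raw == ""), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric %s '%s' at site '%s', sample '%s' in %s",
                 what, raw[bad[1, 1], bad[1, 2]], site_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]], path))
  out <- which(!is.na(num) & (num < lower | num > upper), arr.ind = TRUE)
  if (nrow(out) > 0)
    stop(sprintf("%s out of [%g,%g] at site '%s', sample '%s': %s",
                 what, lower, upper, site_ids[out[1, 1]],
                 sample_ids[out[1, 2]], raw[out[1, 1], out[1, 2]]))
  dimnames(num) <- list(site_ids, sample_ids)
  num
}

#' Write a beta-value matrix (and optional detection layer) to TSV
#'
#' @param x a `BetaMatrix`.
#' @param path output TSV for beta values.
#' @param detection_path optional output TSV for the detection layer.
#' @param header_lines provenance lines to prepend (written as `#`-comments).
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL,
                              header_lines = character(0)) {
  stopifnot(inherits(x, "BetaMatrix"))
  write_grid <- function(m, p) {
    df <- data.frame(site_id = rownames(m), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
    write_tsv_raw(df, p, header_lines)
  }
  write_grid(x$values, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p)) stop("no detection layer to write")
    write_grid(x$detection_p, detection_path)
  }
  invisible(NULL)
}

#' Read sample covariates (age, sex, BMI)
#'
#' Expects a TSV with columns `sample_id`, `age`, `sex`, `bmi`. Sex codes
#' `F`/`M`/`0`/`1` (any case) are normalised to 0 = female, 1 = male. BMI may
#' be missing; age must lie in `[0, 120]` years.
#'
#' @param path TSV path.
#' @return data.frame with columns sample_id, age, sex, bmi.
#' @export
read_covariates <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("sample_id", "age", "sex", "bmi")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  age <- as.numeric(df$age)
  if (any(is.na(age))) stop("non-numeric age for sample ",
                            df$sample_id[which(is.na(age))[1]])
  if (any(age < 0)) stop("negative age for sample ", df$sample_id[which(age < 0)[1]])
  if (any(age > 120)) stop("implausible age (>120) for sample ",
                           df$sample_id[which(age > 120)[1]])
  sex_raw <- toupper(trimws(as.character(df$sex)))
  sex <- c("F" = 0, "M" = 1, "0" = 0, "1" = 1)[sex_raw]
  if (any(is.na(sex)))
    stop("unknown sex code '", sex_raw[which(is.na(sex))[1]], "' for sample ",
         df$sample_id[which(is.na(sex))[1]])
  bmi <- suppressWarnings(as.numeric(df$bmi))
  if (any(!is.na(bmi) & bmi <= 0)) stop("non-positive BMI")
  data.frame(sample_id = as.character(df$sample_id), age = age,
             sex = unname(sex), bmi = bmi, stringsAsFactors = FALSE)
}

#' Write sample covariates to TSV
#' @param covariates data.frame as returned by [read_covariates()].
#' @param path output path.
#' @param header_lines provenance `#`-comment lines.
#' @export
write_covariates <- function(covariates, path, header_lines = character(0)) {
  df <- data.frame(sample_id = covariates$sample_id,
                   age = fmt_num(covariates$age),
                   sex = covariates$sex,
                   bmi = fmt_num(covariates$bmi),
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path, header_lines)
}

#' Read an Illumina-style probe manifest (CSV)
#'
#' Required columns: `probe_id`, `chrom`, `pos`, `relation`. Optional:
#' `strand`, `cgi_id`, `gene`, `feature_group`; extra columns are ignored.
#' `relation` is case-normalised into the closed vocabulary
#' island / n_shore / s_shore / n_shelf / s_shelf / open_sea (an empty
#' relation means open sea, the Illumina convention). Positions are 1-based.
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#")
  need <- c("probe_id", "chrom", "pos", "relation")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in manifest: ",
         df$probe_id[which(duplicated(df$probe_id))[1]])
  pos <- as.integer(df$pos)
  if (any(is.na(pos) | pos < 1)) stop("manifest positions must be integers >= 1")
  rel <- tolower(trimws(as.character(df$relation)))
  rel[rel == "" | is.na(rel)] <- "open_sea"
  bad <- setdiff(unique(rel), RELATION_LEVELS)
  if (length(bad) > 0)
    stop("relation value(s) outside vocabulary: ", paste(bad, collapse = ", "))
  opt <- function(col, default = NA_character_) {
    if (col %in% colnames(df)) {
      v <- as.character(df[[col]])
      v[v == ""] <- NA_character_
      v
    } else rep(default, nrow(df))
  }
  fg <- tolower(opt("feature_group"))
  badf <- setdiff(unique(fg[!is.na(fg)]), FEATURE_LEVELS)
  if (length(badf) > 0)
    stop("feature_group value(s) outside vocabulary: ", paste(badf, collapse = ", "))
  data.frame(probe_id = as.character(df$probe_id),
             chrom = as.character(df$chrom), pos = pos,
             strand = opt("strand"), cgi_id = opt("cgi_id"),
             relation = rel, gene = opt("gene"), feature_group = fg,
             stringsAsFactors = FALSE)
}

#' Write a probe manifest to CSV
#' @param manifest manifest data.frame.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

#' Read chromatin-state segments from BED3+1
#'
#' BED coordinates are 0-based half-open; the fourth column carries the
#' chromatin-state label (an integer 1-15, possibly with a textual suffix such
#' as `4_Strong_Enhancer`). Segments are validated to be non-empty and
#' non-overlapping per chromosome and returned sorted by (chrom, start).
#'
#' @param path BED path.
#' @return data.frame with chrom, start, end, state.
#' @export
read_bed_states <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#",
                          col.names = c("chrom", "start", "end", "state"),
                          colClasses = c("character", "integer", "integer", "character"))
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1]
    stop(sprintf("empty or inverted interval %s:%d-%d", df$chrom[i],
                 df$start[i], df$end[i]))
  }
  state <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", df$state)))
  if (any(is.na(state) | state < 1 | state > 15))
    stop("chromatin-state labels must parse to integers in 1..15")
  df$state <- state
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping segments on ", ch)
  }
  df
}

#' Write per-site association results to TSV
#'
#' Columns: probe_id, n_used, slope_age, correlation, p_age, adjusted_p,
#' class. Floats at full double precision so a write/read round-trip is exact.
#'
#' @param results association data.frame (see [fit_all_sites()]).
#' @param path output path.
#' @param header_lines provenance `#`-comment lines.
#' @export
write_association_table <- function(results, path, header_lines = character(0)) {
  cols <- c("probe_id", "n_used", "slope_age", "correlation", "p_age",
            "adjusted_p", "class")
  if (!"adjusted_p" %in% colnames(results)) {
    nt <- attr(results, "n_tests")
    results$adjusted_p <- if (is.null(nt)) NA_real_ else
      pmin(1, results$p_age * nt)
  }
  df <- results[, intersect(cols, colnames(results)), drop = FALSE]
  for (col in c("slope_age", "correlation", "p_age", "adjusted_p"))
    if (col %in% colnames(df)) df[[col]] <- fmt_num(df[[col]])
  write_tsv_raw(df, path, header_lines)
}

#' Read an association table written by [write_association_table()]
#' @param path TSV path.
#' @return association data.frame.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_raw(path)
  for (col in c("slope_age", "correlation", "p_age", "adjusted_p"))
    if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
  if ("class" %in% colnames(df)) {
    bad <- setdiff(unique(df$class[!is.na(df$class)]), CLASS_LEVELS)
    if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Read a SNP position table (TSV with chrom, pos, maf)
#' @param path TSV path.
#' @param min_maf SNPs below this minor-allele frequency are dropped
#'   (default 0.01, the conventional common-variant cutoff).
#' @return data.frame with chrom, pos, maf.
#' @export
read_snp_table <- function(path, min_maf = 0.01) {
  df <- read_tsv_raw(path)
  need <- c("chrom", "pos", "maf")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) stop("missing SNP table columns: ", paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  if (any(is.na(df$pos) | df$pos < 1)) stop("SNP positions must be integers >= 1")
  if (any(is.na(df$maf) | df$maf < 0 | df$maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  df <- df[df$maf >= min_maf, c("chrom", "pos", "maf"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a generic data.frame to TSV with full float precision
#' @param df data.frame.
#' @param path output path.
#' @param header_lines provenance `#`-comment lines.
#' @export
write_table_tsv <- function(df, path, header_lines = character(0)) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write_tsv_raw(out, path, header_lines)
}
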