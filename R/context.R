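# Genomic context for methylation sites: CpG-island membership and flanks
# (shores 0-2 kb, shelves 2-4 kb; N = upstream/lower coordinates, S =
# downstream), chromatin-state overlap, and correlation-ordered binned
# fraction curves. The CGI predicate is the conjunctive Gardiner-Garden
# definition: length > 200 bp AND GC >= 50% AND observed/expected CpG > 0.6
# (a disjunctive mode is available for sensitivity analysis).

#' CpG-island predicate
#'
#' @param length island length in bp.
#' @param gc GC content as a fraction.
#' @param obs_exp observed/expected CpG ratio.
#' @param conjunctive if `TRUE` (default) all three conditions must hold
#'   (standard Gardiner-Garden reading); if `FALSE`, any one suffices.
#' @return logical.
#' @export
is_cgi <- function(length, gc, obs_exp, conjunctive = TRUE) {
  if (any(length < 0 | gc < 0 | obs_exp < 0, na.rm = TRUE))
    stop("inputs must be non-negative")
  a <- length > 200; b <- gc >= 0.5; c <- obs_exp > 0.6
  if (conjunctive) a & b & c else a | b | c
}

#' Observed/expected CpG ratio from nucleotide counts
#'
#' `(n_cpg * length) / (n_c * n_g)`, 0 when the denominator is 0. Invariant
#' to duplicating the sequence (all counts and the length scale together).
#'
#' @param n_c,n_g,n_cpg counts of C, G and CpG dinucleotides.
#' @param length sequence length, > 0.
#' @return numeric ratio.
#' @export
obs_exp_ratio <- function(n_c, n_g, n_cpg, length) {
  if (any(length <= 0)) stop("length must be positive")
  denom <- n_c * n_g
  ifelse(denom == 0, 0, n_cpg * length / denom)
}

#' Map site positions to island / shore / shelf / open-sea relation
#'
#' Positions inside an island (1-based inclusive span) map to `island`;
#' 1-2000 bp upstream of the nearest island edge to `n_shore`, downstream to
#' `s_shore`; 2001-4000 bp to `n_shelf` / `s_shelf`; anything farther is
#' `open_sea`. The nearest island wins; exact distance ties resolve to the
#' upstream (lower-coordinate) island.
#'
#' @param pos 1-based site positions on one chromosome.
#' @param islands data.frame with 1-based inclusive `start`, `end`
#'   (non-overlapping) for that chromosome.
#' @return character vector of relations.
#' @export
map_relation <- function(pos, islands) {
  if (nrow(islands) == 0) return(rep("open_sea", length(pos)))
  o <- order(islands$start)
  st <- islands$start[o]; en <- islands$end[o]
  if (any(st[-1] <= en[-length(en)])) stop("islands must be non-overlapping")
  vapply(pos, function(p) {
    i <- findInterval(p, st)
    if (i >= 1 && p <= en[i]) return("island")
    # gap to island i on the left (site is downstream of it -> S side) and to
    # island i+1 on the right (site is upstream of it -> N side)
    d_left <- if (i >= 1) p - en[i] else Inf
    d_right <- if (i < length(st)) st[i + 1] - p else Inf
    if (d_left <= d_right) { d <- d_left; side <- "s" }
    else { d <- d_right; side <- "n" }
    if (d <= 2000) paste0(side, "_shore")
    else if (d <= 4000) paste0(side, "_shelf")
    else "open_sea"
  }, character(1))
}

#' Chromatin state at site positions
#'
#' Segments use BED convention (0-based half-open); site positions are
#' 1-based, so a segment `[start, end)` covers 1-based positions
#' `start+1 .. end`. Uncovered positions get `NA`.
#'
#' @param pos 1-based positions on one chromosome.
#' @param segments sorted, non-overlapping segments for that chromosome
#'   (columns start, end, state).
#' @return integer vector of states (NA when uncovered).
#' @export
map_chromatin_state <- function(pos, segments) {
  if (nrow(segments) == 0) return(rep(NA_integer_, length(pos)))
  o <- order(segments$start)
  st <- segments$start[o]; en <- segments$end[o]; state <- segments$state[o]
  i <- findInterval(pos - 1, st)
  out <- rep(NA_integer_, length(pos))
  hit <- i >= 1
  hit[hit] <- (pos - 1)[hit] < en[i[hit]]
  out[hit] <- state[i[hit]]
  out
}

#' Chromatin states for a whole manifest
#'
#' @param manifest manifest data.frame (chrom, pos).
#' @param segments chromatin segments table (chrom, start, end, state).
#' @return integer vector aligned with the manifest rows.
#' @export
map_chromatin_states <- function(manifest, segments) {
  out <- rep(NA_integer_, nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    mi <- manifest$chrom == ch
    out[mi] <- map_chromatin_state(manifest$pos[mi],
                                   segments[segments$chrom == ch, , drop = FALSE])
  }
  out
}

#' Assign sites to equal-count bins ordered by correlation
#'
#' Sites are stably sorted by (correlation, probe_id) and split into
#' `n_bins` contiguous bins whose sizes differ by at most 1, larger bins
#' first. Bin mean correlations are therefore non-decreasing in bin index.
#'
#' @param results association results (probe_id, correlation).
#' @param n_bins number of bins (default 100).
#' @return data.frame: probe_id, correlation, bin.
#' @export
bin_by_correlation <- function(results, n_bins = 100) {
  n <- nrow(results)
  if (n_bins < 1) stop("n_bins must be at least 1")
  if (n_bins > n) stop("more bins than sites")
  o <- order(results$correlation, results$probe_id)
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- data.frame(probe_id = results$probe_id[o],
                    correlation = results$correlation[o], bin = bin,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Per-bin category fractions
#'
#' For each bin, the fraction of sites in each category of a categorical
#' partition (island relation, feature group, promoter/enhancer annotation,
#' or chromatin state). Every site must carry a category belonging to the
#' partition; fractions within a bin sum to 1.
#'
#' @param bins output of [bin_by_correlation()].
#' @param categories named character vector (names = probe ids) giving each
#'   site's category.
#' @param partition the closed set of categories (include an explicit
#'   "other"/"none" level if needed).
#' @return data.frame: bin, n_sites, mean_correlation, then one fraction
#'   column per category.
#' @export
bin_fractions <- function(bins, categories, partition) {
  cat <- categories[bins$probe_id]
  if (any(is.na(cat))) {
    bad <- bins$probe_id[which(is.na(cat))[1]]
    stop("site without a category: ", bad)
  }
  out_of <- setdiff(unique(cat), partition)
  if (length(out_of) > 0) {
    bad <- bins$probe_id[which(cat %in% out_of)[1]]
    stop("site '", bad, "' has category outside the partition: ",
         cat[match(bad, bins$probe_id)])
  }
  f <- factor(cat, levels = partition)
  tab <- table(bins$bin, f)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  mc <- tapply(bins$correlation, bins$bin, mean)
  ns <- as.integer(rowSums(tab))
  out <- data.frame(bin = as.integer(rownames(tab)), n_sites = ns,
                    mean_correlation = as.numeric(mc[rownames(tab)]),
                    row.names = NULL)
  for (lev in partition) out[[lev]] <- as.numeric(frac[, lev])
  out
}

#' Per-bin CpG-island summary statistics
#'
#' For each bin, the mean island length, CpG percentage and observed/expected
#' ratio over sites that link to an island (via `cgi_id`); bins with no
#' island-linked sites report `NA`.
#'
#' @param bins output of [bin_by_correlation()].
#' @param islands island table (cgi_id, length, pct_cpg, obs_exp).
#' @param site_cgi named character vector (names = probe ids) giving each
#'   site's island id (`NA` for non-island sites).
#' @return data.frame: bin, n_island_sites, mean_length, mean_pct_cpg,
#'   mean_obs_exp.
#' @export
bin_cgi_stats <- function(bins, islands, site_cgi) {
  cgi <- site_cgi[bins$probe_id]
  idx <- match(cgi, islands$cgi_id)
  df <- data.frame(bin = bins$bin, length = islands$length[idx],
                   pct_cpg = islands$pct_cpg[idx],
                   obs_exp = islands$obs_exp[idx])
  agg <- function(col) {
    v <- tapply(df[[col]], df$bin, function(z)
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
    as.numeric(v)
  }
  nz <- as.integer(tapply(!is.na(df$length), df$bin, sum))
  data.frame(bin = sort(unique(bins$bin)), n_island_sites = nz,
             mean_length = agg("length"), mean_pct_cpg = agg("pct_cpg"),
             mean_obs_exp = agg("obs_exp"), row.names = NULL)
}
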