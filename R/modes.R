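# Mode counting of per-site beta distributions by fixed-bandwidth Gaussian
# kernel density estimation: the density (bandwidth = smoothing factor, default
# 0.05) is evaluated on a fixed 512-point grid over [0,1]; modes are strict
# local maxima after merging flat plateaus, kept if their peak density reaches
# at least a small floor (0.5% of the global maximum, suppressing numerical
# ripple). No assumption is made about the underlying number of modes.

#' Count modes of a beta-value sample
#'
#' @param values numeric vector of betas (missing values dropped; at least 10
#'   non-missing values required). Values are clipped to `[0, 1]`.
#' @param smoothing Gaussian kernel bandwidth on the beta scale
#'   (default 0.05).
#' @param grid_n number of grid points over `[0, 1]` (default 512).
#' @param peak_floor minimum peak density relative to the global maximum
#'   (default 0.005).
#' @return list with `n_modes`, `mode_locations` (strictly increasing beta
#'   values of the density maxima) and `smoothing`.
#' @export
count_modes <- function(values, smoothing = 0.05, grid_n = 512,
                        peak_floor = 0.005) {
  x <- values[!is.na(values)]
  if (length(x) < 10) stop("at least 10 non-missing values required")
  if (smoothing <= 0) stop("smoothing must be positive")
  x <- pmin(pmax(x, 0), 1)
  if (max(x) - min(x) < .Machine$double.eps)
    return(list(n_modes = 1L, mode_locations = x[1], smoothing = smoothing))
  d <- stats::density(x, bw = smoothing, from = 0, to = 1, n = grid_n)
  locs <- density_modes(d$x, d$y, peak_floor)
  list(n_modes = length(locs), mode_locations = locs, smoothing = smoothing)
}

# Strict local maxima of a gridded density with plateau merging: runs of equal
# density are collapsed to their midpoint; a run is a mode iff it is higher
# than both neighbouring runs (boundary runs compare to their single
# neighbour). Peaks below peak_floor * max are dropped.
density_modes <- function(gx, gy, peak_floor) {
  r <- rle(gy)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_max <- logical(k)
  for (j in seq_len(k)) {
    left_ok <- j == 1 || r$values[j] > r$values[j - 1]
    right_ok <- j == k || r$values[j] > r$values[j + 1]
    is_max[j] <- left_ok && right_ok
  }
  is_max <- is_max & r$values >= peak_floor * max(gy)
  mid <- floor((starts + ends) / 2)
  sort(gx[mid[is_max]])
}

#' Mode profiles for every site of a beta matrix
#'
#' @param x a [beta_matrix()] or sites-x-samples matrix.
#' @param smoothing,grid_n,peak_floor see [count_modes()].
#' @return data.frame: probe_id, n_modes, mode_locations (comma-joined),
#'   smoothing.
#' @export
count_modes_matrix <- function(x, smoothing = 0.05, grid_n = 512,
                               peak_floor = 0.005) {
  values <- if (inherits(x, "BetaMatrix")) x$values else x
  prof <- lapply(seq_len(nrow(values)), function(i)
    count_modes(values[i, ], smoothing, grid_n, peak_floor))
  data.frame(probe_id = rownames(values),
             n_modes = vapply(prof, function(p) p$n_modes, integer(1)),
             mode_locations = vapply(prof, function(p)
               paste(sprintf("%.6f", p$mode_locations), collapse = ","),
               character(1)),
             smoothing = smoothing, row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate sites by number of modes
#'
#' @param profiles data.frame with an `n_modes` column (e.g. from
#'   [count_modes_matrix()]).
#' @return data.frame with modality classes 1, 2, 3, >3, their counts and
#'   fractions (fractions sum to 1).
#' @export
modality_table <- function(profiles) {
  n <- profiles$n_modes
  if (length(n) == 0) stop("no mode profiles supplied")
  counts <- c(`1` = sum(n == 1), `2` = sum(n == 2), `3` = sum(n == 3),
              `>3` = sum(n > 3))
  data.frame(modality = names(counts), count = as.integer(counts),
             fraction = as.numeric(counts) / length(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distance from each CpG to the nearest SNP
#'
#' The interrogated CpG dinucleotide occupies positions `pos` and `pos + 1`;
#' the distance to a SNP is the minimum over both, so a SNP inside the
#' dinucleotide is at distance 0 and a SNP at `pos + 2` is at distance 1.
#' SNPs farther than `window` (default 50 bp, the probe length) are ignored.
#'
#' @param manifest manifest data.frame (probe_id, chrom, pos).
#' @param snps SNP table (chrom, pos).
#' @param window maximum distance considered, bp.
#' @return data.frame: probe_id, min_distance (NA when no SNP within the
#'   window).
#' @export
snp_distance <- function(manifest, snps, window = 50) {
  out <- rep(NA_real_, nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    sp <- sort(snps$pos[snps$chrom == ch])
    mi <- which(manifest$chrom == ch)
    if (length(sp) == 0 || length(mi) == 0) next
    for (i in mi) {
      p <- manifest$pos[i]
      near <- sp[sp >= p - window & sp <= p + 1 + window]
      if (length(near) == 0) next
      d <- pmin(abs(near - p), abs(near - (p + 1)))
      d <- min(d)
      if (d <= window) out[i] <- d
    }
  }
  data.frame(probe_id = manifest$probe_id, min_distance = out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate modality against SNP proximity
#'
#' Builds the contingency table of modality class (1, 2, 3, >3 modes) against
#' SNP distance class (at-site, <=1 bp, <=2 bp, <=10 bp, >10 bp within the
#' window, none) and tests association with a chi-square test (no continuity
#' correction). Empty rows/columns are collapsed with a warning.
#'
#' @param profiles mode profiles (probe_id, n_modes).
#' @param proximities output of [snp_distance()].
#' @return list with `counts`, `fractions` (per modality class), `statistic`,
#'   `p_value`.
#' @export
modality_by_snp <- function(profiles, proximities) {
  d <- merge(profiles[, c("probe_id", "n_modes")], proximities,
             by = "probe_id")
  modality <- cut(pmin(d$n_modes, 4), breaks = c(0, 1, 2, 3, 4),
                  labels = c("1", "2", "3", ">3"))
  dist <- d$min_distance
  dist_class <- ifelse(is.na(dist), "none",
                ifelse(dist == 0, "at_site",
                ifelse(dist <= 1, "within_1bp",
                ifelse(dist <= 2, "within_2bp",
                ifelse(dist <= 10, "within_10bp", "beyond_10bp")))))
  dist_class <- factor(dist_class, levels = c("at_site", "within_1bp",
                                              "within_2bp", "within_10bp",
                                              "beyond_10bp", "none"))
  tab <- table(modality, dist_class)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("empty modality or distance classes collapsed before testing")
  test_tab <- tab[keep_r, keep_c, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(test_tab, correct = FALSE))
  fractions <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  list(counts = tab, fractions = fractions,
       statistic = unname(ct$statistic), p_value = ct$p.value)
}
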