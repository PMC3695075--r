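# Synthetic 450K-like cohorts with ground truth. The generator plants the
# statistical structure the analysis assumes: a bimodal low/high beta
# landscape, logit-linear age drift toward hemimethylation for affected sites,
# SNP-driven bi/trimodality under Hardy-Weinberg genotype mixtures, X-linked
# sex dimorphism, and age-correlated expression trends.

SITE_CLASSES <- c("stable_low", "stable_high", "promoter_conserved",
                  "age_hyper", "age_hypo", "snp_modal", "x_linked")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Integer apportionment by largest remainder: counts sum exactly to n.
apportion <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

logit <- function(p) log(p / (1 - p))

#' Default site-class mixture for synthetic catalogs
#'
#' 29% of sites are age-affected, split 60.5% hypomethylating / 39.5%
#' hypermethylating; the remainder is divided among stable unmethylated and
#' methylated sites, conserved promoter sites, SNP-modal sites and X-linked
#' sites at prevalences typical of a 450K autosomal landscape.
#'
#' @return named numeric vector over the seven site classes, summing to 1.
#' @export
default_class_mix <- function() {
  c(age_hyper = 0.29 * 0.395, age_hypo = 0.29 * 0.605,
    promoter_conserved = 0.10, stable_low = 0.28, stable_high = 0.28,
    snp_modal = 0.03, x_linked = 0.02)
}

#' Describe a synthetic cohort
#' @param n_samples number of individuals (>= 2).
#' @param age_min,age_max age range in years.
#' @param sex_ratio fraction male, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, age_min = 14, age_max = 94,
                        sex_ratio = 0.5, seed = 1L) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (age_min >= age_max) stop("age_min must be less than age_max")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples), age_min = age_min,
                 age_max = age_max, sex_ratio = sex_ratio,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate cohort covariates (age, sex, BMI)
#'
#' Ages are drawn from a mixture density with extra mass around 17, 45 and 67
#' years over a uniform background, truncated to the requested range, so the
#' cohort reproduces the multi-bump age structure typical of a multigeneration
#' population sample. BMI is drawn from a truncated normal around 26 kg/m2.
#'
#' @param spec a [cohort_spec()].
#' @return covariates data.frame (sample_id, age, sex, bmi).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    draw_ages <- function(k) {
      comp <- sample.int(4, k, replace = TRUE, prob = c(0.15, 0.30, 0.20, 0.35))
      a <- numeric(k)
      a[comp == 1] <- stats::rnorm(sum(comp == 1), 17, 2.5)
      a[comp == 2] <- stats::rnorm(sum(comp == 2), 45, 10)
      a[comp == 3] <- stats::rnorm(sum(comp == 3), 67, 8)
      a[comp == 4] <- stats::runif(sum(comp == 4), spec$age_min, spec$age_max)
      a
    }
    ages <- numeric(0)
    while (length(ages) < n) {
      cand <- draw_ages(2L * n)
      ages <- c(ages, cand[cand >= spec$age_min & cand <= spec$age_max])
    }
    ages <- round(ages[seq_len(n)], 1)
    sex <- stats::rbinom(n, 1, spec$sex_ratio)
    bmi <- pmax(15, stats::rnorm(n, 26, 4))
    data.frame(sample_id = sprintf("S%04d", seq_len(n)), age = ages,
               sex = sex, bmi = round(bmi, 2), stringsAsFactors = FALSE)
  })
}

# Draw per-site truth parameters for one class. Effects live on the logit
# scale so betas stay inside (0,1) without truncation artifacts; age-affected
# sites start away from hemimethylation and drift toward it (hyper sites rise
# from a low baseline, hypo sites fall from a high one).
draw_truth <- function(class, k, age_mid) {
  z <- function(lo, hi) stats::runif(k, lo, hi)
  baseline <- slope <- noise <- rep(NA_real_, k)
  maf <- rep(NA_real_, k)
  gm <- matrix(NA_real_, k, 3)
  if (k == 0) {
  } else if (class == "stable_low") {
    baseline <- z(logit(0.03), logit(0.20)); slope <- 0
    noise <- z(0.15, 0.40)
  } else if (class == "stable_high") {
    baseline <- z(logit(0.80), logit(0.97)); slope <- 0
    noise <- z(0.15, 0.40)
  } else if (class == "promoter_conserved") {
    baseline <- z(logit(0.02), logit(0.08)); slope <- 0
    noise <- z(0.10, 0.25)
  } else if (class == "age_hyper") {
    slope <- z(0.008, 0.035)
    baseline <- z(logit(0.15), logit(0.45)) - slope * age_mid
    noise <- z(0.20, 0.50)
  } else if (class == "age_hypo") {
    slope <- -z(0.008, 0.035)
    baseline <- z(logit(0.55), logit(0.85)) - slope * age_mid
    noise <- z(0.20, 0.50)
  } else if (class == "snp_modal") {
    maf <- z(0.10, 0.50)
    mid <- z(0.45, 0.55)
    gm <- cbind(z(0.03, 0.12), mid, z(0.88, 0.97))
    baseline <- logit(mid); slope <- 0
    noise <- z(0.02, 0.04)  # beta-scale noise within genotype clusters
  } else if (class == "x_linked") {
    baseline <- z(-0.3, 0.3)   # female hemimethylation around beta = 0.5
    slope <- 0.010             # female-specific drift; males stay extreme
    noise <- z(0.20, 0.30)
  }
  data.frame(class = rep(class, k), baseline_logit = baseline,
             slope_per_year = rep(slope, length.out = k), noise_sd = noise,
             snp_maf = maf, gm_low = gm[, 1], gm_mid = gm[, 2],
             gm_high = gm[, 3], stringsAsFactors = FALSE)
}

#' Generate a synthetic site catalog with ground truth
#'
#' Builds a probe manifest, per-site truth table, chromatin-state segments, a
#' SNP table and a CpG-island table with the spatial structure the analysis
#' exploits: hypermethylating sites are grouped into long CpG islands overlaid
#' with state-4 (strong enhancer) chromatin, conserved promoter sites into
#' promoter islands (state 1), hypomethylating sites sit in open sea under
#' state-5 chromatin, islands carry shore (<= 2 kb) and shelf (2-4 kb) flank
#' sites, SNP-modal sites carry a common SNP inside the CpG dinucleotide, and
#' X-linked sites live on chrX.
#'
#' @param m_sites total number of probes.
#' @param class_mix named proportions over the seven site classes
#'   (default [default_class_mix()]); must sum to 1.
#' @param layout list of layout parameters: `sites_per_island` (range),
#'   `gap` (inter-island spacing range, bp), `state_fidelity` (probability an
#'   affected site gets its characteristic chromatin state).
#' @param seed integer RNG seed.
#' @return list with elements `manifest`, `truth`, `segments`, `snps`,
#'   `islands`.
#' @export
generate_site_catalog <- function(m_sites, class_mix = default_class_mix(),
                                  layout = list(), seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix proportions must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative")
  bad <- setdiff(names(class_mix), SITE_CLASSES)
  if (length(bad) > 0) stop("unknown site class(es): ", paste(bad, collapse = ", "))
  lay <- utils::modifyList(list(sites_per_island = c(5L, 8L),
                                gap = c(9000L, 15000L),
                                state_fidelity = 0.85), layout)
  with_seed(seed, {
    counts <- apportion(m_sites, class_mix)
    get_n <- function(cl) if (cl %in% names(counts)) counts[[cl]] else 0L

    # --- island plan ------------------------------------------------------
    split_sizes <- function(total, lo, hi) {
      sizes <- integer(0)
      while (sum(sizes) < total) sizes <- c(sizes, sample(seq(lo, hi), 1))
      excess <- sum(sizes) - total
      sizes[length(sizes)] <- sizes[length(sizes)] - excess
      if (length(sizes) > 1 && sizes[length(sizes)] < lo) {
        sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + sizes[length(sizes)]
        sizes <- sizes[-length(sizes)]
      }
      sizes[sizes > 0]
    }
    lo <- lay$sites_per_island[1]; hi <- lay$sites_per_island[2]
    n_bg_island_sites <- get_n("stable_high") %/% 2L
    plan <- rbind(
      if (get_n("age_hyper") > 0)
        data.frame(type = "hyper", k = split_sizes(get_n("age_hyper"), lo, hi)),
      if (get_n("promoter_conserved") > 0)
        data.frame(type = "conserved", k = split_sizes(get_n("promoter_conserved"), lo, hi)),
      if (n_bg_island_sites > 0)
        data.frame(type = "background", k = split_sizes(n_bg_island_sites, lo, hi)))
    n_islands <- nrow(plan)
    plan <- plan[sample.int(n_islands), , drop = FALSE]

    # Hyper-hosting islands are longer and CpG-richer (the structure the
    # binned CGI statistics are designed to recover); all islands satisfy the
    # CGI predicate (length > 200, GC >= 0.5, obs/exp > 0.6).
    ilen <- ifelse(plan$type == "hyper",
                   round(stats::runif(n_islands, 800, 3000)),
                   round(stats::runif(n_islands, 250, 1000)))
    iobs <- ifelse(plan$type == "background",
                   stats::runif(n_islands, 0.62, 0.85),
                   stats::runif(n_islands, 0.80, 1.15))
    ipct <- ifelse(plan$type == "background",
                   stats::runif(n_islands, 4, 10), stats::runif(n_islands, 8, 18))
    igc <- stats::runif(n_islands, 0.50, 0.72)
    gaps <- round(stats::runif(n_islands, lay$gap[1], lay$gap[2]))
    istart <- 10000 + cumsum(gaps) + cumsum(c(0, ilen[-n_islands]))
    iend <- istart + ilen - 1L
    cgi_id <- sprintf("CGI%05d", seq_len(n_islands))
    two_genes <- stats::runif(n_islands) < 0.2
    igenes <- ifelse(two_genes,
                     sprintf("GENE%05d;GENE%05dB", seq_len(n_islands), seq_len(n_islands)),
                     sprintf("GENE%05d", seq_len(n_islands)))
    islands <- data.frame(cgi_id = cgi_id, chrom = "chr1",
                          start = as.integer(istart), end = as.integer(iend),
                          length = as.integer(ilen), pct_cpg = ipct,
                          obs_exp = iobs, gc_content = igc, type = plan$type,
                          genes = igenes, stringsAsFactors = FALSE)

    # --- site placement ---------------------------------------------------
    site <- function(class, chrom, pos, cgi, gene, feature)
      data.frame(class = class, chrom = chrom, pos = as.integer(pos),
                 cgi_id = cgi, gene = gene, feature_group = feature,
                 stringsAsFactors = FALSE)
    rows <- vector("list", 0)
    feat_for <- function(type, k) switch(type,
      hyper = sample(c("tss1500", "utr5", "first_exon"), k, replace = TRUE),
      conserved = rep("tss200", k),
      background = sample(c("body", "tss1500"), k, replace = TRUE))
    for (i in seq_len(n_islands)) {
      k <- plan$k[i]
      pos <- sort(sample(seq(istart[i] + 5L, iend[i] - 5L), k))
      cls <- switch(plan$type[i], hyper = "age_hyper",
                    conserved = "promoter_conserved", background = "stable_high")
      gene1 <- sub(";.*$", "", igenes[i])
      rows[[length(rows) + 1]] <-
        site(cls, "chr1", pos, cgi_id[i], gene1, feat_for(plan$type[i], k))
    }

    # Shore and shelf flank sites from the stable_low pool, one of each per
    # island while the pool lasts; inter-island gaps (>= 9 kb) guarantee the
    # flank belongs to its own island.
    n_low <- get_n("stable_low")
    n_flank <- min(2L * n_islands, n_low %/% 2L)
    flank_islands <- rep(seq_len(n_islands), length.out = n_flank)
    for (j in seq_len(n_flank)) {
      i <- flank_islands[j]
      shelf <- j > n_islands
      off <- if (shelf) sample(2001:4000, 1) else sample(1:2000, 1)
      s_side <- stats::runif(1) < 0.5
      pos <- if (s_side) iend[i] + off else istart[i] - off
      if (pos < 1) { pos <- iend[i] + off; s_side <- TRUE }
      rows[[length(rows) + 1]] <- site("stable_low", "chr1", pos, cgi_id[i],
                                       NA_character_,
                                       sample(c("body", "intergenic"), 1))
    }

    # Open-sea block: remaining stable sites, hypomethylating and SNP-modal
    # sites, spaced >= 5 kb so they are unambiguous open sea.
    sea_classes <- c(rep("stable_low", n_low - n_flank),
                     rep("stable_high", get_n("stable_high") - n_bg_island_sites),
                     rep("age_hypo", get_n("age_hypo")),
                     rep("snp_modal", get_n("snp_modal")))
    sea_classes <- sample(sea_classes)
    n_sea <- length(sea_classes)
    if (n_sea > 0) {
      sea_pos <- max(iend) + 1000000 +
        cumsum(sample(5000:7000, n_sea, replace = TRUE))
      hypo_gene_idx <- cumsum(sea_classes == "age_hypo")
      sea_gene <- ifelse(sea_classes == "age_hypo",
                         sprintf("HGENE%05d", hypo_gene_idx), NA_character_)
      sea_feat <- ifelse(sea_classes == "age_hypo",
                         sample(c("body", "utr3"), n_sea, replace = TRUE),
                         sample(c("body", "intergenic"), n_sea, replace = TRUE))
      rows[[length(rows) + 1]] <- site(sea_classes, "chr1", sea_pos,
                                       NA_character_, sea_gene, sea_feat)
    }
    if (get_n("x_linked") > 0) {
      xp <- 100000 + cumsum(sample(5000:7000, get_n("x_linked"), replace = TRUE))
      rows[[length(rows) + 1]] <- site("x_linked", "chrX", xp, NA_character_,
                                       NA_character_, "intergenic")
    }
    cat <- do.call(rbind, rows)
    cat <- cat[order(cat$chrom, cat$pos), , drop = FALSE]
    cat$probe_id <- sprintf("cg%08d", seq_len(nrow(cat)))
    rownames(cat) <- NULL

    # Relation from coordinates (consistent with map_relation by design).
    rel <- rep("open_sea", nrow(cat))
    on1 <- cat$chrom == "chr1"
    rel[on1] <- map_relation(cat$pos[on1], islands)
    cat$relation <- rel

    # --- chromatin states -------------------------------------------------
    pick_state <- function(cls, n) {
      fid <- lay$state_fidelity
      keep <- stats::runif(n) < fid
      pref <- switch(cls, age_hyper = 4L, age_hypo = 5L,
                     promoter_conserved = 1L, NA_integer_)
      base <- sample(c(1:3, 6:14), n, replace = TRUE)
      if (cls %in% c("stable_low", "stable_high", "snp_modal"))
        base[stats::runif(n) < 0.25] <- 15L  # repetitive chromatin share
      if (is.na(pref)) base else ifelse(keep, pref, base)
    }
    state <- integer(nrow(cat))
    for (cl in unique(cat$class)) {
      idx <- which(cat$class == cl)
      state[idx] <- pick_state(cl, length(idx))
    }
    seg_list <- lapply(unique(cat$chrom), function(ch) {
      idx <- which(cat$chrom == ch)
      p <- cat$pos[idx]
      mid <- floor((p[-1] + p[-length(p)]) / 2)
      start0 <- c(max(0, p[1] - 500), mid)
      end0 <- c(mid, p[length(p)] + 500)
      data.frame(chrom = ch, start = as.integer(start0), end = as.integer(end0),
                 state = state[idx], stringsAsFactors = FALSE)
    })
    segments <- do.call(rbind, seg_list)
    segments <- segments[segments$start < segments$end, , drop = FALSE]
    segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
    rownames(segments) <- NULL

    # --- truth table ------------------------------------------------------
    age_mid <- 54  # reference mid-age for baseline anchoring
    truth <- do.call(rbind, lapply(SITE_CLASSES, function(cl) {
      idx <- which(cat$class == cl)
      if (length(idx) == 0) return(NULL)
      tr <- draw_truth(cl, length(idx), age_mid)
      tr$probe_id <- cat$probe_id[idx]
      tr
    }))
    truth <- truth[match(cat$probe_id, truth$probe_id),
                   c("probe_id", "class", "baseline_logit", "slope_per_year",
                     "noise_sd", "snp_maf", "gm_low", "gm_mid", "gm_high")]
    rownames(truth) <- NULL

    # --- SNP table --------------------------------------------------------
    snp_rows <- list()
    smi <- which(cat$class == "snp_modal")
    if (length(smi) > 0)
      snp_rows[[1]] <- data.frame(
        chrom = cat$chrom[smi],
        pos = cat$pos[smi] + sample(0:1, length(smi), replace = TRUE),
        maf = truth$snp_maf[match(cat$probe_id[smi], truth$probe_id)])
    stab <- which(cat$class %in% c("stable_low", "stable_high") & cat$chrom == "chr1")
    n_bg_snp <- round(0.02 * length(stab))
    if (n_bg_snp > 0) {
      pick <- sample(stab, n_bg_snp)
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        chrom = cat$chrom[pick],
        pos = cat$pos[pick] + sample(2:40, n_bg_snp, replace = TRUE),
        maf = stats::runif(n_bg_snp, 0.01, 0.5))
    }
    n_at <- round(0.005 * length(stab))
    if (n_at > 0) {
      pick <- sample(stab, n_at)
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        chrom = cat$chrom[pick], pos = cat$pos[pick],
        maf = stats::runif(n_at, 0.01, 0.5))
    }
    snps <- if (length(snp_rows) > 0) do.call(rbind, snp_rows) else
      data.frame(chrom = character(0), pos = integer(0), maf = numeric(0))
    snps <- unique(snps[order(snps$chrom, snps$pos), , drop = FALSE])
    rownames(snps) <- NULL

    manifest <- data.frame(probe_id = cat$probe_id, chrom = cat$chrom,
                           pos = cat$pos, strand = "+", cgi_id = cat$cgi_id,
                           relation = cat$relation, gene = cat$gene,
                           feature_group = cat$feature_group,
                           stringsAsFactors = FALSE)
    list(manifest = manifest, truth = truth, segments = segments, snps = snps,
         islands = islands)
  })
}

#' Generate a beta-value matrix from a truth table and cohort
#'
#' For logit-scale classes, `beta = plogis(baseline + slope * age + eps)` with
#' `eps ~ N(0, noise_sd)`; SNP-modal sites draw a Hardy-Weinberg genotype per
#' sample and emit the genotype mean plus beta-scale noise; X-linked sites are
#' hemimethylated in females (with the female-specific age slope) and extreme
#' in males. Betas are clipped to `[0.001, 0.999]`. A detection-p layer is
#' attached: near-zero for good calls, with a small planted fraction of bad
#' probes/calls so probe-level QC has something to remove.
#'
#' @param truth truth table from [generate_site_catalog()].
#' @param cohort covariates from [generate_cohort()].
#' @param seed integer RNG seed.
#' @param bad_probe_rate fraction of probes with a degraded (~5% undetected)
#'   call profile.
#' @param sporadic_undetected_rate per-call rate of sporadic detection failure.
#' @return a [beta_matrix()] with a detection layer.
#' @export
generate_beta_matrix <- function(truth, cohort, seed = 1L,
                                 bad_probe_rate = 0.005,
                                 sporadic_undetected_rate = 0.001) {
  if (anyDuplicated(truth$probe_id)) stop("duplicate probe ids in truth table")
  with_seed(seed, {
    m <- nrow(truth); n <- nrow(cohort)
    age <- cohort$age; male <- cohort$sex == 1
    vals <- matrix(NA_real_, m, n,
                   dimnames = list(truth$probe_id, cohort$sample_id))
    logit_cls <- truth$class %in% c("stable_low", "stable_high",
                                    "promoter_conserved", "age_hyper", "age_hypo")
    if (any(logit_cls)) {
      idx <- which(logit_cls)
      eta <- outer(truth$baseline_logit[idx], rep(1, n)) +
        outer(truth$slope_per_year[idx], age)
      eps <- matrix(stats::rnorm(length(idx) * n), length(idx), n) *
        truth$noise_sd[idx]
      vals[idx, ] <- stats::plogis(eta + eps)
    }
    xi <- which(truth$class == "x_linked")
    if (length(xi) > 0) {
      eta_f <- outer(truth$baseline_logit[xi], rep(1, n)) +
        outer(truth$slope_per_year[xi], age)
      eta <- eta_f
      eta[, male] <- -3.5
      eps <- matrix(stats::rnorm(length(xi) * n), length(xi), n) *
        truth$noise_sd[xi]
      vals[xi, ] <- stats::plogis(eta + eps)
    }
    si <- which(truth$class == "snp_modal")
    for (i in si) {
      g <- stats::rbinom(n, 2, truth$snp_maf[i])
      mu <- c(truth$gm_high[i], truth$gm_mid[i], truth$gm_low[i])[g + 1]
      vals[i, ] <- mu + stats::rnorm(n, 0, truth$noise_sd[i])
    }
    vals <- pmin(pmax(vals, 0.001), 0.999)
    dp <- matrix(stats::runif(m * n, 0, 0.005), m, n,
                 dimnames = dimnames(vals))
    bad_probes <- which(stats::runif(m) < bad_probe_rate)
    if (length(bad_probes) > 0) {
      fail <- matrix(stats::runif(length(bad_probes) * n) < 0.05,
                     length(bad_probes), n)
      dp[bad_probes, ][fail] <- stats::runif(sum(fail), 0.02, 0.5)
    }
    spor <- stats::runif(m * n) < sporadic_undetected_rate
    dp[spor] <- stats::runif(sum(spor), 0.02, 0.5)
    beta_matrix(vals, dp)
  })
}

#' Generate an expression matrix with planted age trends
#'
#' Each probe is assigned a direction (decrease / increase / flat with age)
#' by Bernoulli draws: background probabilities apply genome-wide, and named
#' gene sets can override them (e.g. elevated decrease probability for genes
#' of hypermethylating CpG islands). Directional probes get a linear-in-age
#' log-expression slope large enough to be detected at cohort scale; flat
#' probes have slope exactly zero. The planted direction is returned as truth.
#'
#' @param gene_map data.frame with columns probe_id, gene.
#' @param cohort covariates data.frame.
#' @param effect_probs list with numeric `decrease`, `increase` (background
#'   probabilities) and optional `gene_sets`: a list of
#'   `list(genes =, decrease =, increase =)` overrides (first match wins).
#' @param noise_sd residual SD of log2 expression (default 0.3).
#' @param seed integer RNG seed.
#' @return list with `matrix` (probes x samples) and `truth`
#'   (probe_id, gene, direction, slope_per_year).
#' @export
generate_expression <- function(gene_map, cohort,
                                effect_probs = list(decrease = 0.160,
                                                    increase = 0.133,
                                                    gene_sets = list()),
                                noise_sd = 0.3, seed = 1L) {
  stopifnot(all(c("probe_id", "gene") %in% colnames(gene_map)))
  p_dec <- effect_probs$decrease; p_inc <- effect_probs$increase
  if (p_dec < 0 || p_inc < 0 || p_dec + p_inc > 1)
    stop("direction probabilities must be non-negative and sum to at most 1")
  sets <- effect_probs$gene_sets
  if (is.null(sets)) sets <- list()
  for (s in sets)
    if (s$decrease < 0 || s$increase < 0 || s$decrease + s$increase > 1)
      stop("gene-set direction probabilities invalid")
  with_seed(seed, {
    m <- nrow(gene_map); n <- nrow(cohort)
    dec <- rep(p_dec, m); inc <- rep(p_inc, m)
    for (s in sets) {
      hit <- gene_map$gene %in% s$genes
      dec[hit] <- s$decrease; inc[hit] <- s$increase
    }
    u <- stats::runif(m)
    direction <- ifelse(u < dec, "decrease",
                        ifelse(u < dec + inc, "increase", "flat"))
    slope <- numeric(m)
    slope[direction == "decrease"] <- -stats::runif(sum(direction == "decrease"), 0.01, 0.03)
    slope[direction == "increase"] <- stats::runif(sum(direction == "increase"), 0.01, 0.03)
    intercept <- stats::rnorm(m, 8, 1)
    sex_eff <- stats::rnorm(m, 0, 0.05)
    expr <- outer(intercept, rep(1, n)) + outer(slope, cohort$age - 50) +
      outer(sex_eff, cohort$sex) +
      matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
    dimnames(expr) <- list(gene_map$probe_id, cohort$sample_id)
    truth <- data.frame(probe_id = gene_map$probe_id, gene = gene_map$gene,
                        direction = direction, slope_per_year = slope,
                        stringsAsFactors = FALSE)
    list(matrix = expr, truth = truth)
  })
}

#' Construct a dataset with a known age-driven variance fraction
#'
#' Builds `X = s %o% age_centered + noise` with site loadings scaled so the
#' expected fraction of total (site-centered) variance driven by age equals
#' `f` exactly; the isotropic noise SD is solved from `f`. The matrix is then
#' mapped affinely into `[0.01, 0.99]` (which changes neither variance
#' proportions nor rank correlations) so it is a valid beta matrix. Used to
#' check that PCA-based variance attribution recovers a planted fraction.
#'
#' @param n_samples,m_sites dimensions.
#' @param f target age-driven variance fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with `beta` (a [beta_matrix()]), `cohort` (covariates) and
#'   `f` (the planted fraction).
#' @export
generate_age_variance_dataset <- function(n_samples = 400, m_sites = 5000,
                                          f = 0.25, seed = 1L) {
  if (f <= 0 || f >= 1) stop("f must lie strictly between 0 and 1")
  with_seed(seed, {
    age <- stats::runif(n_samples, 14, 94)
    a <- age - mean(age)
    var_a <- sum(a^2) / (n_samples - 1)
    s <- stats::rnorm(m_sites)
    s <- s / sqrt(mean(s^2))       # sum(s^2) = m_sites
    sigma <- sqrt(var_a * (1 - f) / f)
    x <- outer(s, a) + matrix(stats::rnorm(m_sites * n_samples, 0, sigma),
                              m_sites, n_samples)
    x <- 0.5 + 0.49 * x / max(abs(x))
    dimnames(x) <- list(sprintf("cg%08d", seq_len(m_sites)),
                        sprintf("S%04d", seq_len(n_samples)))
    cohort <- data.frame(sample_id = colnames(x), age = age,
                         sex = stats::rbinom(n_samples, 1, 0.5),
                         bmi = stats::rnorm(n_samples, 26, 4),
                         stringsAsFactors = FALSE)
    list(beta = beta_matrix(x), cohort = cohort, f = f)
  })
}

#' Materialise a complete synthetic dataset directory
#'
#' Generates a cohort, site catalog, beta matrix (with detection layer) and
#' expression data, and writes every file through the package's writers:
#' beta.tsv, detection.tsv, covariates.tsv, manifest.csv, segments.bed,
#' snps.tsv, islands.tsv, expression.tsv, gene_map.tsv, site_truth.tsv,
#' expression_truth.tsv.
#'
#' @param dir output directory (created if needed).
#' @param n_samples,m_sites cohort and catalog sizes.
#' @param seed integer RNG seed.
#' @param class_mix site-class proportions.
#' @param expression_probs background direction probabilities plus planted
#'   suppression for genes of hypermethylating islands (see
#'   [generate_expression()]); `NULL` uses the defaults with hyper-island
#'   genes at decrease 0.2694 / increase 0.0291 and hypo genes at 0.248 /
#'   0.0688.
#' @param header_lines provenance lines for the TSV writers.
#' @return (invisibly) a list of the generated in-memory objects.
#' @export
simulate_dataset <- function(dir, n_samples = 421, m_sites = 10000, seed = 1L,
                             class_mix = default_class_mix(),
                             expression_probs = NULL,
                             header_lines = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cohort_spec(n_samples, seed = seed))
  catalog <- generate_site_catalog(m_sites, class_mix, seed = seed + 1L)
  beta <- generate_beta_matrix(catalog$truth, cohort, seed = seed + 2L)

  hyper_genes <- unlist(strsplit(
    catalog$islands$genes[catalog$islands$type == "hyper"], ";"))
  hypo_genes <- unique(stats::na.omit(
    catalog$manifest$gene[catalog$truth$class == "age_hypo"]))
  if (is.null(expression_probs))
    expression_probs <- list(
      decrease = 0.160, increase = 0.133,
      gene_sets = list(list(genes = hyper_genes, decrease = 0.2694, increase = 0.0291),
                       list(genes = hypo_genes, decrease = 0.248, increase = 0.0688)))
  all_genes <- unique(c(
    unlist(strsplit(catalog$islands$genes, ";")), hypo_genes,
    sprintf("BG%05d", seq_len(max(1, round(m_sites / 10))))))
  gene_map <- data.frame(
    probe_id = sprintf("ep%07d", seq_len(2L * length(all_genes))),
    gene = rep(all_genes, each = 2L), stringsAsFactors = FALSE)
  expr <- generate_expression(gene_map, cohort, expression_probs,
                              seed = seed + 3L)

  p <- function(f) file.path(dir, f)
  write_beta_matrix(beta, p("beta.tsv"), p("detection.tsv"), header_lines)
  write_covariates(cohort, p("covariates.tsv"), header_lines)
  write_manifest(catalog$manifest, p("manifest.csv"))
  utils::write.table(catalog$segments, p("segments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_table_tsv(catalog$snps, p("snps.tsv"), header_lines)
  write_table_tsv(catalog$islands, p("islands.tsv"), header_lines)
  write_table_tsv(catalog$truth, p("site_truth.tsv"), header_lines)
  edf <- data.frame(probe_id = rownames(expr$matrix), expr$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_table_tsv(edf, p("expression.tsv"), header_lines)
  write_table_tsv(gene_map, p("gene_map.tsv"), header_lines)
  write_table_tsv(expr$truth, p("expression_truth.tsv"), header_lines)
  invisible(list(cohort = cohort, catalog = catalog, beta = beta,
                 expression = expr, gene_map = gene_map))
}
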