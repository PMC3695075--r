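test_that("cohort generation respects range, size and seed", {
  spec <- cohort_spec(421, 14, 94, 0.5, seed = 1)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 421)
  expect_true(all(cohort$age >= 14 & cohort$age <= 94))
  expect_true(all(cohort$sex %in% c(0, 1)))
  expect_identical(cohort, generate_cohort(spec))

  expect_equal(nrow(generate_cohort(cohort_spec(2, seed = 3))), 2)
  expect_error(cohort_spec(1), "at least 2")
  expect_error(cohort_spec(10, 50, 40), "age_min")
})

test_that("site catalog hits exact class counts and a consistent geometry", {
  mix <- c(age_hyper = 0.1, age_hypo = 0.2, stable_low = 0.35,
           stable_high = 0.35)
  catalog <- generate_site_catalog(1000, mix, seed = 2)
  counts <- table(catalog$truth$class)
  expect_equal(unname(counts[c("age_hyper", "age_hypo", "stable_low",
                               "stable_high")]),
               c(100L, 200L, 350L, 350L), ignore_attr = TRUE)
  expect_error(generate_site_catalog(100, c(age_hyper = 0.5)), "sum to 1")

  # every flank site sits at the distance its relation claims, relative to
  # the linked island's edge
  man <- catalog$manifest
  isl <- catalog$islands
  idx <- match(man$cgi_id, isl$cgi_id)
  for (i in which(man$relation == "s_shelf")) {
    off <- man$pos[i] - isl$end[idx[i]]
    expect_true(off >= 2001 && off <= 4000)
  }
  for (i in which(man$relation == "n_shore")) {
    off <- isl$start[idx[i]] - man$pos[i]
    expect_true(off >= 1 && off <= 2000)
  }

  # manifest relation agrees with coordinate-based mapping
  on1 <- man$chrom == "chr1"
  expect_identical(man$relation[on1], map_relation(man$pos[on1], isl))

  # determinism
  expect_identical(catalog, generate_site_catalog(1000, mix, seed = 2))
})

test_that("truth slopes respect class sign constraints", {
  truth <- small_dataset()$catalog$truth
  expect_true(all(truth$slope_per_year[truth$class == "age_hyper"] > 0))
  expect_true(all(truth$slope_per_year[truth$class == "age_hypo"] < 0))
  expect_true(all(truth$slope_per_year[truth$class %in%
                  c("stable_low", "stable_high", "promoter_conserved")] == 0))
  gm <- truth[truth$class == "snp_modal", c("gm_low", "gm_mid", "gm_high")]
  expect_true(all(gm$gm_low < gm$gm_mid & gm$gm_mid < gm$gm_high))
})

test_that("beta generation reduces to closed forms in the noiseless limit", {
  cohort <- toy_covariates(60)
  base_truth <- function(class, baseline, slope) {
    data.frame(probe_id = "cg1", class = class, baseline_logit = baseline,
               slope_per_year = slope, noise_sd = 1e-12, snp_maf = NA,
               gm_low = NA, gm_mid = NA, gm_high = NA,
               stringsAsFactors = FALSE)
  }
  bm <- generate_beta_matrix(base_truth("stable_low", -2, 0), cohort, seed = 1)
  expect_equal(unname(bm$values[1, ]), rep(plogis(-2), 60), tolerance = 1e-9)

  bm <- generate_beta_matrix(base_truth("age_hyper", -3, 0.03), cohort, seed = 1)
  o <- order(cohort$age)
  expect_true(all(diff(bm$values[1, o][!duplicated(cohort$age[o])]) > 0))
})

test_that("SNP-modal sites follow Hardy-Weinberg genotype fractions", {
  cohort <- generate_cohort(cohort_spec(10000, seed = 9))
  truth <- data.frame(probe_id = "cg1", class = "snp_modal",
                      baseline_logit = 0, slope_per_year = 0,
                      noise_sd = 0.01, snp_maf = 0.5, gm_low = 0.1,
                      gm_mid = 0.5, gm_high = 0.9, stringsAsFactors = FALSE)
  bm <- generate_beta_matrix(truth, cohort, seed = 10)
  v <- bm$values[1, ]
  frac <- c(mean(v < 0.3), mean(v >= 0.3 & v < 0.7), mean(v >= 0.7))
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.03)
})

test_that("x-linked sites are hemimethylated in females, extreme in males", {
  ds <- small_dataset()
  xs <- ds$catalog$truth$probe_id[ds$catalog$truth$class == "x_linked"]
  v <- ds$beta$values[xs, , drop = FALSE]
  male <- ds$cohort$sex == 1
  expect_true(mean(v[, male]) < 0.15)
  f <- mean(v[, !male])
  expect_true(f > 0.35 && f < 0.65)
})

test_that("pooled stable-site betas are bimodal with low/high modes", {
  ds <- small_dataset()
  stable <- ds$catalog$truth$class %in% c("stable_low", "stable_high")
  pooled <- as.vector(ds$beta$values[stable, seq_len(20)])
  mp <- count_modes(pooled, smoothing = 0.05)
  expect_equal(mp$n_modes, 2L)
  expect_true(mp$mode_locations[1] < 0.25)
  expect_true(mp$mode_locations[2] > 0.75)
})

test_that("expression generator plants directions at the requested rates", {
  cohort <- toy_covariates(50)
  gene_map <- data.frame(probe_id = sprintf("ep%05d", 1:28984),
                         gene = sprintf("G%05d", rep(1:14492, each = 2)),
                         stringsAsFactors = FALSE)
  ex <- generate_expression(gene_map, cohort,
                            effect_probs = list(decrease = 0.160,
                                                increase = 0.133,
                                                gene_sets = list()),
                            seed = 5)
  expect_equal(mean(ex$truth$direction == "decrease"), 0.160, tolerance = 0.01 / 0.160)
  expect_equal(mean(ex$truth$direction == "increase"), 0.133, tolerance = 0.01 / 0.133)
  expect_identical(ex$matrix,
                   generate_expression(gene_map, cohort, seed = 5)$matrix)

  # forced suppression of a gene set, near-noiseless: every probe of the set
  # gets a negative fitted slope
  gm2 <- gene_map[1:40, ]
  ex2 <- generate_expression(gm2, cohort,
                             effect_probs = list(decrease = 0, increase = 0,
                               gene_sets = list(list(genes = gm2$gene,
                                                     decrease = 1, increase = 0))),
                             noise_sd = 1e-6, seed = 6)
  tr <- fit_all_expression(ex2$matrix, cohort)
  expect_true(all(tr$slope_age < 0))
  expect_true(all(tr$direction == "decrease"))
})

test_that("simulate_dataset writes a complete, re-readable directory", {
  d <- withr::local_tempdir()
  simulate_dataset(d, n_samples = 40, m_sites = 300, seed = 8)
  files <- c("beta.tsv", "detection.tsv", "covariates.tsv", "manifest.csv",
             "segments.bed", "snps.tsv", "islands.tsv", "site_truth.tsv",
             "expression.tsv", "gene_map.tsv", "expression_truth.tsv")
  expect_true(all(file.exists(file.path(d, files))))
  bm <- read_beta_matrix(file.path(d, "beta.tsv"), file.path(d, "detection.tsv"))
  expect_equal(dim(bm), c(300L, 40L))
  man <- read_manifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 300)
  seg <- read_bed_states(file.path(d, "segments.bed"))
  expect_true(nrow(seg) > 0)
})
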