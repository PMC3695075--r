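test_that("expression trend fitting classifies exact and null signals", {
  cov <- toy_covariates(50)
  e_dec <- setNames(-cov$age, cov$sample_id)
  tr <- fit_expression(e_dec, cov)
  expect_equal(tr$direction, "decrease")
  expect_lt(tr$p, 1e-12)

  e_const <- setNames(rep(5, 50), cov$sample_id)
  tr2 <- fit_expression(e_const, cov)
  expect_equal(tr2$direction, "flat")
  expect_true(is.na(tr2$p))

  expect_error(fit_expression(e_dec[1:3], cov[1:3, ]), "4 complete")

  # slope equals simple regression when sex is constant
  cov1 <- cov; cov1$sex <- 0
  set.seed(61)
  y <- 3 - 0.01 * cov1$age + rnorm(50, 0, 0.1)
  tr3 <- fit_expression(setNames(y, cov1$sample_id), cov1)
  b_oracle <- sum((cov1$age - mean(cov1$age)) * (y - mean(y))) /
    sum((cov1$age - mean(cov1$age))^2)
  expect_equal(tr3$slope_age, b_oracle, tolerance = 1e-12)
})

test_that("null probes are called directional at about the nominal rate", {
  cov <- toy_covariates(60, seed = 62)
  set.seed(63)
  m <- matrix(rnorm(4000 * 60, 8, 1), 4000, 60,
              dimnames = list(sprintf("ep%04d", 1:4000), cov$sample_id))
  tr <- fit_all_expression(m, cov)
  non_flat <- mean(tr$direction != "flat")
  expect_lt(abs(non_flat - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  expect_lt(abs(mean(tr$direction == "decrease") - 0.025),
            3.5 * sqrt(0.025 * 0.975 / 4000))
})

test_that("direction enrichment chi-square equals the closed form", {
  # gene-level toy: 100 in-set genes with 27 decreases, 900 background with 144
  genes <- sprintf("G%04d", 1:1000)
  direction <- rep("flat", 1000)
  direction[1:27] <- "decrease"                 # in set (first 100 genes)
  direction[101:244] <- "decrease"              # background
  trends <- data.frame(probe_id = paste0("ep", 1:1000), p = 0.001,
                       slope_age = ifelse(direction == "decrease", -1, 0),
                       direction = direction, stringsAsFactors = FALSE)
  gene_map <- data.frame(probe_id = trends$probe_id, gene = genes,
                         stringsAsFactors = FALSE)
  enr <- direction_enrichment(trends, gene_map, genes[1:100])
  o <- matrix(c(27, 73, 144, 756), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(enr$statistic[enr$direction == "decrease"], sum((o - e)^2 / e))
  expect_equal(enr$in_set_frac[enr$direction == "decrease"], 0.27)

  expect_error(direction_enrichment(trends, gene_map, character(0)), "empty")
})

test_that("planted suppression at cohort scale is strongly enriched", {
  # 412 hyper-island genes at 27% decrease vs 28984 mapped probes at 16%
  set.seed(64)
  n_bg <- 28572; n_set <- 412
  genes <- sprintf("G%05d", seq_len(n_bg + n_set))
  in_set <- genes[seq_len(n_set)]
  dirs <- c(ifelse(runif(n_set) < 0.2694, "decrease", "flat"),
            ifelse(runif(n_bg) < 0.16, "decrease", "flat"))
  trends <- data.frame(probe_id = paste0("ep", seq_along(genes)), p = 0.01,
                       slope_age = ifelse(dirs == "decrease", -1, 1),
                       direction = dirs, stringsAsFactors = FALSE)
  gene_map <- data.frame(probe_id = trends$probe_id, gene = genes,
                         stringsAsFactors = FALSE)
  enr <- direction_enrichment(trends, gene_map, in_set)
  expect_lt(enr$p[enr$direction == "decrease"], 0.01)
  expect_gt(enr$in_set_frac[enr$direction == "decrease"],
            enr$background_frac[enr$direction == "decrease"])
})

test_that("fisher overlap test matches hypergeometric enumeration", {
  universe <- letters[1:8]
  res <- set_overlap_fisher(letters[1:4], letters[c(1:3, 5)], universe)
  # 2x2 table: overlap 3, a-only 1, b-only 1, neither 3; one-tailed p is the
  # hypergeometric tail P(X >= 3) drawing 4 from 4 marked / 8
  p_oracle <- sum(dhyper(3:4, 4, 4, 4))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # doubling all counts sharpens an enriched overlap
  uni2 <- c(universe, paste0(universe, "2"))
  res2 <- set_overlap_fisher(c(letters[1:4], paste0(letters[1:4], "2")),
                             c(letters[c(1:3, 5)], paste0(letters[c(1:3, 5)], "2")),
                             uni2)
  expect_lt(res2$p_value, res$p_value)

  # disjoint sets covering the universe: no over-enrichment signal
  res3 <- set_overlap_fisher(letters[1:4], letters[5:8], universe)
  expect_equal(res3$p_value, 1)

  expect_error(set_overlap_fisher("z", letters[1:2], letters[1:8]), "subsets")
  expect_error(set_overlap_fisher("a", "b", character(0)), "universe")
})
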