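test_that("CGI predicate applies the three thresholds conjunctively", {
  expect_true(is_cgi(250, 0.55, 0.7))
  expect_false(is_cgi(200, 0.55, 0.7))   # strict > on length
  expect_false(is_cgi(250, 0.55, 0.6))   # strict > on obs/exp
  expect_false(is_cgi(250, 0.49, 0.7))   # gc is >=
  expect_true(is_cgi(250, 0.50, 0.7))
  expect_true(is_cgi(100, 0.55, 0.1, conjunctive = FALSE))
})

test_that("observed/expected CpG ratio follows the count formula", {
  # "CGCGCG": 3 C, 3 G, 3 CpG, length 6
  expect_equal(obs_exp_ratio(3, 3, 3, 6), 2.0)
  expect_equal(obs_exp_ratio(5, 4, 0, 20), 0)
  expect_equal(obs_exp_ratio(0, 10, 0, 20), 0)
  expect_equal(obs_exp_ratio(6, 6, 6, 12), obs_exp_ratio(3, 3, 3, 6))
  expect_error(obs_exp_ratio(1, 1, 1, 0), "positive")
})

test_that("island relation mapping respects shores, shelves and sides", {
  islands <- data.frame(cgi_id = c("a", "b"), start = c(10000L, 30000L),
                        end = c(11000L, 31000L), stringsAsFactors = FALSE)
  expect_equal(map_relation(10000, islands), "island")  # island start
  expect_equal(map_relation(11000, islands), "island")  # island end
  expect_equal(map_relation(10000 - 1500, islands), "n_shore")
  expect_equal(map_relation(11000 + 1500, islands), "s_shore")
  expect_equal(map_relation(11000 + 3000, islands), "s_shelf")
  expect_equal(map_relation(10000 - 2500, islands), "n_shelf")
  expect_equal(map_relation(11000 + 4001, islands), "open_sea")
  expect_equal(map_relation(1, islands), "open_sea")

  # every position maps to exactly one vocabulary value
  set.seed(51)
  pos <- sample(1:40000, 500)
  rel <- map_relation(pos, islands)
  expect_true(all(rel %in% c("island", "n_shore", "s_shore", "n_shelf",
                             "s_shelf", "open_sea")))
})

test_that("chromatin-state lookup matches a linear-scan oracle", {
  seg <- data.frame(chrom = "chr1", start = c(0L, 100L, 500L),
                    end = c(100L, 300L, 900L), state = c(4L, 1L, 15L),
                    stringsAsFactors = FALSE)
  expect_equal(map_chromatin_state(50, seg), 4L)
  expect_equal(map_chromatin_state(101, seg), 1L)
  expect_true(is.na(map_chromatin_state(450, seg)))

  set.seed(52)
  pos <- sample(1:1000, 1000, replace = TRUE)
  fast <- map_chromatin_state(pos, seg)
  slow <- vapply(pos, function(p) {
    hit <- which(seg$start <= p - 1 & p - 1 < seg$end)
    if (length(hit) == 0) NA_integer_ else seg$state[hit]
  }, integer(1))
  expect_identical(fast, slow)
})

test_that("correlation bins are equal-count, ordered and permutation-stable", {
  set.seed(53)
  res <- data.frame(probe_id = sprintf("cg%04d", 1:101),
                    correlation = runif(101, -1, 1), stringsAsFactors = FALSE)
  b100 <- bin_by_correlation(res[1:100, ], 100)
  expect_equal(as.vector(table(b100$bin)), rep(1L, 100))

  b <- bin_by_correlation(res, 100)
  expect_equal(sum(b$bin == 1), 2)  # remainder goes to the first bin
  expect_equal(sum(b$bin == 2), 1)
  means <- tapply(b$correlation, b$bin, mean)
  expect_true(all(diff(means) >= 0))

  shuffled <- res[sample(101), ]
  b2 <- bin_by_correlation(shuffled, 100)
  expect_identical(b2[order(b2$probe_id), ], b[order(b$probe_id), ],
                   ignore_attr = TRUE)
  expect_error(bin_by_correlation(res, 0), "at least 1")
  expect_error(bin_by_correlation(res, 500), "more bins")
})

test_that("bin fractions are a normalised partition and reject unlabeled sites", {
  res <- data.frame(probe_id = sprintf("cg%03d", 1:60),
                    correlation = seq(-1, 1, length.out = 60),
                    stringsAsFactors = FALSE)
  bins <- bin_by_correlation(res, 10)
  cats <- setNames(rep(c("island", "open_sea"), 30), res$probe_id)
  bf <- bin_fractions(bins, cats, c("island", "open_sea", "n_shore"))
  expect_true(all(abs(rowSums(bf[, c("island", "open_sea", "n_shore")]) - 1)
                  < 1e-9))
  single <- bin_fractions(bins, setNames(rep("island", 60), res$probe_id),
                          "island")
  expect_true(all(single$island == 1))

  cats2 <- cats; cats2["cg007"] <- "volcano"
  expect_error(bin_fractions(bins, cats2, c("island", "open_sea")), "cg007")
  expect_error(bin_fractions(bins, cats[-1], c("island", "open_sea")),
               "without a category")
})

test_that("per-bin island statistics equal a brute-force group-by", {
  set.seed(54)
  islands <- data.frame(cgi_id = sprintf("CGI%02d", 1:20),
                        length = sample(200:2000, 20),
                        pct_cpg = runif(20, 5, 20),
                        obs_exp = runif(20, 0.6, 1.2), stringsAsFactors = FALSE)
  res <- data.frame(probe_id = sprintf("cg%03d", 1:200),
                    correlation = rnorm(200), stringsAsFactors = FALSE)
  site_cgi <- setNames(sample(c(islands$cgi_id, NA), 200, replace = TRUE),
                       res$probe_id)
  bins <- bin_by_correlation(res, 10)
  st <- bin_cgi_stats(bins, islands, site_cgi)
  for (bn in st$bin) {
    ids <- bins$probe_id[bins$bin == bn]
    lens <- islands$length[match(site_cgi[ids], islands$cgi_id)]
    want <- if (all(is.na(lens))) NA_real_ else mean(lens, na.rm = TRUE)
    expect_equal(st$mean_length[st$bin == bn], want)
  }

  # identical islands: every bin mean equals the common stats
  isl1 <- islands; isl1$length <- 500L; isl1$pct_cpg <- 10; isl1$obs_exp <- 0.8
  st1 <- bin_cgi_stats(bins, isl1, site_cgi)
  got <- st1$mean_length[!is.na(st1$mean_length)]
  expect_true(all(got == 500))
})
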