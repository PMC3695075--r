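# Shared in-code fixtures. All data are generated programmatically; nothing
# is read from disk except files the tests themselves write to tempdirs.

# A tiny hand-built BetaMatrix with a detection layer.
tiny_beta <- function() {
  v <- matrix(c(0.1, 0.4, 0.9, 0.2, 0.5, 0.8), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), c("S1", "S2")))
  dp <- matrix(0, 3, 2, dimnames = dimnames(v))
  beta_matrix(v, dp)
}

# A small simulated dataset (cohort + catalog + beta), cached per session so
# several test files can share it without regenerating.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(cohort_spec(150, seed = 42))
      catalog <- generate_site_catalog(2000, seed = 43)
      beta <- generate_beta_matrix(catalog$truth, cohort, seed = 44)
      cache <<- list(cohort = cohort, catalog = catalog, beta = beta)
    }
    cache
  }
})

# Simple covariate table with both sexes and no missing BMI.
toy_covariates <- function(n = 40, seed = 7) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             age = round(runif(n, 14, 94), 1),
             sex = rep_len(c(0, 1), n),
             bmi = round(rnorm(n, 26, 3), 1),
             stringsAsFactors = FALSE)
}

# Beta rows as a matrix keyed to a covariate table.
row_matrix <- function(rows, covariates) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("cg", seq_len(nrow(m)))
  colnames(m) <- covariates$sample_id
  m
}
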