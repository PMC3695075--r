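#' Construct a validated beta-value matrix
#'
#' A `BetaMatrix` holds per-site methylation fractions (beta values) for a
#' cohort: a numeric matrix with sites in rows and samples in columns, all
#' non-missing values in `[0, 1]`, plus an optional same-shape layer of
#' per-call detection p-values. Missing calls are `NA`.
#'
#' @param values numeric matrix, sites x samples, with unique rownames
#'   (probe ids) and colnames (sample ids); values in `[0, 1]` or `NA`.
#' @param detection_p optional numeric matrix of per-call detection
#'   p-values with identical dimensions and dimnames.
#' @return an object of class `BetaMatrix` (a list with elements `values`
#'   and `detection_p`).
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (sites) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate site ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at site '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values)))
      stop("`detection_p` must be a matrix with the same shape as `values`")
    if (!identical(dimnames(detection_p), dimnames(values)))
      stop("`detection_p` dimnames must match `values`")
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values must lie in [0,1]")
  }
  structure(list(values = values, detection_p = detection_p),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d sites x %d samples (%s detection layer, %d missing calls)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "no" else "with",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

#' Subset a BetaMatrix by site and/or sample ids
#'
#' @param x a `BetaMatrix`.
#' @param sites,samples character vectors of ids (or logical/integer
#'   indices); `NULL` keeps everything.
#' @return a `BetaMatrix`.
#' @export
subset_beta <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "BetaMatrix"))
  if (is.null(sites)) sites <- seq_len(nrow(x$values))
  if (is.null(samples)) samples <- seq_len(ncol(x$values))
  v <- x$values[sites, samples, drop = FALSE]
  dp <- if (is.null(x$detection_p)) NULL else
    x$detection_p[sites, samples, drop = FALSE]
  beta_matrix(v, dp)
}
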