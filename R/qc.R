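# Probe- and sample-level quality control. A call is "detected" iff its
# detection p-value is <= the threshold; a probe is kept iff its detected
# fraction is strictly greater than the call-rate threshold (the comparison
# directions follow the thresholds' conventional wording: detection p <= 0.01,
# call rate > 0.98). No sample-level exclusion is applied; per-sample call
# rates are reported only.

#' Filter probes by detection call rate
#'
#' @param x a [beta_matrix()] with a detection layer.
#' @param max_detection_p a call is detected iff `detection_p <=` this
#'   (default 0.01).
#' @param min_call_rate a probe is kept iff its detected fraction is `>` this
#'   (default 0.98, strict).
#' @return list with `matrix` (the surviving `BetaMatrix`, undetected calls
#'   set to `NA`) and `report` (probe_id, call_rate, removed).
#' @export
filter_probes <- function(x, max_detection_p = 0.01, min_call_rate = 0.98) {
  stopifnot(inherits(x, "BetaMatrix"))
  if (is.null(x$detection_p)) stop("beta matrix has no detection p-value layer")
  if (max_detection_p <= 0 || max_detection_p > 1 ||
      min_call_rate <= 0 || min_call_rate > 1)
    stop("thresholds must lie in (0, 1]")
  detected <- x$detection_p <= max_detection_p & !is.na(x$values)
  call_rate <- rowMeans(detected)
  keep <- call_rate > min_call_rate
  report <- data.frame(probe_id = rownames(x$values), call_rate = call_rate,
                       removed = !keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  vals <- x$values[keep, , drop = FALSE]
  vals[!detected[keep, , drop = FALSE]] <- NA_real_
  dp <- x$detection_p[keep, , drop = FALSE]
  list(matrix = beta_matrix(vals, dp), report = report)
}

#' Per-sample call rates
#'
#' Fraction of sites detected (detection p <= threshold) in each sample. No
#' filtering is performed; samples are reported only.
#'
#' @param x a [beta_matrix()] with a detection layer.
#' @param max_detection_p detection threshold (default 0.01).
#' @return data.frame with sample_id and call_rate.
#' @export
sample_call_rates <- function(x, max_detection_p = 0.01) {
  stopifnot(inherits(x, "BetaMatrix"))
  if (is.null(x$detection_p)) stop("beta matrix has no detection p-value layer")
  detected <- x$detection_p <= max_detection_p & !is.na(x$values)
  data.frame(sample_id = colnames(x$values), call_rate = colMeans(detected),
             row.names = NULL, stringsAsFactors = FALSE)
}
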