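#' Beta values from intensities
#'
#' The methylation fraction at each probe is computed as
#' `beta = meth / (meth + unmeth + offset)`, the standard Illumina
#' formula with a positive offset (default 100) that stabilises
#' low-intensity probes and keeps beta strictly below 1.
#'
#' @param x An [intensity_data] object, or a list with `meth` and
#'   `unmeth` matrices.
#' @param offset Positive stabilising offset added to the denominator.
#' @return Probes x samples matrix of beta values in `[0, 1)`.
#' @export
beta_values <- function(x, offset = 100) {
  if (offset <= 0) abort("offset must be positive")
  x$meth / (x$meth + x$unmeth + offset)
}

#' M-values from intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`, the log2 ratio of
#' methylated to unmethylated intensities. The offset (default 1, the
#' smallest perturbation preventing division by zero) guarantees finite
#' values; for large intensities M approaches `logit2(beta)`.
#'
#' @inheritParams beta_values
#' @param offset Positive offset added to both intensities.
#' @return Probes x samples matrix of M-values (unbounded, finite).
#' @export
m_values <- function(x, offset = 1) {
  if (offset <= 0) abort("offset must be positive")
  log2((x$meth + offset) / (x$unmeth + offset))
}

#' Case-control difference in percent methylation
#'
#' Per-probe effect size: `100 * (mean beta in cases - mean beta in
#' controls)`, in percentage points. Positive values mean relative
#' hypermethylation in cases; negative values hypomethylation. Missing
#' beta values are excluded per group.
#'
#' @param beta Probes x samples beta matrix.
#' @param case_labels Logical vector (length = samples): `TRUE` = case.
#' @return Tibble with `probe_id` and `delta_percent`.
#' @export
delta_beta <- function(beta, case_labels) {
  case_labels <- as.logical(case_labels)
  if (length(case_labels) != ncol(beta)) {
    abort("case_labels length must equal the number of samples")
  }
  if (!any(case_labels, na.rm = TRUE) || !any(!case_labels, na.rm = TRUE)) {
    abort("need at least one case and one control")
  }
  mcase <- rowMeans(beta[, which(case_labels), drop = FALSE], na.rm = TRUE)
  mctrl <- rowMeans(beta[, which(!case_labels), drop = FALSE], na.rm = TRUE)
  tibble(probe_id = rownames(beta),
         delta_percent = unname(100 * (mcase - mctrl)))
}
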