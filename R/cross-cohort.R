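#' Per-probe difference of association test statistics
#'
#' Joins two EWAS result tables on probe id and computes
#' `diff = t_a - t_b`, retaining the direction of effect. Both results
#' must come from pipelines run with identical settings for the
#' comparison to be meaningful.
#'
#' @param results_a,results_b Tibbles with `probe_id` and
#'   `t_statistic` columns (e.g. from [run_ewas()]).
#' @return Tibble with `probe_id`, `stat_a`, `stat_b`, `diff`.
#' @export
statistic_difference <- function(results_a, results_b) {
  a <- dplyr::select(as_tibble(results_a), "probe_id", stat_a = "t_statistic")
  b <- dplyr::select(as_tibble(results_b), "probe_id", stat_b = "t_statistic")
  out <- dplyr::inner_join(a, b, by = "probe_id")
  if (nrow(out) == 0) abort("no probes shared between the two result tables")
  dplyr::mutate(out, diff = .data$stat_a - .data$stat_b)
}

#' Flag the tail of the test-statistic-difference distribution
#'
#' Fits location and scale to the per-probe differences and flags the
#' probes strictly beyond the tail cutoff. `method = "empirical"` uses
#' the empirical quantile (linear interpolation); `method =
#' "normal_fit"` uses the normal quantile `mean + sd * qnorm(tail)`
#' from the sample mean and standard deviation. Flagging is a
#' qualitative, hypothesis-generating screen: no per-probe p-value is
#' attached.
#'
#' @param diffs Tibble from [statistic_difference()] (or any tibble
#'   with `probe_id` and `diff`).
#' @param tail Tail probability (default 0.025, the lower 2.5
#'   percentile).
#' @param method `"empirical"` or `"normal_fit"`.
#' @param side `"lower"` (default) flags `diff < cutoff`; `"upper"`
#'   flags `diff > cutoff` at the mirrored quantile.
#' @return A `cross_cohort_result` tibble (`probe_id`, `stat_a`,
#'   `stat_b`, `diff`, `flagged`) with attributes `fit_mean`,
#'   `fit_sd`, `cutoff`, `method`, `tail`, `side`.
#' @export
flag_lower_tail <- function(diffs, tail = 0.025,
                            method = c("empirical", "normal_fit"),
                            side = c("lower", "upper")) {
  method <- match.arg(method)
  side <- match.arg(side)
  d <- diffs$diff
  if (length(d) < 100) {
    warn("fewer than 100 differences; the tail estimate is unstable")
  }
  fit_mean <- mean(d)
  fit_sd <- sd(d)
  if (is.na(fit_sd) || fit_sd == 0) {
    abort("test-statistic differences are degenerate (zero variance)")
  }
  q <- if (side == "lower") tail else 1 - tail
  cutoff <- switch(method,
                   empirical = unname(quantile(d, probs = q, type = 7)),
                   normal_fit = fit_mean + fit_sd * qnorm(q))
  out <- dplyr::mutate(as_tibble(diffs),
                       flagged = if (side == "lower") d < cutoff else d > cutoff)
  class(out) <- c("cross_cohort_result", class(out))
  attr(out, "fit_mean") <- fit_mean
  attr(out, "fit_sd") <- fit_sd
  attr(out, "cutoff") <- cutoff
  attr(out, "method") <- method
  attr(out, "tail") <- tail
  attr(out, "side") <- side
  out
}

#' @export
glance.cross_cohort_result <- function(x, ...) {
  tibble(n_probes = nrow(x), n_flagged = sum(x$flagged),
         fit_mean = attr(x, "fit_mean"), fit_sd = attr(x, "fit_sd"),
         cutoff = attr(x, "cutoff"), method = attr(x, "method"),
         tail = attr(x, "tail"), side = attr(x, "side"))
}

#' Two-cohort qualitative screen
#'
#' Runs the identical QC -> cell deconvolution -> EWAS pipeline on two
#' cohorts with the same settings, then computes the per-probe
#' test-statistic difference and flags the tail. A settings hash is
#' recorded to guarantee both cohorts were processed identically.
#'
#' @param cohort_a,cohort_b Lists with elements `data`
#'   ([intensity_data]), `annotation`, `sample_sheet`, and `reference`
#'   (cell-type reference beta matrix; may be shared).
#' @param settings A [pipeline_settings()] list.
#' @return A `cross_cohort_result` (see [flag_lower_tail()]) with
#'   attributes `settings_hash` and `ewas` (the two result tables).
#' @export
paired_screen <- function(cohort_a, cohort_b, settings = pipeline_settings()) {
  run_one <- function(cohort) {
    qc <- run_qc(cohort$data, cohort$annotation, cohort$sample_sheet,
                 thresholds = settings$qc)
    ref <- cohort$reference
    props <- estimate_cell_proportions(
      beta_values(qc$data, offset = settings$beta_offset), ref)
    cc <- deconvolution_covariates(props, mode = settings$deconvolution_mode)
    run_ewas(qc$data, qc$sample_sheet, qc$annotation,
             cell_covariates = cc, moderation = settings$moderation,
             beta_offset = settings$beta_offset, m_offset = settings$m_offset)
  }
  res_a <- run_one(cohort_a)
  res_b <- run_one(cohort_b)
  diffs <- statistic_difference(res_a, res_b)
  if (sd(diffs$diff) == 0) {
    abort("cohorts yield identical statistics (degenerate difference distribution)")
  }
  out <- flag_lower_tail(diffs, tail = settings$tail,
                         method = settings$tail_method)
  attr(out, "settings_hash") <- rlang::hash(settings)
  attr(out, "ewas") <- list(cohort_a = res_a, cohort_b = res_b)
  out
}

#' Serialise a cross-cohort screen
#'
#' Writes the per-probe differences with flags as TSV and the fit
#' parameters and cutoff as JSON.
#'
#' @param result A `cross_cohort_result`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cross_cohort <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "cross_cohort_diffs.tsv")
  js <- file.path(dir, "cross_cohort_summary.json")
  readr::write_tsv(as_tibble(result), tsv)
  jsonlite::write_json(as.list(glance(result)), js,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
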