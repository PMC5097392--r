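#' Quality-control thresholds
#'
#' Bundles the tunable QC thresholds. Defaults follow common 27K
#' whole-blood practice: a measurement fails detection at p > 0.05; a
#' probe is dropped when more than 1% of samples fail detection or more
#' than 5% of samples have beadcount below 3; a sample is dropped when
#' more than 1% of its sites fail detection. All comparisons are
#' strict.
#'
#' @param detection_p_max Detection p-value above which a single
#'   measurement counts as failed.
#' @param probe_detection_frac Probe removed when the failed-detection
#'   sample fraction strictly exceeds this.
#' @param bead_min Beadcount below which a measurement is unreliable.
#' @param bead_frac Probe removed when the low-bead sample fraction
#'   strictly exceeds this.
#' @param sample_detection_frac Sample removed when its failed-site
#'   fraction strictly exceeds this.
#' @param concordance_delta Absolute beta difference defining replicate
#'   concordance ([replicate_concordance()]).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(detection_p_max = 0.05,
                          probe_detection_frac = 0.01,
                          bead_min = 3,
                          bead_frac = 0.05,
                          sample_detection_frac = 0.01,
                          concordance_delta = 0.10) {
  structure(list(detection_p_max = detection_p_max,
                 probe_detection_frac = probe_detection_frac,
                 bead_min = bead_min,
                 bead_frac = bead_frac,
                 sample_detection_frac = sample_detection_frac,
                 concordance_delta = concordance_delta),
            class = "qc_thresholds")
}

#' Annotation-based probe filters
#'
#' Removes probes flagged for a SNP within 5 bp of the interrogated
#' CpG, probes over genomic repeat regions, and probes on the sex
#' chromosomes (X/Y). Each removal gets one primary reason with fixed
#' precedence SNP > repeat > sex, so the ledger is deterministic.
#'
#' @param probes Character vector of probe ids present in the dataset.
#' @param annotation Probe annotation tibble (see
#'   [read_probe_annotation()]); must cover every probe.
#' @return List with `kept` (character vector) and `removed` (tibble
#'   `probe_id`, `reason`).
#' @export
filter_probes_annotation <- function(probes, annotation) {
  miss <- setdiff(probes, annotation$probe_id)
  if (length(miss) > 0) {
    abort(sprintf("probe(s) missing from annotation: %s%s",
                  paste(head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) ", ..." else ""))
  }
  ann <- annotation[match(probes, annotation$probe_id), ]
  reason <- rep(NA_character_, length(probes))
  sex <- ann$chromosome %in% c("X", "Y")
  reason[sex] <- "sex_chromosome"
  reason[ann$repeat_region %in% TRUE] <- "repeat_under_probe"
  reason[ann$snp_within_5bp %in% TRUE] <- "snp_under_probe"
  removed <- tibble(probe_id = probes[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  list(kept = probes[is.na(reason)], removed = removed)
}

#' Signal-based probe filters
#'
#' Removes probes whose fraction of samples with `beadcount < bead_min`
#' strictly exceeds `bead_frac`, or whose fraction of samples with
#' `detection_p > detection_p_max` strictly exceeds
#' `probe_detection_frac`. When both conditions hold the recorded
#' reason is `low_beadcount`.
#'
#' @param detection_p,beadcount Probes x samples matrices restricted to
#'   the current probe and sample sets.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `kept` and `removed` as in
#'   [filter_probes_annotation()].
#' @export
filter_probes_signal <- function(detection_p, beadcount,
                                 thresholds = qc_thresholds()) {
  if (ncol(detection_p) == 0) abort("empty sample set")
  low_bead <- rowMeans(beadcount < thresholds$bead_min) > thresholds$bead_frac
  det_fail <- rowMeans(detection_p > thresholds$detection_p_max) >
    thresholds$probe_detection_frac
  reason <- rep(NA_character_, nrow(detection_p))
  reason[det_fail] <- "high_detection_p"
  reason[low_bead] <- "low_beadcount"
  probes <- rownames(detection_p)
  removed <- tibble(probe_id = probes[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  list(kept = probes[is.na(reason)], removed = removed)
}

#' Subject-level filters
#'
#' First removes samples whose fraction of sites with
#' `detection_p > detection_p_max` strictly exceeds
#' `sample_detection_frac` (evaluated on the probes surviving
#' annotation filtering), then samples with any missing model covariate
#' (case status, age, gender, pack-years, batch).
#'
#' @param detection_p Probes x samples detection p-value matrix.
#' @param sample_sheet Sample sheet tibble.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `kept` (sample ids) and `removed` (tibble
#'   `sample_id`, `reason`).
#' @export
filter_samples <- function(detection_p, sample_sheet,
                           thresholds = qc_thresholds()) {
  samples <- colnames(detection_p)
  ss <- sample_sheet[match(samples, sample_sheet$sample_id), ]
  frac_fail <- colMeans(detection_p > thresholds$detection_p_max)
  reason <- rep(NA_character_, length(samples))
  reason[!ss$covariates_complete] <- "incomplete_covariates"
  reason[frac_fail > thresholds$sample_detection_frac] <- "sample_detection_fail"
  if (all(!is.na(reason))) abort("all samples removed by subject-level QC: unusable dataset")
  removed <- tibble(sample_id = samples[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  list(kept = samples[is.na(reason)], removed = removed)
}

#' Technical replicate concordance
#'
#' For every pair declared via `replicate_of`, reports the Pearson
#' correlation of beta values across probes and the fraction of probes
#' with `|delta beta| <= concordance_delta` (default 0.10). Both
#' metrics are reported; neither gates the pipeline.
#'
#' @param beta Probes x samples beta matrix.
#' @param sample_sheet Sample sheet tibble with `replicate_of`.
#' @param thresholds A [qc_thresholds()] list.
#' @return Tibble with one row per replicate pair: `sample_id`,
#'   `replicate_of`, `n_probes`, `correlation`, `frac_concordant`.
#' @export
replicate_concordance <- function(beta, sample_sheet,
                                  thresholds = qc_thresholds()) {
  pairs <- sample_sheet[!is.na(sample_sheet$replicate_of), ]
  if (nrow(pairs) == 0) abort("no replicate pairs declared via replicate_of")
  purrr::pmap_dfr(list(pairs$sample_id, pairs$replicate_of), function(rep_id, orig_id) {
    if (!all(c(rep_id, orig_id) %in% colnames(beta))) {
      abort(sprintf("replicate pair (%s, %s) not present in beta matrix", rep_id, orig_id))
    }
    a <- beta[, rep_id]
    b <- beta[, orig_id]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10) {
      abort(sprintf("replicate pair (%s, %s) shares fewer than 10 probes", rep_id, orig_id))
    }
    tibble(sample_id = rep_id, replicate_of = orig_id, n_probes = sum(ok),
           correlation = cor(a[ok], b[ok]),
           frac_concordant = mean(abs(a[ok] - b[ok]) <= thresholds$concordance_delta))
  })
}

#' Run the full QC cascade
#'
#' Applies, in order: annotation probe filters, subject-level filters
#' (detection failure, then incomplete covariates, then removal of
#' technical-replicate duplicate columns after concordance is
#' computed), and signal-based probe filters. The order means failed
#' samples do not drive probe loss. Every removal is recorded with one
#' reason; the stage ledger conserves counts (before - removed =
#' after), and the cascade is idempotent.
#'
#' @param data An [intensity_data] object.
#' @param annotation Probe annotation tibble covering all probes.
#' @param sample_sheet Sample sheet tibble covering all samples.
#' @param thresholds A [qc_thresholds()] list.
#' @return A `qc_result` list: filtered `data`, `annotation`,
#'   `sample_sheet`, and `report` (list of `stages`, `removals`,
#'   `concordance` tibbles).
#' @export
run_qc <- function(data, annotation, sample_sheet,
                   thresholds = qc_thresholds()) {
  stopifnot(inherits(data, "intensity_data"))
  ss <- sample_sheet[match(sample_ids(data), sample_sheet$sample_id), ]
  if (anyNA(ss$sample_id)) abort("sample sheet does not cover every sample in the data")
  stages <- list()
  removals <- list()

  # stage 1: annotation probe filters
  n0 <- nrow(data$meth)
  ann_f <- filter_probes_annotation(probe_ids(data), annotation)
  data <- data[ann_f$kept, ]
  stages$annotation_probes <- tibble(stage = "annotation_probes", unit = "probe",
                                     n_before = n0, n_removed = n0 - length(ann_f$kept),
                                     n_after = length(ann_f$kept))
  removals$probes_ann <- ann_f$removed

  # replicate concordance (reported, not gating), on current probes
  concordance <- NULL
  if (any(!is.na(ss$replicate_of))) {
    concordance <- replicate_concordance(beta_values(data), ss, thresholds)
  }

  # stage 2: subject-level filters
  s0 <- ncol(data$meth)
  samp_f <- filter_samples(data$detection_p, ss, thresholds)
  rep_dup <- intersect(samp_f$kept, ss$sample_id[!is.na(ss$replicate_of)])
  kept_samples <- setdiff(samp_f$kept, rep_dup)
  sample_removed <- dplyr::bind_rows(
    samp_f$removed,
    tibble(sample_id = rep_dup,
           reason = rep("technical_replicate", length(rep_dup))))
  data <- data[, kept_samples]
  ss <- ss[match(kept_samples, ss$sample_id), ]
  stages$samples <- tibble(stage = "samples", unit = "sample",
                           n_before = s0, n_removed = s0 - length(kept_samples),
                           n_after = length(kept_samples))
  removals$samples <- sample_removed

  # stage 3: signal probe filters on surviving samples
  p0 <- nrow(data$meth)
  sig_f <- filter_probes_signal(data$detection_p, data$beadcount, thresholds)
  data <- data[sig_f$kept, ]
  stages$signal_probes <- tibble(stage = "signal_probes", unit = "probe",
                                 n_before = p0, n_removed = p0 - length(sig_f$kept),
                                 n_after = length(sig_f$kept))
  removals$probes_sig <- sig_f$removed

  report <- list(
    stages = dplyr::bind_rows(stages),
    removals = dplyr::bind_rows(
      dplyr::rename(removals$probes_ann, item_id = "probe_id"),
      dplyr::rename(removals$samples, item_id = "sample_id"),
      dplyr::rename(removals$probes_sig, item_id = "probe_id")),
    concordance = concordance,
    thresholds = thresholds)
  structure(list(data = data,
                 annotation = annotation[match(probe_ids(data), annotation$probe_id), ],
                 sample_sheet = ss,
                 report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(as.data.frame(x$report$stages), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) x$report$removals

#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_probes = nrow(x$data$meth),
         n_samples = ncol(x$data$meth),
         n_probes_removed = sum(x$report$stages$n_removed[x$report$stages$unit == "probe"]),
         n_samples_removed = sum(x$report$stages$n_removed[x$report$stages$unit == "sample"]))
}

#' Serialise a QC report
#'
#' Writes the per-item removal ledger as TSV and the stage summary
#' (plus thresholds and replicate concordance) as JSON.
#'
#' @param qc A `qc_result` from [run_qc()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(qc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ledger <- file.path(dir, "qc_ledger.tsv")
  summary_path <- file.path(dir, "qc_summary.json")
  readr::write_tsv(qc$report$removals, ledger)
  jsonlite::write_json(
    list(stages = qc$report$stages,
         thresholds = unclass(qc$report$thresholds),
         concordance = qc$report$concordance),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(ledger, summary_path))
}
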