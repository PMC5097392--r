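#' Pipeline settings
#'
#' Aggregates every stage threshold behind one object so a run (or a
#' pair of cohort runs) is fully described by its settings: QC
#' thresholds, transform offsets, FDR levels, cross-cohort tail,
#' network configuration, kME cutoff, deconvolution covariate mode,
#' and variance moderation.
#'
#' @param qc A [qc_thresholds()] list.
#' @param beta_offset,m_offset Transform offsets.
#' @param fdr_levels Primary and secondary FDR levels.
#' @param tail Cross-cohort tail probability.
#' @param tail_method `"empirical"` or `"normal_fit"`.
#' @param network A [network_config()].
#' @param kme_cutoff Strict module-membership cutoff.
#' @param deconvolution_mode `"proportions"` or
#'   `"principal_components"`.
#' @param moderation Empirical-Bayes variance moderation in the EWAS.
#' @param seed Seed recorded in run manifests.
#' @return A `pipeline_settings` list.
#' @export
pipeline_settings <- function(qc = qc_thresholds(),
                              beta_offset = 100, m_offset = 1,
                              fdr_levels = c(0.05, 0.10),
                              tail = 0.025,
                              tail_method = "empirical",
                              network = network_config(),
                              kme_cutoff = 0.85,
                              deconvolution_mode = "proportions",
                              moderation = TRUE,
                              seed = 1L) {
  stopifnot(tail > 0, tail < 0.5, kme_cutoff > 0, kme_cutoff <= 1,
            all(fdr_levels > 0 & fdr_levels < 1))
  structure(list(qc = qc, beta_offset = beta_offset, m_offset = m_offset,
                 fdr_levels = fdr_levels, tail = tail,
                 tail_method = tail_method, network = network,
                 kme_cutoff = kme_cutoff,
                 deconvolution_mode = deconvolution_mode,
                 moderation = moderation, seed = seed),
            class = "pipeline_settings")
}

#' Run the full analysis pipeline
#'
#' Chains QC, cell-type deconvolution, differential methylation,
#' comethylation network analysis and (when gene sets are supplied)
#' enrichment of the kME-limited COPD-associated modules. When
#' `outdir` is given, every stage artifact is written as TSV/JSON
#' together with a run manifest (settings hash, seed, row counts, file
#' checksums), so a run is resumable and auditable.
#'
#' @param data An [intensity_data] object.
#' @param annotation Probe annotation tibble.
#' @param sample_sheet Sample sheet tibble.
#' @param reference Cell-type reference beta matrix.
#' @param gene_sets Optional `gene_set_collection` for enrichment.
#' @param settings A [pipeline_settings()] list.
#' @param outdir Optional output directory.
#' @return A `copd_pipeline` list: `qc`, `proportions`,
#'   `cell_covariates`, `ewas`, `significant`, `network`,
#'   `eigengene_logistic`, `enrichment`, `settings`.
#' @export
run_pipeline <- function(data, annotation, sample_sheet, reference,
                         gene_sets = NULL,
                         settings = pipeline_settings(),
                         outdir = NULL) {
  qc <- run_qc(data, annotation, sample_sheet, thresholds = settings$qc)
  beta <- beta_values(qc$data, offset = settings$beta_offset)
  props <- estimate_cell_proportions(beta, reference)
  cc <- deconvolution_covariates(props, mode = settings$deconvolution_mode)
  ewas <- run_ewas(qc$data, qc$sample_sheet, qc$annotation,
                   cell_covariates = cc, moderation = settings$moderation,
                   beta_offset = settings$beta_offset,
                   m_offset = settings$m_offset)
  sig <- significant_sets(ewas, settings$fdr_levels)

  M <- m_values(qc$data, offset = settings$m_offset)
  traits <- data.frame(copd = as.numeric(qc$sample_sheet$copd_case),
                       age = qc$sample_sheet$age,
                       pack_years = qc$sample_sheet$pack_years)
  network <- build_network(M, traits, settings$network)

  trait_mods <- dplyr::filter(network$module_trait, .data$trait == "copd",
                              .data$p_value < 0.05)
  eg_logit <- purrr::map_dfr(trait_mods$module, function(mod) {
    e <- eigengene_matrix(network$eigengenes)[, mod]
    tryCatch(
      dplyr::mutate(eigengene_logistic(e, qc$sample_sheet), module = mod,
                    separated = FALSE, .before = 1),
      error = function(err) {
        tibble(module = mod, separated = TRUE, coefficient = NA_real_,
               std_error = NA_real_, z_statistic = NA_real_,
               p_value = NA_real_, n = nrow(qc$sample_sheet))
      })
  })

  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(trait_mods) > 0) {
    enrichment <- purrr::map_dfr(trait_mods$module, function(mod) {
      lim <- limit_module(network$assignment, network$kme,
                          cutoff = settings$kme_cutoff)
      lim <- dplyr::filter(lim, .data$module == mod)
      if (nrow(lim) == 0) return(NULL)
      dplyr::mutate(module_enrichment(lim, qc$annotation, gene_sets),
                    module = mod, .before = 1)
    })
  }

  out <- structure(list(qc = qc, proportions = props, cell_covariates = cc,
                        ewas = ewas, significant = sig, network = network,
                        eigengene_logistic = eg_logit,
                        enrichment = enrichment, settings = settings),
                   class = "copd_pipeline")
  if (!is.null(outdir)) write_pipeline_artifacts(out, outdir)
  out
}

#' @export
print.copd_pipeline <- function(x, ...) {
  cat("<copd_pipeline>\n")
  g <- glance(x$qc)
  cat(sprintf("  post-QC: %d probes x %d samples\n", g$n_probes, g$n_samples))
  cat(sprintf("  EWAS: %d probes, %d at FDR < %g, %d more at FDR < %g\n",
              nrow(x$ewas), length(x$significant$fdr5),
              x$settings$fdr_levels[1],
              length(x$significant$fdr10_additional),
              x$settings$fdr_levels[2]))
  sizes <- attr(x$network$assignment, "sizes")
  cat(sprintf("  network: %d modules (%s)\n", length(sizes),
              paste(names(sizes), as.integer(sizes), sep = ":", collapse = ", ")))
  invisible(x)
}

write_pipeline_artifacts <- function(x, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  paths <- c(paths, write_qc_report(x$qc, outdir))
  wr <- function(tbl, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(as_tibble(tbl), p)
    p
  }
  paths <- c(paths, wr(x$proportions, "cell_proportions.tsv"))
  paths <- c(paths, wr(x$ewas, "ewas_results.tsv"))
  paths <- c(paths, wr(tidy(x$network), "module_assignment.tsv"))
  paths <- c(paths, wr(x$network$module_trait, "module_trait.tsv"))
  paths <- c(paths, wr(x$network$eigengenes, "eigengenes.tsv"))
  if (nrow(x$eigengene_logistic) > 0) {
    paths <- c(paths, wr(x$eigengene_logistic, "eigengene_logistic.tsv"))
  }
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
    paths <- c(paths, wr(x$enrichment, "enrichment.tsv"))
  }
  manifest <- list(
    settings_hash = rlang::hash(x$settings),
    seed = x$settings$seed,
    n_probes = nrow(x$ewas),
    n_samples = ncol(x$qc$data$meth),
    files = purrr::map(setNames(paths, basename(paths)), function(p) {
      list(md5 = unname(tools::md5sum(p)), rows = length(readLines(p)) - 1L)
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(outdir, "manifest.json")))
}
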