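#' Simulation configuration
#'
#' Defines a two-arm (and optionally two-cohort) 27K-like whole-blood
#' methylation study with known ground truth. Defaults emulate the
#' study design the pipeline targets: 93 cases / 269 smoking controls
#' in the primary cohort and 678 / 427 in the comparison cohort,
#' planted differentially methylated positions (DMPs) with mean beta
#' differences of 0.05-0.12 hypomethylated in cases, planted
#' comethylation blocks, case-shifted blood cell composition
#' (granulocytosis with relative lymphopenia, making composition
#' confounding active by default), batch effects, and planted QC
#' artifacts (SNP/repeat/sex probes, low-beadcount and
#' detection-failure probes, one failing sample, incomplete
#' covariates, technical replicate pairs).
#'
#' @param seed Base random seed.
#' @param n_probes Number of probes before QC.
#' @param n_cases,n_controls Primary-cohort arm sizes (post-QC).
#' @param n_cases_b,n_controls_b Comparison-cohort arm sizes.
#' @param n_planted_dmps Number of planted DMPs.
#' @param delta_range Interval of planted |mean beta difference|.
#' @param dmp_direction `"hypo"` (cases lower, the default) or
#'   `"hyper"`.
#' @param module_sizes Sizes of planted comethylation blocks.
#' @param module_cor Target within-block correlation of the latent
#'   factor structure.
#' @param cell_types Cell-type labels, granulocytes last.
#' @param markers_per_type Reference marker probes per cell type.
#' @param marker_high,marker_low Marker beta in the marked type vs the
#'   rest.
#' @param cell_sd Per-probe per-cell-type beta dispersion of the
#'   reference away from the shared baseline (drives composition
#'   confounding).
#' @param dirichlet_control,dirichlet_case Dirichlet concentration
#'   parameters of the arm-specific cell-proportion draws.
#' @param confounding If `FALSE`, cases use the control Dirichlet (no
#'   composition shift).
#' @param n_batches,batch_sd Batch count and per-probe batch shift sd
#'   on the M scale.
#' @param m_noise_sd Measurement noise sd on the M scale.
#' @param intensity_median Median total fluorescence intensity
#'   (lognormal).
#' @param snp_frac,repeat_frac,sex_frac Fractions of probes flagged
#'   SNP-under-probe / repeat / on X or Y.
#' @param lowbead_frac,detfail_frac Fractions of clean probes planted
#'   to fail the beadcount / detection probe filters.
#' @param n_failed_samples Extra samples planted to fail sample-level
#'   detection QC.
#' @param n_incomplete Extra samples with missing pack-years.
#' @param n_replicate_pairs Technical replicate pairs (one male, one
#'   female).
#' @param shared_frac For paired cohorts, fraction of planted DMPs
#'   shared between cohorts (the rest are cohort-A-specific).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_probes = 2000,
                              n_cases = 93, n_controls = 269,
                              n_cases_b = 678, n_controls_b = 427,
                              n_planted_dmps = 100,
                              delta_range = c(0.05, 0.12),
                              dmp_direction = c("hypo", "hyper"),
                              module_sizes = c(60, 50, 40),
                              module_cor = 0.7,
                              cell_types = c("NK", "CD8T", "CD4T",
                                             "Bcell", "Mono", "Gran"),
                              markers_per_type = 50,
                              marker_high = 0.85, marker_low = 0.15,
                              cell_sd = 0.07,
                              dirichlet_control = c(NK = 3.0, CD8T = 4.8,
                                                    CD4T = 9.0, Bcell = 3.0,
                                                    Mono = 4.2, Gran = 36.0),
                              dirichlet_case = c(NK = 2.4, CD8T = 3.6,
                                                 CD4T = 6.6, Bcell = 2.4,
                                                 Mono = 4.8, Gran = 40.2),
                              confounding = TRUE,
                              n_batches = 2, batch_sd = 0.1,
                              m_noise_sd = 0.35,
                              intensity_median = 2000,
                              snp_frac = 0.05, repeat_frac = 0.03,
                              sex_frac = 0.04,
                              lowbead_frac = 0.01, detfail_frac = 0.01,
                              n_failed_samples = 1,
                              n_incomplete = 3,
                              n_replicate_pairs = 2,
                              shared_frac = 0.5) {
  dmp_direction <- match.arg(dmp_direction)
  stopifnot(delta_range[1] > 0, delta_range[2] < 0.5,
            all(c(snp_frac, repeat_frac, sex_frac, lowbead_frac,
                  detfail_frac, shared_frac) >= 0),
            all(c(snp_frac, repeat_frac, sex_frac, lowbead_frac,
                  detfail_frac, shared_frac) <= 1),
            all(module_sizes > 0), n_probes > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

logit2 <- function(b) log2(b / (1 - b))
sigmoid2 <- function(m) 1 / (1 + 2^(-m))

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  w <- g / rowSums(g)
  colnames(w) <- names(alpha)
  w
}

#' Plan the probe-level structure of a simulated cohort
#'
#' Draws the probe annotation (chromosomes, positions, nearest genes)
#' and plants the QC artifact probes: SNP-under-probe and
#' repeat-region flags, sex-chromosome probes, and the probes designed
#' to fail the beadcount and detection signal filters. Paired cohorts
#' share one plan so their annotations and surviving probe sets are
#' identical.
#'
#' @param config A [simulation_config()].
#' @param reference Reference from [generate_reference()].
#' @param seed Seed (defaults to the config seed).
#' @return List with `annotation` and the planted probe id vectors
#'   (`snp_probes`, `repeat_probes`, `sex_probes`, `lowbead_probes`,
#'   `detfail_probes`, `clean`).
#' @export
plant_probe_structure <- function(config, reference, seed = config$seed) {
  withr::local_seed(seed + 10L)
  n <- config$n_probes
  probes <- rownames(reference)
  markers <- attr(reference, "markers")
  n_snp <- round(config$snp_frac * n)
  n_rep <- round(config$repeat_frac * n)
  n_sex <- round(config$sex_frac * n)
  non_marker <- setdiff(probes, markers$probe_id)
  artifact <- sample(non_marker, n_snp + n_rep + n_sex)
  snp_probes <- artifact[seq_len(n_snp)]
  repeat_probes <- artifact[n_snp + seq_len(n_rep)]
  sex_probes <- artifact[n_snp + n_rep + seq_len(n_sex)]
  chromosome <- sample(as.character(1:22), n, replace = TRUE)
  names(chromosome) <- probes
  chromosome[sex_probes] <- sample(c("X", "Y"), n_sex, replace = TRUE)
  annotation <- tibble(
    probe_id = probes,
    chromosome = unname(chromosome),
    position = sample.int(2e8, n, replace = TRUE),
    nearest_gene = paste0("G", sprintf("%05d", ceiling(seq_len(n) / 2))),
    snp_within_5bp = probes %in% snp_probes,
    repeat_region = probes %in% repeat_probes)
  clean <- setdiff(non_marker, artifact)
  n_lowbead <- round(config$lowbead_frac * n)
  n_detfail <- round(config$detfail_frac * n)
  planted_bad <- sample(clean, n_lowbead + n_detfail)
  lowbead_probes <- planted_bad[seq_len(n_lowbead)]
  detfail_probes <- planted_bad[n_lowbead + seq_len(n_detfail)]
  list(annotation = annotation,
       snp_probes = snp_probes, repeat_probes = repeat_probes,
       sex_probes = sex_probes, lowbead_probes = lowbead_probes,
       detfail_probes = detfail_probes,
       clean = setdiff(clean, planted_bad))
}

#' Generate a synthetic cell-type reference
#'
#' Marker probes get well-separated beta means (`marker_high` in their
#' own type, `marker_low` elsewhere) with small within-type noise;
#' non-marker probes share a bimodal baseline (an equal mixture of
#' Beta(2, 10) and Beta(10, 2)) plus a per-type deviation of sd
#' `cell_sd`. All values are clipped to `[0.02, 0.98]`.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to the config seed).
#' @return Probes x cell-types beta matrix with attribute `markers`
#'   (tibble `probe_id`, `cell_type`).
#' @export
generate_reference <- function(config, seed = config$seed) {
  withr::local_seed(seed)
  k <- length(config$cell_types)
  n <- config$n_probes
  if (config$markers_per_type * k > n) {
    abort("marker count exceeds probe count")
  }
  probes <- sprintf("cg%08d", seq_len(n))
  mix <- rbinom(n, 1, 0.5)
  baseline <- ifelse(mix == 1, rbeta(n, 2, 10), rbeta(n, 10, 2))
  ref <- baseline + matrix(rnorm(n * k, 0, config$cell_sd), n, k)
  dimnames(ref) <- list(probes, config$cell_types)
  marker_idx <- matrix(seq_len(config$markers_per_type * k),
                       ncol = k)  # first probes reserved as markers
  for (j in seq_len(k)) {
    idx <- marker_idx[, j]
    ref[idx, ] <- config$marker_low +
      matrix(rnorm(length(idx) * k, 0, 0.01), length(idx), k)
    ref[idx, j] <- config$marker_high + rnorm(length(idx), 0, 0.01)
  }
  ref <- pmin(pmax(ref, 0.02), 0.98)
  attr(ref, "markers") <- tibble(
    probe_id = probes[as.vector(marker_idx)],
    cell_type = rep(config$cell_types, each = config$markers_per_type))
  ref
}

#' Generate a synthetic cohort
#'
#' Draws per-sample cell proportions from arm-specific Dirichlet
#' distributions, mixes the reference methylomes into per-probe true
#' beta values, plants case effects at the DMPs on the beta scale,
#' adds latent-factor comethylation blocks, batch shifts and
#' measurement noise on the M scale, inverts to (meth, unmeth)
#' intensities with lognormal total intensity so the offset-100 beta
#' formula recovers beta within noise, and emits detection p-values,
#' beadcounts, annotation flags, replicate columns and covariates.
#' Extra artifact samples (detection failures, incomplete covariates,
#' replicates) are appended beyond the nominal arm sizes so the
#' post-QC cohort matches `n_cases` / `n_controls`.
#'
#' @param config A [simulation_config()].
#' @param reference Optional reference from [generate_reference()]
#'   (shared across paired cohorts).
#' @param cohort_id Label written to the sample sheet.
#' @param dmp_ids Optional explicit planted-DMP probe ids (paired
#'   designs); default samples them from clean probes.
#' @param probe_plan Optional probe-structure plan from
#'   [plant_probe_structure()]; paired cohorts share one so their
#'   annotations and probe sets are identical.
#' @param n_cases,n_controls Arm sizes; default from the config.
#' @param seed Seed; default the config seed.
#' @return A `sim_cohort` list: `data` ([intensity_data]),
#'   `annotation`, `sample_sheet`, `reference`, and `truth` (planted
#'   DMPs, module map, true cell proportions, batches, artifact ids,
#'   seed).
#' @export
generate_cohort <- function(config, reference = NULL,
                            cohort_id = "cohort_A", dmp_ids = NULL,
                            probe_plan = NULL,
                            n_cases = config$n_cases,
                            n_controls = config$n_controls,
                            seed = config$seed) {
  if (is.null(reference)) reference <- generate_reference(config, seed = seed)
  if (is.null(probe_plan)) {
    probe_plan <- plant_probe_structure(config, reference, seed = seed)
  }
  withr::local_seed(seed + 1L)
  n <- config$n_probes
  probes <- rownames(reference)
  markers <- attr(reference, "markers")
  annotation <- probe_plan$annotation
  snp_probes <- probe_plan$snp_probes
  repeat_probes <- probe_plan$repeat_probes
  sex_probes <- probe_plan$sex_probes
  lowbead_probes <- probe_plan$lowbead_probes
  detfail_probes <- probe_plan$detfail_probes
  clean <- probe_plan$clean

  if (is.null(dmp_ids)) {
    dmp_ids <- sample(clean, min(config$n_planted_dmps, length(clean)))
  } else if (!all(dmp_ids %in% probes)) {
    abort("dmp_ids must be probe ids of the reference")
  }
  module_pool <- setdiff(clean, dmp_ids)
  module_map <- tibble(probe_id = character(0), module = character(0))
  if (length(config$module_sizes) > 0 &&
      sum(config$module_sizes) <= length(module_pool)) {
    picked <- sample(module_pool, sum(config$module_sizes))
    module_map <- tibble(
      probe_id = picked,
      module = rep(paste0("block", seq_along(config$module_sizes)),
                   times = config$module_sizes))
  }

  # --- samples --------------------------------------------------------
  n_main <- n_cases + n_controls
  n_extra <- config$n_failed_samples + config$n_incomplete +
    config$n_replicate_pairs
  ids_main <- sprintf("%s_S%04d", cohort_id, seq_len(n_main))
  is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_controls))
  ids_fail <- if (config$n_failed_samples > 0)
    sprintf("%s_FAIL%02d", cohort_id, seq_len(config$n_failed_samples)) else character(0)
  ids_inc <- if (config$n_incomplete > 0)
    sprintf("%s_INC%02d", cohort_id, seq_len(config$n_incomplete)) else character(0)

  gender <- ifelse(is_case, ifelse(runif(n_main) < 0.538, "male", "female"),
                   ifelse(runif(n_main) < 0.725, "male", "female"))
  # replicate sources: one male and one female control, alternating
  ctrl_idx <- which(!is_case)
  rep_sources <- character(0)
  if (config$n_replicate_pairs > 0) {
    males <- ids_main[ctrl_idx][gender[ctrl_idx] == "male"]
    females <- ids_main[ctrl_idx][gender[ctrl_idx] == "female"]
    want <- rep(c("male", "female"), length.out = config$n_replicate_pairs)
    rep_sources <- vapply(seq_len(config$n_replicate_pairs), function(i) {
      if (want[i] == "male" && length(males) >= i) males[i]
      else if (length(females) >= i) females[i] else ids_main[ctrl_idx][i]
    }, character(1))
  }
  ids_rep <- if (length(rep_sources) > 0)
    paste0(rep_sources, "_REP") else character(0)

  all_ids <- c(ids_main, ids_fail, ids_inc, ids_rep)
  case_all <- c(is_case, rep(FALSE, length(ids_fail) + length(ids_inc)),
                rep(FALSE, length(ids_rep)))
  n_tot <- length(all_ids)

  # --- cell proportions and true beta --------------------------------
  alpha_case <- if (config$confounding) config$dirichlet_case else config$dirichlet_control
  W <- matrix(0, n_tot, length(config$cell_types),
              dimnames = list(all_ids, config$cell_types))
  W[case_all, ] <- rdirichlet(sum(case_all), alpha_case)
  W[!case_all, ] <- rdirichlet(sum(!case_all), config$dirichlet_control)
  if (length(ids_rep) > 0) W[ids_rep, ] <- W[rep_sources, ]  # same biology
  beta_true <- reference %*% t(W)

  deltas <- runif(length(dmp_ids), config$delta_range[1], config$delta_range[2])
  sign_d <- if (config$dmp_direction == "hypo") -1 else 1
  case_cols <- which(case_all)
  beta_true[dmp_ids, case_cols] <- pmin(pmax(
    beta_true[dmp_ids, case_cols] + sign_d * deltas, 0.01), 0.99)

  M_sig <- logit2(pmin(pmax(beta_true, 0.01), 0.99))

  # comethylation blocks: latent factor per block on the M scale
  if (nrow(module_map) > 0) {
    factor_scale <- config$m_noise_sd *
      sqrt(config$module_cor / (1 - config$module_cor)) / 0.85
    for (blk in unique(module_map$module)) {
      bp <- module_map$probe_id[module_map$module == blk]
      f <- rnorm(n_tot)
      if (length(ids_rep) > 0) f[match(ids_rep, all_ids)] <- f[match(rep_sources, all_ids)]
      loading <- runif(length(bp), 0.75, 0.95)
      M_sig[bp, ] <- M_sig[bp, ] + outer(loading, f) * factor_scale
    }
  }

  # batch shifts on M
  batch <- sample(paste0("B", seq_len(config$n_batches)), n_tot, replace = TRUE)
  if (length(ids_rep) > 0) {  # replicates plated on a different array
    batch[match(ids_rep, all_ids)] <-
      sample(paste0("B", seq_len(config$n_batches)), length(ids_rep), replace = TRUE)
  }
  batch_eff <- matrix(rnorm(n * config$n_batches, 0, config$batch_sd),
                      n, config$n_batches,
                      dimnames = list(probes, paste0("B", seq_len(config$n_batches))))
  M_obs <- M_sig + batch_eff[, batch] +
    matrix(rnorm(n * n_tot, 0, config$m_noise_sd), n, n_tot)
  beta_obs <- sigmoid2(M_obs)

  # intensities: total ~ lognormal; offset-100 beta recovers beta_obs
  total <- matrix(rlnorm(n * n_tot, log(config$intensity_median), 0.3), n, n_tot)
  meth <- beta_obs * (total + 100)
  unmeth <- pmax(total - meth, 0)
  dimnames(meth) <- dimnames(unmeth) <- list(probes, all_ids)

  # detection p-values and beadcounts with planted failures
  detection_p <- matrix(runif(n * n_tot, 0, 0.01), n, n_tot,
                        dimnames = list(probes, all_ids))
  # plant probe-level failures among the main samples (those surviving
  # subject-level QC) so the strict fractions are met deterministically
  for (pid in detfail_probes) {  # fails in 2% of surviving samples (> 1%)
    cols <- sample(ids_main, ceiling(0.02 * n_main))
    detection_p[pid, cols] <- runif(length(cols), 0.06, 0.5)
  }
  for (sid in ids_fail) {        # 2% of clean sites fail (> 1%)
    rows <- sample(clean, ceiling(0.02 * n))
    detection_p[rows, sid] <- runif(length(rows), 0.06, 0.5)
  }
  beadcount <- matrix(3 + rpois(n * n_tot, 12), n, n_tot,
                      dimnames = list(probes, all_ids))
  for (pid in lowbead_probes) {  # beadcount < 3 in 6% of samples (> 5%)
    cols <- sample(ids_main, ceiling(0.06 * n_main))
    beadcount[pid, cols] <- sample(0:2, length(cols), replace = TRUE)
  }

  data <- intensity_data(meth, unmeth, detection_p, beadcount)

  # --- sample sheet ---------------------------------------------------
  age <- ifelse(case_all, rnorm(n_tot, 61.4, 7.7), rnorm(n_tot, 48.9, 6.4))
  age <- pmin(pmax(age, 40), 80)
  pack_years <- ifelse(case_all, rnorm(n_tot, 42.2, 22.1), rnorm(n_tot, 39.2, 20.5))
  pack_years <- pmax(pack_years, 20)
  gender_all <- c(gender,
                  sample(c("male", "female"), length(ids_fail) + length(ids_inc),
                         replace = TRUE),
                  rep(NA_character_, length(ids_rep)))
  sheet <- tibble(sample_id = all_ids, copd_case = case_all,
                  age = age, gender = gender_all,
                  pack_years = pack_years, batch = batch,
                  cohort = cohort_id, replicate_of = NA_character_)
  if (length(ids_rep) > 0) {  # replicates copy their source's covariates
    src <- match(rep_sources, sheet$sample_id)
    dst <- match(ids_rep, sheet$sample_id)
    sheet$replicate_of[dst] <- rep_sources
    sheet$gender[dst] <- sheet$gender[src]
    sheet$age[dst] <- sheet$age[src]
    sheet$pack_years[dst] <- sheet$pack_years[src]
  }
  sheet$pack_years[sheet$sample_id %in% ids_inc] <- NA_real_
  sheet <- validate_sample_sheet(sheet)

  truth <- structure(list(
    dmp = tibble(probe_id = dmp_ids, delta = sign_d * deltas,
                 direction = config$dmp_direction),
    modules = module_map,
    cell_proportions = as_tibble(cbind(tibble(sample_id = all_ids), W)),
    batch = tibble(sample_id = all_ids, batch = batch),
    markers = markers,
    artifact_probes = tibble(
      probe_id = c(snp_probes, repeat_probes, sex_probes,
                   lowbead_probes, detfail_probes),
      kind = rep(c("snp", "repeat", "sex", "lowbead", "detfail"),
                 c(length(snp_probes), length(repeat_probes),
                   length(sex_probes), length(lowbead_probes),
                   length(detfail_probes)))),
    artifact_samples = tibble(
      sample_id = c(ids_fail, ids_inc, ids_rep),
      kind = rep(c("detection_fail", "incomplete", "replicate"),
                 c(length(ids_fail), length(ids_inc), length(ids_rep)))),
    seed = seed), class = "sim_truth")

  structure(list(data = data, annotation = annotation,
                 sample_sheet = sheet, reference = reference,
                 truth = truth),
            class = "sim_cohort")
}

#' Generate paired cohorts with a shared reference
#'
#' Cohort A carries all planted DMPs; cohort B carries only the shared
#' subset (fraction `shared_frac` of the planted set), so the
#' remaining effects are A-specific by construction. Probe sets,
#' annotation, and the cell reference are identical across cohorts.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort_a`, `cohort_b` (each a `sim_cohort`), and
#'   `truth` (tibble `probe_id`, `sharing` in
#'   `{shared, A_specific}`).
#' @export
generate_paired_cohorts <- function(config) {
  reference <- generate_reference(config, seed = config$seed)
  probe_plan <- plant_probe_structure(config, reference, seed = config$seed)
  withr::local_seed(config$seed + 100L)
  all_dmps <- sample(probe_plan$clean,
                     min(config$n_planted_dmps, length(probe_plan$clean)))
  n_shared <- round(config$shared_frac * length(all_dmps))
  shared <- all_dmps[seq_len(n_shared)]
  cohort_a <- generate_cohort(config, reference, cohort_id = "cohort_A",
                              dmp_ids = all_dmps, probe_plan = probe_plan,
                              seed = config$seed + 1000L)
  cohort_b <- generate_cohort(config, reference, cohort_id = "cohort_B",
                              dmp_ids = shared, probe_plan = probe_plan,
                              n_cases = config$n_cases_b,
                              n_controls = config$n_controls_b,
                              seed = config$seed + 2000L)
  list(cohort_a = cohort_a, cohort_b = cohort_b,
       truth = tibble(probe_id = all_dmps,
                      sharing = ifelse(all_dmps %in% shared,
                                       "shared", "A_specific")))
}
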