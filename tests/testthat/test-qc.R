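test_that("annotation filters remove flagged probes with fixed reason precedence", {
  ann <- tibble::tibble(
    probe_id = sprintf("cg%02d", 1:10),
    chromosome = c("1", "X", "X", "Y", "3", "4", "5", "6", "7", "8"),
    position = 1:10,
    nearest_gene = "G",
    snp_within_5bp = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                       FALSE, FALSE, FALSE, FALSE, FALSE),
    repeat_region = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE))
  f <- filter_probes_annotation(ann$probe_id, ann)
  expect_setequal(f$kept, c("cg06", "cg07", "cg08", "cg09", "cg10"))
  # probe both SNP-flagged and on X gets the SNP reason
  expect_equal(f$removed$reason[f$removed$probe_id == "cg02"], "snp_under_probe")
  expect_equal(sort(unique(f$removed$reason)),
               c("repeat_under_probe", "sex_chromosome", "snp_under_probe"))
  # conservation at this stage
  expect_equal(length(f$kept) + nrow(f$removed), 10)
  # clean annotation: identity, empty ledger
  ann2 <- dplyr::mutate(ann, chromosome = "1", snp_within_5bp = FALSE,
                        repeat_region = FALSE)
  f2 <- filter_probes_annotation(ann2$probe_id, ann2)
  expect_equal(f2$kept, ann2$probe_id)
  expect_equal(nrow(f2$removed), 0)
  expect_error(filter_probes_annotation(c(ann$probe_id, "cg99"), ann), "cg99")
})

test_that("signal filters use strict fractions at their boundaries", {
  n_samp <- 100
  probes <- c("at_bead_boundary", "over_bead", "det_two_pct", "clean")
  bead <- matrix(10L, 4, n_samp, dimnames = list(probes, NULL))
  bead["at_bead_boundary", 1:5] <- 1L  # exactly 5% -> kept
  bead["over_bead", 1:6] <- 1L         # 6% -> removed
  dp <- matrix(0.001, 4, n_samp, dimnames = list(probes, NULL))
  dp["det_two_pct", 1:2] <- 0.2        # 2% > 1% -> removed
  colnames(bead) <- colnames(dp) <- paste0("s", seq_len(n_samp))
  f <- filter_probes_signal(dp, bead)
  expect_setequal(f$kept, c("at_bead_boundary", "clean"))
  expect_equal(f$removed$reason[f$removed$probe_id == "over_bead"],
               "low_beadcount")
  expect_equal(f$removed$reason[f$removed$probe_id == "det_two_pct"],
               "high_detection_p")
  f_all <- filter_probes_signal(dp * 0, bead * 0 + 10L)
  expect_equal(nrow(f_all$removed), 0)
  expect_error(filter_probes_signal(dp[, 0], bead[, 0]), "empty sample")
})

test_that("sample filters remove detection failures then incomplete covariates", {
  ss <- tiny_sample_sheet(2, 2)
  ss$pack_years[4] <- NA
  ss <- validate_ss(ss)
  dp <- matrix(0.001, 1000, 4, dimnames = list(sprintf("p%04d", 1:1000),
                                               ss$sample_id))
  dp[1:20, 2] <- 0.2  # 2% of sites failing -> removed
  f <- filter_samples(dp, ss)
  expect_setequal(f$kept, c("s01", "s03"))
  expect_equal(f$removed$reason[f$removed$sample_id == "s02"],
               "sample_detection_fail")
  expect_equal(f$removed$reason[f$removed$sample_id == "s04"],
               "incomplete_covariates")
  ss2 <- tiny_sample_sheet(2, 2)
  expect_equal(nrow(filter_samples(dp * 0, ss2)$removed), 0)
})

test_that("replicate concordance reports correlation and concordant fraction", {
  withr::local_seed(42)
  n <- 1000
  base <- runif(n, 0.05, 0.95)
  beta <- cbind(orig = base, rep_same = base,
                rep_noise = pmin(pmax(base + rnorm(n, 0, 0.01), 0), 1),
                rep_indep = runif(n))
  rownames(beta) <- sprintf("p%04d", 1:n)
  ss <- tibble::tibble(sample_id = colnames(beta),
                       replicate_of = c(NA, "orig", "orig", "orig"))
  cc <- replicate_concordance(beta, ss)
  expect_equal(cc$correlation[cc$sample_id == "rep_same"], 1)
  expect_equal(cc$frac_concordant[cc$sample_id == "rep_same"], 1)
  expect_gt(cc$frac_concordant[cc$sample_id == "rep_noise"], 0.99)
  expect_lt(abs(cc$correlation[cc$sample_id == "rep_indep"]), 0.1)
  ss_small <- ss[1:2, ]
  expect_error(replicate_concordance(beta[1:5, ], ss_small), "fewer than 10")
})

test_that("run_qc accounts for every planted artifact and is idempotent", {
  cfg <- simulation_config(seed = 5, n_probes = 1200)
  sim <- generate_cohort(cfg)
  qc <- run_qc(sim$data, sim$annotation, sim$sample_sheet)
  truth <- sim$truth

  reason_counts <- table(qc$report$removals$reason)
  planted <- table(truth$artifact_probes$kind)
  expect_equal(unname(reason_counts["snp_under_probe"]),
               unname(planted["snp"]))
  expect_equal(unname(reason_counts["repeat_under_probe"]),
               unname(planted["repeat"]))
  expect_equal(unname(reason_counts["sex_chromosome"]),
               unname(planted["sex"]))
  expect_equal(unname(reason_counts["low_beadcount"]),
               unname(planted["lowbead"]))
  expect_equal(unname(reason_counts["high_detection_p"]),
               unname(planted["detfail"]))
  expect_equal(unname(reason_counts["sample_detection_fail"]), cfg$n_failed_samples)
  expect_equal(unname(reason_counts["incomplete_covariates"]), cfg$n_incomplete)
  expect_equal(unname(reason_counts["technical_replicate"]), cfg$n_replicate_pairs)

  # stage conservation
  st <- qc$report$stages
  expect_true(all(st$n_before - st$n_removed == st$n_after))
  expect_equal(sum(st$n_removed[st$unit == "probe"]) +
                 nrow(qc$data$meth), cfg$n_probes)

  # idempotence
  qc2 <- run_qc(qc$data, qc$annotation, qc$sample_sheet)
  expect_equal(sum(qc2$report$stages$n_removed), 0)
  expect_equal(probe_ids(qc2$data), probe_ids(qc$data))

  # post-QC arm sizes match the nominal design
  expect_equal(sum(qc$sample_sheet$copd_case), cfg$n_cases)
  expect_equal(sum(!qc$sample_sheet$copd_case), cfg$n_controls)
})

test_that("an artifact-free dataset passes QC unchanged", {
  cfg <- simulation_config(seed = 6, n_probes = 400, snp_frac = 0,
                           repeat_frac = 0, sex_frac = 0, lowbead_frac = 0,
                           detfail_frac = 0, n_failed_samples = 0,
                           n_incomplete = 0, n_replicate_pairs = 0,
                           n_cases = 20, n_controls = 30,
                           module_sizes = integer(0), n_planted_dmps = 0)
  sim <- generate_cohort(cfg)
  qc <- run_qc(sim$data, sim$annotation, sim$sample_sheet)
  expect_equal(sum(qc$report$stages$n_removed), 0)
  expect_equal(dim(qc$data), dim(sim$data))
})
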