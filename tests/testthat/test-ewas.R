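test_that("the design matrix codes covariates and batches as documented", {
  ss <- tiny_sample_sheet(4, 4, batches = 3)
  X <- build_design(ss)
  expect_equal(colnames(X)[1:5],
               c("(Intercept)", "case", "age", "gender_male", "pack_years"))
  expect_equal(sum(grepl("^batch_", colnames(X))), 2)
  expect_equal(unname(X[, "case"]), as.numeric(ss$copd_case))
  expect_equal(unname(X[, "gender_male"]), as.numeric(ss$gender == "male"))
  # five cell covariates: 1 + 1 + 3 continuous/binary + (B-1) + 5 columns
  ss_big <- tiny_sample_sheet(10, 10, batches = 3)
  cc <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(ss_big$sample_id, paste0("c", 1:5)))
  expect_equal(ncol(build_design(ss_big, cc)), 5 + 2 + 5)
  # perfect case/batch confounding is rejected with the column named
  ss2 <- tiny_sample_sheet(4, 4, batches = 1)
  ss2$batch <- ifelse(ss2$copd_case, "B1", "B2")
  expect_error(build_design(ss2), "batch_B2")
})

test_that("unmoderated per-probe fits match the normal-equations oracle", {
  withr::local_seed(21)
  ss <- tiny_sample_sheet(3, 3)
  X <- build_design(ss)
  M <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("p", 1:5), ss$sample_id))
  fit <- fit_probe_models(M, X, moderation = FALSE)
  for (i in 1:5) {
    lmfit <- summary(stats::lm(M[i, ] ~ 0 + X))
    co <- lmfit$coefficients["Xcase", ]
    expect_equal(unname(fit$coefficient[i]), unname(co["Estimate"]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$t_statistic[i]), unname(co["t value"]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$p_value[i]), unname(co["Pr(>|t|)"]),
                 tolerance = 1e-10)
  }
  expect_equal(fit$df_residual, 6 - ncol(X))
})

test_that("moderated statistics agree with the independent empirical-Bayes engine", {
  skip_if_not_installed("limma")
  withr::local_seed(22)
  ss <- tiny_sample_sheet(10, 12, batches = 2)
  X <- build_design(ss)
  M <- matrix(rnorm(300 * 22, sd = rep(sqrt(1 / rgamma(300, 4, 4)), 22)),
              300, 22, dimnames = list(sprintf("p%03d", 1:300), ss$sample_id))
  fit <- fit_probe_models(M, X, moderation = TRUE)
  lfit <- limma::eBayes(limma::lmFit(M, X))
  expect_equal(unname(fit$coefficient), unname(lfit$coefficients[, "case"]),
               tolerance = 1e-10)
  expect_equal(fit$df_prior, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s2_prior, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$t_statistic), unname(lfit$t[, "case"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$p_value), unname(lfit$p.value[, "case"]),
               tolerance = 1e-6)
})

test_that("variance moderation shrinks towards the prior and handles constants", {
  withr::local_seed(23)
  ss <- tiny_sample_sheet(5, 5)
  X <- build_design(ss)
  M <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("p%03d", 1:100), ss$sample_id))
  M[1, ] <- 5  # constant probe
  fit_off <- fit_probe_models(M, X, moderation = FALSE)
  expect_equal(fit_off$t_statistic[[1]], 0)
  expect_equal(fit_off$p_value[[1]], 1)
  fit_on <- fit_probe_models(M, X, moderation = TRUE)
  # moderated variances lie between the observed variance and the prior
  s2 <- fit_on$sigma2[-1]
  between <- (fit_on$s2_post[-1] >= pmin(s2, fit_on$s2_prior) - 1e-12) &
    (fit_on$s2_post[-1] <= pmax(s2, fit_on$s2_prior) + 1e-12)
  expect_true(all(between))
  # constant probe is rescued by the prior variance
  expect_gt(fit_on$s2_post[[1]], 0)
})

test_that("BH adjustment matches the exhaustive suffix-min oracle exactly", {
  withr::local_seed(24)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    p <- runif(n)
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # m_total treats the supplied p as the smallest among m_total tests
  p <- sort(runif(20, 0, 1e-3))
  expect_equal(bh_adjust(p, m_total = 5000), bh_oracle(p, m = 5000))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(runif(10), m_total = 5), "m_total")
})

test_that("significance sets use strict thresholds", {
  res <- tibble::tibble(probe_id = paste0("p", 1:4),
                        fdr_q = c(0.01, 0.05, 0.07, 0.2))
  s <- significant_sets(res)
  expect_equal(s$fdr5, "p1")
  expect_equal(s$fdr10_additional, c("p2", "p3"))  # 0.05 exactly is not < 0.05
  empty <- significant_sets(res[0, ])
  expect_length(empty$fdr5, 0)
})

test_that("genomic inflation is calibrated, scale-equivariant, and degenerate-safe", {
  withr::local_seed(25)
  df <- 350
  t0 <- stats::rt(1e4, df = df)
  lam <- genomic_inflation(t0, df)
  expect_lt(abs(lam - 1), 0.05)
  expect_equal(genomic_inflation(2 * t0, df), 4 * lam)
  expect_equal(genomic_inflation(rep(0, 200), df), 0)
})

test_that("the null EWAS is calibrated and confounding is removed by deconvolution", {
  # no planted effects, no composition shift: uniform p-values
  cfg <- simulation_config(seed = 31, n_probes = 1500, n_planted_dmps = 0,
                           confounding = FALSE, module_sizes = integer(0),
                           snp_frac = 0, repeat_frac = 0, sex_frac = 0,
                           lowbead_frac = 0, detfail_frac = 0,
                           n_failed_samples = 0, n_incomplete = 0,
                           n_replicate_pairs = 0)
  sim <- generate_cohort(cfg)
  res <- run_ewas(sim$data, sim$sample_sheet)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.015)
  expect_lte(length(significant_sets(res)$fdr5), 1)
  # case-shifted composition, no direct effects: inflation appears and
  # is removed by the deconvolution covariates
  cfg2 <- simulation_config(seed = 32, n_probes = 1500, n_planted_dmps = 0,
                            module_sizes = integer(0),
                            snp_frac = 0, repeat_frac = 0, sex_frac = 0,
                            lowbead_frac = 0, detfail_frac = 0,
                            n_failed_samples = 0, n_incomplete = 0,
                            n_replicate_pairs = 0)
  sim2 <- generate_cohort(cfg2)
  res_un <- run_ewas(sim2$data, sim2$sample_sheet)
  props <- estimate_cell_proportions(beta_values(sim2$data), sim2$reference)
  cc <- deconvolution_covariates(props)
  res_adj <- run_ewas(sim2$data, sim2$sample_sheet, cell_covariates = cc)
  expect_gt(genomic_inflation(res_un$t_statistic, attr(res_un, "df_total")), 1.3)
  lam_adj <- genomic_inflation(res_adj$t_statistic, attr(res_adj, "df_total"))
  expect_gt(lam_adj, 0.85)
  expect_lt(lam_adj, 1.15)
})

test_that("run_ewas returns a ranked annotated table with planted effects on top", {
  cfg <- simulation_config(seed = 33, n_probes = 800, n_planted_dmps = 30)
  sim <- generate_cohort(cfg)
  qc <- run_qc(sim$data, sim$annotation, sim$sample_sheet)
  props <- estimate_cell_proportions(beta_values(qc$data), sim$reference)
  res <- run_ewas(qc$data, qc$sample_sheet, qc$annotation,
                  cell_covariates = deconvolution_covariates(props))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(res$p_value))
  expect_true(all(diff(res$fdr_q[order(res$p_value)]) >= -1e-15))
  top <- res$probe_id[seq_len(20)]
  expect_gt(mean(top %in% sim$truth$dmp$probe_id), 0.9)
  # planted hypomethylation shows as negative delta among the hits
  hits <- res[res$probe_id %in% sim$truth$dmp$probe_id, ]
  expect_true(all(hits$delta_percent < 0))
})
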