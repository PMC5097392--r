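#' Build the EWAS design matrix
#'
#' Predictors: intercept, COPD case indicator, age, gender (male = 1,
#' female = 0), pack-years of smoking, treatment-coded batch indicators
#' (reference batch = first level alphabetically), and any cell-type
#' covariates. Continuous covariates are passed through
#' un-standardised. The matrix must be full column rank; perfect
#' confounding (e.g. case status nested in batch) is an error naming
#' the collinear columns.
#'
#' @param sample_sheet Sample sheet tibble with complete covariates
#'   (guaranteed after [run_qc()]).
#' @param cell_covariates Optional samples x k numeric matrix from
#'   [deconvolution_covariates()], rows aligned to (or named by) the
#'   sample sheet's samples.
#' @return Samples x predictors numeric matrix with sample ids as
#'   rownames.
#' @export
build_design <- function(sample_sheet, cell_covariates = NULL) {
  ss <- sample_sheet
  if (any(!ss$covariates_complete)) {
    abort("sample sheet contains incomplete covariates; run QC first")
  }
  batch <- factor(ss$batch, levels = sort(unique(ss$batch)))
  X <- cbind(`(Intercept)` = 1,
             case = as.numeric(ss$copd_case),
             age = ss$age,
             gender_male = as.numeric(ss$gender == "male"),
             pack_years = ss$pack_years)
  if (nlevels(batch) > 1) {
    B <- model.matrix(~batch)[, -1, drop = FALSE]
    colnames(B) <- paste0("batch_", levels(batch)[-1])
    X <- cbind(X, B)
  }
  rownames(X) <- ss$sample_id
  if (!is.null(cell_covariates)) {
    cc <- as.matrix(cell_covariates)
    if (!is.null(rownames(cc))) cc <- cc[ss$sample_id, , drop = FALSE]
    if (nrow(cc) != nrow(X)) abort("cell covariates not aligned to samples")
    if (is.null(colnames(cc))) colnames(cc) <- paste0("cell", seq_len(ncol(cc)))
    X <- cbind(X, cc)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  X
}

#' Per-probe linear models with optional variance moderation
#'
#' Fits ordinary least squares of each probe's M-values on the design
#' and extracts the case-effect coefficient, its t-statistic, and a
#' two-sided p-value. With `moderation = TRUE` (default), residual
#' variances are shrunk towards a common prior by empirical Bayes:
#' the prior degrees of freedom `d0` and prior variance `s0^2` are
#' estimated by method of moments on `log s^2` across probes, each
#' probe's variance becomes `(d0 s0^2 + d s^2) / (d0 + d)`, and the
#' moderated t-statistic has `d0 + d` degrees of freedom.
#'
#' @param M Probes x samples M-value matrix.
#' @param design Design matrix from [build_design()].
#' @param moderation Apply empirical-Bayes variance shrinkage?
#' @param coef Name of the design column whose effect is tested.
#' @return An `ewas_fit` object; see [tidy.ewas_fit()].
#' @export
fit_probe_models <- function(M, design, moderation = TRUE, coef = "case") {
  if (!coef %in% colnames(design)) {
    abort(sprintf("design has no column '%s'", coef))
  }
  n <- ncol(M)
  if (n != nrow(design)) abort("M and design are not aligned")
  p <- ncol(design)
  d <- n - p
  if (d <= 0) abort("zero residual degrees of freedom")
  qx <- qr(design)
  B <- qr.coef(qx, t(M))                  # p x G
  res <- t(M) - design %*% B              # n x G
  s2 <- colSums(res^2) / d
  # constant probes fit exactly (intercept only); zero them out rather
  # than leaving floating-point dust that fabricates t-statistics
  flat <- rowSums((M - rowMeans(M))^2) == 0
  if (any(flat)) {
    B[match(coef, rownames(B)), flat] <- 0
    s2[flat] <- 0
  }
  xtx_inv <- chol2inv(qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE])
  u <- sqrt(xtx_inv[match(coef, colnames(design)), match(coef, colnames(design))])
  b <- B[match(coef, rownames(B)), ]

  if (moderation) {
    sq <- squeeze_variances(s2, d)
    s2_post <- sq$s2_post
    df_total <- d + sq$df_prior
    df_prior <- sq$df_prior
    s2_prior <- sq$s2_prior
  } else {
    s2_post <- s2
    df_total <- d
    df_prior <- 0
    s2_prior <- NA_real_
  }
  tt <- b / (sqrt(s2_post) * u)
  pval <- 2 * pt(-abs(tt), df = pmin(df_total, 1e300))
  zerovar <- s2_post == 0
  tt[zerovar & b == 0] <- 0
  pval[zerovar & b == 0] <- 1
  structure(list(probe_id = rownames(M), coefficient = b,
                 sigma2 = s2, s2_post = s2_post,
                 t_statistic = tt, p_value = pval,
                 df_residual = d, df_prior = df_prior, s2_prior = s2_prior,
                 df_total = df_total, stdev_unscaled = u,
                 moderation = moderation, coef = coef,
                 n_samples = n),
            class = "ewas_fit")
}

# Method-of-moments fit of a scaled inverse-chi-square prior to the
# observed residual variances, on the log scale (Fisher's log-variance
# moments: E[log s^2] = log s0^2 + digamma(d/2) - log(d/2),
# Var[log s^2] = trigamma(d/2), plus the prior's trigamma term).
squeeze_variances <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) return(list(df_prior = Inf, s2_prior = mean(s2), s2_post = s2))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    df_prior <- Inf
    s2_prior <- exp(mean(e))
    s2_post <- rep(s2_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + df * s2) / (df_prior + df)
  }
  list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
}

# Newton solve of trigamma(x) = y for x > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' @describeIn fit_probe_models Per-probe coefficient table.
#' @param x An `ewas_fit` object.
#' @param ... Unused.
#' @export
tidy.ewas_fit <- function(x, ...) {
  tibble(probe_id = x$probe_id,
         coefficient = unname(x$coefficient),
         t_statistic = unname(x$t_statistic),
         df = rep(x$df_total, length(x$probe_id)),
         p_value = unname(x$p_value))
}

#' @describeIn fit_probe_models One-row fit summary.
#' @export
glance.ewas_fit <- function(x, ...) {
  tibble(n_probes = length(x$probe_id), n_samples = x$n_samples,
         df_residual = x$df_residual, df_prior = x$df_prior,
         s2_prior = x$s2_prior, moderation = x$moderation)
}

#' @export
print.ewas_fit <- function(x, ...) {
  cat(sprintf("<ewas_fit> %d probes, %d samples, coef '%s', %s\n",
              length(x$probe_id), x$n_samples, x$coef,
              if (x$moderation)
                sprintf("moderated t (d0 = %.2f)", x$df_prior)
              else "ordinary t"))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q(i) = min_{j >= i} p(j) * m / j`, clipped at 1
#' and mapped back to input order. `m_total` lets a subset of p-values
#' be adjusted as if they were the smallest among `m_total` tests,
#' which reproduces genome-wide adjusted values from a printed top
#' table.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m_total Total number of tests; defaults to `length(p)`.
#' @return Adjusted p-values (q-values), same order as `p`.
#' @export
bh_adjust <- function(p, m_total = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  m <- m_total %||% length(p)
  if (m < length(p)) abort("m_total must be >= length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Split results at FDR significance thresholds
#'
#' Returns the probes significant at the primary FDR level (strictly
#' below) and the additional probes that approach significance between
#' the primary and secondary levels.
#'
#' @param results Tibble with `probe_id` and `fdr_q` columns.
#' @param thresholds Two increasing FDR levels (default 5% and 10%).
#' @return List with elements `fdr5` and `fdr10_additional` (probe id
#'   vectors, names reflect the default thresholds).
#' @export
significant_sets <- function(results, thresholds = c(0.05, 0.10)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  list(fdr5 = results$probe_id[results$fdr_q < thresholds[1]],
       fdr10_additional = results$probe_id[results$fdr_q >= thresholds[1] &
                                             results$fdr_q < thresholds[2]])
}

#' Genomic inflation factor
#'
#' `lambda = median(t^2) / qf(0.5, 1, df)`: under the null, `t^2` is
#' F(1, df) distributed, and the reference median tends to the
#' chi-square value 0.4549 as df grows. Values well above 1 indicate
#' systematic inflation, e.g. from unadjusted cell-composition
#' confounding.
#'
#' @param t_statistic Per-probe t-statistics.
#' @param df Their degrees of freedom (scalar).
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(t_statistic, df) {
  t_statistic <- t_statistic[!is.na(t_statistic)]
  if (length(t_statistic) < 100) {
    warn("genomic inflation estimated on fewer than 100 probes")
  }
  median(t_statistic^2) / qf(0.5, 1, df)
}

#' Run a complete differential-methylation analysis
#'
#' Convenience wrapper: computes M-values and beta values, builds the
#' design (case + age + gender + pack-years + batch + cell
#' covariates), fits per-probe models, and assembles the ranked result
#' table with delta-beta effect sizes, BH-adjusted q-values, and
#' nearest-gene annotation.
#'
#' @param data A QC'd [intensity_data] object.
#' @param sample_sheet Matching sample sheet (complete covariates).
#' @param annotation Optional probe annotation (adds `chromosome` and
#'   `nearest_gene`).
#' @param cell_covariates Optional matrix from
#'   [deconvolution_covariates()].
#' @param moderation Apply empirical-Bayes variance shrinkage?
#' @param beta_offset,m_offset Transform offsets (see [beta_values()],
#'   [m_values()]).
#' @return An `ewas_result` tibble ordered by p-value: `probe_id`,
#'   `chromosome`, `nearest_gene`, `delta_percent`, `coefficient`,
#'   `t_statistic`, `df`, `p_value`, `fdr_q`, `rank`.
#' @export
run_ewas <- function(data, sample_sheet, annotation = NULL,
                     cell_covariates = NULL, moderation = TRUE,
                     beta_offset = 100, m_offset = 1) {
  ss <- sample_sheet[match(sample_ids(data), sample_sheet$sample_id), ]
  design <- build_design(ss, cell_covariates)
  M <- m_values(data, offset = m_offset)
  fit <- fit_probe_models(M, design, moderation = moderation)
  out <- tidy(fit)
  db <- delta_beta(beta_values(data, offset = beta_offset), ss$copd_case)
  out <- dplyr::left_join(out, db, by = "probe_id")
  if (!is.null(annotation)) {
    out <- dplyr::left_join(
      out, annotation[, intersect(c("probe_id", "chromosome", "nearest_gene"),
                                  names(annotation))],
      by = "probe_id")
  } else {
    out$chromosome <- NA_character_
    out$nearest_gene <- NA_character_
  }
  out$fdr_q <- bh_adjust(out$p_value)
  out <- dplyr::arrange(out, .data$p_value)
  out$rank <- seq_len(nrow(out))
  out <- dplyr::select(out, "probe_id", "chromosome", "nearest_gene",
                       "delta_percent", "coefficient", "t_statistic",
                       "df", "p_value", "fdr_q", "rank")
  class(out) <- c("ewas_result", class(out))
  attr(out, "moderation") <- moderation
  attr(out, "df_residual") <- fit$df_residual
  attr(out, "df_total") <- fit$df_total
  out
}
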