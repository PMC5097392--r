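#' Select cell-type discriminating probes
#'
#' Ranks probes on a reference methylome matrix (probes x reference
#' columns, each column labelled with its cell type; replicate columns
#' per type allowed). For each cell type the top `n_per_type` probes by
#' absolute one-vs-rest mean beta difference are taken, restricted to
#' probes with nonzero between-type variance (when replicate columns
#' exist, probes are additionally ranked by between-type F statistic to
#' break ties). The union is deduplicated.
#'
#' @param reference Probes x columns beta matrix in `[0,1]`; colnames
#'   are cell-type labels (repeats = replicates).
#' @param n_per_type Markers requested per cell type.
#' @return Character vector of probe ids.
#' @export
select_discriminating_probes <- function(reference, n_per_type = 50) {
  types <- unique(colnames(reference))
  if (length(types) < 2) abort("reference must contain at least 2 cell types")
  type_means <- vapply(types, function(ct) {
    rowMeans(reference[, colnames(reference) == ct, drop = FALSE])
  }, numeric(nrow(reference)))
  between_var <- apply(type_means, 1, var)
  fstat <- between_f_statistic(reference, types)
  selected <- character(0)
  for (ct in types) {
    diff <- abs(type_means[, ct] -
                  rowMeans(type_means[, setdiff(types, ct), drop = FALSE]))
    eligible <- which(between_var > 0 & diff > 0)
    ord <- eligible[order(-diff[eligible], -fstat[eligible])]
    take <- head(ord, n_per_type)
    if (length(take) < n_per_type) {
      warn(sprintf("only %d discriminating probes available for %s (requested %d)",
                   length(take), ct, n_per_type))
    }
    selected <- c(selected, rownames(reference)[take])
  }
  unique(selected)
}

between_f_statistic <- function(reference, types) {
  groups <- factor(colnames(reference), levels = types)
  k <- length(types)
  n <- ncol(reference)
  gm <- rowMeans(reference)
  type_means <- vapply(types, function(ct) {
    rowMeans(reference[, groups == ct, drop = FALSE])
  }, numeric(nrow(reference)))
  n_per <- as.vector(table(groups))
  ssb <- as.vector((sweep(type_means, 1, gm))^2 %*% n_per)
  sst <- rowSums((reference - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  if (n - k <= 0) return(ssb)  # one column per type: rank by between-SS
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
}

#' Estimate whole-blood cell-type proportions
#'
#' Reference-based deconvolution: each sample's beta profile on the
#' discriminating probes is projected onto the reference cell-type
#' methylomes by constrained least squares, `min_w ||y - X w||^2`
#' subject to `w >= 0` and `sum(w) <= 1`. The constraint is handled by
#' nonnegative least squares on an augmented system with a slack
#' variable and a heavily weighted sum row, which recovers exact
#' mixtures to machine precision.
#'
#' @param beta Probes x samples beta matrix (must contain the
#'   discriminating probes).
#' @param reference Probes x cell-types reference beta matrix (one
#'   column per type; average replicate columns first).
#' @param probes Probe ids to project on; defaults to
#'   [select_discriminating_probes()] of the reference.
#' @param condition_max Maximum acceptable condition number of the
#'   reference on the projection probes.
#' @return A `cell_proportions` tibble: `sample_id`, one column per
#'   cell type, and `residual` (residual norm of the fit).
#' @export
estimate_cell_proportions <- function(beta, reference,
                                      probes = NULL,
                                      condition_max = 1e8) {
  types <- unique(colnames(reference))
  ref <- vapply(types, function(ct) {
    rowMeans(reference[, colnames(reference) == ct, drop = FALSE])
  }, numeric(nrow(reference)))
  rownames(ref) <- rownames(reference)
  if (is.null(probes)) probes <- select_discriminating_probes(reference)
  probes <- intersect(probes, rownames(beta))
  if (length(probes) < length(types)) {
    abort("fewer projection probes than cell types")
  }
  X <- ref[probes, , drop = FALSE]
  cond <- kappa(X, exact = TRUE)
  if (!is.finite(cond) || cond > condition_max) {
    abort(sprintf("reference columns are collinear on the projection probes (condition number %.3g)",
                  cond))
  }
  Y <- beta[probes, , drop = FALSE]
  if (anyNA(Y)) abort("missing beta values on the projection probes")
  k <- ncol(X)
  big <- 1e4 * max(abs(X), 1)
  # variables (w_1..w_k, slack); heavy row enforces sum(w) + slack = 1
  Xa <- rbind(cbind(X, 0), c(rep(big, k), big))
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    w <- nnls_lawson_hanson(Xa, c(Y[, j], big))[seq_len(k)]
    list(w = w, resid = sqrt(sum((Y[, j] - X %*% w)^2)))
  })
  W <- t(vapply(fits, function(f) f$w, numeric(k)))
  colnames(W) <- colnames(X)
  out <- as_tibble(W)
  out <- dplyr::mutate(out,
                       sample_id = colnames(Y),
                       residual = vapply(fits, function(f) f$resid, numeric(1)),
                       .before = 1)
  class(out) <- c("cell_proportions", class(out))
  out
}

# Lawson-Hanson active-set nonnegative least squares:
# min ||A x - b||^2 subject to x >= 0.
nnls_lawson_hanson <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * nrow(A)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      if (!any(passive)) { z <- numeric(n); break }
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Build regression covariates from cell proportions
#'
#' `mode = "proportions"` drops the last cell type (proportions are
#' compositional, so one column is redundant) and centres the rest.
#' `mode = "principal_components"` returns the leading principal
#' components of the centred proportion matrix (count = cell types -
#' 1), with the deterministic sign convention that each loading
#' vector's first nonzero entry is positive.
#'
#' @param proportions A `cell_proportions` tibble from
#'   [estimate_cell_proportions()].
#' @param mode `"proportions"` or `"principal_components"`.
#' @param drop_type Cell type dropped in proportions mode (default the
#'   last column, conventionally granulocytes).
#' @return Samples x k numeric matrix with sample ids as rownames and
#'   attribute `mode`.
#' @export
deconvolution_covariates <- function(proportions,
                                     mode = c("proportions", "principal_components"),
                                     drop_type = NULL) {
  mode <- match.arg(mode)
  types <- setdiff(names(proportions), c("sample_id", "residual"))
  W <- as.matrix(proportions[types])
  rownames(W) <- proportions$sample_id
  k_out <- length(types) - 1
  if (k_out >= nrow(W)) abort("more covariates than samples")
  if (mode == "proportions") {
    drop_type <- drop_type %||% types[length(types)]
    keep <- setdiff(types, drop_type)
    out <- scale(W[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  } else {
    Wc <- scale(W, center = TRUE, scale = FALSE)
    sv <- svd(Wc)
    pos <- sv$d > max(sv$d) * 1e-10
    if (!any(pos)) abort("cell proportions are identical across samples; no principal components")
    n_pc <- min(k_out, sum(pos))
    if (n_pc < k_out) {
      warn(sprintf("only %d principal components have nonzero variance", n_pc))
    }
    V <- sv$v[, seq_len(n_pc), drop = FALSE]
    for (j in seq_len(n_pc)) {    # sign: first nonzero loading positive
      nz <- which(abs(V[, j]) > 1e-12)[1]
      if (V[nz, j] < 0) V[, j] <- -V[, j]
    }
    out <- Wc %*% V
    colnames(out) <- paste0("cellPC", seq_len(n_pc))
  }
  attr(out, "mode") <- mode
  out
}
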