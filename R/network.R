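#' Network configuration
#'
#' Parameters for the signed weighted comethylation network: the soft
#' threshold exponent (default 12, at which scale-free topology is
#' typically reached on methylation data), signed adjacency, minimum
#' module size, and whether module dissimilarity uses the topological
#' overlap measure (default) or raw adjacency.
#'
#' @param power Soft-threshold exponent, >= 1.
#' @param signed Use the signed adjacency `((1 + cor)/2)^power`?
#' @param min_module_size Smallest allowed module (smaller clusters go
#'   to grey).
#' @param use_tom Cluster on `1 - TOM` (default) instead of `1 - A`.
#' @param cut_fraction Static cut height as a fraction of the merge
#'   height range.
#' @param split_gap Minimum relative height gap for recursively
#'   splitting a cluster into two subtrees.
#' @return A `network_config` list.
#' @export
network_config <- function(power = 12, signed = TRUE, min_module_size = 30,
                           use_tom = TRUE, cut_fraction = 0.9,
                           split_gap = 0.05) {
  if (power < 1) abort("power must be >= 1")
  if (min_module_size < 3) abort("min_module_size must be >= 3")
  structure(list(power = power, signed = signed,
                 min_module_size = min_module_size, use_tom = use_tom,
                 cut_fraction = cut_fraction, split_gap = split_gap),
            class = "network_config")
}

#' Probe-probe correlation matrix
#'
#' Pearson correlations across samples. Zero-variance probes cannot be
#' correlated and are excluded with a warning.
#'
#' @param M Probes x samples M-value matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained probes.
#' @export
correlation_matrix <- function(M) {
  if (ncol(M) < 3) abort("need at least 3 samples")
  v <- apply(M, 1, var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d zero-variance probe(s) from the network", sum(v == 0)))
    M <- M[v > 0, , drop = FALSE]
  }
  cor(t(M))
}

#' Soft-thresholded adjacency
#'
#' Signed network: `A = ((1 + cor)/2)^power`, mapping correlation -1
#' to adjacency 0 and +1 to 1 so anticorrelated probes never share a
#' module. Unsigned: `A = |cor|^power`. The diagonal is set to 1.
#'
#' @param cor_mat Correlation matrix.
#' @param config A [network_config()].
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(cor_mat, config = network_config()) {
  A <- if (config$signed) ((1 + cor_mat) / 2)^config$power
  else abs(cor_mat)^config$power
  diag(A) <- 1
  A
}

#' Scan soft-threshold powers for scale-free fit
#'
#' For each candidate power, computes connectivities `k_i = sum_j A_ij
#' (j != i)`, bins `log10(k)`, and regresses log10 bin frequency on
#' log10 mean bin connectivity. The signed fit index `R^2` is negated
#' when the slope is positive (a scale-free topology requires a
#' decreasing frequency-connectivity relationship).
#'
#' @param M Probes x samples M-value matrix (>= 50 probes).
#' @param powers Candidate exponents.
#' @param config A [network_config()] (its `power` is ignored here).
#' @param n_bins Number of connectivity bins.
#' @return Tibble with `power`, `r_squared`, `slope`, `mean_k`,
#'   `median_k`, `max_k`.
#' @export
soft_threshold_scan <- function(M, powers = 1:20, config = network_config(),
                                n_bins = 10) {
  if (nrow(M) < 50) abort("need at least 50 probes for a meaningful scan")
  cm <- correlation_matrix(M)
  base <- if (config$signed) (1 + cm) / 2 else abs(cm)
  diag(base) <- 0
  purrr::map_dfr(powers, function(pw) {
    k <- rowSums(base^pw)
    fit <- scale_free_fit(k, n_bins)
    tibble(power = pw, r_squared = fit$r_squared, slope = fit$slope,
           mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) {
    return(list(r_squared = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 2) return(list(r_squared = NA_real_, slope = NA_real_))
  x <- log10(kmean[ok])
  y <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r_squared = unname(if (!is.na(slope) && slope > 0) -r2 else r2),
       slope = unname(slope))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)`
#' for `i != j`, where the sum excludes `u = i, j` and connectivities
#' `k` exclude the diagonal; `TOM_ii = 1`. Values lie in `[0, 1]`:
#' high overlap means two probes share most of their network
#' neighbourhood.
#'
#' @param A Symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @return TOM matrix.
#' @export
topological_overlap <- function(A) {
  stopifnot(isSymmetric(unname(A)))
  k <- rowSums(A) - 1
  shared <- A %*% A - 2 * A          # sum_{u != i,j} A_iu A_uj (diag(A) = 1)
  kmin <- outer(k, k, pmin)
  TOM <- (shared + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Detect comethylation modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' (`1 - TOM` or `1 - A`), followed by a hybrid cut: a static cut at
#' `cut_fraction` of the merge-height range, then recursive splitting
#' of each cluster at its subtree root whenever both children reach
#' `min_module_size` and the root merge height exceeds the children's
#' by a relative gap of at least `split_gap`. Clusters below
#' `min_module_size` are unassigned ("grey"). Modules are labelled by
#' decreasing size through the conventional colour list.
#'
#' @param dissimilarity Symmetric dissimilarity matrix (probe
#'   dimnames required).
#' @param config A [network_config()].
#' @return A `module_assignment` tibble (`probe_id`, `module`) with
#'   attributes `sizes` (named vector) and `hclust` (the dendrogram).
#' @export
detect_modules <- function(dissimilarity, config = network_config()) {
  probes <- rownames(dissimilarity)
  n <- length(probes)
  if (n < 2 * config$min_module_size) {
    warn("fewer than 2 * min_module_size probes; at most one module is detectable")
  }
  hc <- hclust(as.dist(dissimilarity), method = "average")
  heights <- hc$height
  h_cut <- min(heights) + config$cut_fraction * diff(range(heights))
  clusters <- cut_and_split(hc, h_cut, config$min_module_size, config$split_gap)
  labels <- rep("grey", n)
  sizes <- vapply(clusters, length, integer(1))
  keep <- which(sizes >= config$min_module_size)
  keep <- keep[order(-sizes[keep])]
  palette <- module_colors()
  for (i in seq_along(keep)) {
    colour <- if (i <= length(palette)) palette[i] else paste0("module", i)
    labels[clusters[[keep[i]]]] <- colour
  }
  out <- tibble(probe_id = probes, module = labels)
  class(out) <- c("module_assignment", class(out))
  attr(out, "sizes") <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  attr(out, "hclust") <- hc
  out
}

module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

# Static height cut, then recursive gap-based splitting of each
# cluster's subtree. Returns a list of member index vectors.
cut_and_split <- function(hc, h_cut, min_size, split_gap) {
  n <- length(hc$order) # leaves
  merge <- hc$merge
  heights <- hc$height
  members <- function(node) {
    if (node < 0) return(-node)
    stack <- node
    out <- integer(0)
    while (length(stack) > 0) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (child in merge[nd, ]) {
        if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
      }
    }
    out
  }
  node_height <- function(node) if (node < 0) 0 else heights[node]
  # top-level clusters: maximal subtrees merged below h_cut
  roots <- integer(0)
  singletons <- integer(0)
  parent <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    for (child in merge[i, ]) if (child > 0) parent[child] <- i
  }
  is_root <- function(i) {
    heights[i] <= h_cut && (parent[i] == 0 || heights[parent[i]] > h_cut)
  }
  for (i in seq_len(nrow(merge))) if (is_root(i)) roots <- c(roots, i)
  assigned <- unlist(lapply(roots, members))
  singletons <- setdiff(seq_len(n), assigned)

  split_rec <- function(node) {
    h_root <- node_height(node)
    if (node < 0 || h_root == 0) return(list(members(node)))
    kids <- merge[node, ]
    sizes <- vapply(kids, function(kd) length(members(kd)), integer(1))
    child_h <- max(vapply(kids, node_height, numeric(1)))
    gap <- (h_root - child_h) / h_root
    if (all(sizes >= min_size) && gap > split_gap) {
      return(c(split_rec(kids[1]), split_rec(kids[2])))
    }
    list(members(node))
  }
  clusters <- unlist(lapply(roots, split_rec), recursive = FALSE)
  c(clusters, as.list(singletons))
}

#' Module eigengenes
#'
#' For each non-grey module, probe profiles are standardised (mean 0,
#' sd 1 across samples) and the module eigengene is the first right
#' singular vector of the probes x samples block: the sample-space
#' summary explaining the most comethylation variance. Eigengenes have
#' unit Euclidean norm and are sign-aligned to correlate positively
#' with the module's mean standardised profile.
#'
#' @param M Probes x samples M-value matrix.
#' @param assignment A `module_assignment` from [detect_modules()].
#' @return A `module_eigengenes` tibble: `sample_id` plus one column
#'   per module, with attribute `var_explained` (named vector of
#'   variance-explained fractions).
#' @export
module_eigengenes <- function(M, assignment) {
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0) abort("no non-grey modules")
  samples <- colnames(M)
  ev <- numeric(0)
  cols <- list()
  for (mod in sort(mods)) {
    probes <- assignment$probe_id[assignment$module == mod]
    block <- M[probes, , drop = FALSE]
    Z <- t(scale(t(block)))   # standardise each probe across samples
    Z[is.na(Z)] <- 0          # constant probes contribute nothing
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    mean_profile <- colMeans(Z)
    if (sum(e * mean_profile) < 0) e <- -e
    cols[[mod]] <- e
    ev[mod] <- sv$d[1]^2 / sum(sv$d^2)
  }
  out <- tibble(sample_id = samples, !!!cols)
  class(out) <- c("module_eigengenes", class(out))
  attr(out, "var_explained") <- ev
  out
}

eigengene_matrix <- function(eigengenes) {
  E <- as.matrix(eigengenes[setdiff(names(eigengenes), "sample_id")])
  rownames(E) <- eigengenes$sample_id
  E
}

cor_with_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  list(t = tt, p = 2 * pt(-abs(tt), df = n - 2))
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait
#' (numeric, or binary 0/1 giving the point-biserial correlation),
#' with a two-sided p-value from the t transform
#' `t = r sqrt((n - 2)/(1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param eigengenes A `module_eigengenes` tibble.
#' @param traits Data frame / tibble of traits, rows aligned to the
#'   eigengene samples.
#' @return Tibble with `module`, `trait`, `correlation`, `p_value`,
#'   `n`.
#' @export
module_trait_association <- function(eigengenes, traits) {
  E <- eigengene_matrix(eigengenes)
  traits <- as.data.frame(traits)
  n <- nrow(E)
  if (nrow(traits) != n) abort("traits not aligned to eigengene samples")
  purrr::map_dfr(names(traits), function(tr) {
    x <- as.numeric(traits[[tr]])
    if (sd(x) == 0) abort(sprintf("trait '%s' is constant", tr))
    r <- as.vector(cor(E, x))
    cp <- cor_with_p(r, n)
    tibble(module = colnames(E), trait = tr, correlation = r,
           p_value = cp$p, n = n)
  })
}

#' Gene significance
#'
#' The signed Pearson correlation of each probe's methylation profile
#' with the trait (for a binary case indicator this is the
#' point-biserial correlation, monotone in the two-sample t
#' statistic), with a two-sided p-value from the t transform. Constant
#' probes get `NA`.
#'
#' @param M Probes x samples M-value matrix.
#' @param trait Numeric or binary (0/1 / logical) vector per sample.
#' @return Tibble with `probe_id`, `gs`, `p_value`.
#' @export
gene_significance <- function(M, trait) {
  trait <- as.numeric(trait)
  if (sd(trait) == 0) abort("trait is constant")
  n <- ncol(M)
  v <- apply(M, 1, sd)
  r <- rep(NA_real_, nrow(M))
  ok <- v > 0
  r[ok] <- as.vector(cor(t(M[ok, , drop = FALSE]), trait))
  p <- rep(NA_real_, nrow(M))
  cp <- cor_with_p(r[ok], n)
  p[ok] <- cp$p
  tibble(probe_id = rownames(M), gs = r, p_value = p)
}

#' Module membership (kME)
#'
#' Correlation of each probe's profile with each module eigengene,
#' with a two-sided p-value from the t transform. Probes strongly
#' correlated with their module's eigengene (high kME) are the
#' module's driver probes.
#'
#' @param M Probes x samples M-value matrix.
#' @param eigengenes A `module_eigengenes` tibble.
#' @return Long tibble with `probe_id`, `module`, `kme`, `p_value`.
#' @export
module_membership <- function(M, eigengenes) {
  E <- eigengene_matrix(eigengenes)
  n <- ncol(M)
  v <- apply(M, 1, sd)
  K <- matrix(NA_real_, nrow(M), ncol(E), dimnames = list(rownames(M), colnames(E)))
  K[v > 0, ] <- cor(t(M[v > 0, , drop = FALSE]), E)
  out <- tidyr::pivot_longer(as_tibble(K, rownames = "probe_id"),
                             -"probe_id", names_to = "module",
                             values_to = "kme")
  cp <- cor_with_p(out$kme, n)
  out$p_value <- cp$p
  out
}

#' Restrict modules to high-membership probes
#'
#' Keeps, per module, the assigned probes whose kME to their own
#' module strictly exceeds the cutoff (default 0.85) - the stringent
#' driver-probe restriction used before gene-set enrichment.
#'
#' @param assignment A `module_assignment`.
#' @param kme Long kME tibble from [module_membership()].
#' @param cutoff Strict kME threshold.
#' @return Tibble with `probe_id`, `module`, `kme` for retained
#'   probes.
#' @export
limit_module <- function(assignment, kme, cutoff = 0.85) {
  own <- dplyr::inner_join(
    dplyr::filter(as_tibble(assignment), .data$module != "grey"),
    as_tibble(kme), by = c("probe_id", "module"))
  dplyr::filter(own, !is.na(.data$kme) & .data$kme > cutoff)
}

#' Eigengene logistic regression
#'
#' Maximum-likelihood logistic regression of case status on a module
#' eigengene plus the clinical covariates age, gender, and pack-years,
#' reporting the Wald test for the eigengene coefficient - the
#' robustness check that a module-trait correlation survives clinical
#' adjustment.
#'
#' @param eigengene Numeric eigengene vector (one value per sample).
#' @param sample_sheet Sample sheet with `copd_case`, `age`, `gender`,
#'   `pack_years` aligned to the eigengene.
#' @return One-row tibble: `coefficient`, `std_error`, `z_statistic`,
#'   `p_value`, `n`; the fitted `glm` is attached as attribute
#'   `model`.
#' @export
eigengene_logistic <- function(eigengene, sample_sheet) {
  d <- data.frame(case = as.numeric(sample_sheet$copd_case),
                  eigengene = eigengene,
                  age = sample_sheet$age,
                  gender_male = as.numeric(sample_sheet$gender == "male"),
                  pack_years = sample_sheet$pack_years)
  X <- as.matrix(d[, -1])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    abort("collinear covariates in the logistic model")
  }
  fit <- suppressWarnings(
    glm(case ~ eigengene + age + gender_male + pack_years,
        data = d, family = binomial()))
  # a diverging MLE (separation) shows as non-convergence or huge
  # standardised coefficients with all fitted probabilities pinned
  probs <- fitted(fit)
  pinned <- all(probs > 1 - 1e-6 | probs < 1e-6)
  diverged <- any(abs(coef(fit)) / pmax(sqrt(diag(vcov(fit))), 1e-12) < 1e-4 &
                    abs(coef(fit)) > 10)
  if (!fit$converged || pinned || diverged) {
    abort("perfect or quasi-perfect separation detected; consider a penalised fit")
  }
  est <- coef(fit)["eigengene"]
  se <- sqrt(vcov(fit)["eigengene", "eigengene"])
  out <- tibble(coefficient = unname(est), std_error = unname(se),
                z_statistic = unname(est / se),
                p_value = unname(2 * pnorm(-abs(est / se))),
                n = nrow(d))
  attr(out, "model") <- fit
  out
}

#' Build a full comethylation network analysis
#'
#' One-call orchestration: correlation matrix, signed adjacency, TOM,
#' module detection, eigengenes, module-trait association, gene
#' significance, and module membership.
#'
#' @param M Probes x samples M-value matrix.
#' @param traits Data frame of traits aligned to samples (first column
#'   used for gene significance; typically the case indicator).
#' @param config A [network_config()].
#' @return A `cometh_network` list with elements `assignment`,
#'   `eigengenes`, `module_trait`, `gs`, `kme`, `config`.
#' @export
build_network <- function(M, traits, config = network_config()) {
  cm <- correlation_matrix(M)
  M <- M[rownames(cm), , drop = FALSE]
  A <- adjacency(cm, config)
  diss <- if (config$use_tom) 1 - topological_overlap(A) else 1 - A
  assignment <- detect_modules(diss, config)
  eg <- module_eigengenes(M, assignment)
  structure(list(assignment = assignment,
                 eigengenes = eg,
                 module_trait = module_trait_association(eg, traits),
                 gs = gene_significance(M, traits[[1]]),
                 kme = module_membership(M, eg),
                 config = config),
            class = "cometh_network")
}

#' @export
print.cometh_network <- function(x, ...) {
  sizes <- attr(x$assignment, "sizes")
  cat(sprintf("<cometh_network> %d probes, %d modules (power %g, %s, %s)\n",
              nrow(x$assignment), length(sizes), x$config$power,
              if (x$config$signed) "signed" else "unsigned",
              if (x$config$use_tom) "TOM" else "adjacency"))
  if (length(sizes)) print(sizes)
  invisible(x)
}

#' @describeIn build_network Per-probe table: module, own-module kME,
#'   gene significance.
#' @param x A `cometh_network`.
#' @param ... Unused.
#' @export
tidy.cometh_network <- function(x, ...) {
  own_kme <- dplyr::select(
    dplyr::inner_join(as_tibble(x$assignment), as_tibble(x$kme),
                      by = c("probe_id", "module")),
    "probe_id", kme_own = "kme")
  out <- dplyr::left_join(as_tibble(x$assignment), own_kme, by = "probe_id")
  dplyr::left_join(out,
                   dplyr::rename(x$gs, gs_p_value = "p_value"),
                   by = "probe_id")
}

#' @describeIn build_network Per-module summary: size, variance
#'   explained, trait correlation.
#' @export
glance.cometh_network <- function(x, ...) {
  sizes <- attr(x$assignment, "sizes")
  ve <- attr(x$eigengenes, "var_explained")
  first_trait <- x$module_trait$trait[1]
  mt <- dplyr::filter(x$module_trait, .data$trait == first_trait)
  tibble(module = names(sizes),
         n_probes = as.integer(sizes),
         var_explained = unname(ve[names(sizes)]),
         trait = first_trait,
         correlation = mt$correlation[match(names(sizes), mt$module)],
         p_value = mt$p_value[match(names(sizes), mt$module)])
}
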