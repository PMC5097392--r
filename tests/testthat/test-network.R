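test_that("correlation matrix matches the Pearson definition", {
  withr::local_seed(61)
  M <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  cm <- correlation_matrix(M)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm[i, j], cor(M[i, ], M[j, ]), tolerance = 1e-12)
  }
  M2 <- rbind(M, dup = M[1, ], neg = -M[1, ])
  cm2 <- correlation_matrix(M2)
  expect_equal(cm2["p1", "dup"], 1)
  expect_equal(cm2["p1", "neg"], -1)
  M3 <- rbind(M, flat = rep(1, 6))
  expect_warning(cm3 <- correlation_matrix(M3), "zero-variance")
  expect_false("flat" %in% rownames(cm3))
})

test_that("signed adjacency follows the power transform", {
  cm <- matrix(c(1, 1, 0, -1,
                 1, 1, 0, 0,
                 0, 0, 1, 0,
                 -1, 0, 0, 1), 4, 4)
  A <- adjacency(cm, network_config(power = 12, signed = TRUE))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 4], 0)
  expect_equal(A[1, 3], 0.5^12)
  expect_true(all(A >= 0 & A <= 1))
  A_un <- adjacency(cm, network_config(power = 6, signed = FALSE))
  expect_equal(A_un[1, 4], 1)
})

test_that("the soft-threshold scan behaves across powers", {
  # modular network with graded sizes and probe loadings, the regime
  # where soft thresholding produces approximate scale-free topology
  withr::local_seed(62)
  n_s <- 150
  sizes <- c(120, 70, 45, 30, 20)
  M <- matrix(rnorm(300 * n_s), 300, n_s)
  for (b in seq_along(sizes)) {
    f <- rnorm(n_s)
    lam <- runif(sizes[b], 0.3, 0.95)
    M <- rbind(M, outer(lam, f) +
                 matrix(rnorm(sizes[b] * n_s, 0, sqrt(1 - lam^2)),
                        sizes[b], n_s))
  }
  rownames(M) <- sprintf("p%04d", seq_len(nrow(M)))
  colnames(M) <- sprintf("s%03d", seq_len(n_s))
  scan <- soft_threshold_scan(M, powers = c(1, 4, 8, 12, 16))
  expect_true(all(diff(scan$mean_k) < 0))     # mean connectivity decreases
  expect_gt(max(scan$r_squared, na.rm = TRUE), 0.8)
  # identical probes: all connectivities equal, fit undefined
  M_id <- matrix(rep(rnorm(30), each = 60), 60, 30) +
    matrix(0, 60, 30)
  rownames(M_id) <- paste0("p", 1:60)
  scan_id <- soft_threshold_scan(M_id, powers = 6)
  expect_true(is.na(scan_id$r_squared))
})

test_that("topological overlap matches the brute-force oracle", {
  # 3-node complete graph
  A3 <- matrix(1, 3, 3)
  expect_equal(topological_overlap(A3)[1, 2], 1)
  # isolated pair with no shared neighbours
  A0 <- diag(4)
  expect_equal(topological_overlap(A0)[1, 2], 0)
  withr::local_seed(63)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
    got <- topological_overlap(A)
    expect_equal(got, tom_oracle(A), tolerance = 1e-12)
    expect_true(all(got >= -1e-12 & got <= 1 + 1e-12))
  }
})

test_that("planted blocks are recovered as modules and noise stays grey", {
  pb <- planted_block_matrix(64)
  diss <- 1 - topological_overlap(adjacency(correlation_matrix(pb$M)))
  asg <- detect_modules(diss)
  expect_gte(mclust::adjustedRandIndex(asg$module, pb$truth), 0.9)
  sizes <- attr(asg, "sizes")
  expect_equal(length(sizes), 3)
  # i.i.d. probes: nothing reaches the minimum module size
  withr::local_seed(65)
  M_noise <- matrix(rnorm(200 * 100), 200, 100,
                    dimnames = list(paste0("p", 1:200), paste0("s", 1:100)))
  diss_n <- 1 - topological_overlap(adjacency(correlation_matrix(M_noise)))
  asg_n <- detect_modules(diss_n)
  expect_true(all(asg_n$module == "grey"))
  # min_module_size larger than the probe count: all grey
  expect_warning(asg_big <- detect_modules(diss_n,
                                           network_config(min_module_size = 300)),
                 "min_module_size")
  expect_true(all(asg_big$module == "grey"))
})

test_that("eigengenes are the leading right singular vector with fixed sign", {
  withr::local_seed(66)
  pb <- planted_block_matrix(66, n_bg = 60, sizes = c(40), n_samples = 50)
  asg <- tibble::tibble(probe_id = rownames(pb$M), module = pb$truth)
  class(asg) <- c("module_assignment", class(asg))
  eg <- module_eigengenes(pb$M, asg)
  block <- pb$M[pb$truth == "block1", ]
  Z <- t(scale(t(block)))
  sv <- svd(Z)
  e_hat <- eg$block1
  expect_equal(sum(e_hat^2), 1, tolerance = 1e-10)
  expect_equal(abs(e_hat), abs(sv$v[, 1]), tolerance = 1e-10)
  expect_gt(cor(e_hat, colMeans(Z)), 0)  # sign convention
  ve <- attr(eg, "var_explained")["block1"]
  expect_equal(unname(ve), sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  # rank-1 module: identical profiles give variance explained 1
  prof <- rnorm(50)
  M1 <- matrix(rep(prof, each = 35), 35, 50,
               dimnames = list(paste0("q", 1:35), paste0("s", 1:50)))
  asg1 <- tibble::tibble(probe_id = rownames(M1), module = "blue")
  eg1 <- module_eigengenes(M1, asg1)
  expect_equal(unname(attr(eg1, "var_explained")["blue"]), 1)
  expect_equal(abs(cor(eg1$blue, prof)), 1, tolerance = 1e-10)
  # probe duplication leaves the eigengene unchanged up to sign
  M_dup <- rbind(M1, M1)
  rownames(M_dup) <- paste0("q", 1:70)
  asg_dup <- tibble::tibble(probe_id = rownames(M_dup), module = "blue")
  eg_dup <- module_eigengenes(M_dup, asg_dup)
  expect_equal(abs(cor(eg_dup$blue, eg1$blue)), 1, tolerance = 1e-10)
})

test_that("module-trait association uses the t transform of the correlation", {
  withr::local_seed(67)
  e <- rnorm(30)
  eg <- tibble::tibble(sample_id = paste0("s", 1:30), mod1 = e / sqrt(sum(e^2)))
  class(eg) <- c("module_eigengenes", class(eg))
  # eigengene equal to the (centred) trait: r = 1
  mt <- module_trait_association(eg, data.frame(tr = eg$mod1))
  expect_equal(mt$correlation, 1)
  # n = 4, r = 0.5 worked example: t = 0.5 sqrt(2 / 0.75), p from t_2
  x <- c(1, 2, 3, 4)
  y <- x + sqrt(15) / 2 * c(1, -1, -1, 1)  # orthogonal noise scaled to r = 0.5
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  t_expect <- 0.5 * sqrt(2 / 0.75)
  expect_equal(t_expect, 0.816, tolerance = 1e-3)
  p_expect <- 2 * pt(-t_expect, df = 2)
  eg2 <- tibble::tibble(sample_id = paste0("s", 1:4), m = x)
  class(eg2) <- c("module_eigengenes", class(eg2))
  mt2 <- module_trait_association(eg2, data.frame(tr = y))
  expect_equal(mt2$correlation, 0.5, tolerance = 1e-10)
  expect_equal(mt2$p_value, p_expect, tolerance = 1e-8)
  expect_error(module_trait_association(eg, data.frame(tr = rep(1, 30))),
               "constant")
})

test_that("gene significance is the point-biserial correlation tied to the t statistic", {
  withr::local_seed(68)
  n <- 40
  trait <- rep(c(1, 0), c(15, 25))
  M <- matrix(rnorm(20 * n), 20, n, dimnames = list(paste0("p", 1:20),
                                                    paste0("s", 1:n)))
  M[1, ] <- trait  # probe equal to the indicator
  M[2, ] <- M[2, ] - 1.5 * trait  # planted hypomethylation in cases
  gs <- gene_significance(M, trait)
  expect_equal(gs$gs[1], 1)
  expect_lt(gs$gs[2], 0)
  # GS^2 (n-2)/(1-GS^2) equals the squared pooled two-sample t statistic
  for (i in 3:6) {
    r <- gs$gs[i]
    t_from_r <- sqrt(r^2 * (n - 2) / (1 - r^2))
    t_pooled <- abs(stats::t.test(M[i, trait == 1], M[i, trait == 0],
                                  var.equal = TRUE)$statistic)
    expect_equal(t_from_r, unname(t_pooled), tolerance = 1e-10)
  }
  M[3, ] <- 7  # constant probe: undefined, reported missing
  gs2 <- gene_significance(M, trait)
  expect_true(is.na(gs2$gs[3]))
})

test_that("module membership is the eigengene correlation and gates limiting", {
  withr::local_seed(69)
  prof <- rnorm(60)
  M <- rbind(matrix(rep(prof, each = 35), 35, 60),
             matrix(rnorm(30 * 60), 30, 60))
  rownames(M) <- paste0("p", 1:65)
  colnames(M) <- paste0("s", 1:60)
  asg <- tibble::tibble(probe_id = rownames(M),
                        module = rep(c("blue", "grey"), c(35, 30)))
  class(asg) <- c("module_assignment", class(asg))
  eg <- module_eigengenes(M, asg)
  kme <- module_membership(M, eg)
  own <- kme$kme[kme$probe_id == "p1" & kme$module == "blue"]
  expect_equal(abs(own), 1, tolerance = 1e-10)
  # definition oracle on a few probes
  for (p in c("p3", "p40", "p60")) {
    expect_equal(kme$kme[kme$probe_id == p & kme$module == "blue"],
                 cor(M[p, ], eg$blue), tolerance = 1e-12)
  }
  # rank-1 module: every member survives the strict kME cutoff
  lim <- limit_module(asg, kme, cutoff = 0.85)
  expect_setequal(lim$probe_id, paste0("p", 1:35))
  # a probe at exactly the cutoff is excluded
  kme_edge <- tibble::tibble(probe_id = "p1", module = "blue", kme = 0.85,
                             p_value = 0.01)
  expect_equal(nrow(limit_module(asg, kme_edge, cutoff = 0.85)), 0)
})

test_that("eigengene logistic regression recovers planted directions and flags separation", {
  withr::local_seed(70)
  n <- 200
  ss <- tibble::tibble(sample_id = paste0("s", 1:n),
                       copd_case = rep(c(TRUE, FALSE), each = n / 2),
                       age = rnorm(n, 55, 8),
                       gender = sample(c("male", "female"), n, TRUE),
                       pack_years = runif(n, 20, 60))
  e <- 0.8 * as.numeric(ss$copd_case) + rnorm(n, 0, 1)
  fit <- eigengene_logistic(e, ss)
  expect_gt(fit$coefficient, 0)
  expect_lt(fit$p_value, 0.05)
  # perfectly separating eigengene
  e_sep <- as.numeric(ss$copd_case) * 2 - 1
  expect_error(eigengene_logistic(e_sep, ss), "separation")
  # collinear covariates
  ss2 <- ss
  ss2$pack_years <- ss2$age
  expect_error(eigengene_logistic(e, ss2), "collinear")
})

test_that("retained members of a signed module are positively intercorrelated", {
  pb <- planted_block_matrix(71)
  M <- pb$M
  traits <- data.frame(tr = rnorm(ncol(M)))
  net <- build_network(M, traits)
  lim <- limit_module(net$assignment, net$kme, cutoff = 0.85)
  mods <- unique(lim$module)
  for (mod in mods) {
    probes <- lim$probe_id[lim$module == mod]
    if (length(probes) < 3) next
    cm <- cor(t(M[probes, ]))
    expect_gt(median(cm[upper.tri(cm)]), 0)
  }
})

test_that("network construction is deterministic", {
  pb <- planted_block_matrix(72, n_bg = 120, sizes = c(40, 35), n_samples = 60)
  traits <- data.frame(tr = rep(c(0, 1), 30))
  n1 <- build_network(pb$M, traits)
  n2 <- build_network(pb$M, traits)
  expect_identical(n1$assignment$module, n2$assignment$module)
  expect_identical(n1$eigengenes, n2$eigengenes)
  expect_identical(n1$module_trait, n2$module_trait)
})
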