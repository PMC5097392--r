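# Small hand-built containers used across test files.

tiny_intensity <- function() {
  m <- matrix(c(300, 1000, 50, 120, 400, 80), nrow = 3,
              dimnames = list(c("cg01", "cg02", "cg03"), c("s1", "s2")))
  u <- matrix(c(100, 0, 450, 380, 100, 20), nrow = 3,
              dimnames = dimnames(m))
  dp <- matrix(runif(6, 0, 0.01), nrow = 3, dimnames = dimnames(m))
  bc <- matrix(15L, nrow = 3, ncol = 2, dimnames = dimnames(m))
  intensity_data(m, u, dp, bc)
}

tiny_sample_sheet <- function(n_cases = 3, n_controls = 3, batches = 1) {
  n <- n_cases + n_controls
  withr::local_seed(n + 1000L * batches)
  validate_ss(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    copd_case = rep(c(TRUE, FALSE), c(n_cases, n_controls)),
    age = round(runif(n, 42, 78), 1),
    gender = rep(c("male", "female", "female", "male"), length.out = n),
    pack_years = round(runif(n, 20, 65), 1),
    batch = sample(rep(paste0("B", seq_len(batches)), length.out = n)),
    cohort = "test", replicate_of = NA_character_))
}

validate_ss <- function(ss) {
  ss$covariates_complete <- !is.na(ss$copd_case) & !is.na(ss$age) &
    !is.na(ss$gender) & !is.na(ss$pack_years) & !is.na(ss$batch)
  ss
}

# planted 3-block latent-factor design used by the network tests
planted_block_matrix <- function(seed, n_bg = 600, sizes = c(60, 50, 40),
                                 n_samples = 200, rho = 0.7) {
  withr::local_seed(seed)
  M <- matrix(rnorm(n_bg * n_samples), n_bg, n_samples)
  truth <- rep("grey", n_bg + sum(sizes))
  blocks <- list()
  for (b in seq_along(sizes)) {
    f <- rnorm(n_samples)
    blocks[[b]] <- sqrt(rho) * matrix(rep(f, each = sizes[b]),
                                      sizes[b], n_samples) +
      sqrt(1 - rho) * matrix(rnorm(sizes[b] * n_samples), sizes[b], n_samples)
    truth[n_bg + sum(sizes[seq_len(b - 1)]) + seq_len(sizes[b])] <-
      paste0("block", b)
  }
  M <- rbind(M, do.call(rbind, blocks))
  rownames(M) <- sprintf("p%05d", seq_len(nrow(M)))
  colnames(M) <- sprintf("s%04d", seq_len(n_samples))
  list(M = M, truth = truth)
}

# independent brute-force oracles ------------------------------------

bh_oracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # exhaustive suffix minimum of p(j) * m / j over j >= i
    q[o[i]] <- min(1, min(p[o][i:n] * (m / (i:n))))
  }
  q
}

tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(n)) {
      if (u != i && u != j) num <- num + A[i, u] * A[u, j]
    }
    TOM[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(TOM) <- dimnames(A)
  TOM
}

hyper_oracle <- function(k, K, n, N) {
  # P(X >= k) by explicit pmf summation with choose()
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
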