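# Shared fixtures and independent brute-force oracles. Oracles never call
# the implementation paths they check.

make_matrix <- function(values, n_row, n_col, scale = "log2",
                        fprefix = "f", sprefix = "s") {
  m <- matrix(values, nrow = n_row, ncol = n_col,
              dimnames = list(sprintf("%s%03d", fprefix, seq_len(n_row)),
                              sprintf("%s%03d", sprefix, seq_len(n_col))))
  expression_matrix(m, scale)
}

two_group_pheno <- function(sample_ids, n_control = length(sample_ids) %/% 2) {
  phenotype_table(sample_ids,
                  rep(c("control", "case"),
                      c(n_control, length(sample_ids) - n_control)),
                  control = "control", case = "case")
}

random_dataset <- function(n_mi = 6, n_mr = 10, n_samp = 12, seed = 42) {
  set.seed(seed)
  mi <- make_matrix(rnorm(n_mi * n_samp, 8), n_mi, n_samp, fprefix = "mir")
  mr <- make_matrix(rnorm(n_mr * n_samp, 8), n_mr, n_samp, fprefix = "g")
  align_dataset(mi, mr, two_group_pheno(colnames(mi)))
}

# lazily-built shared recovery-scenario run (used by several acceptance
# checks; heavy, so computed once per session)
fixture_env <- new.env(parent = emptyenv())

recovery_fit <- function() {
  if (is.null(fixture_env$recovery)) {
    sim <- simulate_dataset(simulation_config(seed = 1))
    fit <- mirlink(sim$dataset, databases = sim$databases)
    fixture_env$recovery <- list(sim = sim, fit = fit)
  }
  fixture_env$recovery
}

# --- independent oracles ----------------------------------------------------

# permutation count for the one-sided negative-correlation test:
# number of permutations with r_null <= r_obs
perm_cor_count <- function(x, y, B) {
  n <- length(x)
  r_obs <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  yc <- y - mean(y)
  idx <- replicate(B, sample.int(n))
  X <- matrix(x[idx], nrow = n)
  Xc <- sweep(X, 2, colMeans(X))
  r_null <- as.vector(crossprod(Xc, yc)) /
    (sqrt(colSums(Xc^2)) * sqrt(sum(yc^2)))
  sum(r_null <= r_obs)
}

# step-up BH from the definition: adj_k = min over i >= k of p_(i) * m / i
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj_sorted)[order(o)]
}

bonferroni_brute <- function(p) pmin(1, p * length(p))

# hypergeometric upper tail from the pmf definition (choose() sums)
hyper_tail_brute <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcox_enum_p <- function(case_vals, ctrl_vals) {
  pooled <- c(case_vals, ctrl_vals)
  n1 <- length(case_vals)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(i) sum(rank(pooled)[i]) - n1 * (n1 + 1) / 2)
  ew <- mean(w_all)
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
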