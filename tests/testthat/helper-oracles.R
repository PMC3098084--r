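# Independent oracles used across the suite. These deliberately take the
# slow, direct route (explicit pair enumeration, exhaustive search) so they
# share no code with the package implementations they check.

# O(n^2) pair classification by explicit enumeration over all object pairs.
brute_pair_counts <- function(p, q) {
  n <- length(p)
  same_p <- outer(p, p, "==")
  same_q <- outer(q, q, "==")
  ut <- upper.tri(same_p)
  list(a = sum(same_p[ut] & same_q[ut]),
       b = sum(!same_p[ut] & !same_q[ut]),
       c = sum(same_p[ut] & !same_q[ut]),
       d = sum(!same_p[ut] & same_q[ut]))
}

# Adjusted Rand from brute-force pair counts (permutation-model centering
# written in terms of a, c, d rather than the contingency table).
brute_arand <- function(p, q) {
  pc <- brute_pair_counts(p, q)
  n2 <- choose(length(p), 2)
  sum_p <- pc$a + pc$c   # pairs together in p
  sum_q <- pc$a + pc$d   # pairs together in q
  expected <- sum_p * sum_q / n2
  denom <- (sum_p + sum_q) / 2 - expected
  if (abs(denom) < 1e-12) {
    return(if (pc$c == 0 && pc$d == 0) 1 else 0)
  }
  (pc$a - expected) / denom
}

# Exhaustive ten-to-two merge by direct enumeration of group assignments
# (logical vectors over cluster labels), scored with brute_arand.
brute_optimal_merge <- function(predicted, truth) {
  labs <- sort(unique(predicted))
  k <- length(labs)
  assign_grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
  keep <- rowSums(assign_grid) >= 1 & rowSums(assign_grid) <= k - 1
  assign_grid <- assign_grid[keep, , drop = FALSE]
  best <- -Inf
  for (r in seq_len(nrow(assign_grid))) {
    merged <- ifelse(predicted %in% labs[assign_grid[r, ]], 1L, 2L)
    sc <- brute_arand(merged, truth)
    if (sc > best) best <- sc
  }
  best
}

# Small complete-data expression matrix with two planted sample classes.
make_mvm <- function(n_genes = 20, n_samples = 8, seed = 1,
                     missing_rate = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  miss <- matrix(runif(n_genes * n_samples) < missing_rate,
                 n_genes, n_samples)
  v[miss] <- NA_real_
  clustgrid:::mvmatrix(v, miss,
                       sprintf("G%03d", seq_len(n_genes)),
                       sprintf("S%02d", seq_len(n_samples)))
}

# A quick small synthetic experiment for end-to-end unit tests.
small_experiment <- function(seed = 1, n_per_class = c(10, 10),
                             n_genes = 400, n_de = 60, de_effect = 2,
                             noise_sd = 0.3, ...) {
  simulate_experiment(sim_config(
    n_samples_per_class = n_per_class, n_genes = n_genes,
    n_de_genes = n_de, de_effect = de_effect, noise_sd = noise_sd,
    n_printtip_blocks = 4, seed = seed, ...))
}

# Fabricated result table: reduced grid x datasets with an additive
# generating model plus noise; used for the meta-analysis recovery tests.
fake_result_table <- function(datasets = paste0("d", 1:3),
                              effects = list(), noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  specs <- enumerate_specs(reduced = TRUE)
  rt <- do.call(rbind, lapply(datasets, function(d) {
    r <- specs; r$dataset <- d; r
  }))
  rt$arand <- 0.5 + rnorm(nrow(rt), 0, noise_sd)
  for (col in names(effects)) {
    for (lev in names(effects[[col]])) {
      hit <- rt[[col]] == lev
      rt$arand[hit] <- rt$arand[hit] + effects[[col]][[lev]]
    }
  }
  rt$arand <- pmin(pmax(rt$arand, -1), 1)
  rt$status <- "ok"
  rt
}
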