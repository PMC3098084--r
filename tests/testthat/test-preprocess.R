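test_that("assembly stacks samples and rejects mismatched layouts", {
  ex <- small_experiment(seed = 2, n_per_class = c(2, 1), n_genes = 50,
                         n_de = 10, flag_rate = 0.1)
  ma <- lapply(ex$scans, compute_ma)
  m <- assemble_matrix(ma)
  expect_equal(dim(m$values), c(length(ma[[1]]$M), 3))
  expect_identical(m$missing[, 2], ma[[2]]$missing)
  expect_identical(is.na(m$values), m$missing)
  bad <- ma
  bad[[2]]$gene_id <- rev(bad[[2]]$gene_id)
  expect_error(assemble_matrix(bad), "layout")
  expect_error(assemble_matrix(list()), "no samples")
})

test_that("filtration applies strict thresholds in a single pass", {
  # 5 genes x 4 samples; sample 4 has 60% missing, sample 3 has 25%
  miss <- matrix(FALSE, 5, 4)
  miss[1:3, 4] <- TRUE          # sample 4: 3/5 = 60% -> removed
  miss[1, 3] <- TRUE            # sample 3: 1/5 = 20% -> kept
  miss[2, c(1, 4)] <- TRUE      # gene 2: 2/4 = 50% -> removed
  v <- matrix(rnorm(20), 5, 4); v[miss] <- NA
  m <- clustgrid:::mvmatrix(v, miss, paste0("g", 1:5), paste0("s", 1:4))
  out <- filter_matrix(m)
  expect_identical(out$sample_ids, c("s1", "s2", "s3"))
  expect_false("g2" %in% out$gene_ids)
  # gene 1 is missing in 1/4 samples (25%) on the INPUT mask -> kept, even
  # though after removing the bad sample 4 its fraction would rise to 1/3
  miss2 <- matrix(FALSE, 5, 4)
  miss2[1, 3] <- TRUE
  miss2[2:4, 4] <- TRUE         # sample 4 bad: 3/5 = 60%
  v2 <- matrix(rnorm(20), 5, 4); v2[miss2] <- NA
  m2 <- clustgrid:::mvmatrix(v2, miss2, paste0("g", 1:5), paste0("s", 1:4))
  out2 <- filter_matrix(m2)
  expect_false("s4" %in% out2$sample_ids)
  expect_true("g1" %in% out2$gene_ids)    # single-pass rule
  # the iterated variant re-evaluates and removes it
  expect_false("g1" %in% filter_matrix(m2, iterate = TRUE)$gene_ids)
  # a gene at 25% missing is kept (strictly below 30%)
  miss3 <- matrix(FALSE, 2, 4); miss3[1, 1] <- TRUE
  v3 <- matrix(rnorm(8), 2, 4); v3[miss3] <- NA
  m3 <- clustgrid:::mvmatrix(v3, miss3, c("a", "b"), paste0("s", 1:4))
  expect_identical(filter_matrix(m3)$gene_ids, c("a", "b"))
  # idempotence
  expect_identical(filter_matrix(out), out)
})

test_that("row-median imputation fills exactly the missing cells", {
  v <- rbind(c(1, 2, NA, 4), c(1, NA, 3, 5), c(0, 0, 0, 0))
  miss <- is.na(v)
  m <- clustgrid:::mvmatrix(v, miss, c("g1", "g2", "g3"), paste0("s", 1:4))
  out <- impute_row(m)
  expect_equal(unname(out$values[1, 3]), 2)   # median of 1, 2, 4
  expect_equal(unname(out$values[2, 2]), 3)   # even-count median of 1, 3, 5
  expect_identical(out$values[!miss], v[!miss])
  expect_false(any(out$missing))
  # identity when complete
  expect_equal(impute_row(out)$values, out$values)
  allmiss <- clustgrid:::mvmatrix(rbind(c(NA, NA)), rbind(c(TRUE, TRUE)),
                                  "g", c("s1", "s2"))
  expect_error(impute_row(allmiss), "no observed")
})

test_that("SVD imputation recovers a rank-1 matrix exactly", {
  v <- outer(c(1, 2, 3), c(1, 2, 4, 8))
  miss <- matrix(FALSE, 3, 4); miss[3, 4] <- TRUE
  v_obs <- v; v_obs[3, 4] <- NA
  m <- clustgrid:::mvmatrix(v_obs, miss, paste0("g", 1:3), paste0("s", 1:4))
  out <- impute_svd(m, k = 1, tol = 1e-9, max_iter = 200)
  expect_equal(unname(out$values[3, 4]), 24, tolerance = 1e-6)
  expect_identical(out$values[!miss], v[!miss])   # observed untouched
  expect_false(any(out$missing))
  expect_true(length(attr(out, "svd_trace")) >= 1)
})

test_that("SVD imputation approximates a noisy low-rank matrix", {
  set.seed(10)
  u <- matrix(rnorm(50 * 3), 50, 3); w <- matrix(rnorm(3 * 20), 3, 20)
  truth <- u %*% w
  v <- truth + matrix(rnorm(1000, 0, 0.01), 50, 20)
  miss <- matrix(runif(1000) < 0.05, 50, 20)
  v_obs <- v; v_obs[miss] <- NA
  m <- clustgrid:::mvmatrix(v_obs, miss, sprintf("g%02d", 1:50),
                            sprintf("s%02d", 1:20))
  out <- impute_svd(m, k = 3, tol = 1e-6, max_iter = 200)
  rmse <- sqrt(mean((out$values[miss] - truth[miss])^2))
  expect_lt(rmse, 0.1)
  # no missing cells: identity with an empty trace
  full <- impute_svd(out, k = 3)
  expect_identical(full$values, out$values)
  expect_length(attr(full, "svd_trace"), 0)
})

test_that("duplicate spots collapse to per-gene means in first order", {
  v <- rbind(c(1, 3), c(3, 5), c(10, 10), c(2, 4))
  m <- clustgrid:::mvmatrix(v, matrix(FALSE, 4, 2),
                            c("G", "G", "H", "G"), c("s1", "s2"))
  out <- collapse_duplicates(m)
  expect_identical(out$gene_ids, c("G", "H"))
  expect_equal(out$values[1, ], c(s1 = 2, s2 = 4))  # mean of three G rows
  expect_equal(unname(out$values[2, ]), c(10, 10))
  nodup <- collapse_duplicates(out)
  expect_identical(nodup$values, out$values)
})

test_that("unlabeled samples are dropped with order preserved", {
  m <- make_mvm(n_genes = 6, n_samples = 5)
  labels <- c(S01 = "A", S03 = "B", S04 = "A", S05 = "B")
  out <- drop_unlabeled(m, labels)
  expect_identical(out$matrix$sample_ids, c("S01", "S03", "S04", "S05"))
  expect_identical(as.character(out$labels), c("A", "B", "A", "B"))
  expect_error(drop_unlabeled(m, c(S01 = "A")), "2 labeled classes")
  expect_error(drop_unlabeled(m, c(X = "A", Y = "B")), "no labeled")
})
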