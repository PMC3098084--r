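test_that("scorer arithmetic on hand-checked genes", {
  v <- rbind(c(1, 2, 3), c(2, 2, 2), c(1, -1, 0), c(0, 0, 0))
  m <- clustgrid:::mvmatrix(v, matrix(FALSE, 4, 3),
                            c("g1", "g2", "g3", "g4"), paste0("s", 1:3))
  expect_equal(unname(score_std(m)), c(1, 0, 1, 0))
  expect_equal(unname(score_m(m)), c(2, 2, 0, 0))
  # translation invariance of STD, sign invariance of M
  m2 <- m; m2$values[1, ] <- m2$values[1, ] + 100
  expect_equal(score_std(m2), score_std(m))
  m3 <- m; m3$values[2, ] <- -m3$values[2, ]
  expect_equal(score_m(m3), score_m(m))
  # one-sample moderated t with nu0 = 0 is the classical t
  t1 <- score_t1(m, nu0 = 0)
  expect_equal(unname(t1[1]), abs(2 / sqrt(1 / 3)), tolerance = 1e-12) # 3.464
  expect_equal(unname(t1[3]), 0)
  # scale invariance at nu0 = 0
  m4 <- m; m4$values[1, ] <- 2 * m4$values[1, ]
  expect_equal(score_t1(m4, nu0 = 0)[1], t1[1])
})

test_that("moderated variance follows the shrinkage formula", {
  # n = 3, s^2 = 1, nu0 = 2, sigma0^2 = 4 -> (2*4 + 2*1)/3 = 10/3
  v <- rbind(c(1, 2, 3), c(-2, 0, 2), c(-2, 0, 2), c(-2, 0, 2))
  expect_equal(moderated_variance(v, nu0 = 0), apply(v, 1, var))
  got <- moderated_variance(v, nu0 = 2, window = 3)
  # gene 1's three intensity-rank neighbors all have s^2 = 4 except itself
  sigma0_g1 <- mean(c(1, 4, 4))
  expect_equal(got[1], (2 * sigma0_g1 + 2 * 1) / 3)
  # regularization keeps constant genes positive
  v2 <- rbind(c(5, 5, 5), c(0, 1, 2), c(3, 1, 8))
  expect_gt(moderated_variance(v2, nu0 = 2, window = 3)[1], 0)
  # nu0 = 0 with two observations still reduces to s^2
  expect_equal(moderated_variance(v[, 1:2, drop = FALSE], nu0 = 0),
               apply(v[, 1:2], 1, var))
  expect_error(moderated_variance(v[, 1, drop = FALSE], nu0 = 2),
               "at least 2")
  # global prior option
  glob <- moderated_variance(v, nu0 = 2, window = "global")
  expect_equal(glob[1], (2 * mean(c(1, 4, 4, 4)) + 2 * 1) / 3)
})

test_that("two-class scores equal Welch-style statistics and are symmetric", {
  v <- rbind(c(0, 1, 2, 3), c(1, 1, 1, 1), c(0, 2, 1, 3))
  m <- clustgrid:::mvmatrix(v, matrix(FALSE, 3, 4),
                            c("g1", "g2", "g3"), paste0("s", 1:4))
  lab <- factor(c("A", "A", "B", "B"))
  t2 <- score_t2(m, lab, nu0 = 0)
  expect_equal(unname(t2[1]), 2 / sqrt(0.5 / 2 + 0.5 / 2), tolerance = 1e-12)
  expect_equal(unname(t2[2]), 0)
  md <- score_mdiff(m, lab)
  expect_equal(unname(md), c(2, 0, 1))
  # label swap leaves both unchanged
  swapped <- factor(c("B", "B", "A", "A"))
  expect_equal(score_t2(m, swapped, nu0 = 0), t2)
  expect_equal(score_mdiff(m, swapped), md)
  expect_error(score_t2(m, factor(c("A", "B", "B", "B")), nu0 = 0),
               "at least 2")
})

test_that("nu0 = 0 moderated t equals textbook t on random matrices", {
  set.seed(20)
  for (i in 1:5) {
    m <- make_mvm(n_genes = 30, n_samples = 10, seed = i)
    lab <- factor(rep(c("A", "B"), each = 5))
    t1_pkg <- score_t1(m, nu0 = 0)
    t1_ref <- abs(rowMeans(m$values)) /
      sqrt(apply(m$values, 1, var) / ncol(m$values))
    expect_equal(unname(t1_pkg), unname(t1_ref), tolerance = 1e-10)
    t2_pkg <- score_t2(m, lab, nu0 = 0)
    t2_ref <- vapply(seq_len(30), function(g)
      abs(t.test(m$values[g, 1:5], m$values[g, 6:10])$statistic), numeric(1))
    expect_equal(unname(t2_pkg), unname(t2_ref), tolerance = 1e-10)
  }
})

test_that("top-n selection is deterministic, tie-broken and nested", {
  m <- make_mvm(n_genes = 40, n_samples = 6, seed = 3)
  scores <- score_std(m)
  f <- select_top(m, scores, 10)
  expect_equal(dim(f), c(6, 10))
  expect_setequal(colnames(f), names(sort(scores, decreasing = TRUE))[1:10])
  # nestedness under the fixed tie-break
  for (n1 in c(5, 10, 20))
    expect_true(all(colnames(select_top(m, scores, n1)) %in%
                      colnames(select_top(m, scores, 30))))
  # ties at the cutoff resolved by ascending gene id
  tied <- stats::setNames(rep(1, 40), m$gene_ids)
  expect_identical(colnames(select_top(m, tied, 3)), c("G001", "G002", "G003"))
  expect_error(select_top(m, scores, 41), "cannot select")
  # selecting everything is a permutation of the full matrix
  expect_setequal(colnames(select_top(m, scores, 40)), m$gene_ids)
})

test_that("principal component projection preserves geometry", {
  m <- make_mvm(n_genes = 15, n_samples = 10, seed = 4)
  k <- 10
  f <- select_pc(m, k)
  centered <- t(m$values - rowMeans(m$values))
  expect_equal(as.matrix(dist(f)), as.matrix(dist(centered)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # components ordered by decreasing variance
  vars <- apply(f, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  # sign convention: largest-magnitude loading positive => deterministic
  expect_identical(select_pc(m, 3), select_pc(m, 3))
  # duplicated sample gives identical projected rows
  m2 <- m; m2$values[, 2] <- m2$values[, 1]
  f2 <- select_pc(m2, 3)
  expect_equal(f2[1, ], f2[2, ], tolerance = 1e-10)
  expect_error(select_pc(m, 11), "exceeds")
  # variance concentrated on one planted axis loads component 1
  set.seed(5)
  u <- rnorm(15)
  v <- outer(u, rnorm(10, 0, 3)) + matrix(rnorm(150, 0, 0.1), 15, 10)
  m3 <- clustgrid:::mvmatrix(v, matrix(FALSE, 15, 10),
                             sprintf("g%02d", 1:15), sprintf("s%02d", 1:10))
  f3 <- select_pc(m3, 3)
  expect_gt(var(f3[, 1]) / sum(apply(f3, 2, var)), 0.9)
})

test_that("z-standardization scales features and handles constants", {
  f <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(out <- standardize_features(f), "constant")
  expect_equal(unname(out[, 1]), c(-1, 0, 1))
  expect_equal(unname(out[, 2]), c(0, 0, 0))
  expect_identical(standardize_features(f, on = FALSE), f)
  f2 <- matrix(rnorm(30), 10, 3)
  out2 <- standardize_features(f2)
  expect_equal(unname(colMeans(out2)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out2, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("the selection registry drives the dispatcher", {
  reg <- selection_registry()
  expect_equal(nrow(reg), 13)
  reg_s <- selection_registry(include_supervised = TRUE)
  expect_equal(nrow(reg_s), 19)
  expect_setequal(reg_s$sel_method[reg_s$supervised], c("T2", "Mdiff"))
  expect_equal(nrow(selection_registry(extra_std_sizes = c(300, 500, 1500))),
               16)
  m <- make_mvm(n_genes = 30, n_samples = 8, seed = 6)
  lab <- factor(rep(c("A", "B"), each = 4))
  for (i in seq_len(nrow(reg_s))) {
    f <- select_features(m, reg_s$sel_method[i],
                         n = min(reg_s$sel_n[i], 8, na.rm = TRUE),
                         labels = lab)
    expect_equal(nrow(f), 8)
  }
  expect_equal(ncol(select_features(m, "NONE")), 30)
})
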