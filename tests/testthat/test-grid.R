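test_that("the factorial grid reproduces the published combinatorics", {
  unsup <- enumerate_specs()
  expect_equal(nrow(unsup), 2780)
  expect_equal(nrow(enumerate_specs(include_supervised = TRUE)) - nrow(unsup),
               1280)
  reduced <- enumerate_specs(reduced = TRUE)
  expect_equal(nrow(reduced), 288)
  expect_equal(nrow(unsup) - nrow(reduced), 2492)
  # structure: no invalid model-based combinations survive
  expect_false(any(unsup$clustering == "mclust" &
                     (unsup$selection == "NONE" |
                        (!is.na(unsup$sel_n) & unsup$sel_method != "PC" &
                           unsup$sel_n > 500))))
  expect_false(any(unsup$supervised))
  # the reduced set matches the surviving sub-processes
  expect_setequal(unique(reduced$normalization),
                  c("norm.pt", "norm.pt.bkg", "norm.glob", "norm.glob.bkg"))
  expect_setequal(unique(reduced$selection),
                  c("NONE", "STD 100", "STD 1000", "PC 15"))
  expect_setequal(unique(reduced$clustering),
                  c("hclust.corr.ward", "hclust.eucl.ward",
                    "hclust.manh.ward", "kmeans", "mclust"))
  # extra STD sizes extend the registry without breaking validity
  extra <- enumerate_specs(extra_std_sizes = c(300, 500, 1500))
  expect_true(all(c("STD 300", "STD 500", "STD 1500") %in% extra$selection))
  expect_false(any(extra$clustering == "mclust" & extra$selection == "STD 1500"))
  expect_true(any(extra$clustering == "mclust" & extra$selection == "STD 500"))
})

test_that("pairwise comparison counts follow the method registries", {
  counts <- pairwise_comparison_counts()
  expect_equal(unname(counts["selection"]), 78)
  expect_equal(unname(counts["clustering"]), 55)
  expect_equal(unname(counts["normalization"]), 10)
  expect_equal(unname(pairwise_comparison_counts(list(x = 4))["x"]), 6)
})

test_that("the grid runner produces one reproducible record per spec", {
  ex <- small_experiment(seed = 41, n_per_class = c(10, 10), n_genes = 200,
                         n_de = 40)
  specs <- enumerate_specs(reduced = TRUE)
  specs <- specs[specs$selection %in% c("STD 100", "PC 15") &
                   specs$normalization %in% c("norm.glob", "norm.pt") &
                   specs$imputation == "ROW", ]
  rt <- run_grid(list(sim1 = ex), specs, seed = 7)
  expect_equal(nrow(rt), nrow(specs))
  expect_true(all(rt$status == "ok"))
  expect_true(all(rt$arand >= -1 & rt$arand <= 1))
  rt2 <- run_grid(list(sim1 = ex), specs, seed = 7)
  expect_identical(rt, rt2)
  # caching reuses upstream stages without changing results: recompute one
  # spec through the single-pipeline path
  i <- which(rt$clustering == "hclust.eucl.ward" &
               rt$selection == "STD 100" & !rt$standardization &
               rt$normalization == "norm.glob")[1]
  pp <- preprocess_scans(ex$scans, ex$true_labels, "norm.glob", "ROW")
  f <- select_features(pp$matrix, "STD", 100)
  part <- cluster_samples(f, "hclust.eucl.ward")
  expect_equal(rt$arand[i], optimal_merge(part, pp$labels)$arand)
})

test_that("failures are recorded as rows, not crashes", {
  ex <- small_experiment(seed = 42, n_per_class = c(6, 6), n_genes = 550,
                         n_de = 40, duplicate_fraction = 0)
  specs <- enumerate_specs()
  # force an invalid combination: mclust with > 500 features
  sp <- specs[specs$clustering == "mclust" & specs$selection == "PC 15" &
                specs$normalization == "no.norm" &
                specs$imputation == "ROW" & !specs$standardization, ]
  sp$selection <- "NONE"; sp$sel_method <- "NONE"; sp$sel_n <- NA_integer_
  rt <- run_grid(list(d = ex), sp, seed = 1)
  expect_equal(nrow(rt), 1)
  expect_true(is.na(rt$arand))
  expect_match(rt$status, "500")
})

test_that("variance decomposition attributes a planted effect", {
  rt <- fake_result_table(effects = list(selection = list(`STD 100` = 0.4)),
                          noise_sd = 0.03, seed = 8)
  vd <- variance_decomposition(rt)
  expect_equal(sum(vd$percent), 100, tolerance = 1e-6)
  non_resid <- vd[vd$term != "Residuals", ]
  sel_share <- sum(non_resid$percent[non_resid$term == "selection"])
  expect_gt(sel_share / sum(non_resid$percent), 0.9)
  expect_true(vd$significant[vd$term == "selection"])
  # interactions of order two are present
  expect_true(any(grepl(":", vd$term)))
})

test_that("a uniformly dominated method is eliminated with its superior named", {
  rt <- fake_result_table(
    effects = list(clustering = list(kmeans = -0.2)),
    noise_sd = 0.02, seed = 9)
  out <- eliminate_methods(rt)
  expect_true("kmeans" %in% out$trace$removed)
  sup <- out$trace$superior[out$trace$removed == "kmeans"]
  expect_true(sup %in% setdiff(unique(rt$clustering), "kmeans"))
  expect_false("kmeans" %in% out$surviving$clustering)
  expect_false(any(out$results$clustering == "kmeans"))
  expect_true(all(out$trace$p_corrected < 0.001))
  # every sub-process retains at least one method
  expect_true(all(lengths(out$surviving) >= 1))
  # termination bound: strictly fewer iterations than methods
  total_methods <- length(unique(rt$normalization)) +
    length(unique(rt$selection)) + length(unique(rt$clustering))
  expect_lte(nrow(out$trace), total_methods - 3)
})

test_that("exchangeable methods yield no removal", {
  rt <- fake_result_table(noise_sd = 0.05, seed = 10)
  out <- eliminate_methods(rt)
  expect_equal(nrow(out$trace), 0)
  expect_setequal(out$surviving$clustering, unique(rt$clustering))
})

test_that("summaries average over datasets per parameter combination", {
  rt <- fake_result_table(datasets = c("d1", "d2"), noise_sd = 0, seed = 11)
  rt$arand <- ifelse(rt$dataset == "d1", 0.2, 0.4)
  s <- summarize_results(rt, by = "clustering")
  expect_true(all(abs(s$combinations$mean_arand - 0.3) < 1e-12))
  expect_equal(sum(s$combinations$n_datasets), nrow(rt))
  expect_equal(nrow(s$summary), length(unique(rt$clustering)))
  expect_equal(s$summary$mean, rep(0.3, nrow(s$summary)))
})
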