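#' Enumerate the factorial grid of analysis specifications
#'
#' Crosses the 5 normalizations, 2 imputations, 2 standardization settings,
#' the gene-selection registry and the 11 clustering methods, and drops the
#' invalid combinations (model-based clustering with more than 500 features,
#' i.e. with selections of 1000+ genes or no selection). The default
#' unsupervised grid has 2780 specifications; adding the supervised
#' selections contributes 1280 more.
#'
#' @param include_supervised Include T2/Mdiff selections?
#' @param reduced Restrict to the high-performing subset surviving the
#'   elimination procedure (4 normalizations, selections NONE/STD 100/
#'   STD 1000/PC 15, Ward hierarchical variants, k-means and Mclust): 288
#'   specifications.
#' @param extra_std_sizes Extra STD selection sizes, e.g.
#'   \code{c(300, 500, 1500)}.
#' @return Data frame with one row per valid specification: columns
#'   \code{normalization}, \code{imputation}, \code{standardization}
#'   (logical), \code{selection}, \code{sel_method}, \code{sel_n},
#'   \code{supervised}, \code{clustering}.
#' @export
enumerate_specs <- function(include_supervised = FALSE, reduced = FALSE,
                            extra_std_sizes = integer(0)) {
  sel <- selection_registry(include_supervised, extra_std_sizes)
  norms <- normalization_methods()
  methods <- clustering_methods()
  if (reduced) {
    norms <- c("norm.pt", "norm.pt.bkg", "norm.glob", "norm.glob.bkg")
    sel <- sel[sel$selection %in% c("NONE", "STD 100", "STD 1000", "PC 15"), ]
    methods <- c("hclust.corr.ward", "hclust.eucl.ward", "hclust.manh.ward",
                 "kmeans", "mclust")
  }
  grid <- expand.grid(normalization = norms,
                      imputation = c("ROW", "SVD"),
                      standardization = c(FALSE, TRUE),
                      selection = sel$selection,
                      clustering = methods,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, sel, by = "selection", sort = FALSE)
  valid <- !(grid$clustering == "mclust" &
               (grid$sel_method == "NONE" |
                  (!is.na(grid$sel_n) & grid$sel_method != "PC" &
                     grid$sel_n > mclust_max_features())))
  grid <- grid[valid, c("normalization", "imputation", "standardization",
                        "selection", "sel_method", "sel_n", "supervised",
                        "clustering")]
  grid <- grid[order(grid$normalization, grid$imputation,
                     grid$standardization, grid$selection, grid$clustering), ]
  rownames(grid) <- NULL
  grid
}

#' Run a grid of cluster analyses over one or more datasets
#'
#' Executes every (dataset, specification) combination: normalize the scans,
#' assemble and filter the M-value matrix, impute, collapse duplicates, drop
#' unlabeled samples, select features, optionally standardize, cluster into
#' \code{n_clusters} groups and score the partition against the true classes
#' by the merge-optimized adjusted Rand index. Upstream stages shared between
#' specifications (same normalization, same normalization+imputation, same
#' selection) are computed once and reused; caching does not change any
#' numeric result.
#'
#' @param datasets Named list; each element a list with \code{scans} (list of
#'   \code{array_scan}) and \code{labels} (named sample_id -> class vector).
#'   A \code{sim_experiment} is also accepted.
#' @param specs Specification data frame from \code{\link{enumerate_specs}}.
#' @param n_clusters Clusters to predict before merging (default 10).
#' @param seed Master seed; a per-run seed is derived deterministically from
#'   it, the dataset index and the specification row.
#' @param nu0,window Moderated-variance hyperparameters for T1/T2.
#' @return A result table: one row per (dataset, spec) with the spec columns,
#'   \code{dataset}, \code{arand} (NA if the run failed) and \code{status}
#'   (\code{"ok"} or the failure reason). Failures never abort the grid.
#' @export
run_grid <- function(datasets, specs = enumerate_specs(), n_clusters = 10,
                     seed = 1, nu0 = 10, window = 101) {
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  out <- vector("list", length(datasets))
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    if (inherits(ds, "sim_experiment"))
      ds <- list(scans = ds$scans, labels = ds$true_labels)
    lab_map <- stats::setNames(as.character(ds$labels), names(ds$labels))
    rows <- specs
    rows$dataset <- names(datasets)[di]
    rows$arand <- NA_real_
    rows$status <- NA_character_
    for (norm in unique(specs$normalization)) {
      base <- tryCatch({
        ma <- lapply(ds$scans, apply_normalization, method = norm)
        filter_matrix(assemble_matrix(ma))
      }, error = function(e) e)
      i_norm <- which(rows$normalization == norm)
      if (inherits(base, "error")) {
        rows$status[i_norm] <- conditionMessage(base)
        next
      }
      for (imp in unique(specs$imputation[i_norm])) {
        prepped <- tryCatch({
          m <- if (imp == "ROW") impute_row(base)
               else suppressWarnings(impute_svd(base))
          drop_unlabeled(collapse_duplicates(m), lab_map)
        }, error = function(e) e)
        i_imp <- i_norm[rows$imputation[i_norm] == imp]
        if (inherits(prepped, "error")) {
          rows$status[i_imp] <- conditionMessage(prepped)
          next
        }
        sel_keys <- unique(rows$selection[i_imp])
        for (sel_key in sel_keys) {
          i_sel <- i_imp[rows$selection[i_imp] == sel_key]
          srow <- rows[i_sel[1], ]
          feats <- tryCatch(
            select_features(prepped$matrix, srow$sel_method, srow$sel_n,
                            labels = prepped$labels, nu0 = nu0,
                            window = window),
            error = function(e) e)
          if (inherits(feats, "error")) {
            rows$status[i_sel] <- conditionMessage(feats)
            next
          }
          for (std in unique(rows$standardization[i_sel])) {
            i_std <- i_sel[rows$standardization[i_sel] == std]
            f <- tryCatch(suppressWarnings(standardize_features(feats, std)),
                          error = function(e) e)
            if (inherits(f, "error")) {
              rows$status[i_std] <- conditionMessage(f)
              next
            }
            for (ri in i_std) {
              run_seed <- (seed + 7919 * di + ri * 104729) %% 2147483629L
              res <- tryCatch({
                part <- cluster_samples(f, rows$clustering[ri],
                                        n_clusters = n_clusters,
                                        seed = run_seed)
                optimal_merge(part, prepped$labels)$arand
              }, error = function(e) e)
              if (inherits(res, "error")) {
                rows$status[ri] <- conditionMessage(res)
              } else {
                rows$arand[ri] <- res
                rows$status[ri] <- "ok"
              }
            }
          }
        }
      }
    }
    out[[di]] <- rows
  }
  rt <- do.call(rbind, out)
  rownames(rt) <- NULL
  rt[, c("dataset", "normalization", "imputation", "standardization",
         "selection", "sel_method", "sel_n", "supervised", "clustering",
         "arand", "status")]
}

#' Decompose adjusted-Rand variance by sub-process
#'
#' Fits a linear model of the adjusted Rand on the categorical sub-process
#' factors (dataset, normalization, standardization, imputation, gene
#' selection with size, clustering method) including all second-order
#' interactions, and reports each term's share of the total sum of squares
#' from the sequential (Type I) analysis-of-variance table.
#'
#' @param rt Result table from \code{\link{run_grid}} (rows with missing
#'   \code{arand} are dropped).
#' @param p_cut Significance threshold (default 0.001).
#' @param order Canonical factor order for the sequential decomposition.
#' @return Data frame with \code{term}, \code{df}, \code{ss}, \code{percent}
#'   (of total SS; sums to 100) , \code{p} and \code{significant}. Factors
#'   with fewer than 2 observed levels are omitted from the model;
#'   inestimable interaction cells are dropped by the fit itself.
#' @export
variance_decomposition <- function(rt, p_cut = 0.001,
                                   order = c("dataset", "normalization",
                                             "standardization", "imputation",
                                             "selection", "clustering")) {
  rt <- rt[!is.na(rt$arand), , drop = FALSE]
  if (nrow(rt) == 0) stop("no successful runs in the result table")
  factors <- order[vapply(order, function(f)
    length(unique(rt[[f]])) >= 2, logical(1))]
  if (length(factors) == 0) stop("no factor has 2 or more levels")
  for (f in factors) rt[[f]] <- factor(as.character(rt[[f]]))
  form <- stats::as.formula(paste("arand ~ (",
                                  paste(factors, collapse = " + "), ")^2"))
  fit <- stats::lm(form, data = rt)
  av <- stats::anova(fit)
  total_ss <- sum(av$`Sum Sq`)
  data.frame(term = rownames(av),
             df = av$Df,
             ss = av$`Sum Sq`,
             percent = 100 * av$`Sum Sq` / total_ss,
             p = av$`Pr(>F)`,
             significant = !is.na(av$`Pr(>F)`) & av$`Pr(>F)` < p_cut,
             row.names = NULL)
}

#' Iterative pairwise-Wilcoxon elimination of inferior methods
#'
#' Within each listed sub-process, every pair of surviving methods is
#' compared by a two-sided Wilcoxon signed-rank test on adjusted-Rand values
#' paired on identical settings of everything else (dataset plus all other
#' sub-process choices), restricted to settings where both methods produced
#' a result. P-values are Bonferroni-corrected by the number of tests in the
#' current iteration; if the smallest corrected p-value falls below
#' \code{alpha}, the pair's least favorable method (lower median of the
#' paired values) is removed together with all its analyses, and the
#' procedure repeats until no more removals are made.
#'
#' @param rt Result table from \code{\link{run_grid}}.
#' @param subprocesses Columns treated as sub-processes (default
#'   normalization, gene selection and clustering method).
#' @param alpha Corrected-p threshold for removal (default 0.001).
#' @param cumulative_bonferroni Use the cumulative number of tests over all
#'   iterations as the correction factor instead of the per-iteration count.
#' @return List with \code{trace} (data frame: \code{iteration},
#'   \code{subprocess}, \code{removed}, \code{p_corrected},
#'   \code{superior}), \code{surviving} (named list of surviving method sets
#'   per sub-process), \code{results} (the surviving rows of \code{rt}) and
#'   \code{notes} (pairs skipped for lack of common settings).
#' @export
eliminate_methods <- function(rt,
                              subprocesses = c("normalization", "selection",
                                               "clustering"),
                              alpha = 0.001,
                              cumulative_bonferroni = FALSE) {
  keep <- !is.na(rt$arand)
  rt <- rt[keep, , drop = FALSE]
  all_cols <- c("dataset", "normalization", "imputation", "standardization",
                "selection", "clustering")
  trace <- list()
  notes <- character(0)
  n_tests_total <- 0
  iteration <- 0
  repeat {
    iteration <- iteration + 1
    tests <- list()
    for (sp in subprocesses) {
      levels_sp <- sort(unique(rt[[sp]]))
      if (length(levels_sp) < 2) next
      key_cols <- setdiff(all_cols, sp)
      for (i in seq_len(length(levels_sp) - 1)) {
        for (j in seq((i + 1), length(levels_sp))) {
          x <- levels_sp[i]; y <- levels_sp[j]
          rx <- rt[rt[[sp]] == x, c(key_cols, "arand")]
          ry <- rt[rt[[sp]] == y, c(key_cols, "arand")]
          mm <- merge(rx, ry, by = key_cols, suffixes = c("_x", "_y"))
          if (nrow(mm) < 1 || all(mm$arand_x == mm$arand_y)) {
            notes <- c(notes, sprintf(
              "%s: pair (%s, %s) skipped (no informative common settings)",
              sp, x, y))
            next
          }
          p <- suppressWarnings(stats::wilcox.test(
            mm$arand_x, mm$arand_y, paired = TRUE, exact = FALSE)$p.value)
          if (is.na(p)) next
          tests[[length(tests) + 1]] <- list(
            sp = sp, x = x, y = y, p = p,
            med_x = stats::median(mm$arand_x),
            med_y = stats::median(mm$arand_y))
        }
      }
    }
    if (length(tests) == 0) break
    n_tests_total <- n_tests_total + length(tests)
    bonf <- if (cumulative_bonferroni) n_tests_total else length(tests)
    pvals <- vapply(tests, `[[`, numeric(1), "p") * bonf
    best <- which.min(pvals)
    if (pvals[best] >= alpha) break
    t0 <- tests[[best]]
    loser <- if (t0$med_x <= t0$med_y) t0$x else t0$y
    winner <- if (identical(loser, t0$x)) t0$y else t0$x
    trace[[length(trace) + 1]] <- data.frame(
      iteration = iteration, subprocess = t0$sp, removed = loser,
      p_corrected = pvals[best], superior = winner)
    rt <- rt[rt[[t0$sp]] != loser, , drop = FALSE]
  }
  surviving <- lapply(stats::setNames(subprocesses, subprocesses),
                      function(sp) sort(unique(rt[[sp]])))
  trace_df <- if (length(trace)) do.call(rbind, trace)
  else data.frame(iteration = integer(0), subprocess = character(0),
                  removed = character(0), p_corrected = numeric(0),
                  superior = character(0))
  list(trace = trace_df, surviving = surviving, results = rt, notes = notes)
}

#' Pairwise comparison counts per sub-process
#'
#' @param method_sets Named list of method vectors (or counts).
#' @return Named integer vector of \code{choose(m, 2)} per sub-process; with
#'   the full registries this gives 78 (13 gene selections), 55 (11
#'   clustering methods) and 10 (5 normalizations).
#' @export
pairwise_comparison_counts <- function(method_sets = list(
  selection = selection_registry()$selection,
  clustering = clustering_methods(),
  normalization = normalization_methods())) {
  vapply(method_sets, function(ms) {
    m <- if (is.numeric(ms) && length(ms) == 1) ms else length(ms)
    choose(m, 2)
  }, numeric(1))
}

#' Summarize a result table by sub-process
#'
#' Averages the adjusted Rand over datasets for every parameter combination
#' and summarizes the distribution of those means per level of one
#' sub-process.
#'
#' @param rt Result table from \code{\link{run_grid}}.
#' @param by Sub-process column to group by (default \code{"selection"}).
#' @return List with \code{combinations} (one row per parameter combination
#'   with its dataset-mean aRand and the number of datasets averaged) and
#'   \code{summary} (per level of \code{by}: n, mean, median, quartiles).
#' @export
summarize_results <- function(rt, by = "selection") {
  stopifnot(by %in% names(rt))
  ok <- rt[!is.na(rt$arand), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful runs to summarize")
  spec_cols <- c("normalization", "imputation", "standardization",
                 "selection", "clustering")
  key <- interaction(ok[spec_cols], drop = TRUE)
  combos <- do.call(rbind, lapply(split(ok, key), function(d) {
    cbind(d[1, spec_cols, drop = FALSE],
          data.frame(mean_arand = mean(d$arand), n_datasets = nrow(d)))
  }))
  rownames(combos) <- NULL
  summ <- do.call(rbind, lapply(split(combos, combos[[by]]), function(d)
    data.frame(level = as.character(d[[by]][1]), n = nrow(d),
               mean = mean(d$mean_arand),
               median = stats::median(d$mean_arand),
               q25 = as.numeric(stats::quantile(d$mean_arand, 0.25)),
               q75 = as.numeric(stats::quantile(d$mean_arand, 0.75)))))
  rownames(summ) <- NULL
  list(combinations = combos, summary = summ)
}
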