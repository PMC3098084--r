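#' Pair counts underlying the Rand index
#'
#' Classifies all \eqn{n(n-1)/2} object pairs by whether they are placed
#' together or apart in two partitions of the same \code{n} objects.
#'
#' @param p,q Cluster label vectors of equal length (any atomic type;
#'   labels are used only for grouping).
#' @return A list with components \code{a} (together in both), \code{b}
#'   (apart in both), \code{c} (together in \code{p}, apart in \code{q}) and
#'   \code{d} (apart in \code{p}, together in \code{q}).
#' @details Computed from the \eqn{s \times t} contingency table of the two
#'   partitions, so the cost is \eqn{O(st)} rather than \eqn{O(n^2)}.
#' @examples
#' pair_counts(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
pair_counts <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 2)
  n <- length(p)
  tab <- table(p, q)
  choose2 <- function(x) x * (x - 1) / 2
  a <- sum(choose2(tab))
  sp <- sum(choose2(rowSums(tab)))   # together in p
  sq <- sum(choose2(colSums(tab)))   # together in q
  cc <- sp - a
  d <- sq - a
  b <- choose2(n) - a - cc - d
  list(a = a, b = b, c = cc, d = d)
}

#' Rand index
#'
#' Fraction of object pairs on which two partitions agree (together in both
#' or apart in both).
#'
#' @inheritParams pair_counts
#' @return A number in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 1/3
#' @export
rand_index <- function(p, q) {
  pc <- pair_counts(p, q)
  (pc$a + pc$b) / (pc$a + pc$b + pc$c + pc$d)
}

#' Adjusted Rand index
#'
#' The Rand index centered at its expectation under the permutation null and
#' rescaled so that identical partitions score 1 (Hubert-Arabie form).
#' Negative values indicate worse-than-chance agreement.
#'
#' @inheritParams pair_counts
#' @return A number in \[-1, 1\]. When the index is degenerate (both
#'   partitions all-singletons or both one single group, so the denominator
#'   vanishes) the value is defined as 1 if the partitions are identical up
#'   to relabeling and 0 otherwise.
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 2)
  tab <- table(p, q)
  adjusted_rand_table(tab)
}

# Hubert-Arabie aRand from a contingency table (matrix of joint counts).
adjusted_rand_table <- function(tab) {
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  denom <- (sum_i + sum_j) / 2 - expected
  if (abs(denom) < .Machine$double.eps * 4) {
    # degenerate: all-singletons vs all-singletons, or one group vs one group
    return(if (isTRUE(all.equal(sum_ij, sum_i)) && isTRUE(all.equal(sum_i, sum_j)) &&
               nrow(tab) == ncol(tab)) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Optimally merge a partition into two groups and score it
#'
#' Emulates a visual inspection of a dendrogram: a clustering into
#' \code{c >= 2} clusters is reduced to a bipartition by exhaustively joining
#' clusters into two non-empty groups and keeping the join that maximizes the
#' adjusted Rand index against the true two-class partition.
#'
#' @param predicted Cluster label vector (the partition to merge).
#' @param truth True class label vector of the same length.
#' @return A list with \code{arand} (the maximal adjusted Rand), \code{merged}
#'   (integer vector of merged labels in \{1, 2\}) and \code{group1}
#'   (the predicted cluster labels joined into group 1).
#' @details All \eqn{2^{c-1} - 1} bipartitions of the \code{c} non-empty
#'   cluster labels are scored on the collapsed contingency table. Ties are
#'   broken by the lexicographically smallest set of cluster labels in group
#'   one. With ten predicted clusters the search covers 511 candidates.
#' @examples
#' optimal_merge(predicted = c(1, 1, 2, 2, 3, 3),
#'               truth     = c(1, 1, 1, 2, 2, 2))
#' @export
optimal_merge <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  labs <- sort(unique(predicted))
  c_n <- length(labs)
  if (c_n < 2) stop("optimal_merge requires at least 2 non-empty clusters")
  tab <- table(factor(predicted, levels = labs), truth)
  tab <- matrix(as.numeric(tab), nrow = c_n,
                dimnames = list(as.character(labs), colnames(tab)))
  masks <- bipartition_masks(c_n)          # (2^(c-1) - 1) x c 0/1 matrix
  scores <- arand_bipartitions(masks, tab)
  best <- max(scores)
  ties <- which(scores >= best - 1e-12)
  pick <- if (length(ties) == 1L) ties else ties[lex_min_index(masks[ties, , drop = FALSE])]
  in1 <- masks[pick, ] == 1
  merged <- ifelse(predicted %in% labs[in1], 1L, 2L)
  list(arand = scores[pick], merged = merged, group1 = labs[in1])
}

# All bipartitions of c labels with label 1 fixed in group 1 and a non-empty
# complement: rows are 0/1 membership indicators for group 1.
bipartition_masks <- function(c_n) {
  n_masks <- 2^(c_n - 1) - 1
  m <- matrix(0L, nrow = n_masks, ncol = c_n)
  m[, 1] <- 1L
  if (c_n > 1) {
    for (j in seq_len(c_n - 1)) {
      # bit j of (mask index - 1) controls membership of label j+1
      m[, j + 1] <- bitwAnd((seq_len(n_masks) - 1L), bitwShiftL(1L, j - 1L)) > 0
    }
  }
  m
}

# Vectorized adjusted Rand of every bipartition (rows of `masks`) of the
# clusters of `tab` (clusters x classes contingency table) against the classes.
arand_bipartitions <- function(masks, tab) {
  g1 <- masks %*% tab                        # n_masks x t
  g2 <- matrix(colSums(tab), nrow = nrow(masks), ncol = ncol(tab), byrow = TRUE) - g1
  ch2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sum_ij <- rowSums(ch2(g1)) + rowSums(ch2(g2))
  sum_i <- ch2(rowSums(g1)) + ch2(rowSums(g2))
  sum_j <- sum(ch2(colSums(tab)))
  expected <- sum_i * sum_j / ch2(n)
  denom <- (sum_i + sum_j) / 2 - expected
  out <- ifelse(abs(denom) < .Machine$double.eps * 4, 0, (sum_ij - expected) / denom)
  as.numeric(out)
}

# Index of the row whose set {j : row[j] == 1} is lexicographically smallest.
lex_min_index <- function(mask_rows) {
  keys <- apply(mask_rows, 1, function(r) paste(sprintf("%03d", which(r == 1)), collapse = ","))
  order(keys)[1]
}

#' Null distribution of the merged adjusted Rand
#'
#' Because the merge step optimizes the adjusted Rand over bipartitions, its
#' chance expectation is positive. This simulates that null: samples are
#' assigned independently and uniformly to \code{n_clusters} labels, merged
#' optimally against the fixed true classes, and scored.
#'
#' @param truth True class label vector.
#' @param n_clusters Number of random cluster labels (default 10).
#' @param reps Number of random partitions (default 1000).
#' @param seed Integer seed; the simulation is reproducible from it.
#' @return A list with \code{samples} (vector of length \code{reps}),
#'   \code{median} and \code{q95} (the 95th percentile).
#' @export
null_distribution <- function(truth, n_clusters = 10, reps = 1000, seed = 1) {
  stopifnot(reps >= 1, n_clusters >= 2, length(truth) >= 2)
  n <- length(truth)
  samples <- withr_seed(seed, {
    vapply(seq_len(reps), function(i) {
      part <- sample.int(n_clusters, n, replace = TRUE)
      if (length(unique(part)) < 2) part[1] <- if (part[1] == 1L) 2L else 1L
      optimal_merge(part, truth)$arand
    }, numeric(1))
  })
  list(samples = samples,
       median = stats::median(samples),
       q95 = as.numeric(stats::quantile(samples, 0.95)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
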