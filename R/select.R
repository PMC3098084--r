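#' Per-gene scores for gene selection
#'
#' Unsupervised scores: \code{score_std} is the sample standard deviation of
#' each gene's M values (denominator n-1); \code{score_m} is the absolute
#' mean M, natural under a common-reference design where a class-separating
#' gene is regulated against the reference in one class only; \code{score_t1}
#' is the one-group moderated t statistic
#' \eqn{t_1 = |\bar M| / \sqrt{\sigma^2_{modif}/n}}.
#' Supervised scores (used only as a positive control): \code{score_t2} is
#' the two-group moderated t statistic
#' \eqn{t_2 = |\bar M_A - \bar M_B| / \sqrt{\sigma^2_{A,modif}/n_A +
#' \sigma^2_{B,modif}/n_B}} and \code{score_mdiff} the absolute between-class
#' mean difference \eqn{|\bar M_A - \bar M_B|}.
#'
#' @param m An imputed \code{mvmatrix}.
#' @param labels Factor with two levels (supervised scores only).
#' @param nu0,window Moderated-variance hyperparameters, see
#'   \code{\link{moderated_variance}}.
#' @return Named numeric vector of per-gene scores.
#' @name gene_scores
NULL

#' @rdname gene_scores
#' @export
score_std <- function(m) {
  check_imputed(m)
  stats::setNames(apply(m$values, 1, stats::sd), m$gene_ids)
}

#' @rdname gene_scores
#' @export
score_m <- function(m) {
  check_imputed(m)
  stats::setNames(abs(rowMeans(m$values)), m$gene_ids)
}

#' @rdname gene_scores
#' @export
score_t1 <- function(m, nu0 = 10, window = 101) {
  check_imputed(m)
  n <- ncol(m$values)
  if (n < 2) stop("score_t1 requires at least 2 samples")
  v <- moderated_variance(m$values, nu0 = nu0, window = window)
  num <- abs(rowMeans(m$values))
  t1 <- num / sqrt(v / n)
  t1[num == 0] <- 0   # a zero numerator dominates a zero variance
  stats::setNames(t1, m$gene_ids)
}

#' @rdname gene_scores
#' @export
score_t2 <- function(m, labels, nu0 = 10, window = 101) {
  check_imputed(m)
  labels <- check_two_classes(m, labels, min_per_class = 2)
  parts <- lapply(levels(labels), function(l)
    m$values[, labels == l, drop = FALSE])
  vs <- lapply(parts, moderated_variance, nu0 = nu0, window = window)
  ns <- vapply(parts, ncol, integer(1))
  num <- abs(rowMeans(parts[[1]]) - rowMeans(parts[[2]]))
  t2 <- num / sqrt(vs[[1]] / ns[1] + vs[[2]] / ns[2])
  t2[num == 0] <- 0   # a zero numerator dominates a zero variance
  stats::setNames(t2, m$gene_ids)
}

#' @rdname gene_scores
#' @export
score_mdiff <- function(m, labels) {
  check_imputed(m)
  labels <- check_two_classes(m, labels, min_per_class = 1)
  a <- rowMeans(m$values[, labels == levels(labels)[1], drop = FALSE])
  b <- rowMeans(m$values[, labels == levels(labels)[2], drop = FALSE])
  stats::setNames(abs(a - b), m$gene_ids)
}

check_imputed <- function(m) {
  stopifnot(inherits(m, "mvmatrix"))
  if (any(m$missing)) stop("gene selection requires an imputed matrix")
  invisible(m)
}

check_two_classes <- function(m, labels, min_per_class) {
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(m$values))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2)
    stop("supervised selection requires exactly 2 classes")
  if (any(table(labels) < min_per_class))
    stop(sprintf("each class needs at least %d samples", min_per_class))
  labels
}

#' Moderated (regularized) per-gene variance
#'
#' Shrinks each gene's sample variance toward a prior variance estimated from
#' genes of similar mean expression:
#' \deqn{\sigma^2_{modif} = \frac{\nu_0 \sigma_0^2 + (n-1) s^2}{\nu_0 + n - 2},}
#' where \eqn{s^2} is the gene's sample variance and \eqn{\sigma_0^2} the mean
#' sample variance of the \code{window} genes nearest in rank of mean M
#' (\code{window = "global"} uses the mean variance of all genes instead).
#' \code{nu0 = 0} recovers the plain sample variance exactly; the prior
#' stabilizes t statistics for small n and rescues zero-variance genes.
#'
#' @param values Genes x samples numeric matrix.
#' @param nu0 Prior strength in pseudo-observations (default 10).
#' @param window Odd neighbor count >= 3, or \code{"global"}.
#' @return Numeric vector of moderated variances, one per gene.
#' @export
moderated_variance <- function(values, nu0 = 10, window = 101) {
  stopifnot(is.matrix(values), nu0 >= 0)
  n <- ncol(values)
  if (n < 2)
    stop("moderated_variance: need at least 2 observations per gene")
  s2 <- apply(values, 1, stats::var)
  # nu0 = 0 reduces to the plain sample variance (also for n = 2, where the
  # shrinkage denominator nu0 + n - 2 would vanish)
  if (nu0 == 0) return(s2)
  if (identical(window, "global")) {
    sigma0 <- rep(mean(s2), length(s2))
  } else {
    stopifnot(window >= 3, window %% 2 == 1)
    w <- min(window, length(s2))
    half <- (w - 1) %/% 2
    ord <- order(rowMeans(values))
    s2_sorted <- s2[ord]
    g <- length(s2)
    sigma0_sorted <- vapply(seq_len(g), function(i) {
      lo <- max(1, min(i - half, g - w + 1))
      mean(s2_sorted[lo:(lo + w - 1)])
    }, numeric(1))
    sigma0 <- numeric(g)
    sigma0[ord] <- sigma0_sorted
  }
  (nu0 * sigma0 + (n - 1) * s2) / (nu0 + n - 2)
}

#' Select the top-scoring genes as clustering features
#'
#' @param m An imputed \code{mvmatrix}.
#' @param scores Named per-gene score vector (higher is better).
#' @param n Number of genes to keep.
#' @return A samples x genes numeric matrix (a feature matrix), columns named
#'   by gene ID in score order. Ties at the cutoff are broken by ascending
#'   gene ID, so selections are nested as \code{n} grows.
#' @export
select_top <- function(m, scores, n) {
  check_imputed(m)
  stopifnot(length(scores) == nrow(m$values))
  if (n > nrow(m$values))
    stop(sprintf("cannot select %d genes from %d", n, nrow(m$values)))
  ord <- order(-scores, m$gene_ids)
  idx <- ord[seq_len(n)]
  f <- t(m$values[idx, , drop = FALSE])
  dimnames(f) <- list(m$sample_ids, m$gene_ids[idx])
  f
}

#' Project samples onto principal components (eigengenes)
#'
#' Genes are centered to mean 0 across samples and the samples are projected
#' onto the top-\code{k} principal axes of the centered matrix; the component
#' scores replace gene features in the clustering.
#'
#' @param m An imputed \code{mvmatrix}.
#' @param k Number of components, \code{k <= min(genes, samples)}.
#' @return A samples x k matrix of component scores, columns \code{PC1..PCk}
#'   ordered by decreasing explained variance. Each component's sign is fixed
#'   so that its largest-magnitude gene loading is positive.
#' @export
select_pc <- function(m, k) {
  check_imputed(m)
  if (k > min(dim(m$values)))
    stop(sprintf("k = %d exceeds min(genes, samples) = %d",
                 k, min(dim(m$values))))
  x <- t(m$values - rowMeans(m$values))       # samples x genes, genes centered
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    load <- sv$v[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k) %*% diag(flip, nrow = k)
  dimnames(scores) <- list(m$sample_ids, paste0("PC", seq_len(k)))
  scores
}

#' Z-standardize gene features
#'
#' Scales each gene (feature column) to mean 0 and standard deviation 1
#' across samples, giving every gene equal weight in the clustering; with
#' \code{on = FALSE} the matrix passes through unchanged. Applied after
#' normalization, imputation and gene selection.
#'
#' @param f Samples x features matrix.
#' @param on Standardize (TRUE) or pass through (FALSE)?
#' @return Matrix of the same shape. Constant features are mapped to all
#'   zeros with a warning.
#' @export
standardize_features <- function(f, on = TRUE) {
  stopifnot(is.matrix(f))
  if (!on) return(f)
  mu <- colMeans(f)
  sdv <- apply(f, 2, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("%d constant feature(s) standardized to all zeros",
                    sum(sdv == 0)))
    sdv[sdv == 0] <- Inf
  }
  scale(f, center = mu, scale = ifelse(is.finite(sdv), sdv, Inf))[, , drop = FALSE]
}

#' Registry of gene selections
#'
#' @param include_supervised Include the class-dependent selections T2 and
#'   Mdiff (positive controls)?
#' @param extra_std_sizes Additional STD sizes beyond \{15, 100, 1000\}
#'   (e.g. \code{c(300, 500, 1500)}).
#' @return Data frame with columns \code{selection} (label, e.g.
#'   \code{"STD 100"}), \code{sel_method}, \code{sel_n} (NA for NONE) and
#'   \code{supervised}. The default registry holds the 13 unsupervised
#'   selections: STD, M, T1 at 15/100/1000 genes, PC at 3/5/15 components,
#'   and NONE.
#' @export
selection_registry <- function(include_supervised = FALSE,
                               extra_std_sizes = integer(0)) {
  sizes <- c(15, 100, 1000)
  rows <- list()
  add <- function(method, n, supervised = FALSE) {
    label <- if (is.na(n)) method else paste(method, n)
    rows[[length(rows) + 1]] <<- data.frame(selection = label,
                                            sel_method = method, sel_n = n,
                                            supervised = supervised)
  }
  for (meth in c("STD", "M", "T1")) for (n in sizes) add(meth, n)
  if (length(extra_std_sizes)) for (n in sort(extra_std_sizes)) add("STD", n)
  for (k in c(3, 5, 15)) add("PC", k)
  add("NONE", NA_integer_)
  if (include_supervised)
    for (meth in c("T2", "Mdiff")) for (n in sizes) add(meth, n, TRUE)
  do.call(rbind, rows)
}

#' Compute clustering features for one gene selection
#'
#' Dispatches on the selection method, producing the samples x features
#' matrix handed to the clustering step.
#'
#' @param m An imputed \code{mvmatrix}.
#' @param method One of \code{STD}, \code{M}, \code{T1}, \code{T2},
#'   \code{Mdiff}, \code{PC}, \code{NONE}.
#' @param n Gene count (or component count for PC); ignored for NONE.
#' @param labels Class factor, required for the supervised methods.
#' @param nu0,window Moderated-variance hyperparameters for T1/T2.
#' @return Samples x features matrix.
#' @export
select_features <- function(m, method, n = NA, labels = NULL,
                            nu0 = 10, window = 101) {
  switch(method,
         STD = select_top(m, score_std(m), n),
         M = select_top(m, score_m(m), n),
         T1 = select_top(m, score_t1(m, nu0, window), n),
         T2 = select_top(m, score_t2(m, labels, nu0, window), n),
         Mdiff = select_top(m, score_mdiff(m, labels), n),
         PC = select_pc(m, n),
         NONE = {
           f <- t(m$values)
           dimnames(f) <- list(m$sample_ids, m$gene_ids)
           f
         },
         stop(sprintf("unknown selection method '%s'", method)))
}
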