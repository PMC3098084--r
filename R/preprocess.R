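#' Assemble per-sample M values into a genes x samples matrix
#'
#' @param ma_list List of \code{ma_spots} (one per sample), all sharing one
#'   spot layout (same gene IDs in the same order).
#' @param sample_ids Optional sample identifiers; defaults to those stored in
#'   the \code{ma_spots}.
#' @return An object of class \code{mvmatrix}: list with \code{values}
#'   (spots x samples numeric matrix, NA where missing), \code{missing}
#'   (logical matrix), \code{gene_ids}, \code{sample_ids}. One row per spot;
#'   duplicate spots are collapsed later by \code{\link{collapse_duplicates}}.
#' @export
assemble_matrix <- function(ma_list, sample_ids = NULL) {
  if (length(ma_list) == 0) stop("no samples to assemble")
  ref_ids <- ma_list[[1]]$gene_id
  for (i in seq_along(ma_list)) {
    if (!identical(ma_list[[i]]$gene_id, ref_ids))
      stop(sprintf("spot layout of sample '%s' differs from sample '%s'",
                   ma_list[[i]]$sample_id, ma_list[[1]]$sample_id))
  }
  if (is.null(sample_ids))
    sample_ids <- vapply(ma_list, `[[`, character(1), "sample_id")
  values <- vapply(ma_list, `[[`, numeric(length(ref_ids)), "M")
  missing <- vapply(ma_list, `[[`, logical(length(ref_ids)), "missing")
  dimnames(values) <- dimnames(missing) <- list(NULL, sample_ids)
  mvmatrix(values, missing, ref_ids, sample_ids)
}

mvmatrix <- function(values, missing, gene_ids, sample_ids) {
  stopifnot(all(dim(values) == dim(missing)),
            nrow(values) == length(gene_ids),
            ncol(values) == length(sample_ids))
  dimnames(values) <- dimnames(missing) <- list(NULL, as.character(sample_ids))
  structure(list(values = values, missing = missing,
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "mvmatrix")
}

#' @export
print.mvmatrix <- function(x, ...) {
  cat(sprintf("mvmatrix: %d genes x %d samples, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing)))
  invisible(x)
}

#' Filter genes and samples by missing-value fraction
#'
#' Keeps the samples with less than \code{max_sample_missing} missing values
#' and the genes with less than \code{max_gene_missing} missing values. Both
#' criteria are evaluated on the input mask in a single simultaneous pass:
#' removing a bad sample never changes which genes are kept. The strict
#' \code{<} comparison means a sample missing exactly 50\% of its values is
#' removed.
#'
#' @param m An \code{mvmatrix}.
#' @param max_sample_missing,max_gene_missing Fraction thresholds in (0, 1].
#' @param iterate If \code{TRUE}, re-apply the pass until a fixed point
#'   (non-default variant).
#' @return The filtered \code{mvmatrix}.
#' @export
filter_matrix <- function(m, max_sample_missing = 0.5, max_gene_missing = 0.3,
                          iterate = FALSE) {
  stopifnot(inherits(m, "mvmatrix"),
            max_sample_missing > 0, max_sample_missing <= 1,
            max_gene_missing > 0, max_gene_missing <= 1)
  repeat {
    keep_s <- colMeans(m$missing) < max_sample_missing
    keep_g <- rowMeans(m$missing) < max_gene_missing
    if (!any(keep_s) || !any(keep_g))
      stop("filtration removed all samples or all genes")
    changed <- !all(keep_s) || !all(keep_g)
    m <- mvmatrix(m$values[keep_g, keep_s, drop = FALSE],
                  m$missing[keep_g, keep_s, drop = FALSE],
                  m$gene_ids[keep_g], m$sample_ids[keep_s])
    if (!iterate || !changed) return(m)
  }
}

#' Impute missing values by the gene (row) median
#'
#' @param m A filtered \code{mvmatrix}; every gene must have at least one
#'   observed value.
#' @return An \code{mvmatrix} with no missing values; observed cells are
#'   untouched.
#' @export
impute_row <- function(m) {
  stopifnot(inherits(m, "mvmatrix"))
  if (any(rowSums(!m$missing) == 0))
    stop("impute_row: some gene has no observed values (filter first)")
  v <- m$values
  for (i in which(rowSums(m$missing) > 0)) {
    miss <- m$missing[i, ]
    v[i, miss] <- stats::median(v[i, !miss])
  }
  mvmatrix(v, matrix(FALSE, nrow(v), ncol(v)), m$gene_ids, m$sample_ids)
}

#' Impute missing values by iterative SVD (eigengene regression)
#'
#' Estimates each missing value as a linear combination of the \code{k} most
#' significant eigengenes. Missing cells are initialized to 0; each round
#' computes the top-\code{k} right singular vectors of the completed matrix,
#' regresses every incomplete gene's observed values on the eigengenes
#' restricted to the observed positions, and re-estimates the gene's missing
#' cells from the fit. Iteration stops when the relative (Frobenius) change
#' of the completed matrix falls below \code{tol}.
#'
#' @param m A filtered \code{mvmatrix}.
#' @param k Number of eigengenes (default 10; capped at
#'   \code{min(dim) - 1}).
#' @param tol Relative-change stopping threshold (default 0.01).
#' @param max_iter Iteration cap (default 100); on hitting it, the last
#'   iterate is returned with a warning and the convergence trace still
#'   attached.
#' @return An \code{mvmatrix} with no missing values; attribute
#'   \code{svd_trace} records the relative change per iteration. Observed
#'   cells are bit-identical to the input.
#' @export
impute_svd <- function(m, k = 10, tol = 0.01, max_iter = 100) {
  stopifnot(inherits(m, "mvmatrix"), k >= 1, tol > 0, max_iter >= 1)
  miss <- m$missing
  if (!any(miss)) {
    out <- mvmatrix(m$values, matrix(FALSE, nrow(miss), ncol(miss)),
                    m$gene_ids, m$sample_ids)
    attr(out, "svd_trace") <- numeric(0)
    return(out)
  }
  if (any(rowSums(!miss) == 0))
    stop("impute_svd: some gene has no observed values (filter first)")
  k <- min(k, min(dim(m$values)) - 1)
  x <- m$values
  x[miss] <- 0
  incomplete <- which(rowSums(miss) > 0)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    sv <- svd(x, nu = 0, nv = k)
    eig <- sv$v[, seq_len(k), drop = FALSE]          # samples x k eigengenes
    x_new <- x
    for (i in incomplete) {
      obs <- !miss[i, ]
      xi <- m$values[i, obs]
      ei <- eig[obs, , drop = FALSE]
      beta <- tryCatch(qr.coef(qr(ei), xi), error = function(e) NULL)
      if (is.null(beta)) next
      beta[is.na(beta)] <- 0
      x_new[i, miss[i, ]] <- eig[miss[i, ], , drop = FALSE] %*% beta
    }
    rel <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x^2)), .Machine$double.eps)
    trace <- c(trace, rel)
    x <- x_new
    if (rel < tol) break
  }
  if (trace[length(trace)] >= tol)
    warning(sprintf("impute_svd: not converged after %d iterations (last relative change %.3g)",
                    max_iter, trace[length(trace)]))
  x[!miss] <- m$values[!miss]   # observed cells stay bit-identical
  out <- mvmatrix(x, matrix(FALSE, nrow(x), ncol(x)), m$gene_ids, m$sample_ids)
  attr(out, "svd_trace") <- trace
  out
}

#' Average duplicate spots of the same gene
#'
#' Rows sharing a gene ID are replaced by their column-wise mean, keeping
#' first-occurrence row order. Requires an imputed (complete) matrix.
#'
#' @param m An \code{mvmatrix} without missing values.
#' @return An \code{mvmatrix} with unique gene IDs.
#' @export
collapse_duplicates <- function(m) {
  stopifnot(inherits(m, "mvmatrix"))
  if (any(m$missing)) stop("collapse_duplicates requires an imputed matrix")
  if (!anyDuplicated(m$gene_ids)) return(m)
  f <- factor(m$gene_ids, levels = unique(m$gene_ids))
  v <- rowsum(m$values, f, reorder = FALSE) / as.vector(table(f))
  mvmatrix(v, matrix(FALSE, nrow(v), ncol(v)), levels(f), m$sample_ids)
}

#' Remove samples without a class label
#'
#' @param m An \code{mvmatrix}.
#' @param labels Named vector mapping sample_id to class (samples absent from
#'   the mapping are unlabeled).
#' @return List with the reduced \code{mvmatrix} (\code{matrix}) and the
#'   class factor aligned to its samples (\code{labels}); original sample
#'   order is preserved.
#' @export
drop_unlabeled <- function(m, labels) {
  stopifnot(inherits(m, "mvmatrix"))
  keep <- m$sample_ids %in% names(labels)
  if (!any(keep)) stop("no labeled samples remain")
  lab <- factor(unname(labels[m$sample_ids[keep]]))
  if (nlevels(lab) < 2)
    stop("fewer than 2 labeled classes remain after dropping unlabeled samples")
  out <- mvmatrix(m$values[, keep, drop = FALSE],
                  m$missing[, keep, drop = FALSE],
                  m$gene_ids, m$sample_ids[keep])
  list(matrix = out, labels = lab)
}

#' Run the full pre-processing chain on raw scans
#'
#' Normalize each scan, assemble the M-value matrix, filter genes/samples by
#' missingness, impute, collapse duplicate genes and drop unlabeled samples —
#' the standard order of the pipeline.
#'
#' @param scans List of \code{\link{array_scan}}.
#' @param labels Named sample_id -> class vector.
#' @param normalization One of \code{\link{normalization_methods}}.
#' @param imputation \code{"ROW"} or \code{"SVD"}.
#' @param svd_k,svd_tol,svd_max_iter SVD-imputation controls.
#' @param ... Passed to \code{\link{apply_normalization}}.
#' @return As \code{\link{drop_unlabeled}}.
#' @export
preprocess_scans <- function(scans, labels,
                             normalization = "norm.glob",
                             imputation = c("ROW", "SVD"),
                             svd_k = 10, svd_tol = 0.01, svd_max_iter = 100,
                             ...) {
  imputation <- match.arg(imputation)
  ma <- lapply(scans, apply_normalization, method = normalization, ...)
  m <- assemble_matrix(ma)
  m <- filter_matrix(m)
  m <- if (imputation == "ROW") impute_row(m)
       else impute_svd(m, k = svd_k, tol = svd_tol, max_iter = svd_max_iter)
  m <- collapse_duplicates(m)
  drop_unlabeled(m, labels)
}
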