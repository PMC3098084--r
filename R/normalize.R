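#' The five normalization procedures
#'
#' @return Character vector: \code{no.norm} (raw log-ratios), \code{norm.pt}
#'   (print-tip MA-loess), \code{norm.pt.bkg} (print-tip MA-loess on
#'   background-corrected intensities), \code{norm.glob} (global MA-loess)
#'   and \code{norm.glob.bkg} (global MA-loess, background-corrected).
#' @export
normalization_methods <- function() {
  c("no.norm", "norm.pt", "norm.pt.bkg", "norm.glob", "norm.glob.bkg")
}

#' Compute M and A values from a raw scan
#'
#' For each spot, \eqn{M = \log_2(R/G)} and \eqn{A = (\log_2 R + \log_2 G)/2}
#' where R and G are the red (sample) and green (reference) channel
#' intensities. With \code{background_correct = TRUE} the locally estimated
#' background is first subtracted from each channel's foreground; spots whose
#' corrected (or raw) intensity is non-positive in either channel — i.e.
#' signal below background — become missing, as do flagged spots. Degenerate
#' spots never raise errors.
#'
#' @param scan An \code{\link{array_scan}}.
#' @param background_correct Subtract background before forming ratios?
#' @return A list of class \code{ma_spots}: \code{M}, \code{A} (numeric, NA
#'   where missing), \code{missing} (logical), \code{gene_id}, \code{block},
#'   \code{sample_id}.
#' @export
compute_ma <- function(scan, background_correct = FALSE) {
  stopifnot(inherits(scan, "array_scan"))
  sp <- scan$spots
  red <- if (background_correct) sp$fg_red - sp$bg_red else sp$fg_red
  green <- if (background_correct) sp$fg_green - sp$bg_green else sp$fg_green
  missing <- sp$flagged | red <= 0 | green <= 0 |
    !is.finite(red) | !is.finite(green)
  M <- A <- rep(NA_real_, nrow(sp))
  ok <- !missing
  M[ok] <- log2(red[ok] / green[ok])
  A[ok] <- (log2(red[ok]) + log2(green[ok])) / 2
  structure(list(M = M, A = A, missing = missing,
                 gene_id = sp$gene_id, block = sp$block,
                 sample_id = scan$sample_id),
            class = "ma_spots")
}

#' Robust loess fit of M on A
#'
#' The dye-effect estimate used by MA-loess normalization: a robust local
#' regression of the log-ratios on the average log-intensities.
#'
#' @param M,A Numeric vectors (NAs allowed; ignored for fitting).
#' @param span Loess span (default 0.3).
#' @param degree Local polynomial degree (default 1).
#' @param iterations Robustness iterations (default 4;
#'   Tukey-biweight reweighting via \code{family = "symmetric"}).
#' @param min_spots Minimum number of non-missing spots required (default 30).
#' @param label Used in error messages to identify the array/block.
#' @return A function that evaluates the fitted curve at given A values
#'   (values outside the observed range are held at the boundary fit).
#' @details If all observed A values coincide the local regression is
#'   undefined; the fit then degenerates to the constant median of M
#'   (documented choice).
#' @export
loess_fit <- function(M, A, span = 0.3, degree = 1, iterations = 4,
                      min_spots = 30, label = "array") {
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < min_spots)
    stop(sprintf("loess fit for %s: only %d non-missing spots (< %d required)",
                 label, sum(ok), min_spots))
  m <- M[ok]; a <- A[ok]
  if (diff(range(a)) < .Machine$double.eps * 8) {
    const <- stats::median(m)
    return(function(x) rep(const, length(x)))
  }
  fit <- stats::loess(m ~ a, span = span, degree = degree,
                      family = "symmetric",
                      control = stats::loess.control(surface = "interpolate",
                                                     iterations = iterations))
  lo <- min(a); hi <- max(a)
  function(x) {
    xx <- pmin(pmax(x, lo), hi)
    as.numeric(stats::predict(fit, newdata = data.frame(a = xx)))
  }
}

#' Apply one of the five normalization procedures to a scan
#'
#' \code{no.norm} returns the raw foreground log-ratios untouched.
#' \code{norm.glob(.bkg)} subtracts a single whole-array loess fit of M on A;
#' \code{norm.pt(.bkg)} subtracts a separate loess fit per print-tip block.
#' The \code{.bkg} variants compute both M and A from background-corrected
#' intensities (and inherit the signal-below-background missingness rule).
#'
#' @param scan An \code{\link{array_scan}}.
#' @param method One of \code{\link{normalization_methods}}.
#' @param span,degree,iterations,min_spots Passed to \code{\link{loess_fit}}.
#' @return An \code{ma_spots} object with normalized M.
#' @export
apply_normalization <- function(scan, method = normalization_methods(),
                                span = 0.3, degree = 1, iterations = 4,
                                min_spots = 30) {
  method <- match.arg(method)
  bkg <- grepl("\\.bkg$", method)
  ma <- compute_ma(scan, background_correct = bkg)
  if (method == "no.norm") return(ma)
  if (grepl("^norm\\.glob", method)) {
    f <- loess_fit(ma$M, ma$A, span, degree, iterations, min_spots,
                   label = sprintf("array '%s'", ma$sample_id))
    ok <- !ma$missing
    ma$M[ok] <- ma$M[ok] - f(ma$A[ok])
  } else {
    for (b in sort(unique(ma$block))) {
      in_b <- ma$block == b & !ma$missing
      if (!any(in_b)) next
      f <- loess_fit(ma$M[in_b], ma$A[in_b], span, degree, iterations,
                     min_spots,
                     label = sprintf("array '%s', block %d", ma$sample_id, b))
      ma$M[in_b] <- ma$M[in_b] - f(ma$A[in_b])
    }
  }
  ma
}
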