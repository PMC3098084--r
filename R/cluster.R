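#' Registry of the eleven clustering methods
#'
#' Six hierarchical variants (Euclidean, Manhattan or correlation distance
#' crossed with Ward and average linkage), k-means (Hartigan-Wong, best of
#' 100 random starts), PAM with Euclidean or correlation distance, a
#' one-dimensional self-organizing map, and Gaussian-mixture model-based
#' clustering (Mclust). Mclust is only valid when the feature matrix has at
#' most 500 columns.
#'
#' @return Character vector of method names.
#' @export
clustering_methods <- function() {
  c("hclust.eucl.ward", "hclust.eucl.ave",
    "hclust.manh.ward", "hclust.manh.ave",
    "hclust.corr.ward", "hclust.corr.ave",
    "kmeans", "pam.eucl", "pam.corr", "som", "mclust")
}

#' Maximum feature count for which Mclust is run
#' @return 500, the gene-count cap for model-based clustering.
#' @export
mclust_max_features <- function() 500L

#' Distance matrix between samples
#'
#' @param f Samples x features matrix.
#' @param metric \code{"eucl"}, \code{"manh"} or \code{"corr"} (1 minus the
#'   Pearson correlation between sample profiles).
#' @return A \code{dist} object.
#' @export
distance_matrix <- function(f, metric = c("eucl", "manh", "corr")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(f), nrow(f) >= 2)
  switch(metric,
         eucl = stats::dist(f, method = "euclidean"),
         manh = stats::dist(f, method = "manhattan"),
         corr = {
           if (ncol(f) < 2)
             stop("correlation distance requires at least 2 features")
           sds <- apply(f, 1, stats::sd)
           if (any(sds == 0)) {
             bad <- rownames(f)[which(sds == 0)[1]]
             if (is.null(bad)) bad <- as.character(which(sds == 0)[1])
             stop(sprintf("correlation distance undefined for constant sample '%s'", bad))
           }
           stats::as.dist(1 - stats::cor(t(f)))
         })
}

#' Cluster samples into a fixed number of clusters
#'
#' @param f Samples x features matrix.
#' @param method One of \code{\link{clustering_methods}}.
#' @param n_clusters Number of clusters to predict (default 10).
#' @param kmeans_starts Random starts for k-means (default 100).
#' @param seed Integer seed making the stochastic methods (kmeans, som)
#'   reproducible.
#' @return Integer vector of cluster labels in \code{1..c} (consecutive,
#'   every cluster non-empty, \code{c <= n_clusters}); some methods can
#'   return fewer than \code{n_clusters} non-empty clusters, which the merge
#'   evaluation accepts for any \code{c >= 2}.
#' @details Hierarchical methods cut the dendrogram at \code{n_clusters};
#'   Ward linkage uses the \code{ward.D2} criterion applied to the supplied
#'   dissimilarities (the pragmatic convention that stays meaningful for
#'   Manhattan and correlation distances). k-means keeps the best of
#'   \code{kmeans_starts} Hartigan-Wong runs by within-cluster sum of
#'   squares. PAM partitions around medoids under the stated metric. The SOM
#'   is a one-dimensional grid of \code{n_clusters} units (100 epochs,
#'   learning rate 0.05 to 0.01, neighborhood radius shrinking to 1);
#'   samples go to their best-matching unit. Mclust fits Gaussian mixtures
#'   (spherical and diagonal families) by EM initialized from model-based
#'   hierarchical clustering and assigns by maximum posterior; it requires
#'   at most \code{\link{mclust_max_features}} features.
#' @export
cluster_samples <- function(f, method = clustering_methods(),
                            n_clusters = 10, kmeans_starts = 100, seed = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(f))
  n <- nrow(f)
  if (n < n_clusters)
    stop(sprintf("%d samples cannot form %d clusters", n, n_clusters))
  if (method == "mclust" && ncol(f) > mclust_max_features())
    stop(errorCondition(sprintf(
      "mclust is only run with %d features or fewer (got %d)",
      mclust_max_features(), ncol(f)),
      class = "clustgrid_invalid_spec"))
  labels <- if (grepl("^hclust\\.", method)) {
    parts <- strsplit(method, ".", fixed = TRUE)[[1]]
    d <- distance_matrix(f, parts[2])
    link <- if (parts[3] == "ward") "ward.D2" else "average"
    stats::cutree(stats::hclust(d, method = link), k = n_clusters)
  } else if (method == "kmeans") {
    withr_seed(seed,
      stats::kmeans(f, centers = n_clusters, nstart = kmeans_starts,
                    iter.max = 50, algorithm = "Hartigan-Wong")$cluster)
  } else if (method %in% c("pam.eucl", "pam.corr")) {
    d <- distance_matrix(f, sub("^pam\\.", "", method))
    cluster::pam(d, k = n_clusters, cluster.only = TRUE)
  } else if (method == "som") {
    withr_seed(seed, som_1d(f, n_units = n_clusters))
  } else {
    withr_seed(seed, mclust_partition(f, n_clusters))
  }
  as.integer(factor(labels))    # consecutive 1..c, non-empty
}

# 1-D self-organizing map: competitive learning on a chain of n_units
# prototypes, linear learning-rate decay 0.05 -> 0.01 over `epochs`,
# neighborhood radius shrinking linearly from n_units/2 to 1.
som_1d <- function(f, n_units, epochs = 100, lr = c(0.05, 0.01)) {
  n <- nrow(f)
  # initialize prototypes along the first principal axis of the data
  x <- scale(f, scale = FALSE)
  pc1 <- svd(x, nu = 1, nv = 1)
  ord <- order(pc1$u[, 1])
  anchors <- f[ord[round(seq(1, n, length.out = n_units))], , drop = FALSE]
  proto <- anchors + matrix(stats::rnorm(length(anchors), 0, 1e-6),
                            nrow = n_units)
  radius0 <- max(n_units / 2, 1)
  for (e in seq_len(epochs)) {
    frac <- (e - 1) / max(epochs - 1, 1)
    alpha <- lr[1] + frac * (lr[2] - lr[1])
    radius <- radius0 + frac * (1 - radius0)
    for (i in sample.int(n)) {
      d2 <- rowSums(sweep(proto, 2, f[i, ])^2)
      bmu <- which.min(d2)
      infl <- exp(-((seq_len(n_units) - bmu)^2) / (2 * radius^2))
      active <- infl > 1e-3
      proto[active, ] <- proto[active, ] +
        alpha * infl[active] * (rep(1, sum(active)) %o% f[i, ] - proto[active, , drop = FALSE])
    }
  }
  apply(f, 1, function(row)
    which.min(rowSums(sweep(proto, 2, row)^2)))
}

# Gaussian mixture partition via mclust, restricted to spherical/diagonal
# covariance families (full covariances are singular when features approach
# the sample count).
mclust_partition <- function(f, n_clusters) {
  models <- if (ncol(f) == 1) c("E", "V") else c("EII", "VII", "EEI", "VVI")
  fit <- mclust::Mclust(f, G = n_clusters, modelNames = models,
                        verbose = FALSE)
  if (is.null(fit))
    stop(errorCondition("Mclust failed to fit any mixture model",
                        class = "clustgrid_cluster_failure"))
  fit$classification
}
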