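# k-means clustering of the PCA chemical space and the cluster-derived
# uncertainty features N_cl, MAE_cl, MdAE_cl, D_cl.

.sq_dist_to_centroids <- function(x, centroids) {
  # n x k matrix of squared Euclidean distances
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") - 2 * x %*% t(centroids)
  d2[d2 < 0] <- 0
  d2
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (j in seq_len(k - 1L)) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0)
      centers[j + 1L] <- sample.int(n, 1L)
    else
      centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j + 1L], ])^2))
  }
  x[centers, , drop = FALSE]
}

.lloyd <- function(x, centroids, maxIter, tol) {
  k <- nrow(centroids)
  trace <- numeric(0)
  prevAssign <- NULL
  assign <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- .sq_dist_to_centroids(x, centroids)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the farthest point
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (!length(empty)) break
      dmin <- d2[cbind(seq_len(nrow(x)), assign)]
      far <- which.max(dmin)
      centroids[empty[1], ] <- x[far, ]
      d2 <- .sq_dist_to_centroids(x, centroids)
      assign <- max.col(-d2, ties.method = "first")
    }
    if (!is.null(prevAssign) && identical(assign, prevAssign)) break
    newCentroids <- centroids
    for (j in seq_len(k))
      newCentroids[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    wcss <- sum(rowSums((x - newCentroids[assign, , drop = FALSE])^2))
    trace <- c(trace, wcss)
    shift <- max(sqrt(rowSums((newCentroids - centroids)^2)))
    centroids <- newCentroids
    prevAssign <- assign
    if (shift == 0) break  # exact fixed point; shift < tol implies the
                           # assignment is about to stabilize and the
                           # identical-assignment check terminates the loop
  }
  wcss <- sum(.sq_dist_to_centroids(x, centroids)[
    cbind(seq_len(nrow(x)), assign)])
  list(centroids = centroids, assign = assign, wcss = wcss, trace = trace)
}

#' Fit a k-means cluster model in PC space
#'
#' Lloyd's algorithm with k-means++ seeding, keeping the best of `nInit`
#' restarts by within-cluster sum of squares. Runs are bit-reproducible
#' given `seed`. Empty clusters are re-seeded from the point farthest from
#' its centroid. Cluster error statistics are filled in later by
#' [clusterErrorStats()].
#'
#' @param x numeric matrix of principal-component coordinates (n x c).
#' @param k number of clusters (default 20).
#' @param seed integer seed.
#' @param nInit number of k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @param tol convergence tolerance on the maximum centroid shift.
#' @return a [ClusterModel-class]. The fitting-set assignment is attached
#'   as attribute `"assign"`; the `wcssTrace` slot holds the per-iteration
#'   WCSS of the winning restart.
#' @export
fitKMeans <- function(x, k = 20L, seed = 1L, nInit = 10L, maxIter = 300L,
                      tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("need at least k points to fit k clusters")
  best <- NULL
  withSeed(seed, {
    for (i in seq_len(nInit)) {
      init <- .kmeanspp_init(x, k)
      fit <- .lloyd(x, init, maxIter, tol)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  dmin <- sqrt(.sq_dist_to_centroids(x, best$centroids)[
    cbind(seq_len(nrow(x)), best$assign)])
  dMean <- vapply(seq_len(k), function(j) {
    v <- dmin[best$assign == j]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  size <- tabulate(best$assign, nbins = k)
  mod <- new("ClusterModel", centroids = best$centroids,
             size = as.integer(size),
             maeCl = rep(NA_real_, k), mdaeCl = rep(NA_real_, k),
             mpeCl = rep(NA_real_, k), dMean = dMean,
             wcss = best$wcss, wcssTrace = best$trace,
             seed = as.integer(seed),
             globalMAE = NA_real_, globalMdAE = NA_real_)
  attr(mod, "assign") <- best$assign
  mod
}

#' Assign molecules to clusters
#'
#' Nearest centroid by Euclidean distance; ties break to the lowest
#' cluster index. Returns the cluster id, the distance D to the centroid,
#' and the ratio D_cl = D / D_mean of that cluster.
#'
#' @param x numeric matrix (n x c) or single PC vector.
#' @param model a fitted [ClusterModel-class].
#' @return data.frame with columns `cluster`, `D`, `dCl`.
#' @export
assignCluster <- function(x, model) {
  stopifnot(is(model, "ClusterModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model@centroids))
    stop("PC dimension does not match the cluster model")
  d2 <- .sq_dist_to_centroids(as.matrix(x), model@centroids)
  cl <- max.col(-d2, ties.method = "first")
  D <- sqrt(d2[cbind(seq_len(nrow(x)), cl)])
  dm <- model@dMean[cl]
  data.frame(cluster = cl, D = D,
             dCl = ifelse(is.na(dm) | dm <= 0, 0, D / dm))
}

#' Per-cluster error statistics
#'
#' Computes MAE_cl, MdAE_cl and the mean percentage error for each cluster
#' from training-fold molecules. Clusters without training members fall
#' back to the global MAE/MdAE with a warning.
#'
#' @param model a [ClusterModel-class].
#' @param assignments integer cluster ids of the training molecules.
#' @param absErrors absolute prediction errors, aligned with
#'   `assignments`.
#' @param signedErrors optional signed errors (for the mean percentage
#'   error).
#' @param yTrue optional true values (for the mean percentage error).
#' @return the model with statistics slots filled.
#' @export
clusterErrorStats <- function(model, assignments, absErrors,
                              signedErrors = NULL, yTrue = NULL) {
  stopifnot(is(model, "ClusterModel"))
  if (!length(assignments) || !length(absErrors))
    stop("empty inputs to clusterErrorStats")
  if (length(assignments) != length(absErrors))
    stop("assignments and absErrors must align")
  k <- nrow(model@centroids)
  gMAE <- mean(absErrors)
  gMdAE <- median(absErrors)
  mae <- mdae <- mpe <- rep(NA_real_, k)
  emptySeen <- FALSE
  for (j in seq_len(k)) {
    sel <- assignments == j
    if (!any(sel)) {
      mae[j] <- gMAE; mdae[j] <- gMdAE
      emptySeen <- TRUE
      next
    }
    mae[j] <- mean(absErrors[sel])
    mdae[j] <- median(absErrors[sel])
    if (!is.null(signedErrors) && !is.null(yTrue))
      mpe[j] <- mean(signedErrors[sel] / yTrue[sel]) * 100
  }
  if (emptySeen)
    warning("clusters without training members fall back to global MAE/MdAE")
  model@maeCl <- mae
  model@mdaeCl <- mdae
  model@mpeCl <- mpe
  model@globalMAE <- gMAE
  model@globalMdAE <- gMdAE
  model
}

#' Distance-quartile error profile
#'
#' For each cluster, members are split into quartiles by distance to the
#' centroid and the mean absolute error is computed per quartile;
#' clusters with fewer than 4 members are skipped with a warning.
#'
#' @param model a [ClusterModel-class].
#' @param assignments,distances,absErrors aligned member vectors.
#' @return data.frame with columns `cluster`, `quartile`, `n`, `mae`.
#' @export
distanceQuartileProfile <- function(model, assignments, distances,
                                    absErrors) {
  stopifnot(is(model, "ClusterModel"))
  k <- nrow(model@centroids)
  out <- list()
  skipped <- FALSE
  for (j in seq_len(k)) {
    sel <- which(assignments == j)
    if (length(sel) < 4) { skipped <- skipped || length(sel) > 0; next }
    d <- distances[sel]; e <- absErrors[sel]
    qs <- quantile(d, c(0.25, 0.5, 0.75), type = 7)
    quart <- findInterval(d, qs, left.open = TRUE) + 1L
    for (q in 1:4) {
      m <- quart == q
      out[[length(out) + 1L]] <- data.frame(
        cluster = j, quartile = q, n = sum(m),
        mae = if (any(m)) mean(e[m]) else NA_real_)
    }
  }
  if (skipped) warning("clusters with fewer than 4 members were skipped")
  if (!length(out))
    return(data.frame(cluster = integer(0), quartile = integer(0),
                      n = integer(0), mae = numeric(0)))
  do.call(rbind, out)
}
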