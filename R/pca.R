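# PCA projection of the scaled descriptor matrix. 20 components are
# retained by default; the same projection underlies both the Euclidean
# similarity feature and the k-means chemical-space clustering.

#' Fit a PCA projection
#'
#' Principal component analysis of a (min-max scaled) descriptor matrix,
#' retaining `c = min(cMax, d, n - 1)` components. Component signs follow
#' the convention that the largest-magnitude loading entry of each
#' component is positive, which makes runs reproducible across platforms.
#'
#' @param x numeric matrix (n x d), n >= 2.
#' @param cMax maximum number of components (default 20).
#' @return a list of class `uqPCA` with `center` (length d mean vector),
#'   `loadings` (d x c orthonormal matrix), `varExplained`
#'   (non-increasing component variances) and `c`.
#' @export
fitPCA <- function(x, cMax = 20L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires at least two rows")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  c_ <- as.integer(min(cMax, ncol(x), nrow(x) - 1L))
  load <- p$rotation[, seq_len(c_), drop = FALSE]
  ve <- p$sdev[seq_len(c_)]^2
  for (k in seq_len(c_)) {
    imax <- which.max(abs(load[, k]))
    if (load[imax, k] < 0) load[, k] <- -load[, k]
  }
  structure(list(center = p$center, loadings = load, varExplained = ve,
                 c = c_, names = colnames(x)),
            class = c("uqPCA", "list"))
}

#' Project a matrix onto a fitted PCA
#'
#' @param x numeric matrix with the same columns as the fitting matrix.
#' @param pca a fitted `uqPCA` from [fitPCA()].
#' @return n x c score matrix.
#' @export
projectPCA <- function(x, pca) {
  stopifnot(inherits(pca, "uqPCA"))
  x <- as.matrix(x)
  if (ncol(x) != length(pca$center))
    stop("matrix does not match the PCA's descriptor count")
  sweep(x, 2, pca$center, "-") %*% pca$loadings
}
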