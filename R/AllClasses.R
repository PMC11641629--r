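#' @import methods
#' @importFrom stats median quantile sd var prcomp glm binomial coef vcov
#'   optim rnorm runif rexp dnorm dcauchy pnorm pcauchy setNames predict
#' @importFrom utils read.csv write.csv head
NULL

.finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' PredictionSet: per-molecule ensemble predictions
#'
#' Container for one prediction task: each molecule carries a standardized
#' SMILES string, the experimental property value, the predictions of the
#' `m` ensemble members (columns of `predictions`), and optionally a fold
#' identifier from the out-of-fold construction of the table.
#'
#' @slot smiles character vector of canonical, stereochemistry-free SMILES.
#' @slot yTrue numeric vector of experimental values (property units:
#'   retention index unitless, retention time seconds, CCS squared angstrom).
#' @slot predictions numeric matrix, one row per molecule, one column per
#'   ensemble member.
#' @slot foldId integer vector of fold assignments (NA when unassigned).
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(
    smiles      = "character",
    yTrue       = "numeric",
    predictions = "matrix",
    foldId      = "integer"
  )
)

setValidity("PredictionSet", function(object) {
  n <- length(object@smiles)
  msg <- character(0)
  if (length(object@yTrue) != n)
    msg <- c(msg, "yTrue length must match smiles length")
  if (nrow(object@predictions) != n)
    msg <- c(msg, "predictions must have one row per molecule")
  if (n > 0 && ncol(object@predictions) < 1)
    msg <- c(msg, "predictions must have at least one column")
  if (!all(is.finite(object@yTrue)))
    msg <- c(msg, "yTrue must be finite")
  if (length(object@predictions) && !all(is.finite(object@predictions)))
    msg <- c(msg, "predictions must be finite")
  if (length(object@foldId) != n)
    msg <- c(msg, "foldId length must match smiles length")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param smiles character vector of SMILES strings (standardize first with
#'   [standardizeSmiles()] when they come from external sources).
#' @param yTrue numeric vector of experimental property values.
#' @param predictions numeric matrix (n x m) of per-model predictions; a
#'   vector is treated as a single-model column.
#' @param foldId optional integer fold assignment per molecule.
#' @return A [PredictionSet-class] object.
#' @examples
#' ps <- PredictionSet(c("CCO", "CCC"), c(450, 300),
#'                     matrix(c(440, 310, 460, 295), ncol = 2))
#' nMolecules(ps)
#' @export
PredictionSet <- function(smiles, yTrue, predictions, foldId = NULL) {
  if (is.vector(predictions)) predictions <- matrix(predictions, ncol = 1)
  predictions <- as.matrix(predictions)
  storage.mode(predictions) <- "double"
  if (is.null(colnames(predictions)))
    colnames(predictions) <- paste0("pred_", seq_len(ncol(predictions)))
  if (is.null(foldId)) foldId <- rep(NA_integer_, length(smiles))
  new("PredictionSet", smiles = as.character(smiles),
      yTrue = as.numeric(yTrue), predictions = predictions,
      foldId = as.integer(foldId))
}

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet with", length(object@smiles), "molecules,",
      ncol(object@predictions), "ensemble member(s)\n")
  nf <- sum(!is.na(object@foldId))
  if (nf > 0)
    cat("  folds assigned for", nf, "molecules (",
        length(unique(object@foldId[!is.na(object@foldId)])), "folds )\n")
  if (length(object@smiles)) {
    k <- min(3L, length(object@smiles))
    cat("  head:", paste(object@smiles[seq_len(k)], collapse = ", "), "\n")
  }
})

#' SimilarityReference: the training-set side of the S_max features
#'
#' Aligned canonical SMILES, circular count fingerprints (sparse matrix,
#' rows = molecules) and PCA-space coordinates of the molecules the base
#' models were trained on.
#'
#' @slot smiles character vector.
#' @slot fingerprints sparse `dgCMatrix` (n x fingerprint length).
#' @slot pcs numeric matrix (n x c) of principal-component coordinates.
#' @exportClass SimilarityReference
setClass("SimilarityReference",
  representation(smiles = "character", fingerprints = "ANY", pcs = "matrix"))

setValidity("SimilarityReference", function(object) {
  n <- length(object@smiles)
  msg <- character(0)
  if (n == 0) msg <- c(msg, "reference must be non-empty")
  if (nrow(object@fingerprints) != n)
    msg <- c(msg, "fingerprints must have one row per molecule")
  if (nrow(object@pcs) != n)
    msg <- c(msg, "pcs must have one row per molecule")
  if (length(msg)) msg else TRUE
})

#' @rdname SimilarityReference-class
#' @param smiles,fingerprints,pcs see slots.
#' @export
SimilarityReference <- function(smiles, fingerprints, pcs) {
  new("SimilarityReference", smiles = smiles, fingerprints = fingerprints,
      pcs = as.matrix(pcs))
}

setMethod("show", "SimilarityReference", function(object) {
  cat("SimilarityReference with", length(object@smiles), "molecules,",
      ncol(object@fingerprints), "fingerprint bins,",
      ncol(object@pcs), "principal components\n")
})

#' ClusterModel: k-means chemical-space clustering with error statistics
#'
#' Centroids of a k-means fit in PCA descriptor space together with the
#' per-cluster uncertainty statistics computed from training-fold
#' molecules: member count, mean and median absolute prediction error
#' (MAE_cl, MdAE_cl), mean percentage error, and the mean member-to-centroid
#' distance D_mean used to normalise the distance feature D_cl.
#'
#' @slot centroids numeric matrix (k x c).
#' @slot size integer member counts.
#' @slot maeCl,mdaeCl,mpeCl,dMean per-cluster statistics (NA before
#'   [clusterErrorStats()] is applied).
#' @slot wcss within-cluster sum of squares of the selected restart.
#' @slot wcssTrace WCSS after each Lloyd iteration of the selected restart.
#' @slot seed integer seed used for the fit.
#' @slot globalMAE,globalMdAE fall-back statistics for empty clusters.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    centroids = "matrix", size = "integer",
    maeCl = "numeric", mdaeCl = "numeric", mpeCl = "numeric",
    dMean = "numeric", wcss = "numeric", wcssTrace = "numeric",
    seed = "integer", globalMAE = "numeric", globalMdAE = "numeric"
  )
)

setValidity("ClusterModel", function(object) {
  k <- nrow(object@centroids)
  msg <- character(0)
  if (k < 1) msg <- c(msg, "at least one centroid required")
  for (s in c("size", "maeCl", "mdaeCl", "mpeCl", "dMean"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("slot %s must have length k", s))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", nrow(object@centroids), "clusters in",
      ncol(object@centroids), "dimensions (seed", object@seed, ")\n")
  cat("  WCSS:", format(object@wcss, digits = 6),
      "| sizes:", paste(object@size, collapse = " "), "\n")
  if (!all(is.na(object@maeCl)))
    cat("  MAE_cl range:", format(range(object@maeCl), digits = 4), "\n")
})

#' MetaClassifier: second-stage model flagging unreliable predictions
#'
#' Either an unregularised logistic regression (coefficients plus standard
#' errors from the inverse observed information) or a gradient-boosting
#' model (100 trees of depth 3, learning rate 0.1) that maps uncertainty
#' features to the probability that the prediction error exceeds the
#' threshold D_t. Predictions with probability at or above `pThreshold`
#' (default 0.15) are flagged as likely unsatisfactory.
#'
#' @slot kind "logistic" or "gradient_boosting".
#' @slot coefficients,se named numeric vectors (logistic only; se > 0).
#' @slot booster raw serialized xgboost model (gradient boosting only).
#' @slot importance data.frame of gain-based feature importances
#'   (gradient boosting only).
#' @slot featureNames the feature columns, in fitting order.
#' @slot pThreshold decision probability threshold in (0, 1).
#' @exportClass MetaClassifier
setClass("MetaClassifier",
  representation(
    kind = "character", coefficients = "numeric", se = "numeric",
    booster = "ANY", importance = "data.frame",
    featureNames = "character", pThreshold = "numeric"
  )
)

setValidity("MetaClassifier", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("logistic", "gradient_boosting"))
    msg <- c(msg, "kind must be 'logistic' or 'gradient_boosting'")
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    msg <- c(msg, "pThreshold must be in (0,1)")
  if (object@kind == "logistic") {
    if (length(object@coefficients) != length(object@se))
      msg <- c(msg, "coefficients and se must align")
    if (length(object@se) && any(object@se <= 0))
      msg <- c(msg, "standard errors must be positive")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetaClassifier", function(object) {
  cat("MetaClassifier (", object@kind, "), p threshold =",
      object@pThreshold, "\n")
  if (object@kind == "logistic") {
    tab <- data.frame(coefficient = object@coefficients, se = object@se)
    print(round(tab, 4))
  } else {
    cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
    if (nrow(object@importance))
      print(head(object@importance, 5))
  }
})

#' EvaluationReport: confusion counts and derived metrics
#'
#' Binary evaluation of an unreliable-prediction flagger, with the positive
#' class being "unsatisfactory prediction". Holds the confusion counts at
#' the decision threshold, threshold-free ROC-AUC, the derived metrics and
#' the full ROC / precision-recall curves.
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot aucROC,f1,precision,recall,accuracy metrics in [0, 1].
#' @slot pThreshold probability threshold the counts refer to.
#' @slot rocCurve,prCurve data.frames of curve points.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    aucROC = "numeric", f1 = "numeric", precision = "numeric",
    recall = "numeric", accuracy = "numeric", pThreshold = "numeric",
    rocCurve = "data.frame", prCurve = "data.frame"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character(0)
  cnt <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(cnt < 0)) msg <- c(msg, "confusion counts must be non-negative")
  mets <- c(object@f1, object@precision, object@recall, object@accuracy)
  if (any(!is.na(mets) & (mets < 0 | mets > 1)))
    msg <- c(msg, "metrics must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (positive = unsatisfactory), p >=",
      object@pThreshold, "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  ROC-AUC %.3f  F1 %.3f  precision %.3f  recall %.3f  accuracy %.3f\n",
              object@aucROC, object@f1, object@precision, object@recall,
              object@accuracy))
})

#' UEModel: everything needed to featurize new predictions
#'
#' The fitted reference side of the uncertainty-estimation pipeline: the
#' similarity reference (training fingerprints and PC vectors), descriptor
#' scaler, PCA projection, cluster model with error statistics, and the
#' descriptor names used. Built with [buildUEModel()] on training-fold
#' molecules, then applied to queries with [computeUEFeatures()].
#'
#' @slot reference a [SimilarityReference-class].
#' @slot scaler,pca fitted parameter lists (see [fitScaler()], [fitPCA()]).
#' @slot clusters a [ClusterModel-class] with error statistics.
#' @slot descriptorNames character vector recording the descriptor set.
#' @exportClass UEModel
setClass("UEModel",
  representation(reference = "SimilarityReference", scaler = "ANY",
                 pca = "ANY", clusters = "ClusterModel",
                 descriptorNames = "character"))

setValidity("UEModel", function(object) {
  msg <- character(0)
  if (!inherits(object@scaler, "uqScaler"))
    msg <- c(msg, "scaler must be a fitted uqScaler")
  if (!inherits(object@pca, "uqPCA"))
    msg <- c(msg, "pca must be a fitted uqPCA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "UEModel", function(object) {
  cat("UEModel\n")
  cat("  reference molecules:", length(object@reference@smiles), "\n")
  cat("  descriptors:", length(object@descriptorNames),
      "| principal components:", ncol(object@reference@pcs), "\n")
  cat("  clusters: k =", nrow(object@clusters@centroids), "\n")
})
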