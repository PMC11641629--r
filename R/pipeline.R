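# Orchestration: building the reference-side model from training folds,
# featurizing queries, and the out-of-fold cross-validation pipeline.

#' Build the uncertainty-estimation reference model
#'
#' Fits everything the features need on the training-fold molecules:
#' descriptor scaler and PCA, training fingerprints and PC vectors
#' (the similarity reference), the k-means cluster model, and the
#' per-cluster error statistics computed from the training molecules'
#' own ensemble errors. Scaler, PCA and clusters are fitted on the
#' training reference only (`fit_scope = train`), so no query information
#' leaks into the features.
#'
#' @param train a [PredictionSet-class] of training-fold molecules (their
#'   out-of-fold ensemble errors feed the cluster statistics).
#' @param k number of clusters (default 20).
#' @param seed integer seed (clustering restarts).
#' @param cMax number of principal components to retain (default 20).
#' @param weights optional ensemble weights.
#' @param referenceSmiles optional separate SMILES set defining the
#'   similarity reference and cluster geometry; defaults to the training
#'   molecules themselves (the usual case, since the base models were
#'   trained on them).
#' @return a [UEModel-class].
#' @export
buildUEModel <- function(train, k = 20L, seed = 1L, cMax = 20L,
                         weights = NULL, referenceSmiles = NULL) {
  stopifnot(is(train, "PredictionSet"))
  smi <- if (is.null(referenceSmiles)) smiles(train)
         else unique(referenceSmiles)
  desc <- computeDescriptors(smi)
  scaler <- fitScaler(desc)
  scaled <- applyScaler(desc, scaler)
  pca <- fitPCA(scaled, cMax = cMax)
  pcs <- projectPCA(scaled, pca)
  fps <- countFingerprintMatrix(smi)
  ref <- SimilarityReference(smi, fps, pcs)
  clusters <- fitKMeans(pcs, k = k, seed = seed)
  if (is.null(referenceSmiles)) {
    assign <- attr(clusters, "assign")
  } else {
    trainScaled <- applyScaler(computeDescriptors(smiles(train)), scaler)
    assign <- assignCluster(projectPCA(trainScaled, pca),
                            clusters)$cluster
  }
  yEns <- ensemblePrediction(predictions(train), weights)
  err <- yEns - yTrue(train)
  clusters <- clusterErrorStats(clusters, assign, abs(err),
                                signedErrors = err, yTrue = yTrue(train))
  new("UEModel", reference = ref, scaler = scaler, pca = pca,
      clusters = clusters, descriptorNames = colnames(desc))
}

#' Compute uncertainty features for query predictions
#'
#' Applies a fitted [UEModel-class] to a query [PredictionSet-class] and
#' returns the full uncertainty feature table: cluster features (N_cl,
#' MAE_cl, MdAE_cl, D_cl), nearest-training-set similarities (S_max,t,
#' S_max,c, S_max,e and optionally S_max,mcs), ensemble spread features
#' (M_s1, M_s2, M_m), and the ensemble prediction.
#'
#' @param query a [PredictionSet-class].
#' @param model a [UEModel-class] from [buildUEModel()].
#' @param mcs compute the (slow) MCS similarity feature (default FALSE).
#' @param mcsTimeout per-pair MCS timeout in seconds.
#' @param weights optional ensemble weights.
#' @return data.frame with one row per query molecule.
#' @export
computeUEFeatures <- function(query, model, mcs = FALSE, mcsTimeout = 10,
                              weights = NULL) {
  stopifnot(is(query, "PredictionSet"), is(model, "UEModel"))
  smi <- smiles(query)
  desc <- computeDescriptors(smi)
  scaled <- applyScaler(desc, model@scaler)
  pcs <- projectPCA(scaled, model@pca)
  fps <- countFingerprintMatrix(smi)
  sim <- batchNearestSimilarity(fps, pcs, model@reference,
                                querySmiles = smi, mcs = mcs,
                                timeout = mcsTimeout)
  asg <- assignCluster(pcs, model@clusters)
  spread <- spreadFeatures(predictions(query))
  yEns <- ensemblePrediction(predictions(query), weights)
  out <- data.frame(
    smiles = smi,
    nCl = asg$cluster,
    maeCl = model@clusters@maeCl[asg$cluster],
    mdaeCl = model@clusters@mdaeCl[asg$cluster],
    dCl = asg$dCl,
    sMaxT = sim$sMaxT, sMaxC = sim$sMaxC, sMaxE = sim$sMaxE,
    stringsAsFactors = FALSE)
  if (mcs) out$sMaxMcs <- sim$sMaxMcs
  out$mS1 <- spread$mS1
  out$mS2 <- spread$mS2
  out$mM <- spread$mM
  out$yEns <- yEns
  out
}

#' Molecule-level fold assignment
#'
#' Assigns every distinct canonical SMILES to one of `nFolds` folds
#' uniformly at random under `seed`; duplicate SMILES always share a
#' fold.
#'
#' @param smi character vector of standardized SMILES.
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @return integer fold ids in `[0, nFolds)`, aligned with `smi`.
#' @export
assignFolds <- function(smi, nFolds = 5L, seed = 1L) {
  if (nFolds < 2) stop("need at least 2 folds")
  uniq <- unique(smi)
  if (length(uniq) < nFolds)
    stop("fewer distinct molecules than folds")
  folds <- withSeed(seed, {
    # balanced assignment: shuffled round-robin over unique molecules
    f <- rep(seq_len(nFolds) - 1L, length.out = length(uniq))
    f[sample.int(length(uniq))]
  })
  folds[match(smi, uniq)]
}

#' Out-of-fold prediction and featurization pipeline
#'
#' Splits the molecules into `nFolds` molecule-level folds; for every
#' fold, trains the base regressor ensemble on the remaining folds,
#' predicts the held-out molecules, builds the [UEModel-class] from the
#' training folds (similarity reference, scaler, PCA, clusters and
#' cluster error statistics all derive from training molecules only), and
#' featurizes the held-out predictions. Every molecule therefore receives
#' predictions from models never trained on it.
#'
#' @param data data.frame with columns `smiles` (standardized) and
#'   `y_true`.
#' @param regressors list of base-regressor interfaces, each a list with
#'   `fit(smiles, y)` returning a model and `predict(model, smiles)`
#'   returning values (see [toyBaseRegressor()]).
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the fold assignment and clustering.
#' @param k number of clusters.
#' @param mcs compute the MCS similarity feature.
#' @return list with `predictions` (a [PredictionSet-class] with fold
#'   ids) and `features` (the uncertainty feature data.frame, aligned).
#' @export
crossvalPipeline <- function(data, regressors, nFolds = 5L, seed = 1L,
                             k = 20L, mcs = FALSE) {
  stopifnot(all(c("smiles", "y_true") %in% names(data)))
  if (length(regressors) < 2)
    stop("need at least two base regressors for an ensemble")
  smi <- data$smiles
  folds <- assignFolds(smi, nFolds, seed)
  m <- length(regressors)
  n <- nrow(data)
  preds <- matrix(NA_real_, n, m)
  # pass 1: out-of-fold predictions for every molecule
  for (f in seq_len(nFolds) - 1L) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    if (!length(testIdx) || !length(trainIdx))
      stop("fold with zero molecules")
    for (j in seq_len(m)) {
      mod <- regressors[[j]]$fit(smi[trainIdx], data$y_true[trainIdx])
      preds[testIdx, j] <- regressors[[j]]$predict(mod, smi[testIdx])
    }
  }
  # pass 2: featurize each fold against a reference built from the other
  # folds; training molecules contribute their own out-of-fold errors to
  # the cluster statistics
  featParts <- vector("list", nFolds)
  for (f in seq_len(nFolds) - 1L) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    trainPS <- PredictionSet(smi[trainIdx], data$y_true[trainIdx],
                             preds[trainIdx, , drop = FALSE])
    ueModel <- buildUEModel(trainPS, k = min(k, length(trainIdx)),
                            seed = seed)
    testPS <- PredictionSet(smi[testIdx], data$y_true[testIdx],
                            preds[testIdx, , drop = FALSE])
    featParts[[f + 1L]] <- cbind(idx = testIdx,
                                 computeUEFeatures(testPS, ueModel,
                                                   mcs = mcs))
  }
  feats <- do.call(rbind, featParts)
  feats <- feats[order(feats$idx), setdiff(names(feats), "idx"),
                 drop = FALSE]
  rownames(feats) <- NULL
  ps <- PredictionSet(smi, data$y_true, preds, foldId = folds)
  list(predictions = ps, features = feats)
}
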