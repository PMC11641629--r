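# Second-stage models: feature assembly, logistic-regression and
# gradient-boosting meta-classifiers, and their evaluation.

.LOGISTIC_FEATURES <- c("maeCl", "dCl", "sMaxT", "sMaxE", "mS1")
.BASE_FEATURES <- c("maeCl", "mdaeCl", "dCl", "sMaxT", "sMaxC", "sMaxE",
                    "mS1", "mS2", "mM")

#' Assemble the meta-model feature table
#'
#' In `"logistic"` mode the six-feature set used for the linear
#' meta-model: MAE_cl, D_cl, S_max,t, S_max,e, M_s1, and the ensemble
#' prediction divided by 1000. In `"full"` mode all uncertainty features
#' (including S_max,mcs when present), a one-hot encoding of the cluster
#' number, and the raw ensemble prediction.
#'
#' @param ue data.frame of uncertainty features as produced by
#'   [computeUEFeatures()] (columns `nCl`, `maeCl`, `mdaeCl`, `dCl`,
#'   `sMaxT`, `sMaxC`, `sMaxE`, optional `sMaxMcs`, `mS1`, `mS2`, `mM`,
#'   `yEns`).
#' @param mode "logistic" or "full".
#' @param k number of clusters for the one-hot encoding (default 20).
#' @return numeric matrix with a fixed, recorded column order.
#' @export
assembleFeatures <- function(ue, mode = c("logistic", "full"), k = 20L) {
  mode <- match.arg(mode)
  need <- if (mode == "logistic") c(.LOGISTIC_FEATURES, "yEns")
          else c("nCl", .BASE_FEATURES, "yEns")
  miss <- setdiff(need, names(ue))
  if (length(miss))
    stop("missing uncertainty feature(s): ", paste(miss, collapse = ", "))
  if (mode == "logistic") {
    out <- cbind(as.matrix(ue[, .LOGISTIC_FEATURES]),
                 yEnsK = ue$yEns / 1000)
    colnames(out) <- c(.LOGISTIC_FEATURES, "yEnsK")
    return(out)
  }
  base <- .BASE_FEATURES
  if ("sMaxMcs" %in% names(ue)) base <- append(base, "sMaxMcs",
                                               after = match("sMaxC", base))
  oneHot <- matrix(0, nrow(ue), k,
                   dimnames = list(NULL, paste0("nCl_", seq_len(k))))
  cl <- as.integer(ue$nCl)
  if (any(cl < 1 | cl > k)) stop("cluster ids outside 1..k")
  oneHot[cbind(seq_len(nrow(ue)), cl)] <- 1
  out <- cbind(as.matrix(ue[, base]), oneHot, yEns = ue$yEns)
  out
}

.check_meta_inputs <- function(features, labels) {
  if (nrow(features) != length(labels)) stop("features and labels must align")
  if (nrow(features) < 50) stop("need at least 50 rows to fit a meta-model")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the labels")
}

#' Fit the logistic-regression meta-classifier
#'
#' Unregularised maximum-likelihood logistic regression (with intercept)
#' of the unsatisfactory/satisfactory label on the assembled features.
#' Standard errors come from the inverse observed information. Feature
#' values are used on their raw scales (no standardization), so the
#' coefficients are directly comparable across refits.
#'
#' @param features numeric matrix from [assembleFeatures()].
#' @param labels 0/1 vector (1 = unsatisfactory).
#' @param pThreshold decision probability threshold (default 0.15).
#' @return a [MetaClassifier-class].
#' @export
fitLogisticMeta <- function(features, labels, pThreshold = 0.15) {
  features <- as.matrix(features)
  if (ncol(features) == 0) features <- matrix(numeric(0), length(labels), 0)
  .check_meta_inputs(features, labels)
  repeat {
    df <- data.frame(features, check.names = FALSE)
    df$.y <- labels
    sep <- FALSE
    fit <- withCallingHandlers(
      if (ncol(features) == 0) glm(.y ~ 1, data = df, family = binomial())
      else glm(.y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || !fit$converged)
      stop("logistic fit did not converge (possible perfect separation); ",
           "check for features that fully determine the labels")
    aliased <- intersect(colnames(features),
                         names(coef(fit))[is.na(coef(fit))])
    if (!length(aliased)) break
    warning("dropping constant/collinear feature(s): ",
            paste(aliased, collapse = ", "))
    features <- features[, setdiff(colnames(features), aliased),
                         drop = FALSE]
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  new("MetaClassifier", kind = "logistic", coefficients = cf, se = se,
      booster = NULL, importance = data.frame(),
      featureNames = if (is.null(colnames(features))) character(0)
                     else colnames(features),
      pThreshold = pThreshold)
}

#' Fit the gradient-boosting meta-classifier
#'
#' 100 boosted trees of depth 3 with learning rate 0.1 (the library
#' defaults for this task class), binary logistic objective, single
#' threaded and deterministic given `seed`. Feature importances use the
#' gain measure.
#'
#' @param features numeric matrix from [assembleFeatures()].
#' @param labels 0/1 vector (1 = unsatisfactory).
#' @param seed integer seed.
#' @param pThreshold decision probability threshold (default 0.15).
#' @param nrounds,maxDepth,eta boosting hyperparameters.
#' @return a [MetaClassifier-class].
#' @export
fitBoostingMeta <- function(features, labels, seed = 1L, pThreshold = 0.15,
                            nrounds = 100L, maxDepth = 3L, eta = 0.1) {
  features <- as.matrix(features)
  .check_meta_inputs(features, labels)
  dtrain <- xgboost::xgb.DMatrix(features, label = labels)
  booster <- withSeed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = maxDepth,
                  eta = eta, nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0))
  imp <- as.data.frame(xgboost::xgb.importance(model = booster))
  new("MetaClassifier", kind = "gradient_boosting",
      coefficients = numeric(0), se = numeric(0),
      booster = xgboost::xgb.save.raw(booster), importance = imp,
      featureNames = colnames(features), pThreshold = pThreshold)
}

#' Predict unsatisfactory-prediction probabilities
#'
#' @param model a [MetaClassifier-class].
#' @param features matrix with the columns the model was fitted on.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, features) {
  stopifnot(is(model, "MetaClassifier"))
  features <- as.matrix(features)
  miss <- setdiff(model@featureNames, colnames(features))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  features <- features[, model@featureNames, drop = FALSE]
  if (model@kind == "logistic") {
    eta <- model@coefficients[1] +
      as.numeric(features %*% model@coefficients[-1])
    1 / (1 + exp(-eta))
  } else {
    booster <- xgboost::xgb.load.raw(model@booster)
    predict(booster, xgboost::xgb.DMatrix(features))
  }
}

#' Flag predictions as likely unsatisfactory
#'
#' A prediction is flagged iff its predicted probability of being
#' unsatisfactory is at least the model's decision threshold p.
#'
#' @param model a [MetaClassifier-class].
#' @param features matrix of features.
#' @return integer 0/1 vector (1 = flagged).
#' @export
flagUnreliable <- function(model, features) {
  as.integer(predictProb(model, features) >= model@pThreshold)
}

#' ROC-AUC by the Mann-Whitney statistic
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted one half; invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric vector (larger = more likely positive).
#' @param labels 0/1 vector.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels must align")
  pos <- labels == 1
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes required for ROC-AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

.roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tpr <- cumsum(lab == 1) / sum(labels == 1)
  fpr <- cumsum(lab == 0) / sum(labels == 0)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
        data.frame(threshold = scores[ord][keep],
                   fpr = fpr[keep], tpr = tpr[keep]))
}

.pr_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(threshold = scores[ord][keep],
             recall = tp[keep] / sum(labels == 1),
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' Build an evaluation report from confusion counts
#'
#' Derives F1, precision, recall and accuracy from the four confusion
#' counts; zero-denominator precision/recall are defined as 0 with a
#' warning.
#'
#' @param tp,tn,fp,fn confusion counts (positive = unsatisfactory).
#' @param pThreshold the probability threshold the counts refer to.
#' @param aucROC optional threshold-free AUC to store alongside.
#' @return an [EvaluationReport-class].
#' @examples
#' metrics(evaluationFromCounts(1030, 5954, 2058, 366))
#' @export
evaluationFromCounts <- function(tp, tn, fp, fn, pThreshold = 0.15,
                                 aucROC = NA_real_) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else { warning("no positive calls; precision defined as 0"); 0 }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { warning("no positive labels; recall defined as 0"); 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  acc <- (tp + tn) / (tp + tn + fp + fn)
  new("EvaluationReport", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn), aucROC = aucROC,
      f1 = f1, precision = prec, recall = rec, accuracy = acc,
      pThreshold = pThreshold,
      rocCurve = data.frame(), prCurve = data.frame())
}

#' Evaluate an unreliable-prediction flagger
#'
#' Confusion counts at the probability threshold (positive call iff
#' probability >= threshold), derived metrics, threshold-free ROC-AUC,
#' and the full ROC and precision-recall curves.
#'
#' @param probabilities predicted probabilities of being unsatisfactory.
#' @param labels 0/1 truth (1 = unsatisfactory).
#' @param pThreshold decision threshold (default 0.15).
#' @return an [EvaluationReport-class].
#' @export
evaluateFlagging <- function(probabilities, labels, pThreshold = 0.15) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must align")
  call <- probabilities >= pThreshold
  tp <- sum(call & labels == 1); fp <- sum(call & labels == 0)
  fn <- sum(!call & labels == 1); tn <- sum(!call & labels == 0)
  auc <- if (length(unique(labels)) == 2) rocAUC(probabilities, labels)
         else NA_real_
  rep <- evaluationFromCounts(tp, tn, fp, fn, pThreshold, aucROC = auc)
  rep@rocCurve <- if (!is.na(auc)) .roc_curve(probabilities, labels)
                  else data.frame()
  rep@prCurve <- if (!is.na(auc)) .pr_curve(probabilities, labels)
                 else data.frame()
  rep
}

#' Binned feature diagnostics
#'
#' Splits a feature's range into equal-width bins and reports per-bin
#' count, MAE, MdAE and the unsatisfactory fraction; useful for the
#' "error grows with spread / falls with similarity" diagnostics.
#'
#' @param featureValues numeric vector.
#' @param absErrors absolute errors, aligned.
#' @param labels 0/1 unsatisfactory labels, aligned.
#' @param nBins number of equal-width bins.
#' @return data.frame with one row per bin (empty bins have count 0).
#' @export
binnedDiagnostics <- function(featureValues, absErrors, labels,
                              nBins = 10L) {
  n <- length(featureValues)
  if (n < nBins) stop("need at least nBins rows")
  lo <- min(featureValues); hi <- max(featureValues)
  if (hi <= lo) {
    bin <- rep(1L, n)
  } else {
    bin <- pmin(nBins,
                1L + floor((featureValues - lo) / (hi - lo) * nBins))
  }
  edges <- seq(lo, if (hi > lo) hi else lo + 1, length.out = nBins + 1L)
  do.call(rbind, lapply(seq_len(nBins), function(b) {
    sel <- bin == b
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n = sum(sel),
               mae = if (any(sel)) mean(absErrors[sel]) else NA_real_,
               mdae = if (any(sel)) median(absErrors[sel]) else NA_real_,
               fracUnsat = if (any(sel)) mean(labels[sel] == 1) else NA_real_)
  }))
}
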