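# Ensemble aggregation, spread features M_s1/M_s2/M_m, error thresholds
# D_t, satisfactory/unsatisfactory labeling, and error-distribution
# diagnostics.

#' Ensemble prediction
#'
#' The (optionally weighted) mean of the predictions of the ensemble
#' members.
#'
#' @param modelPreds numeric vector of per-model predictions, or a matrix
#'   with one row per molecule.
#' @param weights optional weights of length m summing to 1; equal by
#'   default.
#' @return the ensemble prediction(s).
#' @export
ensemblePrediction <- function(modelPreds, weights = NULL) {
  if (is.null(dim(modelPreds))) modelPreds <- matrix(modelPreds, nrow = 1)
  m <- ncol(modelPreds)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m)
    stop("weights length must equal the ensemble size")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  out <- as.numeric(modelPreds %*% weights)
  if (length(out) == 1) out else out
}

#' Ensemble spread features
#'
#' M_s1 is the mean absolute difference between the model predictions and
#' the ensemble prediction, M_s2 the root-mean-square difference, and M_m
#' the range (largest minus smallest prediction). For every ensemble
#' M_s1 <= M_s2 <= M_m.
#'
#' @param modelPreds numeric vector (one molecule) or matrix (n x m).
#' @param yEns the ensemble prediction(s); computed as the unweighted mean
#'   when missing.
#' @return for a vector input a named numeric vector `(mS1, mS2, mM)`;
#'   for a matrix a data.frame with those columns.
#' @examples
#' spreadFeatures(c(10, 20, 30))   # 6.667, 8.165, 20
#' @export
spreadFeatures <- function(modelPreds, yEns = NULL) {
  vec <- is.null(dim(modelPreds))
  if (vec) modelPreds <- matrix(modelPreds, nrow = 1)
  if (ncol(modelPreds) < 2)
    stop("spread features require at least two ensemble members")
  if (is.null(yEns)) yEns <- rowMeans(modelPreds)
  dev <- modelPreds - yEns
  mS1 <- rowMeans(abs(dev))
  mS2 <- sqrt(rowMeans(dev^2))
  mM <- apply(modelPreds, 1, max) - apply(modelPreds, 1, min)
  if (vec) c(mS1 = mS1, mS2 = mS2, mM = mM)
  else data.frame(mS1 = mS1, mS2 = mS2, mM = mM)
}

#' Error threshold D_t for a satisfied fraction
#'
#' D_t is the empirical f-quantile (linear interpolation, type 7) of the
#' absolute errors: predictions with error strictly above D_t are labeled
#' unsatisfactory, so a fraction of about 1 - f of the data set is
#' flagged. With f = 0.85 (the default working point) 15 percent of the
#' predictions are unsatisfactory.
#'
#' @param absErrors numeric vector of absolute errors.
#' @param f satisfied fraction(s) in (0, 1); may be a vector such as
#'   `c(0.80, 0.85, 0.90, 0.95)`.
#' @return named numeric vector of thresholds (names are the f values).
#' @export
computeThreshold <- function(absErrors, f = 0.85) {
  if (!length(absErrors)) stop("absErrors must be non-empty")
  if (any(f <= 0 | f >= 1)) stop("f must lie strictly between 0 and 1")
  out <- quantile(absErrors, probs = f, type = 7, names = FALSE)
  names(out) <- format(f, trim = TRUE)
  out
}

#' Label predictions as unsatisfactory
#'
#' A prediction is unsatisfactory (label 1) iff its absolute error is
#' strictly greater than the threshold D_t; errors equal to the threshold
#' are satisfactory.
#'
#' @param absErrors numeric vector.
#' @param dT threshold from [computeThreshold()].
#' @return integer vector of 0/1 labels (1 = unsatisfactory).
#' @export
labelPredictions <- function(absErrors, dT) {
  as.integer(absErrors > dT)
}

#' Fit an error-distribution family
#'
#' Maximum-likelihood fits for the error-distribution diagnostics: an
#' exponential distribution on absolute errors (closed form: rate
#' lambda = 1 / mean), or normal / Cauchy distributions on signed errors
#' (Cauchy by numeric maximum likelihood). The exponential shape is what
#' ensemble prediction errors typically follow, i.e. signed errors are
#' Laplace-like rather than normal.
#'
#' @param errors numeric vector (absolute errors for "exponential",
#'   signed errors otherwise); at least 10 values.
#' @param family "exponential", "normal" or "cauchy".
#' @return list of class `uqErrorFit` with `family`, `params`, `logLik`.
#' @export
fitErrorDistribution <- function(errors,
                                 family = c("exponential", "normal",
                                            "cauchy")) {
  family <- match.arg(family)
  if (length(errors) < 10) stop("need at least 10 error samples")
  if (family == "exponential") {
    if (any(errors < 0))
      stop("exponential family applies to absolute errors (non-negative)")
    mu <- mean(errors)
    if (mu <= 0) stop("mean absolute error must be positive")
    lambda <- 1 / mu
    ll <- sum(log(lambda) - lambda * errors)
    fit <- list(family = family, params = c(lambda = lambda), logLik = ll)
  } else if (family == "normal") {
    mu <- mean(errors)
    sigma <- sqrt(mean((errors - mu)^2))  # MLE variant
    ll <- sum(dnorm(errors, mu, sigma, log = TRUE))
    fit <- list(family = family, params = c(mean = mu, sd = sigma),
                logLik = ll)
  } else {
    nll <- function(p) -sum(dcauchy(errors, p[1], exp(p[2]), log = TRUE))
    start <- c(median(errors), log(max(IQR(errors) / 2, 1e-8)))
    opt <- optim(start, nll, method = "Nelder-Mead")
    fit <- list(family = family,
                params = c(location = opt$par[1], scale = exp(opt$par[2])),
                logLik = -opt$value)
  }
  structure(fit, class = "uqErrorFit")
}

#' Tail probability of a fitted error distribution
#'
#' For the exponential fit, `P(|error| > t) = exp(-lambda t)`. For the
#' normal and Cauchy fits, the probability that the signed error falls
#' outside `[-t, t]`.
#'
#' @param fit a `uqErrorFit` from [fitErrorDistribution()].
#' @param t non-negative threshold.
#' @return probability in [0, 1].
#' @export
tailProbability <- function(fit, t) {
  stopifnot(inherits(fit, "uqErrorFit"), t >= 0)
  p <- fit$params
  switch(fit$family,
    exponential = exp(-p[["lambda"]] * t),
    normal = 1 - (pnorm(t, p[["mean"]], p[["sd"]]) -
                    pnorm(-t, p[["mean"]], p[["sd"]])),
    cauchy = 1 - (pcauchy(t, p[["location"]], p[["scale"]]) -
                    pcauchy(-t, p[["location"]], p[["scale"]])))
}

#' @importFrom stats IQR
NULL
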