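# Synthetic molecule libraries and simulated prediction ensembles with
# the statistical structure the uncertainty-estimation method assumes:
# Laplace-tailed error magnitudes driven by a latent difficulty, with a
# correlated-bias component shared across ensemble members and an
# independent per-model noise component.

.library_cache <- new.env(parent = emptyenv())

.alkyl_chains <- function(maxLen) vapply(seq_len(maxLen), function(n)
  strrep("C", n), character(1))

# Deterministic enumeration of a few thousand small molecules: linear and
# branched alkanes, alcohols, amines, ethers, halides, nitriles, acids,
# aldehydes, substituted benzenes and related rings. High-complexity
# scaffolds are deliberately rarer than plain chains, so
# chemical-difficulty coupling has sparse regions to exploit.
.enumerate_pool <- function() {
  chains <- .alkyl_chains(12)
  branched <- character(0)
  for (n in 4:10) {
    for (i in 2:(n - 2)) {
      branched <- c(branched,
                    paste0(strrep("C", i), "(C)", strrep("C", n - i)))
      if (n >= 6)
        branched <- c(branched,
                      paste0(strrep("C", i), "(CC)", strrep("C", n - i)))
    }
  }
  bases <- c(chains[2:10], branched)
  suffixes <- c("O", "N", "F", "Cl", "Br", "C#N", "C(=O)O", "C=O", "OC",
                "OCC")
  prefixes <- c("O", "N", "F", "Cl", "Br")
  mono <- as.vector(outer(bases, suffixes, paste0))
  di <- as.vector(outer(prefixes, as.vector(outer(bases, suffixes, paste0)),
                        paste0))
  ethers <- as.vector(outer(chains[1:6],
                            as.vector(outer("O", chains[1:6], paste0)),
                            paste0))
  amines <- as.vector(outer(chains[1:6],
                            as.vector(outer("N", chains[1:5], paste0)),
                            paste0))
  subs <- c("C", "CC", "CCC", "CCCC", "CC(C)C", "O", "OC", "N", "F",
            "Cl", "Br", "C#N", "C(=O)O", "C=O")
  # written before an aromatic/ring atom only groups that keep valences
  # legal in prefix position
  subsPre <- setdiff(subs, c("C=O", "C#N"))
  benzMono <- paste0(subsPre, "c1ccccc1")
  benzPara <- as.vector(outer(subsPre, subs, function(a, b)
    paste0(a, "c1ccc(", b, ")cc1")))
  benzMeta <- as.vector(outer(subsPre[1:8], subs[1:8], function(a, b)
    paste0(a, "c1cccc(", b, ")c1")))
  rings <- c("C1CCCCC1", "C1CCCC1", "c1ccncc1", "c1ccoc1", "c1ccsc1")
  ringSub <- as.vector(outer(subsPre, rings, function(s, r) paste0(s, r)))
  unique(c(chains, branched, mono, di, ethers, amines, benzMono,
           benzPara, benzMeta, rings, ringSub))
}

.standardized_pool <- function() {
  if (!exists("pool", envir = .library_cache)) {
    raw <- .enumerate_pool()
    can <- tryCatch(standardizeSmiles(raw), error = function(e) NULL)
    if (is.null(can)) {
      can <- vapply(raw, function(s)
        tryCatch(standardizeSmiles(s), error = function(e) NA_character_),
        character(1))
      can <- can[!is.na(can)]
    }
    can <- filterSupported(unique(can))$kept
    assign("pool", can, envir = .library_cache)
  }
  get("pool", envir = .library_cache)
}

#' Generate a synthetic molecule library
#'
#' Draws `n` unique, valid, filter-passing canonical SMILES from a
#' deterministic combinatorial enumeration of small organic molecules
#' (alkanes, alcohols, amines, ethers, halides, nitriles, acids,
#' substituted benzenes and small rings).
#'
#' @param n number of molecules.
#' @param seed integer seed for the subsample.
#' @return character vector of `n` canonical SMILES.
#' @export
generateMoleculeLibrary <- function(n, seed = 1L) {
  pool <- .standardized_pool()
  if (n > length(pool))
    stop(sprintf("library capacity is %d molecules; %d requested",
                 length(pool), n))
  withSeed(seed, sort(sample(pool, n)))
}

#' Simulate a true molecular property
#'
#' A retention-index-like surrogate: a baseline plus contributions from
#' the heavy-atom and heteroatom counts plus smooth molecule-specific
#' noise. Values are positive and deterministic given the seed.
#'
#' @param smilesList character vector of SMILES.
#' @param seed integer seed.
#' @param a,b heavy-atom and heteroatom coefficients.
#' @return numeric vector of property values.
#' @export
simulateTrueProperty <- function(smilesList, seed = 1L, a = 20, b = 35) {
  toks <- lapply(smilesList, tokenizeSmiles)
  heavy <- vapply(toks, function(t) length(t$elements), numeric(1))
  hetero <- vapply(toks, function(t) sum(t$elements != "C"), numeric(1))
  noise <- withSeed(seed, rnorm(length(smilesList), 0, 15))
  pmax(100 + a * heavy + b * hetero + noise, 1)
}

#' Simulation configuration for synthetic ensembles
#'
#' @param mModels ensemble size m (>= 2).
#' @param s0 base error scale, property units.
#' @param gamma difficulty coefficient (>= 0): the per-molecule error
#'   scale is `s0 * exp(gamma * u)` for latent difficulty u in [0, 1].
#' @param kappa correlated-bias share in [0, 1]: the fraction of the
#'   error scale shared by all ensemble members; `tau = 1 - kappa` is the
#'   independent per-model share.
#' @param tail "laplace" (exponential error magnitudes) or "normal".
#' @param seed integer seed.
#' @return validated list of class `uqSimConfig`.
#' @export
simulationConfig <- function(mModels = 5L, s0 = 15, gamma = 2,
                             kappa = 0.5, tail = c("laplace", "normal"),
                             seed = 1L) {
  tail <- match.arg(tail)
  if (mModels < 2) stop("ensemble simulation requires m >= 2 models")
  if (s0 < 0 || gamma < 0) stop("scales must be non-negative")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  structure(list(mModels = as.integer(mModels), s0 = s0, gamma = gamma,
                 kappa = kappa, tau = 1 - kappa, tail = tail,
                 seed = as.integer(seed)),
            class = "uqSimConfig")
}

# scale parameter = mean absolute value for both tail families
.rtail <- function(n, scale, tail) {
  if (tail == "laplace") scale * rexp(n) * sample(c(-1, 1), n, replace = TRUE)
  else rnorm(n, 0, scale * sqrt(pi / 2))
}

#' Simulate ensemble predictions with latent difficulty
#'
#' For each molecule a latent difficulty `u ~ Uniform(0, 1)` (or a
#' supplied vector, e.g. from [chemicalDifficulty()]) sets the error
#' scale `s = s0 * exp(gamma * u)`. A shared bias with mean magnitude
#' `kappa * s` (identical across the m members) plus independent
#' per-model noise with mean magnitude `(1 - kappa) * s` is added to the
#' true value.
#'
#' @param yTrue numeric vector of true property values.
#' @param config a `uqSimConfig` from [simulationConfig()].
#' @param u optional difficulty vector in [0, 1].
#' @param seed overrides `config$seed`.
#' @return list with `predictions` (n x m matrix), `u`, `scale` and
#'   `bias` (the latent values, for recovery tests).
#' @export
simulateEnsemble <- function(yTrue, config = simulationConfig(),
                             u = NULL, seed = NULL) {
  stopifnot(inherits(config, "uqSimConfig"))
  n <- length(yTrue)
  if (is.null(seed)) seed <- config$seed
  m <- config$mModels
  withSeed(seed, {
    if (is.null(u)) u <- runif(n)
    s <- config$s0 * exp(config$gamma * u)
    bias <- .rtail(n, config$kappa * s, config$tail)
    noise <- matrix(.rtail(n * m, rep(config$tau * s, m), config$tail),
                    n, m)
    preds <- yTrue + bias + noise
    list(predictions = preds, u = u, scale = s, bias = bias)
  })
}

#' Chemistry-derived difficulty
#'
#' Maps molecular complexity (size, heteroatom and ring content) to a
#' difficulty rank in [0, 1]; complex, rare molecules come out hard.
#' Used to couple the simulated error scale to the same chemical-space
#' structure the similarity and cluster features see.
#'
#' @param smilesList character vector of SMILES.
#' @return numeric vector in [0, 1].
#' @export
chemicalDifficulty <- function(smilesList) {
  toks <- lapply(smilesList, tokenizeSmiles)
  score <- vapply(toks, function(t) {
    length(t$elements) + 2.5 * sum(t$elements != "C") + 2 * t$nRings
  }, numeric(1))
  (rank(score, ties.method = "average") - 0.5) / length(score)
}

#' Toy nearest-neighbor base regressor
#'
#' A deterministic 1-nearest-neighbor regressor over descriptor
#' principal components, implementing the `fit`/`predict` interface that
#' [crossvalPipeline()] consumes. With `dropFraction > 0` a seeded
#' bootstrap removes that fraction of training molecules, which is how
#' ensemble diversity is generated for otherwise deterministic models.
#'
#' @param seed integer seed for the bootstrap drop.
#' @param dropFraction fraction of training molecules removed (default
#'   0, i.e. exact memorization of the training set).
#' @return list with `fit(smiles, y)` and `predict(model, smiles)`.
#' @export
toyBaseRegressor <- function(seed = 1L, dropFraction = 0) {
  fit <- function(smiles, y) {
    if (!length(smiles)) stop("empty training set")
    keep <- seq_along(smiles)
    if (dropFraction > 0) {
      nKeep <- max(2L, round(length(smiles) * (1 - dropFraction)))
      keep <- withSeed(seed, sort(sample(seq_along(smiles), nKeep)))
    }
    smiles <- smiles[keep]; y <- y[keep]
    desc <- computeDescriptors(smiles)
    scaler <- fitScaler(desc)
    pca <- fitPCA(applyScaler(desc, scaler), cMax = 20L)
    list(pcs = projectPCA(applyScaler(desc, scaler), pca), y = y,
         scaler = scaler, pca = pca)
  }
  predict <- function(model, smiles) {
    desc <- computeDescriptors(smiles)
    pcs <- projectPCA(applyScaler(desc, model$scaler), model$pca)
    d2 <- outer(rowSums(pcs^2), rowSums(model$pcs^2), "+") -
      2 * pcs %*% t(model$pcs)
    model$y[max.col(-d2, ties.method = "first")]
  }
  list(fit = fit, predict = predict)
}

#' Toy regressor ensemble
#'
#' @param m ensemble size.
#' @param seed base seed; member j uses `seed + j`.
#' @param dropFraction bootstrap drop per member (default 0.1).
#' @return list of m [toyBaseRegressor()] interfaces.
#' @export
toyEnsemble <- function(m = 4L, seed = 1L, dropFraction = 0.1) {
  lapply(seq_len(m), function(j)
    toyBaseRegressor(seed = seed + j, dropFraction = dropFraction))
}

#' Run the full synthetic uncertainty-estimation study
#'
#' Generates a molecule library, simulates true values and
#' difficulty-coupled ensemble predictions, splits the library into a
#' training reference (biased towards easy, common molecules, as real
#' training sets are) and a query set, builds the [UEModel-class] on the
#' reference, featurizes the queries, labels the worst error fraction,
#' and fits/evaluates the meta-classifiers.
#'
#' @param n library size.
#' @param seed integer master seed.
#' @param config a `uqSimConfig`.
#' @param refFraction fraction of molecules used as training reference.
#' @param refBias exponential down-weighting of difficult molecules in
#'   the reference draw (0 = unbiased).
#' @param k number of clusters.
#' @param f satisfied fraction defining the error threshold D_t.
#' @param pThreshold decision probability threshold.
#' @param boosting also fit the gradient-boosting meta-model.
#' @return list with the feature table, labels, fitted models, single
#'   feature and meta-model AUCs, threshold, and evaluation reports.
#' @export
simulateStudy <- function(n = 2000L, seed = 1L,
                          config = simulationConfig(),
                          refFraction = 0.65, refBias = 3, k = 20L,
                          f = 0.85, pThreshold = 0.15,
                          boosting = FALSE) {
  lib <- generateMoleculeLibrary(n, seed)
  y <- simulateTrueProperty(lib, seed + 1L)
  u <- chemicalDifficulty(lib)
  sim <- simulateEnsemble(y, config, u = u, seed = seed + 2L)
  nRef <- round(n * refFraction)
  refIdx <- withSeed(seed + 3L, {
    w <- exp(-refBias * u)
    sort(sample.int(n, nRef, prob = w))
  })
  qIdx <- setdiff(seq_len(n), refIdx)
  refPS <- PredictionSet(lib[refIdx], y[refIdx],
                         sim$predictions[refIdx, , drop = FALSE])
  queryPS <- PredictionSet(lib[qIdx], y[qIdx],
                           sim$predictions[qIdx, , drop = FALSE])
  model <- buildUEModel(refPS, k = k, seed = seed)
  feats <- computeUEFeatures(queryPS, model)
  yEns <- feats$yEns
  absErr <- abs(yEns - y[qIdx])
  dT <- computeThreshold(absErr, f)
  labels <- labelPredictions(absErr, dT)
  X <- assembleFeatures(feats, mode = "logistic")
  logit <- fitLogisticMeta(X, labels, pThreshold = pThreshold)
  probs <- predictProb(logit, X)
  # per-feature AUCs, oriented so larger score = more likely unsatisfactory
  orient <- c(maeCl = 1, mdaeCl = 1, dCl = 1, sMaxT = -1, sMaxC = -1,
              sMaxE = 1, mS1 = 1, mS2 = 1, mM = 1)
  singleAUC <- vapply(names(orient), function(fname)
    rocAUC(orient[[fname]] * feats[[fname]], labels), numeric(1))
  out <- list(
    smiles = lib[qIdx], features = feats, labels = labels,
    absErrors = absErr, dT = dT, u = u[qIdx],
    model = model, logistic = logit,
    probabilities = probs,
    singleFeatureAUC = singleAUC,
    aucLogistic = rocAUC(probs, labels),
    evaluation = evaluateFlagging(probs, labels, pThreshold))
  if (boosting) {
    # the tree model can memorize the table, so its accuracy is measured
    # with 5-fold cross-validated predictions (molecule-level rows)
    Xf <- assembleFeatures(feats, mode = "full", k = k)
    cvFold <- assignFolds(lib[qIdx], nFolds = 5L, seed = seed + 4L)
    pgb <- numeric(length(labels))
    for (fold in 0:4) {
      tr <- cvFold != fold
      gbf <- fitBoostingMeta(Xf[tr, , drop = FALSE], labels[tr],
                             seed = seed)
      pgb[!tr] <- predictProb(gbf, Xf[!tr, , drop = FALSE])
    }
    out$boosting <- fitBoostingMeta(Xf, labels, seed = seed,
                                    pThreshold = pThreshold)
    out$aucBoosting <- rocAUC(pgb, labels)
    out$evaluationBoosting <- evaluateFlagging(pgb, labels, pThreshold)
  }
  out
}
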