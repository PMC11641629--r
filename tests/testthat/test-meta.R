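.fakeUE <- function(n, k = 20, seed = 1, mcs = FALSE) {
  withr::with_seed(seed, {
    ue <- data.frame(
      nCl = sample.int(k, n, replace = TRUE),
      maeCl = runif(n, 10, 60), mdaeCl = runif(n, 5, 40),
      dCl = runif(n, 0, 3),
      sMaxT = runif(n), sMaxC = runif(n), sMaxE = runif(n, 0, 5),
      mS1 = runif(n, 0, 50), mS2 = runif(n, 0, 60), mM = runif(n, 0, 120),
      yEns = runif(n, 500, 2500))
    if (mcs) ue$sMaxMcs <- runif(n)
    ue
  })
}

test_that("feature assembly produces the documented column sets", {
  ue <- .fakeUE(30)
  X <- assembleFeatures(ue, "logistic")
  expect_identical(colnames(X),
                   c("maeCl", "dCl", "sMaxT", "sMaxE", "mS1", "yEnsK"))
  expect_identical(ncol(X), 6L)
  expect_equal(X[, "yEnsK"], ue$yEns / 1000)

  Xf <- assembleFeatures(ue, "full", k = 20)
  expect_identical(ncol(Xf), 9L + 20L + 1L)   # base + one-hot + yEns
  Xm <- assembleFeatures(.fakeUE(30, mcs = TRUE), "full", k = 20)
  expect_identical(ncol(Xm), 10L + 20L + 1L)
  expect_true("sMaxMcs" %in% colnames(Xm))
  # one-hot encoding is exact
  expect_equal(unname(rowSums(Xf[, paste0("nCl_", 1:20)])), rep(1, 30))
  expect_error(assembleFeatures(ue[, -2], "logistic"), "maeCl")
})

test_that("intercept-only logistic fit matches the closed form", {
  labels <- rep(c(1, 0), c(30, 70))
  fit <- fitLogisticMeta(matrix(numeric(0), 100, 0), labels)
  expect_equal(unname(fit@coefficients[1]), log(0.3 / 0.7),
               tolerance = 1e-6)
})

test_that("pure-noise features stay within 3 standard errors of zero", {
  set.seed(61)
  n <- 10000
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  p <- 1 / (1 + exp(-(-1 + 1.5 * x[, "signal"])))
  labels <- rbinom(n, 1, p)
  fit <- fitLogisticMeta(x, labels)
  expect_lt(abs(fit@coefficients["noise"]) / fit@se["noise"], 3)
  expect_gt(abs(fit@coefficients["signal"]) / fit@se["signal"], 3)
})

test_that("logistic regression recovers known coefficients", {
  set.seed(71)
  n <- 20000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  eta <- -1 + 2 * x[, 1]
  labels <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fitLogisticMeta(x, labels)
  expect_lt(abs(fit@coefficients[1] - (-1)) / fit@se[1], 3)
  expect_lt(abs(fit@coefficients["x"] - 2) / fit@se["x"], 3)
  expect_true(all(fit@se > 0))
})

test_that("degenerate logistic inputs raise errors", {
  x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fitLogisticMeta(x, rep(1, 100)), "both classes")
  expect_error(fitLogisticMeta(x[1:30, , drop = FALSE],
                               rep(c(0, 1), 15)), "at least 50")
  sep <- matrix(c(1:50, 101:150), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fitLogisticMeta(sep, rep(c(0, 1), each = 50)),
               "separation")
})

test_that("gradient boosting concentrates gain on informative features", {
  set.seed(81)
  n <- 2000
  x <- cbind(inf = rnorm(n), c1 = rep(1, n), c2 = rep(0, n),
             c3 = rep(2, n))
  labels <- as.integer(x[, "inf"] + rnorm(n, 0, 0.3) > 0)
  fit <- fitBoostingMeta(x, labels, seed = 5)
  expect_s4_class(fit, "MetaClassifier")
  imp <- fit@importance
  expect_gt(imp$Gain[imp$Feature == "inf"], 0.95)
  # determinism under the seed
  fit2 <- fitBoostingMeta(x, labels, seed = 5)
  expect_identical(fit@importance, fit2@importance)
  p <- predictProb(fit, x)
  expect_true(all(p > 0 & p < 1))
})

test_that("ROC-AUC equals the Mann-Whitney concordance probability", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAUC(1:4, rep(1, 4)), "both classes")

  # brute force over positive-negative pairs, ties count one half
  set.seed(91)
  scores <- sample(seq(0, 1, 0.1), 60, replace = TRUE)
  labels <- rbinom(60, 1, 0.4)
  pos <- which(labels == 1); neg <- which(labels == 0)
  conc <- 0
  for (i in pos) for (j in neg)
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(rocAUC(scores, labels), conc / (length(pos) * length(neg)))
  # invariant under strictly monotone transforms
  expect_equal(rocAUC(exp(3 * scores) - 1, labels), rocAUC(scores, labels))
})

test_that("ROC-AUC matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(95)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAUC(scores, labels), ref, tolerance = 1e-12)
})

test_that("evaluation reports are internally consistent", {
  set.seed(101)
  probs <- runif(400)
  labels <- rbinom(400, 1, probs)
  rep <- evaluateFlagging(probs, labels, pThreshold = 0.15)
  cc <- confusionCounts(rep)
  expect_equal(sum(cc), 400)
  m <- metrics(rep)
  expect_equal(unname(m["precision"]), cc[["tp"]] / (cc[["tp"]] + cc[["fp"]]))
  expect_equal(unname(m["recall"]), cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]))
  expect_equal(unname(m["f1"]),
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  expect_equal(unname(m["accuracy"]), (cc[["tp"]] + cc[["tn"]]) / 400)
  # positive call iff probability >= threshold
  expect_equal(cc[["tp"]] + cc[["fp"]], sum(probs >= 0.15))

  perfect <- evaluateFlagging(labels, labels, pThreshold = 0.5)
  expect_equal(unname(metrics(perfect)[c("f1", "precision", "recall")]),
               c(1, 1, 1))
  expect_warning(none <- evaluateFlagging(probs, labels, pThreshold = 2),
                 "precision")
  expect_equal(confusionCounts(none)[["tp"]], 0)
  expect_equal(metrics(none)[["precision"]], 0)
})

test_that("binned diagnostics partition the rows", {
  set.seed(111)
  x <- runif(200, 0, 10)
  err <- x + rnorm(200, 0, 0.2)
  lab <- as.integer(err > quantile(err, 0.85))
  d <- binnedDiagnostics(x, err, lab, nBins = 8)
  expect_identical(nrow(d), 8L)
  expect_equal(sum(d$n), 200)
  occupied <- d[d$n > 0, ]
  expect_true(all(diff(occupied$mae) > 0))   # error grows with the feature

  dc <- binnedDiagnostics(rep(3, 50), err[1:50], lab[1:50], nBins = 5)
  expect_equal(dc$n, c(50, 0, 0, 0, 0))
  expect_error(binnedDiagnostics(1:3, 1:3, c(0, 1, 0), nBins = 5),
               "at least")
})
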