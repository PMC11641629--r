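test_that("k-means finds the optimal 2-cluster solution of a hand case", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit <- fitKMeans(x, k = 2, seed = 4, nInit = 5)
  got <- centroids(fit)[order(centroids(fit)[, 1]), ]
  expect_equal(unname(got), rbind(c(0, 0.5), c(10, 0.5)))
  # matches the exhaustive minimum-WCSS partition search
  expect_equal(fit@wcss, kmeansOracle(x, 2), tolerance = 1e-12)
})

test_that("k-means oracle agreement on random small instances", {
  set.seed(50)
  for (rep in 1:5) {
    x <- matrix(rnorm(14), ncol = 2)
    fit <- fitKMeans(x, k = 3, seed = rep, nInit = 25)
    expect_equal(fit@wcss, kmeansOracle(x, 3), tolerance = 1e-8)
  }
})

test_that("k = n gives zero WCSS; WCSS never increases across iterations", {
  set.seed(8)
  x <- matrix(rnorm(20), ncol = 2)
  fit <- fitKMeans(x, k = 10, seed = 2)
  expect_lt(fit@wcss, 1e-12)

  x2 <- matrix(rnorm(400), ncol = 2)
  fit2 <- fitKMeans(x2, k = 6, seed = 3, nInit = 3)
  expect_true(all(diff(fit2@wcssTrace) <= 1e-9))
  expect_error(fitKMeans(x[1:3, ], k = 5), "at least k")
})

test_that("k-means is reproducible and centroids equal member means", {
  set.seed(12)
  x <- matrix(rnorm(300), ncol = 3)
  f1 <- fitKMeans(x, k = 5, seed = 77)
  f2 <- fitKMeans(x, k = 5, seed = 77)
  expect_identical(centroids(f1), centroids(f2))
  expect_identical(attr(f1, "assign"), attr(f2, "assign"))

  asg <- attr(f1, "assign")
  expect_identical(as.integer(tabulate(asg, 5)), f1@size)
  expect_equal(sum(f1@size), nrow(x))
  for (j in 1:5) {
    expect_equal(unname(centroids(f1)[j, ]),
                 unname(colMeans(x[asg == j, , drop = FALSE])),
                 tolerance = 1e-8)
  }
  expect_true(all(f1@dMean[f1@size >= 2] > 0))
})

test_that("well-separated blobs are recovered for every seed", {
  set.seed(99)
  x <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
             matrix(rnorm(60, 20, 0.2), ncol = 2))
  truth <- rep(1:2, each = 30)
  for (s in 1:20) {
    fit <- fitKMeans(x, k = 2, seed = s, nInit = 5)
    asg <- attr(fit, "assign")
    agree <- max(mean(asg == truth), mean(asg == 3 - truth))
    expect_equal(agree, 1, info = paste("seed", s))
  }
  # cross-check WCSS against the reference implementation
  ref <- stats::kmeans(x, 2, nstart = 5)
  expect_equal(fitKMeans(x, k = 2, seed = 1)@wcss, ref$tot.withinss,
               tolerance = 1e-8)
})

test_that("cluster assignment computes D and D_cl with tie-breaking", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit <- fitKMeans(x, k = 2, seed = 1)
  ctr <- centroids(fit)
  a <- assignCluster(ctr[1, ], fit)
  expect_equal(a$D, 0)
  expect_equal(a$dCl, 0)

  target <- which(abs(ctr[, 1] - 10) < 1e-9)
  b <- assignCluster(c(9, 0), fit)
  expect_identical(b$cluster, as.integer(target))
  expect_equal(b$D, sqrt(1.25))

  mid <- colMeans(ctr)   # equidistant between both centroids
  expect_identical(assignCluster(mid, fit)$cluster, 1L)
})

test_that("cluster error statistics and global fallback", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1), c(10, 0.5))
  fit <- fitKMeans(x, k = 2, seed = 1)
  asg <- attr(fit, "assign")
  lowCluster <- asg[1]
  # craft per-cluster errors: (1, 3) in one cluster, (1, 2, 9) in the other
  errs <- numeric(5)
  errs[asg == lowCluster] <- c(1, 3)
  errs[asg != lowCluster] <- c(1, 2, 9)
  fit2 <- clusterErrorStats(fit, asg, errs)
  expect_equal(fit2@maeCl[lowCluster], 2)
  expect_equal(fit2@mdaeCl[lowCluster], 2)
  other <- 3 - lowCluster
  expect_equal(fit2@maeCl[other], 4)
  expect_equal(fit2@mdaeCl[other], 2)

  # a cluster that receives no training members falls back to the
  # global statistics with a warning
  expect_warning(
    fit3 <- clusterErrorStats(fit, rep(lowCluster, 5), 1:5),
    "fall back")
  expect_equal(fit3@maeCl[other], mean(1:5))
  expect_equal(fit3@mdaeCl[other], 3)
  expect_error(clusterErrorStats(fit, integer(0), numeric(0)), "empty")
})

test_that("distance-quartile profiles split and aggregate correctly", {
  fit <- fitKMeans(matrix(rnorm(40), ncol = 2), k = 2, seed = 1)
  asg <- rep(1L, 8)
  d <- 1:8
  prof <- distanceQuartileProfile(fit, asg, d, abs_errors <- as.numeric(d))
  q1 <- prof[prof$cluster == 1, ]
  expect_equal(q1$mae, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(q1$n, rep(2L, 4))

  profC <- distanceQuartileProfile(fit, asg, d, rep(2, 8))
  expect_equal(profC$mae[profC$cluster == 1], rep(2, 4))

  expect_warning(
    small <- distanceQuartileProfile(fit, c(1L, 1L, 1L, 2L, 2L, 2L),
                                     1:6, 1:6),
    "fewer than 4")
  expect_identical(nrow(small), 0L)

  # error growing with distance implies increasing quartile MAE
  set.seed(5)
  d2 <- runif(40, 0, 10)
  e2 <- d2 + rnorm(40, 0, 0.05)
  prof2 <- distanceQuartileProfile(fit, rep(1L, 40), d2, e2)
  expect_true(all(diff(prof2$mae[prof2$cluster == 1]) > 0))
})
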