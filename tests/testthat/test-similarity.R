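.namedFp <- function(pos, counts = rep(1, length(pos))) {
  out <- as.numeric(counts)
  names(out) <- as.character(pos)
  out
}

test_that("Tanimoto similarity follows the on-set definition", {
  fp <- countFingerprint("CCO")
  expect_equal(tanimotoSimilarity(fp, fp), 1)
  expect_equal(tanimotoSimilarity(.namedFp(c(1, 2)), .namedFp(c(3, 4))), 0)
  expect_equal(tanimotoSimilarity(.namedFp(c(1, 2)), .namedFp(c(1, 3))),
               1 / 3)
  # counts are binarized: multiplicities do not change the value
  expect_equal(tanimotoSimilarity(.namedFp(c(1, 2), c(5, 9)),
                                  .namedFp(c(1, 3), c(2, 2))), 1 / 3)
  expect_equal(tanimotoSimilarity(numeric(0), numeric(0)), 0)
})

test_that("cosine similarity uses the raw counts", {
  a <- c(2, 1, 0); b <- c(4, 2, 0)
  expect_equal(cosineSimilarity(a, b), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 3)), 0)
  expect_equal(cosineSimilarity(c(2, 1, 0), c(1, 0, 3)), 2 / sqrt(50))
  expect_warning(z <- cosineSimilarity(c(0, 0), c(1, 1)), "zero")
  expect_equal(z, 0)
})

test_that("Euclidean distance behaves as an L2 metric", {
  expect_equal(euclideanDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_error(euclideanDistance(1:3, 1:2), "mismatch")
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5); cc <- rnorm(5)
    expect_equal(euclideanDistance(a, b), euclideanDistance(b, a))
    expect_lte(euclideanDistance(a, cc),
               euclideanDistance(a, b) + euclideanDistance(b, cc) + 1e-12)
  }
})

test_that("MCS similarity hand cases hold", {
  self <- mcsSimilarity("c1ccccc1O", "c1ccccc1O")
  expect_equal(self$S, 1)
  expect_equal(self$X, self$A)

  m <- mcsSimilarity("CC", "CCC")
  expect_equal(m$A, 3)      # 2 atoms + 1 bond
  expect_equal(m$B, 5)      # 3 atoms + 2 bonds
  expect_equal(m$X, 3)
  expect_equal(m$S, 0.6)

  # aromatic atoms never match aliphatic atoms
  expect_equal(mcsSimilarity("c1ccccc1", "C1CCCCC1")$S, 0)
  # ring bonds only match ring bonds: hexane shares only atoms (no
  # bonds) with cyclohexane under the ring-matching rule
  hex <- mcsSimilarity("CCCCCC", "C1CCCCC1")
  expect_equal(hex$X, 1)
  # bond order must agree; the common substructure must stay
  # connected, so only a single atom remains
  expect_equal(mcsSimilarity("C=C", "CC")$X, 1)
})

test_that("MCS agrees with the exhaustive oracle on diverse pairs", {
  fx <- mcsFixtureSmiles()
  set.seed(19)
  pairs <- cbind(sample(length(fx), 25, replace = TRUE),
                 sample(length(fx), 25, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    a <- fx[pairs[r, 1]]; b <- fx[pairs[r, 2]]
    o <- mcsOracle(a, b)
    m <- mcsSimilarity(a, b)
    expect_equal(m$X, o$X, info = paste(a, b))
    expect_equal(m$S, o$S, info = paste(a, b))
  }
})

test_that("MCS is symmetric and bounded", {
  fx <- mcsFixtureSmiles()[c(2, 7, 12, 22, 28)]
  for (a in fx) for (b in fx) {
    sAB <- mcsSimilarity(a, b)$S
    sBA <- mcsSimilarity(b, a)$S
    expect_equal(sAB, sBA)
    expect_gte(sAB, 0); expect_lte(sAB, 1)
  }
})

test_that("MCS timeout returns a flagged lower bound", {
  # near-zero budget: search must stop early and flag the result
  a <- standardizeSmiles("CC(C)CC(C)CC(C)CC(C)C")
  b <- standardizeSmiles("CC(C)CC(C)CC(C)CC(C)CC")
  res <- mcsSimilarity(a, b, timeout = 1e-4)
  expect_true(res$timedOut)
  expect_gte(res$S, 0)
  expect_lte(res$S, 1)
  full <- mcsSimilarity(a, b, timeout = 60)
  expect_false(full$timedOut)
  expect_lte(res$S, full$S + 1e-12)
})

.makeReference <- function(smi) {
  desc <- computeDescriptors(smi)
  sc <- fitScaler(desc)
  pca <- fitPCA(applyScaler(desc, sc), cMax = 5)
  SimilarityReference(smi, countFingerprintMatrix(smi),
                      projectPCA(applyScaler(desc, sc), pca))
}

test_that("nearest similarity equals a brute-force linear scan", {
  refSmi <- generateMoleculeLibrary(50, seed = 21)
  ref <- .makeReference(refSmi)
  qSmi <- generateMoleculeLibrary(60, seed = 22)
  qSmi <- setdiff(qSmi, refSmi)[1:5]
  qDesc <- computeDescriptors(qSmi)
  # rebuild the query-side features against the reference scaler/pca
  desc <- computeDescriptors(refSmi)
  sc <- fitScaler(desc)
  pca <- fitPCA(applyScaler(desc, sc), cMax = 5)
  qPcs <- projectPCA(applyScaler(qDesc, sc), pca)
  for (qi in seq_along(qSmi)) {
    qfp <- countFingerprint(qSmi[qi])
    q <- list(fp = qfp, pc = qPcs[qi, ], smiles = qSmi[qi])
    # brute force with the pairwise primitives
    bestT <- bestC <- 0; bestE <- Inf
    for (ri in seq_along(refSmi)) {
      rfp <- countFingerprint(refSmi[ri])
      bestT <- max(bestT, tanimotoSimilarity(qfp, rfp))
      bestC <- max(bestC, cosineSimilarity(qfp, rfp))
      bestE <- min(bestE, euclideanDistance(q$pc, ref@pcs[ri, ]))
    }
    expect_equal(nearestSimilarity(q, ref, "tanimoto"), bestT)
    expect_equal(nearestSimilarity(q, ref, "cosine"), bestC)
    expect_equal(nearestSimilarity(q, ref, "euclidean"), bestE)
  }
})

test_that("nearest similarity handles self-hits and tiny references", {
  refSmi <- standardizeSmiles(c("CCO", "CCC", "c1ccccc1"))
  ref <- .makeReference(refSmi)
  q <- list(fp = countFingerprint("CCO"),
            pc = ref@pcs[1, ], smiles = "CCO")
  expect_equal(nearestSimilarity(q, ref, "tanimoto"), 1)
  expect_equal(nearestSimilarity(q, ref, "euclidean"), 0)
  # excludeSelf drops the identical reference molecule
  expect_lt(nearestSimilarity(q, ref, "tanimoto", excludeSelf = TRUE), 1)

  one <- .makeReference(standardizeSmiles(c("CCO", "CCC")))
  oneRef <- SimilarityReference(one@smiles[1],
                                one@fingerprints[1, , drop = FALSE],
                                one@pcs[1, , drop = FALSE])
  q2 <- list(fp = countFingerprint("CCC"), pc = one@pcs[2, ],
             smiles = "CCC")
  expect_equal(nearestSimilarity(q2, oneRef, "tanimoto"),
               tanimotoSimilarity(countFingerprint("CCC"),
                                  countFingerprint("CCO")))
  # dropping the only molecule leaves an empty reference
  q3 <- list(fp = countFingerprint("CCO"), pc = one@pcs[1, ],
             smiles = one@smiles[1])
  expect_error(nearestSimilarity(q3, oneRef, "tanimoto",
                                 excludeSelf = TRUE), "empty")
})

test_that("adding reference molecules is monotone for S_max", {
  refSmi <- generateMoleculeLibrary(30, seed = 31)
  refSmall <- .makeReference(refSmi[1:10])
  refBig <- .makeReference(refSmi)
  # use the big reference's PC space for both scans
  refSmallAligned <- SimilarityReference(
    refSmi[1:10], refSmall@fingerprints, refBig@pcs[1:10, , drop = FALSE])
  q <- list(fp = countFingerprint("CCCCO"),
            pc = rep(0, ncol(refBig@pcs)), smiles = "CCCCO")
  expect_gte(nearestSimilarity(q, refBig, "tanimoto"),
             nearestSimilarity(q, refSmallAligned, "tanimoto"))
  expect_lte(nearestSimilarity(q, refBig, "euclidean"),
             nearestSimilarity(q, refSmallAligned, "euclidean"))
})
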