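test_that("standardization maps identical structures to identical strings", {
  expect_identical(standardizeSmiles("OCC"), standardizeSmiles("CCO"))
  # stereochemistry is stripped before canonicalization
  expect_identical(standardizeSmiles("C[C@H](O)CC"),
                   standardizeSmiles("CC(O)CC"))
  expect_identical(standardizeSmiles("F/C=C/F"),
                   standardizeSmiles("FC=CF"))
})

test_that("standardization is idempotent and vectorized", {
  raw <- c("OCC", "c1ccccc1O", "CC(=O)OC", "C[C@@H](N)C(=O)O",
           "ClC(Cl)Cl", "CC(C)(C)c1ccc(O)cc1")
  can <- standardizeSmiles(raw)
  expect_length(can, length(raw))
  expect_identical(standardizeSmiles(can), can)
})

test_that("unparsable SMILES raise a structured parse error", {
  err <- tryCatch(standardizeSmiles("C1CC"), error = identity)
  expect_s3_class(err, "molUQ_parse_error")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
  # failure inside a batch is attributed to the offending string
  err2 <- tryCatch(standardizeSmiles(c("CCO", "C1CC", "CCN")),
                   error = identity)
  expect_s3_class(err2, "molUQ_parse_error")
  expect_match(conditionMessage(err2), "C1CC", fixed = TRUE)
  expect_error(standardizeSmiles(character(0)))
  expect_error(standardizeSmiles(""))
})

test_that("filtering applies the element, length and ring rules", {
  res <- filterSupported(c("CCO", "CC[Se]C", "c1ccccc1"))
  expect_identical(res$kept, c("CCO", "c1ccccc1"))
  expect_identical(res$rejected$reason, "element")

  long <- strrep("C", 251)
  expect_identical(filterSupported(long)$rejected$reason, "length")
  expect_identical(filterSupported(strrep("C", 250))$rejected$reason,
                   character(0))

  # 10 smallest-set-of-smallest-rings rings: rejected
  tenRings <- paste(rep("C1CC1", 10), collapse = ".")
  expect_identical(filterSupported(tenRings)$rejected$reason, "rings")
  nineRings <- paste(rep("C1CC1", 9), collapse = ".")
  expect_identical(filterSupported(nineRings)$rejected,
                   data.frame(smiles = character(0),
                              reason = character(0)))
})

test_that("tokenizer ring count agrees with graph circuit rank", {
  mols <- standardizeSmiles(c("C1CC1", "c1ccc2ccccc2c1", "CC(C)CC",
                              "C1CC2CCC1C2", "c1ccccc1C1CCCC1"))
  for (smi in mols) {
    g <- molUQ:::molGraph(smi)
    circuitRank <- nrow(g$bonds) - g$n + 1L   # connected molecules
    expect_equal(molUQ:::tokenizeSmiles(smi)$nRings, circuitRank,
                 info = smi)
  }
})

test_that("filtering is total and idempotent on the kept set", {
  input <- c("CCO", "CC[Se]C", "invalid(((", "c1ccccc1", strrep("C", 260))
  res <- filterSupported(input)
  expect_setequal(res$rejected$reason, c("element", "parse", "length"))
  again <- filterSupported(res$kept)
  expect_identical(again$kept, res$kept)
  expect_identical(nrow(again$rejected), 0L)
})

test_that("deduplication keeps one record per SMILES, reproducibly", {
  ps <- PredictionSet(c("CCO", "CCC", "CCO"), c(1, 2, 3),
                      matrix(1:6, ncol = 2))
  d1 <- deduplicateEntries(ps, seed = 5)
  expect_identical(sort(smiles(d1)), c("CCC", "CCO"))
  expect_identical(smiles(deduplicateEntries(ps, seed = 5)), smiles(d1))
  expect_identical(yTrue(deduplicateEntries(ps, seed = 5)), yTrue(d1))
  # all-unique input is untouched
  uniq <- PredictionSet(c("CCO", "CCC"), c(1, 2), matrix(1:4, ncol = 2))
  expect_identical(smiles(deduplicateEntries(uniq, seed = 9)),
                   smiles(uniq))
  # preserves the set of canonical SMILES
  many <- c("CCO", "CCO", "CCC", "CCN", "CCN", "CCN")
  expect_setequal(deduplicateEntries(many, seed = 2), unique(many))
})

test_that("prediction tables round-trip through CSV", {
  ps <- PredictionSet(standardizeSmiles(c("CCO", "CCC", "c1ccccc1")),
                      c(450.5, 300, 960),
                      matrix(c(440, 310, 950, 460, 295, 975), ncol = 2),
                      foldId = c(0L, 1L, 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  writePredictionTable(ps, path)
  back <- readPredictionTable(path, mExpected = 2)
  expect_identical(smiles(back), smiles(ps))
  expect_equal(yTrue(back), yTrue(ps))
  expect_equal(unname(predictions(back)), unname(predictions(ps)))
  expect_identical(foldId(back), foldId(ps))
})

test_that("malformed prediction tables give located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,y_true,pred_1,pred_2",
               "CCO,450,440,NA",
               "CCC,300,310,295"), path)
  err <- tryCatch(readPredictionTable(path), error = identity)
  expect_s3_class(err, "molUQ_table_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "pred_2")

  writeLines(c("smiles,value", "CCO,1"), path)
  expect_error(readPredictionTable(path), "missing required")

  writeLines(c("smiles,y_true,pred_1", "CCO,450,440"), path)
  expect_error(readPredictionTable(path, mExpected = 2), "expected 2")
})

test_that("reference sets read from plain text and CSV", {
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CCO", "OCC", "CCN"), txt)
  smi <- readReferenceSmiles(txt)
  expect_identical(smi, standardizeSmiles(c("CCO", "OCC", "CCN")))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,weight", "CCO,1", "CCN,2"), csv)
  expect_identical(readReferenceSmiles(csv),
                   standardizeSmiles(c("CCO", "CCN")))
})
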