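# The four molecular-similarity measures and the nearest-training-set
# (S_max) features.

#' Tanimoto similarity of count fingerprints
#'
#' Computed on the binarized on-sets (presence/absence); counts do not
#' change the value. Two empty fingerprints have similarity 0 by
#' convention.
#'
#' @param a,b fingerprints as named position vectors from
#'   [countFingerprint()] or full-length numeric vectors.
#' @return similarity in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b) {
  onA <- .fp_positions(a); onB <- .fp_positions(b)
  u <- length(union(onA, onB))
  if (u == 0) return(0)
  length(intersect(onA, onB)) / u
}

.fp_positions <- function(x) {
  if (!is.null(names(x))) as.integer(names(x)[x > 0]) else which(x > 0)
}

.fp_dense <- function(x, len = .FP_LENGTH) {
  if (is.null(names(x))) {
    if (length(x) != len) stop("fingerprint length mismatch")
    return(as.numeric(x))
  }
  out <- numeric(len)
  out[as.integer(names(x))] <- as.numeric(x)
  out
}

#' Cosine similarity of count fingerprints
#'
#' Computed on the raw counts (the additive fingerprint), where counting
#' multiplicities matters. A zero vector yields 0 with a warning.
#'
#' @param a,b fingerprints as named position vectors or full-length
#'   numeric vectors.
#' @return similarity in [0, 1].
#' @export
cosineSimilarity <- function(a, b) {
  if (is.null(names(a)) && is.null(names(b))) {
    if (length(a) != length(b)) stop("fingerprint length mismatch")
    da <- as.numeric(a); db <- as.numeric(b)
  } else {
    da <- .fp_dense(a); db <- .fp_dense(b)
  }
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) {
    warning("zero fingerprint vector; cosine similarity defined as 0")
    return(0)
  }
  sum(da * db) / (na * nb)
}

#' Euclidean distance between principal-component vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative distance.
#' @export
euclideanDistance <- function(a, b) {
  if (length(a) != length(b)) stop("vector length mismatch")
  sqrt(sum((a - b)^2))
}

# --- Maximum common substructure ------------------------------------------

.mcs_labels <- function(g) {
  paste(g$elements, g$aromatic)
}

# Bond compatibility matrix: entries code (label, ring) pairs; ring bonds
# only match ring bonds (and non-ring only non-ring), bond orders must
# agree, aromatic bonds (label 4) only match aromatic bonds.
.bond_code_matrix <- function(g) {
  m <- matrix(NA_integer_, g$n, g$n)
  if (nrow(g$bonds)) {
    code <- g$bonds$label * 2L + as.integer(g$bonds$ring)
    m[cbind(g$bonds$i, g$bonds$j)] <- code
    m[cbind(g$bonds$j, g$bonds$i)] <- code
  }
  m
}

#' Maximum common substructure similarity
#'
#' Finds the connected maximum common substructure of two molecules under
#' the matching rules: equal element, aromatic atoms match only aromatic
#' atoms, equal bond order, and ring bonds match only ring bonds. The
#' similarity is S = X / (A + B - X), where X is the number of atoms plus
#' bonds in the MCS and A, B are the atoms-plus-bonds totals of the two
#' molecules (heavy atoms only).
#'
#' The search is exact branch-and-bound; when `timeout` seconds elapse the
#' best substructure found so far is returned with `timedOut = TRUE`
#' (a lower bound on the true similarity).
#'
#' @param smilesA,smilesB standardized SMILES strings.
#' @param timeout per-pair time budget in seconds (default 10).
#' @return list with elements `X`, `A`, `B`, `S`, `timedOut`.
#' @examples
#' mcsSimilarity("CC", "CCC")$S   # 3 / 5
#' @export
mcsSimilarity <- function(smilesA, smilesB, timeout = 10) {
  gA <- molGraph(smilesA); gB <- molGraph(smilesB)
  mcsSimilarityGraphs(gA, gB, timeout = timeout)
}

# Graph-level entry point (reused by batch feature computation).
mcsSimilarityGraphs <- function(gA, gB, timeout = 10) {
  A <- gA$n + nrow(gA$bonds)
  B <- gB$n + nrow(gB$bonds)
  labA <- .mcs_labels(gA); labB <- .mcs_labels(gB)
  compat <- outer(labA, labB, "==")
  st <- new.env(parent = emptyenv())
  st$best <- 0
  st$deadline <- Sys.time() + timeout
  st$timedOut <- FALSE
  if (any(compat)) {
    bmA <- .bond_code_matrix(gA); bmB <- .bond_code_matrix(gB)
    st$mapA <- integer(gA$n); st$mapB <- integer(gB$n)
    st$forbidden <- !compat
    st$best <- 1   # any compatible atom pair is a common subgraph
    mdeg <- min(max(gA$degree, 0), max(gB$degree, 0))
    .mcs_search(st, bmA, bmB, score = 0, nmapped = 0L, mdeg = mdeg)
  }
  X <- st$best
  S <- if (A + B - X > 0) X / (A + B - X) else 1
  list(X = X, A = A, B = B, S = S, timedOut = st$timedOut)
}

# Branch over candidate atom pairs: include the chosen pair or forbid it.
# `score` accumulates atoms + bonds of the current common subgraph.
.mcs_search <- function(st, bmA, bmB, score, nmapped, mdeg) {
  if (st$timedOut) return(invisible())
  if (Sys.time() > st$deadline) { st$timedOut <- TRUE; return(invisible()) }
  # candidate pairs: unmapped, not forbidden, and (once the mapping is
  # non-empty) connected to the mapped core by a compatible bond
  bestPair <- NULL; bestGain <- -1L
  candA <- which(st$mapA == 0L)
  candB <- which(st$mapB == 0L)
  if (!length(candA) || !length(candB)) return(invisible())
  mapped <- which(st$mapA != 0L)
  nCandA <- 0L
  for (a in candA) {
    rowOK <- FALSE
    for (b in candB) {
      if (st$forbidden[a, b]) next
      if (nmapped == 0L) {
        gain <- 0L
      } else {
        gain <- 0L
        for (ap in mapped) {
          ca <- bmA[a, ap]
          if (!is.na(ca)) {
            cb <- bmB[b, st$mapA[ap]]
            if (!is.na(cb) && ca == cb) gain <- gain + 1L
          }
        }
        if (gain == 0L) next   # would disconnect the common subgraph
      }
      rowOK <- TRUE
      if (gain > bestGain) { bestGain <- gain; bestPair <- c(a, b) }
    }
    if (rowOK) nCandA <- nCandA + 1L
  }
  if (is.null(bestPair)) return(invisible())
  # optimistic bound: each further atom adds at most 1 + mdeg to the score
  maxNew <- min(nCandA, length(candB))
  if (score + maxNew * (1 + mdeg) <= st$best) return(invisible())
  a <- bestPair[1]; b <- bestPair[2]
  # include branch
  st$mapA[a] <- b; st$mapB[b] <- a
  newScore <- score + 1 + bestGain
  if (newScore > st$best) st$best <- newScore
  .mcs_search(st, bmA, bmB, newScore, nmapped + 1L, mdeg)
  st$mapA[a] <- 0L; st$mapB[b] <- 0L
  if (st$timedOut) return(invisible())
  # exclude branch
  st$forbidden[a, b] <- TRUE
  .mcs_search(st, bmA, bmB, score, nmapped, mdeg)
  st$forbidden[a, b] <- FALSE
  invisible()
}

# --- Nearest-training-set features ----------------------------------------

#' Nearest-training-set similarity (S_max features)
#'
#' Linear scan over a [SimilarityReference-class]: the maximum similarity
#' for the Tanimoto, cosine and MCS measures, or the minimum distance for
#' the Euclidean measure.
#'
#' @param query a list describing one molecule with elements `fp`
#'   (fingerprint, named position vector), `pc` (principal-component
#'   vector) and `smiles`, as required by the chosen measure.
#' @param reference a [SimilarityReference-class].
#' @param measure one of "tanimoto", "cosine", "euclidean", "mcs".
#' @param excludeSelf drop reference molecules whose SMILES equals the
#'   query's (off by default; queries are normally disjoint from the
#'   reference).
#' @param timeout per-pair MCS timeout in seconds.
#' @return a single numeric value.
#' @export
nearestSimilarity <- function(query, reference,
                              measure = c("tanimoto", "cosine",
                                          "euclidean", "mcs"),
                              excludeSelf = FALSE, timeout = 10) {
  measure <- match.arg(measure)
  stopifnot(is(reference, "SimilarityReference"))
  idx <- seq_along(reference@smiles)
  if (excludeSelf && !is.null(query$smiles))
    idx <- idx[reference@smiles != query$smiles]
  if (!length(idx)) stop("empty similarity reference")
  if (measure == "euclidean") {
    pcs <- reference@pcs[idx, , drop = FALSE]
    d2 <- rowSums(sweep(pcs, 2, as.numeric(query$pc))^2)
    return(sqrt(max(0, min(d2))))
  }
  if (measure == "mcs") {
    best <- 0
    for (i in idx) {
      s <- mcsSimilarity(query$smiles, reference@smiles[i],
                         timeout = timeout)$S
      if (s > best) best <- s
    }
    return(best)
  }
  fp <- .fp_dense(query$fp)
  fps <- reference@fingerprints[idx, , drop = FALSE]
  if (measure == "tanimoto") {
    qOn <- as.numeric(fp > 0)
    common <- as.numeric((fps > 0) %*% Matrix::Matrix(qOn, ncol = 1))
    refOn <- Matrix::rowSums(fps > 0)
    union <- refOn + sum(qOn) - common
    vals <- ifelse(union > 0, common / union, 0)
    return(max(vals))
  }
  # cosine
  dots <- as.numeric(fps %*% Matrix::Matrix(fp, ncol = 1))
  nq <- sqrt(sum(fp^2))
  nr <- sqrt(Matrix::rowSums(fps^2))
  if (nq == 0) {
    warning("zero fingerprint vector; cosine similarity defined as 0")
    return(0)
  }
  vals <- ifelse(nr > 0, dots / (nq * nr), 0)
  max(vals)
}

# Batch S_max computation via sparse matrix algebra; returns a data.frame
# with one row per query.
batchNearestSimilarity <- function(queryFps, queryPcs, reference,
                                   querySmiles = NULL, mcs = FALSE,
                                   timeout = 10) {
  stopifnot(is(reference, "SimilarityReference"))
  rf <- reference@fingerprints
  rfBin <- rf > 0
  qBin <- queryFps > 0
  common <- as.matrix(qBin %*% Matrix::t(rfBin))
  onQ <- Matrix::rowSums(qBin)
  onR <- Matrix::rowSums(rfBin)
  union <- outer(as.numeric(onQ), as.numeric(onR), "+") - common
  tani <- ifelse(union > 0, common / union, 0)
  dots <- as.matrix(queryFps %*% Matrix::t(rf))
  nQ <- sqrt(Matrix::rowSums(queryFps^2))
  nR <- sqrt(Matrix::rowSums(rf^2))
  den <- outer(as.numeric(nQ), as.numeric(nR))
  cosi <- ifelse(den > 0, dots / den, 0)
  rp <- reference@pcs
  d2 <- outer(rowSums(queryPcs^2), rowSums(rp^2), "+") -
    2 * queryPcs %*% t(rp)
  d2[d2 < 0] <- 0
  out <- data.frame(
    sMaxT = apply(tani, 1, max),
    sMaxC = apply(cosi, 1, max),
    sMaxE = sqrt(apply(d2, 1, min))
  )
  if (mcs) {
    if (is.null(querySmiles)) stop("querySmiles required for MCS")
    qg <- molGraphs(querySmiles)
    rg <- molGraphs(reference@smiles)
    out$sMaxMcs <- vapply(seq_along(qg), function(qi) {
      best <- 0
      for (ri in seq_along(rg)) {
        s <- mcsSimilarityGraphs(qg[[qi]], rg[[ri]], timeout = timeout)$S
        if (s > best) best <- s
      }
      best
    }, numeric(1))
  }
  out
}
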