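# Circular (ECFP-style) count fingerprints: radius 3, folded to 8192
# positions, with counts rather than bits. Counting matters for the cosine
# similarity; the Tanimoto similarity uses the binarized on-sets.

.FP_LENGTH <- 8192L
.FP_RADIUS <- 3L
.HASH_MOD <- 2147483647  # 2^31 - 1; exact in doubles up to products < 2^53

.hash_ints <- function(v) {
  acc <- 7
  for (x in v) acc <- (acc * 31 + x + 1) %% .HASH_MOD
  acc
}

# Per-atom iterative neighborhood hashing (Morgan algorithm). An atom stops
# emitting identifiers once its environment no longer grows, so a lone atom
# contributes exactly its radius-0 identifier.
.morgan_ids <- function(g, radius = .FP_RADIUS) {
  n <- g$n
  elemCode <- vapply(g$elements, function(el) {
    idx <- match(el, .ELEMENT_COUNT_SET)
    if (!is.na(idx)) idx else 100 + sum(utf8ToInt(el))  # stable cross-molecule
  }, numeric(1))
  ids <- vapply(seq_len(n), function(a) {
    .hash_ints(c(0, elemCode[a], g$degree[a], as.integer(g$aromatic[a]),
                 as.integer(g$inRing[a])))
  }, numeric(1))
  env <- lapply(seq_len(n), function(a) a)  # atoms within current radius
  active <- rep(TRUE, n)
  out <- ids
  if (radius >= 1 && n > 1) {
    for (r in seq_len(radius)) {
      # snapshot the radius-(r-1) state: updates within a sweep must not
      # see each other, or the result would depend on atom ordering
      newIds <- ids
      newEnv <- env
      for (a in which(active)) {
        nbr <- g$adj[[a]]$nbr
        if (length(nbr) == 0) { active[a] <- FALSE; next }
        grown <- sort(unique(c(env[[a]], unlist(env[nbr]))))
        if (length(grown) == length(env[[a]])) { active[a] <- FALSE; next }
        newEnv[[a]] <- grown
        ord <- order(g$adj[[a]]$lab, ids[nbr])
        pairs <- as.vector(rbind(g$adj[[a]]$lab[ord], ids[nbr][ord]))
        newIds[a] <- .hash_ints(c(r, ids[a], pairs))
        out <- c(out, newIds[a])
      }
      ids <- newIds
      env <- newEnv
      if (!any(active)) break
    }
  }
  out
}

#' Compute a circular count fingerprint
#'
#' Environment identifiers of radius 0..3 around every heavy atom are
#' hashed and folded modulo 8192; counts accumulate on fold collisions.
#' Counts are invariant to the input atom ordering of the same structure.
#'
#' @param smi one standardized SMILES string.
#' @return named numeric vector: names are 1-based positions in
#'   `[1, 8192]`, values are environment counts (all >= 1).
#' @examples
#' fp <- countFingerprint("CCO")
#' sum(fp)   # number of emitted atom environments
#' @export
countFingerprint <- function(smi) {
  stopifnot(is.character(smi), length(smi) == 1)
  g <- molGraph(smi)
  ids <- .morgan_ids(g)
  pos <- (ids %% .FP_LENGTH) + 1
  tab <- table(pos)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Compute fingerprints for many molecules as a sparse matrix
#'
#' @param smilesVec character vector of standardized SMILES.
#' @param graphs optional pre-built molecular graphs (internal reuse).
#' @return a sparse `dgCMatrix` (molecules x 8192) of environment counts.
#' @export
countFingerprintMatrix <- function(smilesVec, graphs = NULL) {
  if (is.null(graphs)) graphs <- molGraphs(smilesVec)
  n <- length(graphs)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (m in seq_len(n)) {
    ids <- .morgan_ids(graphs[[m]])
    pos <- (ids %% .FP_LENGTH) + 1
    tab <- table(pos)
    ii <- c(ii, rep(m, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n, .FP_LENGTH),
                       dimnames = list(smilesVec, NULL))
}
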