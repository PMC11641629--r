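# Internal molecular-graph machinery.
#
# Graphs are derived from OpenBabel SDF output (atoms appear in SMILES
# order), while atom-level aromaticity is read off the canonical SMILES
# itself: an atom is aromatic iff it is written in lowercase. A bond is
# treated as aromatic iff both end atoms are aromatic and the bond lies on
# a cycle. Ring membership of bonds is perceived as "not a bridge".

.ORGANIC_TWO <- c("Cl", "Br")
.ORGANIC_ONE <- c("B", "C", "N", "O", "F", "P", "S", "I")
.AROMATIC_ONE <- c("b", "c", "n", "o", "p", "s")

.parse_error <- function(smiles, detail) {
  stop(errorCondition(
    sprintf("cannot parse SMILES '%s': %s", smiles, detail),
    class = c("molUQ_parse_error", "error"), smiles = smiles))
}

# Lexical scan of a SMILES string. Returns the heavy-atom element symbols
# in order of appearance, their aromatic flags, and the number of ring
# closures (= smallest-set-of-smallest-rings size, by the circuit rank
# identity for connected SMILES).
tokenizeSmiles <- function(smi) {
  chars <- strsplit(smi, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- character(0)
  aromatic <- logical(0)
  closures <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .parse_error(smi, "unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]*", "", body)     # isotope
      sym <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
      if (!length(sym) || !nzchar(sym))
        .parse_error(smi, sprintf("bracket atom '[%s]'", body))
      # two-letter symbol only if the second letter cannot start a new token
      first <- substr(sym, 1, 1)
      if (nchar(sym) == 2) {
        two <- sym
        # aromatic two-letter atoms (se, as) and H-counts like [CH3]
        if (substr(two, 2, 2) == "H" || grepl("^[a-z]", first) &&
            !two %in% c("se", "as"))
          sym <- first
        if (grepl("^[A-Z]", first) && substr(two, 2, 2) == "H")
          sym <- first
      }
      isar <- grepl("^[a-z]", sym)
      el <- paste0(toupper(substr(sym, 1, 1)),
                   if (nchar(sym) > 1) substr(sym, 2, nchar(sym)) else "")
      elements <- c(elements, el)
      aromatic <- c(aromatic, isar)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .ORGANIC_TWO) {
      elements <- c(elements, paste0(ch, chars[i + 1L]))
      aromatic <- c(aromatic, FALSE)
      i <- i + 2L
    } else if (ch %in% .ORGANIC_ONE) {
      elements <- c(elements, ch)
      aromatic <- c(aromatic, FALSE)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ONE) {
      elements <- c(elements, toupper(ch))
      aromatic <- c(aromatic, TRUE)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closures <- closures + 1L
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) .parse_error(smi, "truncated %nn ring closure")
      closures <- closures + 1L
      i <- i + 3L
    } else if (ch %in% c("-", "=", "#", "$", ":", "(", ")", ".", "/", "\\",
                         "@", "+")) {
      i <- i + 1L
    } else {
      .parse_error(smi, sprintf("unexpected character '%s'", ch))
    }
  }
  if (closures %% 2L != 0L) .parse_error(smi, "unmatched ring bond")
  list(elements = elements, aromatic = aromatic,
       nRings = closures %/% 2L)
}

# Batch conversion of canonical SMILES to molecular graphs.
# Returns a list of graphs: n, elements, aromatic, degree, inRing,
# bonds (i, j, order, ring, aromatic, label), adj (per-atom neighbor and
# bond-label lists).
.graph_cache <- new.env(parent = emptyenv())

molGraphs <- function(smilesVec) {
  stopifnot(is.character(smilesVec), length(smilesVec) > 0)
  cached <- vapply(smilesVec, exists, logical(1), envir = .graph_cache)
  if (all(cached))
    return(lapply(smilesVec, get, envir = .graph_cache))
  out <- .molGraphsUncached(unique(smilesVec[!cached]))
  for (g in out) assign(g$smiles, g, envir = .graph_cache)
  lapply(smilesVec, get, envir = .graph_cache)
}

.molGraphsUncached <- function(smilesVec) {
  toks <- lapply(smilesVec, tokenizeSmiles)
  multi <- which(vapply(toks, function(t) length(t$elements), integer(1)) > 1L)
  sdfs <- NULL
  if (length(multi)) {
    named <- smilesVec[multi]
    names(named) <- paste0("m", seq_along(named))
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(named))
    if (length(sdfs) != length(multi))
      stop("SMILES to SDF conversion dropped molecules; standardize first")
  }
  sdfPos <- match(seq_along(smilesVec), multi)
  lapply(seq_along(smilesVec), function(idx) {
    tok <- toks[[idx]]
    if (length(tok$elements) == 1L) {
      # single heavy atom: no bonds, no SDF round-trip needed
      return(list(smiles = smilesVec[idx], n = 1L,
                  elements = tok$elements, aromatic = tok$aromatic,
                  degree = 0L, inRing = FALSE,
                  bonds = data.frame(i = integer(0), j = integer(0),
                                     order = integer(0), ring = logical(0),
                                     aromatic = logical(0),
                                     label = integer(0)),
                  adj = list(list(nbr = integer(0), lab = integer(0)))))
    }
    sdf <- sdfs[[sdfPos[idx]]]
    ab <- ChemmineR::atomblock(sdf)
    natoms <- nrow(ab)
    elements <- sub("_.*$", "", rownames(ab))
    if (length(tok$elements) != natoms ||
        !all(toupper(tok$elements) == toupper(elements)))
      .parse_error(smilesVec[idx],
                   "atom tokenization does not match perceived structure")
    aromatic <- tok$aromatic
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(dim(bb)) || nrow(bb) == 0) {
      bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                          ring = logical(0), aromatic = logical(0),
                          label = integer(0))
    } else {
      bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
      bo <- as.integer(bb[, 3])
      ring <- rep(FALSE, length(bi))
      if (length(bi) > 0) {
        g <- igraph::graph_from_edgelist(cbind(bi, bj), directed = FALSE)
        br <- igraph::bridges(g)
        ring[-as.integer(br)] <- TRUE
        if (length(br) == 0) ring[] <- TRUE
      }
      arb <- ring & aromatic[bi] & aromatic[bj]
      label <- ifelse(arb, 4L, bo)
      bonds <- data.frame(i = bi, j = bj, order = bo, ring = ring,
                          aromatic = arb, label = label)
    }
    degree <- tabulate(c(bonds$i, bonds$j), nbins = natoms)
    inRing <- rep(FALSE, natoms)
    if (nrow(bonds))
      inRing[unique(c(bonds$i[bonds$ring], bonds$j[bonds$ring]))] <- TRUE
    adj <- vector("list", natoms)
    for (a in seq_len(natoms)) adj[[a]] <- list(nbr = integer(0), lab = integer(0))
    if (nrow(bonds)) {
      for (b in seq_len(nrow(bonds))) {
        i <- bonds$i[b]; j <- bonds$j[b]; lab <- bonds$label[b]
        adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$lab <- c(adj[[i]]$lab, lab)
        adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$lab <- c(adj[[j]]$lab, lab)
      }
    }
    list(smiles = smilesVec[idx], n = natoms, elements = elements,
         aromatic = aromatic, degree = degree, inRing = inRing,
         bonds = bonds, adj = adj)
  })
}

molGraph <- function(smi) molGraphs(smi)[[1]]
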