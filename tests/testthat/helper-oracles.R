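# Independent oracles used by the similarity and clustering tests.
# These deliberately avoid the package's own search/fit code paths.

# --- MCS oracle -----------------------------------------------------------
# Enumerates every connected edge-subgraph of the smaller molecule
# (subsets of its bonds, plus single atoms) and tests whether it embeds
# into the other molecule as a labeled subgraph (igraph VF2 monomorphism
# with vertex colors = element+aromaticity, edge colors = bond
# label+ring flag). The maximum atoms+bonds score over embeddable
# subgraphs is the MCS size.

.oracle_graph <- function(smi) {
  g <- molUQ:::molGraph(smi)
  vcol <- as.integer(factor(paste(g$elements, g$aromatic),
                            levels = NULL))
  list(g = g,
       vkey = paste(g$elements, g$aromatic),
       ekey = if (nrow(g$bonds)) paste(g$bonds$label, g$bonds$ring)
              else character(0))
}

.oracle_embeds <- function(subAtoms, subBonds, A, B) {
  # build the pattern from molecule A's selected atoms/bonds and test
  # monomorphism into molecule B
  vkeys <- unique(c(A$vkey[subAtoms], B$vkey))
  ekeys <- unique(c(A$ekey[subBonds], B$ekey))
  patV <- match(A$vkey[subAtoms], vkeys)
  tgtV <- match(B$vkey, vkeys)
  aidx <- match(seq_len(A$g$n), subAtoms)
  pat <- igraph::make_empty_graph(n = length(subAtoms), directed = FALSE)
  if (length(subBonds)) {
    el <- rbind(aidx[A$g$bonds$i[subBonds]], aidx[A$g$bonds$j[subBonds]])
    pat <- igraph::add_edges(pat, as.vector(el))
  }
  tgt <- igraph::make_empty_graph(n = B$g$n, directed = FALSE)
  if (nrow(B$g$bonds))
    tgt <- igraph::add_edges(tgt, as.vector(rbind(B$g$bonds$i,
                                                  B$g$bonds$j)))
  igraph::subgraph_isomorphic(
    pat, tgt, method = "vf2",
    vertex.color1 = match(B$vkey, vkeys),       # color1 = target
    vertex.color2 = patV,                        # color2 = pattern
    edge.color1 = if (length(B$ekey)) match(B$ekey, ekeys) else NULL,
    edge.color2 = if (length(subBonds))
      match(A$ekey[subBonds], ekeys) else NULL)
}

.oracle_connected_bond_subsets <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(list())
  out <- list()
  for (mask in seq_len(2^nb - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0)
    atoms <- sort(unique(c(g$bonds$i[sel], g$bonds$j[sel])))
    sub <- igraph::graph_from_edgelist(
      cbind(match(g$bonds$i[sel], atoms), match(g$bonds$j[sel], atoms)),
      directed = FALSE)
    if (igraph::components(sub)$no == 1L)
      out[[length(out) + 1L]] <- list(atoms = atoms, bonds = sel)
  }
  out
}

mcsOracle <- function(smilesA, smilesB) {
  A <- .oracle_graph(smilesA)
  B <- .oracle_graph(smilesB)
  if (A$g$n + nrow(A$g$bonds) > B$g$n + nrow(B$g$bonds)) {
    tmp <- A; A <- B; B <- tmp
  }
  best <- 0
  # single-atom subgraphs
  for (key in unique(A$vkey))
    if (key %in% B$vkey) { best <- max(best, 1); break }
  for (sub in .oracle_connected_bond_subsets(A$g)) {
    score <- length(sub$atoms) + length(sub$bonds)
    if (score <= best) next
    if (.oracle_embeds(sub$atoms, sub$bonds, A, B)) best <- score
  }
  XA <- A$g$n + nrow(A$g$bonds)
  XB <- B$g$n + nrow(B$g$bonds)
  list(X = best, S = if (XA + XB - best > 0) best / (XA + XB - best) else 1)
}

# Fixture molecules for exhaustive MCS comparison: small (<= 7 heavy
# atoms), chemically diverse, all standardizable.
mcsFixtureSmiles <- function() {
  molUQ::standardizeSmiles(c(
    "C", "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CC(C)O", "OCCO",
    "CC=O", "CC(=O)C", "CC(=O)O", "C=C", "C=CC", "C#N", "CC#N",
    "CCl", "CCCl", "ClCCCl", "CBr", "CCN", "CNC", "COC", "CCOC",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "c1ccccc1", "c1ccoc1",
    "C1CC1O", "CC1CC1", "c1ccncc1",
    "Cc1ccccc1", "Oc1ccccc1", "CCCCCC", "CC(C)CC(C)C", "CCc1ccccc1"))
}

# --- exhaustive k-means oracle --------------------------------------------
# Minimum WCSS over all partitions of n points into k non-empty groups
# (n small). Returns the optimal WCSS.
kmeansOracle <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assignments <- rep(1L, n)
  recurse <- function(i, maxUsed) {
    if (i > n) {
      if (maxUsed == k) {
        w <- 0
        for (j in seq_len(k)) {
          pts <- x[assignments == j, , drop = FALSE]
          ctr <- colMeans(pts)
          w <- w + sum(sweep(pts, 2, ctr)^2)
        }
        if (w < best) best <<- w
      }
      return()
    }
    for (j in seq_len(min(maxUsed + 1L, k))) {
      assignments[i] <<- j
      recurse(i + 1L, max(maxUsed, j))
    }
  }
  recurse(1L, 0L)
  best
}

# Laplace sampler for the distribution-diagnostics tests (scale = mean
# absolute value), independent of the package's internal sampler.
rlaplaceOracle <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}
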