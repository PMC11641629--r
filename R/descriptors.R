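# Real-valued 1D/2D molecular descriptors and min-max scaling.
#
# The descriptor set combines OpenBabel whole-molecule properties,
# functional-group counts, fixed-order element counts, and
# graph-topological measures computed from the molecular graph. The set is
# deliberately implementation-defined (its names are recorded in the matrix
# metadata): the uncertainty-estimation method only requires a consistent,
# reasonably diverse 2D descriptor space.

.ELEMENT_COUNT_SET <- c("C", "N", "O", "F", "Si", "P", "S", "Cl", "Br",
                        "B", "I")

.descriptor_cache <- new.env(parent = emptyenv())

.graph_descriptors <- function(g) {
  nb <- nrow(g$bonds)
  deg <- g$degree
  het <- sum(!g$elements %in% "C")
  hal <- sum(g$elements %in% c("F", "Cl", "Br", "I"))
  if (g$n > 1 && nb > 0) {
    ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j),
                                      directed = FALSE)
    if (igraph::vcount(ig) < g$n)
      ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
    dmat <- igraph::distances(ig)
    fin <- dmat[is.finite(dmat)]
    wiener <- sum(fin) / 2
    diam <- max(fin)
    ncomp <- igraph::components(ig)$no
  } else {
    wiener <- 0; diam <- 0; ncomp <- g$n
  }
  c(heavyAtoms = g$n,
    nBonds = nb,
    nRings = nb - g$n + ncomp,
    nAromaticAtoms = sum(g$aromatic),
    nAromaticBonds = if (nb) sum(g$bonds$aromatic) else 0,
    nRingBonds = if (nb) sum(g$bonds$ring) else 0,
    nRingAtoms = sum(g$inRing),
    nHeteroAtoms = het,
    fracHetero = if (g$n) het / g$n else 0,
    nHalogens = hal,
    nDoubleBonds = if (nb) sum(g$bonds$order == 2 & !g$bonds$aromatic) else 0,
    nTripleBonds = if (nb) sum(g$bonds$order == 3) else 0,
    maxDegree = if (g$n) max(deg) else 0,
    meanDegree = if (g$n) mean(deg) else 0,
    nBranchPoints = sum(deg >= 3),
    nTerminalAtoms = sum(deg == 1),
    wienerIndex = wiener,
    graphDiameter = diam)
}

.OB_PROPS <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "TPSA")

#' Compute the molecular descriptor matrix
#'
#' One row per molecule, fixed column order within a session. Descriptors
#' that fail to compute for a molecule are imputed to 0 with a warning.
#' Results are memoized by SMILES within the R session.
#'
#' @param smilesList character vector of standardized SMILES.
#' @param useCache logical; reuse per-SMILES cached rows.
#' @return numeric matrix with descriptor names as colnames and SMILES as
#'   rownames.
#' @examples
#' d <- computeDescriptors(c("CCO", "c1ccccc1"))
#' d[, c("heavyAtoms", "nAromaticAtoms")]
#' @export
computeDescriptors <- function(smilesList, useCache = TRUE) {
  stopifnot(is.character(smilesList), length(smilesList) > 0)
  uniq <- unique(smilesList)
  todo <- if (useCache)
    uniq[!vapply(uniq, exists, logical(1), envir = .descriptor_cache)]
  else uniq
  if (length(todo)) {
    graphs <- molGraphs(todo)
    props <- tryCatch(
      ChemmineOB::forEachMol("SMILES", paste(todo, collapse = "\n"),
                             ChemmineOB::prop_OB),
      error = function(e) NULL)
    # functional-group counts need an SDF round-trip; single-atom
    # molecules carry none and are skipped
    multi <- which(vapply(graphs, function(g) g$n, integer(1)) > 1L)
    grp <- NULL
    if (length(multi)) {
      named <- todo[multi]
      names(named) <- paste0("m", seq_along(named))
      grp <- tryCatch(suppressWarnings(
        ChemmineR::groups(ChemmineR::smiles2sdf(named),
                          groups = "fctgroup", type = "countMA")),
        error = function(e) NULL)
      if (!is.null(grp)) grp <- as.matrix(grp)
    }
    grpPos <- match(seq_along(todo), multi)
    fgNames <- if (!is.null(grp)) paste0("fg", colnames(grp))
               else paste0("fg", seq_len(12))
    failed <- FALSE
    for (i in seq_along(todo)) {
      gd <- .graph_descriptors(graphs[[i]])
      ec <- vapply(.ELEMENT_COUNT_SET,
                   function(el) sum(graphs[[i]]$elements == el), numeric(1))
      names(ec) <- paste0("n", .ELEMENT_COUNT_SET)
      pv <- if (!is.null(props) && i <= length(props)) {
        v <- suppressWarnings(as.numeric(unlist(props[[i]][1, .OB_PROPS])))
        names(v) <- .OB_PROPS
        v
      } else setNames(rep(NA_real_, length(.OB_PROPS)), .OB_PROPS)
      gv <- setNames(rep(0, length(fgNames)), fgNames)
      if (!is.null(grp) && !is.na(grpPos[i]))
        gv[] <- as.numeric(grp[grpPos[i], ])
      row <- c(gd, ec, pv, gv)
      if (any(!is.finite(row))) {
        row[!is.finite(row)] <- 0
        failed <- TRUE
      }
      assign(todo[i], row, envir = .descriptor_cache)
    }
    if (failed)
      warning("some descriptors failed to compute and were imputed to 0")
  }
  rows <- lapply(smilesList, get, envir = .descriptor_cache)
  mat <- do.call(rbind, rows)
  rownames(mat) <- smilesList
  mat
}

#' Fit and apply min-max scaling
#'
#' `fitScaler` records per-descriptor minima and maxima on a fitting set;
#' `applyScaler` maps values linearly so the fitting set spans [0, 1].
#' Constant descriptors are flagged and always map to 0. Out-of-sample
#' values may fall outside [0, 1]; they are deliberately not clipped so
#' Euclidean distances remain meaningful for outliers.
#'
#' @param x numeric matrix (molecules x descriptors).
#' @return `fitScaler`: a list with `min`, `max`, `constant`, usable with
#'   `applyScaler`; `applyScaler`: the rescaled matrix.
#' @examples
#' sc <- fitScaler(matrix(c(2, 4, 6), ncol = 1))
#' applyScaler(matrix(8), sc)   # 1.5: linear extrapolation
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("cannot fit scaler on empty matrix")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs <= mins,
                 names = colnames(x)),
            class = c("uqScaler", "list"))
}

#' @rdname fitScaler
#' @param scaler a fitted scaler from `fitScaler`.
#' @export
applyScaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "uqScaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min))
    stop("matrix does not match the scaler's descriptor count")
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
  out[, scaler$constant] <- 0
  out
}
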