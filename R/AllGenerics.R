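#' @name accessors
#' @title Accessors for molUQ classes
#' @description Slot accessors for the core S4 containers.
#' @param x an object.
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))
#' @rdname accessors
#' @export
setGeneric("yTrue", function(x) standardGeneric("yTrue"))
#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
#' @rdname accessors
#' @export
setGeneric("foldId", function(x) standardGeneric("foldId"))
#' @rdname accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))
#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("clusterStats", function(x) standardGeneric("clusterStats"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setMethod("smiles", "PredictionSet", function(x) x@smiles)
#' @rdname accessors
#' @export
setMethod("smiles", "SimilarityReference", function(x) x@smiles)
#' @rdname accessors
#' @export
setMethod("yTrue", "PredictionSet", function(x) x@yTrue)
#' @rdname accessors
#' @export
setMethod("predictions", "PredictionSet", function(x) x@predictions)
#' @rdname accessors
#' @export
setMethod("foldId", "PredictionSet", function(x) x@foldId)
#' @rdname accessors
#' @export
setMethod("nMolecules", "PredictionSet", function(x) length(x@smiles))
#' @rdname accessors
#' @export
setMethod("nModels", "PredictionSet", function(x) ncol(x@predictions))
#' @rdname accessors
#' @export
setMethod("centroids", "ClusterModel", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("clusterStats", "ClusterModel", function(x) {
  data.frame(cluster = seq_len(nrow(x@centroids)), size = x@size,
             maeCl = x@maeCl, mdaeCl = x@mdaeCl, mpeCl = x@mpeCl,
             dMean = x@dMean)
})

#' @rdname accessors
#' @export
setMethod("confusionCounts", "EvaluationReport", function(x) {
  c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn)
})

#' @rdname accessors
#' @export
setMethod("metrics", "EvaluationReport", function(x) {
  c(aucROC = x@aucROC, f1 = x@f1, precision = x@precision,
    recall = x@recall, accuracy = x@accuracy)
})

#' Subset a PredictionSet
#' @param x a PredictionSet.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PredictionSet", function(x, i, j, ..., drop = FALSE) {
  new("PredictionSet", smiles = x@smiles[i], yTrue = x@yTrue[i],
      predictions = x@predictions[i, , drop = FALSE], foldId = x@foldId[i])
})
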