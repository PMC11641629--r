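# JSON artifacts for fitted model components. Each artifact carries a
# format-version field so readers can reject incompatible files.

.FORMAT_VERSION <- "1.0"

#' Save and load a fitted UEModel as JSON
#'
#' Serializes the scaler, PCA projection, cluster model (centroids,
#' statistics, seed) and the similarity reference (SMILES and sparse
#' fingerprint triplets) to a single JSON artifact.
#'
#' @param model a [UEModel-class].
#' @param path output JSON path.
#' @return `path` (`saveUEModel`) or a [UEModel-class] (`loadUEModel`).
#' @export
saveUEModel <- function(model, path) {
  stopifnot(is(model, "UEModel"))
  fps <- methods::as(model@reference@fingerprints, "TsparseMatrix")
  obj <- list(
    format_version = .FORMAT_VERSION,
    kind = "ue_model",
    descriptor_names = model@descriptorNames,
    scaler = list(min = unname(model@scaler$min),
                  max = unname(model@scaler$max),
                  constant = unname(model@scaler$constant)),
    pca = list(center = unname(model@pca$center),
               loadings = model@pca$loadings,
               var_explained = model@pca$varExplained),
    clusters = list(
      centroids = model@clusters@centroids,
      size = model@clusters@size,
      mae_cl = model@clusters@maeCl, mdae_cl = model@clusters@mdaeCl,
      mpe_cl = model@clusters@mpeCl, d_mean = model@clusters@dMean,
      wcss = model@clusters@wcss, seed = model@clusters@seed,
      global_mae = model@clusters@globalMAE,
      global_mdae = model@clusters@globalMdAE),
    reference = list(
      smiles = model@reference@smiles,
      fp_i = fps@i + 1L, fp_j = fps@j + 1L, fp_x = fps@x,
      fp_dim = dim(fps),
      pcs = model@reference@pcs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveUEModel
#' @export
loadUEModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "ue_model"))
    stop("not a UEModel artifact")
  if (!identical(obj$format_version, .FORMAT_VERSION))
    stop("unsupported artifact format version: ", obj$format_version)
  scaler <- structure(list(min = obj$scaler$min, max = obj$scaler$max,
                           constant = obj$scaler$constant,
                           names = obj$descriptor_names),
                      class = c("uqScaler", "list"))
  pca <- structure(list(center = obj$pca$center,
                        loadings = as.matrix(obj$pca$loadings),
                        varExplained = obj$pca$var_explained,
                        c = ncol(as.matrix(obj$pca$loadings)),
                        names = obj$descriptor_names),
                   class = c("uqPCA", "list"))
  cl <- obj$clusters
  clusters <- new("ClusterModel", centroids = as.matrix(cl$centroids),
                  size = as.integer(cl$size), maeCl = cl$mae_cl,
                  mdaeCl = cl$mdae_cl, mpeCl = cl$mpe_cl,
                  dMean = cl$d_mean, wcss = cl$wcss,
                  wcssTrace = numeric(0), seed = as.integer(cl$seed),
                  globalMAE = cl$global_mae, globalMdAE = cl$global_mdae)
  fps <- Matrix::sparseMatrix(i = obj$reference$fp_i,
                              j = obj$reference$fp_j,
                              x = obj$reference$fp_x,
                              dims = obj$reference$fp_dim)
  ref <- SimilarityReference(obj$reference$smiles, fps,
                             as.matrix(obj$reference$pcs))
  new("UEModel", reference = ref, scaler = scaler, pca = pca,
      clusters = clusters, descriptorNames = obj$descriptor_names)
}

#' Save and load a meta-classifier as JSON
#'
#' Logistic models store coefficients and standard errors directly;
#' gradient-boosting models embed the booster bytes base64-encoded.
#'
#' @param model a [MetaClassifier-class].
#' @param path JSON path.
#' @return `path` or a [MetaClassifier-class].
#' @export
saveMetaClassifier <- function(model, path) {
  stopifnot(is(model, "MetaClassifier"))
  obj <- list(format_version = .FORMAT_VERSION, kind = "meta_classifier",
              model_kind = model@kind,
              feature_names = model@featureNames,
              p_threshold = model@pThreshold)
  if (model@kind == "logistic") {
    obj$coefficients <- as.list(model@coefficients)
    obj$se <- as.list(model@se)
  } else {
    obj$booster_b64 <- jsonlite::base64_enc(model@booster)
    obj$importance <- model@importance
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveMetaClassifier
#' @export
loadMetaClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "meta_classifier"))
    stop("not a MetaClassifier artifact")
  if (identical(obj$model_kind, "logistic")) {
    new("MetaClassifier", kind = "logistic",
        coefficients = unlist(obj$coefficients), se = unlist(obj$se),
        booster = NULL, importance = data.frame(),
        featureNames = obj$feature_names, pThreshold = obj$p_threshold)
  } else {
    new("MetaClassifier", kind = "gradient_boosting",
        coefficients = numeric(0), se = numeric(0),
        booster = jsonlite::base64_dec(obj$booster_b64),
        importance = as.data.frame(obj$importance),
        featureNames = obj$feature_names, pThreshold = obj$p_threshold)
  }
}
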