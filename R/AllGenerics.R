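#' @rdname EvaluationResult-class
#' @param object an object.
#' @export
setGeneric("meanAUC", function(object) standardGeneric("meanAUC"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("perDisease", function(object) standardGeneric("perDisease"))

#' @rdname OptimizerRun-class
#' @param object an object.
#' @export
setGeneric("bestGenome", function(object) standardGeneric("bestGenome"))

#' @rdname OptimizerRun-class
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))

#' @rdname OptimizerRun-class
#' @export
setGeneric("runHistory", function(object) standardGeneric("runHistory"))

#' @rdname MirnaDataset-class
#' @param object an object.
#' @export
setGeneric("mirnaIds", function(object) standardGeneric("mirnaIds"))

#' @rdname MirnaDataset-class
#' @export
setGeneric("diseaseIds", function(object) standardGeneric("diseaseIds"))

setMethod("meanAUC", "EvaluationResult", function(object) object@meanAUC)
setMethod("perDisease", "EvaluationResult", function(object) object@perDisease)
setMethod("bestGenome", "OptimizerRun", function(object) object@bestGenome)
setMethod("bestFitness", "OptimizerRun", function(object) object@bestFitness)
setMethod("runHistory", "OptimizerRun", function(object) object@history)
setMethod("mirnaIds", "MirnaDataset", function(object) object@mirnaIds)
setMethod("diseaseIds", "MirnaDataset", function(object) object@diseaseIds)

setMethod("show", "DiseaseHierarchy", function(object) {
  cat(sprintf("DiseaseHierarchy: %d terms, %d edges, %d root(s)\n",
    length(object@terms), nrow(object@edges),
    sum(!(object@terms %in% object@edges[, 2L]))))
})

setMethod("show", "MirnaDataset", function(object) {
  cat(sprintf(paste0(
    "MirnaDataset: %d miRNAs, %d diseases (%d associations)\n",
    "  targets: %d genes; families: %d; coords: %d; text sources: %s\n"),
    length(object@mirnaIds), length(object@diseaseIds), sum(object@md),
    ncol(object@mt), ncol(object@mf), nrow(object@coords),
    if (length(object@docs)) paste(names(object@docs), collapse = ", ")
    else "none"))
})

setMethod("show", "MiraiConfig", function(object) {
  src <- c(targets = object@useTargets, family = object@useFamily,
    neighbors = object@useNeighbors, pubmed = object@usePubmed,
    mirbase_abstract = object@useMirbaseAbstracts,
    mirbase_description = object@useMirbaseDescription)
  cat("MiraiConfig\n")
  cat("  sources: disease (mandatory)",
    if (any(src)) paste0(", ", paste(names(src)[src], collapse = ", "))
    else "", "\n", sep = "")
  cat(sprintf("  NBI on targets: %s; TF-IDF: pubmed=%s abstr=%s descr=%s\n",
    object@nbiOnTargets, object@tfidfPubmed, object@tfidfMirbaseAbstracts,
    object@tfidfMirbaseDescription))
  cat(sprintf("  infer in matrix: %s; expand query: %s\n",
    object@inferInMatrix, object@expandQuery))
  cat(sprintf("  cutoffs: %s; latent dim: %d\n",
    if (length(object@cutoffs)) paste(object@cutoffs, collapse = ", ")
    else "(none)", object@dim))
})

setMethod("show", "LatentSpace", function(object) {
  cat(sprintf("LatentSpace: dim %d, %d miRNAs, %d features\n",
    object@dim, nrow(object@mirnaVectors), nrow(object@featureVectors)))
})

setMethod("show", "KrigingModel", function(object) {
  cat(sprintf(
    "KrigingModel: %d archived points, mu = %.4f, sigma2 = %.3g, nugget = %g\n",
    nrow(object@X), object@mu, object@sigma2, object@nugget))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: %d disease(s) (>= %d associations), mean AUC = %.4f\n",
    nrow(object@perDisease), object@diseaseMin, object@meanAUC))
})

setMethod("show", "OptimizerRun", function(object) {
  cat(sprintf(
    "OptimizerRun: %d real evaluations, best fitness = %.6f\n  genome: %s\n",
    object@realEvals, object@bestFitness, formatGenome(object@bestGenome)))
})
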