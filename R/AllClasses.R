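#' @import methods
NULL

#' Disease hierarchy (directed acyclic subsumption graph)
#'
#' Stores a MeSH-like subsumption hierarchy as a set of terms plus
#' parent-to-child edges. Broader terms are parents; more specific terms are
#' children. The graph must be acyclic, which is enforced at construction
#' time, and ancestor/descendant queries are transitively closed.
#'
#' @slot terms character vector of disease term labels.
#' @slot edges two-column character matrix, columns `parent` and `child`.
#'
#' @seealso [DiseaseHierarchy()] for the user constructor,
#'   [diseaseAncestors()], [diseaseDescendants()], [diseaseSimilarity()].
#' @export
setClass("DiseaseHierarchy",
  representation(terms = "character", edges = "matrix"))

setValidity("DiseaseHierarchy", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns (parent, child)")
  if (nrow(e) > 0) {
    if (!all(e %in% object@terms)) {
      return("every edge endpoint must be a known term")
    }
  }
  if (anyDuplicated(object@terms)) return("terms must be unique")
  if (hierarchyHasCycle(object@terms, e)) return("hierarchy contains a cycle")
  TRUE
})

# Kahn topological check; returns TRUE when a cycle exists.
hierarchyHasCycle <- function(terms, edges) {
  if (nrow(edges) == 0L) return(FALSE)
  indeg <- stats::setNames(integer(length(terms)), terms)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  children <- split(edges[, 2L], edges[, 1L])
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(terms)
}

#' Multi-source miRNA dataset
#'
#' Container for the raw inputs of the predictor: the binary
#' miRNA-by-gene (MT), miRNA-by-disease (MD) and miRNA-by-family (MF)
#' association matrices, genomic coordinates backing the miRNA-neighbour
#' weights (MN), per-source word-count matrices backing the text block (MW),
#' and the disease subsumption hierarchy.
#'
#' @slot mirnaIds ordered character vector of miRNA identifiers.
#' @slot diseaseIds ordered character vector of disease terms (MD columns).
#' @slot mt binary miRNA x gene matrix.
#' @slot md binary miRNA x disease matrix.
#' @slot mf binary miRNA x family matrix (at most one family per miRNA).
#' @slot coords data.frame with columns `mirna`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates, GFF3 dialect).
#' @slot docs named list of word-count matrices (rows = miRNAs), one per
#'   text source among `"pubmed"`, `"mirbase_abstract"`,
#'   `"mirbase_description"`.
#' @slot hierarchy a [DiseaseHierarchy-class] object.
#'
#' @seealso [MirnaDataset()], [generatePlanted()], [readDataset()].
#' @export
setClass("MirnaDataset",
  representation(
    mirnaIds = "character", diseaseIds = "character",
    mt = "matrix", md = "matrix", mf = "matrix",
    coords = "data.frame", docs = "list",
    hierarchy = "DiseaseHierarchy"))

setValidity("MirnaDataset", function(object) {
  n <- length(object@mirnaIds)
  for (nm in c("mt", "md", "mf")) {
    m <- slot(object, nm)
    if (nrow(m) != n) return(sprintf("%s must have one row per miRNA", nm))
    if (!isBinaryMatrix(m)) return(sprintf("%s entries must be 0/1", nm))
  }
  if (ncol(object@md) != length(object@diseaseIds)) {
    return("md must have one column per disease term")
  }
  if (ncol(object@mf) > 0 && any(rowSums(object@mf) > 1)) {
    return("each miRNA belongs to at most one family")
  }
  cc <- object@coords
  need <- c("mirna", "chrom", "start", "end", "strand")
  if (!all(need %in% names(cc))) {
    return("coords needs columns mirna, chrom, start, end, strand")
  }
  if (nrow(cc) > 0 && any(cc$start > cc$end, na.rm = TRUE)) {
    return("coordinate start must be <= end")
  }
  if (length(object@docs) > 0) {
    bad <- setdiff(names(object@docs), textSources())
    if (length(bad)) return(paste("unknown text source:", bad[[1L]]))
    for (src in names(object@docs)) {
      if (nrow(object@docs[[src]]) != n) {
        return(sprintf("docs[[%s]] must have one row per miRNA", src))
      }
    }
  }
  TRUE
})

textSources <- function() c("pubmed", "mirbase_abstract", "mirbase_description")

#' Decoded predictor configuration
#'
#' The decoded counterpart of the 35-bit genome: which data sources feed the
#' assembled matrix, which transformations are applied, the disease-weight
#' discretization cutoffs, the latent dimension (a multiple of 50 in
#' [50, 800]) and whether disease queries are expanded with descendant terms.
#' The disease-association block is mandatory and therefore has no flag.
#'
#' @slot useTargets,useFamily,useNeighbors use the target-gene / family /
#'   genomic-neighbour block.
#' @slot usePubmed,useMirbaseAbstracts,useMirbaseDescription use the
#'   corresponding text block.
#' @slot nbiOnTargets apply network-based inference to the target block.
#' @slot tfidfPubmed,tfidfMirbaseAbstracts,tfidfMirbaseDescription apply
#'   TF-IDF weighting to the corresponding text block.
#' @slot inferInMatrix propagate disease annotations to broader terms before
#'   similarity computation.
#' @slot cutoffs ascending numeric vector on the 0.05-step grid (possibly
#'   empty, meaning the raw binary disease matrix is used).
#' @slot dim latent-space dimension.
#' @slot expandQuery expand disease queries with descendant terms.
#'
#' @seealso [decodeGenome()], [encodeGenome()], [MiraiConfig()].
#' @export
setClass("MiraiConfig",
  representation(
    useTargets = "logical", useFamily = "logical", useNeighbors = "logical",
    usePubmed = "logical", useMirbaseAbstracts = "logical",
    useMirbaseDescription = "logical",
    nbiOnTargets = "logical", tfidfPubmed = "logical",
    tfidfMirbaseAbstracts = "logical", tfidfMirbaseDescription = "logical",
    inferInMatrix = "logical", cutoffs = "numeric", dim = "integer",
    expandQuery = "logical"))

setValidity("MiraiConfig", function(object) {
  if (object@dim %% 50L != 0L || object@dim < 50L || object@dim > 800L) {
    return("dim must be a multiple of 50 in [50, 800]")
  }
  if (length(object@cutoffs)) {
    if (is.unsorted(object@cutoffs, strictly = TRUE)) {
      return("cutoffs must be strictly ascending")
    }
    onGrid <- vapply(object@cutoffs,
      function(c) any(abs(c - cutoffGrid()) < 1e-9), logical(1))
    if (!all(onGrid)) return("cutoffs must lie on the 0.05 grid")
  }
  TRUE
})

#' Latent semantic space
#'
#' The result of the truncated singular value decomposition of the assembled
#' miRNA x feature matrix. With M ~ U S V', miRNAs are embedded as the rows
#' of U S and features as the rows of V S, so both live in one comparable
#' space and can be ranked against each other by cosine.
#'
#' @slot dim number of retained singular triplets.
#' @slot mirnaVectors |miRNA| x dim matrix (rows named by miRNA id).
#' @slot featureVectors |features| x dim matrix (rows named by column id).
#' @slot colIds feature (column) identifiers of the assembled matrix.
#'
#' @seealso [buildLatentSpace()], [queryDisease()].
#' @export
setClass("LatentSpace",
  representation(dim = "integer", mirnaVectors = "matrix",
    featureVectors = "matrix", colIds = "character"))

setValidity("LatentSpace", function(object) {
  if (ncol(object@mirnaVectors) != object@dim ||
      ncol(object@featureVectors) != object@dim) {
    return("vector widths must equal dim")
  }
  if (nrow(object@featureVectors) != length(object@colIds)) {
    return("one feature vector per column id required")
  }
  TRUE
})

#' Ordinary-kriging Gaussian process surrogate
#'
#' Archive of real fitness evaluations together with the fitted
#' ordinary-kriging model used to predict the mean and uncertainty of the
#' fitness at untested genomes. The spatial correlation between two genomes
#' x, x' is exp(-sum_i theta_i |x_i - x'_i|^p_i); a small nugget is added to
#' the diagonal for numerical stability.
#'
#' @slot X archive genomes, one row per evaluated (deduplicated) genome.
#' @slot y archive fitness values.
#' @slot theta per-coordinate correlation decay (> 0).
#' @slot power per-coordinate smoothness exponent in [1, 2].
#' @slot nugget diagonal jitter.
#' @slot mu,sigma2 generalized-least-squares mean and process variance.
#' @slot cholR upper Cholesky factor of the correlation matrix.
#' @slot alpha solve(R, y - mu).
#' @slot Rinv1 solve(R, 1); @slot denom sum(Rinv1).
#'
#' @seealso [fitKriging()], [predict,KrigingModel-method],
#'   [spatialCorrelation()], [meritValue()].
#' @export
setClass("KrigingModel",
  representation(X = "matrix", y = "numeric", theta = "numeric",
    power = "numeric", nugget = "numeric", mu = "numeric",
    sigma2 = "numeric", cholR = "matrix", alpha = "numeric",
    Rinv1 = "numeric", denom = "numeric"))

setValidity("KrigingModel", function(object) {
  if (nrow(object@X) != length(object@y)) return("|X| must equal |y|")
  if (any(object@theta <= 0)) return("theta must be positive")
  if (any(object@power < 1 | object@power > 2)) {
    return("power must lie in [1, 2]")
  }
  TRUE
})

#' Cross-validation result
#'
#' Per-disease ranking metrics from five-fold cross-validation plus their
#' mean AUC, which is the fitness maximized by the optimizer.
#'
#' @slot perDisease data.frame with columns `disease`, `nPositives`, `auc`,
#'   `rPrecision`.
#' @slot precisionAtRecall diseases x recall-levels matrix of precisions.
#' @slot meanAUC arithmetic mean of the per-disease AUCs.
#' @slot diseaseMin minimum association count for a disease to be evaluated.
#' @slot seed seed used for the fold partition.
#'
#' @seealso [crossValidate()], [meanAUC()].
#' @export
setClass("EvaluationResult",
  representation(perDisease = "data.frame", precisionAtRecall = "matrix",
    meanAUC = "numeric", diseaseMin = "integer", seed = "integer"))

setValidity("EvaluationResult", function(object) {
  if (nrow(object@perDisease) > 0) {
    m <- mean(object@perDisease$auc)
    if (abs(m - object@meanAUC) > 1e-12) {
      return("meanAUC must be the mean of the per-disease AUCs")
    }
  }
  TRUE
})

#' Optimizer run state
#'
#' Final population, per-real-generation fitness history and the best genome
#' found by the (surrogate-assisted) binary differential evolution run.
#'
#' @slot population final lambda x N genome matrix.
#' @slot fitness real fitness of the final population.
#' @slot bestGenome best genome ever real-evaluated.
#' @slot bestFitness its real fitness.
#' @slot history data.frame with columns `generation`, `realEvals`, `best`,
#'   `mean`, `worst` (one row per real generation, including initialization).
#' @slot realEvals total number of real fitness evaluations spent.
#' @slot control the [optimizerControl()] list used.
#'
#' @seealso [runOptimizer()], [bestGenome()], [runHistory()].
#' @export
setClass("OptimizerRun",
  representation(population = "matrix", fitness = "numeric",
    bestGenome = "integer", bestFitness = "numeric",
    history = "data.frame", realEvals = "integer", control = "list"))
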