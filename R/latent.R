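#' Assemble the weighted multi-source matrix
#'
#' Horizontally concatenates the configured blocks in fixed order: the
#' mandatory disease block, then (when enabled) target genes, families,
#' genomic neighbours, and the three text sources. Each block is transformed
#' per its configuration bit: network-based inference for targets, TF-IDF
#' for text; transformation bits are ignored when the corresponding source
#' is off. Column identifiers are namespaced (`disease:`, `gene:`, `fam:`,
#' `nbr:`, `word:<source>:`) so names never collide.
#'
#' @param dataset a [MirnaDataset-class].
#' @param config a [MiraiConfig-class].
#' @param holdoutDisease forwarded to [buildDiseaseBlock()].
#' @param neighborWindow decay window for [neighborWeights()], bp.
#' @param measure disease similarity function, see [diseaseSimilarity()].
#' @return numeric miRNA x feature matrix.
#' @export
assembleMatrix <- function(dataset, config, holdoutDisease = NULL,
                           neighborWindow = 50000,
                           measure = diseaseSimilarity) {
  blocks <- list(buildDiseaseBlock(dataset@md, dataset@hierarchy, config,
    holdoutDisease = holdoutDisease, measure = measure))
  if (config@useTargets) {
    if (ncol(dataset@mt) == 0L) {
      stop("source 'targets' selected but absent from the dataset",
        call. = FALSE)
    }
    blk <- if (config@nbiOnTargets) applyNBI(dataset@mt) else dataset@mt
    colnames(blk) <- paste0("gene:", colnames(dataset@mt))
    blocks <- c(blocks, list(blk))
  }
  if (config@useFamily) {
    if (ncol(dataset@mf) == 0L) {
      stop("source 'family' selected but absent from the dataset",
        call. = FALSE)
    }
    blk <- dataset@mf
    colnames(blk) <- paste0("fam:", colnames(dataset@mf))
    blocks <- c(blocks, list(blk))
  }
  if (config@useNeighbors) {
    if (nrow(dataset@coords) == 0L) {
      stop("source 'neighbors' selected but absent from the dataset",
        call. = FALSE)
    }
    blk <- neighborWeights(dataset@coords, dataset@mirnaIds,
      window = neighborWindow)
    colnames(blk) <- paste0("nbr:", colnames(blk))
    blocks <- c(blocks, list(blk))
  }
  textOn <- c(pubmed = config@usePubmed,
    mirbase_abstract = config@useMirbaseAbstracts,
    mirbase_description = config@useMirbaseDescription)
  textTfidf <- c(pubmed = config@tfidfPubmed,
    mirbase_abstract = config@tfidfMirbaseAbstracts,
    mirbase_description = config@tfidfMirbaseDescription)
  for (src in textSources()) {
    if (!textOn[[src]]) next
    counts <- dataset@docs[[src]]
    if (is.null(counts) || ncol(counts) == 0L) {
      stop("source '", src, "' selected but absent from the dataset",
        call. = FALSE)
    }
    blk <- if (textTfidf[[src]]) applyTFIDF(counts) else counts
    colnames(blk) <- paste0("word:", src, ":", colnames(blk))
    blocks <- c(blocks, list(blk))
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- dataset@mirnaIds
  out
}

#' Build the latent space by truncated SVD
#'
#' Computes the top-`dim` singular triplets of the assembled matrix,
#' M ~ U S V', and embeds miRNAs as rows of U S and features as rows of
#' V S, so rows and columns are components of one comparable space. Small
#' matrices (both sides < 200) go through a dense SVD; larger ones through
#' an exact eigendecomposition of the smaller Gram matrix (the feature
#' embedding is recovered as M'U, avoiding division by small singular
#' values). The sign of each component is fixed so the largest-magnitude
#' entry of each left singular vector is positive, making the decomposition
#' deterministic.
#'
#' @param matrix numeric miRNA x feature matrix with dimnames.
#' @param dim requested dimension; clamped (with a warning) to
#'   `min(nrow, ncol)`.
#' @return a [LatentSpace-class].
#' @export
buildLatentSpace <- function(matrix, dim) {
  if (all(matrix == 0)) stop("cannot decompose an all-zero matrix",
    call. = FALSE)
  maxDim <- min(nrow(matrix), ncol(matrix))
  if (dim > maxDim) {
    warning("requested dimension ", dim, " exceeds min(rows, cols) = ",
      maxDim, "; clamping")
    dim <- maxDim
  }
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  dim <- as.integer(dim)
  if (max(base::dim(matrix)) < 200L) {
    s <- svd(matrix, nu = dim, nv = dim)
    sigma <- s$d[seq_len(dim)]
    mv <- s$u %*% diag(sigma, dim)
    fv <- s$v %*% diag(sigma, dim)
  } else if (nrow(matrix) <= ncol(matrix)) {
    e <- eigen(tcrossprod(matrix), symmetric = TRUE)
    U <- e$vectors[, seq_len(dim), drop = FALSE]
    sigma <- sqrt(pmax(e$values[seq_len(dim)], 0))
    mv <- U %*% diag(sigma, dim)
    fv <- crossprod(matrix, U)        # = V S exactly
  } else {
    e <- eigen(crossprod(matrix), symmetric = TRUE)
    V <- e$vectors[, seq_len(dim), drop = FALSE]
    sigma <- sqrt(pmax(e$values[seq_len(dim)], 0))
    fv <- V %*% diag(sigma, dim)
    mv <- matrix %*% V                # = U S exactly
  }
  # sign convention: largest-magnitude component of each left singular
  # vector (equivalently of U S, since S >= 0) made positive
  for (j in seq_len(dim)) {
    k <- which.max(abs(mv[, j]))
    if (mv[k, j] < 0) {
      mv[, j] <- -mv[, j]
      fv[, j] <- -fv[, j]
    }
  }
  rownames(mv) <- rownames(matrix)
  rownames(fv) <- colnames(matrix)
  new("LatentSpace", dim = dim, mirnaVectors = mv, featureVectors = fv,
    colIds = colnames(matrix))
}

# Feature columns carrying positive association signal for a disease term.
# The no_assoc indicator marks absence and is excluded from queries.
diseaseColumns <- function(colIds, disease) {
  exact <- colIds == paste0("disease:", disease)
  binned <- startsWith(colIds, paste0("disease:", disease, "@")) &
    !endsWith(colIds, "@no_assoc")
  colIds[exact | binned]
}

#' Rank miRNAs for a disease query
#'
#' The query vector is the centroid of the feature vectors of all positive
#' association columns of the disease (its bare column, or its `>=cutoff`
#' bin columns when discretization is on). With `expand = TRUE` the columns
#' of all descendant (more specific) diseases in the hierarchy are pooled
#' into the centroid as well, mirroring the matrix-side inference direction.
#' miRNAs are returned sorted by decreasing cosine to the query, ties broken
#' by miRNA identifier.
#'
#' @param space a [LatentSpace-class].
#' @param disease queried disease term.
#' @param expand expand the query with descendant diseases.
#' @param hierarchy a [DiseaseHierarchy-class]; required when
#'   `expand = TRUE`.
#' @return data.frame with columns `rank`, `mirna`, `cosine`.
#' @export
queryDisease <- function(space, disease, expand = FALSE, hierarchy = NULL) {
  terms <- disease
  if (expand && !is.null(hierarchy) && disease %in% hierarchy@terms) {
    terms <- c(disease, diseaseDescendants(hierarchy, disease))
  }
  cols <- unique(unlist(lapply(terms, diseaseColumns, colIds = space@colIds)))
  if (length(cols) == 0L) stop("unknown disease: ", disease, call. = FALSE)
  q <- colMeans(space@featureVectors[cols, , drop = FALSE])
  scores <- rowCosine(space@mirnaVectors, q)
  ord <- order(-scores, names(scores))
  data.frame(rank = seq_along(ord), mirna = names(scores)[ord],
    cosine = unname(scores[ord]), stringsAsFactors = FALSE)
}

#' Serialize / restore a latent space
#'
#' The archive is a single RDS file (R's documented binary serialization)
#' holding the dimension, both identifier vectors and both embedding blocks.
#'
#' @param space a [LatentSpace-class].
#' @param path file path.
#' @return `readLatentSpace` returns the restored, re-validated
#'   [LatentSpace-class]; `writeLatentSpace` returns `path` invisibly.
#' @export
writeLatentSpace <- function(space, path) {
  saveRDS(list(dim = space@dim, mirnaIds = rownames(space@mirnaVectors),
    colIds = space@colIds, mirnaVectors = space@mirnaVectors,
    featureVectors = space@featureVectors), path)
  invisible(path)
}

#' @rdname writeLatentSpace
#' @export
readLatentSpace <- function(path) {
  x <- readRDS(path)
  new("LatentSpace", dim = as.integer(x$dim), mirnaVectors = x$mirnaVectors,
    featureVectors = x$featureVectors, colIds = x$colIds)
}
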