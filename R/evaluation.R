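#' Area under the ROC curve of a ranked retrieval list
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive is ranked above the negative; tied scores count 0.5.
#' `rankingAUC` takes an ordered identifier list (best first) and the set of
#' positives; `scoreAUC` takes raw scores and 0/1 labels and handles ties.
#'
#' @param ranked character vector, best-ranked first.
#' @param positives subset of `ranked`.
#' @return AUC in [0, 1]; errors when either class is empty.
#' @examples
#' rankingAUC(c("a", "b", "c", "d"), c("a", "c"))  # 0.75
#' @export
rankingAUC <- function(ranked, positives) {
  scoreAUC(rev(seq_along(ranked)), ranked %in% positives)
}

#' @rdname rankingAUC
#' @param scores numeric scores, larger = better.
#' @param labels logical (or 0/1) vector, TRUE for positives.
#' @export
scoreAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores) # average ranks on ties
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision at fixed recall levels
#'
#' For recall level r, the precision at the smallest cut-off depth whose
#' top of the ranking captures `ceiling(r * |positives|)` positives.
#'
#' @inheritParams rankingAUC
#' @param levels recall fractions in (0, 1].
#' @return named numeric vector of precisions, one per level.
#' @export
precisionAtRecall <- function(ranked, positives,
                              levels = seq(0.1, 1, by = 0.1)) {
  if (any(levels <= 0 | levels > 1)) {
    stop("recall levels must lie in (0, 1]", call. = FALSE)
  }
  isPos <- ranked %in% positives
  P <- sum(isPos)
  if (P == 0L || P == length(ranked)) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  posDepth <- which(isPos) # depth at which the k-th positive is captured
  out <- vapply(levels, function(r) {
    k <- ceiling(r * P)
    k / posDepth[[k]]
  }, numeric(1))
  stats::setNames(out, paste0("recall_", format(levels, trim = TRUE)))
}

#' R-precision of a ranked retrieval list
#'
#' Precision within the top R ranks, R being the number of positives; this
#' makes precisions comparable across diseases with very different numbers
#' of known associations.
#'
#' @inheritParams rankingAUC
#' @return precision in [0, 1].
#' @export
rPrecision <- function(ranked, positives) {
  R <- sum(ranked %in% positives)
  if (R == 0L || R == length(ranked)) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  mean(ranked[seq_len(R)] %in% positives)
}

#' Per-disease five-fold cross-validation
#'
#' For every disease with at least `diseaseMin` associations, its known
#' positive miRNAs are randomly partitioned into five near-equal folds.
#' Per fold, the fold's (miRNA, disease) entries are removed from MD, the
#' evaluated disease is excluded from the similarity-augmentation step of
#' the disease block, the matrix is re-assembled, the latent space rebuilt,
#' and the disease queried; the held-out miRNAs are scored as positives
#' against every miRNA never associated with the disease in the full
#' dataset (training positives are not scored). The five folds' (score,
#' label) pools are concatenated per disease before computing AUC,
#' R-precision and precision at recall, so small folds do not destabilize
#' the metrics.
#'
#' @param dataset a [MirnaDataset-class].
#' @param config a [MiraiConfig-class]; the latent dimension is clamped to
#'   the assembled matrix size when necessary.
#' @param diseaseMin minimum association count for a disease to be
#'   evaluated (20 for literature-scale data; lower it for small synthetic
#'   datasets). Diseases with fewer than 5 positives are always skipped.
#' @param seed seed for the fold partitions.
#' @param levels recall levels for [precisionAtRecall()].
#' @param nFolds number of folds.
#' @return an [EvaluationResult-class].
#' @export
crossValidate <- function(dataset, config, diseaseMin = 20L, seed = 1L,
                          levels = seq(0.1, 1, by = 0.1), nFolds = 5L) {
  md <- dataset@md
  counts <- colSums(md)
  eligible <- dataset@diseaseIds[counts >= max(diseaseMin, 5L)]
  skipped <- dataset@diseaseIds[counts >= diseaseMin & counts < 5L]
  if (length(skipped)) {
    message("skipping ", length(skipped), " disease(s) with < 5 positives")
  }
  perDisease <- data.frame(disease = character(), nPositives = integer(),
    auc = numeric(), rPrecision = numeric(), stringsAsFactors = FALSE)
  par <- matrix(numeric(), 0L, length(levels),
    dimnames = list(NULL, paste0("recall_", format(levels, trim = TRUE))))
  withSeed(seed, {
    for (d in eligible) {
      pos <- dataset@mirnaIds[md[, d] == 1]
      folds <- sample(rep_len(seq_len(nFolds), length(pos)))
      scores <- numeric()
      ids <- character()
      isPos <- logical()
      for (f in seq_len(nFolds)) {
        testM <- pos[folds == f]
        if (length(testM) == 0L) next
        md2 <- md
        md2[testM, d] <- 0
        ds2 <- dataset
        ds2@md <- md2
        A <- assembleMatrix(ds2, config, holdoutDisease = d)
        k <- min(config@dim, nrow(A), ncol(A))
        space <- buildLatentSpace(A, k)
        ranking <- queryDisease(space, d, expand = config@expandQuery,
          hierarchy = dataset@hierarchy)
        # negatives: never associated with d in the FULL dataset
        keep <- ranking$mirna %in% testM | !(ranking$mirna %in% pos)
        sub <- ranking[keep, ]
        scores <- c(scores, sub$cosine)
        ids <- c(ids, sub$mirna)
        isPos <- c(isPos, sub$mirna %in% testM)
      }
      ord <- order(-scores, ids)
      pooled <- ids[ord]
      pooledPos <- pooled[isPos[ord]]
      perDisease <- rbind(perDisease, data.frame(disease = d,
        nPositives = length(pos), auc = scoreAUC(scores, isPos),
        rPrecision = rPrecision(pooled, pooledPos),
        stringsAsFactors = FALSE))
      par <- rbind(par, precisionAtRecall(pooled, pooledPos, levels))
    }
  })
  rownames(par) <- perDisease$disease
  new("EvaluationResult", perDisease = perDisease, precisionAtRecall = par,
    meanAUC = if (nrow(perDisease)) mean(perDisease$auc) else NaN,
    diseaseMin = as.integer(diseaseMin), seed = as.integer(seed))
}

#' Cross-validated fitness of a genome
#'
#' Decodes the genome, runs [crossValidate()] and returns the mean AUC --
#' the quantity the optimizer maximizes. Deterministic given (dataset,
#' genome, seed). A degenerate configuration whose assembled matrix cannot
#' be decomposed scores 0 (with a message).
#'
#' @param dataset a [MirnaDataset-class].
#' @param genome 35-bit genome (vector or string).
#' @param diseaseMin,seed forwarded to [crossValidate()].
#' @return mean AUC in [0, 1].
#' @export
genomeFitness <- function(dataset, genome, diseaseMin = 20L, seed = 1L) {
  config <- decodeGenome(genome)
  tryCatch(
    meanAUC(crossValidate(dataset, config, diseaseMin = diseaseMin,
      seed = seed)),
    error = function(e) {
      message("degenerate configuration scored 0: ", conditionMessage(e))
      0
    })
}

# Cosine of every annotated (miRNA, disease) pair in the full latent space.
annotatedPairCosines <- function(dataset, config, neighborWindow = 50000) {
  A <- assembleMatrix(dataset, config, neighborWindow = neighborWindow)
  k <- min(config@dim, nrow(A), ncol(A))
  space <- buildLatentSpace(A, k)
  out <- data.frame(mirna = character(), disease = character(),
    cosine = numeric(), stringsAsFactors = FALSE)
  for (d in dataset@diseaseIds) {
    ann <- dataset@mirnaIds[dataset@md[, d] == 1]
    if (length(ann) == 0L) next
    ranking <- queryDisease(space, d, expand = FALSE)
    cs <- ranking$cosine[match(ann, ranking$mirna)]
    out <- rbind(out, data.frame(mirna = ann, disease = d, cosine = cs,
      stringsAsFactors = FALSE))
  }
  list(pairs = out, space = space)
}

#' Flag putative mis-annotations
#'
#' Builds the latent space on the full dataset, computes the cosine of
#' every annotated (miRNA, disease) pair, and scores each pair by the
#' negated z-score of its cosine against the distribution of all annotated
#' pairs' cosines. Pairs whose score exceeds the threshold (cosine more
#' than `threshold` standard deviations below the mean) are flagged as
#' putative false associations. If all cosines are identical (zero
#' variance) nothing is flagged.
#'
#' @param dataset a [MirnaDataset-class].
#' @param config a [MiraiConfig-class].
#' @param threshold invalidation score above which a pair is flagged.
#' @return data.frame `mirna`, `disease`, `cosine`, `score`, `flagged`,
#'   sorted by decreasing score.
#' @export
detectInvalid <- function(dataset, config, threshold = 2) {
  pairs <- annotatedPairCosines(dataset, config)$pairs
  s <- stats::sd(pairs$cosine)
  if (!is.finite(s) || s < 1e-12) {
    pairs$score <- 0
    pairs$flagged <- FALSE
  } else {
    pairs$score <- -(pairs$cosine - mean(pairs$cosine)) / s
    pairs$flagged <- pairs$score > threshold
  }
  pairs[order(-pairs$score, pairs$mirna, pairs$disease), ]
}

#' Predict novel miRNA-disease associations
#'
#' Builds the latent space on the full dataset and reports, per disease,
#' the `topK` highest-cosine miRNAs not already annotated to it; the
#' combined list is sorted by decreasing cosine. Annotated pairs never
#' appear in the output.
#'
#' @param dataset a [MirnaDataset-class].
#' @param config a [MiraiConfig-class].
#' @param topK candidates kept per disease.
#' @return data.frame `disease`, `mirna`, `cosine`.
#' @export
predictNovel <- function(dataset, config, topK = 10L) {
  out <- data.frame(disease = character(), mirna = character(),
    cosine = numeric(), stringsAsFactors = FALSE)
  if (topK <= 0L) return(out)
  A <- assembleMatrix(dataset, config)
  k <- min(config@dim, nrow(A), ncol(A))
  space <- buildLatentSpace(A, k)
  for (d in dataset@diseaseIds) {
    ranking <- queryDisease(space, d, expand = config@expandQuery,
      hierarchy = dataset@hierarchy)
    ann <- dataset@mirnaIds[dataset@md[, d] == 1]
    novel <- ranking[!(ranking$mirna %in% ann), ]
    novel <- utils::head(novel, topK)
    if (nrow(novel)) {
      out <- rbind(out, data.frame(disease = d, mirna = novel$mirna,
        cosine = novel$cosine, stringsAsFactors = FALSE))
    }
  }
  out[order(-out$cosine, out$disease, out$mirna), ]
}
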