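#' Specification of a planted synthetic dataset
#'
#' The generator emulates the statistical structure the predictor exploits:
#' miRNAs and diseases are partitioned into co-clusters ("groups") and every
#' evidence source carries the same low-rank block signal plus Bernoulli
#' noise -- within-group associations are drawn with probability `pIn`,
#' cross-group ones with `pOut`; genes and families are group-biased the
#' same way; same-group miRNAs are placed within `clusterSpan` bp on a
#' shared chromosome; documents share group-specific vocabulary; and a
#' disease hierarchy nests each group's diseases under a broader class
#' term. A configurable number of cross-group associations are injected as
#' planted errors and of within-group associations deleted as held-out
#' pairs, both recorded in the ground truth.
#'
#' @param nMirnas,nDiseases,nGenes,nFamilies,nGroups sizes.
#' @param pIn,pOut within-/cross-group association probabilities
#'   (0 <= pOut < pIn <= 1).
#' @param hierarchyDepth 2 nests group diseases under class terms under one
#'   root; 1 puts all diseases directly under the root.
#' @param clusterSpan bp span of each group's genomic cluster.
#' @param docVocab group-specific words per group; @param docLength tokens
#'   per document.
#' @param nPlantedErrors,nHeldOut planted wrong / deleted true associations.
#' @param seed generation seed.
#' @return a validated spec list of class `plantedSpec`.
#' @export
plantedSpec <- function(nMirnas = 60L, nDiseases = 12L, nGenes = 40L,
                        nFamilies = 8L, nGroups = 4L, pIn = 0.7,
                        pOut = 0.02, hierarchyDepth = 2L,
                        clusterSpan = 40000L, docVocab = 25L,
                        docLength = 60L, nPlantedErrors = 1L,
                        nHeldOut = 1L, seed = 42L) {
  spec <- list(nMirnas = as.integer(nMirnas),
    nDiseases = as.integer(nDiseases), nGenes = as.integer(nGenes),
    nFamilies = as.integer(nFamilies), nGroups = as.integer(nGroups),
    pIn = pIn, pOut = pOut, hierarchyDepth = as.integer(hierarchyDepth),
    clusterSpan = as.integer(clusterSpan), docVocab = as.integer(docVocab),
    docLength = as.integer(docLength),
    nPlantedErrors = as.integer(nPlantedErrors),
    nHeldOut = as.integer(nHeldOut), seed = as.integer(seed))
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1)) {
    stop("need 0 <= pOut < pIn <= 1", call. = FALSE)
  }
  if (spec$nGroups < 1L || spec$nMirnas < spec$nGroups ||
      spec$nDiseases < spec$nGroups || spec$nGenes < spec$nGroups ||
      spec$nFamilies < spec$nGroups) {
    stop("every group must be non-empty", call. = FALSE)
  }
  if (pIn * floor(spec$nMirnas / spec$nGroups) < 5) {
    stop("infeasible spec: expected within-group associations per disease ",
      "below 5; raise pIn or the group size", call. = FALSE)
  }
  class(spec) <- "plantedSpec"
  spec
}

evenGroups <- function(n, g) sort(rep_len(seq_len(g), n))

#' Generate a planted synthetic dataset
#'
#' Deterministic given the spec seed. See [plantedSpec()] for the planted
#' structure. The ground truth records group memberships, the injected
#' cross-group errors and the deleted within-group pairs, so recovery can
#' be scored.
#'
#' @param spec a [plantedSpec()].
#' @return list with elements `dataset` (a [MirnaDataset-class]) and
#'   `groundTruth` (list `mirnaGroups`, `diseaseGroups`, `plantedErrors`,
#'   `heldOut`).
#' @export
generatePlanted <- function(spec = plantedSpec()) {
  stopifnot(inherits(spec, "plantedSpec"))
  withSeed(spec$seed, {
    mirnaIds <- sprintf("mir-%03d", seq_len(spec$nMirnas))
    mGroup <- evenGroups(spec$nMirnas, spec$nGroups)
    dGroup <- evenGroups(spec$nDiseases, spec$nGroups)
    diseaseIds <- sprintf("disease_g%d_%02d", dGroup,
      stats::ave(dGroup, dGroup, FUN = seq_along))
    gGroup <- evenGroups(spec$nGenes, spec$nGroups)
    geneIds <- sprintf("gene_g%d_%02d", gGroup,
      stats::ave(gGroup, gGroup, FUN = seq_along))
    fGroup <- evenGroups(spec$nFamilies, spec$nGroups)
    familyIds <- sprintf("fam_g%d_%02d", fGroup,
      stats::ave(fGroup, fGroup, FUN = seq_along))

    blockBernoulli <- function(rowGroup, colGroup) {
      same <- outer(rowGroup, colGroup, "==")
      p <- ifelse(same, spec$pIn, spec$pOut)
      matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow(same))
    }
    md <- blockBernoulli(mGroup, dGroup)
    mt <- blockBernoulli(mGroup, gGroup)
    # exactly one group-matching family per miRNA
    mf <- matrix(0, spec$nMirnas, spec$nFamilies)
    for (i in seq_len(spec$nMirnas)) {
      fams <- which(fGroup == mGroup[[i]])
      mf[i, if (length(fams) > 1L) sample(fams, 1L) else fams] <- 1
    }
    # genomic clusters: one chromosome region per group
    start <- 1e6 * mGroup +
      floor(stats::runif(spec$nMirnas, 0, spec$clusterSpan))
    coords <- data.frame(mirna = mirnaIds,
      chrom = paste0("chr", mGroup),
      start = as.integer(start), end = as.integer(start + 80L),
      strand = sample(c("+", "-"), spec$nMirnas, replace = TRUE),
      stringsAsFactors = FALSE)
    # documents: group vocabulary plus a common background vocabulary
    commonWords <- sprintf("common%03d", seq_len(spec$docVocab))
    # tokenization-safe words: alphanumeric, >= 3 characters
    groupWords <- lapply(seq_len(spec$nGroups), function(g) {
      sprintf("topic%02dw%03d", g, seq_len(spec$docVocab))
    })
    vocab <- c(commonWords, unlist(groupWords))
    docs <- lapply(textSources(), function(src) {
      m <- matrix(0, spec$nMirnas, length(vocab),
        dimnames = list(mirnaIds, vocab))
      for (i in seq_len(spec$nMirnas)) {
        pool <- c(groupWords[[mGroup[[i]]]], commonWords)
        prob <- c(rep(3, spec$docVocab), rep(1, spec$docVocab))
        draw <- sample(pool, spec$docLength, replace = TRUE, prob = prob)
        tab <- table(draw)
        m[i, names(tab)] <- as.numeric(tab)
      }
      m
    })
    names(docs) <- textSources()
    # hierarchy: root -> class per group -> group diseases
    if (spec$hierarchyDepth >= 2L) {
      classes <- sprintf("disease_class_g%d", seq_len(spec$nGroups))
      edges <- rbind(
        data.frame(parent = "disease_root", child = classes),
        data.frame(parent = classes[dGroup], child = diseaseIds))
    } else {
      edges <- data.frame(parent = "disease_root", child = diseaseIds)
    }
    hierarchy <- DiseaseHierarchy(edges = edges)

    dimnames(md) <- list(mirnaIds, diseaseIds)
    dimnames(mt) <- list(mirnaIds, geneIds)
    dimnames(mf) <- list(mirnaIds, familyIds)

    # planted cross-group errors
    cross <- which(outer(mGroup, dGroup, "!=") & md == 0, arr.ind = TRUE)
    nErr <- min(spec$nPlantedErrors, nrow(cross))
    errIdx <- if (nErr > 0L) {
      cross[sample(nrow(cross), nErr), , drop = FALSE]
    } else {
      cross[0L, , drop = FALSE]
    }
    for (k in seq_len(nErr)) md[errIdx[k, 1L], errIdx[k, 2L]] <- 1
    plantedErrors <- data.frame(mirna = mirnaIds[errIdx[, 1L]],
      disease = diseaseIds[errIdx[, 2L]], stringsAsFactors = FALSE)

    # held-out within-group true associations
    within <- which(outer(mGroup, dGroup, "==") & md == 1, arr.ind = TRUE)
    nHold <- min(spec$nHeldOut, nrow(within))
    holdIdx <- if (nHold > 0L) {
      within[sample(nrow(within), nHold), , drop = FALSE]
    } else {
      within[0L, , drop = FALSE]
    }
    for (k in seq_len(nHold)) md[holdIdx[k, 1L], holdIdx[k, 2L]] <- 0
    heldOut <- data.frame(mirna = mirnaIds[holdIdx[, 1L]],
      disease = diseaseIds[holdIdx[, 2L]], stringsAsFactors = FALSE)

    dataset <- MirnaDataset(mirnaIds, diseaseIds, md, mt = mt, mf = mf,
      coords = coords, docs = docs, hierarchy = hierarchy)
    list(dataset = dataset,
      groundTruth = list(
        mirnaGroups = stats::setNames(mGroup, mirnaIds),
        diseaseGroups = stats::setNames(dGroup, diseaseIds),
        plantedErrors = plantedErrors, heldOut = heldOut))
  })
}

#' Benchmark fitness functions on 35-bit genomes
#'
#' Pure, deterministic test functions for exercising the optimizer in
#' isolation: `onemax` (number of ones, optimum 35 at the all-ones genome),
#' `leading_ones` (length of the leading run of ones, optimum 35),
#' `quadratic` (smooth unimodal `1 - (hamming(x, target)/N)^2` around a
#' fixed target genome, optimum 1) and `noisy_quadratic` (the same plus a
#' small deterministic genome-hash perturbation of amplitude 0.02).
#'
#' @param name one of `"onemax"`, `"leading_ones"`, `"quadratic"`,
#'   `"noisy_quadratic"`.
#' @param genomeLength genome length N.
#' @return a function(genome) -> numeric(1), with attribute `optimum`.
#' @export
benchmarkFitness <- function(name, genomeLength = 35L) {
  n <- as.integer(genomeLength)
  target <- rep_len(c(1L, 1L, 0L, 1L, 0L), n)
  fn <- switch(name,
    onemax = function(genome) sum(genome),
    leading_ones = function(genome) {
      z <- which(genome == 0)
      if (length(z) == 0L) length(genome) else z[[1L]] - 1L
    },
    quadratic = function(genome) {
      1 - (sum(genome != target) / n)^2
    },
    noisy_quadratic = function(genome) {
      h <- sum(genome * seq_len(n) * 2654435761) %% 1000
      1 - (sum(genome != target) / n)^2 + 0.02 * (h / 1000 - 0.5)
    },
    stop("unknown benchmark: ", name, call. = FALSE))
  attr(fn, "optimum") <- switch(name,
    onemax = n, leading_ones = n, quadratic = 1, noisy_quadratic = 1.01)
  fn
}
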