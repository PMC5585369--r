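#' Construct a multi-source miRNA dataset
#'
#' @param mirnaIds,diseaseIds ordered identifier vectors.
#' @param mt,md,mf binary association matrices (miRNA x gene / disease /
#'   family); dimnames are set from the identifier vectors if missing.
#' @param coords data.frame `mirna`, `chrom`, `start`, `end`, `strand`.
#' @param docs named list of per-source word-count matrices.
#' @param hierarchy a [DiseaseHierarchy-class].
#' @return a validated [MirnaDataset-class].
#' @export
MirnaDataset <- function(mirnaIds, diseaseIds, md,
                         mt = matrix(0, length(mirnaIds), 0),
                         mf = matrix(0, length(mirnaIds), 0),
                         coords = data.frame(mirna = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character()),
                         docs = list(),
                         hierarchy = DiseaseHierarchy()) {
  rownames(mt) <- rownames(md) <- rownames(mf) <- mirnaIds
  colnames(md) <- diseaseIds
  docs <- lapply(docs, function(m) { rownames(m) <- mirnaIds; m })
  new("MirnaDataset", mirnaIds = mirnaIds, diseaseIds = diseaseIds,
    mt = mt, md = md, mf = mf, coords = coords, docs = docs,
    hierarchy = hierarchy)
}

#' Network-based inference weighting of a bipartite association matrix
#'
#' Two-step equal-split mass diffusion on the miRNA-gene bipartite graph.
#' Each row starts with one unit of resource on each of its genes; every
#' gene splits its resource equally among the miRNAs targeting it, then
#' every miRNA splits what it received equally among its target genes. Row
#' sums are conserved; rows with no targets come back all zero.
#'
#' @param mt binary miRNA x gene matrix.
#' @return weighted matrix with the dimnames of `mt`.
#' @examples
#' mt <- rbind(m1 = c(1, 1, 0), m2 = c(0, 1, 1))
#' colnames(mt) <- paste0("g", 1:3)
#' applyNBI(mt)["m1", ]  # 0.75 1.00 0.25
#' @export
applyNBI <- function(mt) {
  stopIfNotBinary(mt, "NBI input")
  kg <- colSums(mt)
  km <- rowSums(mt)
  # gene -> miRNA split, then miRNA -> gene split
  B <- sweep(mt, 2L, ifelse(kg > 0, kg, 1), "/")
  C <- sweep(mt, 1L, ifelse(km > 0, km, 1), "/")
  out <- (mt %*% t(B)) %*% C
  dimnames(out) <- dimnames(mt)
  out
}

#' TF-IDF weighting of a word-count matrix
#'
#' Each miRNA with at least one word counts as a document. The weight of
#' word w in document i is `count(i, w) * ln(N / df(w))` with N the number
#' of documents and df(w) the number of documents containing w. Words that
#' occur in no document are dropped; an empty document set yields a matrix
#' with zero columns.
#'
#' @param wordCounts non-negative integer miRNA x word matrix.
#' @return weighted matrix (rows preserved, all-zero rows for non-documents).
#' @export
applyTFIDF <- function(wordCounts) {
  if (any(wordCounts < 0) || any(!is.finite(wordCounts))) {
    stop("word counts must be finite and non-negative", call. = FALSE)
  }
  isDoc <- rowSums(wordCounts) > 0
  N <- sum(isDoc)
  df <- colSums(wordCounts[isDoc, , drop = FALSE] > 0)
  keep <- df > 0
  out <- wordCounts[, keep, drop = FALSE]
  df <- df[keep]
  if (N > 0L) {
    out <- sweep(out, 2L, log(N / df), "*")
  }
  out
}

#' Propagate disease annotations to broader terms
#'
#' Sets, for every annotated (miRNA, disease) pair, all subsuming
#' (transitively broader) terms of the disease that are columns of `md` to
#' 1 as well. E.g. an annotation to "Colonic Neoplasms" implies one to
#' "Colorectal Neoplasms" when the former is nested under the latter. The
#' operation is idempotent and only adds annotations. Columns absent from
#' the hierarchy are passed through untouched.
#'
#' @param md binary miRNA x disease matrix with disease column names.
#' @param hierarchy a [DiseaseHierarchy-class].
#' @return binary matrix of the same shape.
#' @export
inferDiseases <- function(md, hierarchy) {
  stopIfNotBinary(md, "md")
  out <- md
  for (d in colnames(md)) {
    if (!d %in% hierarchy@terms) next
    anc <- diseaseAncestors(hierarchy, d, includeSelf = FALSE)
    anc <- intersect(anc, colnames(md))
    if (length(anc)) {
      out[, anc] <- pmax(out[, anc, drop = FALSE], md[, d])
    }
  }
  out
}

#' Similarity-augmented weight of a miRNA-disease association
#'
#' The association weight m in [0, 1] of (miRNA, disease) is the maximum
#' semantic similarity between the queried disease and any disease the
#' miRNA is annotated to; a miRNA directly annotated to the disease scores
#' 1, one with no annotations scores 0.
#'
#' @param mirna miRNA identifier (a row name of `md`).
#' @param disease queried disease term (a column name of `md`).
#' @param md binary miRNA x disease matrix.
#' @param hierarchy a [DiseaseHierarchy-class].
#' @param measure similarity function with the signature of
#'   [diseaseSimilarity()].
#' @return a real number in [0, 1].
#' @export
associationWeight <- function(mirna, disease, md, hierarchy,
                              measure = diseaseSimilarity) {
  if (!mirna %in% rownames(md)) stop("unknown miRNA: ", mirna, call. = FALSE)
  if (!disease %in% colnames(md)) {
    stop("unknown disease: ", disease, call. = FALSE)
  }
  ann <- colnames(md)[md[mirna, ] == 1]
  if (length(ann) == 0L) return(0)
  max(vapply(ann, function(d) measure(disease, d, hierarchy, strict = FALSE),
    numeric(1)))
}

#' Discretize an association weight into overlapping indicator bins
#'
#' With cutoffs c1 < c2 < ... < ck, a weight m below c1 maps to the single
#' indicator `no_assoc`; otherwise it maps to one indicator `>=cj` for every
#' cutoff cj <= m (overlapping upper bins). A value exactly at a cutoff goes
#' to the upper bins only, so e.g. m = 0.8 with cutoffs 1/3 and 2/3 yields
#' both `>=0.3333` and `>=0.6667`.
#'
#' @param m association weight in [0, 1].
#' @param cutoffs strictly increasing cutoffs in (0, 1).
#' @return character vector of indicator labels.
#' @export
discretizeWeight <- function(m, cutoffs) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > 1) {
    stop("association weight must be a single value in [0, 1]", call. = FALSE)
  }
  if (length(cutoffs) == 0L) stop("at least one cutoff required", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  if (m < cutoffs[[1L]]) return("no_assoc")
  paste0(">=", fmtCutoff(cutoffs[cutoffs <= m]))
}

# element-wise so a cutoff's label never depends on the rest of the vector
fmtCutoff <- function(cutoffs) {
  vapply(cutoffs, function(x) format(x, trim = TRUE), character(1))
}

binLabels <- function(cutoffs) {
  c("no_assoc", paste0(">=", fmtCutoff(cutoffs)))
}

#' Genomic-proximity weights between miRNAs
#'
#' Linear decay of co-location: w_ij = max(0, 1 - |start_i - start_j| / D)
#' when the two miRNAs sit on the same chromosome (strand ignored), 0
#' otherwise; the diagonal is forced to 0. Clustered miRNAs tend to be
#' co-transcribed, which motivates the proximity signal; the window D
#' defaults to 50 kb.
#'
#' @param coords data.frame `mirna`, `chrom`, `start`, `end`, `strand`.
#' @param mirnaIds row/column order of the output; miRNAs without
#'   coordinates get zero rows (with a message).
#' @param window decay window D in bp.
#' @return symmetric miRNA x miRNA weight matrix.
#' @export
neighborWeights <- function(coords, mirnaIds = coords$mirna,
                            window = 50000) {
  n <- length(mirnaIds)
  W <- matrix(0, n, n, dimnames = list(mirnaIds, mirnaIds))
  idx <- match(mirnaIds, coords$mirna)
  missing <- is.na(idx)
  if (any(missing)) {
    message("no coordinates for ", sum(missing),
      " miRNA(s); zero neighbour rows emitted")
  }
  chrom <- coords$chrom[idx]
  start <- coords$start[idx]
  ok <- !missing & !is.na(chrom) & !is.na(start)
  for (i in which(ok)) {
    same <- ok & chrom == chrom[[i]]
    w <- pmax(0, 1 - abs(start - start[[i]]) / window)
    W[i, same] <- w[same]
  }
  diag(W) <- 0
  W
}

#' Build the (possibly discretized) disease block
#'
#' The mandatory block of the assembled matrix. Depending on the
#' configuration, disease annotations are first propagated to broader terms
#' ([inferDiseases()]); then, if no cutoffs are configured, the raw binary
#' matrix is returned. Otherwise every (miRNA, disease) pair receives its
#' similarity-augmented weight ([associationWeight()]) and is expanded into
#' one indicator column per disease and bin ([discretizeWeight()]), i.e.
#' `|diseases| * (1 + |cutoffs|)` columns.
#'
#' @param md binary miRNA x disease matrix.
#' @param hierarchy a [DiseaseHierarchy-class].
#' @param config a [MiraiConfig-class].
#' @param holdoutDisease optional disease excluded from the similarity
#'   augmentation (its column keeps its raw 0/1 weights); used by the
#'   cross-validation protocol so the evaluated disease never borrows
#'   similarity signal.
#' @param measure similarity function, see [diseaseSimilarity()].
#' @return weighted matrix with `disease:`-namespaced columns.
#' @export
buildDiseaseBlock <- function(md, hierarchy, config, holdoutDisease = NULL,
                              measure = diseaseSimilarity) {
  stopIfNotBinary(md, "md")
  if (config@inferInMatrix) md <- inferDiseases(md, hierarchy)
  diseases <- colnames(md)
  if (length(config@cutoffs) == 0L) {
    out <- md
    colnames(out) <- paste0("disease:", diseases)
    return(out)
  }
  S <- similarityMatrix(hierarchy, diseases, measure = measure)
  W <- matrix(0, nrow(md), length(diseases), dimnames = dimnames(md))
  for (i in seq_len(nrow(md))) {
    ann <- md[i, ] == 1
    if (any(ann)) W[i, ] <- apply(S[ann, , drop = FALSE], 2L, max)
  }
  if (!is.null(holdoutDisease) && holdoutDisease %in% diseases) {
    W[, holdoutDisease] <- md[, holdoutDisease]
  }
  cuts <- config@cutoffs
  labs <- binLabels(cuts)
  cols <- as.vector(t(outer(diseases, labs, function(d, l) {
    paste0("disease:", d, "@", l)
  })))
  out <- matrix(0, nrow(md), length(cols),
    dimnames = list(rownames(md), cols))
  for (d in seq_along(diseases)) {
    base <- (d - 1L) * length(labs)
    out[, base + 1L] <- as.numeric(W[, d] < cuts[[1L]])
    for (k in seq_along(cuts)) {
      out[, base + 1L + k] <- as.numeric(W[, d] >= cuts[[k]])
    }
  }
  out
}
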