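# Tab-separated readers for the exchange formats: association lists,
# genomic coordinates, hierarchy edges and per-miRNA documents. All files
# are UTF-8 TSV with a header line; '#' lines are comments.

readTsv <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
    comment.char = "#", quote = "", stringsAsFactors = FALSE,
    fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(path, " lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  df
}

#' Read the tab-separated exchange formats
#'
#' `readAssociationTable` reads a two-column association list
#' (`mirna<TAB><value>`); `readCoordinateTable` a coordinate table
#' (`mirna, chrom, start, end, strand`; 1-based inclusive);
#' `readHierarchyTable` a `parent<TAB>child` edge list; and
#' `readDocumentTable` per-miRNA documents (`mirna, source, text`).
#' Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param valueCol name of the second association column (e.g. `"disease"`).
#' @return a data.frame.
#' @export
readAssociationTable <- function(path, valueCol) {
  readTsv(path, c("mirna", valueCol))
}

#' @rdname readAssociationTable
#' @export
readCoordinateTable <- function(path) {
  df <- readTsv(path, c("mirna", "chrom", "start", "end", "strand"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname readAssociationTable
#' @export
readHierarchyTable <- function(path) {
  readTsv(path, c("parent", "child"))
}

#' @rdname readAssociationTable
#' @export
readDocumentTable <- function(path) {
  readTsv(path, c("mirna", "source", "text"))
}

#' Tokenize free text for the word-count matrix
#'
#' Lowercases, splits on non-alphanumeric characters and drops tokens
#' shorter than 3 characters. No stemming is applied.
#'
#' @param text character vector.
#' @return list of token vectors, one per input element.
#' @export
tokenizeText <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nchar(t) >= 3L])
}

associationsToMatrix <- function(df, rowIds, colIds, valueCol) {
  m <- matrix(0, length(rowIds), length(colIds),
    dimnames = list(rowIds, colIds))
  if (nrow(df)) {
    m[cbind(match(df$mirna, rowIds), match(df[[valueCol]], colIds))] <- 1
  }
  m
}

#' Read a dataset directory
#'
#' Expects the TSV dialects written by [writeDataset()]:
#' `mirna_disease.tsv`, `mirna_gene.tsv`, `mirna_family.tsv`, `coords.tsv`,
#' `hierarchy.tsv` and (optionally) `documents.tsv`. The miRNA universe is
#' the union of identifiers across files, ordered lexicographically;
#' diseases are the terms of the miRNA-disease file.
#'
#' @param dir directory path.
#' @return a [MirnaDataset-class].
#' @export
readDataset <- function(dir) {
  mdTab <- readAssociationTable(file.path(dir, "mirna_disease.tsv"),
    "disease")
  mtTab <- readAssociationTable(file.path(dir, "mirna_gene.tsv"), "gene")
  mfTab <- readAssociationTable(file.path(dir, "mirna_family.tsv"),
    "family")
  coords <- readCoordinateTable(file.path(dir, "coords.tsv"))
  hierTab <- readHierarchyTable(file.path(dir, "hierarchy.tsv"))
  mirnaIds <- sort(unique(c(mdTab$mirna, mtTab$mirna, mfTab$mirna,
    coords$mirna)))
  diseaseIds <- sort(unique(mdTab$disease))
  md <- associationsToMatrix(mdTab, mirnaIds, diseaseIds, "disease")
  mt <- associationsToMatrix(mtTab, mirnaIds, sort(unique(mtTab$gene)),
    "gene")
  mf <- associationsToMatrix(mfTab, mirnaIds, sort(unique(mfTab$family)),
    "family")
  docs <- list()
  docPath <- file.path(dir, "documents.tsv")
  if (file.exists(docPath)) {
    docTab <- readDocumentTable(docPath)
    for (src in intersect(textSources(), unique(docTab$source))) {
      sub <- docTab[docTab$source == src, ]
      toks <- tokenizeText(sub$text)
      vocab <- sort(unique(unlist(toks)))
      m <- matrix(0, length(mirnaIds), length(vocab),
        dimnames = list(mirnaIds, vocab))
      for (k in seq_len(nrow(sub))) {
        tab <- table(toks[[k]])
        i <- match(sub$mirna[[k]], mirnaIds)
        m[i, names(tab)] <- m[i, names(tab)] + as.numeric(tab)
      }
      docs[[src]] <- m
    }
  }
  hierarchy <- DiseaseHierarchy(terms = diseaseIds, edges = hierTab)
  MirnaDataset(mirnaIds, diseaseIds, md, mt = mt, mf = mf,
    coords = coords, docs = docs, hierarchy = hierarchy)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

matrixToAssociations <- function(m, valueCol) {
  idx <- which(m == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(mirna = rownames(m)[idx[, 1L]],
    value = colnames(m)[idx[, 2L]], stringsAsFactors = FALSE)
  names(df)[2L] <- valueCol
  df
}

#' Write a dataset directory
#'
#' Writes the TSV exchange files read back by [readDataset()]. Documents
#' are serialized by repeating each counted token, which round-trips
#' through [tokenizeText()].
#'
#' @param dataset a [MirnaDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(matrixToAssociations(dataset@md, "disease"),
    file.path(dir, "mirna_disease.tsv"))
  writeTsv(matrixToAssociations(dataset@mt, "gene"),
    file.path(dir, "mirna_gene.tsv"))
  writeTsv(matrixToAssociations(dataset@mf, "family"),
    file.path(dir, "mirna_family.tsv"))
  writeTsv(dataset@coords, file.path(dir, "coords.tsv"))
  e <- dataset@hierarchy@edges
  writeTsv(as.data.frame(e, stringsAsFactors = FALSE),
    file.path(dir, "hierarchy.tsv"))
  if (length(dataset@docs)) {
    rows <- list()
    for (src in names(dataset@docs)) {
      m <- dataset@docs[[src]]
      for (i in seq_len(nrow(m))) {
        nz <- which(m[i, ] > 0)
        if (length(nz) == 0L) next
        text <- paste(rep(colnames(m)[nz], m[i, nz]), collapse = " ")
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = rownames(m)[[i]], source = src, text = text,
          stringsAsFactors = FALSE)
      }
    }
    writeTsv(do.call(rbind, rows), file.path(dir, "documents.tsv"))
  }
  invisible(dir)
}
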