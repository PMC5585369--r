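#' Construct a disease hierarchy
#'
#' @param terms character vector of disease terms. Endpoints of `edges` are
#'   added automatically.
#' @param edges data.frame (or two-column matrix) of parent -> child pairs,
#'   parent being the broader term.
#' @return a [DiseaseHierarchy-class] object; construction fails on cycles.
#' @examples
#' h <- DiseaseHierarchy(
#'   edges = data.frame(parent = c("neoplasms", "colorectal"),
#'                      child  = c("colorectal", "colonic")))
#' diseaseAncestors(h, "colonic")
#' @export
DiseaseHierarchy <- function(terms = character(), edges = NULL) {
  if (is.null(edges)) {
    e <- matrix(character(), ncol = 2L,
      dimnames = list(NULL, c("parent", "child")))
  } else {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    colnames(e) <- c("parent", "child")
    storage.mode(e) <- "character"
  }
  terms <- unique(c(terms, as.character(e)))
  new("DiseaseHierarchy", terms = terms, edges = e)
}

# Named list term -> character vector of direct parents.
parentMap <- function(hierarchy) {
  split(hierarchy@edges[, "parent"], hierarchy@edges[, "child"])
}

childMap <- function(hierarchy) {
  split(hierarchy@edges[, "child"], hierarchy@edges[, "parent"])
}

transitiveClosure <- function(start, stepMap) {
  out <- character()
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(stepMap[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Ancestors and descendants of a disease term
#'
#' Ancestors are the transitively broader (subsuming) terms; descendants the
#' transitively more specific ones.
#'
#' @param hierarchy a [DiseaseHierarchy-class].
#' @param term a term present in the hierarchy.
#' @param includeSelf include the term itself in the result.
#' @param excludeRoots drop terms that have no parent (the hierarchy roots);
#'   used by the similarity measure so that sharing only the root carries no
#'   information.
#' @return character vector of terms.
#' @export
diseaseAncestors <- function(hierarchy, term, includeSelf = TRUE,
                             excludeRoots = FALSE) {
  if (!term %in% hierarchy@terms) {
    stop("unknown disease term: ", term, call. = FALSE)
  }
  anc <- transitiveClosure(term, parentMap(hierarchy))
  if (includeSelf) anc <- unique(c(term, anc))
  if (excludeRoots) {
    roots <- setdiff(hierarchy@terms, hierarchy@edges[, "child"])
    anc <- setdiff(anc, roots)
  }
  anc
}

#' @rdname diseaseAncestors
#' @export
diseaseDescendants <- function(hierarchy, term, includeSelf = FALSE) {
  if (!term %in% hierarchy@terms) {
    stop("unknown disease term: ", term, call. = FALSE)
  }
  dsc <- transitiveClosure(term, childMap(hierarchy))
  if (includeSelf) dsc <- unique(c(term, dsc))
  dsc
}

#' Semantic similarity between two disease terms
#'
#' Ancestor-Dice similarity: with A(d) the self-inclusive, root-exclusive
#' ancestor set of d, sim(d1, d2) = 2 |A(d1) n A(d2)| / (|A(d1)| + |A(d2)|).
#' It is symmetric, sim(d, d) = 1, and 0 when the two terms share no
#' non-root ancestor. Any hierarchy-only measure with these properties can
#' be substituted through the `measure` argument of the matrix-building
#' functions.
#'
#' @param d1,d2 disease terms.
#' @param hierarchy a [DiseaseHierarchy-class].
#' @param strict error on a term absent from the hierarchy (default). With
#'   `strict = FALSE` an unknown term is similar only to itself (1) and has
#'   similarity 0 to every other term.
#' @return a real number in [0, 1].
#' @examples
#' h <- DiseaseHierarchy(edges = data.frame(
#'   parent = c("root", "A", "A"), child = c("A", "B", "C")))
#' diseaseSimilarity("B", "C", h)  # share {A}: 2*1/(2+2) = 0.5
#' @export
diseaseSimilarity <- function(d1, d2, hierarchy, strict = TRUE) {
  known <- c(d1, d2) %in% hierarchy@terms
  if (!all(known)) {
    if (strict) {
      stop("unknown disease term: ", c(d1, d2)[!known][[1L]], call. = FALSE)
    }
    return(if (identical(d1, d2)) 1 else 0)
  }
  if (identical(d1, d2)) return(1)
  a1 <- diseaseAncestors(hierarchy, d1, includeSelf = TRUE, excludeRoots = TRUE)
  a2 <- diseaseAncestors(hierarchy, d2, includeSelf = TRUE, excludeRoots = TRUE)
  if (length(a1) == 0L || length(a2) == 0L) return(0)
  2 * length(intersect(a1, a2)) / (length(a1) + length(a2))
}

# Pairwise similarity matrix over `terms`, tolerant of unknown terms.
similarityMatrix <- function(hierarchy, terms,
                             measure = diseaseSimilarity) {
  n <- length(terms)
  S <- diag(1, n)
  dimnames(S) <- list(terms, terms)
  if (n < 2L) return(S)
  ancSets <- lapply(terms, function(d) {
    if (d %in% hierarchy@terms) {
      diseaseAncestors(hierarchy, d, includeSelf = TRUE, excludeRoots = TRUE)
    } else {
      NULL # unknown: similar only to itself
    }
  })
  defaultMeasure <- identical(measure, diseaseSimilarity)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- if (defaultMeasure) {
        a1 <- ancSets[[i]]; a2 <- ancSets[[j]]
        if (is.null(a1) || is.null(a2) || !length(a1) || !length(a2)) 0
        else 2 * length(intersect(a1, a2)) / (length(a1) + length(a2))
      } else {
        measure(terms[[i]], terms[[j]], hierarchy, strict = FALSE)
      }
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}
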