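#' Reflected binary (Gray) code conversions
#'
#' `grayToInt` decodes a Gray-coded bit vector (first element most
#' significant) to its integer; `intToGray` is the inverse. Consecutive
#' integers differ in exactly one Gray bit.
#'
#' @param bits integer/numeric vector of 0/1 values.
#' @param n non-negative integer `< 2^width`.
#' @param width number of bits of the Gray field.
#' @return an integer, respectively an integer vector of 0/1 values.
#' @examples
#' grayToInt(c(0, 1, 0, 0))  # 7
#' intToGray(7, 4)           # 0 1 0 0
#' @export
grayToInt <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("bits must be 0/1", call. = FALSE)
  b <- as.integer(bits)
  for (i in seq_along(b)[-1L]) b[i] <- bitwXor(b[i - 1L], b[i])
  sum(b * 2L^(rev(seq_along(b)) - 1L))
}

#' @rdname grayToInt
#' @export
intToGray <- function(n, width = 4L) {
  if (n < 0 || n >= 2^width) {
    stop("n must lie in [0, ", 2^width - 1, "]", call. = FALSE)
  }
  b <- as.integer(intToBits(n))[seq_len(width)]
  b <- rev(b) # most significant first
  g <- b
  for (i in seq_along(b)[-1L]) g[i] <- bitwXor(b[i - 1L], b[i])
  g
}

#' Construct a configuration directly
#'
#' @param useTargets,useFamily,useNeighbors,usePubmed,useMirbaseAbstracts,useMirbaseDescription
#'   source inclusion flags.
#' @param nbiOnTargets,tfidfPubmed,tfidfMirbaseAbstracts,tfidfMirbaseDescription,inferInMatrix
#'   transformation flags.
#' @param cutoffs ascending cutoffs on the 0.05 grid (possibly empty).
#' @param dim latent dimension, a multiple of 50 in [50, 800].
#' @param expandQuery expand disease queries with descendant terms.
#' @return a validated [MiraiConfig-class].
#' @export
MiraiConfig <- function(useTargets = FALSE, useFamily = FALSE,
                        useNeighbors = FALSE, usePubmed = FALSE,
                        useMirbaseAbstracts = FALSE,
                        useMirbaseDescription = FALSE,
                        nbiOnTargets = FALSE, tfidfPubmed = FALSE,
                        tfidfMirbaseAbstracts = FALSE,
                        tfidfMirbaseDescription = FALSE,
                        inferInMatrix = FALSE, cutoffs = numeric(),
                        dim = 50L, expandQuery = FALSE) {
  new("MiraiConfig", useTargets = useTargets, useFamily = useFamily,
    useNeighbors = useNeighbors, usePubmed = usePubmed,
    useMirbaseAbstracts = useMirbaseAbstracts,
    useMirbaseDescription = useMirbaseDescription,
    nbiOnTargets = nbiOnTargets, tfidfPubmed = tfidfPubmed,
    tfidfMirbaseAbstracts = tfidfMirbaseAbstracts,
    tfidfMirbaseDescription = tfidfMirbaseDescription,
    inferInMatrix = inferInMatrix, cutoffs = as.numeric(cutoffs),
    dim = as.integer(dim), expandQuery = expandQuery)
}

#' Decode a 35-bit genome into a configuration
#'
#' Bit layout (1-based): 1-6 source inclusion (targets, family, neighbours,
#' PubMed abstracts, miRBase abstracts, miRBase descriptions); 7 NBI on
#' targets; 8-10 TF-IDF on the three text sources; 11 inference of broader
#' diseases in the matrix; 12-30 the nineteen discretization cutoffs
#' 0.05 k for k = 1..19; 31-34 the Gray-coded latent dimension (bit 31 most
#' significant, `dim = 50 (d + 1)` with d the decoded integer); 35 query
#' expansion. The mandatory disease source has no bit.
#'
#' @param genome integer/numeric vector of exactly 35 bits, or a 35-character
#'   "0"/"1" string.
#' @return a [MiraiConfig-class].
#' @examples
#' cfg <- decodeGenome(strrep("0", 35))
#' cfg@dim  # 50
#' @export
decodeGenome <- function(genome) {
  g <- parseGenome(genome)
  d <- grayToInt(g[31:34])
  MiraiConfig(
    useTargets = g[1] == 1L, useFamily = g[2] == 1L,
    useNeighbors = g[3] == 1L, usePubmed = g[4] == 1L,
    useMirbaseAbstracts = g[5] == 1L, useMirbaseDescription = g[6] == 1L,
    nbiOnTargets = g[7] == 1L, tfidfPubmed = g[8] == 1L,
    tfidfMirbaseAbstracts = g[9] == 1L, tfidfMirbaseDescription = g[10] == 1L,
    inferInMatrix = g[11] == 1L,
    cutoffs = cutoffGrid()[g[12:30] == 1L],
    dim = 50L * (d + 1L),
    expandQuery = g[35] == 1L)
}

#' Encode a configuration into its 35-bit genome
#'
#' Inverse of [decodeGenome()]: `decodeGenome(encodeGenome(cfg))` recovers
#' `cfg` for every representable configuration.
#'
#' @param config a [MiraiConfig-class].
#' @return integer vector of 35 bits.
#' @export
encodeGenome <- function(config) {
  validObject(config)
  cutBits <- integer(19L)
  for (c in config@cutoffs) {
    k <- which(abs(cutoffGrid() - c) < 1e-9)
    cutBits[k] <- 1L
  }
  as.integer(c(
    config@useTargets, config@useFamily, config@useNeighbors,
    config@usePubmed, config@useMirbaseAbstracts,
    config@useMirbaseDescription,
    config@nbiOnTargets, config@tfidfPubmed, config@tfidfMirbaseAbstracts,
    config@tfidfMirbaseDescription, config@inferInMatrix,
    cutBits,
    intToGray(config@dim %/% 50L - 1L, 4L),
    config@expandQuery))
}

#' Parse / format the genome literal syntax
#'
#' A genome literal is a 35-character string of "0"/"1", bit 1 leftmost.
#'
#' @param genome a bit vector or genome string.
#' @return `parseGenome` returns an integer vector of 35 bits;
#'   `formatGenome` the 35-character string.
#' @export
parseGenome <- function(genome) {
  if (is.character(genome)) {
    if (length(genome) != 1L || !grepl("^[01]+$", genome)) {
      stop("genome string must contain only 0/1", call. = FALSE)
    }
    genome <- as.integer(strsplit(genome, "")[[1L]])
  }
  if (length(genome) != 35L) {
    stop("genome must have exactly 35 bits, got ", length(genome),
      call. = FALSE)
  }
  if (!all(genome %in% c(0, 1))) stop("genome bits must be 0/1", call. = FALSE)
  as.integer(genome)
}

#' @rdname parseGenome
#' @export
formatGenome <- function(genome) {
  paste(as.integer(genome), collapse = "")
}
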