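# Shared fixtures, all generated in code.

# chain hierarchy: root -> A -> {B, C}
chainHierarchy <- function() {
  DiseaseHierarchy(edges = data.frame(
    parent = c("root", "A", "A"), child = c("A", "B", "C")))
}

# the default planted fixture (seed 42), generated once per test run
plantedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePlanted(plantedSpec())
    cache
  }
})

# configuration mirroring the reported best parametrization, at a latent
# dimension the 60-miRNA fixture can support
informativeConfig <- function() {
  MiraiConfig(useTargets = TRUE, useFamily = TRUE, useNeighbors = TRUE,
    nbiOnTargets = TRUE, inferInMatrix = TRUE,
    cutoffs = c(0.05, 0.25, 0.65), dim = 50L, expandQuery = TRUE)
}

# tiny 4-miRNA, 2-disease dataset for exercising the assembly plumbing
tinyDataset <- function() {
  mirnas <- paste0("m", 1:4)
  diseases <- c("d1", "d2")
  md <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  mt <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  colnames(mt) <- paste0("g", 1:3)
  mf <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  colnames(mf) <- c("f1", "f2")
  coords <- data.frame(mirna = mirnas, chrom = c("chr1", "chr1", "chr2",
    "chr2"), start = c(100L, 25100L, 100L, 500100L),
    end = c(180L, 25180L, 180L, 500180L),
    strand = c("+", "-", "+", "-"), stringsAsFactors = FALSE)
  docs <- list(pubmed = matrix(c(2, 0, 0, 0, 0, 3, 1, 1), 4, 2,
    dimnames = list(mirnas, c("cancer", "pathway"))))
  h <- DiseaseHierarchy(edges = data.frame(
    parent = c("root", "root"), child = c("d1", "d2")))
  MirnaDataset(mirnas, diseases, md, mt = mt, mf = mf, coords = coords,
    docs = docs, hierarchy = h)
}

randomGenome <- function(n = 35L) sample(0:1, n, replace = TRUE)
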