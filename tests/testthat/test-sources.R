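test_that("network-based inference performs two-step equal-split diffusion", {
  mt <- rbind(m1 = c(1, 1, 0), m2 = c(0, 1, 1))
  colnames(mt) <- paste0("g", 1:3)
  out <- applyNBI(mt)
  # hand-executed diffusion: step 1 gives m1 = 1.5, m2 = 0.5
  expect_equal(unname(out["m1", ]), c(0.75, 1.0, 0.25))
  # fixed point: a single miRNA targeting a single gene
  one <- matrix(1, 1, 1, dimnames = list("m", "g"))
  expect_equal(unname(applyNBI(one)[1, 1]), 1)
  # all-zero row stays all-zero
  mt2 <- rbind(a = c(1, 1), b = c(0, 0))
  expect_equal(unname(applyNBI(mt2)["b", ]), c(0, 0))
  expect_error(applyNBI(rbind(c(0.5, 1))), "binary")
})

test_that("diffusion conserves each row's resource on random binary matrices", {
  set.seed(1)
  for (rep in 1:10) {
    m <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12)
    out <- applyNBI(m)
    expect_equal(rowSums(out), rowSums(m), tolerance = 1e-12)
    expect_true(all(out >= 0))
  }
})

test_that("TF-IDF weights are count * ln(N/df) and drop absent words", {
  wc <- rbind(a = c(3, 1), b = c(0, 2))
  colnames(wc) <- c("rare", "everywhere")
  out <- applyTFIDF(wc)
  expect_equal(out["a", "rare"], 3 * log(2))
  # word in every document gets weight 0 everywhere
  expect_equal(unname(out[, "everywhere"]), c(0, 0))
  # absent words are dropped
  wc2 <- cbind(wc, never = c(0, 0))
  expect_false("never" %in% colnames(applyTFIDF(wc2)))
  # empty document set: zero columns, not an error
  empty <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_equal(ncol(applyTFIDF(empty)), 0L)
  # constant corpus is the zero matrix
  const <- matrix(1, 3, 4)
  expect_true(all(applyTFIDF(const) == 0))
})

test_that("disease inference propagates to broader terms, idempotently", {
  h <- DiseaseHierarchy(edges = data.frame(
    parent = c("colorectal"), child = c("colonic")))
  md <- matrix(c(1, 0, 0, 0), 2, 2,
    dimnames = list(c("m1", "m2"), c("colonic", "colorectal")))
  out <- inferDiseases(md, h)
  expect_equal(out["m1", "colorectal"], 1)
  expect_equal(inferDiseases(out, h), out) # idempotent
  expect_true(all(out >= md))              # monotone: only adds 1s
  # flat hierarchy: unchanged
  flat <- DiseaseHierarchy(terms = c("colonic", "colorectal"))
  expect_equal(inferDiseases(md, flat), md)
  # cyclic hierarchy rejected at construction
  expect_error(DiseaseHierarchy(edges = data.frame(
    parent = c("a", "b"), child = c("b", "a"))), "cycle")
})

test_that("ancestor-Dice similarity matches its closed form on the chain", {
  h <- chainHierarchy()
  expect_equal(diseaseSimilarity("B", "B", h), 1)
  expect_equal(diseaseSimilarity("B", "C", h), 0.5) # share {A}
  expect_equal(diseaseSimilarity("B", "C", h), diseaseSimilarity("C", "B", h))
  # two children of the root only share the (excluded) root
  h2 <- DiseaseHierarchy(edges = data.frame(
    parent = c("root", "root"), child = c("x", "y")))
  expect_equal(diseaseSimilarity("x", "y", h2), 0)
  expect_error(diseaseSimilarity("B", "nope", h), "nope")
  expect_equal(diseaseSimilarity("B", "nope", h, strict = FALSE), 0)
})

test_that("similarity agrees with brute-force ancestor enumeration on random DAGs", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    terms <- paste0("t", seq_len(n))
    # random DAG: edges only from lower to higher index
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) adj[i, j] <- runif(1) < 0.15
    }
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    h <- DiseaseHierarchy(terms, data.frame(
      parent = terms[idx[, 1]], child = terms[idx[, 2]]))
    # oracle: reachability by boolean matrix powers (independent algorithm)
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
    roots <- which(colSums(adj) == 0)
    ancOracle <- function(j) setdiff(c(j, which(reach[, j])), roots)
    pair <- sample(n, 2)
    a1 <- ancOracle(pair[1]); a2 <- ancOracle(pair[2])
    want <- if (!length(a1) || !length(a2)) 0 else
      2 * length(intersect(a1, a2)) / (length(a1) + length(a2))
    expect_equal(
      diseaseSimilarity(terms[pair[1]], terms[pair[2]], h), want)
  }
})

test_that("association weight is the max similarity to any annotated disease", {
  h <- chainHierarchy()
  md <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
    dimnames = list(c("m1", "m2"), c("B", "C", "A")))
  expect_equal(associationWeight("m1", "B", md, h), 1)   # direct annotation
  expect_equal(associationWeight("m2", "B", md, h), 0)   # no annotations
  expect_equal(associationWeight("m1", "C", md, h), 0.5) # sibling via A
})

test_that("discretization yields overlapping upper bins and a strict no_assoc", {
  cuts <- c(1 / 3, 2 / 3)
  expect_length(discretizeWeight(0.8, cuts), 2L) # both upper bins
  expect_equal(discretizeWeight(0, cuts), "no_assoc")
  expect_length(discretizeWeight(1, c(0.2, 0.5, 0.9)), 3L)
  # a value exactly at a cutoff goes to the upper bin only
  expect_false("no_assoc" %in% discretizeWeight(1 / 3, cuts))
  # monotone non-decreasing bin count past the first cutoff
  sizes <- vapply(seq(0.34, 1, by = 0.05),
    function(m) length(discretizeWeight(m, cuts)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(discretizeWeight(1.2, cuts), "0, 1")
})

test_that("neighbour weights decay linearly on shared chromosomes", {
  coords <- data.frame(mirna = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 1000L, 26000L, 1000L),
    end = c(1080L, 1080L, 26080L, 1080L),
    strand = "+", stringsAsFactors = FALSE)
  W <- neighborWeights(coords, window = 50000)
  expect_equal(W["a", "b"], 1)          # same position
  expect_equal(W["a", "c"], 0.5)        # 25 kb of a 50 kb window
  expect_equal(W["a", "d"], 0)          # different chromosome
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(0, 4))
  # miRNA without coordinates: zero row
  expect_message(W2 <- neighborWeights(coords, c(coords$mirna, "ghost")),
    "no coordinates")
  expect_equal(unname(W2["ghost", ]), rep(0, 5))
})

test_that("the disease block honours cutoffs, inference and pass-through", {
  ds <- tinyDataset()
  cfg0 <- MiraiConfig() # no cutoffs, no inference
  blk <- buildDiseaseBlock(ds@md, ds@hierarchy, cfg0)
  expect_equal(unname(blk), unname(ds@md))
  expect_equal(colnames(blk), paste0("disease:", ds@diseaseIds))
  # one cutoff: 2 columns per disease (no_assoc + one bin)
  cfg1 <- MiraiConfig(cutoffs = 0.05)
  blk1 <- buildDiseaseBlock(ds@md, ds@hierarchy, cfg1)
  expect_equal(ncol(blk1), 2L * length(ds@diseaseIds))
  # annotated pairs have weight 1 >= 0.5 -> indicator 1
  cfg5 <- MiraiConfig(cutoffs = 0.5)
  blk5 <- buildDiseaseBlock(ds@md, ds@hierarchy, cfg5)
  expect_equal(unname(blk5[, "disease:d1@>=0.5"]), unname(ds@md[, "d1"]))
  # holdout disease keeps raw weights only
  md2 <- ds@md
  h <- chainHierarchy()
  mdc <- matrix(c(1, 0, 0, 0), 2, 2,
    dimnames = list(c("m1", "m2"), c("B", "C")))
  withHold <- buildDiseaseBlock(mdc, h, MiraiConfig(cutoffs = 0.25),
    holdoutDisease = "C")
  # m1 is annotated to B (sim 0.5 to C) but C is held out -> no_assoc
  expect_equal(unname(withHold["m1", "disease:C@no_assoc"]), 1)
})
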