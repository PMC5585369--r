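test_that("assembly concatenates the configured blocks with namespaces", {
  ds <- tinyDataset()
  # all source bits off: disease block only
  A0 <- assembleMatrix(ds, MiraiConfig())
  expect_equal(colnames(A0), paste0("disease:", ds@diseaseIds))
  # targets on, NBI off: raw 0/1 gene columns
  At <- assembleMatrix(ds, MiraiConfig(useTargets = TRUE))
  geneCols <- At[, startsWith(colnames(At), "gene:")]
  expect_equal(unname(geneCols), unname(ds@mt))
  # NBI on: weighted, rows conserved
  An <- assembleMatrix(ds, MiraiConfig(useTargets = TRUE,
    nbiOnTargets = TRUE))
  expect_equal(rowSums(An[, startsWith(colnames(An), "gene:")]),
    rowSums(ds@mt), tolerance = 1e-12)
  # family block: exactly one 1 per row for miRNAs with a family
  Af <- assembleMatrix(ds, MiraiConfig(useFamily = TRUE))
  expect_equal(unname(rowSums(Af[, startsWith(colnames(Af), "fam:")])),
    rep(1, 4))
  # fixed block order
  Aall <- assembleMatrix(ds, MiraiConfig(useTargets = TRUE,
    useFamily = TRUE, useNeighbors = TRUE, usePubmed = TRUE))
  ns <- sub(":.*", "", colnames(Aall))
  expect_equal(rle(ns)$values, c("disease", "gene", "fam", "nbr", "word"))
  # selected-but-missing source errors by name
  dsNoDocs <- ds
  dsNoDocs@docs <- list()
  expect_error(assembleMatrix(dsNoDocs, MiraiConfig(usePubmed = TRUE)),
    "pubmed")
})

test_that("full-rank decomposition preserves row geometry", {
  set.seed(3)
  M <- matrix(rnorm(12 * 9), 12, 9,
    dimnames = list(paste0("m", 1:12), paste0("c", 1:9)))
  space <- buildLatentSpace(M, 9L)
  cosOrig <- function(A) {
    n <- sqrt(rowSums(A^2))
    (A %*% t(A)) / outer(n, n)
  }
  expect_equal(cosOrig(space@mirnaVectors), cosOrig(M), tolerance = 1e-8)
})

test_that("truncation error equals the tail singular energy (Eckart-Young)", {
  set.seed(4)
  M <- matrix(rnorm(50 * 80), 50, 80,
    dimnames = list(paste0("m", 1:50), paste0("c", 1:80)))
  k <- 10L
  space <- buildLatentSpace(M, k)
  sigma <- sqrt(colSums(space@mirnaVectors^2)) # ||U S|| columns = singular values
  Mhat <- (space@mirnaVectors %*% diag(1 / sigma)) %*% t(space@featureVectors)
  errImpl <- sqrt(sum((M - Mhat)^2))
  dFull <- svd(M)$d # dense full-SVD oracle
  expect_equal(errImpl, sqrt(sum(dFull[(k + 1):50]^2)), tolerance = 1e-8)
  # rank-1 matrix at dim 1 reconstructs exactly
  r1 <- outer(1:5, c(2, 0, 1))
  dimnames(r1) <- list(paste0("m", 1:5), paste0("c", 1:3))
  s1 <- buildLatentSpace(r1, 1L)
  sg <- sqrt(sum(s1@mirnaVectors^2))
  expect_equal(s1@mirnaVectors %*% t(s1@featureVectors) / sg, r1,
    tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the Gram-matrix path agrees with the dense SVD", {
  set.seed(5)
  M <- matrix(rnorm(40 * 220), 40, 220,
    dimnames = list(paste0("m", 1:40), paste0("c", 1:220)))
  k <- 6L
  space <- buildLatentSpace(M, k) # 220 columns: Gram path
  s <- svd(M, nu = k, nv = k)    # dense oracle
  mvOracle <- s$u %*% diag(s$d[1:k], k)
  fvOracle <- s$v %*% diag(s$d[1:k], k)
  for (j in 1:k) { # align the oracle to the package's sign convention
    i <- which.max(abs(mvOracle[, j]))
    if (mvOracle[i, j] < 0) {
      mvOracle[, j] <- -mvOracle[, j]
      fvOracle[, j] <- -fvOracle[, j]
    }
  }
  expect_equal(unname(space@mirnaVectors), mvOracle, tolerance = 1e-6)
  expect_equal(unname(space@featureVectors), fvOracle, tolerance = 1e-6)
})

test_that("decomposition is deterministic and clamps oversized dimensions", {
  set.seed(6)
  M <- matrix(rnorm(10 * 6), 10, 6,
    dimnames = list(paste0("m", 1:10), paste0("c", 1:6)))
  s1 <- buildLatentSpace(M, 4L)
  s2 <- buildLatentSpace(M, 4L)
  expect_identical(s1@mirnaVectors, s2@mirnaVectors)
  expect_identical(s1@featureVectors, s2@featureVectors)
  expect_warning(sBig <- buildLatentSpace(M, 50L), "clamp")
  expect_equal(sBig@dim, 6L)
  expect_error(buildLatentSpace(matrix(0, 3, 3), 2L), "all-zero")
})

test_that("disease queries rank by cosine with stable id tie-breaks", {
  # m2 is the only miRNA annotated to d2; oracle = cosine in original space
  mirnas <- paste0("m", 1:4)
  md <- rbind(c(1, 0), c(0, 1), c(1, 0), c(1, 0))
  dimnames(md) <- list(mirnas, c("d1", "d2"))
  ds <- MirnaDataset(mirnas, c("d1", "d2"), md)
  A <- assembleMatrix(ds, MiraiConfig())
  space <- buildLatentSpace(A, 2L)
  ranking <- queryDisease(space, "d2")
  expect_equal(ranking$mirna[[1]], "m2")
  # oracle: dense SVD embeddings computed directly in the test
  s <- svd(A)
  mv <- s$u %*% diag(s$d)
  fv <- s$v %*% diag(s$d)
  q <- fv[match("disease:d2", colnames(A)), ]
  oracle <- as.numeric(mv %*% q) / (sqrt(rowSums(mv^2)) * sqrt(sum(q^2)))
  expect_equal(ranking$cosine, sort(oracle, decreasing = TRUE),
    tolerance = 1e-8)
  # global positive scaling leaves the ranking invariant
  r2 <- queryDisease(buildLatentSpace(3.7 * A, 2L), "d2")
  expect_equal(r2$mirna, ranking$mirna)
  # expand on a flat hierarchy is a no-op
  flat <- DiseaseHierarchy(terms = c("d1", "d2"))
  r3 <- queryDisease(space, "d2", expand = TRUE, hierarchy = flat)
  expect_equal(r3, ranking)
  expect_error(queryDisease(space, "d9"), "unknown disease")
})

test_that("latent spaces serialize and restore losslessly", {
  set.seed(7)
  M <- matrix(rnorm(8 * 5), 8, 5,
    dimnames = list(paste0("m", 1:8), paste0("c", 1:5)))
  space <- buildLatentSpace(M, 3L)
  path <- withr::local_tempfile(fileext = ".rds")
  writeLatentSpace(space, path)
  back <- readLatentSpace(path)
  expect_equal(back@mirnaVectors, space@mirnaVectors)
  expect_equal(back@featureVectors, space@featureVectors)
  expect_equal(back@colIds, space@colIds)
})
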