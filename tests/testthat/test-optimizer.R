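test_that("the probability estimation operator matches its closed form", {
  # sigmoid midpoint: x1 + F (x2 - x3) = 0.5 is unreachable on bits with
  # F = 0.8, so check with F chosen to land exactly on the midpoint
  expect_equal(mutantProbability(0, 1, 0, F = 0.5, b = 6), 0.5)
  # hand evaluations at F = 0.8, b = 6
  expect_equal(mutantProbability(1, 1, 0, 0.8, 6), 1 / (1 + exp(-6)))
  expect_equal(mutantProbability(0, 0, 1, 0.8, 6), 1 / (1 + exp(6)))
  expect_equal(mutantProbability(1, 1, 0, 0.8, 6) +
    mutantProbability(0, 0, 1, 0.8, 6), 1) # symmetry about the midpoint
  # monotone increasing in x1 + F (x2 - x3)
  drifts <- c(mutantProbability(0, 0, 1, 0.8, 6),
    mutantProbability(0, 0, 0, 0.8, 6), mutantProbability(1, 0, 0, 0.8, 6),
    mutantProbability(1, 1, 0, 0.8, 6))
  expect_true(all(diff(drifts) > 0))
  expect_error(mutantProbability(1, 1, 0, F = -1), "non-negative")
})

test_that("binary mutation samples bits at the operator probability", {
  set.seed(21)
  draws <- replicate(10000, mbdeMutate(1L, 1L, 0L, 0.8, 6))
  p <- mutantProbability(1, 1, 0, 0.8, 6)
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / 10000))
  # identical difference partners and a steep slope: mutant = base
  base <- randomGenome()
  other <- randomGenome()
  expect_equal(mbdeMutate(base, other, other, 0.8, b = 1000), base)
  # seeded reproducibility
  set.seed(5); m1 <- mbdeMutate(base, randomGenome(), randomGenome())
  set.seed(5); m2 <- mbdeMutate(base, randomGenome(), randomGenome())
  expect_identical(m1, m2)
})

test_that("crossover obeys its limits and expected mixing rate", {
  set.seed(22)
  target <- rep(0L, 35L)
  mutant <- rep(1L, 35L)
  expect_equal(deCrossover(target, mutant, CR = 1), mutant)
  # CR = 0: exactly the one forced coordinate comes from the mutant
  expect_equal(sum(deCrossover(target, mutant, CR = 0)), 1L)
  # expected mutant-coordinate count = 1 + CR (N - 1)
  counts <- replicate(4000, sum(deCrossover(target, mutant, CR = 0.8)))
  expect_lt(abs(mean(counts) - (1 + 0.8 * 34)), 0.15)
})

test_that("greedy selection maximizes and keeps the target on ties", {
  a <- rep(0L, 5L); b <- rep(1L, 5L)
  expect_equal(deSelect(0.3, 0.7, a, b), b)
  expect_equal(deSelect(0.7, 0.3, a, b), a)
  expect_equal(deSelect(0.5, 0.5, a, b), a)              # tie rule
  expect_equal(deSelect(NaN, 0.1, a, b), b)              # non-finite -> -Inf
})

test_that("parallel evaluation equals sequential, in order, with failure slots", {
  pop <- matrix(rep(0:1, each = 35L), 2, 35, byrow = TRUE)
  pop <- rbind(pop, pop)
  fn <- benchmarkFitness("onemax")
  f1 <- parallelEvaluate(pop, fn, workers = 1L)
  f4 <- parallelEvaluate(pop, fn, workers = 4L)
  expect_identical(f1, f4)
  expect_equal(f1, c(0, 35, 0, 35))
  # a failing genome scores -Inf without disturbing the others
  brittle <- function(g) if (sum(g) == 0) stop("boom") else sum(g)
  w <- testthat::capture_warnings(
    fb <- parallelEvaluate(pop, brittle, workers = 1L))
  expect_match(w, "failed", all = TRUE)
  expect_length(w, 2L)
  expect_equal(fb, c(-Inf, 35, -Inf, 35))
  alwaysBad <- function(g) stop("no")
  expect_error(suppressWarnings(parallelEvaluate(pop, alwaysBad)),
    "all fitness")
})

test_that("ordinary kriging interpolates its archive", {
  expect_equal(spatialCorrelation(c(1, 0, 1), c(1, 0, 1)), 1) # sc(x, x) = 1
  expect_equal(spatialCorrelation(0.5, 0, theta = 2, power = 1), exp(-1))
  set.seed(23)
  X <- matrix(sample(0:1, 12 * 35, replace = TRUE), 12, 35)
  X <- X[!duplicated(apply(X, 1, paste, collapse = "")), ]
  y <- rowSums(X) / 35
  gp <- fitKriging(X, y, nugget = 1e-8)
  pr <- predict(gp, X)
  expect_true(all(abs(pr$mean - y) <= 1e-6))
  expect_true(all(pr$sd <= 1e-3))
  # uncertainty grows away from the archive
  far <- 1L - X[1, ]
  expect_gt(predict(gp, far)$sd, max(pr$sd))
  # duplicate archive entries are merged, not fatal
  gp2 <- fitKriging(rbind(X, X[1, ]), c(y, y[1]))
  expect_equal(nrow(gp2@X), nrow(X))
  # likelihood-tuned theta stays on the candidate grid
  gp3 <- fitKriging(X, y, optimizeTheta = TRUE)
  expect_true(gp3@theta[1] %in% c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1))
})

test_that("the merit function trades mean against uncertainty", {
  expect_equal(meritValue(0.8, 0.05, -2), 0.9)
  expect_equal(meritValue(0.7, 0), 0.7)        # xi = 0: pure mean
  expect_equal(meritValue(0.7, 0.3, 0), 0.7)   # omega = 0: exploitation
  expect_error(meritValue(0.5, -0.1), "non-negative")
})

test_that("optimizer runs are reproducible, monotone and within budget", {
  fn <- benchmarkFitness("onemax")
  ctrl <- optimizerControl(lambda = 10L, realGenerations = 8L,
    surrogateGenerations = 0L, seed = 9L)
  r1 <- runOptimizer(fn, ctrl)
  r2 <- runOptimizer(fn, ctrl)
  expect_identical(runHistory(r1), runHistory(r2))
  expect_identical(bestGenome(r1), bestGenome(r2))
  expect_false(is.unsorted(runHistory(r1)$best))
  expect_equal(r1@realEvals, 10L * 9L) # lambda * (t + 1)
  expect_equal(nrow(runHistory(r1)), 9L)
  # surrogate-assisted mode runs and stays monotone too
  r3 <- runOptimizer(benchmarkFitness("quadratic"),
    optimizerControl(lambda = 10L, realGenerations = 4L,
      surrogateGenerations = 5L, seed = 9L))
  expect_false(is.unsorted(runHistory(r3)$best))
  expect_equal(r3@realEvals, 50L)
  expect_error(optimizerControl(lambda = 3L), ">= 4")
})
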