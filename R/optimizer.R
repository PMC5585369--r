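#' Per-bit mutant probability of binary differential evolution
#'
#' Maps the classical DE mutant arithmetic `x1 + F (x2 - x3)` through a
#' sigmoid into a sampling probability:
#' `P = 1 / (1 + exp(-2 b (x1 + F (x2 - x3) - 0.5) / (1 + 2 F)))`.
#' It is monotone increasing in `x1 + F (x2 - x3)` and equals 0.5 at the
#' midpoint 0.5.
#'
#' @param x1,x2,x3 bits (vectors) of the base and the two difference
#'   partners.
#' @param F scale factor (>= 0).
#' @param b sigmoid slope (> 0); 6 is the customary value.
#' @return probability in (0, 1), vectorized.
#' @export
mutantProbability <- function(x1, x2, x3, F = 0.8, b = 6) {
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  1 / (1 + exp(-2 * b * (x1 + F * (x2 - x3) - 0.5) / (1 + 2 * F)))
}

#' Binary DE mutation
#'
#' Draws each coordinate of the mutant as 1 with [mutantProbability()],
#' independently. Consumes the R random stream.
#'
#' @param base,p2,p3 genomes of three distinct population members.
#' @param F,b see [mutantProbability()].
#' @return mutant genome (integer bits).
#' @export
mbdeMutate <- function(base, p2, p3, F = 0.8, b = 6) {
  p <- mutantProbability(base, p2, p3, F, b)
  as.integer(stats::runif(length(base)) <= p)
}

#' Binomial crossover
#'
#' Coordinate j of the trial takes the mutant value when a uniform draw is
#' <= CR or j is the one forced coordinate (so the trial always differs
#' from the target in at least one mutant coordinate); otherwise the target
#' value.
#'
#' @param target,mutant equal-length genomes.
#' @param CR crossover probability in [0, 1].
#' @return trial genome.
#' @export
deCrossover <- function(target, mutant, CR = 0.8) {
  n <- length(target)
  if (length(mutant) != n) stop("length mismatch", call. = FALSE)
  take <- stats::runif(n) <= CR
  take[sample.int(n, 1L)] <- TRUE
  out <- target
  out[take] <- mutant[take]
  as.integer(out)
}

#' Greedy one-to-one replacement
#'
#' Keeps the higher-fitness genome (maximization); ties keep the target, so
#' the population's best fitness never decreases. Non-finite fitness values
#' are treated as -Inf.
#'
#' @param targetFitness,trialFitness fitness values on the same scale.
#' @param target,trial the corresponding genomes.
#' @return the surviving genome.
#' @export
deSelect <- function(targetFitness, trialFitness, target, trial) {
  if (!is.finite(targetFitness)) targetFitness <- -Inf
  if (!is.finite(trialFitness)) trialFitness <- -Inf
  if (trialFitness > targetFitness) trial else target
}

#' Evaluate a population, optionally in parallel
#'
#' Master-slave evaluation of a pure per-genome fitness function. Results
#' are identical to sequential evaluation and returned in population order
#' for any worker count (fewer workers than genomes is the normal case). A
#' genome whose evaluation fails scores -Inf (with a warning); if every
#' evaluation fails the call aborts.
#'
#' @param population genome matrix (one genome per row) or list of genomes.
#' @param fitnessFn function(genome) -> numeric(1); must not depend on the
#'   R random stream (seed internally if stochastic).
#' @param workers number of parallel workers (forked; falls back to
#'   sequential evaluation where forking is unavailable).
#' @return numeric fitness vector in population order.
#' @export
parallelEvaluate <- function(population, fitnessFn, workers = 1L) {
  genomes <- if (is.matrix(population)) {
    lapply(seq_len(nrow(population)), function(i) population[i, ])
  } else {
    population
  }
  evalOne <- function(g) {
    tryCatch(as.numeric(fitnessFn(g)), error = function(e) {
      warning("fitness evaluation failed: ", conditionMessage(e),
        call. = FALSE)
      -Inf
    })
  }
  fit <- if (workers > 1L && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(genomes, evalOne, mc.cores = workers))
  } else {
    vapply(genomes, evalOne, numeric(1))
  }
  fit[!is.finite(fit)] <- -Inf
  if (all(fit == -Inf)) stop("all fitness evaluations failed", call. = FALSE)
  fit
}

#' Optimizer settings
#'
#' Defaults follow the published tuning setup: population 50, 50 real
#' generations, 100 surrogate generations per real generation, F = 0.8,
#' CR = 0.8, b = 6, omega = -2, 35-bit genomes. `surrogateGenerations = 0`
#' disables the surrogate entirely (plain parallel binary DE).
#'
#' @param lambda population size (>= 4).
#' @param realGenerations number of real-evaluation generations t; the real
#'   evaluation budget is `lambda * (realGenerations + 1)` including the
#'   initial population.
#' @param surrogateGenerations surrogate generations mu per real generation.
#' @param F,CR,b differential-evolution operator parameters.
#' @param omega merit exploration weight (negative for maximization).
#' @param genomeLength bits per genome.
#' @param workers parallel workers for real evaluations.
#' @param seed master seed; runs are bit-reproducible given the seed and
#'   independent of the worker count.
#' @param theta,nugget,optimizeTheta kriging settings, see [fitKriging()].
#' @return a named list of settings.
#' @export
optimizerControl <- function(lambda = 50L, realGenerations = 50L,
                             surrogateGenerations = 100L, F = 0.8, CR = 0.8,
                             b = 6, omega = -2, genomeLength = 35L,
                             workers = 1L, seed = 1L, theta = 0.1,
                             nugget = 1e-8, optimizeTheta = FALSE) {
  if (lambda < 4L) {
    stop("lambda must be >= 4 (three distinct partners plus the target)",
      call. = FALSE)
  }
  if (CR < 0 || CR > 1) stop("CR must lie in [0, 1]", call. = FALSE)
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  list(lambda = as.integer(lambda),
    realGenerations = as.integer(realGenerations),
    surrogateGenerations = as.integer(surrogateGenerations),
    F = F, CR = CR, b = b, omega = omega,
    genomeLength = as.integer(genomeLength),
    workers = as.integer(workers), seed = as.integer(seed),
    theta = theta, nugget = nugget, optimizeTheta = optimizeTheta)
}

# One DE generation worth of trial vectors for the whole population.
makeTrials <- function(pop, F, CR, b) {
  lambda <- nrow(pop)
  trials <- pop
  for (i in seq_len(lambda)) {
    partners <- sample(setdiff(seq_len(lambda), i), 3L)
    mutant <- mbdeMutate(pop[partners[1L], ], pop[partners[2L], ],
      pop[partners[3L], ], F, b)
    trials[i, ] <- deCrossover(pop[i, ], mutant, CR)
  }
  trials
}

#' Run (surrogate-assisted) parallel binary differential evolution
#'
#' The loop: a random initial population is real-evaluated in parallel and
#' archived. Then for each of t real generations: if mu > 0, an
#' ordinary-kriging surrogate is (re)fitted on the archive and the
#' population evolves mu binary-DE generations scored and selected by the
#' merit function only (generation-based evolution control); the resulting
#' population is real-evaluated in parallel, archived, and greedily
#' selected against the incumbents on real fitness only. With mu = 0 the
#' surrogate phase is skipped and each real generation evaluates one
#' generation of DE trials (plain parallel binary DE). The best real
#' fitness is monotone non-decreasing and the total real-evaluation budget
#' is `lambda * (t + 1)`.
#'
#' All stochastic draws happen sequentially on the master from the control
#' seed and the fitness function must be pure, so runs are reproducible and
#' independent of worker scheduling.
#'
#' @param fitnessFn pure fitness function over genomes (maximized).
#' @param control an [optimizerControl()] list.
#' @return an [OptimizerRun-class].
#' @examples
#' run <- runOptimizer(benchmarkFitness("onemax"),
#'   optimizerControl(lambda = 10, realGenerations = 5,
#'     surrogateGenerations = 0, genomeLength = 35, seed = 1))
#' bestFitness(run)
#' @export
runOptimizer <- function(fitnessFn, control = optimizerControl()) {
  withSeed(control$seed, {
    lambda <- control$lambda
    N <- control$genomeLength
    pop <- matrix(sample(0:1, lambda * N, replace = TRUE), lambda, N)
    fit <- parallelEvaluate(pop, fitnessFn, control$workers)
    archX <- pop
    archY <- fit
    evals <- lambda
    history <- data.frame(generation = 0L, realEvals = evals,
      best = max(fit), mean = mean(fit[is.finite(fit)]), worst = min(fit))
    for (g in seq_len(control$realGenerations)) {
      if (control$surrogateGenerations > 0L) {
        ok <- is.finite(archY)
        gp <- fitKriging(archX[ok, , drop = FALSE], archY[ok],
          theta = control$theta, nugget = control$nugget,
          optimizeTheta = control$optimizeTheta)
        cur <- pop
        pr <- predict(gp, cur)
        curMerit <- meritValue(pr$mean, pr$sd, control$omega)
        for (s in seq_len(control$surrogateGenerations)) {
          trials <- makeTrials(cur, control$F, control$CR, control$b)
          pr <- predict(gp, trials)
          trialMerit <- meritValue(pr$mean, pr$sd, control$omega)
          imp <- trialMerit > curMerit
          cur[imp, ] <- trials[imp, ]
          curMerit[imp] <- trialMerit[imp]
        }
        cand <- cur
      } else {
        cand <- makeTrials(pop, control$F, control$CR, control$b)
      }
      candFit <- parallelEvaluate(cand, fitnessFn, control$workers)
      evals <- evals + lambda
      archX <- rbind(archX, cand)
      archY <- c(archY, candFit)
      imp <- candFit > fit # ties keep the incumbent
      pop[imp, ] <- cand[imp, ]
      fit[imp] <- candFit[imp]
      history <- rbind(history, data.frame(generation = g,
        realEvals = evals, best = max(fit),
        mean = mean(fit[is.finite(fit)]), worst = min(fit)))
    }
    bestIdx <- which.max(archY)
    new("OptimizerRun", population = pop, fitness = fit,
      bestGenome = as.integer(archX[bestIdx, ]),
      bestFitness = archY[[bestIdx]], history = history,
      realEvals = as.integer(evals), control = control)
  })
}

#' Real evaluations needed to reach a fitness threshold
#'
#' Reads a run's history and returns the real-evaluation count at which the
#' best fitness first reached `threshold` (Inf when never reached). Used to
#' compare surrogate-assisted and plain runs on a common budget axis.
#'
#' @param run an [OptimizerRun-class].
#' @param threshold fitness threshold.
#' @return number of real evaluations, or Inf.
#' @export
evalsToThreshold <- function(run, threshold) {
  h <- runHistory(run)
  hit <- which(h$best >= threshold)
  if (length(hit) == 0L) return(Inf)
  h$realEvals[[min(hit)]]
}
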