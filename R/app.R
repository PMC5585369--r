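# Command-line entry point tying the modules into one workflow:
# simulate -> (predict | evaluate | tune | invalidate). A thin Rscript
# wrapper lives in inst/exec/mirlsa.R.

usageError <- function(...) {
  structure(class = c("mirlsaUsageError", "error", "condition"),
    list(message = paste0(...), call = NULL))
}

parseFlags <- function(args, allowed) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop(usageError("unexpected argument: ", a))
    key <- substring(a, 3L)
    if (!key %in% allowed) stop(usageError("unknown flag: --", key))
    if (i == length(args)) stop(usageError("--", key, " needs a value"))
    flags[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

flagOr <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else flags[[key]]
}

writeProvenance <- function(dir, command, flags, seed) {
  rec <- list(command = command, flags = flags, seed = seed,
    package = "mirlsa",
    version = as.character(utils::packageVersion("mirlsa")))
  jsonlite::write_json(rec, file.path(dir, "run.json"),
    auto_unbox = TRUE, pretty = TRUE)
}

cliSimulate <- function(flags) {
  out <- flags[["out"]]
  if (is.null(out)) stop(usageError("simulate needs --out DIR"))
  seed <- as.integer(flagOr(flags, "seed", "42"))
  preset <- flagOr(flags, "preset", "default")
  spec <- switch(preset,
    default = plantedSpec(seed = seed),
    tiny = plantedSpec(nMirnas = 30L, nDiseases = 6L, nGenes = 20L,
      nFamilies = 6L, nGroups = 3L, pIn = 0.8, docVocab = 10L,
      docLength = 30L, seed = seed),
    stop(usageError("unknown preset: ", preset)))
  gen <- generatePlanted(spec)
  writeDataset(gen$dataset, out)
  gt <- rbind(
    if (nrow(gen$groundTruth$plantedErrors)) {
      cbind(kind = "planted_error", gen$groundTruth$plantedErrors)
    },
    if (nrow(gen$groundTruth$heldOut)) {
      cbind(kind = "held_out", gen$groundTruth$heldOut)
    },
    data.frame(kind = "mirna_group",
      mirna = names(gen$groundTruth$mirnaGroups),
      disease = as.character(gen$groundTruth$mirnaGroups)))
  writeTsv(gt, file.path(out, "ground_truth.tsv"))
  writeProvenance(out, "simulate", flags, seed)
  message("dataset written to ", out)
  0L
}

cliGenome <- function(flags) {
  g <- flags[["genome"]]
  if (is.null(g)) stop(usageError("a --genome BITSTRING is required"))
  tryCatch(decodeGenome(g), error = function(e) {
    stop(usageError(conditionMessage(e)))
  })
}

cliEvaluate <- function(flags) {
  dataDir <- flags[["data"]]
  if (is.null(dataDir)) stop(usageError("evaluate needs --data DIR"))
  config <- cliGenome(flags)
  out <- flagOr(flags, "out", dataDir)
  seed <- as.integer(flagOr(flags, "seed", "1"))
  diseaseMin <- as.integer(flagOr(flags, "disease-min", "20"))
  dataset <- readDataset(dataDir)
  res <- crossValidate(dataset, config, diseaseMin = diseaseMin,
    seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeTsv(perDisease(res), file.path(out, "per_disease.tsv"))
  writeTsv(cbind(disease = rownames(res@precisionAtRecall),
    as.data.frame(res@precisionAtRecall)),
    file.path(out, "precision_at_recall.tsv"))
  jsonlite::write_json(
    list(meanAUC = meanAUC(res), diseases = nrow(perDisease(res)),
      diseaseMin = diseaseMin, seed = seed),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeProvenance(out, "evaluate", flags, seed)
  message(sprintf("mean AUC %.4f over %d disease(s)", meanAUC(res),
    nrow(perDisease(res))))
  0L
}

cliPredict <- function(flags) {
  dataDir <- flags[["data"]]
  if (is.null(dataDir)) stop(usageError("predict needs --data DIR"))
  config <- cliGenome(flags)
  out <- flagOr(flags, "out", dataDir)
  topK <- as.integer(flagOr(flags, "top-k", "10"))
  dataset <- readDataset(dataDir)
  novel <- predictNovel(dataset, config, topK = topK)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeTsv(novel, file.path(out, "novel_predictions.tsv"))
  writeProvenance(out, "predict", flags, NA_integer_)
  message(nrow(novel), " candidate association(s) written")
  0L
}

cliInvalidate <- function(flags) {
  dataDir <- flags[["data"]]
  if (is.null(dataDir)) stop(usageError("invalidate needs --data DIR"))
  config <- cliGenome(flags)
  out <- flagOr(flags, "out", dataDir)
  threshold <- as.numeric(flagOr(flags, "threshold", "2"))
  dataset <- readDataset(dataDir)
  inv <- detectInvalid(dataset, config, threshold = threshold)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeTsv(inv, file.path(out, "invalidations.tsv"))
  writeProvenance(out, "invalidate", flags, NA_integer_)
  message(sum(inv$flagged), " pair(s) flagged")
  0L
}

cliTune <- function(flags) {
  seed <- as.integer(flagOr(flags, "seed", "1"))
  mode <- flagOr(flags, "mode", "pgpabde")
  if (!mode %in% c("pgpabde", "pbde")) {
    stop(usageError("--mode must be pgpabde or pbde"))
  }
  mu <- as.integer(flagOr(flags, "surrogate-gens", "100"))
  if (mode == "pbde") mu <- 0L
  control <- optimizerControl(
    lambda = as.integer(flagOr(flags, "pop", "50")),
    realGenerations = as.integer(flagOr(flags, "real-gens", "50")),
    surrogateGenerations = mu,
    F = as.numeric(flagOr(flags, "F", "0.8")),
    CR = as.numeric(flagOr(flags, "CR", "0.8")),
    b = as.numeric(flagOr(flags, "b", "6")),
    omega = as.numeric(flagOr(flags, "omega", "-2")),
    workers = as.integer(flagOr(flags, "workers", "1")),
    seed = seed)
  if (!is.null(flags[["benchmark"]])) {
    fitnessFn <- benchmarkFitness(flags[["benchmark"]])
    out <- flags[["out"]]
    if (is.null(out)) stop(usageError("tune needs --out DIR"))
  } else {
    dataDir <- flags[["data"]]
    if (is.null(dataDir)) {
      stop(usageError("tune needs --data DIR or --benchmark NAME"))
    }
    out <- flagOr(flags, "out", dataDir)
    dataset <- readDataset(dataDir)
    diseaseMin <- as.integer(flagOr(flags, "disease-min", "20"))
    fitnessFn <- function(genome) {
      genomeFitness(dataset, genome, diseaseMin = diseaseMin, seed = seed)
    }
  }
  run <- runOptimizer(fitnessFn, control)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  h <- runHistory(run)
  writeTsv(data.frame(real_eval_count = h$realEvals, best = h$best,
    mean = h$mean, worst = h$worst), file.path(out, "history.tsv"))
  cfg <- decodeGenome(bestGenome(run))
  lines <- c(paste0("genome\t", formatGenome(bestGenome(run))),
    paste0("fitness\t", format(bestFitness(run), digits = 10)),
    paste0("dim\t", cfg@dim),
    paste0("cutoffs\t", paste(cfg@cutoffs, collapse = ",")),
    paste0("sources\t", paste(c("disease",
      c("targets", "family", "neighbors", "pubmed", "mirbase_abstract",
        "mirbase_description")[c(cfg@useTargets, cfg@useFamily,
        cfg@useNeighbors, cfg@usePubmed, cfg@useMirbaseAbstracts,
        cfg@useMirbaseDescription)]), collapse = ",")))
  writeLines(lines, file.path(out, "best_genome.txt"))
  writeProvenance(out, "tune", flags, seed)
  message(sprintf("best fitness %.6f after %d real evaluations",
    bestFitness(run), run@realEvals))
  0L
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a planted synthetic dataset),
#' `evaluate` (five-fold cross-validation of a genome), `predict`
#' (novel-association candidates), `invalidate` (flag putative
#' mis-annotations) and `tune` (optimize the 35-bit genome with
#' surrogate-assisted binary DE; `--mode pbde` or `--surrogate-gens 0`
#' disables the surrogate). Every run writes its outputs as TSV plus a
#' `run.json` provenance record (command, flags, seed, package version)
#' from which it can be reproduced.
#'
#' @param argv character vector of command-line arguments.
#' @return exit code, invisibly: 0 on success, 2 on a usage error, 1 on a
#'   runtime failure.
#' @examples
#' dir <- tempfile()
#' mirlsaMain(c("simulate", "--out", dir, "--preset", "tiny"))
#' @export
mirlsaMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0L) {
      stop(usageError("usage: mirlsa <simulate|predict|evaluate|tune|",
        "invalidate> [--flag value ...]"))
    }
    cmd <- argv[[1L]]
    rest <- argv[-1L]
    switch(cmd,
      simulate = cliSimulate(parseFlags(rest,
        c("out", "preset", "seed"))),
      evaluate = cliEvaluate(parseFlags(rest,
        c("data", "genome", "seed", "disease-min", "out"))),
      predict = cliPredict(parseFlags(rest,
        c("data", "genome", "top-k", "out"))),
      invalidate = cliInvalidate(parseFlags(rest,
        c("data", "genome", "threshold", "out"))),
      tune = cliTune(parseFlags(rest,
        c("data", "benchmark", "pop", "real-gens", "surrogate-gens", "F",
          "CR", "b", "omega", "workers", "seed", "mode", "out",
          "disease-min"))),
      stop(usageError("unknown subcommand: ", cmd)))
  },
  mirlsaUsageError = function(e) {
    message("usage error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
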