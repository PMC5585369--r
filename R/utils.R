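# Internal helpers shared across modules.

# TRUE when every entry of m is exactly 0 or 1 (and finite).
isBinaryMatrix <- function(m) {
  is.numeric(m) && all(is.finite(m)) && all(m == 0 | m == 1)
}

stopIfNotBinary <- function(m, what = "matrix") {
  if (!isBinaryMatrix(m)) {
    stop(what, " must be a binary (0/1) matrix", call. = FALSE)
  }
  invisible(TRUE)
}

# Cosine between each row of A and vector v; rows (or v) with zero norm
# score 0 rather than NaN so degenerate vectors sort last.
rowCosine <- function(A, v) {
  vn <- sqrt(sum(v^2))
  rn <- sqrt(rowSums(A^2))
  if (vn == 0) {
    return(stats::setNames(numeric(nrow(A)), rownames(A)))
  }
  num <- as.numeric(A %*% v)
  out <- ifelse(rn > 0, num / (rn * vn), 0)
  stats::setNames(out, rownames(A))
}

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# The 19-value cutoff grid 0.05, 0.10, ..., 0.95.
cutoffGrid <- function() round(seq_len(19L) * 0.05, 2)
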