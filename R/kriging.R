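#' Spatial correlation between two configuration vectors
#'
#' `sc(x, x') = exp(-sum_i theta_i |x_i - x'_i|^p_i)`. On binary genomes
#' |x_i - x'_i| is 0 or 1, so the exponent p_i has no effect there; it
#' matters for real-valued inputs.
#'
#' @param x,xp numeric vectors of equal length.
#' @param theta positive decay parameters (recycled).
#' @param power smoothness exponents in [1, 2] (recycled).
#' @return a correlation in (0, 1]; `sc(x, x) = 1`.
#' @export
spatialCorrelation <- function(x, xp, theta = 0.1, power = 1) {
  d <- length(x)
  theta <- rep_len(theta, d)
  power <- rep_len(power, d)
  exp(-sum(theta * abs(x - xp)^power))
}

# n x m cross-correlation matrix between the rows of X and the rows of Y.
corrMatrix <- function(X, Y, theta, power) {
  W <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(ncol(X))) {
    W <- W + theta[[i]] * abs(outer(X[, i], Y[, i], "-"))^power[[i]]
  }
  exp(-W)
}

solveChol <- function(U, v) backsolve(U, backsolve(U, v, transpose = TRUE))

#' Fit an ordinary-kriging surrogate to archived evaluations
#'
#' Fits a Gaussian-process model with constant mean (estimated by
#' generalized least squares) and the correlation of
#' [spatialCorrelation()], plus a nugget on the diagonal. Duplicate
#' genomes are merged (mean of their observed fitness) before fitting so
#' the correlation matrix stays non-singular. With `optimizeTheta = TRUE`
#' a uniform theta is selected by maximizing the concentrated log marginal
#' likelihood over a bounded grid.
#'
#' @param X matrix of evaluated genomes (one row each).
#' @param y their real fitness values.
#' @param theta,power correlation hyperparameters (recycled per coordinate).
#' @param nugget diagonal jitter; increase it if fitting fails.
#' @param optimizeTheta tune a uniform theta by maximum likelihood.
#' @param thetaGrid candidate values for the likelihood search.
#' @return a [KrigingModel-class].
#' @export
fitKriging <- function(X, y, theta = 0.1, power = 1, nugget = 1e-8,
                       optimizeTheta = FALSE,
                       thetaGrid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("|X| must equal |y|", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 archived points", call. = FALSE)
  key <- apply(X, 1L, paste, collapse = "")
  if (anyDuplicated(key)) {
    y <- as.numeric(tapply(y, key, mean)[unique(key)])
    X <- X[!duplicated(key), , drop = FALSE]
  }
  d <- ncol(X)
  theta <- rep_len(theta, d)
  power <- rep_len(power, d)
  if (optimizeTheta) {
    ll <- vapply(thetaGrid, function(th) {
      fit <- try(krigCore(X, y, rep_len(th, d), power, nugget),
        silent = TRUE)
      if (inherits(fit, "try-error")) return(-Inf)
      fit$logLik
    }, numeric(1))
    theta <- rep_len(thetaGrid[[which.max(ll)]], d)
  }
  core <- krigCore(X, y, theta, power, nugget)
  new("KrigingModel", X = X, y = y, theta = theta, power = power,
    nugget = nugget, mu = core$mu, sigma2 = core$sigma2,
    cholR = core$cholR, alpha = core$alpha, Rinv1 = core$Rinv1,
    denom = core$denom)
}

krigCore <- function(X, y, theta, power, nugget) {
  n <- nrow(X)
  R <- corrMatrix(X, X, theta, power) + diag(nugget, n)
  cholR <- tryCatch(chol(R), error = function(e) {
    stop("correlation matrix is singular; increase the nugget",
      call. = FALSE)
  })
  Rinv1 <- solveChol(cholR, rep(1, n))
  denom <- sum(Rinv1)
  mu <- sum(Rinv1 * y) / denom
  resid <- y - mu
  alpha <- solveChol(cholR, resid)
  sigma2 <- sum(resid * alpha) / n
  logLik <- -0.5 * (n * log(max(sigma2, 1e-300)) +
    2 * sum(log(diag(cholR))))
  list(mu = mu, sigma2 = sigma2, cholR = cholR, alpha = alpha,
    Rinv1 = Rinv1, denom = denom, logLik = logLik)
}

#' Predict fitness mean and uncertainty at new genomes
#'
#' Ordinary-kriging predictor: mean `mu + r' R^-1 (y - mu)` and standard
#' deviation from the kriging variance (clamped at zero), where r is the
#' correlation between the query and the archive. At an archived point the
#' mean interpolates the observed value (up to the nugget) and the
#' uncertainty is ~0.
#'
#' @param object a [KrigingModel-class].
#' @param newdata genome vector or matrix (one genome per row).
#' @param ... ignored.
#' @return data.frame with columns `mean` and `sd`.
#' @export
setMethod("predict", "KrigingModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  r <- corrMatrix(object@X, newdata, object@theta, object@power)
  mean <- object@mu + as.numeric(crossprod(r, object@alpha))
  u <- solveChol(object@cholR, r) # R^-1 r, one column per query
  rRr <- colSums(r * u)
  oneRr <- as.numeric(crossprod(object@Rinv1, r))
  var <- object@sigma2 * pmax(0, 1 - rRr + (1 - oneRr)^2 / object@denom)
  data.frame(mean = mean, sd = sqrt(var))
})

#' Merit of a surrogate prediction
#'
#' `f_m = f_hat - omega * xi`. For maximization omega must be negative
#' (default -2), so uncertain regions of the search space gain merit and
#' the surrogate phase balances exploration against exploitation;
#' `omega = 0` exploits the surrogate mean only.
#'
#' @param fhat predicted mean fitness.
#' @param xi predicted standard deviation (>= 0).
#' @param omega exploration weight.
#' @return merit value(s).
#' @examples
#' meritValue(0.8, 0.05, -2)  # 0.9
#' @export
meritValue <- function(fhat, xi, omega = -2) {
  if (any(xi < 0)) stop("xi must be non-negative", call. = FALSE)
  fhat - omega * xi
}
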