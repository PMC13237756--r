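# Conjugate blocked Gibbs sampler for the Gaussian linear mixed model
#   y = X b + u[participant] + e,  e ~ N(0, sigma^2),  u_j ~ N(0, sigma_u^2)
# with weakly informative priors b ~ N(0, priorSD^2 I) (default SD 10) and
# inverse-gamma(a0, b0) priors on both variances. (b, u) are drawn as one
# conjugate block — b from its multivariate-normal conditional marginalized
# over u (Woodbury on the block-diagonal marginal covariance), then u | b —
# which decorrelates participant-level coefficients from the intercepts;
# sigma^2 and sigma_u^2 have inverse-gamma full conditionals. All
# per-iteration work is O(p^2 J) via precomputed block sums.

#' Gibbs sampler for the Bayesian linear mixed model
#'
#' @param design list from \code{\link{buildDesign}} (y, X, pid). A design
#'   with zero rows runs in prior-only mode (fixed effects drawn from their
#'   prior).
#' @param chains number of chains (>= 2)
#' @param iterations iterations per chain, including warmup
#' @param warmup warmup iterations discarded per chain
#' @param seed master seed; chain c uses a seed derived from (seed, c)
#' @param priorSD prior SD of the fixed effects (N(0, priorSD^2)), default 10
#' @param a0,b0 inverse-gamma hyperparameters for both variances
#' @param sigmaFixed if non-NULL, the residual SD is held at this known
#'   value instead of being sampled
#' @param randomIntercept include the participant random intercept (set
#'   FALSE to disable the random effects entirely)
#' @return a \linkS4class{PosteriorDraws}
#' @export
gibbsSample <- function(design, chains = 4, iterations = 2000, warmup = 1000,
                        seed = 1L, priorSD = 10, a0 = 0.001, b0 = 0.001,
                        sigmaFixed = NULL, randomIntercept = TRUE) {
  if (chains < 2) stopLabeled("gibbs", "need >= 2 chains, got ", chains)
  if (warmup >= iterations)
    stopLabeled("gibbs", "warmup must be smaller than iterations")
  X <- design$X
  y <- design$y
  p <- ncol(X)
  keep <- iterations - warmup
  fixedNames <- colnames(X)

  if (length(y) == 0L || nrow(X) == 0L) {      # prior-only mode
    draws <- array(NA_real_, c(keep, chains, p),
                   dimnames = list(NULL, NULL, fixedNames))
    for (ch in seq_len(chains)) {
      withSeed(deriveSeed(seed, paste0("chain", ch)), {
        draws[, ch, ] <- matrix(stats::rnorm(keep * p, 0, priorSD), keep, p)
      })
    }
    return(new("PosteriorDraws", draws = draws, fixedNames = fixedNames,
               warmup = as.integer(warmup), seed = as.integer(seed)))
  }
  if (!all(is.finite(y)))
    stopLabeled("gibbs", "response contains non-finite values")

  n <- length(y)
  pidIdx <- as.integer(design$pid)
  J <- nlevels(design$pid)
  nj <- tabulate(pidIdx, J)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  S <- rowsum(X, pidIdx, reorder = TRUE)           # J x p block column sums
  ty <- drop(rowsum(y, pidIdx, reorder = TRUE))    # block sums of y
  priorPrec <- diag(1 / priorSD^2, p)

  paramNames <- c(fixedNames,
                  if (randomIntercept) "sigma_u",
                  if (is.null(sigmaFixed)) "sigma",
                  if (randomIntercept) paste0("u[", levels(design$pid), "]"))
  nPar <- length(paramNames)
  draws <- array(NA_real_, c(keep, chains, nPar),
                 dimnames = list(NULL, NULL, paramNames))

  for (ch in seq_len(chains)) {
    withSeed(deriveSeed(seed, paste0("chain", ch)), {
      sdY <- max(stats::sd(y), 1e-3)
      sigma <- if (is.null(sigmaFixed))
        sdY * stats::runif(1, 0.5, 2) else sigmaFixed
      sigmaU <- if (randomIntercept) sdY * stats::runif(1, 0.25, 1) else 0
      b <- stats::rnorm(p, 0, 0.5)
      u <- rep(0, J)
      for (it in seq_len(iterations)) {
        # b | sigma, sigma_u (marginal over u): Sigma^-1 = I/s^2 - c_j J_j
        if (randomIntercept) {
          cj <- sigmaU^2 / (sigma^2 * (sigma^2 + nj * sigmaU^2))
          Vinv <- XtX / sigma^2 - crossprod(S, S * cj) + priorPrec
          rhs <- Xty / sigma^2 - drop(crossprod(S, cj * ty))
        } else {
          Vinv <- XtX / sigma^2 + priorPrec
          rhs <- Xty / sigma^2
        }
        U <- chol(Vinv)
        m <- backsolve(U, forwardsolve(t(U), rhs))
        b <- drop(m + backsolve(U, stats::rnorm(p)))
        rj <- ty - drop(S %*% b)                 # block sums of y - Xb
        # u | b and sigma_u | u
        if (randomIntercept) {
          prec <- nj / sigma^2 + 1 / sigmaU^2
          u <- stats::rnorm(J, rj / sigma^2 / prec, sqrt(1 / prec))
          sigmaU <- sqrt(1 / stats::rgamma(1, a0 + J / 2,
                                           b0 + sum(u^2) / 2))
        }
        # sigma | b, u
        if (is.null(sigmaFixed)) {
          ssr <- yty - 2 * sum(b * Xty) + drop(crossprod(b, XtX %*% b))
          if (randomIntercept)
            ssr <- ssr - 2 * sum(u * rj) + sum(nj * u^2)
          sigma <- sqrt(1 / stats::rgamma(1, a0 + n / 2, b0 + ssr / 2))
        }
        if (it > warmup) {
          draws[it - warmup, ch, ] <-
            c(b, if (randomIntercept) sigmaU,
              if (is.null(sigmaFixed)) sigma,
              if (randomIntercept) u)
        }
      }
    })
  }
  new("PosteriorDraws", draws = draws, fixedNames = fixedNames,
      warmup = as.integer(warmup), seed = as.integer(seed))
}

#' Fit one of the standard models to a long alpha-power table
#'
#' Convenience wrapper: \code{\link{buildDesign}} then
#' \code{\link{gibbsSample}}.
#'
#' @param table long alpha-power table
#' @param model model id 1-7 or custom term expression
#' @param ... passed to \code{\link{gibbsSample}}
#' @return list(draws = \linkS4class{PosteriorDraws}, design, model)
#' @export
fitModel <- function(table, model = 3, ...) {
  design <- buildDesign(table, model)
  list(draws = gibbsSample(design, ...), design = design, model = model)
}
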