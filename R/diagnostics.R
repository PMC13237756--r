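# Convergence diagnostics: split-chain R-hat and effective sample size with
# Geyer initial-monotone-sequence truncation of the autocorrelation sum.

splitChainMatrix <- function(x) {
  # x: iterations x chains -> iterations/2 x (2 chains)
  n <- nrow(x)
  half <- n %/% 2
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

chainAutocov <- function(v) {
  # biased (1/n) autocovariance via FFT
  n <- length(v)
  v <- v - mean(v)
  nfft <- 2^ceiling(log2(2 * n))
  F <- stats::fft(c(v, rep(0, nfft - n)))
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE))[seq_len(n)] / nfft
  ac / n  # biased autocovariance: (1/n) sum_i v_i v_{i+t}
}

rhatOne <- function(x) {
  m <- splitChainMatrix(x)
  n <- nrow(m)
  cm <- colMeans(m)
  cv <- apply(m, 2, stats::var)
  W <- mean(cv)
  B <- n * stats::var(cm)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

essOne <- function(x) {
  m <- splitChainMatrix(x)
  n <- nrow(m); nChains <- ncol(m)
  cv <- apply(m, 2, stats::var)
  W <- mean(cv)
  if (W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(m))
  varPlus <- (n - 1) / n * W + B / n
  acov <- rowMeans(apply(m, 2, chainAutocov))
  rho <- 1 - (W - acov * n / (n - 1)) / varPlus
  # Geyer: sum consecutive pairs while positive, enforcing monotone decrease
  tauSum <- 0; prevP <- Inf; t <- 1
  while (t + 1 <= length(rho)) {
    P <- rho[t] + rho[t + 1]
    if (P < 0) break
    P <- min(P, prevP)
    tauSum <- tauSum + P
    prevP <- P
    t <- t + 2
  }
  tau <- max(-1 + 2 * tauSum, 1 / (n * nChains))
  min(n * nChains / tau, n * nChains)
}

#' Split-chain R-hat and effective sample size per parameter
#'
#' R-hat splits each chain in half and compares within- to between-chain
#' variance; ESS sums the chain-averaged autocorrelations with Geyer
#' initial-monotone truncation.
#'
#' @param draws a \linkS4class{PosteriorDraws} (>= 2 chains, >= 4 kept
#'   iterations per chain)
#' @param parameters parameter names (default: fixed effects plus variance
#'   components)
#' @return data.frame: parameter, rhat, ess
#' @export
mcmcDiagnostics <- function(draws, parameters = NULL) {
  d <- dim(draws@draws)
  if (d[2] < 2) stopLabeled("diagnostics", "need >= 2 chains, have ", d[2])
  if (d[1] < 4)
    stopLabeled("diagnostics", "need >= 4 draws per chain, have ", d[1])
  pn <- dimnames(draws@draws)[[3]]
  if (is.null(parameters))
    parameters <- intersect(c(draws@fixedNames, "sigma_u", "sigma"), pn)
  out <- data.frame(parameter = parameters,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(parameters)) {
    x <- draws@draws[, , parameters[i]]
    out$rhat[i] <- rhatOne(x)
    out$ess[i] <- essOne(x)
  }
  out
}
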