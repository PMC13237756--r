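# Posterior summaries: medians, 95% credible intervals, sign posterior
# probabilities mapped to verbal evidence strata, marginalized sleep slopes
# within group and moderator strata, effect differences over the observed
# sleep range, and posterior predictive checks.

#' Map a posterior probability to its verbal evidence stratum
#'
#' PP is the percentage of posterior mass on the dominant side of zero
#' (50-100). Boundaries are resolved by rounding to the nearest integer
#' percent: none (50), anecdotal (51-74), moderate (75-90), strong (91-96),
#' very strong (97-99), extreme (> 99).
#'
#' @param pp posterior probability in percent, 50 <= pp <= 100 (vectorized)
#' @return character stratum label(s)
#' @export
evidenceStratum <- function(pp) {
  if (any(pp < 50 | pp > 100))
    stopLabeled("stratum", "PP must lie in [50, 100] percent")
  r <- round(pp)
  out <- character(length(pp))
  out[r <= 50] <- "none"
  out[r >= 51 & r <= 74] <- "anecdotal"
  out[r >= 75 & r <= 90] <- "moderate"
  out[r >= 91 & r <= 96] <- "strong"
  out[r >= 97 & r <= 99] <- "very strong"
  out[r > 99] <- "extreme"
  out
}

ppFromDraws <- function(d) 100 * max(mean(d > 0), mean(d < 0))

#' Summarize posterior draws
#'
#' Per parameter: posterior median, 95\% credible interval (2.5th-97.5th
#' percentiles), posterior probability that the coefficient differs from
#' zero in its dominant direction, the verbal evidence stratum, and
#' split-chain R-hat / ESS diagnostics.
#'
#' @param draws a \linkS4class{PosteriorDraws}
#' @param parameters parameter names (default: fixed effects plus variance
#'   components)
#' @return data.frame: parameter, median, lower, upper, pp, stratum, rhat,
#'   ess
#' @export
summarizePosterior <- function(draws, parameters = NULL) {
  pn <- dimnames(draws@draws)[[3]]
  if (is.null(parameters))
    parameters <- intersect(c(draws@fixedNames, "sigma_u", "sigma"), pn)
  diag <- tryCatch(mcmcDiagnostics(draws, parameters),
                   error = function(e) data.frame(
                     parameter = parameters, rhat = NA_real_,
                     ess = NA_real_, stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(parameters, function(par) {
    d <- as.vector(draws@draws[, , par])
    q <- stats::quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
    pp <- ppFromDraws(d)
    data.frame(parameter = par, median = q[1], lower = q[2], upper = q[3],
               pp = pp, stratum = evidenceStratum(pp),
               stringsAsFactors = FALSE)
  }))
  out$rhat <- diag$rhat[match(out$parameter, diag$parameter)]
  out$ess <- diag$ess[match(out$parameter, diag$parameter)]
  rownames(out) <- NULL
  out
}

# Per-draw derivative of the expected response in Sleep, with the other
# variables held at the values in `at`. The model is linear in Sleep, so the
# derivative is the sum over Sleep-involved columns of the coefficient times
# the product of the remaining factors.
sleepSlopeDraws <- function(draws, design, at) {
  cn <- colnames(design$X)
  if (!any(vapply(strsplit(cn, ":", fixed = TRUE),
                  function(f) "Sleep" %in% f, logical(1))))
    stopLabeled("slopes", "model contains no Sleep term")
  d <- dim(draws@draws)
  b <- matrix(draws@draws[, , draws@fixedNames],
              nrow = d[1] * d[2],
              dimnames = list(NULL, draws@fixedNames))
  slope <- numeric(nrow(b))
  for (col in cn) {
    fac <- strsplit(col, ":", fixed = TRUE)[[1]]
    if (!"Sleep" %in% fac) next
    others <- fac[fac != "Sleep"]
    mult <- 1
    for (f in others) {
      if (is.null(at[[f]]))
        stopLabeled("slopes", "no stratum value supplied for ", f)
      mult <- mult * at[[f]]
    }
    slope <- slope + b[, col] * mult
  }
  slope
}

axisStrata <- list(
  Eyes = data.frame(label = c("Closed", "Open"), value = c(0, 1)),
  ML = c("Left", "Midline", "Right"),
  AP = c("Posterior", "Central", "Anterior"),
  IS = c("Inferior", "Mid-Transverse", "Superior"))

#' Marginalized sleep slopes within group and moderator strata
#'
#' For each cocaine-use group and each stratum of the moderators that
#' interact with Sleep in the model, the posterior of the derivative of
#' expected log alpha power with respect to sleep quality. Eye strata are
#' evaluated at closed/open (0/1); electrode-axis strata at the 15th, 50th
#' and 85th percentiles of the corresponding coordinate in the design.
#' The per-draw difference over the observed sleep range (slope times
#' range) is summarized alongside.
#'
#' @param draws a \linkS4class{PosteriorDraws}
#' @param design the design the draws were fit to
#' @param model model id or expression (used to label output)
#' @param probs percentiles defining the axis strata
#' @return data.frame: model, moderator, stratum, group, slope, lower,
#'   upper, pp, stratum_label (evidence), delta (median over observed sleep
#'   range)
#' @export
marginalSlopes <- function(draws, design, model = NULL,
                           probs = c(0.15, 0.5, 0.85)) {
  cn <- colnames(design$X)
  facs <- strsplit(cn, ":", fixed = TRUE)
  sleepCols <- vapply(facs, function(f) "Sleep" %in% f, logical(1))
  if (!any(sleepCols))
    stopLabeled("slopes", "model contains no Sleep term")
  moderators <- setdiff(unique(unlist(facs[sleepCols])),
                        c("Sleep", "Group"))
  strata <- if (!length(moderators)) {
    data.frame(moderator = "N/A", stratum = "N/A", stringsAsFactors = FALSE)
  } else {
    grids <- lapply(moderators, function(v) {
      if (v == "Eyes") {
        axisStrata$Eyes
      } else {
        q <- stats::quantile(design$X[, v], probs, names = FALSE)
        data.frame(label = axisStrata[[v]], value = q,
                   stringsAsFactors = FALSE)
      }
    })
    names(grids) <- moderators
    idx <- expand.grid(lapply(grids, function(g) seq_len(nrow(g))),
                       KEEP.OUT.ATTRS = FALSE)
    df <- data.frame(
      moderator = paste(moderators, collapse = " x "),
      stratum = apply(idx, 1, function(i) paste(
        mapply(function(v, j) grids[[v]]$label[j], moderators, i),
        collapse = " x ")),
      stringsAsFactors = FALSE)
    for (v in moderators) df[[paste0("value_", v)]] <-
      grids[[v]]$value[idx[[v]]]
    df
  }
  sleepRange <- diff(range(design$X[, "Sleep"]))
  groups <- data.frame(label = c("Abstinent", "Non-Abstinent"),
                       value = c(0, 1), stringsAsFactors = FALSE)
  rows <- list()
  for (si in seq_len(nrow(strata))) {
    for (gi in seq_len(nrow(groups))) {
      at <- list(Group = groups$value[gi])
      for (v in moderators) at[[v]] <- strata[[paste0("value_", v)]][si]
      sl <- sleepSlopeDraws(draws, design, at)
      q <- stats::quantile(sl, c(0.5, 0.025, 0.975), names = FALSE)
      pp <- ppFromDraws(sl)
      row <- data.frame(
        model = if (is.null(model)) NA_character_ else as.character(model),
        moderator = strata$moderator[si],
        stratum = strata$stratum[si],
        group = groups$label[gi],
        slope = q[1], lower = q[2], upper = q[3], pp = pp,
        evidence = evidenceStratum(pp),
        delta = stats::median(sl * sleepRange),
        stringsAsFactors = FALSE)
      for (v in moderators) row[[paste0("value_", v)]] <- at[[v]]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior difference over the observed sleep range
#'
#' Per draw, slope times (max - min) of the observed sleep values,
#' summarized by median and 95\% credible interval.
#'
#' @param slopeDraws numeric vector of per-draw slopes
#' @param sleepValues observed sleep-quality values (>= 2 distinct)
#' @return list: delta draws, median, lower, upper, range
#' @export
deltaOverRange <- function(slopeDraws, sleepValues) {
  r <- range(sleepValues)
  if (diff(r) == 0)
    stopLabeled("delta", "sleep values are constant; range undefined")
  d <- slopeDraws * diff(r)
  q <- stats::quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
  list(draws = d, median = q[1], lower = q[2], upper = q[3],
       range = diff(r))
}

#' Posterior predictive check on response mean and SD
#'
#' Simulates replicate response vectors from randomly selected posterior
#' draws (fixed effects, participant intercepts and residual noise) and
#' compares the observed mean and SD against the replicate distributions
#' via tail probabilities P(T_rep >= T_obs).
#'
#' @param draws a \linkS4class{PosteriorDraws} (fit with random intercepts)
#' @param design the design the draws were fit to
#' @param nReps replicate count (0 returns an empty report)
#' @param seed RNG seed
#' @return data.frame: statistic, observed, replicate_mean, p_tail
#' @export
posteriorPredictiveCheck <- function(draws, design, nReps = 200, seed = 1L) {
  if (nReps == 0)
    return(data.frame(statistic = character(0), observed = numeric(0),
                      replicate_mean = numeric(0), p_tail = numeric(0)))
  d <- dim(draws@draws)
  pn <- dimnames(draws@draws)[[3]]
  b <- matrix(draws@draws[, , draws@fixedNames],
              nrow = d[1] * d[2], dimnames = list(NULL, draws@fixedNames))
  uCols <- grep("^u\\[", pn, value = TRUE)
  pidIdx <- as.integer(design$pid)
  obs <- c(mean = mean(design$y), sd = stats::sd(design$y))
  repStats <- matrix(NA_real_, nReps, 2)
  withSeed(seed, {
    pick <- sample.int(nrow(b), nReps, replace = TRUE)
    for (i in seq_len(nReps)) {
      k <- pick[i]
      it <- (k - 1) %% d[1] + 1
      ch <- (k - 1) %/% d[1] + 1
      mu <- drop(design$X %*% b[k, ])
      if (length(uCols)) {
        u <- draws@draws[it, ch, uCols]
        mu <- mu + u[pidIdx]
      }
      sigma <- if ("sigma" %in% pn) draws@draws[it, ch, "sigma"] else 0
      yrep <- mu + stats::rnorm(length(mu), 0, sigma)
      repStats[i, ] <- c(mean(yrep), stats::sd(yrep))
    }
  })
  data.frame(statistic = c("mean", "sd"),
             observed = as.numeric(obs),
             replicate_mean = colMeans(repStats),
             p_tail = c(mean(repStats[, 1] >= obs[1]),
                        mean(repStats[, 2] >= obs[2])),
             stringsAsFactors = FALSE)
}

#' Write a marginal-slope table as TSV
#'
#' Columns mirror the standard reporting layout: Model, Moderator, Stratum,
#' Group, Slope, CrI, PP, evidence, delta-over-range.
#'
#' @param slopes data.frame from \code{\link{marginalSlopes}}
#' @param path file path
#' @export
writeSlopeTable <- function(slopes, path) {
  utils::write.table(slopes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
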