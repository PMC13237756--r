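test_that("design construction expands the model suite correctly", {
  tab <- smallAlphaTable()
  d3 <- buildDesign(tab, 3)
  expect_equal(sort(colnames(d3$X)),
               sort(c("(Intercept)", "Sleep", "Group", "Sleep:Group", "Eyes",
                      "ML", "AP", "IS", "ML:AP", "ML:IS", "AP:IS",
                      "ML:AP:IS")))
  expect_equal(ncol(buildDesign(tab, 1)$X), 10)
  expect_equal(ncol(buildDesign(tab, 2)$X), 10)
  expect_equal(ncol(buildDesign(tab, 4)$X), 15)
  expect_equal(ncol(buildDesign(tab, 5)$X), 15)
  # coding: abstinent and closed are the references
  expect_equal(unique(d3$X[tab$group == "abstinent", "Group"]), 0)
  expect_equal(unique(d3$X[tab$condition == "closed", "Eyes"]), 0)
  # custom four-way expression and the "x" spelling both work
  d4 <- buildDesign(tab, "Sleep x Group x Eyes x AP + ML * AP * IS")
  expect_true("Sleep:Group:Eyes:AP" %in% colnames(d4$X))
  expect_error(buildDesign(tab, "Sleep x Weather"), "Weather")
  expect_error(buildDesign(tab[0, ], 3), "empty")
})

test_that("Gibbs posterior matches the closed-form conjugate posterior", {
  tab <- smallAlphaTable(4, 4, seed = 17)
  set.seed(17)
  sub <- tab[sample(nrow(tab), 300), ]
  d <- buildDesign(sub, 3)
  sigma <- 0.5
  draws <- gibbsSample(d, chains = 4, iterations = 1500, warmup = 500,
                       seed = 8, sigmaFixed = sigma, randomIntercept = FALSE)
  Vinv <- crossprod(d$X) / sigma^2 + diag(1 / 100, ncol(d$X))
  V <- solve(Vinv)
  m <- drop(V %*% crossprod(d$X, d$y)) / sigma^2
  diag_ <- mcmcDiagnostics(draws)
  for (j in seq_len(ncol(d$X))) {
    dj <- parameterDraws(draws, colnames(d$X)[j])
    mcse <- sd(dj) / sqrt(diag_$ess[j])
    expect_lt(abs(mean(dj) - m[j]), 3 * mcse)
    expect_lt(abs(sd(dj) / sqrt(V[j, j]) - 1), 0.10)
  }
})

test_that("prior-only sampling reproduces the N(0, 10) prior", {
  tab <- smallAlphaTable()
  d <- buildDesign(tab, 3)
  d$y <- numeric(0)
  d$X <- d$X[0, , drop = FALSE]
  d$pid <- factor(character(0))
  draws <- gibbsSample(d, chains = 2, iterations = 3000, warmup = 1000,
                       seed = 3)
  for (par in c("Sleep", "Group")) {
    dj <- parameterDraws(draws, par)
    expect_lt(abs(mean(dj)), 3 * 10 / sqrt(length(dj)))
    expect_lt(abs(sd(dj) / 10 - 1), 0.05)
  }
})

test_that("sampling is reproducible and guards its preconditions", {
  tab <- smallAlphaTable()
  d <- buildDesign(tab, 2)
  a <- gibbsSample(d, chains = 2, iterations = 200, warmup = 100, seed = 21)
  b <- gibbsSample(d, chains = 2, iterations = 200, warmup = 100, seed = 21)
  expect_identical(posteriorArray(a), posteriorArray(b))
  c <- gibbsSample(d, chains = 2, iterations = 200, warmup = 100, seed = 22)
  expect_false(identical(posteriorArray(a), posteriorArray(c)))
  expect_error(gibbsSample(d, chains = 1), "chains")
  d2 <- d
  d2$y[1] <- NaN
  expect_error(gibbsSample(d2, chains = 2, iterations = 100, warmup = 50),
               "non-finite")
})

test_that("diagnostics behave on constructed chains", {
  mk <- function(x) new("PosteriorDraws",
                        draws = array(x, c(dim(x)[1], dim(x)[2], 1),
                                      dimnames = list(NULL, NULL, "b")),
                        fixedNames = "b", warmup = 0L, seed = 1L)
  set.seed(100)
  N <- 1000
  iid <- mk(matrix(rnorm(N * 4), N, 4))
  di <- mcmcDiagnostics(iid, "b")
  expect_gt(di$rhat, 0.99); expect_lt(di$rhat, 1.01)
  expect_lt(abs(di$ess - 4 * N) / (4 * N), 0.20)
  # AR(1) with rho = 0.5 -> ESS about N_total / 3
  ar <- matrix(0, N, 4)
  for (ch in 1:4) {
    x <- numeric(N); x[1] <- rnorm(1)
    for (i in 2:N) x[i] <- 0.5 * x[i - 1] + rnorm(1) * sqrt(1 - 0.25)
    ar[, ch] <- x
  }
  da <- mcmcDiagnostics(mk(ar), "b")
  expect_lt(abs(da$ess - 4 * N / 3) / (4 * N / 3), 0.25)
  # chains from shifted distributions fail convergence
  sh <- mk(cbind(matrix(rnorm(2 * N), N), matrix(rnorm(2 * N, 3), N)))
  expect_gt(mcmcDiagnostics(sh, "b")$rhat, 1.1)
  expect_error(mcmcDiagnostics(mk(matrix(rnorm(N), N, 1)), "b"), "chains")
  # cross-check ESS against an independent estimator on the AR(1) chains
  skip_if_not_installed("coda")
  codaEss <- sum(vapply(1:4, function(ch)
    unname(coda::effectiveSize(coda::mcmc(ar[, ch]))), numeric(1)))
  expect_lt(abs(da$ess - codaEss) / codaEss, 0.35)
})

test_that("posterior summaries report PP, strata and quantiles", {
  mk <- function(v) new("PosteriorDraws",
                        draws = array(v, c(length(v) / 2, 2, 1),
                                      dimnames = list(NULL, NULL, "b")),
                        fixedNames = "b", warmup = 0L, seed = 1L)
  allPos <- summarizePosterior(mk(abs(rnorm(400)) + 0.01), "b")
  expect_equal(allPos$pp, 100)
  expect_equal(allPos$stratum, "extreme")
  half <- summarizePosterior(mk(c(-1, -1, 1, 1)), "b")
  expect_equal(half$pp, 50)
  expect_equal(half$stratum, "none")
  expect_equal(summarizePosterior(mk(c(-1, 1, 1, 1)), "b")$pp, 75)
  s <- summarizePosterior(mk(1:400), "b")
  expect_true(s$lower <= s$median && s$median <= s$upper)
})

test_that("evidence strata follow the printed boundaries and are monotone", {
  expect_equal(evidenceStratum(50), "none")
  expect_equal(evidenceStratum(64.1), "anecdotal")
  expect_equal(evidenceStratum(87.8), "moderate")
  expect_equal(evidenceStratum(93), "strong")
  expect_equal(evidenceStratum(98), "very strong")
  expect_equal(evidenceStratum(99.5), "extreme")
  expect_equal(evidenceStratum(100), "extreme")
  expect_error(evidenceStratum(40), "50")
  ranks <- c(none = 1, anecdotal = 2, moderate = 3, strong = 4,
             "very strong" = 5, extreme = 6)
  grid <- seq(50, 100, by = 0.25)
  expect_false(is.unsorted(ranks[evidenceStratum(grid)]))
})

test_that("marginal slopes equal coefficient combinations and collapse without moderation", {
  tab <- smallAlphaTable(4, 4, seed = 23)
  fit2 <- fitModel(tab, 2, chains = 2, iterations = 600, warmup = 200,
                   seed = 9)
  ms2 <- marginalSlopes(fit2$draws, fit2$design, 2)
  # no sleep interactions: slope = Sleep coefficient in every row
  sMed <- median(parameterDraws(fit2$draws, "Sleep"))
  expect_equal(ms2$slope, rep(sMed, nrow(ms2)), tolerance = 1e-12)
  fit3 <- fitModel(tab, 3, chains = 2, iterations = 600, warmup = 200,
                   seed = 9)
  d3 <- fit3$design
  # non-abstinent slope draws are exactly b_Sleep + b_Sleep:Group
  sl <- restalpha:::sleepSlopeDraws(fit3$draws, d3, list(Group = 1))
  expect_equal(sl, parameterDraws(fit3$draws, "Sleep") +
                 parameterDraws(fit3$draws, "Sleep:Group"),
               tolerance = 1e-12)
  # model with no Sleep term refuses
  fit1 <- fitModel(tab, 1, chains = 2, iterations = 300, warmup = 100,
                   seed = 9)
  expect_error(marginalSlopes(fit1$draws, fit1$design, 1), "no Sleep")
  # moderator strata labels for the axis models
  fit6 <- fitModel(tab, 6, chains = 2, iterations = 400, warmup = 150,
                   seed = 9)
  ms6 <- marginalSlopes(fit6$draws, fit6$design, 6)
  expect_setequal(unique(ms6$stratum),
                  c("Posterior", "Central", "Anterior"))
  expect_equal(nrow(ms6), 6)
})

test_that("marginal slopes match the finite-difference oracle for models 2-7", {
  tab <- smallAlphaTable(3, 3, seed = 41)
  for (m in 2:7) {
    fit <- fitModel(tab, m, chains = 2, iterations = 400, warmup = 200,
                    seed = 50 + m)
    des <- fit$design
    ms <- marginalSlopes(fit$draws, des, m)
    bbar <- colMeans(matrix(posteriorArray(fit$draws)[, , fixedEffectNames(fit$draws)],
                            ncol = length(fixedEffectNames(fit$draws)),
                            dimnames = list(NULL, fixedEffectNames(fit$draws))))
    cn <- colnames(des$X)
    facs <- strsplit(cn, ":", fixed = TRUE)
    moderators <- setdiff(unique(unlist(facs[vapply(facs, function(f)
      "Sleep" %in% f, logical(1))])), c("Sleep", "Group"))
    for (r in seq_len(nrow(ms))) {
      at <- list(Group = as.numeric(ms$group[r] == "Non-Abstinent"),
                 Eyes = 0.25, ML = 0.1, AP = -0.2, IS = 0.3)
      for (v in moderators) at[[v]] <- ms[[paste0("value_", v)]][r]
      # finite difference of the posterior-mean prediction in Sleep,
      # built through the formula interface (independent route)
      newrow <- function(s) {
        dd <- data.frame(Sleep = s, Group = at$Group, Eyes = at$Eyes,
                         ML = at$ML, AP = at$AP, IS = at$IS)
        drop(stats::model.matrix(des$formula, dd) %*% bbar)
      }
      fd <- (newrow(6) - newrow(5)) / 1
      sl <- restalpha:::sleepSlopeDraws(fit$draws, des, at)
      expect_lt(abs(mean(sl) - fd), 1e-8)
    }
  }
})

test_that("delta over the observed sleep range is slope times range", {
  d1 <- deltaOverRange(rep(-0.2, 100), c(3, 7, 10))
  expect_equal(d1$median, -1.4)
  expect_equal(deltaOverRange(rep(0, 50), c(0, 10))$median, 0)
  set.seed(5)
  sym <- -0.15 + rnorm(20000, 0, 0.03)
  d3 <- deltaOverRange(sym, c(0, 10))
  expect_equal(d3$median, -1.5, tolerance = 0.01)
  expect_error(deltaOverRange(rep(1, 10), c(4, 4)), "constant")
})

test_that("posterior predictive checks calibrate and detect misfit", {
  tab <- smallAlphaTable(4, 4, seed = 71)
  fit <- fitModel(tab, 3, chains = 2, iterations = 800, warmup = 300,
                  seed = 13)
  ppc <- posteriorPredictiveCheck(fit$draws, fit$design, nReps = 200,
                                  seed = 2)
  expect_true(all(ppc$p_tail >= 0.05 & ppc$p_tail <= 0.95))
  # shifting the observed response after fitting breaks the mean check
  shifted <- fit$design
  shifted$y <- shifted$y + 10
  ppcBad <- posteriorPredictiveCheck(fit$draws, shifted, nReps = 200,
                                     seed = 2)
  expect_lt(ppcBad$p_tail[ppcBad$statistic == "mean"], 0.01)
  empty <- posteriorPredictiveCheck(fit$draws, fit$design, nReps = 0)
  expect_equal(nrow(empty), 0)
})
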