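#' Generative parameters for synthetic cohorts
#'
#' Defaults reproduce the effect regime the analysis is designed to detect:
#' a sleep slope of -0.19 log10 units per sleep point in the abstinent group
#' and -0.05 in the non-abstinent group (interaction +0.14), a group shift of
#' -0.36, an eyes-open alpha reduction, and posterior/right/superior spatial
#' gradients. Cohort size defaults elsewhere are 15 abstinent + 17
#' non-abstinent participants.
#'
#' @param beta0 baseline log10 alpha power
#' @param betaGroup non-abstinent group shift
#' @param betaSleep sleep slope in the abstinent (reference) group
#' @param betaSleepGroup sleep x group interaction
#' @param betaEyes eyes-open shift
#' @param gammaML,gammaAP,gammaIS spatial gradients (+right, +anterior,
#'   +superior axes); negative gammaAP puts more alpha posteriorly
#' @param extraCoefs optional named numeric of higher-order coefficients;
#'   names are ":"-joined products of Sleep, Group, Eyes, ML, AP, IS
#'   (e.g. \code{c("Sleep:Group:AP" = -0.02)})
#' @param sigmaParticipant SD of participant random intercepts (log10 units)
#' @param sigmaNoise observation SD (log10 units, tabular mode)
#' @param artifactRate per-(channel, 2-s block) artifact probability
#' @param artifactAmplitude artifact transient amplitude, microvolts
#' @param alphaFreqs frequencies of the alpha comb (Hz); defaults to the 11
#'   alpha-band bin centers at 0.5 Hz resolution
#' @param backgroundRms RMS of the 1/f background, microvolts (0 disables)
#' @param sleepMean,sleepSD location/scale of the discretized normal sleep
#'   quality distribution (integers 0-10, same in both groups)
#' @param seed master seed for generator randomness
#' @return a \linkS4class{GenParams}
#' @export
genParams <- function(beta0 = 1.35, betaGroup = -0.36, betaSleep = -0.19,
                      betaSleepGroup = 0.14, betaEyes = -0.30,
                      gammaML = 0.05, gammaAP = -0.15, gammaIS = 0.10,
                      extraCoefs = numeric(0), sigmaParticipant = 0.5,
                      sigmaNoise = 0.4, artifactRate = 0.02,
                      artifactAmplitude = 250,
                      alphaFreqs = seq(8, 13, by = 0.5),
                      backgroundRms = 10, sleepMean = 6, sleepSD = 2,
                      seed = 20260927L) {
  new("GenParams", beta0 = beta0, betaGroup = betaGroup,
      betaSleep = betaSleep, betaSleepGroup = betaSleepGroup,
      betaEyes = betaEyes, gammaML = gammaML, gammaAP = gammaAP,
      gammaIS = gammaIS, extraCoefs = extraCoefs,
      sigmaParticipant = sigmaParticipant, sigmaNoise = sigmaNoise,
      artifactRate = artifactRate, artifactAmplitude = artifactAmplitude,
      alphaFreqs = alphaFreqs, backgroundRms = backgroundRms,
      sleepMean = sleepMean, sleepSD = sleepSD, seed = as.integer(seed))
}

#' Generate a participant cohort
#'
#' Sleep quality is drawn from a discretized normal (integers 0-10) with the
#' same location in both groups. Days since last use respect the abstinence
#' definition: abstinent participants report 30-104 days, non-abstinent 1-13
#' days. Random intercepts are N(0, sigmaParticipant).
#'
#' @param nAbstinent,nNonAbstinent group sizes (>= 1)
#' @param params a \linkS4class{GenParams}
#' @return data.frame: id, group ("abstinent"/"non_abstinent"),
#'   sleep_quality, days_since_use, random_intercept
#' @export
generateCohort <- function(nAbstinent = 15, nNonAbstinent = 17,
                           params = genParams()) {
  if (nAbstinent < 1 || nNonAbstinent < 1)
    stop("group counts must be >= 1", call. = FALSE)
  n <- nAbstinent + nNonAbstinent
  withSeed(deriveSeed(params@seed, "cohort"), {
    sleep <- pmin(10, pmax(0, round(stats::rnorm(n, params@sleepMean,
                                                 params@sleepSD))))
    daysAb <- sample(30:104, nAbstinent, replace = TRUE)
    daysNon <- pmin(13, 1 + stats::rpois(nNonAbstinent, 2.5))
    u <- stats::rnorm(n, 0, params@sigmaParticipant)
  })
  data.frame(
    id = sprintf("P%02d", seq_len(n)),
    group = rep(c("abstinent", "non_abstinent"), c(nAbstinent, nNonAbstinent)),
    sleep_quality = as.integer(sleep),
    days_since_use = as.integer(c(daysAb, daysNon)),
    random_intercept = u,
    stringsAsFactors = FALSE)
}

# Linear predictor of log10 alpha power for rows of (participant covariates x
# electrode coordinates x eye condition); the generative counterpart of the
# mixed models' fixed-effect structure plus the participant intercept.
linearPredictor <- function(params, group01, sleep, eyes01, ml, ap, is_, u = 0) {
  lp <- params@beta0 + params@betaGroup * group01 +
    (params@betaSleep + params@betaSleepGroup * group01) * sleep +
    params@betaEyes * eyes01 +
    params@gammaML * ml + params@gammaAP * ap + params@gammaIS * is_ + u
  if (length(params@extraCoefs)) {
    vals <- list(Sleep = sleep, Group = group01, Eyes = eyes01,
                 ML = ml, AP = ap, IS = is_)
    for (term in names(params@extraCoefs)) {
      fac <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (!all(fac %in% names(vals)))
        stop("unknown variable in extraCoefs term: ", term, call. = FALSE)
      prod <- 1
      for (f in fac) prod <- prod * vals[[f]]
      lp <- lp + params@extraCoefs[[term]] * prod
    }
  }
  lp
}

#' Generate a long-format alpha-power table directly (tabular fast path)
#'
#' Emits one row per participant x electrode x eye condition whose
#' log10 alpha power equals the generative linear predictor plus the
#' participant random intercept and N(0, sigmaNoise) observation noise.
#' With 32 participants and the default 65-electrode montage this is 4160
#' rows, 130 per participant.
#'
#' @param cohort data.frame from \code{\link{generateCohort}}
#' @param layout an \linkS4class{ElectrodeLayout}
#' @param params a \linkS4class{GenParams}
#' @return long data.frame (see \code{\link{buildLongTable}} for the schema)
#' @export
generateAlphaTable <- function(cohort, layout = buildDefaultLayout(),
                               params = genParams()) {
  if (!nrow(cohort)) stop("cohort must be nonempty", call. = FALSE)
  co <- cartesianCoords(layout)
  labs <- electrodeLabels(layout)
  nE <- length(labs)
  conds <- c("closed", "open")
  rows <- expand.grid(electrode = seq_len(nE), condition = conds,
                      pidx = seq_len(nrow(cohort)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rows$pidx; e <- rows$electrode
  g01 <- as.numeric(cohort$group[p] == "non_abstinent")
  eyes01 <- as.numeric(rows$condition == "open")
  lp <- linearPredictor(params, g01, cohort$sleep_quality[p], eyes01,
                        co[e, "ml"], co[e, "ap"], co[e, "is"],
                        cohort$random_intercept[p])
  withSeed(deriveSeed(params@seed, "table"), {
    noise <- if (params@sigmaNoise > 0)
      stats::rnorm(length(lp), 0, params@sigmaNoise) else 0
  })
  out <- data.frame(
    participant = cohort$id[p],
    electrode = labs[e],
    ml = co[e, "ml"], ap = co[e, "ap"], is = co[e, "is"],
    condition = rows$condition,
    log_alpha_power = lp + noise,
    group = cohort$group[p],
    sleep_quality = cohort$sleep_quality[p],
    days_since_use = cohort$days_since_use[p],
    stringsAsFactors = FALSE)
  out[order(out$participant, out$condition, out$electrode), , drop = FALSE]
}

#' Generate a raw multichannel recording (waveform mode)
#'
#' Synthesizes 90 s of 500 Hz EEG whose measured log10 alpha band power
#' (tapered-FFT pipeline, log-then-band-average) matches the generative
#' linear predictor at every electrode. Alpha content is a comb of equal-
#' amplitude sinusoids at the alpha bin centers (default 8-13 Hz in 0.5 Hz
#' steps) with independent random phase per channel per 2-s block, each
#' component calibrated so its bin power equals 10^(linear predictor).
#' A 1/f background (spectrally shaped Gaussian noise) is superposed when
#' \code{backgroundRms > 0}. Scalp potentials are synthesized for all 65
#' electrodes and emitted referenced to FCz (64 recorded channels), matching
#' the acquisition convention.
#'
#' @param profile one-row data.frame (a cohort row)
#' @param condition "open" or "closed"
#' @param layout an \linkS4class{ElectrodeLayout} containing "FCz"
#' @param params a \linkS4class{GenParams}
#' @param durationS recording length, seconds
#' @param srate sampling rate, Hz
#' @param calibrationTaper taper fraction the downstream spectral analysis
#'   will use; the comb amplitude cancels the taper's phase-averaged bin
#'   bias so the measured band power matches the linear predictor
#' @return a \linkS4class{RawRecording} with the 64 non-reference channels
#' @export
generateRecording <- function(profile, condition = c("closed", "open"),
                              layout = buildDefaultLayout(),
                              params = genParams(), durationS = 90,
                              srate = 500, calibrationTaper = 0.10) {
  condition <- match.arg(condition)
  if (nrow(profile) != 1) stop("profile must be a single cohort row",
                               call. = FALSE)
  labs <- electrodeLabels(layout)
  co <- cartesianCoords(layout)
  nCh <- length(labs)
  g01 <- as.numeric(profile$group == "non_abstinent")
  eyes01 <- as.numeric(condition == "open")
  lp <- linearPredictor(params, g01, profile$sleep_quality, eyes01,
                        co[, "ml"], co[, "ap"], co[, "is"],
                        profile$random_intercept)
  winN <- as.integer(2 * srate)
  # per-component amplitude so each comb bin carries power 10^lp (a^2/2),
  # corrected for (a) the analysis taper's phase-averaged bin bias and
  # (b) the expected power shrinkage of the average reference: with
  # independent phases, E P'_i = Q_i (1 - 2/n) + sum_j Q_j / n^2, which is
  # inverted here so the re-referenced measurement hits the target.
  delta <- combCalibrationOffset(winN, srate, params@alphaFreqs,
                                 calibrationTaper)
  Ptarget <- 10^(lp - delta)
  S <- sum(Ptarget) / (1 - 1 / nCh)
  Q <- (Ptarget - S / nCh^2) / (1 - 2 / nCh)
  if (any(Q <= 0))
    stopLabeled("generate", "spatial power spread too extreme for the ",
                "average-reference calibration")
  amp <- sqrt(2 * Q)
  nBlocks <- floor(durationS * srate / winN)
  nSamp <- as.integer(durationS * srate)
  tt <- (seq_len(winN) - 1) / srate
  nF <- length(params@alphaFreqs)
  Cb <- cospi(2 * outer(params@alphaFreqs, tt))   # nF x winN
  Sb <- sinpi(2 * outer(params@alphaFreqs, tt))
  s <- matrix(0, nCh, nSamp)
  withSeed(deriveSeed(params@seed, paste("rec", profile$id, condition)), {
    for (b in seq_len(nBlocks)) {
      ph <- matrix(stats::runif(nCh * nF, 0, 2 * pi), nCh, nF)
      blk <- cos(ph) %*% Cb - sin(ph) %*% Sb     # sum_f cos(2 pi f t + ph)
      idx <- ((b - 1) * winN + 1):(b * winN)
      s[, idx] <- amp * blk
    }
    if (nBlocks * winN < nSamp)                   # trailing remainder: comb
      s[, (nBlocks * winN + 1):nSamp] <- 0        # left silent; segmenter
    if (params@backgroundRms > 0) {               # discards it anyway
      s <- s + pinkNoise(nCh, nSamp, params@backgroundRms)
    }
  })
  rownames(s) <- labs
  refIdx <- match("FCz", labs)
  if (is.na(refIdx))
    stop("layout must contain the online reference FCz", call. = FALSE)
  v <- sweep(s[-refIdx, , drop = FALSE], 2, s[refIdx, ], "-")
  new("RawRecording", id = profile$id, condition = condition,
      channels = labs[-refIdx], samples = v, srate = srate)
}

# Phase-averaged log10 bias of the band-mean comb power under a given
# analysis taper: with tapering, a bin-centered sinusoid leaks a little
# power out of its own bin, and band-edge bins are not compensated by a
# neighbor on both sides. The expected tapered bin power of cos(w_j t + phi)
# averaged over phase is (|W(k-j)|^2 + |W(k+j)|^2)/4 for spectral window W,
# which lets the generator cancel the bias exactly.
combCalibrationOffset <- function(winN, srate, freqs, taperFraction) {
  if (taperFraction == 0) return(0)
  w <- taperWindow(winN, taperFraction)
  msq <- mean(w^2)
  W2 <- Mod(stats::fft(w))^2
  bins <- as.integer(round(freqs * winN / srate))    # DFT bin indices
  idx <- function(k) (k %% winN) + 1
  P <- vapply(bins, function(k) {
    e <- sum((W2[idx(k - bins)] + W2[idx(k + bins)]) / 4)
    2 * e / (winN^2 * msq)
  }, numeric(1))
  mean(log10(P / 0.5))
}

# Spectrally shaped Gaussian noise with a 1/f amplitude profile (exponent 1
# in power), RMS-normalized per channel.
pinkNoise <- function(nCh, nSamp, rms) {
  freqs <- seq(0, floor(nSamp / 2), by = 1)
  shape <- c(0, 1 / sqrt(freqs[-1]))              # |H(f)| ~ f^(-1/2)
  out <- matrix(0, nCh, nSamp)
  for (ch in seq_len(nCh)) {
    w <- stats::rnorm(nSamp)
    W <- stats::fft(w)
    half <- length(shape)
    mult <- c(shape, rev(shape[2:(nSamp - half + 1)]))
    x <- Re(stats::fft(W * mult, inverse = TRUE)) / nSamp
    out[ch, ] <- x / stats::sd(x) * rms
  }
  out
}

#' Inject high-amplitude artifact transients
#'
#' Randomly selected (channel, 2-s-aligned block) sites receive a square
#' transient of \code{artifactAmplitude} microvolts spanning the first tenth
#' of the block; the step edges and the amplitude both exceed the default
#' detection thresholds. Ground-truth sites are returned for round-trip
#' testing.
#'
#' @param recording a \linkS4class{RawRecording}
#' @param params a \linkS4class{GenParams} (rate, amplitude, seed)
#' @return list(recording = modified recording, sites = data.frame(channel,
#'   block))
#' @export
injectArtifacts <- function(recording, params = genParams()) {
  s <- recording@samples
  winN <- as.integer(2 * recording@srate)
  nBlocks <- floor(ncol(s) / winN)
  nCh <- nrow(s)
  withSeed(deriveSeed(params@seed,
                      paste("artifact", recording@id, recording@condition)), {
    hit <- which(matrix(stats::runif(nCh * nBlocks) < params@artifactRate,
                        nCh, nBlocks), arr.ind = TRUE)
  })
  if (nrow(hit)) {
    for (i in seq_len(nrow(hit))) {
      ch <- hit[i, 1]; b <- hit[i, 2]
      idx <- ((b - 1) * winN + 1):((b - 1) * winN + max(2, winN %/% 10))
      s[ch, idx] <- s[ch, idx] + params@artifactAmplitude
    }
  }
  out <- recording
  out@samples <- s
  list(recording = out,
       sites = data.frame(channel = recording@channels[hit[, 1]],
                          block = as.integer(hit[, 2]),
                          stringsAsFactors = FALSE))
}
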