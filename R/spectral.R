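# Spectral estimation: tapered FFT periodograms on 2-s epochs, averaged
# across epochs, then log10 alpha (8-13 Hz) band power per electrode.
# 2-s epochs give an exactly 0.5 Hz frequency grid, so the inclusive alpha
# band holds exactly 11 bins.

#' Split-cosine-bell (Tukey) taper
#'
#' A raised-cosine ramp over the first and last \code{taperFraction/2} of
#' the epoch, flat in between. \code{taperFraction = 1} is a full Hanning
#' window, 0 is rectangular. The default 0.10 tapers 10\% of the epoch.
#'
#' @param n window length, samples
#' @param taperFraction total tapered fraction in [0, 1]
#' @return numeric taper of length n
#' @export
taperWindow <- function(n, taperFraction = 0.10) {
  if (taperFraction < 0 || taperFraction > 1)
    stopLabeled("taper", "taperFraction must lie in [0, 1], got ",
                taperFraction)
  if (taperFraction == 0) return(rep(1, n))
  p <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  r <- taperFraction
  lo <- p < r / 2
  hi <- p > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * p[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - p[hi]) / r - 1)))
  w
}

#' Apply a split-cosine-bell taper to samples
#'
#' @param x numeric vector or channels x samples matrix
#' @param taperFraction total tapered fraction (see
#'   \code{\link{taperWindow}})
#' @return tapered samples, same shape
#' @export
applyTaper <- function(x, taperFraction = 0.10) {
  if (is.matrix(x)) {
    w <- taperWindow(ncol(x), taperFraction)
    sweep(x, 2, w, "*")
  } else {
    x * taperWindow(length(x), taperFraction)
  }
}

#' Epoch-averaged one-sided periodogram
#'
#' Each channel-epoch is demeaned, tapered, and Fourier transformed; the
#' one-sided periodogram is normalized so that under a rectangular taper its
#' sum equals the (population) variance of the epoch, with taper power loss
#' compensated by dividing by the taper's mean square. Periodograms are then
#' combined across epochs, by arithmetic mean of power (default) or by mean
#' of log10 power (stored as the geometric mean, the alternative averaging
#' order).
#'
#' @param clean a \linkS4class{CleanEpochSet} (or \linkS4class{EpochSet})
#' @param taperFraction total tapered fraction, default 0.10
#' @param epochAverage "power" or "log-power"
#' @param floorEps power floor used only for \code{epochAverage =
#'   "log-power"} to keep empty bins finite
#' @return a \linkS4class{PowerSpectrum}
#' @export
periodogram <- function(clean, taperFraction = 0.10,
                        epochAverage = c("power", "log-power"),
                        floorEps = 1e-20) {
  epochAverage <- match.arg(epochAverage)
  d <- dim(clean@epochs)
  if (d[3] < 1)
    stopLabeled("periodogram", "no retained epochs")
  nCh <- d[1]; n <- d[2]; m <- d[3]
  w <- taperWindow(n, taperFraction)
  msq <- mean(w^2)
  nHalf <- n %/% 2
  freqs <- (seq_len(nHalf)) * clean@srate / n
  acc <- matrix(0, nHalf, nCh)
  for (k in seq_len(m)) {
    e <- clean@epochs[, , k]
    dim(e) <- c(nCh, n)
    e <- e - rowMeans(e)
    e <- sweep(e, 2, w, "*")
    X <- stats::mvfft(t(e))                 # n x channels
    p2 <- Mod(X[2:(nHalf + 1), , drop = FALSE])^2 / n^2
    fac <- rep(2, nHalf)
    if (n %% 2 == 0) fac[nHalf] <- 1        # Nyquist bin not doubled
    P <- p2 * fac / msq
    acc <- acc + if (epochAverage == "power") P else log10(pmax(P, floorEps))
  }
  acc <- acc / m
  if (epochAverage == "log-power") acc <- 10^acc
  colnames(acc) <- clean@channels
  new("PowerSpectrum", freqs = freqs, power = acc,
      channels = clean@channels, nEpochs = as.integer(m),
      epochAverage = epochAverage)
}

#' Log10 alpha band power per channel
#'
#' Each bin's power is log10-transformed first, then averaged over the bins
#' with band[1] <= f <= band[2] inclusive (11 bins for the 8-13 Hz band at
#' 0.5 Hz resolution). Units: log10 microvolts squared.
#'
#' @param spectrum a \linkS4class{PowerSpectrum}
#' @param band numeric length-2, band edges in Hz (inclusive)
#' @param floorEps optional power floor (microvolts squared); when NULL
#'   (default), a zero-power bin inside the band raises an error advising a
#'   floor (e.g. 1e-20)
#' @return named numeric, log10 alpha power per channel
#' @export
alphaBandPower <- function(spectrum, band = c(8, 13), floorEps = NULL) {
  if (band[1] > band[2] || band[1] < min(spectrum@freqs) ||
      band[2] > max(spectrum@freqs))
    stopLabeled("band", "band [", band[1], ", ", band[2],
                "] outside the spectrum range")
  sel <- spectrum@freqs >= band[1] & spectrum@freqs <= band[2]
  P <- spectrum@power[sel, , drop = FALSE]
  if (any(P <= 0)) {
    if (is.null(floorEps))
      stopLabeled("band", "zero-power bin inside the band; supply floorEps ",
                  "(e.g. 1e-20) to floor empty bins")
    P <- pmax(P, floorEps)
  }
  out <- colMeans(log10(P))
  names(out) <- spectrum@channels
  out
}

#' Assemble the long-format modelling table
#'
#' One row per participant x electrode x eye condition, log10 alpha power
#' joined with participant covariates and Cartesian electrode coordinates.
#' Row order is deterministic: participant, condition, electrode label.
#'
#' @param power long data.frame with columns participant, condition,
#'   electrode, log_alpha_power (e.g. accumulated from
#'   \code{\link{alphaBandPower}} calls)
#' @param covariates data.frame with columns id, group, sleep_quality,
#'   days_since_use
#' @param layout an \linkS4class{ElectrodeLayout}
#' @return data.frame: participant, electrode, ml, ap, is, condition,
#'   log_alpha_power, group, sleep_quality, days_since_use
#' @export
buildLongTable <- function(power, covariates, layout = buildDefaultLayout()) {
  need <- c("participant", "condition", "electrode", "log_alpha_power")
  if (!all(need %in% names(power)))
    stopLabeled("long-table", "power table must have columns: ",
                paste(need, collapse = ", "))
  for (p in unique(power$participant)) {
    conds <- unique(power$condition[power$participant == p])
    if (!all(c("closed", "open") %in% conds))
      stopLabeled("long-table", "participant ", p,
                  " is missing a condition (has: ",
                  paste(conds, collapse = ", "), ")")
    if (!p %in% covariates$id)
      stopLabeled("long-table", "no covariates for participant ", p)
  }
  cv <- covariates[match(power$participant, covariates$id), ]
  co <- cartesianCoords(layout)
  eidx <- match(power$electrode, electrodeLabels(layout))
  if (anyNA(eidx))
    stopLabeled("long-table", "electrode(s) not in layout: ",
                paste(unique(power$electrode[is.na(eidx)]), collapse = ", "))
  out <- data.frame(
    participant = power$participant,
    electrode = power$electrode,
    ml = co[eidx, "ml"], ap = co[eidx, "ap"], is = co[eidx, "is"],
    condition = power$condition,
    log_alpha_power = power$log_alpha_power,
    group = cv$group,
    sleep_quality = cv$sleep_quality,
    days_since_use = cv$days_since_use,
    stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$condition, out$electrode), ]
  rownames(out) <- NULL
  out
}

#' Measure log alpha power for one clean epoch set
#'
#' Convenience wrapper: periodogram then \code{\link{alphaBandPower}}.
#'
#' @inheritParams periodogram
#' @inheritParams alphaBandPower
#' @return named numeric, log10 alpha power per channel
#' @export
measureAlphaPower <- function(clean, taperFraction = 0.10, band = c(8, 13),
                              epochAverage = "power", floorEps = NULL) {
  sp <- periodogram(clean, taperFraction, epochAverage)
  alphaBandPower(sp, band, floorEps)
}

#' Write / read the long alpha-power table as TSV
#'
#' Fixed column order: participant, electrode, ml, ap, is, condition,
#' log_alpha_power, group, sleep_quality, days_since_use.
#'
#' @param table the long table
#' @param path file path
#' @export
writeAlphaTable <- function(table, path) {
  cols <- c("participant", "electrode", "ml", "ap", "is", "condition",
            "log_alpha_power", "group", "sleep_quality", "days_since_use")
  utils::write.table(format(table[, cols], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlphaTable
#' @export
readAlphaTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
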