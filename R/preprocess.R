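# Preprocessing: average re-reference -> 2-s segmentation -> artifact
# detection -> channel rule (40%, Hjorth interpolation) -> segment rule
# (10%, rejection). The stage order is fixed; both thresholds are strict
# inequalities ("more than").

#' Re-reference a recording to the average reference
#'
#' The online reference (FCz by default) is first recovered as an explicit
#' all-zero channel if absent, then every channel has the instantaneous mean
#' across all channels subtracted. After re-referencing the cross-channel
#' mean is zero at every sample. Idempotent.
#'
#' @param recording a \linkS4class{RawRecording}
#' @param layout an \linkS4class{ElectrodeLayout}; all recording channels
#'   must appear in it
#' @param refLabel label of the online reference to recover
#' @return a \linkS4class{RawRecording} including the recovered reference
#' @export
rereferenceAverage <- function(recording, layout = buildDefaultLayout(),
                               refLabel = "FCz") {
  unknown <- setdiff(recording@channels, electrodeLabels(layout))
  if (length(unknown))
    stopLabeled("rereference", "channel labels not in layout: ",
                paste(unknown, collapse = ", "))
  s <- recording@samples
  chans <- recording@channels
  if (!refLabel %in% chans && refLabel %in% electrodeLabels(layout)) {
    s <- rbind(s, matrix(0, 1, ncol(s)))
    chans <- c(chans, refLabel)
  }
  s <- sweep(s, 2, colMeans(s), "-")
  rownames(s) <- chans
  out <- recording
  out@channels <- chans
  out@samples <- s
  out
}

#' Cut a recording into contiguous fixed-length epochs
#'
#' Non-overlapping windows; a trailing remainder shorter than the window is
#' discarded.
#'
#' @param recording a \linkS4class{RawRecording}
#' @param windowS window length, seconds (default 2)
#' @return an \linkS4class{EpochSet}
#' @export
segmentEpochs <- function(recording, windowS = 2) {
  winN <- as.integer(round(windowS * recording@srate))
  nSamp <- ncol(recording@samples)
  if (nSamp < winN)
    stopLabeled("segment", "recording shorter than one window (",
                nSamp / recording@srate, " s < ", windowS, " s)")
  m <- nSamp %/% winN
  ep <- array(recording@samples[, seq_len(m * winN), drop = FALSE],
              dim = c(nrow(recording@samples), winN, m))
  new("EpochSet", id = recording@id, condition = recording@condition,
      channels = recording@channels, epochs = ep, srate = recording@srate)
}

#' Flag artifact-contaminated (channel, epoch) cells
#'
#' A cell is flagged when any sample magnitude exceeds
#' \code{absThresholdUv} or any sample-to-sample step exceeds
#' \code{stepThresholdUv} within the epoch. These are conventional
#' resting-EEG screening values.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param absThresholdUv absolute amplitude threshold, microvolts
#' @param stepThresholdUv successive-difference threshold, microvolts
#' @return an \linkS4class{ArtifactMask}
#' @export
detectArtifacts <- function(epochs, absThresholdUv = 100,
                            stepThresholdUv = 50) {
  if (absThresholdUv <= 0 || stepThresholdUv <= 0)
    stopLabeled("detect", "thresholds must be positive")
  d <- dim(epochs@epochs)
  flags <- matrix(FALSE, d[1], d[3])
  for (k in seq_len(d[3])) {
    e <- epochs@epochs[, , k, drop = FALSE]
    dim(e) <- d[1:2]
    absBad <- apply(abs(e), 1, max) > absThresholdUv
    stepBad <- apply(abs(e[, -1, drop = FALSE] - e[, -d[2], drop = FALSE]),
                     1, max) > stepThresholdUv
    flags[, k] <- absBad | stepBad
  }
  rownames(flags) <- epochs@channels
  new("ArtifactMask", flags = flags)
}

#' Hjorth Laplacian interpolation of one channel in one epoch
#'
#' Replacement samples are the distance-weighted mean of the channel's
#' nearest neighbors, weights proportional to 1/angular-distance and
#' normalized to sum 1. Neighbors themselves flagged in the epoch are
#' excluded.
#'
#' @param epoch numeric matrix, channels x samples
#' @param channel channel index to replace
#' @param graph a \linkS4class{NeighborGraph}
#' @param flagged optional logical vector (per channel) of artifact flags in
#'   this epoch; flagged neighbors are excluded
#' @return numeric vector of replacement samples
#' @export
hjorthInterpolate <- function(epoch, channel, graph, flagged = NULL) {
  nb <- graph@neighbors[channel, ]
  d <- graph@distances[channel, ]
  if (!is.null(flagged)) {
    keep <- !flagged[nb]
    nb <- nb[keep]; d <- d[keep]
  }
  if (!length(nb))
    stopLabeled("hjorth", "no usable neighbors for channel ",
                graph@labels[channel])
  w <- 1 / pmax(d, 1e-12)
  w <- w / sum(w)
  drop(w %*% epoch[nb, , drop = FALSE])
}

#' Channel rule: interpolate channels bad in more than a fraction of epochs
#'
#' Channels whose flagged fraction strictly exceeds \code{frac} (default
#' 40\%) are replaced by Hjorth interpolation in every epoch, and their
#' flags are cleared before the segment rule is evaluated. When all of a bad
#' channel's neighbors are themselves flagged in some epoch, the unweighted
#' neighbor mean is used there and the cell's flag is kept.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param mask an \linkS4class{ArtifactMask} matching \code{epochs}
#' @param graph a \linkS4class{NeighborGraph} over the epoch channels
#' @param frac interpolation threshold (strict), default 0.40
#' @return list(epochs = updated EpochSet, mask = updated ArtifactMask,
#'   interpolated = character labels)
#' @export
applyChannelRule <- function(epochs, mask, graph, frac = 0.40) {
  d <- dim(epochs@epochs)
  if (!identical(dim(mask@flags), c(d[1], d[3])))
    stopLabeled("channel-rule", "mask does not match epochs")
  badFrac <- rowMeans(mask@flags)
  bad <- which(badFrac > frac)
  if (length(bad) == d[1])
    stopLabeled("channel-rule", "all channels exceed the bad fraction; ",
                "recording unrecoverable")
  ep <- epochs@epochs
  flags <- mask@flags
  origFlags <- mask@flags
  for (ch in bad) {
    for (k in seq_len(d[3])) {
      e <- ep[, , k]
      usable <- !origFlags[, k]
      usable[bad] <- FALSE                   # never lean on other bad channels
      nb <- graph@neighbors[ch, ]
      if (any(usable[nb])) {
        ep[ch, , k] <- hjorthInterpolate(e, ch, graph, flagged = !usable)
        flags[ch, k] <- FALSE
      } else {
        ep[ch, , k] <- colMeans(e[nb, , drop = FALSE])
        # no clean neighbor: keep the flag so the segment rule can judge
      }
    }
  }
  out <- epochs
  out@epochs <- ep
  list(epochs = out, mask = new("ArtifactMask", flags = flags),
       interpolated = epochs@channels[bad])
}

#' Segment rule: drop epochs with too many bad sensors
#'
#' Epochs whose fraction of flagged sensors strictly exceeds \code{frac}
#' (default 10\%) are dropped; the rest are retained with provenance.
#'
#' @param epochs an \linkS4class{EpochSet} (after the channel rule)
#' @param mask the matching \linkS4class{ArtifactMask}
#' @param frac rejection threshold (strict), default 0.10
#' @param interpolated labels of channels interpolated by the channel rule
#'   (recorded as provenance)
#' @return a \linkS4class{CleanEpochSet}
#' @export
applySegmentRule <- function(epochs, mask, frac = 0.10,
                             interpolated = character(0)) {
  d <- dim(epochs@epochs)
  if (!identical(dim(mask@flags), c(d[1], d[3])))
    stopLabeled("segment-rule", "mask does not match epochs")
  badFrac <- colMeans(mask@flags)
  dropIdx <- which(badFrac > frac)
  if (length(dropIdx) == d[3])
    stopLabeled("segment-rule", "all epochs dropped; recording unusable")
  keep <- setdiff(seq_len(d[3]), dropIdx)
  winS <- d[2] / epochs@srate
  new("CleanEpochSet", id = epochs@id, condition = epochs@condition,
      channels = epochs@channels,
      epochs = epochs@epochs[, , keep, drop = FALSE],
      srate = epochs@srate, interpolated = interpolated,
      dropped = as.integer(dropIdx),
      retainedSeconds = winS * length(keep))
}

#' Full preprocessing chain for one recording
#'
#' Average re-reference (with reference recovery), 2-s segmentation,
#' artifact detection, channel rule, segment rule, in that order.
#'
#' @param recording a \linkS4class{RawRecording}
#' @param layout an \linkS4class{ElectrodeLayout}
#' @param graph optional precomputed \linkS4class{NeighborGraph} over the
#'   layout (in layout label order)
#' @param windowS epoch length, seconds
#' @param absThresholdUv,stepThresholdUv artifact thresholds (microvolts)
#' @param channelFrac,segmentFrac rule thresholds (strict fractions)
#' @return a \linkS4class{CleanEpochSet}
#' @export
preprocessRecording <- function(recording, layout = buildDefaultLayout(),
                                graph = NULL, windowS = 2,
                                absThresholdUv = 100, stepThresholdUv = 50,
                                channelFrac = 0.40, segmentFrac = 0.10) {
  rr <- rereferenceAverage(recording, layout)
  ep <- segmentEpochs(rr, windowS)
  mask <- detectArtifacts(ep, absThresholdUv, stepThresholdUv)
  if (is.null(graph)) graph <- nearestNeighbors(layout, 4)
  # graph rows follow layout order; remap to epoch channel order
  remap <- match(ep@channels, graph@labels)
  if (anyNA(remap))
    stopLabeled("preprocess", "graph does not cover all channels")
  g2 <- new("NeighborGraph", labels = ep@channels,
            neighbors = matrix(match(graph@labels[graph@neighbors[remap, ]],
                                     ep@channels),
                               nrow = length(remap)),
            distances = graph@distances[remap, , drop = FALSE])
  if (anyNA(g2@neighbors))
    stopLabeled("preprocess", "neighbor graph references channels missing ",
                "from the recording")
  cr <- applyChannelRule(ep, mask, g2, channelFrac)
  applySegmentRule(cr$epochs, cr$mask, segmentFrac, cr$interpolated)
}

#' Remove the least-squares EOG projection from every channel
#'
#' A regression-based stand-in for ocular artifact correction: each channel
#' has its projection onto the EOG reference removed.
#'
#' @param recording a \linkS4class{RawRecording}
#' @param eog numeric vector (length = samples) or the label of a channel in
#'   the recording to use as the EOG reference
#' @return corrected \linkS4class{RawRecording}
#' @export
eogRegress <- function(recording, eog) {
  if (is.character(eog)) {
    idx <- match(eog, recording@channels)
    if (is.na(idx)) stopLabeled("eog", "no channel named ", eog)
    eog <- recording@samples[idx, ]
  }
  if (length(eog) != ncol(recording@samples))
    stopLabeled("eog", "EOG length must match the recording")
  ss <- sum(eog^2)
  if (ss < 1e-20) stopLabeled("eog", "EOG reference has zero variance")
  beta <- recording@samples %*% eog / ss
  out <- recording
  out@samples <- recording@samples - tcrossprod(drop(beta), eog)
  rownames(out@samples) <- out@channels
  out
}
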