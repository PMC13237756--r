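# Shared fixtures, built in code.

# A recording holding a given channels x samples matrix.
makeRecording <- function(samples, channels = paste0("ch", seq_len(nrow(samples))),
                          srate = 500, id = "T01", condition = "closed") {
  rownames(samples) <- channels
  new("RawRecording", id = id, condition = condition, channels = channels,
      samples = samples, srate = srate)
}

# An EpochSet from a channels x samples x epochs array.
makeEpochSet <- function(arr, channels = paste0("ch", seq_len(dim(arr)[1])),
                         srate = 500, id = "T01", condition = "closed") {
  new("EpochSet", id = id, condition = condition, channels = channels,
      epochs = arr, srate = srate)
}

# A CleanEpochSet wrapping all epochs of an array (no rejection applied).
makeCleanSet <- function(arr, channels = paste0("ch", seq_len(dim(arr)[1])),
                         srate = 500, id = "T01", condition = "closed") {
  new("CleanEpochSet", id = id, condition = condition, channels = channels,
      epochs = arr, srate = srate, interpolated = character(0),
      dropped = integer(0), retainedSeconds = dim(arr)[2] / srate * dim(arr)[3])
}

# Single-channel clean set from a vector, cut into 2-s epochs.
cleanFromSignal <- function(x, srate = 500, channel = "Cz") {
  rec <- makeRecording(matrix(x, 1), channels = channel, srate = srate)
  ep <- segmentEpochs(rec, 2)
  makeCleanSet(ep@epochs, channels = channel, srate = srate)
}

# Small symmetric test layout: vertex plus 4 equidistant neighbors plus a
# spread of outer electrodes; includes FCz so waveform generation works.
smallLayout <- function() {
  electrodeLayout(
    labels = c("Cz", "N1", "N2", "N3", "N4", "FCz", "P7x", "P8x", "Fpx"),
    theta = c(0, 30, 30, 30, 30, 45, 90, 90, 72),
    phi = c(0, 0, 90, 180, -90, 90, -150, -30, 90))
}

# Minimal long table for design/model tests, built from a tiny cohort.
smallAlphaTable <- function(nA = 3, nN = 3, seed = 99, sigmaNoise = 0.3,
                            sigmaParticipant = 0.3) {
  p <- genParams(sigmaNoise = sigmaNoise,
                 sigmaParticipant = sigmaParticipant, seed = seed)
  cohort <- generateCohort(nA, nN, p)
  generateAlphaTable(cohort, buildDefaultLayout(), p)
}
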