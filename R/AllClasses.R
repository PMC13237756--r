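#' @import methods
NULL

#' ElectrodeLayout: scalp montage with spherical and Cartesian coordinates
#'
#' Electrode positions on the unit sphere. Spherical angles follow the
#' convention: \code{theta} is the polar angle in degrees measured from the
#' superior (vertex) axis, \code{phi} the azimuth in degrees measured from the
#' right-lateral axis toward the anterior axis. Derived Cartesian axes are
#' ML (medial-lateral, +right), AP (anterior-posterior, +anterior) and
#' IS (inferior-superior, +superior); they are the continuous spatial
#' covariates used by the mixed models.
#'
#' @slot labels character, unique channel names
#' @slot theta numeric, polar angle per electrode (degrees, 0 = vertex)
#' @slot phi numeric, azimuth per electrode (degrees, 0 = right ear,
#'   90 = nasion)
#' @slot coords numeric matrix (n x 3, columns ml/ap/is) on the unit sphere
#' @export
setClass("ElectrodeLayout",
  representation(labels = "character", theta = "numeric", phi = "numeric",
                 coords = "matrix"),
  validity = function(object) {
    n <- length(object@labels)
    if (anyDuplicated(object@labels)) return("electrode labels must be unique")
    if (length(object@theta) != n || length(object@phi) != n)
      return("theta/phi length must match labels")
    if (!is.numeric(object@coords) || nrow(object@coords) != n ||
        ncol(object@coords) != 3)
      return("coords must be an n x 3 numeric matrix")
    norms <- rowSums(object@coords^2)
    if (any(abs(norms - 1) > 1e-12))
      return("Cartesian coordinates must lie on the unit sphere (|r|=1)")
    TRUE
  })

#' NeighborGraph: k-nearest-neighbor relations on a montage
#'
#' For each electrode, the indices and great-circle (angular, radians)
#' distances of its k nearest neighbors, sorted by ascending distance.
#' Supports Hjorth Laplacian channel interpolation.
#'
#' @slot labels character, electrode labels (same order as the layout)
#' @slot neighbors integer matrix (n x k) of neighbor indices
#' @slot distances numeric matrix (n x k) of angular distances, radians
#' @export
setClass("NeighborGraph",
  representation(labels = "character", neighbors = "matrix",
                 distances = "matrix"),
  validity = function(object) {
    n <- length(object@labels)
    if (nrow(object@neighbors) != n || nrow(object@distances) != n)
      return("neighbor matrices must have one row per electrode")
    if (!identical(dim(object@neighbors), dim(object@distances)))
      return("neighbors and distances must have identical dimensions")
    if (any(object@neighbors == seq_len(n)))
      return("neighbor lists must exclude self")
    if (any(object@distances < 0)) return("distances must be nonnegative")
    if (ncol(object@distances) > 1 &&
        any(apply(object@distances, 1, is.unsorted)))
      return("distances must be sorted ascending within each row")
    TRUE
  })

#' RawRecording: one multichannel resting-state EEG acquisition
#'
#' The unit of acquisition: one participant under one eye condition.
#' Samples are microvolts, channels x time.
#'
#' @slot id character participant id
#' @slot condition "open" or "closed"
#' @slot channels character channel labels (rows of \code{samples})
#' @slot samples numeric matrix, channels x time, microvolts
#' @slot srate sampling rate, Hz
#' @export
setClass("RawRecording",
  representation(id = "character", condition = "character",
                 channels = "character", samples = "matrix",
                 srate = "numeric"),
  validity = function(object) {
    if (!object@condition %in% c("open", "closed"))
      return("condition must be 'open' or 'closed'")
    if (nrow(object@samples) != length(object@channels))
      return("samples must have one row per channel")
    if (length(object@srate) != 1 || object@srate <= 0)
      return("srate must be a single positive number")
    if (anyDuplicated(object@channels))
      return("channel labels must be unique")
    TRUE
  })

#' EpochSet: fixed-length segments cut from a recording
#'
#' @slot id participant id
#' @slot condition eye condition
#' @slot channels channel labels
#' @slot epochs numeric array, channels x samples-per-epoch x epochs
#' @slot srate sampling rate, Hz
#' @export
setClass("EpochSet",
  representation(id = "character", condition = "character",
                 channels = "character", epochs = "array",
                 srate = "numeric"),
  validity = function(object) {
    d <- dim(object@epochs)
    if (length(d) != 3) return("epochs must be a 3-d array")
    if (d[1] != length(object@channels))
      return("epoch array must have one row per channel")
    TRUE
  })

#' ArtifactMask: per (channel, epoch) artifact flags
#'
#' @slot flags logical matrix, channels x epochs
#' @export
setClass("ArtifactMask",
  representation(flags = "matrix"),
  validity = function(object) {
    if (!is.logical(object@flags)) return("flags must be logical")
    TRUE
  })

#' CleanEpochSet: artifact-managed epochs with provenance
#'
#' Retained 2-s epochs after channel interpolation (40% rule) and segment
#' rejection (10% rule), with a record of what was altered or dropped.
#'
#' @slot id participant id
#' @slot condition eye condition
#' @slot channels channel labels
#' @slot epochs retained epochs, channels x samples x retained-count
#' @slot srate sampling rate, Hz
#' @slot interpolated labels of Hjorth-interpolated channels
#' @slot dropped integer indices (in the original set) of dropped epochs
#' @slot retainedSeconds seconds of retained data
#' @export
setClass("CleanEpochSet",
  representation(id = "character", condition = "character",
                 channels = "character", epochs = "array", srate = "numeric",
                 interpolated = "character", dropped = "integer",
                 retainedSeconds = "numeric"),
  validity = function(object) {
    d <- dim(object@epochs)
    if (length(d) != 3) return("epochs must be a 3-d array")
    winS <- d[2] / object@srate
    if (abs(object@retainedSeconds - winS * d[3]) > 1e-9)
      return("retainedSeconds must equal window length x retained count")
    if (length(object@dropped) &&
        any(object@dropped < 1))
      return("dropped indices must be positive")
    TRUE
  })

#' PowerSpectrum: epoch-averaged one-sided power spectra per channel
#'
#' Normalized so that, under a rectangular taper, the one-sided power summed
#' over non-DC bins equals the time-domain (population) variance of the
#' demeaned epoch; taper power loss is compensated by the taper mean square.
#'
#' @slot freqs frequency grid, Hz (spacing = 1/window length)
#' @slot power numeric matrix, bins x channels, microvolts squared.
#'   When \code{epochAverage = "log-power"} was used this holds the geometric
#'   mean across epochs.
#' @slot channels channel labels
#' @slot nEpochs number of epochs averaged
#' @slot epochAverage "power" (arithmetic mean) or "log-power" (geometric)
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "matrix", channels = "character",
                 nEpochs = "integer", epochAverage = "character"),
  validity = function(object) {
    if (nrow(object@power) != length(object@freqs))
      return("power must have one row per frequency bin")
    if (ncol(object@power) != length(object@channels))
      return("power must have one column per channel")
    if (any(object@power < 0)) return("power must be nonnegative")
    TRUE
  })

#' GenParams: generative parameters for the synthetic cohort
#'
#' Coefficients are on the log10 alpha-power scale and mirror the structure
#' the mixed models estimate: a sleep-by-group interaction, an eye-condition
#' shift, linear spatial gradients along the ML/AP/IS electrode axes, a
#' participant random intercept, and observation noise. Waveform mode adds a
#' 1/f background and sporadic high-amplitude artifacts.
#'
#' @slot beta0 baseline log10 alpha power (abstinent, sleep 0, eyes closed,
#'   electrode at the coordinate origin)
#' @slot betaGroup shift for the non-abstinent group
#' @slot betaSleep slope of log alpha power in sleep quality (abstinent)
#' @slot betaSleepGroup sleep x group interaction (added slope, non-abstinent)
#' @slot betaEyes shift for eyes open
#' @slot gammaML,gammaAP,gammaIS spatial gradients along the Cartesian axes
#' @slot extraCoefs named numeric, optional higher-order coefficients; names
#'   are ":"-joined products of Sleep, Group, Eyes, ML, AP, IS
#' @slot sigmaParticipant SD of participant random intercepts
#' @slot sigmaNoise observation SD (tabular mode), log10 units
#' @slot artifactRate probability an artifact hits a given (channel, 2-s
#'   block) site in waveform mode
#' @slot artifactAmplitude artifact transient amplitude, microvolts
#' @slot alphaFreqs frequencies (Hz) of the alpha comb components
#' @slot backgroundRms RMS amplitude of the 1/f background, microvolts
#' @slot sleepMean,sleepSD location/scale of the discretized sleep-quality
#'   distribution (same in both groups)
#' @slot seed master seed for all generator randomness
#' @export
setClass("GenParams",
  representation(beta0 = "numeric", betaGroup = "numeric",
                 betaSleep = "numeric", betaSleepGroup = "numeric",
                 betaEyes = "numeric", gammaML = "numeric",
                 gammaAP = "numeric", gammaIS = "numeric",
                 extraCoefs = "numeric", sigmaParticipant = "numeric",
                 sigmaNoise = "numeric", artifactRate = "numeric",
                 artifactAmplitude = "numeric", alphaFreqs = "numeric",
                 backgroundRms = "numeric", sleepMean = "numeric",
                 sleepSD = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@sigmaParticipant < 0 || object@sigmaNoise < 0)
      return("standard deviations must be nonnegative")
    if (object@artifactRate < 0 || object@artifactRate > 1)
      return("artifactRate must lie in [0, 1]")
    if (length(object@extraCoefs) && is.null(names(object@extraCoefs)))
      return("extraCoefs must be named")
    TRUE
  })

#' PosteriorDraws: MCMC draws from the Gibbs sampler
#'
#' Post-warmup draws, one slice per chain. Parameters are the fixed effects
#' (named by design column), the random-intercept SD \code{sigma_u}, the
#' residual SD \code{sigma}, and the participant intercepts \code{u[...]}.
#'
#' @slot draws numeric array, iterations x chains x parameters (dimnames on
#'   the parameter axis)
#' @slot fixedNames names of the fixed-effect parameters
#' @slot warmup warmup iterations discarded per chain
#' @slot seed master seed used
#' @export
setClass("PosteriorDraws",
  representation(draws = "array", fixedNames = "character",
                 warmup = "integer", seed = "integer"),
  validity = function(object) {
    d <- dim(object@draws)
    if (length(d) != 3) return("draws must be iterations x chains x params")
    pn <- dimnames(object@draws)[[3]]
    if (is.null(pn)) return("draws must carry parameter names")
    if (!all(object@fixedNames %in% pn))
      return("fixedNames must be a subset of parameter names")
    sd_ok <- TRUE
    for (s in intersect(c("sigma", "sigma_u"), pn))
      if (any(object@draws[, , s] < 0)) sd_ok <- FALSE
    if (!sd_ok) return("SD draws must be nonnegative")
    TRUE
  })

setMethod("show", "ElectrodeLayout", function(object) {
  cat("ElectrodeLayout with", length(object@labels), "electrodes\n")
  cat("  labels:", paste(utils::head(object@labels, 6), collapse = ", "),
      if (length(object@labels) > 6) "..." else "", "\n")
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@id, object@condition, nrow(object@samples),
              ncol(object@samples), object@srate,
              ncol(object@samples) / object@srate))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet %s [%s]: %d epochs x %d channels x %d samples\n",
              object@id, object@condition, d[3], d[1], d[2]))
})

setMethod("show", "CleanEpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "CleanEpochSet %s [%s]: %d epochs retained (%.0f s), %d dropped, %d channel(s) interpolated\n",
    object@id, object@condition, d[3], object@retainedSeconds,
    length(object@dropped), length(object@interpolated)))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins (%.2g-%.2g Hz) x %d channels, %d epoch(s) averaged [%s]\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              length(object@channels), object@nEpochs, object@epochAverage))
})

setMethod("show", "PosteriorDraws", function(object) {
  d <- dim(object@draws)
  cat(sprintf("PosteriorDraws: %d chains x %d kept iterations, %d parameters (%d fixed effects)\n",
              d[2], d[1], d[3], length(object@fixedNames)))
})

# ---- accessors ----

#' @describeIn ElectrodeLayout-class electrode labels
#' @param layout an ElectrodeLayout
#' @export
electrodeLabels <- function(layout) layout@labels

#' Cartesian electrode coordinates
#'
#' @param layout an ElectrodeLayout
#' @return n x 3 matrix with columns ml, ap, is
#' @export
cartesianCoords <- function(layout) layout@coords

#' Spherical electrode angles (degrees)
#'
#' @param layout an ElectrodeLayout
#' @return data.frame with label, theta_deg, phi_deg
#' @export
sphericalAngles <- function(layout)
  data.frame(label = layout@labels, theta_deg = layout@theta,
             phi_deg = layout@phi)

#' @rdname RawRecording-class
#' @param x a RawRecording or EpochSet-like object
#' @export
channelLabels <- function(x) x@channels

#' @rdname RawRecording-class
#' @export
sampleRate <- function(x) x@srate

#' @rdname RawRecording-class
#' @export
recordingSamples <- function(x) x@samples

#' @rdname EpochSet-class
#' @param x an EpochSet or CleanEpochSet
#' @export
epochArray <- function(x) x@epochs

#' @rdname EpochSet-class
#' @export
nEpochs <- function(x) dim(x@epochs)[3]

#' @rdname CleanEpochSet-class
#' @param x a CleanEpochSet
#' @export
interpolatedChannels <- function(x) x@interpolated

#' @rdname CleanEpochSet-class
#' @export
droppedEpochs <- function(x) x@dropped

#' @rdname CleanEpochSet-class
#' @export
retainedSeconds <- function(x) x@retainedSeconds

#' @rdname ArtifactMask-class
#' @param mask an ArtifactMask
#' @export
artifactFlags <- function(mask) mask@flags

#' Fraction of epochs flagged bad, per channel
#' @param mask an ArtifactMask
#' @export
channelBadFraction <- function(mask) rowMeans(mask@flags)

#' Fraction of sensors flagged bad, per epoch
#' @param mask an ArtifactMask
#' @export
epochBadFraction <- function(mask) colMeans(mask@flags)

#' @rdname PosteriorDraws-class
#' @param x a PosteriorDraws
#' @export
posteriorArray <- function(x) x@draws

#' @rdname PosteriorDraws-class
#' @export
fixedEffectNames <- function(x) x@fixedNames

#' Draws of one parameter, pooled across chains
#' @param x a PosteriorDraws
#' @param parameter parameter name
#' @export
parameterDraws <- function(x, parameter) {
  pn <- dimnames(x@draws)[[3]]
  if (!parameter %in% pn)
    stop("unknown parameter: ", parameter, call. = FALSE)
  as.vector(x@draws[, , parameter])
}
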