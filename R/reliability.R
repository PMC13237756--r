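# Split-half internal consistency of alpha power: the retained epochs are
# split by original temporal order into a first and a second half, band
# power computed per half, and Pearson r taken across participants per
# electrode x condition.

#' Split-half log alpha power for one clean epoch set
#'
#' Retained epochs are partitioned by temporal order into the first
#' ceiling(m/2) and the last floor(m/2); log alpha band power is computed
#' independently for each half.
#'
#' @param clean a \linkS4class{CleanEpochSet} with >= 2 retained epochs
#' @param taperFraction,band,epochAverage,floorEps spectral settings (see
#'   \code{\link{measureAlphaPower}})
#' @return list(first, second): named numeric vectors per channel
#' @export
splitHalfPower <- function(clean, taperFraction = 0.10, band = c(8, 13),
                           epochAverage = "power", floorEps = NULL) {
  m <- dim(clean@epochs)[3]
  if (m < 2)
    stopLabeled("split-half", "need >= 2 retained epochs, have ", m)
  nFirst <- ceiling(m / 2)
  takeHalf <- function(idx) {
    h <- clean
    h@epochs <- clean@epochs[, , idx, drop = FALSE]
    h@retainedSeconds <- clean@retainedSeconds * length(idx) / m
    h@dropped <- integer(0)
    h
  }
  list(first = measureAlphaPower(takeHalf(seq_len(nFirst)), taperFraction,
                                 band, epochAverage, floorEps),
       second = measureAlphaPower(takeHalf((nFirst + 1):m), taperFraction,
                                  band, epochAverage, floorEps))
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y numeric vectors across participants, length >= 3, nonzero
#'   variance
#' @return correlation coefficient in [-1, 1]
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stopLabeled("pearson", "x and y must have equal length")
  if (length(x) < 3)
    stopLabeled("pearson", "need n >= 3, have ", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopLabeled("pearson", "zero variance in one of the arguments")
  stats::cor(x, y)
}

#' Split-half reliability report across a cohort
#'
#' For each electrode x condition, the Pearson correlation across
#' participants between first-half and second-half log alpha power, with a
#' below-threshold consistency flag (default threshold r = 0.7).
#'
#' @param halves long data.frame with columns participant, condition,
#'   electrode, first, second (one row per participant x condition x
#'   electrode, e.g. accumulated from \code{\link{splitHalfPower}})
#' @param threshold flag electrodes with r below this value
#' @return data.frame: electrode, condition, r, flagged
#' @export
reliabilityReport <- function(halves, threshold = 0.7) {
  need <- c("participant", "condition", "electrode", "first", "second")
  if (!all(need %in% names(halves)))
    stopLabeled("reliability", "halves must have columns: ",
                paste(need, collapse = ", "))
  if (length(unique(halves$participant)) < 3)
    stopLabeled("reliability", "need >= 3 participants")
  cells <- unique(halves[, c("electrode", "condition")])
  cells <- cells[order(cells$condition, cells$electrode), ]
  r <- mapply(function(el, cond) {
    sub <- halves[halves$electrode == el & halves$condition == cond, ]
    pearsonR(sub$first, sub$second)
  }, cells$electrode, cells$condition)
  out <- data.frame(electrode = cells$electrode,
                    condition = cells$condition,
                    r = as.numeric(r),
                    flagged = as.numeric(r) < threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a reliability report as TSV
#'
#' @param report data.frame from \code{\link{reliabilityReport}}
#' @param path file path
#' @export
writeReliabilityReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
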