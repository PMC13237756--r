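test_that("average re-referencing recovers the reference and zeroes the mean", {
  lay <- buildDefaultLayout()
  chans <- setdiff(electrodeLabels(lay), "FCz")
  set.seed(1)
  rec <- makeRecording(matrix(rnorm(64 * 100), 64), channels = chans)
  rr <- rereferenceAverage(rec, lay)
  expect_length(channelLabels(rr), 65)
  expect_true("FCz" %in% channelLabels(rr))
  expect_lt(max(abs(colMeans(recordingSamples(rr)))), 1e-10)
  # idempotent
  rr2 <- rereferenceAverage(rr, lay)
  expect_equal(recordingSamples(rr2), recordingSamples(rr),
               tolerance = 1e-10)
  # identical signals on all channels cancel to zero
  same <- makeRecording(matrix(rep(sin(1:100), 65), 65, byrow = TRUE),
                        channels = electrodeLabels(lay))
  expect_lt(max(abs(recordingSamples(rereferenceAverage(same, lay)))), 1e-12)
  # unknown labels are rejected
  badRec <- makeRecording(matrix(0, 2, 10), channels = c("Cz", "Nope"))
  expect_error(rereferenceAverage(badRec, lay), "Nope")
})

test_that("segmentation cuts non-overlapping 2-s windows and drops remainders", {
  rec <- makeRecording(matrix(seq_len(45000), 1), srate = 500)
  ep <- segmentEpochs(rec, 2)
  expect_equal(dim(epochArray(ep)), c(1, 1000, 45))
  # windows are contiguous and ordered
  expect_equal(epochArray(ep)[1, , 2], 1001:2000)
  rec91 <- makeRecording(matrix(rnorm(45500), 1), srate = 500)
  expect_equal(nEpochs(segmentEpochs(rec91, 2)), 45)
  short <- makeRecording(matrix(rnorm(500), 1), srate = 500)
  expect_error(segmentEpochs(short, 2), "shorter")
})

test_that("artifact detection flags amplitude and step exceedances per cell", {
  arr <- array(0, c(5, 1000, 10))
  ep <- makeEpochSet(arr)
  expect_false(any(artifactFlags(detectArtifacts(ep))))
  # one 150 uV sample at (channel 3, epoch 7) flags exactly that cell
  arr2 <- arr
  arr2[3, 500, 7] <- 150
  m <- detectArtifacts(makeEpochSet(arr2))
  expect_true(artifactFlags(m)[3, 7])
  expect_equal(sum(artifactFlags(m)), 1)
  # a 60 uV step with amplitude below 100 uV trips only the step criterion
  arr3 <- arr
  arr3[1, 500:1000, 2] <- 60
  m3 <- detectArtifacts(makeEpochSet(arr3))
  expect_true(artifactFlags(m3)[1, 2])
  expect_false(artifactFlags(detectArtifacts(makeEpochSet(arr3),
                                             stepThresholdUv = 70))[1, 2])
  # bad fractions are recomputable counts
  arr4 <- arr
  arr4[2, 1, c(1, 3, 5, 7, 9)] <- 200
  m4 <- detectArtifacts(makeEpochSet(arr4))
  expect_equal(channelBadFraction(m4)[[2]], 0.5)
})

test_that("channel rule interpolates strictly above 40% and clears flags", {
  lay <- smallLayout()
  g <- nearestNeighbors(lay, 4)
  n <- length(electrodeLabels(lay))
  mk <- function(badEpochs) {
    arr <- array(rep(seq_len(n), 1000 * 100), c(n, 1000, 100))
    arr[match("N1", electrodeLabels(lay)), 1, badEpochs] <- 500
    makeEpochSet(arr, channels = electrodeLabels(lay))
  }
  # 41 of 100 epochs bad -> interpolated, flags cleared
  ep41 <- mk(1:41)
  m41 <- detectArtifacts(ep41)
  out41 <- applyChannelRule(ep41, m41, g)
  expect_equal(out41$interpolated, "N1")
  expect_false(any(artifactFlags(out41$mask)))
  # exactly 40% -> untouched
  ep40 <- mk(1:40)
  m40 <- detectArtifacts(ep40)
  out40 <- applyChannelRule(ep40, m40, g)
  expect_length(out40$interpolated, 0)
  expect_identical(epochArray(out40$epochs), epochArray(ep40))
  # no flags -> identity
  clean <- mk(integer(0))
  outC <- applyChannelRule(clean, detectArtifacts(clean), g)
  expect_identical(epochArray(outC$epochs), epochArray(clean))
  # non-target channels never change
  other <- setdiff(seq_len(n), match("N1", electrodeLabels(lay)))
  expect_identical(epochArray(out41$epochs)[other, , ],
                   epochArray(ep41)[other, , ])
})

test_that("segment rule drops epochs strictly above 10% bad sensors", {
  flags <- matrix(FALSE, 65, 45)
  flags[1:7, 10] <- TRUE     # 7/65 = 10.8% -> dropped
  flags[1:6, 20] <- TRUE     # 6/65 = 9.2% -> retained
  arr <- array(rnorm(65 * 1000 * 45), c(65, 1000, 45))
  ep <- makeEpochSet(arr, channels = electrodeLabels(buildDefaultLayout()))
  clean <- applySegmentRule(ep, new("ArtifactMask", flags = flags))
  expect_equal(droppedEpochs(clean), 10L)
  expect_equal(nEpochs(clean), 44)
  expect_equal(retainedSeconds(clean), 88)
  # retained epochs keep their samples untouched
  expect_identical(epochArray(clean)[, , 19], arr[, , 20])
  # clean input retains everything
  all0 <- applySegmentRule(ep, new("ArtifactMask",
                                   flags = matrix(FALSE, 65, 45)))
  expect_equal(nEpochs(all0), 45)
  expect_equal(retainedSeconds(all0), 90)
  # all epochs bad is unrecoverable
  expect_error(applySegmentRule(ep, new("ArtifactMask",
                                        flags = matrix(TRUE, 65, 45))),
               "all epochs")
})

test_that("Hjorth interpolation is a normalized inverse-distance mean", {
  lay <- smallLayout()
  g <- nearestNeighbors(lay, 4)
  n <- length(electrodeLabels(lay))
  iCz <- match("Cz", electrodeLabels(lay))
  # constant neighbors reproduce the constant
  epoch <- matrix(rep(3.5, n * 10), n)
  expect_equal(hjorthInterpolate(epoch, iCz, g), rep(3.5, 10))
  # a field linear in ML is exact at the vertex (symmetric neighbor set)
  co <- cartesianCoords(lay)
  field <- matrix(rep(2 * co[, "ml"] + 0.3, 5), n)
  est <- hjorthInterpolate(field, iCz, g)
  expect_lt(max(abs(est - (2 * co[iCz, "ml"] + 0.3))), 1e-9)
  # flagged neighbors are excluded; a single usable neighbor is copied
  flagged <- rep(TRUE, n)
  keep <- g@neighbors[iCz, 2]
  flagged[keep] <- FALSE
  vals <- matrix(seq_len(n * 3), n)
  expect_equal(hjorthInterpolate(vals, iCz, g, flagged), vals[keep, ])
  expect_error(hjorthInterpolate(vals, iCz, g, rep(TRUE, n)), "no usable")
})

test_that("EOG regression removes the projection and nothing else", {
  set.seed(9)
  eog <- rnorm(200)
  ortho <- rnorm(200)
  ortho <- ortho - sum(ortho * eog) / sum(eog^2) * eog
  rec <- makeRecording(rbind(2 * eog, ortho, eog + 0.5 * ortho),
                       channels = c("a", "b", "c"), srate = 100)
  out <- eogRegress(rec, eog)
  expect_lt(max(abs(recordingSamples(out)[1, ])), 1e-10)
  expect_equal(recordingSamples(out)[2, ], unname(ortho), tolerance = 1e-10)
  # hand-computed 3-sample least squares: y = (1,2,3), e = (1,0,1)
  rec3 <- makeRecording(matrix(c(1, 2, 3), 1), srate = 3)
  out3 <- eogRegress(rec3, c(1, 0, 1))
  expect_equal(recordingSamples(out3)[1, ], c(1, 2, 3) - 2 * c(1, 0, 1))
  expect_error(eogRegress(rec3, c(0, 0, 0)), "zero variance")
})

test_that("artifact-free input survives the full chain intact", {
  lay <- smallLayout()
  p0 <- genParams(backgroundRms = 2, artifactRate = 0, sigmaParticipant = 0)
  coh <- generateCohort(1, 1, p0)
  rec <- generateRecording(coh[1, ], "closed", lay, p0, durationS = 20)
  clean <- preprocessRecording(rec, lay, nearestNeighbors(lay, 4))
  expect_equal(nEpochs(clean), 10)
  expect_length(droppedEpochs(clean), 0)
  expect_length(interpolatedChannels(clean), 0)
  expect_equal(retainedSeconds(clean), 20)
})
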