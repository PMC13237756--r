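test_that("split-cosine-bell taper has the stated shape", {
  x <- rnorm(1000)
  expect_identical(applyTaper(x, 0), x)
  for (f in c(0.1, 0.5, 1)) {
    w <- taperWindow(1000, f)
    expect_equal(w[1], 0)
    expect_equal(w[1000], 0)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(w, rev(w))
  }
  # full fraction is a Hanning window
  n <- 64
  expect_equal(taperWindow(n, 1),
               0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
               tolerance = 1e-12)
  # 10% taper leaves the middle 90% flat
  w10 <- taperWindow(1000, 0.10)
  expect_true(all(w10[51:950] == 1))
  expect_error(taperWindow(100, 1.2), "taperFraction")
})

test_that("periodogram satisfies the sine and Parseval oracles", {
  sr <- 500
  t <- (0:(45 * 1000 - 1)) / sr
  clean <- cleanFromSignal(sin(2 * pi * 10 * t), sr)
  sp <- periodogram(clean, 0)
  expect_equal(sp@freqs[2] - sp@freqs[1], 0.5)
  expect_equal(unname(sp@power[sp@freqs == 10, 1]), 0.5, tolerance = 1e-6)
  expect_lt(sum(sp@power[sp@freqs != 10, 1]), 1e-6)
  # Parseval on white noise, rectangular taper
  set.seed(4)
  wn <- rnorm(2000, sd = 3)
  spw <- periodogram(cleanFromSignal(wn, sr), 0)
  v <- mean((wn[1:1000] - mean(wn[1:1000]))^2) / 2 +
    mean((wn[1001:2000] - mean(wn[1001:2000]))^2) / 2
  expect_equal(sum(spw@power), v, tolerance = 1e-8)
  # constant signal has no power anywhere off DC
  spc <- periodogram(cleanFromSignal(rep(5, 1000), sr), 0)
  expect_lt(max(spc@power), 1e-20)
  expect_error(periodogram(makeCleanSet(array(0, c(1, 1000, 0)))),
               "retained")
})

test_that("band power is log-then-mean over 11 inclusive bins", {
  sr <- 500
  mkSpec <- function(powerVec) {
    new("PowerSpectrum", freqs = seq(0.5, 250, by = 0.5),
        power = matrix(rep(powerVec, length.out = 500), ncol = 1),
        channels = "Cz", nEpochs = 1L, epochAverage = "power")
  }
  expect_equal(sum(mkSpec(1)@freqs >= 8 & mkSpec(1)@freqs <= 13), 11)
  expect_equal(unname(alphaBandPower(mkSpec(1))), 0)
  expect_equal(unname(alphaBandPower(mkSpec(10))), 1)
  # two-bin toy spectrum fixes the log-then-average order:
  # mean(log10(10), log10(1000)) = 2, not log10(mean) = 2.70
  sp2 <- new("PowerSpectrum", freqs = c(9, 10),
             power = matrix(c(10, 1000), ncol = 1), channels = "Cz",
             nEpochs = 1L, epochAverage = "power")
  expect_equal(unname(alphaBandPower(sp2, band = c(9, 10))), 2)
  # zero bins error unless floored
  spz <- mkSpec(c(rep(1, 16), 0, rep(1, 483)))
  expect_error(alphaBandPower(spz), "floorEps")
  expect_equal(unname(alphaBandPower(spz, floorEps = 1e-20)),
               -20 / 11, tolerance = 1e-12)
  expect_error(alphaBandPower(mkSpec(1), band = c(200, 300)), "range")
})

test_that("band power is taper-invariant within 2% and scales with amplitude", {
  sr <- 500
  t <- (0:(45 * 1000 - 1)) / sr
  x <- sin(2 * pi * 10 * t)
  clean <- cleanFromSignal(x, sr)
  band0 <- sum(periodogram(clean, 0)@power[periodogram(clean, 0)@freqs >= 8 &
                                             periodogram(clean, 0)@freqs <= 13, 1])
  for (f in c(0.05, 0.1, 0.2)) {
    sp <- periodogram(clean, f)
    mass <- sum(sp@power[sp@freqs >= 8 & sp@freqs <= 13, 1])
    expect_lt(abs(mass - band0) / band0, 0.02)
  }
  # doubling amplitude raises log power by exactly log10(4)
  p1 <- alphaBandPower(periodogram(clean, 0), floorEps = 1e-300)
  p2 <- alphaBandPower(periodogram(cleanFromSignal(2 * x, sr), 0),
                       floorEps = 1e-300)
  expect_equal(unname(p2 - p1), log10(4), tolerance = 1e-9)
})

test_that("epoch averaging order flag switches arithmetic/geometric means", {
  # two epochs with bin powers p and 4p: arithmetic mean 2.5p,
  # geometric mean 2p
  sr <- 500
  t <- (0:999) / sr
  x <- c(sin(2 * pi * 10 * t), 2 * sin(2 * pi * 10 * t))
  clean <- cleanFromSignal(x, sr)
  ar <- periodogram(clean, 0, "power")
  ge <- periodogram(clean, 0, "log-power")
  expect_equal(unname(ar@power[ar@freqs == 10, 1]), 2.5 * 0.5,
               tolerance = 1e-9)
  expect_equal(unname(ge@power[ge@freqs == 10, 1]), 2 * 0.5,
               tolerance = 1e-9)
})

test_that("long-table assembly validates, orders and counts rows", {
  lay <- buildDefaultLayout()
  labs <- electrodeLabels(lay)
  mkPower <- function(ids) {
    do.call(rbind, lapply(ids, function(id)
      expand.grid(participant = id, condition = c("open", "closed"),
                  electrode = labs, log_alpha_power = 0.5,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  }
  cov <- data.frame(id = c("P01", "P02"), group = c("abstinent",
                                                    "non_abstinent"),
                    sleep_quality = c(6, 4), days_since_use = c(40, 2))
  tab <- buildLongTable(mkPower(c("P01", "P02")), cov, lay)
  expect_equal(nrow(tab), 260)
  expect_equal(sum(tab$participant == "P01"), 130)
  expect_false(is.unsorted(order(tab$participant, tab$condition,
                                 tab$electrode)))
  expect_equal(unname(tab$ml[tab$electrode == "Cz"]),
               rep(0, 4))
  # missing condition / covariates are labeled errors
  half <- mkPower("P01")
  half <- half[half$condition == "open", ]
  expect_error(buildLongTable(half, cov, lay), "missing a condition")
  expect_error(buildLongTable(mkPower("P03"), cov, lay), "P03")
  # TSV round trip preserves values
  path <- tempfile(fileext = ".tsv")
  writeAlphaTable(tab, path)
  back <- readAlphaTable(path)
  expect_equal(back$log_alpha_power, tab$log_alpha_power, tolerance = 1e-12)
  expect_equal(back$electrode, tab$electrode)
})
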