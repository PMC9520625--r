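test_that("signal generation is seed-deterministic and class-symmetric at zero separation", {
  p <- echoModelParams()
  a <- generateSignal(1, p, seed = 42)
  b <- generateSignal(1, p, seed = 42)
  expect_identical(a@amplitudes, b@amplitudes)
  expect_false(identical(a@amplitudes,
                         generateSignal(1, p, seed = 43)@amplitudes))

  p0 <- echoModelParams(separation = 0)
  intact <- generateSignal(1, p0, seed = 7)
  crack <- generateSignal(0, p0, seed = 7)
  expect_identical(intact@amplitudes, crack@amplitudes)
  expect_identical(crack@label, 0L)

  expect_error(generateSignal(2, p), "classLabel")
})

test_that("the noiseless intact spectrum peaks at the carrier frequency", {
  p <- echoModelParams(noiseSd = 0)
  rec <- generateSignal(1, p, seed = 3)
  kStar <- p@nSamples * p@carrierFreq / p@sampleRate
  k <- bruteDftArgmax(rec@amplitudes)
  expect_lte(abs(k - kStar), 1)

  ## the crack class peaks below the carrier (its shifted frequency falls
  ## off the bin grid and damping broadens the peak, hence the wider band)
  kc <- bruteDftArgmax(generateSignal(0, p, seed = 3)@amplitudes)
  kcStar <- p@nSamples * (p@carrierFreq - p@crackFreqShift) / p@sampleRate
  expect_lte(abs(kc - kcStar), 2)
  expect_lt(kc, kStar - 1)
})

test_that("crack-class energy is reduced in expectation", {
  p <- echoModelParams()
  energy <- function(rec) sum(rec@amplitudes^2)
  eI <- vapply(1:20, function(s) energy(generateSignal(1, p, s)), numeric(1))
  eC <- vapply(1:20, function(s) energy(generateSignal(0, p, s + 500)),
               numeric(1))
  expect_lt(mean(eC), mean(eI))
})

test_that("dataset generation is reproducible with the stated class layout", {
  ds <- generateDataset(296, 304, seed = 1)
  expect_length(ds, 600)
  labs <- vapply(ds, recordLabel, integer(1))
  expect_identical(sum(labs == 1L), 296L)
  expect_identical(labs[1:296], rep(1L, 296))

  ds2 <- generateDataset(296, 304, seed = 1)
  expect_identical(lapply(ds, amplitudes), lapply(ds2, amplitudes))

  expect_length(generateDataset(0, 0, seed = 1), 0)
})
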