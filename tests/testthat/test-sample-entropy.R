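test_that("sample entropy matches the brute-force pair-counting oracle", {
  ## perfectly regular series
  expect_identical(sampleEntropy(rep(1, 100)), 0)

  ## short periodic series, absolute tolerance
  x <- rep(c(1, 2, 3), 4)
  cfg <- sampEnConfig(embedDim = 2, rMode = "absolute", rValue = 0.1)
  expect_equal(sampleEntropy(x, cfg), bruteSampEn(x, 2L, 0.1))

  ## random series across embedding dimensions and tolerance rules
  set.seed(21)
  for (z in 1:3) {
    y <- rnorm(120)
    r <- 0.4
    cfgA <- sampEnConfig(embedDim = z, rMode = "absolute", rValue = r)
    expect_equal(sampleEntropy(y, cfgA), bruteSampEn(y, as.integer(z), r))
    cfgR <- sampEnConfig(embedDim = z)
    expect_equal(sampleEntropy(y, cfgR),
                 bruteSampEn(y, as.integer(z), 0.2 * sd(y)))
  }
})

test_that("white noise is more entropic than a sine; rescaling changes nothing", {
  n <- 0:449
  sine <- sin(2 * pi * 0.05 * n)
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(450)
    expect_gt(sampleEntropy(noise), sampleEntropy(sine))
  }
  set.seed(3)
  y <- rnorm(200)
  expect_equal(sampleEntropy(3.7 * y), sampleEntropy(y))
  expect_equal(sampleEntropy(-2 * y), sampleEntropy(y))
})

test_that("degenerate entropy cases: short series, no matches", {
  expect_error(sampleEntropy(c(1, 2, 3)), "short")
  ## steep ramp with a tiny absolute tolerance: no matches even at dim z
  ramp <- cumsum(rep(10, 50))
  expect_error(sampleEntropy(ramp, sampEnConfig(rMode = "absolute",
                                                rValue = 1e-6)),
               "undefined")
  ## z-matches exist but no (z+1)-matches: infinite sentinel with warning
  x <- c(0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0, 4)
  cfg <- sampEnConfig(embedDim = 2, rMode = "absolute", rValue = 0.5)
  expect_warning(v <- sampleEntropy(x, cfg), "Inf")
  expect_identical(v, Inf)
})

test_that("mean mode entropy aggregates per-mode values arithmetically", {
  x <- amplitudes(generateSignal(1, seed = 5))
  res <- vmdDecompose(x, vmdConfig(nModes = 3, maxIter = 60))
  cfg <- sampEnConfig()
  byHand <- mean(vapply(1:3, function(m)
    sampleEntropy(res@modes[m, ], cfg), numeric(1)))
  expect_equal(meanModeEntropy(res, cfg), byHand)

  ## single mode reduces to that mode's entropy
  r1 <- vmdDecompose(x, vmdConfig(nModes = 1, maxIter = 60))
  expect_equal(meanModeEntropy(r1, cfg), sampleEntropy(r1@modes[1, ], cfg))

  ## identical modes give the single-mode value
  rDup <- r1
  rDup@modes <- rbind(r1@modes, r1@modes)
  rDup@omegas <- c(r1@omegas, r1@omegas)
  expect_equal(meanModeEntropy(rDup, cfg),
               sampleEntropy(r1@modes[1, ], cfg))
})

test_that("mode-count selection is an argmin over candidate decompositions", {
  x <- amplitudes(generateSignal(1, seed = 1))
  tmpl <- vmdConfig(maxIter = 60)
  expect_identical(as.integer(selectM(x, tmpl,
                                      sampEnConfig(candidates = 3))), 3L)
  cfg <- sampEnConfig(candidates = c(2, 3, 4))
  m1 <- selectM(x, tmpl, cfg)
  m2 <- selectM(x, tmpl, cfg)
  expect_identical(as.integer(m1), as.integer(m2))
  ent <- attr(m1, "entropies")
  expect_identical(as.integer(m1), c(2L, 3L, 4L)[which.min(ent)])
})
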