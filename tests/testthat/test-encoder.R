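## a ModeMatrix with hand-chosen values for exact-geometry checks
handMatrix <- function() {
  S <- rbind(c(0.0, 0.5, 1.0, -1.0, 0.25),
             c(1.0, -0.5, 0.0, 0.5, -0.25),
             c(-1.0, 0.0, 0.5, 1.0, 0.75))
  new("ModeMatrix", S = S, sMax = max(S), sMin = min(S))
}

test_that("the mode matrix records the decomposition with true extrema", {
  x <- amplitudes(generateSignal(1, seed = 2))
  res <- vmdDecompose(x, vmdConfig(nModes = 3, maxIter = 60))
  mm <- buildModeMatrix(res)
  expect_identical(mm@S, res@modes)
  ## full-scan oracle
  expect_identical(mm@sMax, max(vapply(seq_len(nrow(mm@S)), function(i)
    max(mm@S[i, ]), numeric(1))))
  expect_identical(mm@sMin, min(mm@S))

  z <- vmdDecompose(rep(0, 100), vmdConfig(nModes = 2, maxIter = 5))
  zm <- buildModeMatrix(z)
  expect_identical(c(zm@sMax, zm@sMin), c(0, 0))
})

test_that("pixel mapping follows the affine geometry exactly", {
  mm <- handMatrix()
  cfg <- encoderConfig()
  co <- mapCoordinates(mm, cfg)
  expect_length(co, 5)
  ## x positions depend only on the mode index
  expect_identical(co[[1]][, "x"], c(288, 900, 1512))
  ## matrix maximum maps to the origin row, minimum to the top bound
  ys <- vapply(seq_len(5), function(l) co[[l]][, "y"], numeric(3))
  expect_identical(ys[cbind(which(mm@S == mm@sMax, arr.ind = TRUE))],
                   rep(1010, sum(mm@S == mm@sMax)))
  expect_identical(ys[cbind(which(mm@S == mm@sMin, arr.ind = TRUE))],
                   rep(190, sum(mm@S == mm@sMin)))

  ## single mode has no x mapping
  m1 <- new("ModeMatrix", S = mm@S[1, , drop = FALSE], sMax = 1, sMin = -1)
  expect_error(mapCoordinates(m1, cfg), "M = 1")

  ## flat matrix pins every vertex to the origin row
  flat <- new("ModeMatrix", S = matrix(2, 3, 4), sMax = 2, sMin = 2)
  coF <- mapCoordinates(flat, cfg)
  expect_true(all(vapply(coF, function(m) all(m[, "y"] == 1010),
                         logical(1))))
})

test_that("y is monotone in the matrix value and vertices stay in bounds", {
  cfg <- encoderConfig()
  set.seed(4)
  for (rep_ in 1:5) {
    S <- matrix(rnorm(3 * 40), 3, 40)
    mm <- new("ModeMatrix", S = S, sMax = max(S), sMin = min(S))
    co <- mapCoordinates(mm, cfg)
    xs <- unlist(lapply(co, function(m) m[, "x"]))
    ys <- unlist(lapply(co, function(m) m[, "y"]))
    expect_true(all(xs >= cfg@originX & xs <= cfg@originX + cfg@drawWidth))
    expect_true(all(ys >= cfg@drawTop & ys <= cfg@originY))
  }
  ## a sorted column maps to monotone y (larger value -> larger y, toward
  ## the origin row)
  S <- matrix(c(sort(rnorm(3)), rnorm(3)), 3, 2)
  mm <- new("ModeMatrix", S = S, sMax = max(S), sMin = min(S))
  co <- mapCoordinates(mm, encoderConfig())
  expect_false(is.unsorted(co[[1]][, "y"]))
})

test_that("rendering is deterministic, exact-size, and color-cycled", {
  mm <- handMatrix()
  cfg <- smallEncoderConfig()
  img <- renderImage(mm, cfg)
  expect_identical(dim(img@pixels),
                   c(cfg@imageHeight, cfg@imageWidth, 3L))
  expect_identical(img@pixels, renderImage(mm, cfg)@pixels)

  ## color cycling: a matrix of B+1 identical columns over-paints to the
  ## same raster as its single-column version, because polyline B+1 reuses
  ## color c1 on identical geometry
  B <- cfg@nColors
  col1 <- handMatrix()@S[, 1, drop = FALSE]
  mk <- function(reps) {
    S <- col1[, rep(1, reps), drop = FALSE]
    new("ModeMatrix", S = S, sMax = max(S), sMin = min(S))
  }
  one <- renderImage(mk(1), cfg)
  cycled <- renderImage(mk(B + 1), cfg)
  expect_identical(cycled@pixels, one@pixels)
  ## ... while stopping at polyline B leaves the last color different
  expect_false(identical(renderImage(mk(B), cfg)@pixels, one@pixels))

  ## per-signal normalization: positive rescaling leaves the raster fixed
  S <- handMatrix()@S
  sc <- new("ModeMatrix", S = 5.5 * S, sMax = 5.5 * max(S),
            sMin = 5.5 * min(S))
  expect_identical(renderImage(sc, cfg)@pixels, renderImage(mm, cfg)@pixels)
})

test_that("the shared background accumulates reserved encodings in order", {
  cfg <- smallEncoderConfig()
  vc <- vmdConfig(maxIter = 40)
  recs <- generateDataset(2, 2, seed = 6)
  ## one record: background equals that record's standalone encoding
  bg1 <- buildBackground(recs[1], vc, cfg)
  mm <- buildModeMatrix(vmdDecompose(recs[[1]]@amplitudes, vc))
  expect_identical(bg1@pixels, renderImage(mm, cfg)@pixels)

  bgAll <- buildBackground(recs, vc, cfg)
  expect_identical(bgAll@pixels, buildBackground(recs, vc, cfg)@pixels)
  expect_error(buildBackground(list(), vc, cfg), "1 record")
})

test_that("dataset encoding reserves per class and labels its images", {
  cfg <- smallEncoderConfig()
  vc <- vmdConfig(maxIter = 40)
  recs <- generateDataset(8, 9, seed = 3)
  enc <- encodeDataset(recs, vc, cfg, nBackgroundPerClass = 2, seed = 5)
  expect_length(enc$images, 13)
  labs <- vapply(enc$images, recordLabel, integer(1))
  expect_identical(sum(labs == 1L), 6L)
  expect_identical(sum(labs == 0L), 7L)
  expect_length(enc$backgroundIndex, 4)

  ## reproducibility of the reservation and the rasters
  enc2 <- encodeDataset(recs, vc, cfg, nBackgroundPerClass = 2, seed = 5)
  expect_identical(enc$backgroundIndex, enc2$backgroundIndex)
  expect_identical(enc$images[[1]]@pixels, enc2$images[[1]]@pixels)

  ## no reservation: encodings sit on a white canvas
  enc0 <- encodeDataset(recs, vc, cfg, nBackgroundPerClass = 0, seed = 5)
  expect_null(enc0$background)
  expect_length(enc0$images, 17)
  mm <- buildModeMatrix(vmdDecompose(recs[[1]]@amplitudes, vc))
  expect_identical(enc0$images[[1]]@pixels, renderImage(mm, cfg)@pixels)

  expect_error(encodeDataset(recs, vc, cfg, nBackgroundPerClass = 8,
                             seed = 1), "more than")
})

test_that("resizing preserves flat images and returns the requested size", {
  px <- array(137L, dim = c(120, 180, 3L))
  img <- new("EncodedImage", pixels = px, label = 1L)
  small <- resizeImage(img, 32)
  expect_identical(dim(small@pixels), c(32L, 32L, 3L))
  expect_true(all(small@pixels == 137L))
  expect_identical(small@label, 1L)
  big <- resizeImage(img, 240)
  expect_identical(dim(big@pixels), c(240L, 240L, 3L))
  expect_true(all(big@pixels == 137L))
})
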