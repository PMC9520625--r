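## Independent oracles and small fixtures shared across tests. These are
## deliberately written as literal, slow re-implementations so they stay
## independent of the package's vectorized code paths.

## sample entropy by direct double loop over ordered template pairs
bruteSampEn <- function(x, z, r) {
  N <- length(x)
  nz <- N - z
  count <- function(m) {
    cnt <- 0L
    for (i in seq_len(nz)) for (j in seq_len(nz)) {
      if (i == j) next
      d <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (d <= r) cnt <- cnt + 1L
    }
    cnt
  }
  -log(count(z + 1L) / count(z))
}

## discrete-spectrum argmax by direct DFT summation (positive bins only)
bruteDftArgmax <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  best <- 1L
  bestP <- -Inf
  for (k in 1:(N %/% 2)) {
    re <- sum(x * cos(2 * pi * k * n / N))
    im <- -sum(x * sin(2 * pi * k * n / N))
    p <- re^2 + im^2
    if (p > bestP) {
      bestP <- p
      best <- k
    }
  }
  best   # cycles per record
}

## reduced-size canvas with the default geometry scaled by 1/5, used where
## a test only needs structural properties of the encoding
smallEncoderConfig <- function(...) {
  encoderConfig(imageWidth = 360, imageHeight = 240, originX = 58,
                originY = 202, drawWidth = 244, drawTop = 38,
                lineWidth = 1, ...)
}

## minimal channel plan and config for fast classifier tests
miniPlan <- function() {
  list(stem = 4L, expansion = 2L, heads = 2L, head = 16L,
       stages = list(
         list(type = "mv2", out = 6L, stride = 2L),
         list(type = "vit", tdim = 8L, depth = 1L, mlp = 16L)))
}

miniVitConfig <- function(seed = 1, epochs = 3, inputSize = 16,
                          batchSize = 8) {
  vitConfig(inputSize = inputSize, batchSize = batchSize, epochs = epochs,
            channelPlan = miniPlan(), seed = seed)
}

## tiny labeled image set with an easy brightness difference: class 1
## bright, class 0 dark, plus pixel noise
brightnessImages <- function(n = 20, size = 16, seed = 1) {
  set.seed(seed)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- as.integer(i <= n / 2)
    base <- if (lab == 1L) 200 else 60
    px <- array(as.integer(pmin(255, pmax(0,
      round(base + rnorm(size * size * 3, 0, 25))))),
      dim = c(size, size, 3L))
    imgs[[i]] <- new("EncodedImage", pixels = px, label = lab)
  }
  imgs
}
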