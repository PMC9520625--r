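test_that("scaled dot-product attention matches its definition", {
  set.seed(1)
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rnorm(15), 5, 3)
  V <- matrix(rnorm(10), 5, 2)
  out <- attention(Q, K, V)
  expect_identical(dim(out), c(4L, 2L))
  ## softmax weights row-normalize: with V the identity the output rows
  ## are the weight rows themselves
  W <- attention(Q, K, diag(5))
  expect_equal(rowSums(W), rep(1, 4))
  expect_true(all(W > 0))

  ## identical key rows give uniform weights independent of the query
  Kc <- matrix(1, 5, 3)
  expect_equal(attention(Q, Kc, V), attention(Q * 10, Kc, V))
  expect_equal(attention(Q, Kc, V)[1, ], colMeans(V))

  ## 2x2 identity case against a scalar evaluation
  I2 <- diag(2)
  got <- attention(I2, I2, I2, dk = 2)
  z <- 1 / sqrt(2)
  w11 <- exp(z) / (exp(z) + exp(0))
  expect_equal(got, matrix(c(w11, 1 - w11, 1 - w11, w11), 2, 2))

  expect_error(attention(Q, K[, 1:2], V), "column")
  expect_error(attention(Q, K, V[1:3, ]), "row")
})

test_that("unfold gathers per-position tokens and fold inverts it", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  u <- unfoldPatches(x, 2, 2)
  expect_identical(dim(u), c(4L, 16L, 3L))
  expect_equal(foldPatches(u, 2, 2, 8, 8), x)

  ## 4 x 4 map with 2 x 2 patches: P = 4 positions, N = 4 patches
  y <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  uy <- unfoldPatches(y, 2, 2)
  expect_identical(dim(uy), c(4L, 4L, 2L))
  ## position 1 of patch (1,1) is pixel (1,1); patch 2 is (3,1)
  expect_identical(uy[1, 1, 1], y[1, 1, 1])
  expect_identical(uy[1, 2, 1], y[3, 1, 1])

  ## single patch covering the map: one patch, P = H*W positions
  u1 <- unfoldPatches(y, 4, 4)
  expect_identical(dim(u1), c(16L, 1L, 2L))
  expect_equal(as.numeric(u1), as.numeric(y))

  expect_error(unfoldPatches(x, 3, 2), "divisible")
})

test_that("the MobileViT block preserves shape and exposes its conv path", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  cfg <- miniVitConfig()
  out <- mobileVitBlock(x, cfg, tdim = 8, depth = 1)
  expect_identical(dim(out), dim(x))

  convOnly <- mobileVitBlock(x, cfg, tdim = 8, depth = 1,
                             transformerIdentity = TRUE)
  expect_identical(dim(convOnly), dim(x))
  expect_false(identical(out, convOnly))
  expect_identical(convOnly,
                   mobileVitBlock(x, cfg, tdim = 8, depth = 1,
                                  transformerIdentity = TRUE))
})

test_that("gradients reach every parameter of the network", {
  ns <- asNamespace("sonocrack")
  cfg <- miniVitConfig()
  set.seed(9)
  mdl <- ns$initModel(cfg)
  meta <- ns$planMeta(cfg)
  x <- array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  fw <- ns$modelForward(mdl$params, mdl$buffers, meta, cfg, x, train = TRUE)
  ce <- ns$crossEntropy(fw$logits, c(1L, 2L))
  gr <- ns$modelBackward(mdl$params, meta, cfg, ce$dlogits, fw$caches)
  norms <- rapply(gr, function(g) sqrt(sum(g^2)), how = "unlist")
  expect_true(all(is.finite(norms)))
  expect_true(all(norms > 0))
})

test_that("training is deterministic, seed-controlled, and inert at lr 0", {
  imgs <- brightnessImages(16, 16)
  cfg0 <- miniVitConfig(epochs = 1)
  cfg0@learningRate <- 0
  ns <- asNamespace("sonocrack")
  m0 <- trainClassifier(imgs, cfg0)
  init <- ns$withSeed(ns$deriveSeed(cfg0@seed, 1), ns$initModel(cfg0))
  diff <- ns$treeSum(function(z) sum(abs(z)),
                     ns$treeMap2(`-`, m0@params, init$params))
  expect_identical(diff, 0)

  cfg <- miniVitConfig(epochs = 2)
  mA <- trainClassifier(imgs, cfg)
  mB <- trainClassifier(imgs, cfg)
  expect_identical(mA@history$loss, mB@history$loss)
  expect_identical(mA@params$fc$W, mB@params$fc$W)

  expect_error(trainClassifier(imgs[1:8], cfg), "2 classes")
})

test_that("the classifier fits an easily separable image set", {
  imgs <- brightnessImages(20, 16)
  model <- trainClassifier(imgs, miniVitConfig(epochs = 10))
  expect_gte(tail(model@history$accuracy, 1), 0.9)

  probs <- predictClassifier(model, imgs)
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-6)
  ## duplicated image gives identical probabilities
  dup <- predictClassifier(model, imgs[c(1, 1)])
  expect_identical(dup[1, ], dup[2, ])

  ## argmax agrees with the confusion counting in evaluateClassifier
  pred <- model@classLevels[max.col(probs, ties.method = "first")]
  labs <- vapply(imgs, recordLabel, integer(1))
  met <- evaluateClassifier(model, imgs)
  expect_identical(met@tp, sum(pred == 0L & labs == 0L))
  expect_identical(met@fp, sum(pred == 0L & labs == 1L))
  expect_identical(met@tn + met@tp, sum(pred == labs))
})
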