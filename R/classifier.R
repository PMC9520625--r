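## MobileViT-style classifier: a convolutional stem and MobileNetV2
## inverted-residual stages interleaved with unfold-transformer-fold
## blocks, a pointwise head, global average pooling and a linear
## classifier, trained with Adam on the cross-entropy loss. All forward
## and backward passes are implemented in nn-layers.R.

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / sqrt(dk)) V}, softmax applied row-wise. This is
#' the attention primitive used (with multiple heads) inside the
#' transformer of every MobileViT block.
#'
#' @param Q,K,V query, key and value matrices; Q and K share the column
#'   dimension \code{dk}, K and V share their row count.
#' @param dk key dimension used in the scale factor; defaults to
#'   \code{ncol(Q)}.
#' @return Matrix with \code{nrow(Q)} rows and \code{ncol(V)} columns.
#' @examples
#' attention(diag(2), diag(2), diag(2))
#' @export
attention <- function(Q, K, V, dk = ncol(Q)) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share the column dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share the row count")
  softmaxRows(tcrossprod(Q, K) / sqrt(dk)) %*% V
}

#' Unfold a feature map into per-position patch tokens
#'
#' Splits an H x W x d tensor into N = (H W)/(h w) patches of size h x w
#' and gathers, for each within-patch position p in 1..P (P = h w), the
#' d-dimensional vectors at that position across all N patches.
#' [foldPatches()] is the exact inverse.
#'
#' @param tensor numeric array H x W x d.
#' @param h,w patch height and width; must divide H and W.
#' @return Array P x N x d.
#' @examples
#' x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
#' u <- unfoldPatches(x, 2, 2)   # P = 4 positions, N = 4 patches
#' stopifnot(identical(dim(u), c(4L, 4L, 3L)))
#' @export
unfoldPatches <- function(tensor, h = 2, w = 2) {
  d <- dim(tensor)
  if (length(d) != 3L) stop("tensor must be H x W x d")
  h <- as.integer(h); w <- as.integer(w)
  x <- tensor
  dim(x) <- c(d[1], d[2], 1L, d[3])   # same linear order: batch dim inserted
  uf <- unfoldTokens(x, h, w)
  aperm(array(uf$tokens, c(uf$S, uf$nSeq, d[3])), c(2, 1, 3))
}

#' Fold per-position patch tokens back to a feature map
#'
#' @param tokens array P x N x d as produced by [unfoldPatches()].
#' @param h,w patch size.
#' @param H,W output spatial dims (with \code{H * W = P * N}).
#' @return Array H x W x d.
#' @export
foldPatches <- function(tokens, h = 2, w = 2, H, W) {
  d <- dim(tokens)
  if (length(d) != 3L) stop("tokens must be P x N x d")
  h <- as.integer(h); w <- as.integer(w)
  if (d[1] != h * w) stop("first dim must equal h * w")
  if (H %% h != 0L || W %% w != 0L || (H %/% h) * (W %/% w) != d[2])
    stop("H, W inconsistent with the patch layout")
  tm <- matrix(aperm(tokens, c(2, 1, 3)), d[1] * d[2], d[3])
  x <- foldTokens(tm, h, w, c(as.integer(H), as.integer(W), 1L, d[3]))
  array(x, dim = c(H, W, d[3]))
}

## ---- block parameter construction -----------------------------------------

makeConvBn <- function(k, cin, cout) {
  list(params = list(conv = list(W = initConvW(k, cin, cout)),
                     bn = initBn(cout)),
       buffers = list(bn = initBnBuf(cout)))
}

makeMv2 <- function(cin, cout, stride, expansion) {
  ce <- cin * expansion
  list(params = list(
         expand = list(W = initConvW(1L, cin, ce)), bnE = initBn(ce),
         dw = list(W = initDwW(ce)), bnD = initBn(ce),
         project = list(W = initConvW(1L, ce, cout)), bnP = initBn(cout)),
       buffers = list(bnE = initBnBuf(ce), bnD = initBnBuf(ce),
                      bnP = initBnBuf(cout)),
       meta = list(cin = cin, cout = cout, stride = stride,
                   residual = stride == 1L && cin == cout))
}

makeTransformerLayer <- function(d, mlp) {
  list(ln1 = initLn(d),
       mha = list(Wq = initLinW(d, d), bq = rep(0, d),
                  Wk = initLinW(d, d), bk = rep(0, d),
                  Wv = initLinW(d, d), bv = rep(0, d),
                  Wo = initLinW(d, d), bo = rep(0, d)),
       ln2 = initLn(d),
       ffn = list(W1 = initLinW(d, mlp), b1 = rep(0, mlp),
                  W2 = initLinW(mlp, d), b2 = rep(0, d)))
}

makeVitBlock <- function(cin, tdim, depth, mlp) {
  list(params = list(
         local3 = list(W = initConvW(3L, cin, cin)), bnL = initBn(cin),
         toT = list(W = initConvW(1L, cin, tdim)),
         layers = lapply(seq_len(depth),
                         function(i) makeTransformerLayer(tdim, mlp)),
         lnOut = initLn(tdim),
         fromT = list(W = initConvW(1L, tdim, cin)), bnF = initBn(cin),
         fuse = list(W = initConvW(3L, 2L * cin, cin)), bnZ = initBn(cin)),
       buffers = list(bnL = initBnBuf(cin), bnF = initBnBuf(cin),
                      bnZ = initBnBuf(cin)),
       meta = list(cin = cin, tdim = tdim, depth = depth, mlp = mlp))
}

## build the full parameter/buffer trees for a config; uses the current RNG
initModel <- function(config) {
  plan <- config@channelPlan
  params <- list()
  buffers <- list()
  stem <- makeConvBn(3L, 3L, plan$stem)
  params$stem <- stem$params
  buffers$stem <- stem$buffers
  cin <- plan$stem
  params$stages <- list()
  buffers$stages <- list()
  meta <- list()
  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    if (st$type == "mv2") {
      blk <- makeMv2(cin, st$out, st$stride, plan$expansion)
      cin <- st$out
    } else {
      blk <- makeVitBlock(cin, st$tdim, st$depth, st$mlp)
    }
    params$stages[[i]] <- blk$params
    buffers$stages[[i]] <- blk$buffers
    meta[[i]] <- c(blk$meta, list(type = st$type))
  }
  head <- makeConvBn(1L, cin, plan$head)
  params$head <- head$params
  buffers$head <- head$buffers
  params$fc <- list(W = initLinW(plan$head, config@nClasses),
                    b = rep(0, config@nClasses))
  list(params = params, buffers = buffers, meta = meta)
}

## ---- block forward/backward -----------------------------------------------

convBnSiluForward <- function(x, p, buf, k, stride, pad, train) {
  cv <- convForward(x, p$conv$W, NULL, k, stride, pad)
  bn <- bnForward(cv$out, p$bn$gamma, p$bn$beta, buf$bn, train)
  ac <- siluForward(bn$out)
  list(out = ac$out, buf = list(bn = bn$buf),
       cache = list(cv = cv$cache, bn = bn$cache, ac = ac$cache))
}

convBnSiluBackward <- function(dout, p, cache) {
  da <- siluBackward(dout, cache$ac)
  bb <- bnBackward(da, p$bn$gamma, cache$bn)
  cb <- convBackward(bb$dx, p$conv$W, cache$cv, hasBias = FALSE)
  list(dx = cb$dx,
       grads = list(conv = list(W = cb$dW),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

mv2Forward <- function(x, p, buf, meta, train) {
  e <- convForward(x, p$expand$W, NULL, 1L, 1L, 0L)
  be <- bnForward(e$out, p$bnE$gamma, p$bnE$beta, buf$bnE, train)
  ae <- siluForward(be$out)
  dw <- dwconvForward(ae$out, p$dw$W, meta$stride)
  bd <- bnForward(dw$out, p$bnD$gamma, p$bnD$beta, buf$bnD, train)
  ad <- siluForward(bd$out)
  pr <- convForward(ad$out, p$project$W, NULL, 1L, 1L, 0L)
  bp <- bnForward(pr$out, p$bnP$gamma, p$bnP$beta, buf$bnP, train)
  out <- if (meta$residual) bp$out + x else bp$out
  list(out = out,
       buf = list(bnE = be$buf, bnD = bd$buf, bnP = bp$buf),
       cache = list(e = e$cache, be = be$cache, ae = ae$cache,
                    dw = dw$cache, bd = bd$cache, ad = ad$cache,
                    pr = pr$cache, bp = bp$cache))
}

mv2Backward <- function(dout, p, meta, cache) {
  g <- list()
  bb <- bnBackward(dout, p$bnP$gamma, cache$bp)
  g$bnP <- list(gamma = bb$dgamma, beta = bb$dbeta)
  cb <- convBackward(bb$dx, p$project$W, cache$pr, hasBias = FALSE)
  g$project <- list(W = cb$dW)
  da <- siluBackward(cb$dx, cache$ad)
  bd <- bnBackward(da, p$bnD$gamma, cache$bd)
  g$bnD <- list(gamma = bd$dgamma, beta = bd$dbeta)
  dwb <- dwconvBackward(bd$dx, p$dw$W, cache$dw)
  g$dw <- list(W = dwb$dW)
  da2 <- siluBackward(dwb$dx, cache$ae)
  be <- bnBackward(da2, p$bnE$gamma, cache$be)
  g$bnE <- list(gamma = be$dgamma, beta = be$dbeta)
  eb <- convBackward(be$dx, p$expand$W, cache$e, hasBias = FALSE)
  g$expand <- list(W = eb$dW)
  dx <- if (meta$residual) eb$dx + dout else eb$dx
  ## order gradients as the params tree
  list(dx = dx, grads = list(expand = g$expand, bnE = g$bnE, dw = g$dw,
                             bnD = g$bnD, project = g$project, bnP = g$bnP))
}

transformerLayerForward <- function(tm, p, S, nSeq, heads) {
  l1 <- lnForward(tm, p$ln1$gamma, p$ln1$beta)
  at <- mhaForward(l1$out, p$mha, S, nSeq, heads)
  h1 <- tm + at$out
  l2 <- lnForward(h1, p$ln2$gamma, p$ln2$beta)
  f1 <- linForward(l2$out, p$ffn$W1, p$ffn$b1)
  fa <- siluForward(f1$out)
  f2 <- linForward(fa$out, p$ffn$W2, p$ffn$b2)
  out <- h1 + f2$out
  list(out = out, cache = list(l1 = l1$cache, at = at$cache,
                               l2 = l2$cache, f1 = f1$cache,
                               fa = fa$cache, f2 = f2$cache))
}

transformerLayerBackward <- function(dout, p, cache) {
  f2 <- linBackward(dout, p$ffn$W2, cache$f2)
  da <- siluBackward(f2$dx, cache$fa)
  f1 <- linBackward(da, p$ffn$W1, cache$f1)
  l2 <- lnBackward(f1$dx, p$ln2$gamma, cache$l2)
  dh1 <- dout + l2$dx
  at <- mhaBackward(dh1, p$mha, cache$at)
  l1 <- lnBackward(at$dx, p$ln1$gamma, cache$l1)
  dx <- dh1 + l1$dx
  list(dx = dx,
       grads = list(ln1 = list(gamma = l1$dgamma, beta = l1$dbeta),
                    mha = at$grads,
                    ln2 = list(gamma = l2$dgamma, beta = l2$dbeta),
                    ffn = list(W1 = f1$dW, b1 = f1$db,
                               W2 = f2$dW, b2 = f2$db)))
}

vitBlockForward <- function(x, p, buf, meta, config, train,
                            transformerIdentity = FALSE) {
  lc <- convForward(x, p$local3$W, NULL, 3L, 1L, 1L)
  bl <- bnForward(lc$out, p$bnL$gamma, p$bnL$beta, buf$bnL, train)
  al <- siluForward(bl$out)
  tt <- convForward(al$out, p$toT$W, NULL, 1L, 1L, 0L)
  uf <- unfoldTokens(tt$out, config@patchH, config@patchW)
  tm <- uf$tokens
  layerCaches <- vector("list", meta$depth)
  if (!transformerIdentity) {
    heads <- config@channelPlan$heads
    for (i in seq_len(meta$depth)) {
      lf <- transformerLayerForward(tm, p$layers[[i]], uf$S, uf$nSeq, heads)
      tm <- lf$out
      layerCaches[[i]] <- lf$cache
    }
    lo <- lnForward(tm, p$lnOut$gamma, p$lnOut$beta)
    tm <- lo$out
  } else lo <- NULL
  fd <- foldTokens(tm, config@patchH, config@patchW, dim(tt$out))
  ft <- convForward(fd, p$fromT$W, NULL, 1L, 1L, 0L)
  bf <- bnForward(ft$out, p$bnF$gamma, p$bnF$beta, buf$bnF, train)
  af <- siluForward(bf$out)
  cat_ <- abind4(x, af$out)
  fz <- convForward(cat_, p$fuse$W, NULL, 3L, 1L, 1L)
  bz <- bnForward(fz$out, p$bnZ$gamma, p$bnZ$beta, buf$bnZ, train)
  az <- siluForward(bz$out)
  list(out = az$out,
       buf = list(bnL = bl$buf, bnF = bf$buf, bnZ = bz$buf),
       cache = list(lc = lc$cache, bl = bl$cache, al = al$cache,
                    tt = tt$cache, uf = uf, layers = layerCaches,
                    lo = if (is.null(lo)) NULL else lo$cache,
                    ttDims = dim(tt$out), ft = ft$cache, bf = bf$cache,
                    af = af$cache, fz = fz$cache, bz = bz$cache,
                    az = az$cache, cin = meta$cin,
                    transformerIdentity = transformerIdentity))
}

## concatenate two (H, W, N, C) arrays along the channel axis; with the
## channel axis last this is a plain concatenation of the linear buffers
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1], da[2], da[3], da[4] + db[4])
  out
}

vitBlockBackward <- function(dout, p, meta, config, cache) {
  daz <- siluBackward(dout, cache$az)
  bz <- bnBackward(daz, p$bnZ$gamma, cache$bz)
  fz <- convBackward(bz$dx, p$fuse$W, cache$fz, hasBias = FALSE)
  cin <- cache$cin
  dxSkip <- fz$dx[, , , seq_len(cin), drop = FALSE]
  dcat <- fz$dx[, , , cin + seq_len(cin), drop = FALSE]
  daf <- siluBackward(dcat, cache$af)
  bf <- bnBackward(daf, p$bnF$gamma, cache$bf)
  ft <- convBackward(bf$dx, p$fromT$W, cache$ft, hasBias = FALSE)
  ufb <- unfoldTokens(ft$dx, config@patchH, config@patchW)
  dtm <- ufb$tokens
  layerGrads <- vector("list", meta$depth)
  if (!cache$transformerIdentity) {
    lo <- lnBackward(dtm, p$lnOut$gamma, cache$lo)
    dtm <- lo$dx
    lnOutG <- list(gamma = lo$dgamma, beta = lo$dbeta)
    for (i in rev(seq_len(meta$depth))) {
      lb <- transformerLayerBackward(dtm, p$layers[[i]], cache$layers[[i]])
      dtm <- lb$dx
      layerGrads[[i]] <- lb$grads
    }
  } else {
    lnOutG <- list(gamma = p$lnOut$gamma * 0, beta = p$lnOut$beta * 0)
    layerGrads <- treeMap(function(x) x * 0, p$layers)
  }
  dtt <- foldTokens(dtm, config@patchH, config@patchW, cache$ttDims)
  tt <- convBackward(dtt, p$toT$W, cache$tt, hasBias = FALSE)
  dal <- siluBackward(tt$dx, cache$al)
  bl <- bnBackward(dal, p$bnL$gamma, cache$bl)
  lc <- convBackward(bl$dx, p$local3$W, cache$lc, hasBias = FALSE)
  dx <- lc$dx + dxSkip
  list(dx = dx,
       grads = list(local3 = list(W = lc$dW),
                    bnL = list(gamma = bl$dgamma, beta = bl$dbeta),
                    toT = list(W = tt$dW),
                    layers = layerGrads,
                    lnOut = lnOutG,
                    fromT = list(W = ft$dW),
                    bnF = list(gamma = bf$dgamma, beta = bf$dbeta),
                    fuse = list(W = fz$dW),
                    bnZ = list(gamma = bz$dgamma, beta = bz$dbeta)))
}

#' Apply a MobileViT block to a feature map
#'
#' The block applies a local 3 x 3 convolution and a pointwise projection
#' to the transformer dimension, unfolds the map into per-position patch
#' tokens, runs a transformer across the patch axis independently per
#' position, folds back, projects to the input depth, concatenates with
#' the block input, and fuses with a 3 x 3 convolution. Output spatial
#' dims and depth equal the input's.
#'
#' Freshly initialized block parameters (seeded from \code{config@seed})
#' are used unless \code{params}/\code{buffers} from a trained model are
#' supplied; \code{transformerIdentity = TRUE} replaces the transformer
#' with the identity, reducing the block to its convolutional path (a test
#' hook for ablation).
#'
#' @param tensor numeric array H x W x d (one item).
#' @param config a [ViTConfig-class] (patch size, heads).
#' @param tdim,depth,mlp transformer width, depth and MLP width used when
#'   initializing fresh parameters.
#' @param params,buffers optional pre-built block parameters.
#' @param transformerIdentity test hook (default FALSE).
#' @return Array H x W x d.
#' @export
mobileVitBlock <- function(tensor, config = vitConfig(), tdim = 64,
                           depth = 2, mlp = 2 * tdim, params = NULL,
                           buffers = NULL, transformerIdentity = FALSE) {
  d <- dim(tensor)
  if (length(d) != 3L) stop("tensor must be H x W x d")
  if (d[1] %% config@patchH != 0L || d[2] %% config@patchW != 0L)
    stop("spatial dims must be divisible by the patch size")
  meta <- list(cin = d[3], tdim = as.integer(tdim),
               depth = as.integer(depth), mlp = as.integer(mlp))
  if (is.null(params)) {
    blk <- withSeed(config@seed,
                    makeVitBlock(d[3], meta$tdim, meta$depth, meta$mlp))
    params <- blk$params
    buffers <- blk$buffers
  }
  x <- tensor
  dim(x) <- c(d[1], d[2], 1L, d[3])
  out <- vitBlockForward(x, params, buffers, meta, config, train = FALSE,
                         transformerIdentity = transformerIdentity)
  array(out$out, dim = d)
}

## ---- full model ------------------------------------------------------------

modelForward <- function(params, buffers, meta, config, x, train) {
  caches <- list()
  st <- convBnSiluForward(x, params$stem, buffers$stem, 3L, 2L, 1L, train)
  buffers$stem <- st$buf
  caches$stem <- st$cache
  h <- st$out
  caches$stages <- vector("list", length(meta))
  for (i in seq_along(meta)) {
    if (meta[[i]]$type == "mv2") {
      blk <- mv2Forward(h, params$stages[[i]], buffers$stages[[i]],
                        meta[[i]], train)
    } else {
      blk <- vitBlockForward(h, params$stages[[i]], buffers$stages[[i]],
                             meta[[i]], config, train)
    }
    buffers$stages[[i]] <- blk$buf
    caches$stages[[i]] <- blk$cache
    h <- blk$out
  }
  hd <- convBnSiluForward(h, params$head, buffers$head, 1L, 1L, 0L, train)
  buffers$head <- hd$buf
  caches$head <- hd$cache
  d <- dim(hd$out)
  ## global average pool: columns of matrix(hd$out) iterate N fastest, then
  ## C, so the reshape gives batch rows directly
  pooled <- matrix(colMeans(matrix(hd$out, d[1] * d[2], d[3] * d[4])),
                   d[3], d[4])
  fc <- linForward(pooled, params$fc$W, params$fc$b)
  caches$pool <- list(dims = d)
  caches$fc <- fc$cache
  list(logits = fc$out, caches = caches, buffers = buffers)
}

modelBackward <- function(params, meta, config, dlogits, caches) {
  grads <- list()
  fc <- linBackward(dlogits, params$fc$W, caches$fc)
  grads$fc <- list(W = fc$dW, b = fc$db)
  d <- caches$pool$dims
  ## distribute pooled gradient evenly over spatial positions
  dpm <- fc$dx / (d[1] * d[2])                  # N x C
  dh <- array(rep(as.numeric(dpm), each = d[1] * d[2]), dim = d)
  hd <- convBnSiluBackward(dh, params$head, caches$head)
  grads$head <- hd$grads
  dx <- hd$dx
  grads$stages <- vector("list", length(meta))
  for (i in rev(seq_along(meta))) {
    if (meta[[i]]$type == "mv2") {
      blk <- mv2Backward(dx, params$stages[[i]], meta[[i]],
                         caches$stages[[i]])
    } else {
      blk <- vitBlockBackward(dx, params$stages[[i]], meta[[i]], config,
                              caches$stages[[i]])
    }
    grads$stages[[i]] <- blk$grads
    dx <- blk$dx
  }
  st <- convBnSiluBackward(dx, params$stem, caches$stem)
  grads$stem <- st$grads
  ## match the params tree order: stem, stages, head, fc
  list(stem = grads$stem, stages = grads$stages, head = grads$head,
       fc = grads$fc)
}

## stage metadata reconstructed from a config (channel bookkeeping)
planMeta <- function(config) {
  plan <- config@channelPlan
  cin <- plan$stem
  meta <- list()
  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    if (st$type == "mv2") {
      meta[[i]] <- list(type = "mv2", cin = cin, cout = st$out,
                        stride = st$stride,
                        residual = st$stride == 1L && cin == st$out)
      cin <- st$out
    } else {
      meta[[i]] <- list(type = "vit", cin = cin, tdim = st$tdim,
                        depth = st$depth, mlp = st$mlp)
    }
  }
  meta
}

## images (list of EncodedImage or numeric arrays) -> (s, s, 3, N) in [0, 1]
imagesToBatchArray <- function(images, size) {
  N <- length(images)
  x <- array(0, dim = c(size, size, N, 3L))
  for (i in seq_len(N)) {
    img <- images[[i]]
    px <- if (is(img, "EncodedImage")) {
      d <- dim(img@pixels)
      if (d[1] != size || d[2] != size) resizeRaster(img@pixels, size)
      else img@pixels
    } else img
    x[, , i, ] <- px / 255
  }
  x
}

## per-channel standardization of a (s, s, N, 3) batch array
normalizeBatch <- function(x, chMean, chSd) {
  d <- dim(x)
  xm <- matrix(x, ncol = 3L)
  xm <- cpp_col_scale_shift(xm, 1 / chSd, -chMean / chSd)
  dim(xm) <- d
  xm
}

imageLabels <- function(images, labels = NULL) {
  if (!is.null(labels)) return(as.integer(labels))
  vapply(images, function(im) {
    if (is(im, "EncodedImage")) im@label else NA_integer_
  }, integer(1))
}

crossEntropy <- function(logits, targetIdx) {
  p <- softmaxRows(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), targetIdx)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), targetIdx)] <-
    dlogits[cbind(seq_len(n), targetIdx)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

#' Train the MobileViT classifier
#'
#' Cross-entropy training with Adam for \code{config@epochs} epochs at the
#' configured batch size and learning rate. Images are bilinearly resized
#' to \code{config@inputSize} and scaled to [0, 1]; no augmentation is
#' applied. The seed in the config controls initialization and epoch
#' shuffling, making training bit-reproducible on one machine.
#'
#' @param images list of labeled [EncodedImage-class] objects, or of
#'   numeric \code{size x size x 3} arrays with 0..255 values when
#'   \code{labels} is given.
#' @param config a [ViTConfig-class].
#' @param labels optional integer labels overriding the image labels.
#' @return A [MobileViTModel-class] with a per-epoch history (mean
#'   minibatch loss and training accuracy).
#' @export
trainClassifier <- function(images, config = vitConfig(), labels = NULL) {
  labs <- imageLabels(images, labels)
  if (anyNA(labs)) stop("all training images must be labeled")
  classLevels <- sort(unique(labs))
  if (length(classLevels) < 2L)
    stop("training requires at least 2 classes present")
  if (length(classLevels) != config@nClasses)
    stop("number of classes present does not match config@nClasses")
  targetIdx <- match(labs, classLevels)
  x <- imagesToBatchArray(images, config@inputSize)
  N <- length(images)
  ## standardize per channel over the training set; the statistics travel
  ## with the model so prediction applies the identical transform
  xm <- matrix(x, ncol = 3L)
  chMean <- colMeans(xm)
  chSd <- pmax(apply(xm, 2, stats::sd), 1e-6)
  x <- normalizeBatch(x, chMean, chSd)

  mdl <- withSeed(deriveSeed(config@seed, 1), initModel(config))
  params <- mdl$params
  buffers <- mdl$buffers
  meta <- planMeta(config)
  state <- adamInit(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  ## learning-rate schedule: linear warmup over the first tenth of the
  ## steps, cosine decay to zero afterwards; config@learningRate is the
  ## base (peak) rate
  stepsPerEpoch <- length(seq(1L, N, by = config@batchSize))
  totalSteps <- config@epochs * stepsPerEpoch
  warmSteps <- max(1L, ceiling(0.1 * totalSteps))
  stepNo <- 0L
  swaK <- min(3L, config@epochs)
  swaSum <- NULL
  for (epoch in seq_len(config@epochs)) {
    ord <- withSeed(deriveSeed(config@seed, 1000 + epoch), sample.int(N))
    losses <- c()
    correct <- 0L
    for (start in seq(1L, N, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, N)]
      xb <- x[, , idx, , drop = FALSE]
      tb <- targetIdx[idx]
      fw <- modelForward(params, buffers, meta, config, xb, train = TRUE)
      buffers <- fw$buffers
      ce <- crossEntropy(fw$logits, tb)
      losses <- c(losses, ce$loss)
      correct <- correct +
        sum(max.col(fw$logits, ties.method = "first") == tb)
      grads <- modelBackward(params, meta, config, ce$dlogits, fw$caches)
      ## global-norm gradient clipping at 1.0, a standard stabilizer for
      ## short-horizon transformer training
      gn <- sqrt(treeSum(function(g) sum(g * g), grads))
      if (gn > 1) grads <- treeMap(function(g) g / gn, grads)
      stepNo <- stepNo + 1L
      lrNow <- config@learningRate *
        (if (stepNo <= warmSteps) stepNo / warmSteps
         else 0.5 * (1 + cos(pi * (stepNo - warmSteps) /
                               max(1L, totalSteps - warmSteps))))
      upd <- adamStep(params, grads, state, lrNow)
      params <- applyWeightDecay(upd$params, lrNow, config@weightDecay)
      state <- upd$state
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                accuracy = correct / N))
    ## stochastic weight averaging over the cosine tail: accumulate the
    ## parameters of the last few epochs and return their mean, which
    ## damps the epoch-to-epoch oscillation of small-batch training
    if (epoch > config@epochs - swaK) {
      swaSum <- if (is.null(swaSum)) params
                else treeMap2(`+`, swaSum, params)
    }
  }
  params <- treeMap(function(p) p / swaK, swaSum)
  buffers$inputNorm <- list(mean = chMean, sd = chSd)
  new("MobileViTModel", params = params, buffers = buffers, config = config,
      classLevels = as.integer(classLevels), history = history)
}

#' Predict class probabilities
#'
#' @param model a trained [MobileViTModel-class].
#' @param images list of [EncodedImage-class] objects or numeric arrays
#'   (0..255 channel values).
#' @return Numeric matrix, one row per image, columns named by class label
#'   in \code{model@classLevels} order; each row sums to 1.
#' @export
predictClassifier <- function(model, images) {
  stopifnot(is(model, "MobileViTModel"))
  config <- model@config
  meta <- planMeta(config)
  N <- length(images)
  if (N == 0L) stop("no images to predict")
  out <- matrix(0, N, config@nClasses)
  bs <- config@batchSize
  nrm <- model@buffers$inputNorm
  for (start in seq(1L, N, by = bs)) {
    idx <- start:min(start + bs - 1L, N)
    xb <- imagesToBatchArray(images[idx], config@inputSize)
    if (!is.null(nrm)) xb <- normalizeBatch(xb, nrm$mean, nrm$sd)
    fw <- modelForward(model@params, model@buffers, meta, config, xb,
                       train = FALSE)
    out[idx, ] <- softmaxRows(fw$logits)
  }
  colnames(out) <- as.character(model@classLevels)
  out
}

#' Evaluate a classifier on labeled images
#'
#' Predicts, takes the argmax class, and tallies the confusion counts with
#' the slight-crack class (label 0) as the positive detection target by
#' default.
#'
#' @param model a trained [MobileViTModel-class].
#' @param images labeled images.
#' @param labels optional label override.
#' @param positiveLabel label counted as positive (default 0, slight
#'   crack).
#' @return A [Metrics-class].
#' @export
evaluateClassifier <- function(model, images, labels = NULL,
                               positiveLabel = 0L) {
  labs <- imageLabels(images, labels)
  if (anyNA(labs)) stop("all evaluation images must be labeled")
  probs <- predictClassifier(model, images)
  pred <- model@classLevels[max.col(probs, ties.method = "first")]
  pos <- as.integer(positiveLabel)
  computeMetrics(tp = sum(pred == pos & labs == pos),
                 fp = sum(pred == pos & labs != pos),
                 fn = sum(pred != pos & labs == pos),
                 tn = sum(pred != pos & labs != pos))
}
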