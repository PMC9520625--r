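## Minimal dense/convolutional network primitives with hand-derived
## backward passes, sufficient for the MobileViT classifier. Activations
## between spatial layers are numeric arrays of dim c(H, W, N, C) — batch
## before channels, so that the (H*W*N, C) channel-matrix view used by
## pointwise ops, batch norm and im2col is a zero-copy reshape. Token
## activations inside transformer blocks are matrices of dim
## (seqLen * nSequences, d) with the sequence index fastest. Convolutions
## are im2col + BLAS matmul. All functions are internal.

## ---- layout helpers -------------------------------------------------------

chanMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

chanArr <- function(m, H, W, N, C) {
  dim(m) <- c(H, W, N, C)
  m
}

padArray <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

## column-broadcast: add/multiply per-channel vector over an (n, C) matrix
bcast <- function(v, n) rep(v, each = n)

## ---- convolutions ---------------------------------------------------------

## standard k x k convolution; W is a (k*k*Cin, Cout) matrix, bias optional
convForward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  if (k == 1L && stride == 1L && pad == 0L) {
    xm <- chanMat(x)
    y <- xm %*% W
    if (!is.null(b)) y <- y + bcast(b, nrow(y))
    return(list(out = chanArr(y, d[1], d[2], d[3], ncol(W)),
                cache = list(xm = xm, dims = d, k = k, stride = stride,
                             pad = pad)))
  }
  xp <- padArray(x, pad)
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  N <- d[3]; C <- d[4]
  cols <- cpp_im2col(xp, dim(xp)[1], dim(xp)[2], N, C, k, Ho, Wo, stride)
  y <- cols %*% W
  if (!is.null(b)) y <- y + bcast(b, nrow(y))
  list(out = chanArr(y, Ho, Wo, N, ncol(W)),
       cache = list(cols = cols, dims = d, Ho = Ho, Wo = Wo,
                    k = k, stride = stride, pad = pad))
}

convBackward <- function(dout, W, cache, hasBias = TRUE) {
  d <- cache$dims
  if (cache$k == 1L && cache$stride == 1L && cache$pad == 0L) {
    dm <- chanMat(dout)
    dW <- crossprod(cache$xm, dm)
    db <- if (hasBias) colSums(dm) else NULL
    dx <- chanArr(tcrossprod(dm, W), d[1], d[2], d[3], d[4])
    return(list(dx = dx, dW = dW, db = db))
  }
  k <- cache$k; N <- d[3]; C <- d[4]
  dm <- chanMat(dout)
  dW <- crossprod(cache$cols, dm)
  db <- if (hasBias) colSums(dm) else NULL
  dcols <- tcrossprod(dm, W)
  p <- cache$pad
  dxp <- cpp_col2im(dcols, d[1] + 2L * p, d[2] + 2L * p, N, C, k,
                    cache$Ho, cache$Wo, cache$stride)
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , ,
                        drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

## depthwise 3 x 3 convolution; W is a (9, C) matrix
dwconvForward <- function(x, W, stride) {
  d <- dim(x)
  xp <- padArray(x, 1L)
  Ho <- (d[1] + 2L - 3L) %/% stride + 1L
  Wo <- (d[2] + 2L - 3L) %/% stride + 1L
  out <- cpp_dwconv_fwd(xp, W, dim(xp)[1], dim(xp)[2], d[3], d[4],
                        Ho, Wo, stride)
  list(out = out, cache = list(xp = xp, dims = d, Ho = Ho, Wo = Wo,
                               stride = stride))
}

dwconvBackward <- function(dout, W, cache) {
  d <- cache$dims
  bw <- cpp_dwconv_bwd(cache$xp, dout, W, dim(cache$xp)[1],
                       dim(cache$xp)[2], d[3], d[4], cache$Ho, cache$Wo,
                       cache$stride)
  dx <- bw$dxp[1L + seq_len(d[1]), 1L + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = bw$dW)
}

## ---- normalization and activation -----------------------------------------

## batch norm over (H, W, N) per channel; buffers carry running stats
bnForward <- function(x, gamma, beta, buf, train, momentum = 0.1,
                      eps = 1e-5) {
  d <- dim(x)
  xm <- chanMat(x)
  n <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- cpp_col_scale_shift(xm, rep(1, length(mu)), -mu)
    v <- colMeans(xc * xc)
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v * n / max(1, n - 1)
  } else {
    mu <- buf$mean
    v <- buf$var
    xc <- cpp_col_scale_shift(xm, rep(1, length(mu)), -mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- cpp_col_scale(xc, invstd)
  y <- cpp_col_scale_shift(xhat, gamma, beta)
  list(out = chanArr(y, d[1], d[2], d[3], d[4]), buf = buf,
       cache = list(xhat = xhat, invstd = invstd, dims = d, n = n))
}

bnBackward <- function(dout, gamma, cache) {
  d <- cache$dims
  n <- cache$n
  dy <- chanMat(dout)
  dgamma <- cpp_colsums_prod(dy, cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- cpp_col_scale(dy, gamma)
  dx <- cpp_bn_bwd(dxhat, cache$xhat, colSums(dxhat) / n,
                   cpp_colsums_prod(dxhat, cache$xhat) / n, cache$invstd)
  list(dx = chanArr(dx, d[1], d[2], d[3], d[4]),
       dgamma = dgamma, dbeta = dbeta)
}

siluForward <- function(x) {
  f <- cpp_silu_fwd(x)
  list(out = f$out, cache = list(x = x, s = f$s))
}

siluBackward <- function(dout, cache) {
  cpp_silu_bwd(dout, cache$x, cache$s)
}

## ---- token-domain layers (matrices (S * Bt, d)) ---------------------------

linForward <- function(x, W, b) {
  y <- x %*% W
  if (!is.null(b)) y <- y + bcast(b, nrow(y))
  list(out = y, cache = list(x = x))
}

linBackward <- function(dout, W, cache, hasBias = TRUE) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache$x, dout),
       db = if (hasBias) colSums(dout) else NULL)
}

## layer norm across the feature (column) dimension, per row
lnForward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  y <- cpp_col_scale_shift(xhat, gamma, beta)
  list(out = y, cache = list(xhat = xhat, invstd = invstd))
}

lnBackward <- function(dout, gamma, cache) {
  dgamma <- cpp_colsums_prod(dout, cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- cpp_col_scale(dout, gamma)
  dx <- (dxhat - rowMeans(dxhat) -
         cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$invstd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## multi-head self-attention over nSeq sequences of length S stacked in a
## (S * nSeq, d) matrix (sequence index fastest within each block of S rows)
mhaForward <- function(x, p, S, nSeq, heads) {
  d <- ncol(x)
  dh <- d %/% heads
  q <- x %*% p$Wq + bcast(p$bq, nrow(x))
  k <- x %*% p$Wk + bcast(p$bk, nrow(x))
  v <- x %*% p$Wv + bcast(p$bv, nrow(x))
  o <- matrix(0, nrow(x), d)
  att <- vector("list", nSeq * heads)
  for (b in seq_len(nSeq)) {
    rows <- (b - 1L) * S + seq_len(S)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- softmaxRows(tcrossprod(q[rows, cols, drop = FALSE],
                                  k[rows, cols, drop = FALSE]) / sqrt(dh))
      o[rows, cols] <- A %*% v[rows, cols, drop = FALSE]
      att[[(b - 1L) * heads + h]] <- A
    }
  }
  out <- o %*% p$Wo + bcast(p$bo, nrow(x))
  list(out = out,
       cache = list(x = x, q = q, k = k, v = v, o = o, att = att,
                    S = S, nSeq = nSeq, heads = heads, dh = dh))
}

mhaBackward <- function(dout, p, cache) {
  x <- cache$x
  n <- nrow(x)
  dWo <- crossprod(cache$o, dout)
  dbo <- colSums(dout)
  do_ <- tcrossprod(dout, p$Wo)
  dq <- matrix(0, n, ncol(x))
  dk <- matrix(0, n, ncol(x))
  dv <- matrix(0, n, ncol(x))
  S <- cache$S; dh <- cache$dh
  for (b in seq_len(cache$nSeq)) {
    rows <- (b - 1L) * S + seq_len(S)
    for (h in seq_len(cache$heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- cache$att[[(b - 1L) * cache$heads + h]]
      dOb <- do_[rows, cols, drop = FALSE]
      Vb <- cache$v[rows, cols, drop = FALSE]
      dv[rows, cols] <- crossprod(A, dOb)
      dA <- tcrossprod(dOb, Vb)
      dZ <- A * (dA - rowSums(dA * A))          # softmax Jacobian
      dq[rows, cols] <- dZ %*% cache$k[rows, cols, drop = FALSE] / sqrt(dh)
      dk[rows, cols] <- crossprod(dZ, cache$q[rows, cols, drop = FALSE]) /
        sqrt(dh)
    }
  }
  dx <- tcrossprod(dq, p$Wq) + tcrossprod(dk, p$Wk) + tcrossprod(dv, p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(x, dq), bq = colSums(dq),
                    Wk = crossprod(x, dk), bk = colSums(dk),
                    Wv = crossprod(x, dv), bv = colSums(dv),
                    Wo = dWo, bo = dbo))
}

## ---- unfold / fold between spatial and token domains ----------------------

## (H, W, N, C) -> token matrix ((H*W/(h*w)) * h*w * N, C): each sequence is
## the N_patch = H*W/(h*w) patches at one within-patch position p, one
## sequence per (p, batch item)
unfoldTokens <- function(x, h, w) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  if (H %% h != 0L || W %% w != 0L)
    stop("spatial dims must be divisible by the patch size")
  y <- aperm(array(x, c(h, H %/% h, w, W %/% w, N, C)),
             c(2, 4, 1, 3, 5, 6))
  list(tokens = matrix(y, (H %/% h) * (W %/% w) * h * w * N, C),
       S = (H %/% h) * (W %/% w), nSeq = h * w * N, dims = d)
}

foldTokens <- function(tokens, h, w, dims) {
  H <- dims[1]; W <- dims[2]; N <- dims[3]; C <- dims[4]
  y <- array(tokens, c(H %/% h, W %/% w, h, w, N, C))
  x <- aperm(y, c(3, 1, 4, 2, 5, 6))
  dim(x) <- c(H, W, N, C)
  x
}

## ---- parameter initialization ---------------------------------------------

initConvW <- function(k, cin, cout)
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)

initDwW <- function(c)
  matrix(stats::rnorm(9L * c, 0, sqrt(2 / 9)), 9L, c)

initLinW <- function(din, dout)
  matrix(stats::rnorm(din * dout, 0, sqrt(1 / din)), din, dout)

initBn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

initBnBuf <- function(c) list(mean = rep(0, c), var = rep(1, c))

initLn <- function(d) list(gamma = rep(1, d), beta = rep(0, d))

## ---- tree utilities over nested parameter lists ---------------------------

treeMap <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(el) treeMap(f, el)))
  f(a)
}

treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- treeMap2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

treeSum <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, function(el) treeSum(f, el),
                                    numeric(1))))
  f(a)
}

## one Adam step over nested parameter/gradient trees; state holds m and v
## trees plus the step counter
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- treeMap2(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- treeMap2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  mh <- 1 - beta1^state$t
  vh <- 1 - beta2^state$t
  upd <- treeMap2(function(m, v) lr * (m / mh) / (sqrt(v / vh) + eps),
                  state$m, state$v)
  params <- treeMap2(`-`, params, upd)
  list(params = params, state = state)
}

adamInit <- function(params)
  list(t = 0L, m = treeMap(function(x) x * 0, params),
       v = treeMap(function(x) x * 0, params))

## decoupled weight decay: shrink weight matrices only, leaving biases and
## normalization parameters (plain vectors) untouched
applyWeightDecay <- function(params, lr, wd) {
  if (wd <= 0) return(params)
  treeMap(function(x) {
    if (is.matrix(x)) x * (1 - lr * wd) else x
  }, params)
}
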