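## Sound-to-image encoding. The M x L mode matrix S of one signal is drawn
## as L vertical polylines: column s_l becomes a polyline through M vertices
## whose x positions are evenly spread over the drawing width and whose y
## positions map the per-signal normalized amplitude between the origin row
## (y_OS, value = S_max) and the top bound (H_S, value = S_min), y measured
## image-down. Polyline colors cycle through the B-color palette with
## period B; later polylines over-paint earlier ones. Optionally the
## polylines are drawn over a shared background canvas accumulated from a
## reserved subset of signals.

#' Stack a decomposition into a mode matrix
#'
#' @param result a [VMDResult-class]; rows of the matrix are the modes in
#'   ascending-center-frequency order.
#' @return A [ModeMatrix-class] with the global extrema of all M x L
#'   entries (per-signal normalization).
#' @export
buildModeMatrix <- function(result) {
  stopifnot(is(result, "VMDResult"))
  if (nrow(result@modes) < 1L) stop("result has no modes")
  S <- result@modes
  new("ModeMatrix", S = S, sMax = max(S), sMin = min(S))
}

#' Map mode-matrix entries to pixel coordinates
#'
#' Vertex m of polyline l sits at
#' \code{x = originX + (m - 1) * drawWidth / (M - 1)} and
#' \code{y = originY + (drawTop - originY) * (sMax - S[m, l]) / (sMax - sMin)}
#' (y image-down: the matrix maximum maps to the origin row, the minimum to
#' the top bound). Coordinates are rounded to the nearest integer pixel.
#' When \code{sMax == sMin} every y is the origin row.
#'
#' @param matrix a [ModeMatrix-class] with M >= 2 rows (the x mapping is
#'   undefined for a single mode).
#' @param config an [EncoderConfig-class].
#' @return List of L matrices, each M x 2 with columns \code{x}, \code{y}.
#' @export
mapCoordinates <- function(matrix, config = encoderConfig()) {
  stopifnot(is(matrix, "ModeMatrix"))
  geom <- coordinateGeometry(matrix, config)
  lapply(seq_len(ncol(geom$Y)), function(l)
    cbind(x = geom$x, y = geom$Y[, l]))
}

## shared coordinate computation: x per mode (length M), Y as M x L matrix
coordinateGeometry <- function(matrix, config) {
  S <- matrix@S
  M <- nrow(S)
  if (M < 2L) stop("M = 1: the x mapping is undefined for a single mode")
  x <- round(config@originX +
               (seq_len(M) - 1) * config@drawWidth / (M - 1))
  if (matrix@sMax == matrix@sMin) {
    Y <- base::matrix(as.numeric(config@originY), nrow = M, ncol = ncol(S))
  } else {
    Y <- config@originY + (config@drawTop - config@originY) *
      (matrix@sMax - S) / (matrix@sMax - matrix@sMin)
  }
  list(x = as.integer(x), Y = round(Y))
}

## palette index of polyline l: colors cycle with period B
polylineColors <- function(L, config) {
  ((seq_len(L) - 1L) %% config@nColors) + 1L
}

## pixel coordinates of one straight segment. No anti-aliasing: the segment
## is sampled at max(|dx|, |dy|) + 1 evenly spaced points rounded to pixels;
## stroke width extends downward (rows y .. y + lineWidth - 1).
segmentPoints <- function(x0, y0, x1, y1, lineWidth) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
  xs <- as.integer(round(seq(x0, x1, length.out = n)))
  ys <- as.integer(round(seq(y0, y1, length.out = n)))
  if (lineWidth > 1L) {
    off <- rep(0L:(lineWidth - 1L), each = n)
    xs <- rep.int(xs, lineWidth)
    ys <- rep.int(ys, lineWidth) + off
  }
  list(x = xs, y = ys)
}

#' Render a mode matrix as a color-cycled polyline image
#'
#' Draws the L polylines in order l = 1..L onto a white canvas (or a copy
#' of \code{background}), polyline l in palette color
#' \code{((l - 1) mod B) + 1}; each polyline connects its M vertices with
#' M - 1 straight segments, later polylines over-painting earlier ones.
#' Rendering is deterministic (nearest-pixel rounding, no anti-aliasing).
#'
#' @param matrix a [ModeMatrix-class].
#' @param config an [EncoderConfig-class].
#' @param background optional [EncodedImage-class] used as the canvas.
#' @param label class label carried on the output image.
#' @return An [EncodedImage-class] of exactly
#'   \code{imageHeight x imageWidth} pixels.
#' @export
renderImage <- function(matrix, config = encoderConfig(),
                        background = NULL, label = NA) {
  stopifnot(is(matrix, "ModeMatrix"))
  validObject(config)
  if (is.null(background)) {
    canvas <- array(255L, dim = c(config@imageHeight, config@imageWidth, 3L))
  } else {
    stopifnot(is(background, "EncodedImage"))
    d <- dim(background@pixels)
    if (d[1] != config@imageHeight || d[2] != config@imageWidth)
      stop("background dimensions do not match the encoder config")
    canvas <- background@pixels
  }
  geom <- coordinateGeometry(matrix, config)
  L <- ncol(geom$Y)
  M <- length(geom$x)
  pal <- grDevices::col2rgb(config@palette)   # 3 x B integer
  cols <- polylineColors(L, config)
  ## gather every segment's pixels in draw order (polyline l ascending,
  ## segment m ascending within it), then paint with three bulk
  ## assignments; R assigns duplicated indices sequentially, so the
  ## last-drawn polyline wins on overlap exactly as in per-segment drawing
  nSeg <- L * (M - 1L)
  px <- vector("list", nSeg)
  py <- vector("list", nSeg)
  pc <- integer(nSeg)
  s <- 0L
  for (l in seq_len(L)) {
    for (m in seq_len(M - 1L)) {
      s <- s + 1L
      pts <- segmentPoints(geom$x[m], geom$Y[m, l],
                           geom$x[m + 1L], geom$Y[m + 1L, l],
                           config@lineWidth)
      px[[s]] <- pts$x
      py[[s]] <- pts$y
      pc[s] <- cols[l]
    }
  }
  xs <- unlist(px, use.names = FALSE)
  ys <- unlist(py, use.names = FALSE)
  ci <- rep.int(pc, lengths(px))
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  keep <- xs >= 1L & xs <= w & ys >= 1L & ys <= h
  if (!all(keep)) { xs <- xs[keep]; ys <- ys[keep]; ci <- ci[keep] }
  lin <- ys + (xs - 1L) * h
  plane <- h * w
  canvas[lin] <- pal[1L, ci]
  canvas[lin + plane] <- pal[2L, ci]
  canvas[lin + 2L * plane] <- pal[3L, ci]
  new("EncodedImage", pixels = canvas, label = as.integer(label))
}

#' Build the shared background canvas
#'
#' Decomposes each reserved record, builds its mode matrix (per-record
#' normalization), and renders its polylines onto one accumulating canvas
#' in record order. The background is a pure function of the reserved
#' records and the configurations.
#'
#' @param records non-empty list of [UltrasoundRecord-class] objects.
#' @param vmdConfig a [VMDConfig-class].
#' @param config an [EncoderConfig-class].
#' @return An [EncodedImage-class] (unlabeled).
#' @export
buildBackground <- function(records, vmdConfig = vmdConfig(),
                            config = encoderConfig()) {
  if (length(records) == 0L) stop("background requires >= 1 record")
  canvas <- NULL
  for (rec in records) {
    mm <- buildModeMatrix(vmdDecompose(rec@amplitudes, vmdConfig))
    canvas <- renderImage(mm, config, background = canvas)
  }
  canvas
}

## resize an integer RGB array to size x size. Downscaling uses box-filter
## (area) averaging so that thin polylines contribute their coverage
## fraction instead of being skipped by point sampling; upscaling uses
## bilinear interpolation. Returns an integer 0..255 array.
resizeRaster <- function(pixels, size) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  out <- array(0L, dim = c(size, size, 3L))
  if (size < h && size < w) {
    ## area average via integral images
    yb <- floor(seq(0, h, length.out = size + 1))
    xb <- floor(seq(0, w, length.out = size + 1))
    y0 <- yb[seq_len(size)]; y1 <- yb[seq_len(size) + 1L]
    x0 <- xb[seq_len(size)]; x1 <- xb[seq_len(size) + 1L]
    sc <- outer(y1 - y0, x1 - x0)
    for (ch in 1:3) {
      I <- matrix(0, h + 1L, w + 1L)
      I[-1, -1] <- t(apply(apply(pixels[, , ch], 2, cumsum), 1, cumsum))
      out[, , ch] <- as.integer(round(
        (I[cbind(rep(y1 + 1L, size), rep(x1 + 1L, each = size))] -
         I[cbind(rep(y0 + 1L, size), rep(x1 + 1L, each = size))] -
         I[cbind(rep(y1 + 1L, size), rep(x0 + 1L, each = size))] +
         I[cbind(rep(y0 + 1L, size), rep(x0 + 1L, each = size))]) / sc))
    }
  } else {
    ## bilinear at target pixel centers
    sy <- (seq_len(size) - 0.5) * h / size + 0.5
    sx <- (seq_len(size) - 0.5) * w / size + 0.5
    y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
    x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
    wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
    for (ch in 1:3) {
      p <- pixels[, , ch]
      top <- p[y0, x0] * outer(1 - wy, 1 - wx) +
        p[y0, x1] * outer(1 - wy, wx)
      bot <- p[y1, x0] * outer(wy, 1 - wx) + p[y1, x1] * outer(wy, wx)
      out[, , ch] <- as.integer(round(top + bot))
    }
  }
  out
}

#' Resize an encoded image
#'
#' Bilinear interpolation to a square raster, as used to feed the
#' classifier.
#'
#' @param image an [EncodedImage-class].
#' @param size output side length in pixels.
#' @return An [EncodedImage-class] of \code{size x size} pixels carrying
#'   the same label.
#' @export
resizeImage <- function(image, size) {
  stopifnot(is(image, "EncodedImage"))
  new("EncodedImage", pixels = resizeRaster(image@pixels, as.integer(size)),
      label = image@label)
}

#' Encode a labeled dataset of waveforms into images
#'
#' Reserves a seeded random selection of \code{nBackgroundPerClass} records
#' per class, builds the shared background from them ([buildBackground()]),
#' and encodes every remaining record onto a copy of that background. The
#' study protocol reserves 30 + 30 of 296 + 304 records, yielding 266
#' intact-class and 274 crack-class images.
#'
#' @param records list of labeled [UltrasoundRecord-class] objects (labels
#'   0 and 1 both present, each class larger than the reservation).
#' @param vmdConfig a [VMDConfig-class].
#' @param encoderConfig an [EncoderConfig-class].
#' @param nBackgroundPerClass records reserved per class (default 30; 0
#'   encodes everything on a white canvas).
#' @param seed seed of the reservation draw.
#' @param outputSize optional side length: when set, returned images are
#'   bilinearly resized (the full-resolution rasters are not kept, which
#'   bounds memory on large datasets).
#' @return List with elements \code{background} ([EncodedImage-class] or
#'   NULL when nothing is reserved), \code{images} (list of labeled
#'   [EncodedImage-class]), and \code{backgroundIndex} (indices of the
#'   reserved records in \code{records}).
#' @export
encodeDataset <- function(records, vmdConfig = vmdConfig(),
                          encoderConfig = encoderConfig(),
                          nBackgroundPerClass = 30, seed = 1,
                          outputSize = NULL) {
  labels <- vapply(records, function(r) r@label, integer(1))
  if (anyNA(labels)) stop("all records must be labeled")
  idxIntact <- which(labels == 1L)
  idxCrack <- which(labels == 0L)
  nb <- as.integer(nBackgroundPerClass)
  if (nb > 0L && (length(idxIntact) <= nb || length(idxCrack) <= nb))
    stop("each class must have more than nBackgroundPerClass records")
  reserved <- integer(0)
  if (nb > 0L) {
    reserved <- withSeed(deriveSeed(seed, 101), {
      sort(c(sample(idxIntact, nb), sample(idxCrack, nb)))
    })
  }
  background <- if (length(reserved))
    buildBackground(records[reserved], vmdConfig, encoderConfig) else NULL
  remaining <- setdiff(seq_along(records), reserved)
  images <- vector("list", length(remaining))
  for (i in seq_along(remaining)) {
    rec <- records[[remaining[i]]]
    mm <- buildModeMatrix(vmdDecompose(rec@amplitudes, vmdConfig))
    img <- renderImage(mm, encoderConfig, background = background,
                       label = rec@label)
    if (!is.null(outputSize)) img <- resizeImage(img, outputSize)
    images[[i]] <- img
  }
  list(background = background, images = images, backgroundIndex = reserved)
}

#' Write an encoded image as PNG
#'
#' @param image an [EncodedImage-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeImagePng <- function(image, path) {
  stopifnot(is(image, "EncodedImage"))
  png::writePNG(image@pixels / 255, target = path)
  invisible(path)
}
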