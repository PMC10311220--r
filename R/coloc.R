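## Grayscale morphology with a ball-topped (non-flat) structuring element.
## shiftMat moves a matrix by (dr, dc), filling vacated cells.
shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

ballOffsets <- function(diameter) {
  r <- (diameter - 1) / 2
  g <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= r^2
  # ball height: a sphere cap of the same radius, in intensity units
  data.frame(dr = g$dr[keep], dc = g$dc[keep],
             h = sqrt(r^2 - d2[keep]))
}

grayErodeBall <- function(img, off) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off))) {
    out <- pmin(out, shiftMat(img, off$dr[k], off$dc[k], Inf) - off$h[k])
  }
  out
}

grayDilateBall <- function(img, off) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off))) {
    out <- pmax(out, shiftMat(img, off$dr[k], off$dc[k], -Inf) + off$h[k])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (spherical-cap) structuring element of the given diameter —
#' the ball "rolls" under the intensity surface, following broad variations
#' while unable to enter features narrower than itself — and subtracts it.
#' A flat-disc opening variant is available behind `flat = TRUE`.
#'
#' @param image 2D numeric intensity matrix.
#' @param ballDiameter ball diameter in pixels (default 25, minimum 3).
#' @param flat use a flat disc instead of the ball-topped element.
#' @return background-subtracted image, same shape, all values >= 0.
#' @examples
#' img <- matrix(10, 32, 32); img[16, 16] <- 200
#' bs <- subtractBackground(img, 7)
#' bs[16, 16]  # bright pixel keeps its excess over background
#' @export
subtractBackground <- function(image, ballDiameter = 25, flat = FALSE) {
  if (length(dim(image)) != 2L) stopf("image must be a 2D matrix")
  if (ballDiameter < 3) stopf("ballDiameter must be >= 3")
  off <- ballOffsets(ballDiameter)
  if (flat) off$h <- 0
  bg <- grayDilateBall(grayErodeBall(image, off), off)
  bg <- pmin(bg, image)  # opening is anti-extensive; guard edge fills
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Signal masks for the two channels
#'
#' Marks "signal" pixels per channel, either by a per-channel Otsu threshold
#' (default) or by fixed thresholds (a pixel is signal when its intensity is
#' strictly greater than the threshold). Input images are expected to be
#' background-subtracted.
#'
#' @param pair an [ImagePair-class].
#' @param params a [colocParams()] block.
#' @return a list with logical matrices `maskA` and `maskB`.
#' @export
signalMasks <- function(pair, params = colocParams()) {
  mk <- function(ch, thr_fixed) {
    if (params$maskMethod == "fixed") {
      ch > thr_fixed
    } else {
      rng <- range(ch)
      if (rng[1] == rng[2]) {
        stopf("otsu thresholding needs a non-constant image")
      }
      thr <- EBImage::otsu(EBImage::Image(ch), range = rng, levels = 256L)
      ch > thr
    }
  }
  list(maskA = mk(channelA(pair), params$fixedThresholdA),
       maskB = mk(channelB(pair), params$fixedThresholdB))
}

#' Mander's overlap coefficients (area form)
#'
#' M1 is the fraction of channel-A signal pixels that co-occur with
#' channel-B signal; M2 the converse. These are area ratios over binary
#' masks, not intensity-weighted sums.
#'
#' @param maskA,maskB logical matrices of identical shape.
#' @return list with `M1`, `M2` (NA when the respective mask is empty) and
#'   counts `nA`, `nB`, `nOverlap`.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' manders(a, a)  # M1 = M2 = 1
#' @export
manders <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stopf("masks must share a shape")
  nA <- sum(maskA); nB <- sum(maskB); nAB <- sum(maskA & maskB)
  list(M1 = if (nA > 0) nAB / nA else NA_real_,
       M2 = if (nB > 0) nAB / nB else NA_real_,
       nA = nA, nB = nB, nOverlap = nAB)
}

#' Pearson correlation over all pixels
#'
#' @param pair an [ImagePair-class]; both channels must be non-constant.
#' @return the product-moment correlation of the two channels' intensities
#'   (NA when either channel is constant).
#' @export
pearsonColoc <- function(pair) {
  a <- as.numeric(channelA(pair)); b <- as.numeric(channelB(pair))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

## top-fraction pixel selection; intensity ties broken by stable pixel
## (column-major) order so the selected count is deterministic
topMask <- function(ch, fraction) {
  n <- length(ch)
  k <- round(fraction * n)
  if (k < 1) stopf("topFraction selects zero pixels")
  ord <- order(as.numeric(ch), seq_len(n), decreasing = TRUE)
  m <- matrix(FALSE, nrow(ch), ncol(ch))
  m[ord[seq_len(k)]] <- TRUE
  m
}

#' Threshold overlap score
#'
#' Selects the top `topFraction` of pixels by intensity in each channel and
#' scores their co-occurrence against the independence expectation
#' `e = nA * nB / N`, rescaled to `[-1, 1]`:
#' `(nAB - e) / (min(nA, nB) - e)` when `nAB >= e`, otherwise
#' `(nAB - e) / (e - max(0, nA + nB - N))`. +1 means the top pixels
#' co-occur maximally, 0 independence, -1 maximal mutual exclusion.
#'
#' @param pair an [ImagePair-class].
#' @param params a [colocParams()] block (`topFraction`, default 0.10).
#' @return the score, a single number in `[-1, 1]`.
#' @export
thresholdOverlapScore <- function(pair, params = colocParams()) {
  a <- channelA(pair); b <- channelB(pair)
  N <- length(a)
  mA <- topMask(a, params$topFraction)
  mB <- topMask(b, params$topFraction)
  nA <- sum(mA); nB <- sum(mB); nAB <- sum(mA & mB)
  e <- nA * nB / N
  if (nAB >= e) {
    den <- min(nA, nB) - e
    if (den == 0) return(if (nAB == e) 0 else 1)
    (nAB - e) / den
  } else {
    den <- e - max(0, nA + nB - N)
    if (den == 0) return(0)
    (nAB - e) / den
  }
}

#' Full colocalization analysis of an image pair
#'
#' Runs the whole chain: rolling-ball background subtraction on each
#' channel, signal masks, Mander's M1/M2, Pearson correlation over all
#' pixels and the threshold overlap score over the top-intensity pixels.
#'
#' @param pair an [ImagePair-class] of raw intensities.
#' @param params a [colocParams()] block.
#' @param subtract apply background subtraction before all scores (default
#'   TRUE); set FALSE when the images are already background-corrected.
#' @return a list of class `"ColocResult"`: `M1`, `M2`, `PCC`, `TOS`,
#'   `nPixelsA`, `nPixelsB`, `nOverlap`.
#' @examples
#' sim <- genImagePair(imagePairSpec(shape = c(32, 32), nSignalA = 40,
#'                                   nSignalB = 40, overlapFraction = 0.5))
#' res <- colocalize(sim$pair, colocParams(maskMethod = "fixed",
#'                   fixedThresholdA = 50, fixedThresholdB = 50),
#'                   subtract = FALSE)
#' c(res$M1, res$M2)
#' @export
colocalize <- function(pair, params = colocParams(), subtract = TRUE) {
  if (subtract) {
    pair <- ImagePair(
      subtractBackground(channelA(pair), params$ballDiameter),
      subtractBackground(channelB(pair), params$ballDiameter),
      pair@pixelSize)
  }
  masks <- signalMasks(pair, params)
  m <- manders(masks$maskA, masks$maskB)
  structure(list(
    M1 = m$M1, M2 = m$M2,
    PCC = pearsonColoc(pair),
    TOS = thresholdOverlapScore(pair, params),
    nPixelsA = m$nA, nPixelsB = m$nB, nOverlap = m$nOverlap
  ), class = "ColocResult")
}
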