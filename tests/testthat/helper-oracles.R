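# Independent oracles used by the property tests. These are deliberately
# naive (enumeration, dense sampling) and share no code with the package's
# implementations.

# Brute-force burst finder: enumerate every contiguous spike window whose
# first ISI is <= isiInit and whose remaining ISIs are <= isiContinue, keep
# the maximal ones (not contained in another satisfying window), then drop
# windows below the spike-count floor.
bruteForceBursts <- function(times, params = burstParams()) {
  n <- length(times)
  wins <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        isis <- diff(times[i:j])
        if (isis[1] <= params$isiInit &&
            all(isis[-1] <= params$isiContinue)) {
          wins[[length(wins) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (!length(wins)) return(matrix(numeric(0), 0, 2))
  w <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(w)), function(k) {
    !any(w[, 1] <= w[k, 1] & w[, 2] >= w[k, 2] &
           (w[, 1] != w[k, 1] | w[, 2] != w[k, 2]))
  }, TRUE)
  w <- w[maximal, , drop = FALSE]
  w[w[, 2] - w[, 1] + 1 >= params$minSpikes, , drop = FALSE]
}

# Dense-sampling Sholl oracle: walk every edge in arc-length steps of `ds`
# micrometres and count sign changes of (distance to soma - radius).
denseShollOracle <- function(arbor, radii, ds = 0.01) {
  nd <- arborNodes(arbor)
  soma <- nd[nd$id == somaId(arbor), ]
  idx <- match(nd$parent, nd$id)
  child <- which(nd$parent != -1)
  counts <- integer(length(radii))
  for (k in child) {
    p <- idx[k]
    len <- sqrt((nd$x[k] - nd$x[p])^2 + (nd$y[k] - nd$y[p])^2 +
                  (nd$z[k] - nd$z[p])^2)
    if (len == 0) next
    t <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
    d <- sqrt((nd$x[p] + t * (nd$x[k] - nd$x[p]) - soma$x)^2 +
                (nd$y[p] + t * (nd$y[k] - nd$y[p]) - soma$y)^2 +
                (nd$z[p] + t * (nd$z[k] - nd$z[p]) - soma$z)^2)
    for (ri in seq_along(radii)) {
      s <- sign(d - radii[ri])
      s <- s[s != 0]  # a grid point exactly on the circle is one crossing
      counts[ri] <- counts[ri] + sum(diff(s) != 0)
    }
  }
  counts
}

# Naive grayscale opening with a ball-topped structuring element, straight
# from the definition: per-pixel min (erosion, subtracting the ball height)
# then per-pixel max (dilation, adding it), offsets outside the image
# skipped.
naiveBallOpening <- function(img, diameter) {
  r <- (diameter - 1) / 2
  off <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  off$h <- sqrt(r^2 - off$dr^2 - off$dc^2)
  nr <- nrow(img); nc <- ncol(img)
  apply_op <- function(m, op, sgn) {
    out <- matrix(NA_real_, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      ii <- i + off$dr; jj <- j + off$dc
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- op(m[cbind(ii[ok], jj[ok])] + sgn * off$h[ok])
    }
    out
  }
  apply_op(apply_op(img, min, -1), max, +1)
}

# random spike train with ISIs straddling the burst-rule thresholds
randomTrain <- function(n, seed) {
  set.seed(seed)
  isis <- stats::runif(n - 1, 0.005, 0.4)
  times <- cumsum(c(stats::runif(1, 0, 0.2), isis))
  SpikeTrain(times, duration = max(times) + 1)
}
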