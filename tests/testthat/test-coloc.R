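test_that("rolling-ball subtraction removes background, keeps features", {
  # flat field is pure background
  expect_equal(max(abs(subtractBackground(matrix(50, 40, 40), 25))), 0)

  # a single bright pixel is narrower than the ball: excess preserved
  img <- matrix(10, 40, 40); img[20, 20] <- 210
  bs <- subtractBackground(img, 25)
  expect_gte(bs[20, 20], 0.95 * 200)

  # a blob much broader than the ball is flattened into the background
  g <- outer(1:80, 1:80, function(i, j) {
    100 * exp(-((i - 40)^2 + (j - 40)^2) / (2 * 30^2))
  })
  expect_lt(max(subtractBackground(g, 25)), 0.10 * 100)

  # oracle comparison: the estimated background equals a naive per-pixel
  # grayscale opening computed straight from the definition
  set.seed(8)
  noise <- matrix(runif(900, 0, 50), 30, 30)
  ours <- noise - subtractBackground(noise, 9)
  expect_equal(ours, pmin(naiveBallOpening(noise, 9), noise),
               tolerance = 1e-12)
  expect_true(all(subtractBackground(noise, 9) >= 0))

  expect_error(subtractBackground(array(0, c(2, 2, 2)), 25), "2D")
})

test_that("signal masks honour fixed and Otsu thresholding", {
  img <- matrix(c(0, 50, 0, 50), 2)
  pair <- ImagePair(img, img)
  p <- colocParams(maskMethod = "fixed", fixedThresholdA = 10,
                   fixedThresholdB = 10)
  m <- signalMasks(pair, p)
  expect_identical(m$maskA, img == 50)

  # threshold above the maximum: empty mask
  p2 <- colocParams(maskMethod = "fixed", fixedThresholdA = 100,
                    fixedThresholdB = 100)
  expect_equal(sum(signalMasks(pair, p2)$maskA), 0)

  # bimodal image under Otsu recovers the true mode assignment
  sim <- genImagePair(imagePairSpec(shape = c(64, 64), nSignalA = 400,
                                    nSignalB = 400, overlapFraction = 0.5,
                                    fgIntensity = 200, bgIntensity = 10,
                                    noiseSigma = 5, seed = 12))
  mo <- signalMasks(sim$pair, colocParams(maskMethod = "otsu"))
  agree <- mean(mo$maskA == sim$maskA)
  expect_gte(agree, 0.999)

  expect_error(signalMasks(ImagePair(matrix(1, 4, 4), matrix(1, 4, 4)),
                           colocParams(maskMethod = "otsu")),
               "non-constant")
  expect_error(colocParams(maskMethod = "fixed"), "fixed")
})

test_that("Mander's coefficients are the stated area ratios", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(manders(a, a)[c("M1", "M2")], list(M1 = 1, M2 = 1))

  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(manders(a, b)[c("M1", "M2")], list(M1 = 0, M2 = 0))

  # |a| = 100, |b| = 200, overlap 25
  b2 <- matrix(FALSE, 20, 20); b2[1:5, 1:5] <- TRUE; b2[11:20, 3:20] <- TRUE
  expect_equal(sum(b2), 205)  # trim to exactly 200
  b2[11:15, 3] <- FALSE
  m <- manders(a, b2)
  expect_equal(m$nA, 100); expect_equal(m$nB, 200)
  expect_equal(m$M1, m$nOverlap / 100)
  expect_equal(m$M2, m$nOverlap / 200)

  # empty mask: undefined, not zero
  none <- matrix(FALSE, 20, 20)
  expect_true(is.na(manders(none, a)$M1))
  expect_error(manders(a, matrix(FALSE, 5, 5)), "shape")

  # symmetry: swapping the channels swaps M1 and M2
  m_ab <- manders(a, b2); m_ba <- manders(b2, a)
  expect_equal(m_ab$M1, m_ba$M2)
  expect_equal(m_ab$M2, m_ba$M1)
})

test_that("Pearson correlation behaves on constructed channels", {
  set.seed(13)
  x <- matrix(runif(10000, 0, 100), 100, 100)
  expect_equal(pearsonColoc(ImagePair(x, x)), 1)
  expect_equal(pearsonColoc(ImagePair(x, 100 - x)), -1)

  # independent channels: correlation within the sampling bound
  y <- matrix(runif(10000, 0, 100), 100, 100)
  expect_lt(abs(pearsonColoc(ImagePair(x, y))), 0.05)

  # invariance under positive affine rescaling
  expect_equal(pearsonColoc(ImagePair(2 * x + 5, y)),
               pearsonColoc(ImagePair(x, y)))

  expect_true(is.na(pearsonColoc(ImagePair(matrix(1, 4, 4), x[1:4, 1:4]))))
})

test_that("threshold overlap score spans its extremes and centre", {
  set.seed(14)
  x <- matrix(runif(10000, 0, 100), 100, 100)
  expect_equal(thresholdOverlapScore(ImagePair(x, x)), 1)

  # maximal mutual exclusion of the top decile: score -1
  a <- matrix(0, 100, 100); a[, 1:10] <- matrix(runif(1000, 50, 100), 100)
  b <- matrix(0, 100, 100); b[, 91:100] <- matrix(runif(1000, 50, 100), 100)
  expect_equal(thresholdOverlapScore(ImagePair(a, b)), -1)

  # independent channels concentrate near the independence expectation
  y <- matrix(runif(10000, 0, 100), 100, 100)
  expect_lt(abs(thresholdOverlapScore(ImagePair(x, y))), 0.1)

  expect_error(
    thresholdOverlapScore(ImagePair(x[1:3, 1:3, drop = FALSE],
                                    y[1:3, 1:3, drop = FALSE]),
                          colocParams(topFraction = 0.01)),
    "zero")
})

test_that("TOS is non-decreasing in the co-occurrence count", {
  # brute force over all feasible nAB at small N, via the score formula
  # applied to constructed masks of fixed sizes
  N <- 100; nA <- 20; nB <- 30
  e <- nA * nB / N
  tosOf <- function(nAB) {
    if (nAB >= e) (nAB - e) / (min(nA, nB) - e)
    else (nAB - e) / (e - max(0, nA + nB - N))
  }
  vals <- vapply(0:20, tosOf, 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[1], -1)   # nAB = 0 with nA + nB <= N
  expect_equal(vals[21], 1)   # nAB = min(nA, nB)
})

test_that("colocalization is exact on constructed pairs", {
  overlaps <- rep(seq(0, 1, 0.1), length.out = 100)
  for (k in seq_len(100)) {
    spec <- imagePairSpec(shape = c(48, 48), nSignalA = 80,
                          nSignalB = 80 + 10 * (k %% 5),
                          overlapFraction = overlaps[k],
                          fgIntensity = 200, bgIntensity = 10,
                          noiseSigma = 0, seed = k)
    sim <- genImagePair(spec)
    res <- colocalize(sim$pair,
                      colocParams(maskMethod = "fixed",
                                  fixedThresholdA = 50,
                                  fixedThresholdB = 50),
                      subtract = FALSE)
    expect_identical(res$M1, sim$truth$trueM1)
    expect_identical(res$M2, sim$truth$trueM2)
  }
})
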