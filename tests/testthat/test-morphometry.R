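straightArbor <- function(len = 100) {
  Arbor(data.frame(id = 1:2, type = c(1, 5), x = c(0, len), y = 0, z = 0,
                   radius = 1, parent = c(-1, 1)))
}

test_that("Sholl crossings match exact geometry on simple arbors", {
  # single straight 100 um process
  p <- shollProfile(straightArbor(100), shollParams(step = 10, rMax = 120))
  expect_equal(p$radius, seq(10, 120, 10))
  expect_equal(p$crossings[p$radius <= 90], rep(1L, 9))
  expect_equal(p$crossings[p$radius > 100], c(0L, 0L))

  # Y-tree bifurcating at 50 um, daughters reaching past 90 um
  th <- pi / 6
  nd <- data.frame(
    id = 1:4, type = c(1, 5, 5, 5),
    x = c(0, 50, 50 + 50 * cos(th), 50 + 50 * cos(th)),
    y = c(0, 0, 50 * sin(th), -50 * sin(th)),
    z = 0, radius = 1, parent = c(-1, 1, 2, 2))
  py <- shollProfile(Arbor(nd), shollParams(step = 10, rMax = 90))
  expect_equal(py$crossings[py$radius < 50], rep(1L, 4))
  expect_equal(py$crossings[py$radius > 50], rep(2L, 4))

  # soma-only arbor: an all-zero profile, not an error
  lone <- Arbor(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                           radius = 1, parent = -1))
  p0 <- shollProfile(lone, shollParams(step = 5, rMax = 20))
  expect_true(all(p0$crossings == 0))
})

test_that("exact Sholl equals the dense-sampling oracle on random arbors", {
  for (seed in 1:50) {
    sim <- genArbor(arborSpec(nMainBranches = 2 + seed %% 4,
                              junctionsPerBranch = seed %% 3,
                              segmentLength = 12 + (seed %% 5) * 4,
                              branchAngleSpread = 25, seed = seed))
    prof <- shollProfile(sim$arbor, shollParams(step = 7.3))
    oracle <- denseShollOracle(sim$arbor, prof$radius, ds = 0.01)
    expect_equal(prof$crossings, oracle,
                 info = paste("seed", seed))
  }
})

test_that("morphometrics follow the stated branch and junction rules", {
  # single unbranched 50 um process
  m1 <- branchMorphometrics(straightArbor(50))
  expect_equal(m1$nMainBranches, 1L)
  expect_equal(m1$longestMainBranch, 50)
  expect_equal(m1$nJunctions, 0L)
  expect_equal(m1$totalProcessLength, 50)

  # branch A: 100 um trunk, 20 um side branch at its midpoint;
  # branch B: 30 um unbranched; stub C: 3 um unbranched
  nd <- data.frame(
    id = 1:6, type = c(1, 5, 5, 5, 5, 5),
    x = c(0, 50, 100, 50, -30, 0),
    y = c(0, 0, 0, 20, 0, 3),
    z = 0, radius = 1, parent = c(-1, 1, 2, 2, 1, 1))
  m <- branchMorphometrics(Arbor(nd))
  expect_equal(m$nMainBranches, 2L)        # stub C excluded
  expect_equal(m$nJunctions, 1L)
  expect_equal(m$longestMainBranch, 100)
  expect_equal(m$totalProcessLength, 153)

  # a 3 um side branch does not make its node a junction
  nd2 <- nd[1:4, ]; nd2$y[4] <- 3
  m2 <- branchMorphometrics(Arbor(nd2))
  expect_equal(m2$nJunctions, 0L)
  expect_equal(m2$nMainBranches, 1L)
})

test_that("morphometrics round-trip generator truth with filter edges", {
  for (seed in 1:100) {
    stubs <- if (seed %% 2 == 0) c(4.9, 5.1) else numeric(0)
    spec <- arborSpec(nMainBranches = 2 + seed %% 5,
                      junctionsPerBranch = 1 + seed %% 3,
                      segmentLength = 15 + (seed %% 4) * 5,
                      branchAngleSpread = 20,
                      stubLengths = stubs, seed = seed)
    sim <- genArbor(spec)
    m <- branchMorphometrics(sim$arbor)
    expect_equal(m$nMainBranches, sim$truth$nMainBranches)
    expect_equal(m$nJunctions, sim$truth$nJunctions)
    expect_equal(m$longestMainBranch, sim$truth$longestMainBranch,
                 tolerance = 1e-9)
    expect_equal(m$totalProcessLength, sim$truth$totalProcessLength,
                 tolerance = 1e-9)
  }
})

test_that("profiles and morphometrics are rigid-motion invariant", {
  sim <- genArbor(arborSpec(nMainBranches = 4, junctionsPerBranch = 2,
                            seed = 33))
  nd <- arborNodes(sim$arbor)
  th <- 0.7; dx <- 123.4; dy <- -56.7
  rot <- nd
  rot$x <- cos(th) * nd$x - sin(th) * nd$y + dx
  rot$y <- sin(th) * nd$x + cos(th) * nd$y + dy
  moved <- Arbor(rot)
  p1 <- shollProfile(sim$arbor, shollParams(step = 6))
  p2 <- shollProfile(moved, shollParams(step = 6))
  expect_equal(p1$crossings, p2$crossings)
  m1 <- branchMorphometrics(sim$arbor)
  m2 <- branchMorphometrics(moved)
  expect_equal(unlist(m1), unlist(m2), tolerance = 1e-9)
})

test_that("SWC files round-trip through read and write", {
  sim <- genArbor(arborSpec(seed = 77))
  f <- tempfile(fileext = ".swc")
  writeSWC(sim$arbor, f)
  back <- readSWC(f)
  expect_equal(arborNodes(back)$x, arborNodes(sim$arbor)$x,
               tolerance = 1e-5)
  expect_equal(somaId(back), somaId(sim$arbor))
  expect_equal(unlist(branchMorphometrics(back)),
               unlist(branchMorphometrics(sim$arbor)), tolerance = 1e-4)
  unlink(f)
})

test_that("zone densities use perimeter distance and analytic areas", {
  zs <- zoneSpec(radius = 250)
  # points at perimeter distances 100, 300, 700
  zd <- zoneDensity(cbind(c(350, 550, 950), 0), zs)
  expect_equal(zd$count, c(1, 1, 0))
  expect_equal(attr(zd, "unassigned"), 1)

  # analytic annulus area for zone 1 at radius 250
  expect_equal(zd$areaMm2[1], pi * (450^2 - 300^2) * 1e-6,
               tolerance = 1e-12)
  expect_equal(zd$densityPerMm2[1], 1 / (pi * (450^2 - 300^2) * 1e-6),
               tolerance = 1e-12)

  # no points: densities zero, areas unchanged
  zd0 <- zoneDensity(matrix(numeric(0), 0, 2), zs)
  expect_equal(zd0$count, c(0, 0, 0))
  expect_equal(zd0$densityPerMm2, c(0, 0, 0))
  expect_equal(zd0$areaMm2, zd$areaMm2)

  # a point inside the aggregate warns and stays unassigned
  expect_warning(zdi <- zoneDensity(cbind(100, 0), zs), "inside")
  expect_equal(attr(zdi, "unassigned"), 1)

  # conservation: band counts plus unassigned equal total points
  set.seed(15)
  pts <- cbind(runif(200, -1200, 1200), runif(200, -1200, 1200))
  zdc <- suppressWarnings(zoneDensity(pts, zs))
  expect_equal(sum(zdc$count) + attr(zdc, "unassigned"), 200)
})
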