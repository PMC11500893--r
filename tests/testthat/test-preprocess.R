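test_that("threshold VOIs behave at the extremes", {
  fx <- suvFixture(array(stats::runif(6^3, 1, 5), c(6, 6, 6)))
  low <- makeVOI(image = fx$image, mode = "threshold", threshold = 0)
  expect_equal(voxelCount(low), 6L^3)
  expect_error(
    makeVOI(image = fx$image, mode = "threshold", threshold = 10),
    "empty VOI")
})

test_that("ground-truth VOI volume matches an independent geometric count", {
  les <- lesionPreset("L1")
  ses <- phantomSession(backgroundActivityMbq = 87.2,
                        acquisitionTimeS = 1730)
  plan <- planTrajectory(les, acquisitionTime = 1730)
  map <- paintGroundTruth(les, plan, ses)
  img <- acquire(map, imagingSettings()[["A"]], ses, seed = 1)
  voi <- makeVOI(les, img)
  # oracle: exact per-voxel covered volume by direct enumeration of
  # (support cell, voxel) interval overlaps — an independent route to the
  # same geometry as the package's separable tensor contraction
  sup <- les@values > 0
  h <- les@gridSpacing
  nT <- dim(sup)
  d <- dim(imageValues(img))
  vs <- imageSpacing(img)
  cT <- (seq_len(nT[1]) - (nT[1] + 1) / 2) * h
  ovAxis <- function(ax) {
    cI <- (seq_len(d[ax]) - (d[ax] + 1) / 2) * vs[ax]
    pmax(outer(cI + vs[ax] / 2, cT + h / 2, pmin) -
           outer(cI - vs[ax] / 2, cT - h / 2, pmax), 0)
  }
  ov <- lapply(1:3, ovAxis)
  idx <- which(sup, arr.ind = TRUE)
  occ <- array(0, d)
  for (q in seq_len(nrow(idx))) {
    a <- which(ov[[1]][, idx[q, 1]] > 0)
    b <- which(ov[[2]][, idx[q, 2]] > 0)
    cc <- which(ov[[3]][, idx[q, 3]] > 0)
    occ[a, b, cc] <- occ[a, b, cc] +
      outer(ov[[1]][a, idx[q, 1]],
            outer(ov[[2]][b, idx[q, 2]], ov[[3]][cc, idx[q, 3]]))
  }
  oracleMask <- occ / prod(vs) >= 0.5
  expect_identical(imageValues(voi), oracleMask)
  # digitization keeps the volume close to the nominal 8.66 mL lesion
  expect_lt(abs(volumeMl(voi) - 8.66) / 8.66, 0.06)
})

test_that("resampling to the native grid is an identity within tolerance", {
  set.seed(7)
  fx <- suvFixture(array(stats::runif(8^3), c(8, 8, 8)), spacing = rep(2, 3))
  out <- resampleImage(fx$image, 2)
  expect_equal(imageValues(out), imageValues(fx$image), tolerance = 1e-6)
})

test_that("uniform images stay uniform under any resampling", {
  fx <- suvFixture(array(3.5, c(10, 10, 10)), spacing = rep(2, 3))
  out <- resampleImage(fx$image, 1.3)
  expect_equal(range(imageValues(out)), c(3.5, 3.5))
})

test_that("linear ramps interpolate exactly in the interior", {
  n <- 11
  ramp <- array(rep(seq_len(n), times = n * n), c(n, n, n))
  fx <- suvFixture(ramp, spacing = rep(2, 3))
  out <- resampleImage(fx$image, 1)
  v <- imageValues(out)
  d <- dim(v)
  # analytic ramp value at the new voxel centres (linear in x, mm scale)
  xNew <- (seq_len(d[1]) - (d[1] + 1) / 2) * 1
  xOld <- (seq_len(n) - (n + 1) / 2) * 2
  expected <- 1 + (xNew - xOld[1]) / 2
  inner <- 3:(d[1] - 2)
  expect_equal(v[inner, 6, 6], expected[inner], tolerance = 1e-10)
})

test_that("FBS discretization follows the floor(I/B)+1 rule", {
  vals <- array(c(0, 0.3125, 1.0, 0.5, 0.1, 2, 0.9, 0.31249), c(8, 1, 1))
  fx <- suvFixture(vals)
  glv <- discretizeFBS(fx$image, fx$voi, B = 0.3125)
  lev <- greyLevels(glv)
  expect_equal(lev[1], 1L)   # I = 0
  expect_equal(lev[2], 2L)   # I = B exactly
  expect_equal(lev[3], 4L)   # I = 1.0: floor(3.2) + 1
  expect_equal(lev[8], 1L)   # just below B
})

test_that("FBN discretization maps extrema to 1 and D", {
  vals <- array(c(0, 8, 4, 2, 6, 7, 1, 3), c(8, 1, 1))
  fx <- suvFixture(vals)
  glv <- discretizeFBN(fx$image, fx$voi, D = 4L)
  lev <- greyLevels(glv)
  expect_equal(lev[1], 1L)   # I = Imin
  expect_equal(lev[2], 4L)   # I = Imax -> D
  expect_equal(lev[3], 3L)   # floor(4 * 4/8) + 1
  glv64 <- discretizeFBN(fx$image, fx$voi, D = 64L)
  expect_equal(max(greyLevels(glv64), na.rm = TRUE), 64L)
})

test_that("FBN is invariant to affine intensity maps; FBS is equivariant", {
  set.seed(21)
  for (rep in 1:5) {
    vals <- array(stats::runif(5^3, 0, 10), c(5, 5, 5))
    fx <- suvFixture(vals)
    fbn1 <- greyLevels(discretizeFBN(fx$image, fx$voi, D = 16L))
    fx2 <- suvFixture(2.5 * vals + 7)
    fbn2 <- greyLevels(discretizeFBN(fx2$image, fx2$voi, D = 16L))
    expect_identical(fbn1, fbn2)
    # FBS: shifting intensities by exactly one bin shifts levels by one
    fbs1 <- greyLevels(discretizeFBS(fx$image, fx$voi, B = 0.5))
    fx3 <- suvFixture(vals + 0.5)
    fbs2 <- greyLevels(discretizeFBS(fx3$image, fx3$voi, B = 0.5))
    expect_identical(fbs2, fbs1 + 1L)
  }
})

test_that("FBN spans exactly 1..D on a ramp with enough distinct values", {
  vals <- array(seq(0, 10, length.out = 6^3), c(6, 6, 6))
  fx <- suvFixture(vals)
  glv <- discretizeFBN(fx$image, fx$voi, D = 64L)
  lev <- greyLevels(glv)
  expect_equal(range(lev, na.rm = TRUE), c(1L, 64L))
})

test_that("degenerate constant VOIs warn and clamp", {
  fx <- suvFixture(array(2, c(3, 3, 3)))
  expect_warning(glv <- discretizeFBN(fx$image, fx$voi, D = 8L),
                 "degenerate")
  expect_true(all(greyLevels(glv) == 1L))
  fxn <- suvFixture(array(c(-0.2, stats::runif(26)), c(3, 3, 3)))
  expect_warning(discretizeFBS(fxn$image, fxn$voi), "clamped")
})
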