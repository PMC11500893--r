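test_that("the registry holds the eight settings with their voxel sizes", {
  st <- imagingSettings()
  expect_identical(names(st), LETTERS[1:8])
  expect_equal(st[["A"]]@voxelSize, rep(2.67, 3))
  expect_equal(st[["B"]]@voxelSize, c(4, 4, 3))
  expect_equal(st[["C"]]@voxelSize, rep(3, 3))
  expect_equal(st[["D"]]@voxelSize, rep(2.73, 3))
  expect_equal(st[["E"]]@voxelSize, rep(3.64, 3))
  expect_equal(st[["F"]]@voxelSize, rep(4, 3))
  expect_equal(st[["G"]]@voxelSize, rep(2.73, 3))
  expect_equal(st[["H"]]@voxelSize, rep(2.73, 3))
})

test_that("zero-activity truth renders to an all-zero image", {
  ses <- phantomSession()
  map <- new("ActivityMap", values = array(0, c(30, 30, 30)),
             spacing = rep(1, 3), origin = rep(-14.5, 3),
             session = ses, lesionName = "zero")
  st <- imagingSettings()[["C"]]
  img <- acquire(map, st, ses, seed = 1)
  expect_true(all(imageValues(img) == 0))
})

test_that("uniform truth with zero noise gives the analytic uniform SUV", {
  ses <- phantomSession(tankVolumeL = 15, backgroundActivityMbq = 88.5,
                        sourceActivityMbq = 1.1)
  conc <- 4.2
  map <- new("ActivityMap", values = array(conc, c(40, 40, 40)),
             spacing = rep(1, 3), origin = rep(-19.5, 3),
             session = ses, lesionName = "flat")
  st <- new("ImagingSetting", code = "X", scannerName = "test",
            voxelSize = rep(2, 3), psfFwhm = 5, postfilterFwhm = 4,
            noiseScale = 0)
  img <- acquire(map, st, ses, seed = 1)
  suvExpected <- conc * (15 * 1000) / ((88.5 + 1.1) * 1000)
  v <- imageValues(img)
  inner <- v[5:16, 5:16, 5:16]
  expect_equal(mean(inner), suvExpected, tolerance = 1e-6)
  expect_lt(stats::sd(inner), 1e-9)
})

test_that("a point source renders with the combined PSF/post-filter width", {
  ses <- phantomSession(backgroundActivityMbq = 1e-9)
  vals <- array(0, c(61, 61, 61))
  vals[31, 31, 31] <- 1000
  map <- new("ActivityMap", values = vals, spacing = rep(1, 3),
             origin = rep(-30, 3), session = ses, lesionName = "pt")
  st <- new("ImagingSetting", code = "X", scannerName = "test",
            voxelSize = rep(1, 3), psfFwhm = 5, postfilterFwhm = 4,
            noiseScale = 0)
  img <- acquire(map, st, ses, seed = 1)
  v <- imageValues(img)
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  prof <- v[, pk[2], pk[3]]
  x <- seq_along(prof) - pk[1]
  sigma <- sqrt(sum(prof * x^2) / sum(prof))
  fwhmMeasured <- 2 * sqrt(2 * log(2)) * sigma
  fwhmExpected <- sqrt(5^2 + 4^2)
  expect_lt(abs(fwhmMeasured - fwhmExpected), 1)  # within one voxel
})

test_that("blur conserves integrated activity away from boundaries", {
  set.seed(3)
  a <- array(0, c(40, 40, 40))
  a[15:25, 15:25, 15:25] <- stats::runif(11^3)
  b <- phantomics:::gaussianSmooth3d(a, rep(2, 3))
  expect_lt(abs(sum(b) / sum(a) - 1), 0.005)
})

test_that("stronger PSF strictly lowers the VOI SUVmax of preset lesions", {
  les <- lesionPreset("L2")
  ses <- phantomSession(backgroundActivityMbq = 72.6,
                        acquisitionTimeS = 1883)
  plan <- planTrajectory(les, acquisitionTime = 1883)
  map <- paintGroundTruth(les, plan, ses)
  mx <- vapply(c(4, 5.5, 7), function(f) {
    st <- new("ImagingSetting", code = "X", scannerName = "t",
              voxelSize = rep(3, 3), psfFwhm = f, postfilterFwhm = 0,
              noiseScale = 0)
    img <- acquire(map, st, ses, seed = 1)
    voi <- makeVOI(les, img)
    max(imageValues(img)[imageValues(voi)])
  }, numeric(1))
  expect_true(all(diff(mx) < 0))
})

test_that("blur increases GLCM homogeneity and lowers contrast", {
  les <- lesionPreset("L3")
  ses <- phantomSession(backgroundActivityMbq = 57.6,
                        acquisitionTimeS = 2600)
  plan <- planTrajectory(les, acquisitionTime = 2600)
  map <- paintGroundTruth(les, plan, ses)
  fts <- lapply(c(4, 7), function(f) {
    st <- new("ImagingSetting", code = "X", scannerName = "t",
              voxelSize = rep(3, 3), psfFwhm = f, postfilterFwhm = 0,
              noiseScale = 0)
    img <- acquire(map, st, ses, seed = 1)
    voi <- makeVOI(les, img)
    glcmFeatures(discretizeFBS(img, voi))
  })
  expect_gt(fts[[2]]["GLCM_Homogeneity"], fts[[1]]["GLCM_Homogeneity"])
  expect_lt(fts[[2]]["GLCM_Contrast"], fts[[1]]["GLCM_Contrast"])
})

test_that("noisy renderings are bit-identical under a repeated seed", {
  les <- lesionPreset("L1")
  ses <- phantomSession(backgroundActivityMbq = 87.2,
                        acquisitionTimeS = 1730)
  plan <- planTrajectory(les, acquisitionTime = 1730)
  map <- paintGroundTruth(les, plan, ses)
  st <- imagingSettings()[["H"]]
  i1 <- acquire(map, st, ses, seed = 99)
  i2 <- acquire(map, st, ses, seed = 99)
  i3 <- acquire(map, st, ses, seed = 100)
  expect_identical(imageValues(i1), imageValues(i2))
  expect_false(identical(imageValues(i1), imageValues(i3)))
})

test_that("the full design yields 24 images with sensible VOI geometry", {
  run <- defaultRun()
  expect_equal(nrow(run$design), 24L)
  expect_equal(sort(unique(run$design$setting)), LETTERS[1:8])
  ft <- run$features
  # order statistics: SUVmax >= SUVmean within every cell
  expect_true(all(ft$CONV_SUVmax >= ft$CONV_SUVmean))
})

test_that("larger voxels give fewer VOI voxels on the same lesion", {
  les <- lesionPreset("L1")
  ses <- phantomSession(backgroundActivityMbq = 87.2,
                        acquisitionTimeS = 1730)
  plan <- planTrajectory(les, acquisitionTime = 1730)
  map <- paintGroundTruth(les, plan, ses)
  st <- imagingSettings()
  imgB <- acquire(map, st[["B"]], ses, seed = 1)
  imgG <- acquire(map, st[["G"]], ses, seed = 1)
  expect_lt(voxelCount(makeVOI(les, imgB)), voxelCount(makeVOI(les, imgG)))
})
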