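test_that("dwell times are proportional to template values", {
  v <- array(0, c(4, 1, 1))
  v[1, 1, 1] <- 2
  v[2, 1, 1] <- 1
  tpl <- new("LesionTemplate", name = "t", gridSpacing = 2.5, values = v)
  plan <- planTrajectory(tpl, baseDwell = 10)
  dw <- dwellTimes(plan)
  expect_equal(sort(dw), c(5, 10))
  expect_equal(max(dw) / min(dw), 2)
})

test_that("travel time between adjacent cells follows distance / speed", {
  v <- array(0, c(4, 1, 1))
  v[c(1, 2)] <- 1
  tpl <- new("LesionTemplate", name = "t", gridSpacing = 2.5, values = v)
  plan <- planTrajectory(tpl, maxSpeed = 2, baseDwell = 3)
  # two waypoints 2.5 mm apart at 2 mm/s: 1.25 s of travel
  expect_equal(totalTime(plan), 2 * 3 + 1.25)
})

test_that("constant templates dwell equally everywhere", {
  tpl <- generateLesion(4, shape = "sphere", seed = 1)
  plan <- planTrajectory(tpl, baseDwell = 7)
  expect_true(all(dwellTimes(plan) == 7))
})

test_that("trajectory speed above the water-safety limit is rejected", {
  tpl <- lesionPreset("L1")
  expect_error(planTrajectory(tpl, maxSpeed = 3, baseDwell = 1), "2")
  expect_error(planTrajectory(tpl, acquisitionTime = 1), "travel")
})

test_that("serpentine visiting order moves between neighbouring cells", {
  tpl <- generateLesion(6, shape = "sphere", seed = 2)
  wp <- waypoints(planTrajectory(tpl, baseDwell = 1))
  steps <- sqrt(rowSums(diff(wp)^2))
  # within a row every step is one cell; row/slice changes are short hops
  expect_lt(stats::median(steps), 2.5 + 1e-9)
})

test_that("background decay follows the half-life law", {
  expect_equal(decayBackground(100, HALF_LIFE_F18), 50)
  expect_equal(decayBackground(100, 0), 100)
  expect_equal(decayBackground(80, 2 * HALF_LIFE_F18), 20)
  expect_error(decayBackground(-1, 10), "positive")
})

test_that("study schedule decays the background to about half by scan end", {
  sch <- sessionSchedule()
  endFrac <- vapply(unique(sch$scanner), function(sc) {
    s <- sch[sch$scanner == sc, ]
    a0 <- s$initial_activity_mbq[s$lesion == "L1"]
    aL3 <- s$initial_activity_mbq[s$lesion == "L3"]
    tL3 <- s$acquisition_time_s[s$lesion == "L3"]
    100 * decayBackground(aL3, tL3) / a0
  }, numeric(1))
  expect_true(all(abs(endFrac - 50) < 3))
})

test_that("painting conserves total source-integrated intensity exactly", {
  les <- lesionPreset("L1")
  ses <- phantomSession(backgroundActivityMbq = 87.2,
                        acquisitionTimeS = 1730)
  plan <- planTrajectory(les, acquisitionTime = 1730)
  map <- paintGroundTruth(les, plan, ses)
  painted <- (imageValues(map) - backgroundConcentration(ses))
  integral <- sum(painted) * prod(imageSpacing(map)) / 1000 *
    ses@acquisitionTimeS
  expected <- ses@sourceActivityMbq * 1000 * sum(dwellTimes(plan))
  expect_equal(integral, expected, tolerance = 1e-12)
})

test_that("painted maps are bit-reproducible for a fixed seed", {
  mk <- function() {
    les <- generateLesion(9, heterogeneity = 0.4, seed = 11)
    plan <- planTrajectory(les, baseDwell = 2)
    paintGroundTruth(les, plan, phantomSession())
  }
  expect_identical(imageValues(mk()), imageValues(mk()))
})

test_that("background level falls across the sequential lesion sessions", {
  sch <- sessionSchedule()
  for (sc in unique(sch$scanner)) {
    s <- sch[sch$scanner == sc, ]
    bg <- vapply(c("L1", "L2", "L3"), function(ln) {
      r <- s[s$lesion == ln, ]
      backgroundConcentration(phantomSession(
        tankVolumeL = r$volume_l,
        backgroundActivityMbq = r$initial_activity_mbq,
        acquisitionTimeS = r$acquisition_time_s))
    }, numeric(1))
    expect_true(all(diff(bg) < 0))
  }
})

test_that("single waypoint with zero background paints only one neighbourhood", {
  v <- array(0, c(1, 1, 1))
  v[1] <- 1
  tpl <- new("LesionTemplate", name = "pt", gridSpacing = 2.5, values = v)
  plan <- planTrajectory(tpl, baseDwell = 5)
  ses <- phantomSession(backgroundActivityMbq = 1e-12)
  map <- paintGroundTruth(tpl, plan, ses)
  vals <- imageValues(map)
  expect_equal(sum(vals > 1e-6), 1L)
})

test_that("waypoints outside the painting cube are rejected", {
  plan <- new("TrajectoryPlan",
              waypoints = matrix(c(40, 0, 0), 1, 3),
              dwellTimes = 1, travelSpeed = 2, totalTime = 1)
  v <- array(1, c(1, 1, 1))
  tpl <- new("LesionTemplate", name = "t", gridSpacing = 2.5, values = v)
  expect_error(paintGroundTruth(tpl, plan, phantomSession()), "cube")
})
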