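#' 18F half-life in seconds
#' @export
HALF_LIFE_F18 <- 6586.2

#' Construct a phantom acquisition session
#'
#' @param tankVolumeL litres of water in the tank (default 15.06, the mean
#'   fill across the study scanners).
#' @param backgroundActivityMbq 18F activity at acquisition start (MBq).
#' @param acquisitionTimeS scan duration (s).
#' @param backgroundHalfLifeS 18F half-life (s).
#' @param sourceActivityMbq 22Na point-source activity (MBq); constant over
#'   any session (2.6-year half-life).
#' @param sourceDiameterMm physical source diameter (mm); rendered as a
#'   point since it is far below all voxel sizes.
#' @param scanner scanner label.
#' @param timeInaccuracyS recorded painting-time inaccuracy (s), metadata.
#' @return a [PhantomSession-class].
#' @examples
#' phantomSession(backgroundActivityMbq = 87.2, acquisitionTimeS = 1730)
#' @export
phantomSession <- function(tankVolumeL = 15.06,
                           backgroundActivityMbq = 88.5,
                           acquisitionTimeS = 1730,
                           backgroundHalfLifeS = HALF_LIFE_F18,
                           sourceActivityMbq = 1.1,
                           sourceDiameterMm = 0.25,
                           scanner = "generic",
                           timeInaccuracyS = 0) {
  new("PhantomSession",
      tankVolumeL = tankVolumeL,
      backgroundActivityMbq = backgroundActivityMbq,
      backgroundHalfLifeS = backgroundHalfLifeS,
      sourceActivityMbq = sourceActivityMbq,
      sourceDiameterMm = sourceDiameterMm,
      acquisitionTimeS = acquisitionTimeS,
      scanner = scanner,
      timeInaccuracyS = timeInaccuracyS)
}

#' Measurement schedule of the five-scanner study
#'
#' Per-scanner water volumes, background activities at the start of each
#' lesion painting, acquisition times and recorded timing inaccuracies.
#' Shipped as a plain CSV in `inst/extdata/session_schedule.csv`.
#'
#' @param file optional path to an alternative schedule CSV with the same
#'   columns.
#' @return data.frame with columns `scanner`, `lesion`, `volume_l`,
#'   `initial_activity_mbq`, `acquisition_time_s`, `time_inaccuracy_s`.
#' @examples
#' head(sessionSchedule())
#' @export
sessionSchedule <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "session_schedule.csv",
                        package = "phantomics", mustWork = TRUE)
  sch <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("scanner", "lesion", "volume_l", "initial_activity_mbq",
            "acquisition_time_s", "time_inaccuracy_s")
  if (!all(need %in% names(sch)))
    stopf("schedule file must have columns: %s", paste(need, collapse = ", "))
  sch
}

#' Radioactive decay of the background activity
#'
#' @param activity0 activity at time zero (MBq); vectorised.
#' @param elapsed elapsed time (s).
#' @param halfLife half-life (s); default 18F.
#' @return activity after `elapsed` seconds: `activity0 * 2^(-elapsed/halfLife)`.
#' @examples
#' decayBackground(100, HALF_LIFE_F18)  # one half-life -> 50
#' @export
decayBackground <- function(activity0, elapsed, halfLife = HALF_LIFE_F18) {
  if (any(activity0 <= 0) || any(halfLife <= 0) || any(elapsed < 0))
    stopf("'activity0' and 'halfLife' must be positive, 'elapsed' >= 0")
  activity0 * 2^(-elapsed / halfLife)
}

#' Plan the point-source trajectory for a lesion template
#'
#' Visits every positive template cell in raster-serpentine order
#' (boustrophedon within each slice, so consecutive waypoints are adjacent)
#' and dwells at cell i for `baseDwell * value_i / max(value)`. Travel
#' between waypoints is budgeted at `maxSpeed`, capped at the 2 mm/s limit
#' that keeps the water surface still.
#'
#' @param template a [LesionTemplate-class].
#' @param maxSpeed travel speed in mm/s, `<= 2`.
#' @param baseDwell dwell time (s) at the hottest cell. Exactly one of
#'   `baseDwell` and `acquisitionTime` must be given.
#' @param acquisitionTime if given instead of `baseDwell`, the dwell scale is
#'   calibrated so the total painting time (dwells + travel) equals this
#'   duration, mirroring how painting time and scan time are matched.
#' @return a [TrajectoryPlan-class].
#' @examples
#' plan <- planTrajectory(lesionPreset("L1"), acquisitionTime = 1730)
#' totalTime(plan)
#' @export
planTrajectory <- function(template, maxSpeed = 2, baseDwell = NULL,
                           acquisitionTime = NULL) {
  stopifnot(is(template, "LesionTemplate"))
  if (maxSpeed <= 0 || maxSpeed > 2)
    stopf("'maxSpeed' must be in (0, 2] mm/s: faster travel stirs the water")
  v <- template@values
  if (!any(v > 0)) stopf("empty template: nothing to paint")
  if (is.null(baseDwell) == is.null(acquisitionTime))
    stopf("give exactly one of 'baseDwell' or 'acquisitionTime'")

  n <- dim(v)
  idx <- which(v > 0, arr.ind = TRUE)
  # serpentine: slices ascending in z; row direction alternates with z,
  # column direction alternates with (y + z)
  yk <- ifelse(idx[, 3] %% 2L == 1L, idx[, 2], -idx[, 2])
  xk <- ifelse((idx[, 2] + idx[, 3]) %% 2L == 0L, idx[, 1], -idx[, 1])
  ord <- order(idx[, 3], yk, xk)
  idx <- idx[ord, , drop = FALSE]

  h <- template@gridSpacing
  wp <- cbind(axisCentres(n[1], h)[idx[, 1]],
              axisCentres(n[2], h)[idx[, 2]],
              axisCentres(n[3], h)[idx[, 3]])
  rel <- v[idx] / max(v)

  travel <- 0
  if (nrow(wp) > 1L) {
    d <- diff(wp)
    travel <- sum(sqrt(rowSums(d^2))) / maxSpeed
  }
  if (is.null(baseDwell)) {
    if (acquisitionTime <= travel)
      stopf("acquisition time %.1f s shorter than travel time %.1f s",
            acquisitionTime, travel)
    baseDwell <- (acquisitionTime - travel) / sum(rel)
  }
  if (baseDwell < 0) stopf("'baseDwell' must be >= 0")
  dwell <- baseDwell * rel

  new("TrajectoryPlan",
      waypoints = wp, dwellTimes = dwell, travelSpeed = maxSpeed,
      totalTime = sum(dwell) + travel)
}

#' Time-averaged decay factor over an acquisition
#'
#' Mean of `2^(-t/halfLife)` over `t` in `[0, duration]`; multiplies the
#' start-of-scan concentration to give the average concentration the scan
#' integrates.
#' @noRd
meanDecayFactor <- function(duration, halfLife) {
  lam <- log(2) / halfLife
  (1 - exp(-lam * duration)) / (lam * duration)
}

#' Paint the ground-truth activity map
#'
#' Converts a trajectory plan into the fine-grid activity distribution the
#' scan integrates: each waypoint cell receives the time-averaged
#' concentration equivalent of the source parked there for its dwell time,
#' superposed on the uniform decaying 18F background at its session-averaged
#' concentration. Total painted intensity (integrated over volume and scan
#' time) equals source activity x total dwell time exactly.
#'
#' @param template the [LesionTemplate-class] being painted (for labelling
#'   and consistency checks).
#' @param plan the [TrajectoryPlan-class] for that template.
#' @param session the [PhantomSession-class] describing background and source.
#' @param fineSpacing painting-map grid pitch in mm (must be <= 1 mm).
#' @param fovMm cubic field of view edge length in mm; must contain the
#'   50 mm painting cube plus blur margin.
#' @return an [ActivityMap-class] in kBq/mL (time-averaged over the scan).
#' @examples
#' les <- lesionPreset("L1")
#' plan <- planTrajectory(les, acquisitionTime = 1730)
#' map <- paintGroundTruth(les, plan, phantomSession(
#'   backgroundActivityMbq = 87.2, acquisitionTimeS = 1730))
#' @export
paintGroundTruth <- function(template, plan, session,
                             fineSpacing = 1, fovMm = 80) {
  stopifnot(is(template, "LesionTemplate"), is(plan, "TrajectoryPlan"),
            is(session, "PhantomSession"))
  if (fineSpacing > 1)
    stopf("'fineSpacing' must be <= 1 mm for a faithful painted map")
  if (fovMm < 50) stopf("'fovMm' must contain the 50 mm painting cube")
  wp <- plan@waypoints
  if (any(abs(wp) > 25 + 1e-9))
    stopf("trajectory leaves the 50 mm painting cube (|coordinate| > 25 mm)")
  if (nrow(wp) != voxelCount(template))
    stopf("plan does not visit exactly the positive cells of the template")

  n <- as.integer(round(fovMm / fineSpacing))
  vals <- array(0, c(n, n, n))
  ax <- axisCentres(n, fineSpacing)
  toIdx <- function(x) {
    i <- as.integer(floor((x - (ax[1] - fineSpacing / 2)) / fineSpacing)) + 1L
    pmin(pmax(i, 1L), n)
  }
  ii <- cbind(toIdx(wp[, 1]), toIdx(wp[, 2]), toIdx(wp[, 3]))
  lin <- ii[, 1] + n * (ii[, 2] - 1L) + n * n * (ii[, 3] - 1L)

  aSrcKbq <- session@sourceActivityMbq * 1000
  cellMl <- fineSpacing^3 / 1000
  tAcq <- session@acquisitionTimeS
  # equivalent time-averaged concentration of a dwell in one fine cell
  dep <- aSrcKbq * plan@dwellTimes / (tAcq * cellMl)
  for (k in seq_along(lin)) vals[lin[k]] <- vals[lin[k]] + dep[k]

  conc0 <- session@backgroundActivityMbq * 1000 / (session@tankVolumeL * 1000)
  bg <- conc0 * meanDecayFactor(tAcq, session@backgroundHalfLifeS)
  vals <- vals + bg

  new("ActivityMap",
      values = vals,
      spacing = rep(fineSpacing, 3),
      origin = rep(ax[1], 3),
      session = session,
      lesionName = template@name)
}

#' Background concentration of a painted map
#'
#' Session-averaged 18F background concentration (kBq/mL) used when painting.
#' @param session a [PhantomSession-class].
#' @return kBq/mL.
#' @export
backgroundConcentration <- function(session) {
  stopifnot(is(session, "PhantomSession"))
  conc0 <- session@backgroundActivityMbq * 1000 / (session@tankVolumeL * 1000)
  conc0 * meanDecayFactor(session@acquisitionTimeS,
                          session@backgroundHalfLifeS)
}
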