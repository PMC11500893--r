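#' @import methods
NULL

#' LesionTemplate: target activity pattern on the painting grid
#'
#' A 3-D non-negative array of relative target activities defined on the
#' isotropic painting grid of the moving-source phantom. The physical support
#' must fit inside the 50 x 50 x 50 mm painting volume that the linear stages
#' can reach; the template is the ground truth that the point source later
#' "paints" with intensity-proportional dwell times.
#'
#' @slot name character label (e.g. `"L1"`).
#' @slot gridSpacing isotropic painting-grid pitch in mm.
#' @slot values 3-D array of relative activities, all `>= 0`, at least one
#'   positive.
#' @seealso [generateLesion()], [lesionPreset()], [planTrajectory()]
#' @export
setClass("LesionTemplate",
  representation(
    name = "character",
    gridSpacing = "numeric",
    values = "array"
  )
)

setValidity("LesionTemplate", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("'values' must be a 3-D array")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (any(v < 0)) return("'values' must be non-negative")
  if (!any(v > 0)) return("'values' must contain at least one positive cell")
  if (length(object@gridSpacing) != 1L || object@gridSpacing <= 0)
    return("'gridSpacing' must be a single positive number (mm)")
  if (any(dim(v) * object@gridSpacing > 50 + 1e-9))
    return("template extent exceeds the 50 mm painting cube")
  TRUE
})

#' TrajectoryPlan: dwell positions of the moving point source
#'
#' Ordered waypoints (mm, relative to the painting-cube centre) with
#' per-waypoint dwell times. Dwell times are proportional to the template
#' activity at each visited cell; travel between waypoints is limited to
#' 2 mm/s so the source does not stir the water.
#'
#' @slot waypoints n x 3 matrix of positions in mm.
#' @slot dwellTimes seconds per waypoint, `>= 0`.
#' @slot travelSpeed mm/s, `<= 2`.
#' @slot totalTime seconds: sum of dwells plus travel (segment length / speed).
#' @seealso [planTrajectory()]
#' @export
setClass("TrajectoryPlan",
  representation(
    waypoints = "matrix",
    dwellTimes = "numeric",
    travelSpeed = "numeric",
    totalTime = "numeric"
  )
)

setValidity("TrajectoryPlan", function(object) {
  if (ncol(object@waypoints) != 3L) return("'waypoints' must be n x 3")
  if (nrow(object@waypoints) != length(object@dwellTimes))
    return("one dwell time per waypoint required")
  if (any(object@dwellTimes < 0)) return("dwell times must be >= 0")
  if (object@travelSpeed <= 0 || object@travelSpeed > 2)
    return("travel speed must be in (0, 2] mm/s")
  seg <- 0
  if (nrow(object@waypoints) > 1L) {
    d <- diff(object@waypoints)
    seg <- sum(sqrt(rowSums(d^2))) / object@travelSpeed
  }
  if (abs(object@totalTime - (sum(object@dwellTimes) + seg)) >
      1e-6 * max(1, object@totalTime))
    return("'totalTime' must equal sum(dwells) + travel time")
  TRUE
})

#' PhantomSession: one acquisition of the painted phantom
#'
#' Bookkeeping for a single scan: the water-tank background (18F, decaying
#' during the acquisition) and the constant-activity 22Na point source.
#'
#' @slot tankVolumeL litres of water in the tank.
#' @slot backgroundActivityMbq 18F activity (MBq) at acquisition start.
#' @slot backgroundHalfLifeS 18F half-life in seconds (6586.2).
#' @slot sourceActivityMbq 22Na source activity (MBq), constant over a scan.
#' @slot sourceDiameterMm physical source diameter (mm); the source is
#'   rendered as a point since it is far smaller than any voxel.
#' @slot acquisitionTimeS scan duration in seconds.
#' @slot scanner character scanner label.
#' @slot timeInaccuracyS recorded difference between actual and estimated
#'   painting time (s); metadata only.
#' @seealso [phantomSession()], [sessionSchedule()]
#' @export
setClass("PhantomSession",
  representation(
    tankVolumeL = "numeric",
    backgroundActivityMbq = "numeric",
    backgroundHalfLifeS = "numeric",
    sourceActivityMbq = "numeric",
    sourceDiameterMm = "numeric",
    acquisitionTimeS = "numeric",
    scanner = "character",
    timeInaccuracyS = "numeric"
  )
)

setValidity("PhantomSession", function(object) {
  for (s in c("tankVolumeL", "backgroundActivityMbq", "backgroundHalfLifeS",
              "sourceActivityMbq", "acquisitionTimeS")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a single positive number", s))
  }
  TRUE
})

#' ImagingSetting: one scanner + reconstruction surrogate
#'
#' Each of the eight settings (codes A-H) is characterised by its
#' reconstruction voxel size and by an effective point-spread function,
#' post-filter and noise scale that stand in for the scanner acquisition and
#' reconstruction chain.
#'
#' @slot code single letter A-H.
#' @slot scannerName scanner model label.
#' @slot voxelSize mm triple (x, y, z).
#' @slot psfFwhm effective system resolution, FWHM in mm.
#' @slot postfilterFwhm Gaussian post-filter FWHM in mm (0 = none).
#' @slot noiseScale dimensionless noise level of the exposure surrogate.
#' @seealso [imagingSettings()], [acquire()]
#' @export
setClass("ImagingSetting",
  representation(
    code = "character",
    scannerName = "character",
    voxelSize = "numeric",
    psfFwhm = "numeric",
    postfilterFwhm = "numeric",
    noiseScale = "numeric"
  )
)

setValidity("ImagingSetting", function(object) {
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be a positive mm triple")
  if (object@psfFwhm < 0 || object@postfilterFwhm < 0 || object@noiseScale < 0)
    return("PSF, post-filter and noise scale must be >= 0")
  if (!grepl("^[A-Z]$", object@code)) return("'code' must be a single letter")
  TRUE
})

#' Volumetric images: painted activity maps and reconstructed SUV images
#'
#' `ActivityMap` holds the fine-grid painted ground truth in kBq/mL
#' (time-averaged over the acquisition); `SUVImage` holds a reconstructed
#' image in SUV units on a scanner voxel grid. Both store spacing and origin
#' (mm; origin is the centre of the first voxel, grids are centred on the
#' painting cube centre).
#'
#' @slot values 3-D numeric array.
#' @slot spacing mm triple.
#' @slot origin mm triple, centre of voxel (1,1,1).
#' @export
setClass("ImageVolume",
  representation(
    values = "array",
    spacing = "numeric",
    origin = "numeric",
    "VIRTUAL"
  )
)

setValidity("ImageVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("'values' must be a 3-D array")
  if (any(!is.finite(object@values))) return("'values' must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("'spacing' must be a positive mm triple")
  if (length(object@origin) != 3L) return("'origin' must be a mm triple")
  TRUE
})

#' @rdname ImageVolume-class
#' @slot session the [PhantomSession-class] the map was painted for.
#' @slot lesionName lesion label.
#' @export
setClass("ActivityMap",
  contains = "ImageVolume",
  representation(session = "PhantomSession", lesionName = "character")
)

#' @rdname ImageVolume-class
#' @slot settingCode imaging-setting code A-H.
#' @export
setClass("SUVImage",
  contains = "ImageVolume",
  representation(settingCode = "character", lesionName = "character")
)

#' VOIMask: segmented volume of interest aligned to an image
#'
#' @slot mask 3-D logical array congruent with its image.
#' @slot spacing mm triple of the image grid.
#' @slot origin mm triple.
#' @seealso [makeVOI()]
#' @export
setClass("VOIMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric")
)

setValidity("VOIMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("'mask' must be a 3-D logical array")
  if (!any(object@mask)) return("VOI mask is empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("'spacing' must be a positive mm triple")
  TRUE
})

#' GreyLevelVolume: discretized VOI intensities
#'
#' Integer grey levels over the VOI (NA outside), produced by the
#' fixed-bin-size (FBS, absolute) or fixed-bin-number (FBN, relative)
#' discretization of SUV values. Texture matrices are computed from this
#' object.
#'
#' @slot levels 3-D integer array over the VOI bounding box; `NA` outside the
#'   VOI.
#' @slot nLevels number of grey levels (maximum level).
#' @slot method `"FBS"` or `"FBN"`.
#' @slot binWidth SUV bin width B (FBS; `NA` for FBN).
#' @slot binCount bin number D (FBN; `NA` for FBS).
#' @slot intensityRange VOI SUV extrema `c(i_min, i_max)`.
#' @slot spacing mm triple of the underlying image grid.
#' @seealso [discretizeFBS()], [discretizeFBN()]
#' @export
setClass("GreyLevelVolume",
  representation(
    levels = "array",
    nLevels = "integer",
    method = "character",
    binWidth = "numeric",
    binCount = "integer",
    intensityRange = "numeric",
    spacing = "numeric"
  )
)

setValidity("GreyLevelVolume", function(object) {
  lv <- object@levels
  if (length(dim(lv)) != 3L) return("'levels' must be a 3-D array")
  inv <- lv[!is.na(lv)]
  if (!length(inv)) return("no in-VOI voxels")
  if (any(inv < 1L)) return("levels must be >= 1")
  if (!object@method %in% c("FBS", "FBN")) return("method must be FBS or FBN")
  if (object@method == "FBN" && any(inv > object@binCount))
    return("FBN levels must be <= binCount")
  if (object@nLevels < max(inv)) return("'nLevels' below observed maximum")
  TRUE
})

#' RobustnessReport: robustness analytics over a feature table
#'
#' Collects the four robustness summaries of a complete lesion x setting x
#' discretization feature design: relative differences against the reference
#' setting, inter-setting coefficients of variation with categories,
#' absolute-agreement intraclass correlation coefficients with categories,
#' and lesion-pair Wilcoxon rank-sum p-values with Benjamini-Hochberg
#' adjustment.
#'
#' @slot rd data.frame: feature, lesion, discretization, setting, rd_percent.
#' @slot cv data.frame: feature, lesion, discretization, cv_percent, category.
#' @slot icc data.frame: feature, discretization, icc, category.
#' @slot pvalues data.frame: feature, discretization, lesion_a, lesion_b,
#'   p_raw, p_adjusted.
#' @slot reference reference setting code.
#' @seealso [buildReport()]
#' @export
setClass("RobustnessReport",
  representation(
    rd = "data.frame",
    cv = "data.frame",
    icc = "data.frame",
    pvalues = "data.frame",
    reference = "character"
  )
)
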