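# Generics and simple accessors. Slot access from user code should go
# through these.

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("imageSpacing", function(x) standardGeneric("imageSpacing"))
#' @rdname accessors
#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))
#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @rdname accessors
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("greyLevels", function(x) standardGeneric("greyLevels"))
#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' Accessors for phantomics objects
#'
#' `imageValues()`, `imageSpacing()` and `imageOrigin()` expose the voxel
#' data and geometry of [ImageVolume-class] objects and [VOIMask-class]
#' masks; `volumeMl()` gives the physical volume of a mask or template
#' support; `voxelCount()` the number of in-VOI voxels; `greyLevels()` /
#' `nLevels()` the discretized levels of a [GreyLevelVolume-class].
#'
#' @param x a phantomics object.
#' @return see details per generic.
#' @name accessors
NULL

setMethod("imageValues", "ImageVolume", function(x) x@values)
setMethod("imageSpacing", "ImageVolume", function(x) x@spacing)
setMethod("imageOrigin", "ImageVolume", function(x) x@origin)
setMethod("imageValues", "VOIMask", function(x) x@mask)
setMethod("imageSpacing", "VOIMask", function(x) x@spacing)
setMethod("imageOrigin", "VOIMask", function(x) x@origin)

setMethod("voxelVolumeMl", "ImageVolume", function(x) prod(x@spacing) / 1000)
setMethod("voxelVolumeMl", "VOIMask", function(x) prod(x@spacing) / 1000)
setMethod("voxelVolumeMl", "LesionTemplate",
          function(x) x@gridSpacing^3 / 1000)

setMethod("voxelCount", "VOIMask", function(x) sum(x@mask))
setMethod("voxelCount", "LesionTemplate", function(x) sum(x@values > 0))
setMethod("voxelCount", "GreyLevelVolume", function(x) sum(!is.na(x@levels)))

setMethod("volumeMl", "VOIMask", function(x) voxelCount(x) * voxelVolumeMl(x))
setMethod("volumeMl", "LesionTemplate",
          function(x) voxelCount(x) * voxelVolumeMl(x))

setMethod("greyLevels", "GreyLevelVolume", function(x) x@levels)
setMethod("nLevels", "GreyLevelVolume", function(x) x@nLevels)

#' @rdname accessors
#' @export
setGeneric("settingCode", function(x) standardGeneric("settingCode"))
setMethod("settingCode", "ImagingSetting", function(x) x@code)
setMethod("settingCode", "SUVImage", function(x) x@settingCode)

#' @rdname accessors
#' @export
setGeneric("lesionName", function(x) standardGeneric("lesionName"))
setMethod("lesionName", "LesionTemplate", function(x) x@name)
setMethod("lesionName", "SUVImage", function(x) x@lesionName)
setMethod("lesionName", "ActivityMap", function(x) x@lesionName)

#' @rdname accessors
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))
setMethod("totalTime", "TrajectoryPlan", function(x) x@totalTime)

#' @rdname accessors
#' @export
setGeneric("dwellTimes", function(x) standardGeneric("dwellTimes"))
setMethod("dwellTimes", "TrajectoryPlan", function(x) x@dwellTimes)

#' @rdname accessors
#' @export
setGeneric("waypoints", function(x) standardGeneric("waypoints"))
setMethod("waypoints", "TrajectoryPlan", function(x) x@waypoints)

#' @rdname accessors
#' @export
setGeneric("rdTable", function(x) standardGeneric("rdTable"))
setMethod("rdTable", "RobustnessReport", function(x) x@rd)
#' @rdname accessors
#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))
setMethod("cvTable", "RobustnessReport", function(x) x@cv)
#' @rdname accessors
#' @export
setGeneric("iccTable", function(x) standardGeneric("iccTable"))
setMethod("iccTable", "RobustnessReport", function(x) x@icc)
#' @rdname accessors
#' @export
setGeneric("pvalueTable", function(x) standardGeneric("pvalueTable"))
setMethod("pvalueTable", "RobustnessReport", function(x) x@pvalues)

setMethod("show", "LesionTemplate", function(object) {
  cat(sprintf(
    "LesionTemplate '%s': %s grid @ %.3g mm, %d active cells, %.3f mL\n",
    object@name, paste(dim(object@values), collapse = "x"),
    object@gridSpacing, voxelCount(object), volumeMl(object)
  ))
})

setMethod("show", "TrajectoryPlan", function(object) {
  cat(sprintf(
    "TrajectoryPlan: %d waypoints, dwell %.1f s, travel %.1f s @ %.2g mm/s, total %.1f s\n",
    nrow(object@waypoints), sum(object@dwellTimes),
    object@totalTime - sum(object@dwellTimes), object@travelSpeed,
    object@totalTime
  ))
})

setMethod("show", "PhantomSession", function(object) {
  cat(sprintf(
    "PhantomSession [%s]: %.2f L tank, %.1f MBq 18F at start (T1/2 %.1f s),\n  22Na source %.2f MBq, acquisition %.0f s\n",
    object@scanner, object@tankVolumeL, object@backgroundActivityMbq,
    object@backgroundHalfLifeS, object@sourceActivityMbq,
    object@acquisitionTimeS
  ))
})

setMethod("show", "ImagingSetting", function(object) {
  cat(sprintf(
    "ImagingSetting %s (%s): voxel %s mm, PSF %.2f mm, post-filter %.2f mm, noise %.3g\n",
    object@code, object@scannerName,
    paste(signif(object@voxelSize, 3), collapse = "x"),
    object@psfFwhm, object@postfilterFwhm, object@noiseScale
  ))
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf(
    "ActivityMap '%s': %s @ %s mm [kBq/mL], range %.3g..%.3g\n",
    object@lesionName, paste(dim(object@values), collapse = "x"),
    paste(signif(object@spacing, 3), collapse = "x"),
    min(object@values), max(object@values)
  ))
})

setMethod("show", "SUVImage", function(object) {
  cat(sprintf(
    "SUVImage '%s' setting %s: %s @ %s mm, SUV range %.3g..%.3g\n",
    object@lesionName, object@settingCode,
    paste(dim(object@values), collapse = "x"),
    paste(signif(object@spacing, 3), collapse = "x"),
    min(object@values), max(object@values)
  ))
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf(
    "VOIMask: %d voxels, %.3f mL on %s grid @ %s mm\n",
    voxelCount(object), volumeMl(object),
    paste(dim(object@mask), collapse = "x"),
    paste(signif(object@spacing, 3), collapse = "x")
  ))
})

setMethod("show", "GreyLevelVolume", function(object) {
  par <- if (object@method == "FBS")
    sprintf("B = %.4g SUV", object@binWidth)
  else sprintf("D = %d", object@binCount)
  cat(sprintf(
    "GreyLevelVolume (%s, %s): %d voxels, %d grey levels\n",
    object@method, par, voxelCount(object), object@nLevels
  ))
})

setMethod("show", "RobustnessReport", function(object) {
  cat(sprintf(
    "RobustnessReport (reference setting %s):\n  %d relative differences, %d CVs, %d ICCs, %d lesion-pair tests\n",
    object@reference, nrow(object@rd), nrow(object@cv), nrow(object@icc),
    nrow(object@pvalues)
  ))
})
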