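# NIfTI and CSV interchange for templates, images, masks and trajectories.

#' Write / read image volumes as NIfTI
#'
#' Volumes are stored with their spacing in the NIfTI pixdim; `.nii` and
#' `.nii.gz` are both accepted.
#'
#' @param x an [ImageVolume-class], [VOIMask-class] or [LesionTemplate-class].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `writeVolumeNifti`: the path, invisibly.
#' @export
writeVolumeNifti <- function(x, path) {
  if (is(x, "LesionTemplate")) {
    arr <- x@values
    sp <- rep(x@gridSpacing, 3)
  } else if (is(x, "VOIMask")) {
    arr <- x@mask * 1L
    sp <- x@spacing
  } else if (is(x, "ImageVolume")) {
    arr <- x@values
    sp <- x@spacing
  } else if (is(x, "GreyLevelVolume")) {
    arr <- x@levels
    arr[is.na(arr)] <- 0L  # 0 marks outside-VOI voxels
    sp <- x@spacing
  } else stopf("unsupported object of class %s", class(x)[1])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @param path file path.
#' @param what `"suv"` returns an [SUVImage-class], `"mask"` a
#'   [VOIMask-class], `"template"` a [LesionTemplate-class] (isotropic
#'   grids only).
#' @param name,settingCode labels attached to the loaded object.
#' @return `readVolumeNifti`: the requested object.
#' @export
readVolumeNifti <- function(path, what = c("suv", "mask", "template"),
                            name = "loaded", settingCode = "X") {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  switch(what,
    suv = new("SUVImage", values = arr, spacing = sp,
              origin = vapply(1:3, function(d)
                axisCentres(dim(arr)[d], sp[d])[1], numeric(1)),
              settingCode = settingCode, lesionName = name),
    mask = new("VOIMask", mask = arr > 0.5, spacing = sp,
               origin = vapply(1:3, function(d)
                 axisCentres(dim(arr)[d], sp[d])[1], numeric(1))),
    template = {
      if (max(abs(diff(sp))) > 1e-6)
        stopf("lesion templates need an isotropic grid")
      new("LesionTemplate", name = name, gridSpacing = sp[1], values = arr)
    })
}

#' Write a trajectory plan as CSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `dwell_s`, one row per waypoint in
#' visiting order.
#'
#' @param plan a [TrajectoryPlan-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryCsv <- function(plan, path) {
  stopifnot(is(plan, "TrajectoryPlan"))
  df <- data.frame(x_mm = plan@waypoints[, 1], y_mm = plan@waypoints[, 2],
                   z_mm = plan@waypoints[, 3], dwell_s = plan@dwellTimes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
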