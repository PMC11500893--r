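#' The eight-imaging-setting registry
#'
#' Loads the registry of the eight reconstruction surrogates (codes A-H).
#' Each setting is characterised by its reconstruction voxel size (taken
#' from the scanner protocols), an effective point-spread function FWHM, a
#' Gaussian post-filter FWHM and a noise scale. The effective PSF and noise
#' values are documented modelling assumptions, not measurements: the true
#' iterative reconstruction algorithms are deliberately not emulated and
#' each setting is treated as a black box characterised by its
#' reconstructed-image properties.
#'
#' @param file optional path to an alternative registry CSV (columns `code`,
#'   `scanner`, `voxel_x_mm`, `voxel_y_mm`, `voxel_z_mm`, `psf_fwhm_mm`,
#'   `postfilter_fwhm_mm`, `noise_scale`).
#' @return named list of [ImagingSetting-class] objects.
#' @examples
#' imagingSettings()[["A"]]
#' @export
imagingSettings <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "imaging_settings.csv",
                        package = "phantomics", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("code", "scanner", "voxel_x_mm", "voxel_y_mm", "voxel_z_mm",
            "psf_fwhm_mm", "postfilter_fwhm_mm", "noise_scale")
  if (!all(need %in% names(tab)))
    stopf("settings file must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    new("ImagingSetting",
        code = tab$code[i],
        scannerName = tab$scanner[i],
        voxelSize = c(tab$voxel_x_mm[i], tab$voxel_y_mm[i], tab$voxel_z_mm[i]),
        psfFwhm = tab$psf_fwhm_mm[i],
        postfilterFwhm = tab$postfilter_fwhm_mm[i],
        noiseScale = tab$noise_scale[i])
  })
  names(out) <- tab$code
  out
}

#' SUV normalisation factor of a session
#'
#' SUV = concentration (kBq/mL) / (administered activity / phantom mass).
#' The phantom "body weight" is the tank water mass (1 g/mL); the
#' administered activity is background plus point source.
#' @noRd
suvFactor <- function(session) {
  massG <- session@tankVolumeL * 1000
  doseKbq <- (session@backgroundActivityMbq + session@sourceActivityMbq) * 1000
  massG / doseKbq
}

#' Render a painted activity map through one imaging setting
#'
#' Surrogate acquisition + reconstruction pipeline: (1) 3-D Gaussian blur of
#' the fine-grid truth at the setting's effective PSF FWHM; (2) box
#' integration onto the setting's voxel grid; (3) Gaussian noise with
#' variance proportional to local intensity (a post-reconstruction Poisson
#' surrogate), scaled by the setting's noise scale and inversely by the
#' session exposure (activity x time) and voxel volume; (4) Gaussian
#' post-filter; (5) SUV conversion against the tank mass. Deterministic for
#' a fixed seed; with `noiseScale = 0` the pipeline is fully deterministic.
#'
#' @param truth an [ActivityMap-class] painted ground truth.
#' @param setting an [ImagingSetting-class].
#' @param session the [PhantomSession-class] of the painting (defaults to
#'   the one stored in `truth`).
#' @param seed integer seed for the noise stage.
#' @return an [SUVImage-class].
#' @examples
#' les <- lesionPreset("L1")
#' plan <- planTrajectory(les, acquisitionTime = 1730)
#' ses <- phantomSession(backgroundActivityMbq = 87.2,
#'                       acquisitionTimeS = 1730)
#' map <- paintGroundTruth(les, plan, ses)
#' img <- acquire(map, imagingSettings()[["A"]], seed = 7)
#' @export
acquire <- function(truth, setting, session = NULL, seed = 1L) {
  stopifnot(is(truth, "ActivityMap"), is(setting, "ImagingSetting"))
  if (is.null(session)) session <- truth@session
  fine <- truth@spacing
  vs <- setting@voxelSize
  if (any(fine > vs + 1e-9))
    stopf("truth grid (%.3g mm) coarser than setting voxel size (%s mm)",
          max(fine), paste(signif(vs, 3), collapse = "x"))

  # (1) PSF blur on the fine grid (sigma in fine-voxel units per axis)
  sig <- fwhmToSigma(setting@psfFwhm) / fine
  v <- gaussianSmooth3d(truth@values, sig, edge = "replicate")

  # (2) box-average onto the setting grid, both grids centred on the cube
  dFine <- dim(v)
  ext <- dFine * fine
  nVox <- pmax(1L, as.integer(floor(ext / vs)))
  out <- array(0, nVox)
  cnt <- array(0, nVox)
  axIdx <- vector("list", 3L)
  for (d in 1:3) {
    cFine <- axisCentres(dFine[d], fine[d])
    lo <- -nVox[d] * vs[d] / 2
    i <- as.integer(floor((cFine - lo) / vs[d])) + 1L
    i[i < 1L | i > nVox[d]] <- NA_integer_
    axIdx[[d]] <- i
  }
  ii <- axIdx[[1]][slice.index(v, 1)]
  jj <- axIdx[[2]][slice.index(v, 2)]
  kk <- axIdx[[3]][slice.index(v, 3)]
  keep <- !(is.na(ii) | is.na(jj) | is.na(kk))
  lin <- ii[keep] + nVox[1] * (jj[keep] - 1L) +
    nVox[1] * nVox[2] * (kk[keep] - 1L)
  sums <- rowsum(as.vector(v)[keep], lin)
  counts <- rowsum(rep(1, sum(keep)), lin)
  at <- as.integer(rownames(sums))
  out[at] <- sums[, 1] / counts[, 1]

  # (3) intensity-proportional noise, scaled by the exposure surrogate
  if (setting@noiseScale > 0) {
    expRel <- (session@backgroundActivityMbq * session@acquisitionTimeS) /
      (88.5 * 1730)
    volRel <- prod(vs) / 27  # relative to a 3 mm isotropic voxel
    sd <- setting@noiseScale * sqrt(pmax(out, 0)) / sqrt(expRel * volRel)
    noise <- withSeed(seed, stats::rnorm(length(out)))
    out <- out + sd * noise
  }

  # (4) Gaussian post-filter on the reconstruction grid
  if (setting@postfilterFwhm > 0) {
    sigPost <- fwhmToSigma(setting@postfilterFwhm) / vs
    out <- gaussianSmooth3d(out, sigPost, edge = "replicate")
  }

  # (5) SUV conversion
  out <- out * suvFactor(session)

  new("SUVImage",
      values = out,
      spacing = vs,
      origin = vapply(1:3, function(d) axisCentres(nVox[d], vs[d])[1],
                      numeric(1)),
      settingCode = setting@code,
      lesionName = truth@lesionName)
}

#' Acquire every lesion through every imaging setting
#'
#' Runs the full study design: each lesion template is painted once per
#' scanner session (background activity and acquisition time from the
#' schedule) and rendered through each of that scanner's settings, giving
#' one image per lesion x setting together with its ground-truth VOI mask.
#'
#' @param lesions named list of [LesionTemplate-class] objects (default the
#'   L1-L3 presets).
#' @param settings named list of [ImagingSetting-class] objects (default
#'   [imagingSettings()]).
#' @param schedule measurement schedule data.frame (default
#'   [sessionSchedule()]).
#' @param seed integer seed; each lesion x setting rendering uses a distinct
#'   sub-seed derived from it.
#' @param fineSpacing,fovMm painting-map geometry, see [paintGroundTruth()].
#' @return list with `images` (named `"<lesion>_<code>"` list of
#'   [SUVImage-class]), `vois` (matching [VOIMask-class]), `sessions`
#'   (per-lesion/scanner [PhantomSession-class] bookkeeping) and `design`
#'   (data.frame of lesion, setting, scanner).
#' @examples
#' \donttest{
#' study <- acquireAll(seed = 1)
#' length(study$images)  # 24
#' }
#' @export
acquireAll <- function(lesions = NULL, settings = imagingSettings(),
                       schedule = sessionSchedule(), seed = 1L,
                       fineSpacing = 1, fovMm = 80) {
  if (is.null(lesions)) {
    lesions <- lapply(c("L1", "L2", "L3"), lesionPreset)
    names(lesions) <- c("L1", "L2", "L3")
  }
  if (is.null(names(lesions)) || any(names(lesions) == ""))
    names(lesions) <- vapply(lesions, lesionName, character(1))

  images <- list()
  vois <- list()
  sessions <- list()
  design <- NULL
  k <- 0L
  for (ln in names(lesions)) {
    les <- lesions[[ln]]
    for (code in names(settings)) {
      st <- settings[[code]]
      row <- schedule[schedule$scanner == st@scannerName &
                        schedule$lesion == ln, , drop = FALSE]
      if (nrow(row) != 1L)
        stopf("schedule has no unique entry for scanner '%s', lesion '%s'",
              st@scannerName, ln)
      ses <- phantomSession(
        tankVolumeL = row$volume_l,
        backgroundActivityMbq = row$initial_activity_mbq,
        acquisitionTimeS = row$acquisition_time_s,
        scanner = st@scannerName,
        timeInaccuracyS = row$time_inaccuracy_s)
      plan <- planTrajectory(les, acquisitionTime = ses@acquisitionTimeS)
      map <- paintGroundTruth(les, plan, ses,
                              fineSpacing = fineSpacing, fovMm = fovMm)
      k <- k + 1L
      img <- acquire(map, st, ses, seed = as.integer(seed) * 1000L + k)
      key <- paste(ln, code, sep = "_")
      images[[key]] <- img
      vois[[key]] <- makeVOI(les, img, mode = "ground_truth")
      sessions[[key]] <- ses
      design <- rbind(design, data.frame(
        lesion = ln, setting = code, scanner = st@scannerName,
        stringsAsFactors = FALSE))
    }
  }
  list(images = images, vois = vois, sessions = sessions, design = design)
}
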