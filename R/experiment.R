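# End-to-end experiment orchestration from a single configuration.

#' Construct a GreyLevelVolume directly from integer levels
#'
#' Wraps a plain integer 3-D array (NA outside the VOI) so texture
#' matrices and features can be computed on hand-made or fixture volumes
#' without running the imaging pipeline.
#'
#' @param levels 3-D integer array, `NA` outside the VOI, levels >= 1.
#' @param spacing mm triple.
#' @param method nominal discretization label.
#' @return a [GreyLevelVolume-class].
#' @examples
#' glv <- greyLevelVolume(array(1L, c(3, 3, 3)))
#' glcmFeatures(glv)["GLCM_Energy"]  # 1
#' @export
greyLevelVolume <- function(levels, spacing = c(1, 1, 1), method = "FBS") {
  storage.mode(levels) <- "integer"
  new("GreyLevelVolume",
      levels = levels, nLevels = max(levels, na.rm = TRUE),
      method = method,
      binWidth = if (method == "FBS") 1.0 else NA_real_,
      binCount = if (method == "FBN") max(levels, na.rm = TRUE)
      else NA_integer_,
      intensityRange = range(levels, na.rm = TRUE),
      spacing = rep_len(spacing, 3L))
}

#' Default experiment configuration
#'
#' The shipped configuration mirrors the study design: the three lesion
#' presets, the five-scanner schedule, the eight-setting registry, B =
#' 0.3125 SUV / D = 64 discretization, native-grid analysis with reference
#' setting D.
#'
#' @param seed master seed.
#' @return a named list understood by [runExperiment()].
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    lesions = c("L1", "L2", "L3"),
    grid_spacing_mm = 2.5,
    fine_spacing_mm = 1,
    fov_mm = 80,
    settings_file = NULL,
    schedule_file = NULL,
    discretization = list(B = 0.3125, D = 64L),
    resampling = list("native"),
    reference_setting = "D",
    seed = as.integer(seed)
  )
}

#' Read an experiment configuration from YAML or JSON
#'
#' Fields absent from the file fall back to [defaultConfig()] values.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration.
#' @return configuration list.
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stopf("configuration file '%s' not found", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- defaultConfig()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  validateConfig(base)
}

#' @noRd
validateConfig <- function(cfg) {
  if (!length(cfg$lesions)) stopf("config: at least one lesion required")
  if (!is.numeric(cfg$discretization$B) || cfg$discretization$B <= 0)
    stopf("config: discretization B must be positive")
  if (cfg$discretization$D < 2) stopf("config: discretization D must be >= 2")
  if (is.null(cfg$seed)) stopf("config: a seed is required")
  cfg
}

#' Run the full experiment
#'
#' Pipeline: lesion generation -> trajectory planning -> activity painting
#' (per scanner session) -> surrogate acquisition through every imaging
#' setting -> ground-truth VOIs -> feature extraction under both
#' discretizations (and any requested resampling levels) -> robustness
#' report. Reruns with the same configuration are bit-identical.
#'
#' @param config configuration list ([defaultConfig()] or
#'   [readExperimentConfig()]).
#' @param outputDir optional directory; when given, the feature table,
#'   report CSVs and a JSON manifest (seed, design counts, file checksums)
#'   are written there.
#' @param keepImages keep the rendered [SUVImage-class] objects in the
#'   return value.
#' @return list with `features` (data.frame), `report`
#'   ([RobustnessReport-class]), `design`, `config`, and optionally
#'   `images`/`vois`.
#' @examples
#' \donttest{
#' res <- runExperiment(defaultConfig(seed = 1))
#' res$report
#' }
#' @export
runExperiment <- function(config = defaultConfig(), outputDir = NULL,
                          keepImages = FALSE) {
  config <- validateConfig(config)
  lesions <- lapply(config$lesions, function(nm) {
    if (nm %in% names(.lesionPresets))
      lesionPreset(nm, gridSpacing = config$grid_spacing_mm)
    else stopf("unknown lesion '%s' (presets: %s)", nm,
               paste(names(.lesionPresets), collapse = ", "))
  })
  names(lesions) <- config$lesions
  settings <- imagingSettings(config$settings_file)
  schedule <- sessionSchedule(config$schedule_file)

  study <- acquireAll(lesions = lesions, settings = settings,
                      schedule = schedule, seed = config$seed,
                      fineSpacing = config$fine_spacing_mm,
                      fovMm = config$fov_mm)
  resampling <- unlist(config$resampling)
  ft <- featureTable(study,
                     B = config$discretization$B,
                     D = as.integer(config$discretization$D),
                     resampling = resampling)
  canIcc <- length(lesions) >= 2 && length(settings) >= 2
  report <- if (canIcc)
    buildReport(ft, reference = config$reference_setting)
  else NULL
  if (!canIcc)
    message("fewer than 2 lesions or settings: robustness report skipped ",
            "(ICC and lesion-pair tests need the full design)")

  out <- list(features = ft, report = report, design = study$design,
              config = config)
  if (keepImages) {
    out$images <- study$images
    out$vois <- study$vois
  }

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    ftPath <- file.path(outputDir, "features.csv")
    utils::write.csv(ft, ftPath, row.names = FALSE)
    paths <- ftPath
    if (!is.null(report))
      paths <- c(paths, writeReport(report, outputDir))
    manifest <- list(
      package = "phantomics",
      version = as.character(utils::packageVersion("phantomics")),
      seed = config$seed,
      lesions = config$lesions,
      settings = names(settings),
      n_feature_rows = nrow(ft),
      n_features = nrow(featureCatalogue()),
      checksums = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Tiny hand-checkable texture fixtures
#'
#' Small grey-level volumes whose texture matrices can be enumerated by
#' hand or by the brute-force oracles of the test suite: a constant cube, a
#' single ramp line, a two-level checkerboard and a seeded random volume.
#'
#' @param seed seed for the random fixture.
#' @return named list of [GreyLevelVolume-class] objects.
#' @examples
#' fx <- generateFixtures(seed = 1)
#' glcmFeatures(fx$constant_cube)["GLCM_Energy"]  # 1
#' @export
generateFixtures <- function(seed = 1L) {
  constant <- greyLevelVolume(array(1L, c(3, 3, 3)))
  ramp <- greyLevelVolume(array(1:5, c(5, 1, 1)))
  cb <- array(0L, c(3, 3, 3))
  idx <- which(array(TRUE, c(3, 3, 3)), arr.ind = TRUE)
  cb[] <- 1L + (idx[, 1] + idx[, 2] + idx[, 3]) %% 2L
  rnd <- withSeed(seed, array(sample.int(4L, 64L, replace = TRUE),
                              c(4, 4, 4)))
  list(constant_cube = constant,
       ramp_line = ramp,
       checkerboard = greyLevelVolume(cb),
       random_4cube = greyLevelVolume(rnd))
}
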