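#' Generate a procedural lesion template
#'
#' Builds a heterogeneous 3-D target activity pattern on the isotropic
#' painting grid. Lesions are mixtures of a smooth radial profile and a
#' lumpy Gaussian-blob field; the `heterogeneity` weight moves the pattern
#' from a compact quasi-spherical lesion towards an irregular multi-focal
#' one. The support is the requested volume's worth of highest-field cells,
#' so the physical volume matches `volumeMl` to within one grid cell.
#'
#' @param volumeMl target lesion volume in mL; must fit the 5x5x5 cm
#'   painting cube (<= 125 mL).
#' @param heterogeneity value in `[0, 1]`: 0 gives a compact smooth lesion,
#'   1 a strongly lumpy, irregular one.
#' @param nBlobs number of Gaussian blobs in the lumpy component.
#' @param shape `"lumpy"` (default) or `"sphere"` for a homogeneous
#'   (all-equal-values) digital ball.
#' @param gridSpacing painting-grid pitch in mm (default 2.5 mm, i.e. a
#'   20^3 grid across the 50 mm cube).
#' @param name label stored in the template.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a [LesionTemplate-class].
#' @examples
#' les <- generateLesion(10, heterogeneity = 0.5, seed = 1)
#' volumeMl(les)
#' @export
generateLesion <- function(volumeMl, heterogeneity = 0.5, nBlobs = 8L,
                           shape = c("lumpy", "sphere"), gridSpacing = 2.5,
                           name = "lesion", seed) {
  shape <- match.arg(shape)
  if (missing(seed)) stopf("'seed' is required: lesion generation is seeded")
  if (volumeMl <= 0) stopf("'volumeMl' must be positive")
  if (volumeMl > 125) {
    stopf(paste(
      "requested volume %.2f mL exceeds the 125 mL capacity of the",
      "5x5x5 cm painting cube"
    ), volumeMl)
  }
  if (heterogeneity < 0 || heterogeneity > 1)
    stopf("'heterogeneity' must be in [0, 1]")
  n <- floor(50 / gridSpacing)
  if (n < 2) stopf("'gridSpacing' too coarse for the 50 mm cube")
  cellMl <- gridSpacing^3 / 1000
  nCells <- round(volumeMl / cellMl)
  if (nCells < 1) stopf("requested volume smaller than one grid cell")
  if (nCells > n^3)
    stopf("requested volume does not fit the painting grid")

  ax <- axisCentres(n, gridSpacing)
  gx <- array(ax, c(n, n, n))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  r2 <- gx^2 + gy^2 + gz^2

  if (shape == "sphere") {
    ord <- order(r2)
    vals <- array(0, c(n, n, n))
    vals[ord[seq_len(nCells)]] <- 1
    return(new("LesionTemplate", name = name, gridSpacing = gridSpacing,
               values = vals))
  }

  withSeed(seed, {
    # radial component: smooth profile filling the cube centre
    r0 <- (3 * volumeMl * 1000 / (4 * pi))^(1 / 3)  # equivalent-sphere radius
    radial <- exp(-r2 / (2 * (0.9 * r0)^2))
    # lumpy component: random Gaussian blobs inside the reachable volume
    blobs <- array(0, c(n, n, n))
    for (b in seq_len(nBlobs)) {
      ctr <- stats::runif(3, -0.75, 0.75) * r0
      sd <- stats::runif(1, 0.18, 0.45) * r0 * (1.3 - 0.6 * heterogeneity)
      amp <- stats::runif(1, 0.5, 1)
      d2 <- (gx - ctr[1])^2 + (gy - ctr[2])^2 + (gz - ctr[3])^2
      blobs <- blobs + amp * exp(-d2 / (2 * sd^2))
    }
    blobs <- blobs / max(blobs)
    field <- (1 - heterogeneity) * radial + heterogeneity * blobs
    # taper keeps the support central and mostly connected
    field <- field * exp(-r2 / (2 * (1.6 * r0)^2))
    ord <- order(field, decreasing = TRUE)
    sup <- ord[seq_len(nCells)]
    vals <- array(0, c(n, n, n))
    lo <- min(field[sup])
    hi <- max(field[sup])
    # rescale support values into (0.1, 1]: strictly positive dwell targets
    vals[sup] <- if (hi > lo) 0.1 + 0.9 * (field[sup] - lo) / (hi - lo) else 1
    new("LesionTemplate", name = name, gridSpacing = gridSpacing,
        values = vals)
  })
}

# Canonical presets: volumes of the three painted lesions with an
# increasing heterogeneity ordering (L1 most compact, L3 most complex).
.lesionPresets <- list(
  L1 = list(volumeMl = 8.66, heterogeneity = 0.25, nBlobs = 4L, seed = 101L),
  L2 = list(volumeMl = 11.55, heterogeneity = 0.55, nBlobs = 8L, seed = 102L),
  L3 = list(volumeMl = 15.44, heterogeneity = 0.85, nBlobs = 14L, seed = 103L)
)

#' Canonical lesion presets L1-L3
#'
#' Three reproducible lesion templates with the study volumes (8.66, 11.55
#' and 15.44 mL) and increasing visual heterogeneity. Volumes are realised
#' as whole painting-grid cells, so they match the nominal values to within
#' half a cell (0.0156 mL at the default 2.5 mm pitch).
#'
#' @param name `"L1"`, `"L2"` or `"L3"`.
#' @param gridSpacing painting-grid pitch in mm.
#' @return a [LesionTemplate-class].
#' @examples
#' volumeMl(lesionPreset("L1"))
#' @export
lesionPreset <- function(name = c("L1", "L2", "L3"), gridSpacing = 2.5) {
  name <- match.arg(name)
  p <- .lesionPresets[[name]]
  generateLesion(p$volumeMl, heterogeneity = p$heterogeneity,
                 nBlobs = p$nBlobs, gridSpacing = gridSpacing,
                 name = name, seed = p$seed)
}
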