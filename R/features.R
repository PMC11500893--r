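# The 46 radiomic indices: conventional SUV statistics, shape, histogram
# and the four texture families. Formulas follow the LIFEx v4 / IBSI
# conventions; the catalogue below is the frozen name registry.

.featureFamilies <- list(
  CONV = c("CONV_SUVmin", "CONV_SUVmean", "CONV_SUVstd", "CONV_SUVmax",
           "CONV_SUVpeak", "CONV_TLG"),
  SHAPE = c("SHAPE_Volume_mL", "SHAPE_Sphericity", "SHAPE_Compacity"),
  HISTO = c("HISTO_Skewness", "HISTO_Kurtosis", "HISTO_Entropy_log10",
            "HISTO_Entropy_log2", "HISTO_Energy"),
  GLCM = c("GLCM_Homogeneity", "GLCM_Energy", "GLCM_Contrast",
           "GLCM_Correlation", "GLCM_Entropy_log10", "GLCM_Entropy_log2",
           "GLCM_Dissimilarity"),
  GLRLM = c("GLRLM_SRE", "GLRLM_LRE", "GLRLM_LGRE", "GLRLM_HGRE",
            "GLRLM_SRLGE", "GLRLM_SRHGE", "GLRLM_LRLGE", "GLRLM_LRHGE",
            "GLRLM_GLNU", "GLRLM_RLNU", "GLRLM_RP"),
  NGLDM = c("NGLDM_Coarseness", "NGLDM_Contrast", "NGLDM_Busyness"),
  GLZLM = c("GLZLM_SZE", "GLZLM_LZE", "GLZLM_LGZE", "GLZLM_HGZE",
            "GLZLM_SZLGE", "GLZLM_SZHGE", "GLZLM_LZLGE", "GLZLM_LZHGE",
            "GLZLM_GLNU", "GLZLM_ZLNU", "GLZLM_ZP")
)

#' The frozen 46-index catalogue
#'
#' Names and families of the radiomic indices the extractor computes.
#' The metabolically active tumour volume (MATV) and `SHAPE_Volume_mL`
#' are the same quantity and are counted once, under the shape family.
#'
#' @return data.frame with columns `name` and `family` (46 rows).
#' @examples
#' nrow(featureCatalogue())  # 46
#' @export
featureCatalogue <- function() {
  data.frame(
    name = unlist(.featureFamilies, use.names = FALSE),
    family = rep(names(.featureFamilies),
                 vapply(.featureFamilies, length, integer(1))),
    stringsAsFactors = FALSE
  )
}

#' Conventional SUV statistics
#'
#' SUVmin/mean/std/max over the VOI, SUVpeak (mean SUV in a 1 mL sphere
#' centred on the hottest VOI voxel, intersected with the VOI), total lesion
#' glycolysis TLG = SUVmean x volume, and the metabolically active volume
#' MATV (mL). SUVstd is the population standard deviation.
#'
#' @param image an [SUVImage-class].
#' @param voi an aligned [VOIMask-class].
#' @return named numeric vector (`CONV_SUVmin`, ..., `CONV_TLG`, `MATV_mL`).
#' @export
conventionalFeatures <- function(image, voi) {
  checkAligned(image, voi)
  v <- image@values[voi@mask]
  volMl <- volumeMl(voi)
  n <- length(v)
  m <- mean(v)
  sdev <- sqrt(sum((v - m)^2) / n)

  # SUVpeak: 1 mL sphere on the voxel grid, centred on the hottest voxel
  rPeak <- (3 * 1000 / (4 * pi))^(1 / 3)  # 6.2035 mm
  idx <- which(voi@mask, arr.ind = TRUE)
  hot <- idx[which.max(v), ]
  d <- dim(voi@mask)
  sp <- voi@spacing
  rad <- pmin(ceiling(rPeak / sp), d - 1)
  rng <- lapply(1:3, function(k)
    seq(max(1, hot[k] - rad[k]), min(d[k], hot[k] + rad[k])))
  gi <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  dist2 <- ((gi$i - hot[1]) * sp[1])^2 + ((gi$j - hot[2]) * sp[2])^2 +
    ((gi$k - hot[3]) * sp[3])^2
  sphere <- gi[dist2 <= rPeak^2, , drop = FALSE]
  inVoi <- voi@mask[cbind(sphere$i, sphere$j, sphere$k)]
  if (volMl < 1)
    warnf("VOI (%.2f mL) smaller than the 1 mL peak sphere; peak taken over the %d available voxels",
          volMl, sum(inVoi))
  peakVox <- sphere[inVoi, , drop = FALSE]
  peak <- mean(image@values[cbind(peakVox$i, peakVox$j, peakVox$k)])

  c(CONV_SUVmin = min(v), CONV_SUVmean = m, CONV_SUVstd = sdev,
    CONV_SUVmax = max(v), CONV_SUVpeak = peak, CONV_TLG = m * volMl,
    MATV_mL = volMl)
}

#' Shape descriptors of the segmented VOI
#'
#' Volume (mL), Sphericity `pi^(1/3) (6V)^(2/3) / A` (clamped to (0, 1]:
#' the mesh estimate can overshoot 1 by a percent on near-perfect digital
#' balls) and Compacity `V / (sqrt(pi) A^(3/2))` with V in mm^3 and the
#' surface area A in mm^2 from the dual-contouring boundary mesh
#' ([surfaceArea()]).
#'
#' @param voi a [VOIMask-class].
#' @return named numeric vector.
#' @export
shapeFeatures <- function(voi) {
  stopifnot(is(voi, "VOIMask"))
  vMm3 <- voxelCount(voi) * prod(voi@spacing)
  A <- surfaceArea(voi@mask, spacing = voi@spacing)
  sph <- min(pi^(1 / 3) * (6 * vMm3)^(2 / 3) / A, 1)
  comp <- vMm3 / (sqrt(pi) * A^(3 / 2))
  c(SHAPE_Volume_mL = vMm3 / 1000, SHAPE_Sphericity = sph,
    SHAPE_Compacity = comp)
}

#' Histogram indices of a discretized VOI
#'
#' Skewness and kurtosis (Pearson, `m4 / m2^2`, not excess) of the grey
#' levels, Shannon entropy of the level histogram in log2 and log10, and
#' energy (sum of squared level probabilities). Zero-variance volumes give
#' skewness/kurtosis 0 with a warning.
#'
#' @param glv a [GreyLevelVolume-class].
#' @return named numeric vector.
#' @export
histogramFeatures <- function(glv) {
  x <- glv@levels[!is.na(glv@levels)]
  if (length(x) < 2L) stopf("histogram features need at least 2 voxels")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warnf("zero-variance volume: skewness and kurtosis undefined, reported as 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  }
  p <- tabulate(x, nbins = glv@nLevels)
  p <- p[p > 0] / length(x)
  h2 <- -sum(p * log2(p))
  c(HISTO_Skewness = skew, HISTO_Kurtosis = kurt,
    HISTO_Entropy_log10 = h2 * log10(2), HISTO_Entropy_log2 = h2,
    HISTO_Energy = sum(p^2))
}

#' Co-occurrence (GLCM) indices
#'
#' Homogeneity, energy, contrast, correlation, entropy (log2/log10) and
#' dissimilarity of the direction-merged co-occurrence probabilities.
#' A constant volume is degenerate: correlation is undefined and reported
#' as 0 with a warning.
#'
#' @inheritParams glcmMatrix
#' @return named numeric vector.
#' @export
glcmFeatures <- function(glv, directions = directions13()) {
  P <- glcmMatrix(glv, directions)
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pos <- P > 0
  ent2 <- -sum(P[pos] * log2(P[pos]))
  pi_ <- rowSums(P)
  mu <- sum(seq_len(L) * pi_)
  s2 <- sum((seq_len(L) - mu)^2 * pi_)
  if (s2 == 0) {
    warnf("constant volume: GLCM correlation undefined, reported as 0")
    corr <- 0
  } else {
    corr <- (sum(i * j * P) - mu^2) / s2
  }
  c(GLCM_Homogeneity = sum(P / (1 + abs(i - j))),
    GLCM_Energy = sum(P^2),
    GLCM_Contrast = sum((i - j)^2 * P),
    GLCM_Correlation = corr,
    GLCM_Entropy_log10 = ent2 * log10(2),
    GLCM_Entropy_log2 = ent2,
    GLCM_Dissimilarity = sum(abs(i - j) * P))
}

#' Run-length (GLRLM) indices
#'
#' Standard eleven indices of the direction-merged run-length matrix; run
#' percentage RP is the run count divided by (voxels x directions), so a
#' single-direction analysis of an N-voxel constant line gives RP = 1/N.
#'
#' @inheritParams glcmMatrix
#' @return named numeric vector.
#' @export
glrlmFeatures <- function(glv, directions = directions13()) {
  rl <- glrlmMatrix(glv, directions)
  M <- rl$matrix
  nRuns <- sum(M)
  nVox <- voxelCount(glv)
  L <- nrow(M); R <- ncol(M)
  i2 <- matrix(seq_len(L)^2, L, R)
  l2 <- matrix(rep(seq_len(R)^2, each = L), L, R)
  c(GLRLM_SRE = sum(M / l2) / nRuns,
    GLRLM_LRE = sum(M * l2) / nRuns,
    GLRLM_LGRE = sum(M / i2) / nRuns,
    GLRLM_HGRE = sum(M * i2) / nRuns,
    GLRLM_SRLGE = sum(M / (i2 * l2)) / nRuns,
    GLRLM_SRHGE = sum(M * i2 / l2) / nRuns,
    GLRLM_LRLGE = sum(M * l2 / i2) / nRuns,
    GLRLM_LRHGE = sum(M * i2 * l2) / nRuns,
    GLRLM_GLNU = sum(rowSums(M)^2) / nRuns,
    GLRLM_RLNU = sum(colSums(M)^2) / nRuns,
    GLRLM_RP = nRuns / (nVox * rl$nDirections))
}

#' Neighbourhood grey-level difference (NGLDM) indices
#'
#' Coarseness, contrast and busyness from the 26-neighbour mean-difference
#' aggregates. A constant volume has no differences: contrast and busyness
#' are 0 and coarseness saturates at `1/eps`.
#'
#' @param glv a [GreyLevelVolume-class].
#' @param eps guard for the coarseness inverse.
#' @return named numeric vector.
#' @export
ngldmFeatures <- function(glv, eps = 1e-6) {
  tb <- ngldmTable(glv)
  p <- tb$p; s <- tb$s; N <- tb$nVoxels
  L <- length(p)
  lev <- seq_len(L)
  present <- p > 0
  Ng <- sum(present)
  coarse <- 1 / (eps + sum(p * s))
  if (Ng > 1) {
    pp <- outer(p[present], p[present])
    dd <- outer(lev[present], lev[present], `-`)^2
    contrast <- sum(pp * dd) / (Ng * (Ng - 1)) * sum(s) / N
    den <- 0
    ip <- lev[present] * p[present]
    den <- sum(abs(outer(ip, ip, `-`)))
    busy <- if (den > 0) sum(p * s) / den else 0
  } else {
    contrast <- 0
    busy <- 0
  }
  c(NGLDM_Coarseness = coarse, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busy)
}

#' Zone-length (GLZLM) indices
#'
#' Standard eleven indices of the size-zone matrix (26-connected zones);
#' zone percentage ZP is the zone count divided by the voxel count.
#'
#' @param glv a [GreyLevelVolume-class].
#' @return named numeric vector.
#' @export
glzlmFeatures <- function(glv) {
  M <- glzlmMatrix(glv)
  nZones <- sum(M)
  nVox <- voxelCount(glv)
  L <- nrow(M); S <- ncol(M)
  i2 <- matrix(seq_len(L)^2, L, S)
  s2 <- matrix(rep(seq_len(S)^2, each = L), L, S)
  c(GLZLM_SZE = sum(M / s2) / nZones,
    GLZLM_LZE = sum(M * s2) / nZones,
    GLZLM_LGZE = sum(M / i2) / nZones,
    GLZLM_HGZE = sum(M * i2) / nZones,
    GLZLM_SZLGE = sum(M / (i2 * s2)) / nZones,
    GLZLM_SZHGE = sum(M * i2 / s2) / nZones,
    GLZLM_LZLGE = sum(M * s2 / i2) / nZones,
    GLZLM_LZHGE = sum(M * i2 * s2) / nZones,
    GLZLM_GLNU = sum(rowSums(M)^2) / nZones,
    GLZLM_ZLNU = sum(colSums(M)^2) / nZones,
    GLZLM_ZP = nZones / nVox)
}

#' Extract the full 46-index feature vector
#'
#' Runs the complete extraction for one image/VOI under one discretization
#' scheme: conventional and shape indices from the SUV image (identical for
#' both schemes by construction), histogram and texture indices from the
#' discretized grey levels.
#'
#' @param image an [SUVImage-class].
#' @param voi an aligned [VOIMask-class].
#' @param discretization `"FBS"` or `"FBN"`.
#' @param B FBS bin width (SUV).
#' @param D FBN bin count.
#' @return named numeric vector of exactly 46 indices, ordered as
#'   [featureCatalogue()].
#' @export
extractFeatures <- function(image, voi, discretization = c("FBS", "FBN"),
                            B = 0.3125, D = 64L) {
  discretization <- match.arg(discretization)
  glv <- if (discretization == "FBS") discretizeFBS(image, voi, B = B)
  else discretizeFBN(image, voi, D = D)
  conv <- conventionalFeatures(image, voi)
  out <- c(conv[setdiff(names(conv), "MATV_mL")],
           shapeFeatures(voi),
           histogramFeatures(glv),
           glcmFeatures(glv),
           glrlmFeatures(glv),
           ngldmFeatures(glv),
           glzlmFeatures(glv))
  cat46 <- featureCatalogue()$name
  stopifnot(identical(names(out), cat46))
  out
}

#' Build the tidy feature table of a study
#'
#' One row per (lesion, setting, discretization, resampling level) with the
#' 46 feature columns plus metadata; the container the robustness
#' statistics consume.
#'
#' @param study output of [acquireAll()].
#' @param discretizations character subset of `c("FBS", "FBN")`.
#' @param B,D discretization parameters.
#' @param resampling `"native"` and/or numeric voxel sizes in mm (e.g.
#'   `c("native", 4, 3, 2.5, 1)`).
#' @return data.frame (a feature table).
#' @examples
#' \donttest{
#' ft <- featureTable(acquireAll(seed = 1))
#' dim(ft)  # 48 x 50
#' }
#' @export
featureTable <- function(study, discretizations = c("FBS", "FBN"),
                         B = 0.3125, D = 64L, resampling = "native") {
  rows <- list()
  for (key in names(study$images)) {
    img0 <- study$images[[key]]
    voi0 <- study$vois[[key]]
    for (res in resampling) {
      if (identical(res, "native")) {
        img <- img0; voi <- voi0; resLab <- "native"
      } else {
        rs <- resampleImage(img0, as.numeric(res), voi = voi0)
        img <- rs$image; voi <- rs$voi
        resLab <- as.character(res)
      }
      for (disc in discretizations) {
        fv <- extractFeatures(img, voi, discretization = disc, B = B, D = D)
        rows[[length(rows) + 1L]] <- data.frame(
          lesion = img0@lesionName, setting = img0@settingCode,
          discretization = disc, resampling = resLab,
          as.list(fv), check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
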