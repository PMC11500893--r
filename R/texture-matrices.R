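# Grey-level texture matrices. All builders take a GreyLevelVolume whose
# `levels` array is NA outside the VOI; grey levels are 1..nLevels.

#' Grey-level co-occurrence matrix
#'
#' Counts symmetric voxel pairs at Chebyshev distance 1 along the given
#' lattice directions, merged into a single matrix and normalised to
#' probabilities (the matrix sums to 1).
#'
#' @param glv a [GreyLevelVolume-class].
#' @param directions integer matrix of lattice directions (rows), default
#'   the 13 unique 3-D directions.
#' @return `nLevels x nLevels` probability matrix.
#' @export
glcmMatrix <- function(glv, directions = directions13()) {
  lv <- glv@levels
  L <- glv@nLevels
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(directions))) {
    nb <- arrayShift(lv, directions[r, ], fill = NA_integer_)
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    a <- lv[ok]; b <- nb[ok]
    tab <- table(factor(a, levels = seq_len(L)),
                 factor(b, levels = seq_len(L)))
    counts <- counts + tab + t(tab)  # symmetric pairs
  }
  tot <- sum(counts)
  if (tot == 0) return(counts)
  counts / tot
}

#' Grey-level run-length matrix
#'
#' Maximal runs of equal grey level along each direction, accumulated over
#' the given directions. Entry `(i, l)` counts runs of level `i` and length
#' `l`. Within any single direction the run-length-weighted total equals the
#' VOI voxel count.
#'
#' @inheritParams glcmMatrix
#' @return list with `matrix` (`nLevels x maxRunLength` counts) and
#'   `nDirections`.
#' @export
glrlmMatrix <- function(glv, directions = directions13()) {
  lv <- glv@levels
  L <- glv@nLevels
  d <- dim(lv)
  n <- prod(d)
  ix <- slice.index(lv, 1); iy <- slice.index(lv, 2); iz <- slice.index(lv, 3)
  allLevels <- integer(0)
  allLengths <- integer(0)
  for (r in seq_len(nrow(directions))) {
    dd <- directions[r, ]
    nz <- which(dd != 0)[1]
    tpos <- switch(nz, ix, iy, iz) * dd[nz]
    k1 <- ix - tpos * dd[1]
    k2 <- iy - tpos * dd[2]
    k3 <- iz - tpos * dd[3]
    ord <- order(k1, k2, k3, tpos)
    lvo <- lv[ord]
    k1o <- k1[ord]; k2o <- k2[ord]; k3o <- k3[ord]
    newline <- c(TRUE, k1o[-1] != k1o[-n] | k2o[-1] != k2o[-n] |
                   k3o[-1] != k3o[-n])
    same <- c(FALSE, !is.na(lvo[-1]) & !is.na(lvo[-n]) &
                lvo[-1] == lvo[-n]) & !newline
    runId <- cumsum(!same)
    keep <- !is.na(lvo)
    if (!any(keep)) next
    lens <- tabulate(runId[keep])
    lvl <- lvo[keep][!duplicated(runId[keep])]
    lens <- lens[lens > 0]
    allLevels <- c(allLevels, lvl)
    allLengths <- c(allLengths, lens)
  }
  if (!length(allLengths))
    return(list(matrix = matrix(0, L, 1), nDirections = nrow(directions)))
  Rmax <- max(allLengths)
  m <- matrix(0, L, Rmax)
  for (k in seq_along(allLengths))
    m[allLevels[k], allLengths[k]] <- m[allLevels[k], allLengths[k]] + 1
  list(matrix = m, nDirections = nrow(directions))
}

#' Grey-level zone-length (size-zone) matrix
#'
#' Zones are 26-connected components of equal grey level; entry `(i, s)`
#' counts zones of level `i` and size `s` voxels. The size-weighted total
#' equals the VOI voxel count.
#'
#' @param glv a [GreyLevelVolume-class].
#' @return `nLevels x maxZoneSize` count matrix.
#' @export
glzlmMatrix <- function(glv) {
  lv <- glv@levels
  L <- glv@nLevels
  d <- dim(lv)
  # pad with NA so neighbour linear offsets never wrap
  pd <- d + 2L
  a <- array(NA_integer_, pd)
  a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lv
  offs <- offsets26()
  linOff <- offs[, 1] + pd[1] * offs[, 2] + pd[1] * pd[2] * offs[, 3]
  todo <- which(!is.na(a))
  visited <- logical(length(a))
  zoneLevel <- integer(0)
  zoneSize <- integer(0)
  stack <- integer(length(todo))
  for (s0 in todo) {
    if (visited[s0]) next
    lev <- a[s0]
    visited[s0] <- TRUE
    top <- 1L
    stack[1L] <- s0
    size <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      size <- size + 1L
      nbs <- cur + linOff
      for (nb in nbs) {
        if (!visited[nb] && !is.na(a[nb]) && a[nb] == lev) {
          visited[nb] <- TRUE
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
    zoneLevel <- c(zoneLevel, lev)
    zoneSize <- c(zoneSize, size)
  }
  Smax <- max(zoneSize)
  m <- matrix(0, L, Smax)
  for (k in seq_along(zoneSize))
    m[zoneLevel[k], zoneSize[k]] <- m[zoneLevel[k], zoneSize[k]] + 1
  m
}

#' Neighbourhood grey-level difference aggregates
#'
#' For every in-VOI voxel with at least one in-VOI 26-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per grey level (the neighbourhood
#' grey-level difference table).
#'
#' @param glv a [GreyLevelVolume-class].
#' @return list with `p` (occurrence probability per level), `s` (summed
#'   absolute neighbourhood difference per level), `nVoxels`.
#' @export
ngldmTable <- function(glv) {
  lv <- glv@levels
  L <- glv@nLevels
  num <- array(0, dim(lv))
  cnt <- array(0, dim(lv))
  offs <- offsets26()
  for (r in seq_len(nrow(offs))) {
    nb <- arrayShift(lv, offs[r, ], fill = NA_integer_)
    ok <- !is.na(nb)
    num[ok] <- num[ok] + nb[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  inv <- !is.na(lv) & cnt > 0
  sdiff <- abs(lv[inv] - num[inv] / cnt[inv])
  levIn <- lv[inv]
  nV <- sum(inv)
  p <- tabulate(levIn, nbins = L) / nV
  s <- vapply(seq_len(L), function(g) sum(sdiff[levIn == g]), numeric(1))
  list(p = p, s = s, nVoxels = nV)
}
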