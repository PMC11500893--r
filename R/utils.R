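# Internal array helpers shared by the phantom, scanner and texture code.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Shift a 3-D array by an integer offset, zero-filling (or `fill`-filling)
#' @noRd
arrayShift <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    o <- off[i]
    if (abs(o) >= d[i]) return(out)
    if (o >= 0) {
      src[[i]] <- seq_len(d[i] - o)
      dst[[i]] <- seq_len(d[i] - o) + o
    } else {
      src[[i]] <- seq_len(d[i] + o) - o
      dst[[i]] <- seq_len(d[i] + o)
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Separable 3-D Gaussian smoothing.
#'
#' `sigma` is given per axis in voxel units; the kernel is normalised so a
#' constant field is preserved and total intensity is conserved away from the
#' array boundary (edge handling: zero padding by default, replicate when
#' `edge = "replicate"`).
#' @noRd
gaussianSmooth3d <- function(a, sigma, edge = c("zero", "replicate")) {
  edge <- match.arg(edge)
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3.5 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    d <- dim(a)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1L])
    out <- matrix(0, nrow = db[1L], ncol = ncol(m))
    n <- db[1L]
    for (j in seq_along(k)) {
      o <- j - r - 1L
      idx <- seq_len(n) + o
      if (edge == "replicate") {
        src <- pmin(pmax(idx, 1L), n)
        out <- out + k[j] * m[src, , drop = FALSE]
      } else {
        keep <- idx >= 1L & idx <= n
        out[keep, ] <- out[keep, ] + k[j] * m[idx[keep], , drop = FALSE]
      }
    }
    a <- aperm(array(out, db), order(perm))
  }
  a
}

#' FWHM (mm) to Gaussian sigma (mm)
#' @noRd
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Voxel/cell centre coordinates of an n-cell axis centred on zero
#' @noRd
axisCentres <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' The 13 unique 3-D lattice directions at Chebyshev distance 1
#' @noRd
directions13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

#' All 26 neighbour offsets
#' @noRd
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)
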