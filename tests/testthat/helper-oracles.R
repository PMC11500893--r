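# Brute-force texture oracles: naive enumeration, independent of the
# package's vectorised implementations.

oracleDirections <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# naive symmetric pair enumeration
oracleGlcm <- function(lev, directions = oracleDirections()) {
  d <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  counts <- matrix(0, L, L)
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    for (r in seq_len(nrow(directions))) {
      q <- c(i, j, k) + directions[r, ]
      if (!inside(q)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) counts else counts / sum(counts)
}

# walk every line voxel by voxel, collect maximal runs
oracleGlrlm <- function(lev, directions = oracleDirections()) {
  d <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  inside <- function(p) all(p >= 1) && all(p <= d)
  runs <- list()
  for (r in seq_len(nrow(directions))) {
    dd <- directions[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      p <- c(i, j, k)
      prev <- p - dd
      if (inside(prev)) next  # not a line start
      vals <- c()
      while (inside(p)) {
        vals <- c(vals, lev[p[1], p[2], p[3]])
        p <- p + dd
      }
      rl <- rle(vals)
      keep <- !is.na(rl$values)
      if (any(keep))
        runs[[length(runs) + 1L]] <-
          cbind(rl$values[keep], rl$lengths[keep])
    }
  }
  rn <- do.call(rbind, runs)
  m <- matrix(0, L, max(rn[, 2]))
  for (q in seq_len(nrow(rn))) m[rn[q, 1], rn[q, 2]] <- m[rn[q, 1], rn[q, 2]] + 1
  m
}

# connected components by iterative label propagation (not flood fill)
oracleGlzlm <- function(lev) {
  d <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  lab <- array(seq_along(lev), d)
  lab[is.na(lev)] <- NA_integer_
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (is.na(lev[i, j, k])) next
      for (r in seq_len(nrow(offs))) {
        q <- c(i, j, k) + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (is.na(lev[q[1], q[2], q[3]])) next
        if (lev[q[1], q[2], q[3]] == lev[i, j, k] &&
            lab[q[1], q[2], q[3]] < lab[i, j, k]) {
          lab[i, j, k] <- lab[q[1], q[2], q[3]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  zs <- table(lab[!is.na(lab)])
  zl <- vapply(as.integer(names(zs)), function(s) lev[s], integer(1))
  m <- matrix(0, L, max(zs))
  for (q in seq_along(zs)) m[zl[q], zs[q]] <- m[zl[q], zs[q]] + 1
  m
}

# naive neighbourhood difference aggregation
oracleNgldm <- function(lev) {
  d <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  s <- numeric(L)
  cnt <- numeric(L)
  nV <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(i, j, k) + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      b <- lev[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    nV <- nV + 1
    cnt[a] <- cnt[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(p = cnt / nV, s = s, nVoxels = nV)
}

# two-way ANOVA mean squares via stats::aov, plugged into the agreement
# formula: an independent route to the ICC
oracleIcc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    row = factor(rep(seq_len(n), k)),
    col = factor(rep(seq_len(k), each = n))
  )
  av <- summary(stats::aov(y ~ row + col, data = df))[[1]]
  msr <- av["row", "Mean Sq"]
  msc <- av["col", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random NA-masked grey-level volume for oracle comparisons
randomGlv <- function(dims, L = 6L, naFrac = 0.2) {
  n <- prod(dims)
  lev <- array(sample.int(L, n, replace = TRUE), dims)
  lev[stats::runif(n) < naFrac] <- NA_integer_
  if (!any(!is.na(lev))) lev[1] <- 1L
  greyLevelVolume(lev)
}
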