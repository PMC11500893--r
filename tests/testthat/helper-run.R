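# One shared default experiment run, computed on first use and reused by
# the design-count, ordering and report tests.
defaultRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runExperiment(defaultConfig(seed = 1))
    cache
  }
})

# small helper: build an SUVImage + VOI directly from an array
suvFixture <- function(values, spacing = c(1, 1, 1), mask = NULL) {
  d <- dim(values)
  img <- new("SUVImage", values = values, spacing = spacing,
             origin = -(d - 1) / 2 * spacing,
             settingCode = "X", lesionName = "fix")
  if (is.null(mask)) mask <- array(TRUE, d)
  voi <- new("VOIMask", mask = mask, spacing = spacing, origin = img@origin)
  list(image = img, voi = voi)
}

digitalBall <- function(r, spacing = 1) {
  n <- 2 * r + 5
  c0 <- (n + 1) / 2
  ix <- array(seq_len(n), c(n, n, n))
  iy <- aperm(ix, c(2, 1, 3))
  iz <- aperm(ix, c(3, 2, 1))
  ((ix - c0)^2 + (iy - c0)^2 + (iz - c0)^2) <= r^2
}
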