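# shared fixtures: digitized spheres and small noiseless phantoms

sphereMask <- function(radiusMm, n = 40L, spacingMm = 1,
                       centerIdx = (n - 1) / 2 - 0.3) {
  g <- gridSpec(rep(n, 3L), rep(spacingMm, 3L), c(0, 0, 0))
  x <- (seq_len(n) - 1) * spacingMm
  c0 <- centerIdx * spacingMm
  d2 <- outer(outer((x - c0)^2, (x - c0)^2, "+"), (x - c0)^2, "+")
  gtvMask(array(d2 <= radiusMm^2, dim = rep(n, 3L)), g)
}

blockMask <- function(n = 10L, dimN = 20L, spacingMm = 1, offset = 3L) {
  g <- gridSpec(rep(dimN, 3L), rep(spacingMm, 3L), c(0, 0, 0))
  a <- array(FALSE, dim = rep(dimN, 3L))
  a[offset + seq_len(n), offset + seq_len(n), offset + seq_len(n)] <- TRUE
  gtvMask(a, g)
}

randomMask <- function(p = 0.3, n = 12L, seed = 1L) {
  g <- gridSpec(rep(n, 3L), c(1, 1, 1), c(0, 0, 0))
  set.seed(seed)
  gtvMask(array(runif(n^3) < p, dim = rep(n, 3L)), g)
}

noiselessPhantom <- function(n = 32L, spacingMm = 2, radii = c(10, 8, 9),
                             seed = 3L) {
  generatePhantom(phantomSpec(shape = rep(n, 3L),
                              spacingMm = rep(spacingMm, 3L),
                              lesionRadiiMm = radii,
                              noiseSd = c(ct = 0, mr = 0, pet = 0),
                              seed = seed))
}

normalizedPhantom <- function(n = 32L, seed = 3L) {
  ph <- noiselessPhantom(n = n, seed = seed)
  list(ct = windowNormalize(ph$ct), mr = windowNormalize(ph$mr),
       pet = windowNormalize(ph$pet), truth = ph$truth)
}
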