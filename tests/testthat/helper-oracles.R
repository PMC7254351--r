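# Independent scalar-loop oracles and small fixtures used across tests.

# Literal element-by-element step-down recursion (no vectorization):
# each output pixel re-sums the de-shadowed pixels above it.
stepDownOracle <- function(aline, gamma) {
  out <- numeric(length(aline))
  for (z in seq_along(aline)) {
    s <- 0
    if (z > 1L) for (k in 1:(z - 1L)) s <- s + out[k]
    out[z] <- aline[z] * exp(-s / gamma)
  }
  out
}

popSdOracle <- function(v) {
  m <- 0
  for (x in v) m <- m + x
  m <- m / length(v)
  s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / length(v))
}

pearsonOracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# A small, fast phantom: one pial vessel with a tail, one capillary
# directly beneath it and one in the clear, in a 64 x 24 x 24 cube.
smallPhantomSpec <- function(seed = 1L, tailStrength = 0.5,
                             noiseScale = 0.01) {
  phantomSpec(
    shape = c(64L, 24L, 24L), dzUm = 8, dxUm = 32, dyUm = 32,
    vessels = data.frame(x_um = 384, y_um = 384, radius_um = 60,
                         depth_um = 60, amplitude = 1),
    tailDecayUm = 200, tailStrength = tailStrength,
    capillaries = data.frame(x_um = c(384, 200), y_um = c(384, 200),
                             z_um = c(300, 350), radius_um = c(8, 8),
                             amplitude = 1),
    attenuationLengthUm = 600, noiseDistribution = "rayleigh",
    noiseScale = noiseScale, seed = seed)
}

randomVolume <- function(dims = c(8L, 3L, 4L), seed = 42L,
                         dzUm = 4, dxUm = 16, dyUm = 16,
                         surfaceIndex = 0L) {
  set.seed(seed)
  OctaVolume(array(runif(prod(dims)), dims), dzUm, dxUm, dyUm,
             surfaceIndex)
}
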