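## Synthetic cerebral-vasculature phantoms.
##
## Construction order (masks are recorded before noise):
##   1. speckle noise floor drawn from the configured distribution;
##   2. depth attenuation multiplier exp(-z_um / attenuationLengthUm)
##      applied to every true-signal component;
##   3. superficial vessels rendered as balls (circular cross-section);
##   4. a tail artifact added beneath every vessel-bearing (x, y)
##      column, seeded from the deepest vessel voxel of that column:
##      tail(z) = vesselValue * tailStrength * exp(-(z - z_bot) * dz /
##      tailDecayUm), extending to the bottom of the cube;
##   5. capillaries rendered as small spheres (at least one voxel);
##   6. volume = max(vessels, capillaries) + tails + noise.

## Voxel-centre coordinate grids in micrometres. Depth of z index j
## (1-based) is (j - 1) * dz below the surface.
.gridUm <- function(spec) {
  list(z = (seq_len(spec@shape[1L]) - 1) * spec@dzUm,
       x = (seq_len(spec@shape[2L]) - 0.5) * spec@dxUm,
       y = (seq_len(spec@shape[3L]) - 0.5) * spec@dyUm)
}

## Voxels of capillary i as an (z, x, y) arr.ind matrix: an ellipsoid
## with semi-axes max(radius, half pitch) so sub-voxel capillaries still
## occupy their containing voxel (partial-volume rendering).
.capillaryVoxels <- function(spec, i, grid = .gridUm(spec)) {
  cp <- spec@capillaries[i, ]
  sz <- max(cp$radius_um, spec@dzUm / 2)
  sx <- max(cp$radius_um, spec@dxUm / 2)
  sy <- max(cp$radius_um, spec@dyUm / 2)
  zi <- which(abs(grid$z - cp$z_um) <= sz)
  xi <- which(abs(grid$x - cp$x_um) <= sx)
  yi <- which(abs(grid$y - cp$y_um) <= sy)
  idx <- NULL
  if (length(zi) && length(xi) && length(yi)) {
    dz2 <- ((grid$z[zi] - cp$z_um) / sz)^2
    dx2 <- ((grid$x[xi] - cp$x_um) / sx)^2
    dy2 <- ((grid$y[yi] - cp$y_um) / sy)^2
    sub <- outer(dz2, outer(dx2, dy2, "+"), "+") <= 1
    w <- which(sub, arr.ind = TRUE)
    if (nrow(w))
      idx <- cbind(zi[w[, 1L]], xi[w[, 2L]], yi[w[, 3L]])
  }
  if (is.null(idx))
    idx <- matrix(c(which.min(abs(grid$z - cp$z_um)),
                    which.min(abs(grid$x - cp$x_um)),
                    which.min(abs(grid$y - cp$y_um))), nrow = 1L)
  idx
}

.linIndex <- function(idx, shp) {
  idx[, 1L] + shp[1L] * (idx[, 2L] - 1L) +
    shp[1L] * shp[2L] * (idx[, 3L] - 1L)
}

#' Generate a synthetic OCTA volume with ground truth
#'
#' Renders the vessels, tail artifacts, capillaries, depth attenuation
#' and speckle noise described by a [PhantomSpec-class] into an
#' [OctaVolume-class], and records ground-truth masks
#' ([PhantomTruth-class]) before noise addition. Deterministic given the
#' spec (the only randomness is the noise floor, seeded from
#' `spec@seed`).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([OctaVolume-class]), `truth`
#'   ([PhantomTruth-class]) and `spec` (the input, for provenance).
#' @examples
#' p <- generatePhantom(defaultCortexSpec(7))
#' p$volume
#' mean(volData(p$volume)[p$truth@tailMask])
#' @seealso [defaultCortexSpec()], [capillaryVisibility()]
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  shp <- spec@shape
  nz <- shp[1L]; nx <- shp[2L]; ny <- shp[3L]
  grid <- .gridUm(spec)
  atten <- exp(-grid$z / spec@attenuationLengthUm)

  ## vessels (balls; brightest wins where two overlap)
  vsig <- array(0, shp)
  v <- spec@vessels
  for (i in seq_len(nrow(v))) {
    r <- v$radius_um[i]
    zi <- which(abs(grid$z - v$depth_um[i]) <= r)
    if (!length(zi)) next
    dx2 <- (grid$x - v$x_um[i])^2
    dy2 <- (grid$y - v$y_um[i])^2
    for (j in zi) {
      rxy2 <- r^2 - (grid$z[j] - v$depth_um[i])^2
      disc <- outer(dx2, dy2, "+") <= rxy2
      val <- v$amplitude[i] * atten[j]
      layer <- vsig[j, , ]
      layer[disc & layer < val] <- val
      vsig[j, , ] <- layer
    }
  }
  vmask <- vsig > 0

  ## tails: per column, seeded from the deepest vessel voxel
  tails <- matrix(0, nz, nx * ny)
  if (spec@tailStrength > 0 && any(vmask)) {
    vm <- matrix(vmask, nrow = nz)
    vs <- matrix(vsig, nrow = nz)
    bot <- integer(ncol(vm))
    for (j in seq_len(nz)) bot[vm[j, ]] <- j
    for (b in sort(unique(bot[bot > 0L]))) {
      if (b >= nz) next
      cols <- which(bot == b)
      prof <- exp(-(((b + 1L):nz) - b) * spec@dzUm / spec@tailDecayUm)
      tails[(b + 1L):nz, cols] <-
        outer(prof, vs[b, cols] * spec@tailStrength)
    }
  }
  tails <- array(tails, shp)

  ## capillaries (spheres; capillary wins over vessel in the masks)
  csig <- array(0, shp)
  for (i in seq_len(nrow(spec@capillaries))) {
    idx <- .capillaryVoxels(spec, i, grid)
    lin <- .linIndex(idx, shp)
    amp <- spec@capillaries$amplitude[i] * atten[idx[, 1L]]
    csig[lin] <- pmax(csig[lin], amp)
  }
  cmask <- csig > 0
  if (any(vmask & cmask)) {
    message("phantom: capillary/vessel overlap; capillary wins in masks")
    vmask[cmask] <- FALSE
  }
  tmask <- tails > 0 & !vmask & !cmask

  ## noise floor (only source of randomness; RNG state restored)
  noise <- 0
  if (spec@noiseScale > 0) {
    hadSeed <- exists(".Random.seed", envir = globalenv())
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    set.seed((spec@seed + 62749L) %% 2147483647L)
    n <- prod(shp)
    noise <- if (spec@noiseDistribution == "rayleigh") {
      spec@noiseScale * sqrt(-2 * log1p(-stats::runif(n)))
    } else {
      abs(stats::rnorm(n, 0, spec@noiseScale))
    }
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
  }

  data <- pmax(vsig, csig) + tails + array(noise, shp)
  list(volume = OctaVolume(data, spec@dzUm, spec@dxUm, spec@dyUm, 0L),
       truth = PhantomTruth(vmask, cmask, tmask),
       spec = spec)
}

#' Default mouse-cortex phantom specification
#'
#' A 256 x 128 x 128 (z-x-y) cube with 4 um axial and 16 um lateral
#' pitch — a ~1 mm deep, ~2 x 2 mm field. Contains 2-4 bright pial
#' vessels (radius 40-100 um, centres shallower than 100 um) casting
#' strong tails, a dense bed of ~2000 deep capillaries (radius 6-10 um)
#' at 300-700 um placed outside the pial footprints, plus a handful of
#' capillaries deliberately placed directly beneath the largest vessel
#' (the shadowed-capillary scenario), depth attenuation with a 700 um
#' 1/e length, and a Rayleigh speckle floor at 2% of the vessel
#' amplitude. Capillaries carry the same unit amplitude as vessels:
#' OCTA flow contrast saturates for perfused vessels of any calibre.
#' All placements are drawn deterministically from `seed`.
#'
#' @param seed integer seed for all random placements.
#' @return a [PhantomSpec-class].
#' @seealso [generatePhantom()]
#' @export
defaultCortexSpec <- function(seed) {
  seed <- as.integer(seed)
  shape <- c(256L, 128L, 128L)
  dz <- 4; dx <- 16; dy <- 16
  extX <- shape[2L] * dx
  extY <- shape[3L] * dy

  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv()))

  ## pial vessels: non-overlapping laterally (rejection sampling)
  set.seed(seed %% 2147483647L)
  nV <- sample(2:4, 1L)
  rad <- stats::runif(nV, 40, 100)
  depth <- stats::runif(nV, 40, 90)
  cx <- numeric(nV); cy <- numeric(nV)
  for (i in seq_len(nV)) {
    for (try in 1:200) {
      px <- stats::runif(1, rad[i] + dx, extX - rad[i] - dx)
      py <- stats::runif(1, rad[i] + dy, extY - rad[i] - dy)
      if (i == 1L || all(sqrt((px - cx[seq_len(i - 1L)])^2 +
                              (py - cy[seq_len(i - 1L)])^2) >
                         rad[i] + rad[seq_len(i - 1L)] + 2 * dx)) break
    }
    cx[i] <- px; cy[i] <- py
  }
  vessels <- data.frame(x_um = cx, y_um = cy, radius_um = rad,
                        depth_um = depth, amplitude = 1)

  ## capillaries: dense deep bed outside the pial footprints, plus
  ## designated shadowed capillaries under the largest vessel
  set.seed((seed + 31337L) %% 2147483647L)
  iv <- which.max(rad)
  nS <- 4L
  ang <- stats::runif(nS, 0, 2 * pi)
  rho <- stats::runif(nS, 0.2, 0.45) * rad[iv]
  shadowed <- data.frame(
    x_um = cx[iv] + rho * cos(ang),
    y_um = cy[iv] + rho * sin(ang),
    z_um = stats::runif(nS, 350, 450),
    radius_um = stats::runif(nS, 6, 10),
    amplitude = 1)

  nC <- sample(1800:2200, 1L)
  got <- 0L
  px <- numeric(0); py <- numeric(0)
  while (got < nC) {
    m <- 2L * (nC - got)
    qx <- stats::runif(m, dx, extX - dx)
    qy <- stats::runif(m, dy, extY - dy)
    free <- rep(TRUE, m)
    for (i in seq_len(nV))
      free <- free & ((qx - cx[i])^2 + (qy - cy[i])^2 >
                        (rad[i] + dx)^2)
    px <- c(px, qx[free]); py <- c(py, qy[free])
    got <- length(px)
  }
  bed <- data.frame(
    x_um = px[seq_len(nC)], y_um = py[seq_len(nC)],
    z_um = stats::runif(nC, 300, 700),
    radius_um = stats::runif(nC, 6, 10),
    amplitude = 1)

  phantomSpec(shape, dz, dx, dy, vessels = vessels,
              tailDecayUm = 300, tailStrength = 0.5,
              capillaries = rbind(shadowed, bed),
              attenuationLengthUm = 700,
              noiseDistribution = "rayleigh", noiseScale = 0.02,
              seed = seed)
}

#' Serialize / restore a PhantomSpec
#'
#' Round-trips a phantom specification through YAML (or JSON via
#' jsonlite) so runs can be archived and replayed.
#'
#' @param spec a [PhantomSpec-class].
#' @param path destination / source file.
#' @return `writePhantomSpec`: `path` invisibly; `readPhantomSpec`: the
#'   restored [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  obj <- list(shape = spec@shape, dz_um = spec@dzUm, dx_um = spec@dxUm,
              dy_um = spec@dyUm, vessels = spec@vessels,
              tail = list(decay_length_um = spec@tailDecayUm,
                          strength = spec@tailStrength),
              capillaries = spec@capillaries,
              attenuation_length_um = spec@attenuationLengthUm,
              noise = list(distribution = spec@noiseDistribution,
                           scale = spec@noiseScale),
              seed = spec@seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  asdf <- function(x) if (is.null(x) || length(x) == 0) data.frame()
                      else as.data.frame(x)
  phantomSpec(obj$shape, obj$dz_um, obj$dx_um, obj$dy_um,
              vessels = asdf(obj$vessels),
              tailDecayUm = obj$tail$decay_length_um,
              tailStrength = obj$tail$strength,
              capillaries = asdf(obj$capillaries),
              attenuationLengthUm = obj$attenuation_length_um,
              noiseDistribution = obj$noise$distribution,
              noiseScale = obj$noise$scale, seed = obj$seed)
}
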