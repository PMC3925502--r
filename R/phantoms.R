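# Synthetic CT phantoms: solid near-water-density nodules in low-density
# parenchyma, with optional vessel cylinders and pleural wall slabs,
# partial-volume blur and additive Gaussian noise. Ground truth is the
# rasterization (voxel-centre inclusion) of the nodule solid before blur
# and noise, so it depends only on the geometry fields.

#' Construct a PhantomSpec
#'
#' Defaults emulate thin-slice chest CT of a solid nodule: spacing
#' (0.7, 0.7, 1.25) mm, lung parenchyma at -850 HU, nodule at 0 HU,
#' soft-tissue wall/vessel at 50 HU, noise sd 40 HU, and a mild 0.5-voxel
#' partial-volume blur. When `shape` is omitted the raster is sized to the
#' nodule plus `margin` mm on every side; when `noduleCenter` is omitted
#' the nodule sits at the volume centre (or abuts the wall slab if one is
#' present).
#'
#' @param noduleRadius nominal radius, mm.
#' @param shape integer length-3 raster dimensions (optional).
#' @param spacing mm/voxel, length 3.
#' @param noduleCenter physical centre, mm (optional).
#' @param lumpiness radial perturbation amplitude as a fraction of the
#'   radius (0 = sphere).
#' @param noduleHu,lungHu mean nodule / background intensity, HU.
#' @param noiseSd additive Gaussian noise sd, HU.
#' @param vessel NULL, or `list(radius = , direction = , hu = )` for an
#'   attached vessel cylinder through the nodule centre.
#' @param pleuralWall NULL, or `list(thickness = , hu = )` for a slab at
#'   the high-x face.
#' @param psfSd Gaussian blur sd in voxels.
#' @param margin mm of clearance used when auto-sizing `shape`.
#' @param rngSeed integer seed for the noise draw.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noduleRadius = 5, noiseSd = 0, psfSd = 0)
#' ph <- makePhantom(spec)
#' sum(maskArray(ph$mask))  # about (4/3) pi 5^3 / voxel volume
#' @export
phantomSpec <- function(noduleRadius = 6, shape = NULL,
                        spacing = c(0.7, 0.7, 1.25), noduleCenter = NULL,
                        lumpiness = 0, noduleHu = 0, lungHu = -850,
                        noiseSd = 40, vessel = NULL, pleuralWall = NULL,
                        psfSd = 0.5, margin = 6, rngSeed = 1L) {
  if (!is.null(pleuralWall)) {
    # default slab thickness exceeds the 6 mm morphological element, as a
    # real chest wall does; thinner slabs would be closed into the lung
    if (is.null(pleuralWall$thickness)) pleuralWall$thickness <- 8
    if (is.null(pleuralWall$hu)) pleuralWall$hu <- 50
  }
  rmax <- noduleRadius * (1 + lumpiness)
  if (is.null(shape)) {
    extent <- 2 * rmax + 2 * margin
    extra <- if (!is.null(pleuralWall)) pleuralWall$thickness else 0
    shape <- as.integer(ceiling(c(extent, extent, extent + extra) /
                                  spacing) + 1L)
    # wall occupies the high-x face; give x room for the slab
    if (!is.null(pleuralWall))
      shape[1] <- as.integer(ceiling((extent + extra +
                                        pleuralWall$thickness) /
                                       spacing[1]) + 1L)
  }
  extent <- (shape - 1L) * spacing
  if (is.null(noduleCenter)) {
    noduleCenter <- extent / 2
    if (!is.null(pleuralWall))  # abut the slab: juxtapleural
      noduleCenter[1] <- extent[1] - pleuralWall$thickness - noduleRadius
  }
  if (!is.null(vessel)) {
    if (is.null(vessel$radius)) vessel$radius <- 1.5
    if (is.null(vessel$direction)) vessel$direction <- c(0, 0, 1)
    vessel$direction <- vessel$direction / sqrt(sum(vessel$direction^2))
    if (is.null(vessel$hu)) vessel$hu <- 50
  }
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      noduleCenter = as.numeric(noduleCenter),
      noduleRadius = as.numeric(noduleRadius),
      lumpiness = as.numeric(lumpiness), noduleHu = as.numeric(noduleHu),
      lungHu = as.numeric(lungHu), noiseSd = as.numeric(noiseSd),
      vessel = if (is.null(vessel)) list() else vessel,
      pleuralWall = if (is.null(pleuralWall)) list() else pleuralWall,
      psfSd = as.numeric(psfSd), rngSeed = as.integer(rngSeed))
}

# Low-order spherical-harmonic-like radial perturbation, normalized to
# max |s| = 1 over a fixed direction grid. Coefficients are a
# deterministic function of the geometry fields only (not of rngSeed), so
# the ground-truth mask never depends on the noise seed.
lumpProfile <- function(spec, lumpKey = NULL) {
  if (is.null(lumpKey))
    lumpKey <- as.integer((round(spec@noduleRadius * 97) +
                             round(spec@lumpiness * 1009)) %% 100000L)
  coef <- withSeed(20000L + lumpKey, stats::rnorm(8))
  basis <- function(u) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    cbind(x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1,
          x * (5 * z^2 - 1), y * (5 * z^2 - 1), x * y * z)
  }
  # fixed Fibonacci direction grid for the normalization constant
  k <- seq_len(400)
  zg <- 1 - (2 * k - 1) / 400
  tg <- pi * (3 - sqrt(5)) * k
  grid <- cbind(sqrt(1 - zg^2) * cos(tg), sqrt(1 - zg^2) * sin(tg), zg)
  m <- max(abs(basis(grid) %*% coef))
  if (m < 1e-12) m <- 1
  function(u) pmax(-1, pmin(1, as.vector(basis(u) %*% coef) / m))
}

# Rasterize the (possibly lumpy) nodule solid by voxel-centre inclusion.
noduleSolid <- function(spec, lumpKey = NULL) {
  d <- spec@shape; sp <- spec@spacing; ctr <- spec@noduleCenter
  dx <- axisCoords(d[1], sp[1]) - ctr[1]
  dy <- axisCoords(d[2], sp[2]) - ctr[2]
  dz <- axisCoords(d[3], sp[3]) - ctr[3]
  px <- array(dx, d)
  py <- array(rep(dy, each = d[1]), d)
  pz <- array(rep(dz, each = d[1] * d[2]), d)
  rr <- sqrt(px^2 + py^2 + pz^2)
  if (spec@lumpiness == 0) return(rr <= spec@noduleRadius + 1e-12)
  s <- lumpProfile(spec, lumpKey)
  safe <- pmax(rr, 1e-9)
  u <- cbind(as.vector(px / safe), as.vector(py / safe), as.vector(pz / safe))
  radField <- spec@noduleRadius * (1 + spec@lumpiness * s(u))
  array(as.vector(rr) <= radField + 1e-12, d)
}

makePhantomImpl <- function(spec, lumpKey = NULL) {
  validObject(spec)
  d <- spec@shape; sp <- spec@spacing
  truth <- noduleSolid(spec, lumpKey)
  img <- array(spec@lungHu, d)
  extent <- (d - 1L) * sp
  if (length(spec@pleuralWall)) {
    wallFrom <- extent[1] - spec@pleuralWall$thickness
    xc <- axisCoords(d[1], sp[1])
    img[xc >= wallFrom - 1e-9, , ] <- spec@pleuralWall$hu
  }
  if (length(spec@vessel)) {
    # distance from voxel centre to the line through the nodule centre
    dx <- axisCoords(d[1], sp[1]) - spec@noduleCenter[1]
    dy <- axisCoords(d[2], sp[2]) - spec@noduleCenter[2]
    dz <- axisCoords(d[3], sp[3]) - spec@noduleCenter[3]
    px <- array(dx, d)
    py <- array(rep(dy, each = d[1]), d)
    pz <- array(rep(dz, each = d[1] * d[2]), d)
    u <- spec@vessel$direction
    dot <- px * u[1] + py * u[2] + pz * u[3]
    perp2 <- pmax(px^2 + py^2 + pz^2 - dot^2, 0)
    img[perp2 <= spec@vessel$radius^2 + 1e-9] <- spec@vessel$hu
  }
  img[truth] <- spec@noduleHu
  if (spec@psfSd > 0) img <- gaussianSmooth(img, spec@psfSd)
  if (spec@noiseSd > 0)
    img <- img + withSeed(spec@rngSeed,
                          array(stats::rnorm(prod(d), 0, spec@noiseSd), d))
  seedIdx <- pmin(pmax(as.integer(round(spec@noduleCenter / sp)) + 1L, 1L), d)
  list(volume = CtVolume(img, sp),
       mask = BinaryMask(truth, sp),
       seed = SeedPoint(seedIdx),
       spec = spec)
}

#' Generate a synthetic nodule phantom
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `volume` ([CtVolume-class]), `mask`
#'   (ground truth, [BinaryMask-class]), `seed` ([SeedPoint-class], the
#'   voxel nearest the nodule centre) and `spec`. Identical specs give
#'   bit-identical output.
#' @export
makePhantom <- function(spec) makePhantomImpl(spec)

#' Generate a longitudinal phantom pair
#'
#' The second phantom scales the nodule volume by `1 + growth` (radius by
#' `(1 + growth)^(1/3)`), keeping the same lumpy shape, so the true percent
#' volume change `(V2 - V1) / V1` equals `growth` up to rasterization
#' error. Noise draws differ between the two time points.
#'
#' @param spec a [PhantomSpec-class] for the first time point.
#' @param growth fractional volume change, `> -1`.
#' @return A list of two phantom lists (see [makePhantom()]).
#' @export
makePair <- function(spec, growth) {
  if (!is.numeric(growth) || growth <= -1)
    stopfmt("growth must be > -1 (got %s)", format(growth))
  first <- makePhantomImpl(spec)
  spec2 <- spec
  spec2@noduleRadius <- spec@noduleRadius * (1 + growth)^(1 / 3)
  spec2@rngSeed <- spec@rngSeed + 1L
  validObject(spec2)
  lumpKey <- as.integer((round(spec@noduleRadius * 97) +
                           round(spec@lumpiness * 1009)) %% 100000L)
  second <- makePhantomImpl(spec2, lumpKey = lumpKey)
  list(first, second)
}

#' Generate a reproducible phantom training/evaluation set
#'
#' Spec fields are drawn uniformly from the supplied ranges; volumes are
#' auto-sized to each nodule. A fraction of cases can carry an attached
#' vessel (juxtavascular) or a pleural wall slab (juxtapleural).
#'
#' @param n number of phantoms (>= 1).
#' @param radius,lumpiness,noiseSd length-2 `c(lo, hi)` ranges (a single
#'   value is a point range).
#' @param vesselProb,wallProb probability that a case gets a vessel / wall.
#' @param stratify if TRUE, the vessel/wall composition is fixed at
#'   `round(n * prob)` cases each (disjointly, in case order) instead of
#'   independent draws — for small sets this guarantees the hard variants
#'   are represented at their population rate.
#' @param spacing mm/voxel.
#' @param psfSd blur sd, voxels.
#' @param margin auto-sizing clearance, mm.
#' @param rngSeed integer seed; the whole set is reproducible from it.
#' @return A list of `n` phantom lists (see [makePhantom()]).
#' @export
makeTrainingSet <- function(n, radius = c(4, 7), lumpiness = c(0, 0.15),
                            noiseSd = c(40, 40), vesselProb = 0,
                            wallProb = 0, stratify = FALSE,
                            spacing = c(0.7, 0.7, 1.25),
                            psfSd = 0.5, margin = 6, rngSeed = 1L) {
  if (n < 1) stopfmt("n must be >= 1")
  rng <- function(x, nm) {
    x <- rep_len(as.numeric(x), 2)
    if (x[1] > x[2]) stopfmt("empty range for %s", nm)
    x
  }
  radius <- rng(radius, "radius")
  lumpiness <- rng(lumpiness, "lumpiness")
  noiseSd <- rng(noiseSd, "noiseSd")
  nWall <- round(n * wallProb)
  nVessel <- round(n * vesselProb)
  withSeed(rngSeed, {
    draws <- lapply(seq_len(n), function(i) list(
      radius = stats::runif(1, radius[1], radius[2]),
      lump = stats::runif(1, lumpiness[1], lumpiness[2]),
      noise = stats::runif(1, noiseSd[1], noiseSd[2]),
      vessel = if (stratify) i > nWall && i <= nWall + nVessel
               else stats::runif(1) < vesselProb,
      wall = if (stratify) i <= nWall else stats::runif(1) < wallProb,
      dir = { d <- stats::rnorm(3); d / sqrt(sum(d^2)) },
      seed = sample.int(.Machine$integer.max %/% 2L, 1)))
    lapply(draws, function(dr) {
      makePhantom(phantomSpec(
        noduleRadius = dr$radius, lumpiness = dr$lump, noiseSd = dr$noise,
        vessel = if (dr$vessel) list(radius = 1.5, direction = dr$dir) else NULL,
        pleuralWall = if (dr$wall) list(thickness = 8) else NULL,
        spacing = spacing, psfSd = psfSd, margin = margin,
        rngSeed = dr$seed))
    })
  })
}
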