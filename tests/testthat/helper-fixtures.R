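# Shared fixtures, all generated in code.

# Canonical anisotropic CT spacing used throughout the tests.
ctSpacing <- c(0.7, 0.7, 1.25)

# A small random volume for I/O round-trips.
randomVolume <- function(d = c(8, 8, 8), sp = ctSpacing, seed = 1) {
  set.seed(seed)
  CtVolume(array(rnorm(prod(d), -400, 300), d), sp)
}

# Random submodular pairwise energy on a small grid: random unaries plus
# attractive Ising-like couplings of random strength.
randomSubmodularEnergy <- function(d = c(2, 2, 3), seed = 1) {
  set.seed(seed)
  n <- prod(d)
  vol <- CtVolume(array(runif(n, -800, 0), d), c(1, 1, 1))
  mod <- intensityModel(-400, 200, -800, 0)
  geom <- new("NoduleGeometry", rInit = 2, center = (d - 1) / 2, r = 2,
              sigmaLoc = c(2, 2, 2),
              window = cbind(c(1L, 1L, 1L), d))
  feats <- computeFeatures(vol, geom, mod)
  par <- drfParams(w = rnorm(4, 0, 2), v = runif(1, 0, 2), model = mod,
                   deltaScale = 1000)
  buildEnergy(vol, par, feats)
}

# Noise-free spherical phantom, handy default for geometry tests.
spherePhantom <- function(radius = 5, noiseSd = 0, psfSd = 0, ...)
  makePhantom(phantomSpec(noduleRadius = radius, noiseSd = noiseSd,
                          psfSd = psfSd, ...))

# Intensity model matching the phantom defaults, for tests that need one
# without fitting (nodule 0 HU, lung -850 HU).
phantomModel <- function() intensityModel(0, 40, -150, 150)
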