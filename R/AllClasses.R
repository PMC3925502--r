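#' @import methods
NULL

#' CT volume
#'
#' A 3D scalar image on a regular anisotropic grid. Intensities are on a
#' Hounsfield-unit-like scale (air about -1000 HU, water about 0 HU).
#' Arrays are indexed `(x, y, z)` with `z` the slice axis; `spacing` follows
#' the same axis order in mm/voxel. Voxel indices are 1-based and the
#' physical position of voxel `(i, j, k)` is `(c(i, j, k) - 1) * spacing +
#' origin`.
#'
#' @slot intensities 3D numeric array of voxel intensities.
#' @slot spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @slot origin numeric length-3, physical position (mm) of voxel (1,1,1).
#'
#' @seealso [CtVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("CtVolume",
  representation(intensities = "array", spacing = "numeric",
                 origin = "numeric"),
  prototype(origin = c(0, 0, 0)))

setValidity("CtVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Binary voxel mask
#'
#' Per-voxel labels on the same raster as a companion [CtVolume-class].
#' Internally labels live in \{-1, +1\} (-1 background, +1 nodule); on disk
#' masks are serialized as 0/1 integer volumes.
#'
#' @slot labels 3D integer array with values in \{-1L, 1L\}.
#' @slot spacing numeric length-3, mm per voxel.
#' @slot origin numeric length-3, mm.
#'
#' @seealso [BinaryMask()], [readMask()], [writeMask()]
#' @export
setClass("BinaryMask",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0)))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!all(object@labels %in% c(-1L, 1L)))
    msg <- c(msg, "labels must take values in {-1, +1}")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Seed point
#'
#' A single user-supplied voxel marking the nodule, the only manual input
#' the segmentation needs. Indices are 1-based voxel indices in `(x, y, z)`
#' order.
#'
#' @slot index integer length-3 voxel index.
#' @export
setClass("SeedPoint", representation(index = "integer"))

setValidity("SeedPoint", function(object) {
  if (length(object@index) != 3L || any(is.na(object@index)) ||
      any(object@index < 1L))
    "index must be 3 positive integers" else TRUE
})

#' Global nodule intensity model
#'
#' Gaussian and uniform (threshold) models of nodule voxel intensity,
#' estimated once from training data: `muInt`/`sigmaInt` are the mean and
#' standard deviation of all ground-truth nodule voxels pooled across the
#' training volumes, and `(tMin, tMax)` their pooled minimum and maximum.
#'
#' @slot muInt,sigmaInt Gaussian mean and sd (HU); `sigmaInt > 0`.
#' @slot tMin,tMax threshold window (HU); `tMin < tMax`.
#' @seealso [fitIntensityModel()]
#' @export
setClass("IntensityModel",
  representation(muInt = "numeric", sigmaInt = "numeric",
                 tMin = "numeric", tMax = "numeric"))

setValidity("IntensityModel", function(object) {
  msg <- character()
  if (!is.finite(object@sigmaInt) || object@sigmaInt <= 0)
    msg <- c(msg, "sigmaInt must be > 0")
  if (!is.finite(object@tMin) || !is.finite(object@tMax) ||
      object@tMin >= object@tMax)
    msg <- c(msg, "tMin must be < tMax")
  if (length(msg)) msg else TRUE
})

#' Estimated nodule geometry
#'
#' Result of the morphological per-nodule geometry estimation: an initial
#' radius from bounding-box growth, a refined centre from the in-slice
#' distance transform, a final radius from sphere expansion, and the
#' per-axis location scale `sigmaLoc = r / spacing` (voxel units) used to
#' normalize the location feature.
#'
#' @slot rInit initial radius estimate (mm).
#' @slot center refined nodule centre, physical mm.
#' @slot r final radius estimate (mm).
#' @slot sigmaLoc numeric length-3, location scale in voxels per axis.
#' @slot window integer 3x2 matrix, the subvolume (crop) in full-volume
#'   voxel indices that per-nodule processing used (lo/hi per axis).
#' @seealso [estimateGeometry()]
#' @export
setClass("NoduleGeometry",
  representation(rInit = "numeric", center = "numeric", r = "numeric",
                 sigmaLoc = "numeric", window = "matrix"))

setValidity("NoduleGeometry", function(object) {
  msg <- character()
  if (object@rInit <= 0) msg <- c(msg, "rInit must be > 0")
  if (object@r <= 0) msg <- c(msg, "r must be > 0")
  if (length(object@sigmaLoc) != 3L || any(object@sigmaLoc <= 0))
    msg <- c(msg, "sigmaLoc must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Per-voxel DRF features
#'
#' The three association features of the model, stored as full arrays over
#' the (sub)volume: `fg`, the squared standardized intensity deviation
#' under the Gaussian intensity model; `fu`, the indicator that the
#' intensity falls outside the open threshold window; and `fl`, the squared
#' nodule-radius-normalized distance from the estimated centre. The model's
#' linear predictor uses `h = (1, fg, fu, fl)` with a leading bias term.
#'
#' @slot fg,fu,fl 3D numeric arrays of identical dimension.
#' @seealso [computeFeatures()]
#' @export
setClass("FeatureVolume",
  representation(fg = "array", fu = "array", fl = "array"))

setValidity("FeatureVolume", function(object) {
  d <- dim(object@fg)
  if (!identical(d, dim(object@fu)) || !identical(d, dim(object@fl)))
    return("fg, fu, fl must share dimensions")
  if (any(object@fg < 0) || any(object@fl < 0))
    return("fg and fl must be non-negative")
  if (!all(object@fu %in% c(0, 1)))
    return("fu must be 0/1")
  TRUE
})

#' DRF parameters
#'
#' The learned parameters of the discriminative random field: association
#' weights `w` (for the feature vector `h = (1, fg, fu, fl)`), interaction
#' weight `v`, the on/off switch `beta` for the interaction term, the
#' intensity-difference scale of the Ising attenuation (`deltaScale`, HU),
#' and the global intensity model the features depend on.
#'
#' Graph-cut inference requires `beta * v >= 0` (submodularity); learning
#' enforces `v >= 0` by default.
#'
#' @slot w numeric length-4 association weights.
#' @slot v numeric scalar interaction weight.
#' @slot beta numeric scalar switch (0 or 1 in practice).
#' @slot deltaScale numeric scalar, HU scale of the attenuation (default 1000).
#' @slot model an [IntensityModel-class].
#' @export
setClass("DrfParams",
  representation(w = "numeric", v = "numeric", beta = "numeric",
                 deltaScale = "numeric", model = "IntensityModel"))

setValidity("DrfParams", function(object) {
  msg <- character()
  if (length(object@w) != 4L || any(!is.finite(object@w)))
    msg <- c(msg, "w must be 4 finite values")
  if (length(object@v) != 1L || !is.finite(object@v))
    msg <- c(msg, "v must be a finite scalar")
  if (length(object@beta) != 1L || !is.finite(object@beta))
    msg <- c(msg, "beta must be a finite scalar")
  if (object@deltaScale <= 0)
    msg <- c(msg, "deltaScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pairwise energy over the voxel 6-neighbourhood graph
#'
#' Minimize-form energy handed to MAP solvers: per-voxel unary costs for
#' labels (-1, +1) and one cost table per unordered 6-neighbour edge. By
#' construction `energy(labels) + totalLogPotential(labels) == 0` for every
#' labeling, so the energy minimizer is the posterior mode.
#'
#' @slot unary numeric n-by-2 matrix; column 1 is the cost of label -1,
#'   column 2 of label +1.
#' @slot edges integer ne-by-2 matrix of linear voxel indices (each
#'   unordered raster-adjacent pair exactly once).
#' @slot edgeCosts numeric ne-by-4 matrix with columns E(-,-), E(-,+),
#'   E(+,-), E(+,+).
#' @slot dim integer length-3 raster dimensions.
#' @slot spacing numeric length-3 mm/voxel (metadata for the result mask).
#' @seealso [buildEnergy()], [solveMap()]
#' @export
setClass("PairwiseEnergy",
  representation(unary = "matrix", edges = "matrix", edgeCosts = "matrix",
                 dim = "integer", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1)))

setValidity("PairwiseEnergy", function(object) {
  msg <- character()
  if (ncol(object@unary) != 2L) msg <- c(msg, "unary must have 2 columns")
  if (nrow(object@unary) != prod(object@dim))
    msg <- c(msg, "unary rows must equal prod(dim)")
  if (nrow(object@edges) != nrow(object@edgeCosts))
    msg <- c(msg, "edges and edgeCosts must have equal rows")
  if (nrow(object@edges) && ncol(object@edges) != 2L)
    msg <- c(msg, "edges must have 2 columns")
  if (nrow(object@edgeCosts) && ncol(object@edgeCosts) != 4L)
    msg <- c(msg, "edgeCosts must have 4 columns")
  if (any(!is.finite(object@unary)) || any(!is.finite(object@edgeCosts)))
    msg <- c(msg, "costs must be finite")
  if (length(msg)) msg else TRUE
})

#' MAP inference result
#'
#' @slot labels a [BinaryMask-class] with the optimal labeling.
#' @slot energy minimize-form energy of `labels`, recomputed independently
#'   of the solver.
#' @slot solver solver name ("maxflow" or "exhaustive").
#' @slot flowStats list of solver diagnostics (e.g. max-flow value).
#' @seealso [solveMap()], [solveMapExhaustive()]
#' @export
setClass("MapResult",
  representation(labels = "BinaryMask", energy = "numeric",
                 solver = "character", flowStats = "list"))

#' Synthetic CT phantom specification
#'
#' Describes one synthetic nodule scene: a solid, near-water-density nodule
#' (spherical, optionally lumpy) embedded in low-density lung parenchyma,
#' optionally with an attached vessel cylinder (juxtavascular) and/or a
#' pleural wall slab at the high-x face (juxtapleural), blurred by a
#' Gaussian point-spread function and corrupted by i.i.d. Gaussian noise.
#'
#' @slot shape integer length-3 raster dimensions.
#' @slot spacing numeric length-3 mm/voxel.
#' @slot noduleCenter physical centre of the nodule (mm).
#' @slot noduleRadius nominal nodule radius (mm).
#' @slot lumpiness amplitude of the radial perturbation as a fraction of
#'   the radius (>= 0; 0 gives a perfect sphere).
#' @slot noduleHu,lungHu mean nodule / background intensity (HU).
#' @slot noiseSd additive Gaussian noise sd (HU, >= 0).
#' @slot vessel empty list, or list(radius, direction, hu): cylinder of
#'   `radius` mm along unit `direction` through the nodule centre.
#' @slot pleuralWall empty list, or list(thickness, hu): slab of
#'   `thickness` mm at the high-x face.
#' @slot psfSd Gaussian blur sd in voxels (>= 0), applied before noise.
#' @slot rngSeed integer seed controlling lumpiness and noise draws.
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 noduleCenter = "numeric", noduleRadius = "numeric",
                 lumpiness = "numeric", noduleHu = "numeric",
                 lungHu = "numeric", noiseSd = "numeric",
                 vessel = "list", pleuralWall = "list",
                 psfSd = "numeric", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 4L))
    msg <- c(msg, "shape must be 3 integers >= 4")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@noduleRadius <= 0) msg <- c(msg, "noduleRadius must be > 0")
  if (object@lumpiness < 0) msg <- c(msg, "lumpiness must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@psfSd < 0) msg <- c(msg, "psfSd must be >= 0")
  if (object@noduleHu <= object@lungHu)
    msg <- c(msg, "noduleHu must exceed lungHu")
  # inflated nodule must fit inside the volume
  extent <- (object@shape - 1L) * object@spacing
  rmax <- object@noduleRadius * (1 + object@lumpiness)
  if (any(object@noduleCenter - rmax < 0) ||
      any(object@noduleCenter + rmax > extent))
    msg <- c(msg, "nodule (inflated by lumpiness) does not fit in the volume")
  if (length(msg)) msg else TRUE
})

#' Simulated-annealing configuration
#'
#' Controls the stochastic search over theta = (w, v) that maximizes the
#' training-set F-score of full graph-cut inference. Defaults: start at
#' theta = 0; bounds `v >= 0` (which also guarantees submodular
#' energies) and `w1, w2, w3 <= 0` (the features are non-negative
#' costs); initial temperature 1, exponential cooling 0.97 per
#' iteration, 500 iterations, reannealing every 125 with a restart from
#' the incumbent best.
#'
#' @slot initialParams numeric length-5 starting theta (w0..w3, v).
#' @slot lower,upper numeric length-5 box bounds (may be infinite).
#' @slot initialTemperature,coolingRate,stepScale,acceptScale annealing
#'   schedule constants; see [annealConfig()].
#' @slot iterations integer number of proposals.
#' @slot reannealInterval integer; reset the temperature every this many
#'   iterations (0 disables).
#' @slot rngSeed integer seed.
#' @seealso [annealConfig()], [trainDrf()]
#' @export
setClass("AnnealConfig",
  representation(initialParams = "numeric", lower = "numeric",
                 upper = "numeric", initialTemperature = "numeric",
                 coolingRate = "numeric", stepScale = "numeric",
                 acceptScale = "numeric", iterations = "integer",
                 reannealInterval = "integer", rngSeed = "integer"))

setValidity("AnnealConfig", function(object) {
  msg <- character()
  if (length(object@initialParams) != 5L)
    msg <- c(msg, "initialParams must have length 5 (w0..w3, v)")
  if (length(object@lower) != 5L || length(object@upper) != 5L ||
      any(object@lower > object@upper))
    msg <- c(msg, "bounds must be length 5 with lower <= upper")
  if (any(object@initialParams < object@lower) ||
      any(object@initialParams > object@upper))
    msg <- c(msg, "initialParams must lie within bounds")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@coolingRate <= 0 || object@coolingRate >= 1)
    msg <- c(msg, "coolingRate must be in (0, 1)")
  if (object@initialTemperature <= 0)
    msg <- c(msg, "initialTemperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' Training result
#'
#' @slot params the best [DrfParams-class] found.
#' @slot bestFscore pooled training F-score of `params`.
#' @slot trace data.frame with one row per iteration: iteration, w0..w3, v,
#'   fscore, temperature, accepted.
#' @seealso [trainDrf()]
#' @export
setClass("TrainResult",
  representation(params = "DrfParams", bestFscore = "numeric",
                 trace = "data.frame"))
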