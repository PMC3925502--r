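#' Construct a CtVolume
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric length-3, mm per voxel.
#' @param origin numeric length-3, mm (default 0).
#' @return A [CtVolume-class].
#' @examples
#' vol <- CtVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(0.7, 0.7, 1.25))
#' dim(vol)
#' @export
CtVolume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  storage.mode(intensities) <- "double"
  new("CtVolume", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @param labels 3D array in \{-1, +1\} (or logical: TRUE maps to +1).
#' @param spacing numeric length-3, mm per voxel.
#' @param origin numeric length-3, mm.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (is.logical(labels)) {
    d <- dim(labels)
    labels <- array(ifelse(labels, 1L, -1L), d)
  }
  storage.mode(labels) <- "integer"
  new("BinaryMask", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a SeedPoint
#'
#' @param index integer length-3, 1-based voxel index (x, y, z).
#' @return A [SeedPoint-class].
#' @export
SeedPoint <- function(index) new("SeedPoint", index = as.integer(index))

#' Construct an IntensityModel
#'
#' @param muInt,sigmaInt Gaussian mean and sd of nodule intensity (HU).
#' @param tMin,tMax threshold window (HU), `tMin < tMax`.
#' @return An [IntensityModel-class].
#' @export
intensityModel <- function(muInt, sigmaInt, tMin, tMax)
  new("IntensityModel", muInt = as.numeric(muInt),
      sigmaInt = as.numeric(sigmaInt), tMin = as.numeric(tMin),
      tMax = as.numeric(tMax))

#' Construct DrfParams
#'
#' @param w numeric length-4 association weights for h = (1, fg, fu, fl).
#' @param v interaction weight (>= 0 for graph-cut inference).
#' @param model an [IntensityModel-class].
#' @param beta interaction switch, default 1.
#' @param deltaScale HU scale of the Ising attenuation, default 1000.
#' @return A [DrfParams-class].
#' @export
drfParams <- function(w, v, model, beta = 1, deltaScale = 1000)
  new("DrfParams", w = as.numeric(w), v = as.numeric(v),
      beta = as.numeric(beta), deltaScale = as.numeric(deltaScale),
      model = model)

# ---- accessors ----

#' Accessors for the core classes
#'
#' `intensities()` and `maskLabels()` return the raw arrays, `spacing()`
#' and `origin()` the grid metadata, `seedIndex()` the 1-based voxel index
#' of a seed, and `seedPhysical()` its physical position in mm.
#'
#' @param x a [CtVolume-class], [BinaryMask-class] or [SeedPoint-class].
#' @param vol the companion volume or mask supplying spacing/origin
#'   (for `seedPhysical`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "CtVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setMethod("maskLabels", "BinaryMask", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setMethod("spacing", "CtVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setMethod("origin", "CtVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("origin", "BinaryMask", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("seedIndex", function(x) standardGeneric("seedIndex"))
#' @rdname accessors
#' @export
setMethod("seedIndex", "SeedPoint", function(x) x@index)

#' @rdname accessors
#' @export
seedPhysical <- function(x, vol)
  (seedIndex(x) - 1) * spacing(vol) + origin(vol)

#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("dim", "CtVolume", function(x) dim(x@intensities))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@labels))

#' Logical view of a mask
#'
#' @param mask a [BinaryMask-class].
#' @return logical array, TRUE where the label is +1.
#' @export
maskArray <- function(mask) mask@labels == 1L

# ---- show methods ----

setMethod("show", "CtVolume", function(object) {
  d <- dim(object)
  cat(sprintf("CtVolume %dx%dx%d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object)
  cat(sprintf("BinaryMask %dx%dx%d, %d positive of %d voxels\n",
              d[1], d[2], d[3], sum(object@labels == 1L),
              length(object@labels)))
})

setMethod("show", "SeedPoint", function(object) {
  cat(sprintf("SeedPoint (%d, %d, %d)\n", object@index[1],
              object@index[2], object@index[3]))
})

setMethod("show", "IntensityModel", function(object) {
  cat(sprintf(
    "IntensityModel: mu %.2f, sigma %.2f, window (%.2f, %.2f) HU\n",
    object@muInt, object@sigmaInt, object@tMin, object@tMax))
})

setMethod("show", "NoduleGeometry", function(object) {
  cat(sprintf(
    "NoduleGeometry: rInit %.2f mm, r %.2f mm, center (%.2f, %.2f, %.2f) mm\n",
    object@rInit, object@r, object@center[1], object@center[2],
    object@center[3]))
})

setMethod("show", "DrfParams", function(object) {
  cat(sprintf("DrfParams: w = (%s), v = %.4g, beta = %g\n",
              paste(sprintf("%.4g", object@w), collapse = ", "),
              object@v, object@beta))
  show(object@model)
})

setMethod("show", "MapResult", function(object) {
  cat(sprintf("MapResult (%s): energy %.6g, %d positive voxels\n",
              object@solver, object@energy,
              sum(object@labels@labels == 1L)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%dx%d: nodule r %.1f mm (lumpiness %.2f) at (%.1f, %.1f, %.1f) mm%s%s\n",
    object@shape[1], object@shape[2], object@shape[3], object@noduleRadius,
    object@lumpiness, object@noduleCenter[1], object@noduleCenter[2],
    object@noduleCenter[3],
    if (length(object@vessel)) ", vessel" else "",
    if (length(object@pleuralWall)) ", pleural wall" else ""))
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf("TrainResult: best F-score %.4f over %d iterations\n",
              object@bestFscore, nrow(object@trace)))
  show(object@params)
})
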