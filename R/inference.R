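# Exact binary MAP inference: min-cut/max-flow on the standard graph
# construction for submodular pairwise energies, an exhaustive reference
# solver for small instances, and the end-to-end seed-to-mask pipeline.

#' Exact MAP labeling by min-cut/max-flow
#'
#' Solves the minimize-form energy globally via the standard s-t graph
#' construction (Kolmogorov-Zabih reparameterisation, Dinic max-flow).
#' Requires every edge table to be submodular, which [buildEnergy()]
#' guarantees when `beta * v >= 0`. Deterministic: ties at zero-capacity
#' cuts resolve by residual-graph reachability under a fixed arc insertion
#' order (an isolated voxel with equal unary costs gets label -1).
#'
#' @param energy a [PairwiseEnergy-class].
#' @return A [MapResult-class]; its `energy` slot is recomputed from the
#'   labeling with [energyOf()], independently of the flow value.
#' @export
solveMap <- function(energy) {
  stopifnot(is(energy, "PairwiseEnergy"))
  ec <- energy@edgeCosts
  if (nrow(ec) &&
      any(ec[, 2] + ec[, 3] - ec[, 1] - ec[, 4] < -1e-9))
    stopfmt("non-submodular edge encountered; re-train with v >= 0")
  sol <- .maxflowSolve(energy@unary, energy@edges, energy@edgeCosts)
  lab <- array(as.integer(sol$labels), energy@dim)
  mask <- BinaryMask(lab, energy@spacing)
  new("MapResult", labels = mask, energy = energyOf(energy, sol$labels),
      solver = "maxflow", flowStats = list(flow = sol$flow))
}

#' MAP by exhaustive enumeration (reference oracle)
#'
#' Enumerates all `2^n` labelings of an energy with at most 20 voxels and
#' returns the minimum; on ties, the lexicographically smallest labeling
#' (-1 before +1, first voxel most significant) wins.
#'
#' @param energy a [PairwiseEnergy-class] over at most 20 voxels.
#' @return A [MapResult-class].
#' @export
solveMapExhaustive <- function(energy) {
  n <- prod(energy@dim)
  if (n > 20) stopfmt("exhaustive solver limited to 20 voxels (got %d)", n)
  ne <- nrow(energy@edges)
  bestE <- Inf
  bestLab <- NULL
  total <- 2^n
  chunk <- min(total, 65536)
  for (startK in seq(0, total - 1, by = chunk)) {
    ks <- startK:min(startK + chunk - 1, total - 1)
    # voxel 1 most significant: lexicographic order in k
    B <- sapply(seq_len(n), function(i) (ks %/% 2^(n - i)) %% 2)
    if (is.null(dim(B))) B <- matrix(B, nrow = 1)
    eTot <- B %*% energy@unary[, 2] + (1 - B) %*% energy@unary[, 1]
    if (ne > 0) {
      for (e in seq_len(ne)) {
        col <- 1L + 2L * B[, energy@edges[e, 1]] + B[, energy@edges[e, 2]]
        eTot <- eTot + energy@edgeCosts[e, col]
      }
    }
    m <- which.min(eTot)          # first minimum: lexicographic tie-break
    if (eTot[m] < bestE) {
      bestE <- eTot[m]
      bestLab <- 2L * B[m, ] - 1L
    }
  }
  mask <- BinaryMask(array(as.integer(bestLab), energy@dim),
                     energy@spacing)
  new("MapResult", labels = mask, energy = bestE, solver = "exhaustive",
      flowStats = list())
}

#' Segment a nodule from a seed point
#'
#' The full inference pipeline: 3D Gaussian pre-smoothing (1 voxel sd) to
#' suppress high-frequency noise, morphological geometry estimation,
#' feature computation on the smoothed volume, energy construction, and
#' exact graph-cut MAP on the processing subvolume. Voxels outside the
#' subvolume are labeled -1. Deterministic given inputs.
#'
#' @param vol a [CtVolume-class].
#' @param seed a [SeedPoint-class].
#' @param params a [DrfParams-class] (see [trainDrf()] or
#'   [readDrfParams()]).
#' @param geometry optionally a precomputed [NoduleGeometry-class] for
#'   `vol` (skips re-estimation).
#' @return A [BinaryMask-class] on the full raster.
#' @examples
#' ph <- makePhantom(phantomSpec(noduleRadius = 5, rngSeed = 3))
#' mod <- intensityModel(0, 40, -150, 150)
#' par <- drfParams(w = c(4, -1, -4, -4), v = 0.5, model = mod)
#' seg <- segmentNodule(ph$volume, ph$seed, par)
#' @export
segmentNodule <- function(vol, seed, params, geometry = NULL) {
  stopifnot(is(vol, "CtVolume"), is(seed, "SeedPoint"),
            is(params, "DrfParams"))
  sm <- CtVolume(gaussianSmooth(vol@intensities, 1), vol@spacing,
                 vol@origin)
  geom <- if (is.null(geometry)) {
    tryCatch(estimateGeometry(sm, seed, params@model),
             error = function(e) stopfmt("segmentNodule [geometry]: %s",
                                         conditionMessage(e)))
  } else geometry
  w <- geom@window
  sub <- CtVolume(cropArray(sm@intensities, w), sm@spacing)
  geomSub <- geom
  geomSub@center <- geom@center - (w[, 1] - 1L) * sm@spacing
  feats <- computeFeatures(sub, geomSub, params@model)
  energy <- tryCatch(buildEnergy(sub, params, feats),
                     error = function(e) stopfmt("segmentNodule [energy]: %s",
                                                 conditionMessage(e)))
  res <- tryCatch(solveMap(energy),
                  error = function(e) stopfmt("segmentNodule [solve]: %s",
                                              conditionMessage(e)))
  full <- array(-1L, dim(vol))
  full[w[1, 1]:w[1, 2], w[2, 1]:w[2, 2], w[3, 1]:w[3, 2]] <-
    res@labels@labels
  BinaryMask(full, vol@spacing, vol@origin)
}

#' Per-voxel association probability map
#'
#' `Pr(x = +1 | y)` under the logistic association model alone (no
#' interaction term), on the processing subvolume; voxels outside it get
#' probability 0. Thresholding this map at 0.5 reproduces
#' [segmentNodule()] with `v = 0`.
#'
#' @inheritParams segmentNodule
#' @return A [CtVolume-class] of probabilities in `[0, 1]`.
#' @export
associationProbability <- function(vol, seed, params, geometry = NULL) {
  sm <- CtVolume(gaussianSmooth(vol@intensities, 1), vol@spacing,
                 vol@origin)
  geom <- if (is.null(geometry)) estimateGeometry(sm, seed, params@model)
          else geometry
  w <- geom@window
  sub <- CtVolume(cropArray(sm@intensities, w), sm@spacing)
  geomSub <- geom
  geomSub@center <- geom@center - (w[, 1] - 1L) * sm@spacing
  feats <- computeFeatures(sub, geomSub, params@model)
  pr <- stats::plogis(linearPredictor(feats, params@w))
  full <- array(0, dim(vol))
  full[w[1, 1]:w[1, 2], w[2, 1]:w[2, 2], w[3, 1]:w[3, 2]] <-
    array(pr, dim(sub))
  CtVolume(full, vol@spacing, vol@origin)
}
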