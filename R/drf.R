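# The discriminative random field over the voxel 6-neighbourhood graph:
# per-voxel features, logistic association potential, intensity-attenuated
# Ising interaction potential, total log-potential, and the conversion to
# a minimize-form pairwise energy for graph-cut inference.

# Numerically stable log(1 / (1 + exp(-eta))), vectorized.
logSigmoid <- function(eta) {
  out <- numeric(length(eta))
  pos <- eta >= 0
  out[pos] <- -log1p(exp(-eta[pos]))
  out[!pos] <- eta[!pos] - log1p(exp(eta[!pos]))
  out
}

#' Compute per-voxel DRF features
#'
#' For each voxel with (pre-smoothed) intensity `n`: `fg = (n - muInt)^2 /
#' sigmaInt^2` (Gaussian intensity cost), `fu = 0` iff `tMin < n < tMax`
#' else 1 (threshold-model cost), and `fl = sum_axes ((p - l) / sigmaLoc)^2`
#' with `p` the voxel index and `l` the estimated centre in voxel units
#' (location cost; equals squared physical distance from the centre over
#' `r^2`, so a voxel one radius away has `fl = 1`).
#'
#' @param vol a [CtVolume-class] (already pre-smoothed by the inference
#'   caller).
#' @param geom a [NoduleGeometry-class] in the same coordinate frame.
#' @param model an [IntensityModel-class].
#' @return A [FeatureVolume-class].
#' @export
computeFeatures <- function(vol, geom, model) {
  stopifnot(is(vol, "CtVolume"), is(geom, "NoduleGeometry"),
            is(model, "IntensityModel"))
  if (model@sigmaInt <= 0) stopfmt("sigmaInt must be positive")
  n <- vol@intensities
  d <- dim(n); sp <- vol@spacing
  fg <- (n - model@muInt)^2 / model@sigmaInt^2
  fu <- array(1 - as.numeric(n > model@tMin & n < model@tMax), d)
  # voxel-unit coordinates: p = index (1-based), centre l = center/sp + 1
  lVox <- geom@center / sp + 1
  tx <- ((seq_len(d[1]) - lVox[1]) / geom@sigmaLoc[1])^2
  ty <- ((seq_len(d[2]) - lVox[2]) / geom@sigmaLoc[2])^2
  tz <- ((seq_len(d[3]) - lVox[3]) / geom@sigmaLoc[3])^2
  fl <- outer(outer(tx, ty, `+`), tz, `+`)
  new("FeatureVolume", fg = fg, fu = fu, fl = fl)
}

# Linear predictor w^T h with h = (1, fg, fu, fl), as a vector.
linearPredictor <- function(features, w)
  w[1] + w[2] * as.vector(features@fg) + w[3] * as.vector(features@fu) +
    w[4] * as.vector(features@fl)

#' Association log-probability
#'
#' `A(x, y) = log(1 / (1 + exp(-x w^T h)))`, the log of the logistic
#' probability of label `x` given the feature vector `h = (1, fg, fu,
#' fl)`. Always `<= 0`, and `exp(A(+1)) + exp(A(-1)) = 1`.
#'
#' @param h numeric length-4 feature vector (leading 1 included).
#' @param x label, -1 or +1.
#' @param w numeric length-4 weights.
#' @return The log-probability (scalar).
#' @examples
#' associationLogProb(c(1, 0, 0, 0), +1, rep(0, 4))  # log(1/2)
#' @export
associationLogProb <- function(h, x, w) {
  stopifnot(length(h) == 4, length(w) == 4, x %in% c(-1, 1))
  logSigmoid(x * sum(w * h))
}

#' Ising interaction potential
#'
#' `I(x_i, x_j, y) = beta * x_i * x_j * v * delta` with `delta = max(1 -
#' |n_i - n_j| / deltaScale, 0)`: equal neighbour labels are rewarded, the
#' reward fading linearly with the intensity difference and vanishing at
#' `deltaScale` HU.
#'
#' @param ni,nj neighbour intensities (HU).
#' @param xi,xj labels in \{-1, +1\}.
#' @param v interaction weight.
#' @param beta switch constant.
#' @param deltaScale attenuation scale in HU (default 1000).
#' @return The potential (vectorized over inputs).
#' @export
interactionPotential <- function(ni, nj, xi, xj, v, beta = 1,
                                 deltaScale = 1000) {
  delta <- pmax(1 - abs(ni - nj) / deltaScale, 0)
  beta * xi * xj * v * delta
}

#' Total log-potential of a labeling
#'
#' The exponent of the DRF posterior (up to the partition function):
#' `sum_i A(x_i, y) + sum_i sum_{j in N_i} I(x_i, x_j, y)` over the
#' 6-neighbourhood, where the double sum visits each unordered edge twice
#' (once per direction).
#'
#' @param vol a [CtVolume-class].
#' @param labels a [BinaryMask-class] of the same shape.
#' @param params a [DrfParams-class].
#' @param features a [FeatureVolume-class] for `vol`.
#' @return Scalar log-potential (larger is more probable).
#' @export
totalLogPotential <- function(vol, labels, params, features) {
  stopifnot(identical(dim(vol), dim(labels)))
  x <- as.vector(labels@labels)
  lp <- linearPredictor(features, params@w)
  assoc <- sum(logSigmoid(x * lp))
  e <- gridEdges6(dim(vol))
  n <- as.vector(vol@intensities)
  inter <- interactionPotential(n[e[, 1]], n[e[, 2]], x[e[, 1]], x[e[, 2]],
                                params@v, params@beta, params@deltaScale)
  assoc + 2 * sum(inter)
}

#' Build the minimize-form pairwise energy
#'
#' Converts the DRF log-potential into the energy handed to MAP solvers:
#' `unary(x) = -A(x)` per voxel and `pairwise(x_i, x_j) = -2 I(x_i, x_j)`
#' per unordered edge (the factor 2 folds the directed double sum), so
#' `energy(labels) + totalLogPotential(labels) = 0` for every labeling and
#' the energy argmin is the posterior mode. Requires `beta * v >= 0`;
#' otherwise the Ising tables are non-submodular and exact graph-cut
#' inference is impossible (re-train with `v >= 0`).
#'
#' @param vol a [CtVolume-class].
#' @param params a [DrfParams-class] with `beta * v >= 0`.
#' @param features a [FeatureVolume-class] for `vol`.
#' @return A [PairwiseEnergy-class].
#' @export
buildEnergy <- function(vol, params, features) {
  if (params@beta * params@v < 0)
    stopfmt("beta * v < 0 gives a non-submodular energy; re-train with v >= 0")
  d <- dim(vol)
  lp <- linearPredictor(features, params@w)
  unary <- cbind(-logSigmoid(-lp), -logSigmoid(lp))
  e <- gridEdges6(d)
  n <- as.vector(vol@intensities)
  delta <- pmax(1 - abs(n[e[, 1]] - n[e[, 2]]) / params@deltaScale, 0)
  iEq <- params@beta * params@v * delta   # I when x_i == x_j
  edgeCosts <- cbind(-2 * iEq, 2 * iEq, 2 * iEq, -2 * iEq)
  new("PairwiseEnergy", unary = unary, edges = e, edgeCosts = edgeCosts,
      dim = as.integer(d), spacing = vol@spacing)
}

#' Evaluate a pairwise energy on a labeling
#'
#' @param energy a [PairwiseEnergy-class].
#' @param labels a [BinaryMask-class] or a vector of labels in \{-1, +1\}.
#' @return The scalar energy.
#' @export
energyOf <- function(energy, labels) {
  x <- if (is(labels, "BinaryMask")) as.vector(labels@labels)
       else as.vector(labels)
  stopifnot(length(x) == nrow(energy@unary))
  b <- (x + 1L) / 2L  # 0 for -1, 1 for +1
  u <- sum(energy@unary[cbind(seq_along(x), b + 1L)])
  if (nrow(energy@edges) == 0) return(u)
  col <- 1L + 2L * b[energy@edges[, 1]] + b[energy@edges[, 2]]
  u + sum(energy@edgeCosts[cbind(seq_len(nrow(energy@edges)), col)])
}
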