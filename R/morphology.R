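# Per-nodule geometry estimation: global intensity constants from training
# data, then initial segmentation -> initial radius -> lung subvolume ->
# seed-component filtering -> centre refinement -> final radius.

#' Fit the global nodule intensity model
#'
#' Pools all ground-truth nodule voxels across the training volumes and
#' returns the Gaussian model (mean, sd) plus the threshold window
#' (pooled min, max).
#'
#' @param training list of cases, each a list with elements `volume`
#'   ([CtVolume-class]) and `mask` ([BinaryMask-class]); the output of
#'   [makeTrainingSet()] works directly.
#' @return An [IntensityModel-class].
#' @examples
#' set <- makeTrainingSet(2, rngSeed = 7)
#' fitIntensityModel(set)
#' @export
fitIntensityModel <- function(training) {
  vals <- unlist(lapply(training, function(case) {
    stopifnot(is(case$volume, "CtVolume"), is(case$mask, "BinaryMask"))
    case$volume@intensities[maskArray(case$mask)]
  }))
  if (length(vals) == 0)
    stopfmt("no positive voxels in the training set")
  if (length(vals) < 2 || stats::sd(vals) == 0 || min(vals) == max(vals))
    stopfmt("degenerate training intensities (all identical); cannot fit sigma or thresholds")
  intensityModel(mean(vals), stats::sd(vals), min(vals), max(vals))
}

#' Denoise and threshold a volume
#'
#' Smooths every slice with a 2D (in-slice) Gaussian of one voxel standard
#' deviation, then labels voxels whose smoothed intensity lies strictly
#' inside `(tMin, tMax)` as positive.
#'
#' @param vol a [CtVolume-class].
#' @param model an [IntensityModel-class].
#' @return A [BinaryMask-class] (the initial segmentation).
#' @export
denoiseAndThreshold <- function(vol, model) {
  stopifnot(is(vol, "CtVolume"), is(model, "IntensityModel"))
  sm <- gaussianSmoothSlices(vol@intensities, 1)
  BinaryMask(sm > model@tMin & sm < model@tMax, vol@spacing, vol@origin)
}

#' Estimate the initial nodule radius
#'
#' Grows a seed-centred box isotropically in physical units (one step =
#' one voxel of the finest axis) and stops at the first box in which the
#' fraction of voxels outside the initial segmentation reaches 0.75;
#' `rInit` is the box half-width at the stop. If the box reaches the
#' volume bounds first, half the largest reached edge is returned with a
#' warning.
#'
#' @param mask initial segmentation ([BinaryMask-class]).
#' @param seed a [SeedPoint-class]; its voxel must be mask-positive.
#' @return `rInit` in mm.
#' @export
estimateInitialRadius <- function(mask, seed) {
  pos <- maskArray(mask)
  d <- dim(mask); sp <- mask@spacing
  idx <- seedIndex(seed)
  if (any(idx > d)) stopfmt("seed index outside the volume")
  if (!pos[idx[1], idx[2], idx[3]])
    stopfmt("seed voxel is not inside the initial segmentation")
  sPhys <- (idx - 1) * sp
  extent <- (d - 1L) * sp
  step <- min(sp)
  hmax <- max(pmax(sPhys, extent - sPhys)) + step
  h <- 0
  repeat {
    h <- h + step
    lo <- pmax(1L, as.integer(ceiling((sPhys - h) / sp - 1e-9)) + 1L)
    hi <- pmin(d, as.integer(floor((sPhys + h) / sp + 1e-9)) + 1L)
    box <- pos[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    fracNeg <- 1 - sum(box) / length(box)
    if (fracNeg >= 0.75) return(h)
    if (all(lo == 1L) && all(hi == d)) {
      warning("bounding box reached the volume bounds before the 0.75 criterion")
      return(max((hi - lo) * sp) / 2)
    }
    if (h > hmax) return(max(extent) / 2)  # unreachable safeguard
  }
}

#' Extract the lung subvolume mask
#'
#' On the inverse of the initial segmentation: morphological close then
#' open with a 6 mm physical-radius ball (anisotropic in voxels); the
#' nodule area is then filled in with a ball of radius `rInit / 2` centred
#' at the seed, and a final close (6 mm) yields the lung mask. Structuring
#' elements are physical-radius balls rasterized by voxel-centre
#' inclusion.
#'
#' @param initialMask initial segmentation ([BinaryMask-class]).
#' @param seed a [SeedPoint-class].
#' @param rInit initial radius, mm (from [estimateInitialRadius()]).
#' @param featureRadius radius of the close/open element, mm (default 6,
#'   under the assumption that most non-nodule lung features are smaller).
#' @return Lung mask as a [BinaryMask-class].
#' @export
extractLungMask <- function(initialMask, seed, rInit, featureRadius = 6) {
  pos <- maskArray(initialMask)
  d <- dim(initialMask); sp <- initialMask@spacing
  if (rInit / 2 < min(sp))
    warning("rInit/2 is below one voxel; fill element degenerates to a single voxel")
  inv <- !pos
  lung <- maskOpen(maskClose(inv, featureRadius, sp), featureRadius, sp)
  sPhys <- (seedIndex(seed) - 1) * sp
  lung <- lung | ballMask(d, sp, c(0, 0, 0), sPhys, max(rInit / 2, 1e-6))
  lung <- maskClose(lung, featureRadius, sp)
  BinaryMask(lung, sp, initialMask@origin)
}

#' Restrict the initial segmentation to the seed's connected component
#'
#' Intersects the initial segmentation with the lung mask and keeps only
#' the 6-connected component containing the seed.
#'
#' @param initialMask,lungMask [BinaryMask-class] objects on one raster.
#' @param seed a [SeedPoint-class].
#' @return A [BinaryMask-class].
#' @export
filterToSeedComponent <- function(initialMask, lungMask, seed) {
  stopifnot(identical(dim(initialMask), dim(lungMask)))
  m <- maskArray(initialMask) & maskArray(lungMask)
  idx <- seedIndex(seed)
  if (!m[idx[1], idx[2], idx[3]])
    stopfmt("seed voxel was excluded by the lung restriction")
  d <- dim(initialMask)
  comp <- array(.seedComponent(as.vector(m), as.integer(d), idx), d)
  BinaryMask(comp, initialMask@spacing, initialMask@origin)
}

#' Refine the nodule centre on the seed slice
#'
#' Computes the 2D Euclidean distance transform (physical in-slice units,
#' distance to the nearest negative voxel) of the filtered segmentation on
#' the seed's slice and returns the 8-connected local maximum closest to
#' the seed. Ties are broken by larger distance value, then lexicographic
#' index.
#'
#' @param filteredMask seed-component mask ([BinaryMask-class]).
#' @param seed a [SeedPoint-class].
#' @return Physical centre, numeric length 3 (mm); the z component is the
#'   seed slice.
#' @export
refineCenter <- function(filteredMask, seed) {
  d <- dim(filteredMask); sp <- filteredMask@spacing
  idx <- seedIndex(seed)
  sl <- maskArray(filteredMask)[, , idx[3]]
  if (!any(sl)) stopfmt("seed slice contains no positive voxels")
  dist <- if (all(sl)) {
    # no in-slice background: distance to the slice edge
    xs <- axisCoords(d[1], sp[1]); ys <- axisCoords(d[2], sp[2])
    outer(pmin(xs - xs[1] + sp[1], xs[d[1]] - xs + sp[1]),
          pmin(ys - ys[1] + sp[2], ys[d[2]] - ys + sp[2]), pmin)
  } else {
    matrix(sqrt(.edtSquared2d(as.vector(!sl), as.integer(d[1:2]), sp[1:2])),
           d[1], d[2])
  }
  # 8-connected local maxima over the positive region
  padded <- matrix(-Inf, d[1] + 2, d[2] + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1)] <- ifelse(sl, dist, -Inf)
  isMax <- sl
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- padded[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy)]
    isMax <- isMax & (ifelse(sl, dist, -Inf) >= nb)
  }
  cand <- which(isMax, arr.ind = TRUE)
  if (nrow(cand) == 0) cand <- which(sl, arr.ind = TRUE)  # safeguard
  sPhys <- (idx[1:2] - 1) * sp[1:2]
  d2seed <- (cand[, 1] - 1) * sp[1] - sPhys[1]
  d2seed <- d2seed^2 + ((cand[, 2] - 1) * sp[2] - sPhys[2])^2
  vals <- dist[cand]
  ord <- order(d2seed, -vals, cand[, 1], cand[, 2])
  best <- cand[ord[1], ]
  unname(c((best[1] - 1) * sp[1], (best[2] - 1) * sp[2],
           (idx[3] - 1) * sp[3]))
}

#' Estimate the final nodule radius
#'
#' Expands a sphere from the refined centre in steps of the finest
#' spacing, stopping at the first radius whose incremental shell contains
#' no positive voxels or at which the in-sphere positive fraction drops
#' below 0.5; returns the last radius before the stop.
#'
#' @param filteredMask seed-component mask ([BinaryMask-class]).
#' @param center physical centre (mm), e.g. from [refineCenter()].
#' @return Radius `r` in mm.
#' @export
estimateFinalRadius <- function(filteredMask, center) {
  d <- dim(filteredMask); sp <- filteredMask@spacing
  pos <- maskArray(filteredMask)
  step <- min(sp)
  dist <- sqrt(distSquaredFrom(d, sp, c(0, 0, 0), center))
  # half-open shells [(k-1) step, k step): a voxel exactly on a shell
  # boundary belongs to the outer shell, so a lone centre voxel gives
  # r = one step via the empty-shell rule
  shell <- floor(dist / step + 1e-9) + 1
  kmax <- max(shell)
  totPer <- tabulate(shell, kmax)
  posPer <- tabulate(shell[pos], kmax)
  cumTot <- cumsum(totPer)
  cumPos <- cumsum(posPer)
  for (k in seq_len(kmax)) {
    if (posPer[k] == 0 && k == 1L)
      stopfmt("no positive voxels around the centre; radius undefined")
    if (posPer[k] == 0 || cumPos[k] / cumTot[k] < 0.5) {
      if (k == 1L) stopfmt("in-sphere fraction below 0.5 at the first step; radius undefined")
      return((k - 1) * step)
    }
  }
  kmax * step  # mask extends to the volume corner
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopfmt("estimateGeometry [%s]: %s", stage, conditionMessage(e)))
}

#' Estimate nodule geometry from a volume and seed
#'
#' Runs the full morphological chain (threshold, initial radius, lung
#' extraction, seed-component filtering, centre refinement, final radius)
#' on a subvolume around the seed and maps results back to full-volume
#' coordinates. The location scale is `sigmaLoc = r / spacing`
#' componentwise (voxel units), so the location feature equals the squared
#' physical distance from the centre divided by `r^2`.
#'
#' All per-nodule processing happens on a crop of half-width
#' `max(cropFactor * rInit, cropMin)` mm around the seed.
#'
#' @param vol a [CtVolume-class] (callers smooth before inference; see
#'   [segmentNodule()]).
#' @param seed a [SeedPoint-class].
#' @param model an [IntensityModel-class].
#' @param cropFactor,cropMin crop half-width control, mm.
#' @return A [NoduleGeometry-class].
#' @examples
#' ph <- makePhantom(phantomSpec(noduleRadius = 6, noiseSd = 0))
#' mod <- intensityModel(0, 40, -150, 150)
#' estimateGeometry(ph$volume, ph$seed, mod)
#' @export
estimateGeometry <- function(vol, seed, model, cropFactor = 8,
                             cropMin = 20) {
  stopifnot(is(vol, "CtVolume"), is(seed, "SeedPoint"),
            is(model, "IntensityModel"))
  d <- dim(vol); sp <- vol@spacing
  idx <- seedIndex(seed)
  if (any(idx > d)) stopfmt("estimateGeometry [seed]: seed outside volume")
  hw <- cropMin
  repeat {
    w <- cropWindow(d, sp, idx, hw)
    sub <- CtVolume(cropArray(vol@intensities, w), sp)
    subSeed <- SeedPoint(idx - w[, 1] + 1L)
    initial <- withStage("threshold", denoiseAndThreshold(sub, model))
    rInit <- withStage("initial-radius",
                       estimateInitialRadius(initial, subSeed))
    full <- all(w[, 1] == 1L) && all(w[, 2] == d)
    if (cropFactor * rInit <= hw || full) break
    hw <- cropFactor * rInit
  }
  lung <- withStage("lung-mask",
                    extractLungMask(initial, subSeed, rInit))
  filtered <- withStage("seed-component",
                        filterToSeedComponent(initial, lung, subSeed))
  ctrSub <- withStage("refine-center", refineCenter(filtered, subSeed))
  r <- withStage("final-radius", estimateFinalRadius(filtered, ctrSub))
  center <- ctrSub + (w[, 1] - 1L) * sp
  new("NoduleGeometry", rInit = rInit, center = center, r = r,
      sigmaLoc = r / sp, window = w)
}
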