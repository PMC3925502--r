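# Learning: voxelwise segmentation metrics, the training-set F-score
# objective of full graph-cut inference, and simulated annealing over
# theta = (w, v).

#' Voxelwise segmentation metrics
#'
#' Counts true/false positives and false negatives over all voxels and
#' derives precision `tp / (tp + fp)`, recall `tp / (tp + fn)` and the
#' F-score `2 P R / (P + R)` (the Dice coefficient of the two voxel
#' sets). Precision of an empty prediction is defined as 0; the F-score
#' is 0 when `P + R = 0`. Volumes are positive-voxel counts times the
#' voxel volume.
#'
#' @param pred,truth [BinaryMask-class] objects on the same raster.
#' @return A one-row data.frame with columns `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fscore`, `volumeMm3` (prediction),
#'   `truthVolumeMm3` and `relativeVolumeError`
#'   `(V_pred - V_truth) / V_truth`.
#' @examples
#' ph <- makePhantom(phantomSpec(noduleRadius = 5))
#' computeMetrics(ph$mask, ph$mask)  # perfect agreement
#' @export
computeMetrics <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  if (!identical(dim(pred), dim(truth)))
    stopfmt("prediction and truth shapes differ")
  p <- maskArray(pred); g <- maskArray(truth)
  if (!any(g))
    stopfmt("empty ground truth: recall and relative volume error undefined")
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  vox <- prod(pred@spacing)
  vPred <- sum(p) * vox
  vTruth <- sum(g) * vox
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, fscore = fscore, volumeMm3 = vPred,
             truthVolumeMm3 = vTruth,
             relativeVolumeError = (vPred - vTruth) / vTruth)
}

#' Percent volume change between two time points
#'
#' @param v1,v2 volumes (mm^3) at the first and second time point; `v1`
#'   must be positive.
#' @return `(v2 - v1) / v1`.
#' @export
percentVolumeChange <- function(v1, v2) {
  if (!is.numeric(v1) || v1 <= 0)
    stopfmt("V1 must be positive; percent volume change undefined")
  (v2 - v1) / v1
}

#' Precompute the per-case inference cache for training
#'
#' Geometry, features and the edge structure do not depend on theta, so
#' they are computed once per training case; each objective evaluation
#' then only rebuilds the costs and re-runs max-flow.
#'
#' @param training list of cases with `volume`, `mask`, `seed` (e.g. from
#'   [makeTrainingSet()]).
#' @param model an [IntensityModel-class].
#' @return An opaque list consumed by [objectiveFscore()].
#' @export
trainingCache <- function(training, model) {
  if (length(training) == 0) stopfmt("empty training set")
  cases <- lapply(training, function(case) {
    vol <- case$volume
    sm <- CtVolume(gaussianSmooth(vol@intensities, 1), vol@spacing)
    geom <- estimateGeometry(sm, case$seed, model)
    w <- geom@window
    sub <- CtVolume(cropArray(sm@intensities, w), sm@spacing)
    geomSub <- geom
    geomSub@center <- geom@center - (w[, 1] - 1L) * sm@spacing
    feats <- computeFeatures(sub, geomSub, model)
    e <- gridEdges6(dim(sub))
    n <- as.vector(sub@intensities)
    truth <- maskArray(case$mask)
    truthWin <- cropArray(truth, w)
    list(fg = as.vector(feats@fg), fu = as.vector(feats@fu),
         fl = as.vector(feats@fl), edges = e,
         absDiff = abs(n[e[, 1]] - n[e[, 2]]), dim = dim(sub),
         truthWin = as.vector(truthWin), truthTotal = sum(truth))
  })
  list(cases = cases, model = model)
}

#' Training-set F-score of inference under parameters theta
#'
#' Runs full graph-cut MAP inference on every training case with
#' `theta = (w0, w1, w2, w3, v)` and returns the F-score of the pooled
#' tp/fp/fn counts across cases (`pooled = FALSE` averages per-case
#' F-scores instead). A negative `v` (non-submodular energy) scores 0
#' with attribute `submodular = FALSE` so the annealer can move away from
#' it rather than aborting.
#'
#' @param theta numeric length-5 parameter vector.
#' @param cache result of [trainingCache()].
#' @param beta,deltaScale interaction constants (defaults 1 and 1000).
#' @param pooled pool counts across cases (default) or average F-scores.
#' @return Scalar F-score in `[0, 1]`.
#' @export
objectiveFscore <- function(theta, cache, beta = 1, deltaScale = 1000,
                            pooled = TRUE) {
  stopifnot(length(theta) == 5)
  w <- theta[1:4]; v <- theta[5]
  if (beta * v < 0) {
    out <- 0
    attr(out, "submodular") <- FALSE
    return(out)
  }
  tps <- fps <- fns <- fss <- numeric(length(cache$cases))
  for (k in seq_along(cache$cases)) {
    cs <- cache$cases[[k]]
    lp <- w[1] + w[2] * cs$fg + w[3] * cs$fu + w[4] * cs$fl
    unary <- cbind(-logSigmoid(-lp), -logSigmoid(lp))
    iEq <- beta * v * pmax(1 - cs$absDiff / deltaScale, 0)
    edgeCosts <- cbind(-2 * iEq, 2 * iEq, 2 * iEq, -2 * iEq)
    sol <- .maxflowSolve(unary, cs$edges, edgeCosts)
    predPos <- sol$labels == 1L
    tp <- sum(predPos & cs$truthWin)
    fp <- sum(predPos & !cs$truthWin)
    fn <- cs$truthTotal - tp
    tps[k] <- tp; fps[k] <- fp; fns[k] <- fn
    pk <- if (tp + fp > 0) tp / (tp + fp) else 0
    rk <- if (tp + fn > 0) tp / (tp + fn) else 0
    fss[k] <- if (pk + rk > 0) 2 * pk * rk / (pk + rk) else 0
  }
  if (pooled) {
    tp <- sum(tps); fp <- sum(fps); fn <- sum(fns)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  } else mean(fss)
}

#' Construct an AnnealConfig
#'
#' @param initialParams starting theta (default all zero).
#' @param lower,upper box bounds. Defaults: `v >= 0` (which also
#'   guarantees submodular energies) and `w1, w2, w3 <= 0` — the three
#'   features are non-negative costs, so rewarding them is never a
#'   sensible model; constraining their sign makes the 500-iteration
#'   search reliable where a fully unbounded one frequently strands on
#'   the zero-score plateau. The bias `w0` stays unbounded.
#' @param initialTemperature,coolingRate exponential schedule
#'   `T(i) = T0 * coolingRate^(i - 1)`.
#' @param iterations number of proposals.
#' @param reannealInterval reset the schedule every this many iterations
#'   (0 disables); the default 125 gives four hot/cold cycles over 500
#'   iterations, which escapes the flat zero-score region around the
#'   all-zero start far more reliably than a single monotone schedule.
#' @param stepScale proposal sd is `stepScale * max(T, 0.05)`; length 1
#'   or one value per coordinate (the default steps `v` more finely than
#'   the association weights, matching its useful scale).
#' @param acceptScale worse moves are accepted with probability
#'   `exp((F' - F) * acceptScale / T)`.
#' @param rngSeed integer seed.
#' @return An [AnnealConfig-class].
#' @export
annealConfig <- function(initialParams = rep(0, 5),
                         lower = c(-Inf, -Inf, -Inf, -Inf, 0),
                         upper = c(Inf, 0, 0, 0, Inf),
                         initialTemperature = 1,
                         coolingRate = 0.97, iterations = 500L,
                         reannealInterval = 125L,
                         stepScale = c(2, 2, 2, 2, 0.5),
                         acceptScale = 50, rngSeed = 1L)
  new("AnnealConfig", initialParams = as.numeric(initialParams),
      lower = as.numeric(lower), upper = as.numeric(upper),
      initialTemperature = as.numeric(initialTemperature),
      coolingRate = as.numeric(coolingRate),
      iterations = as.integer(iterations),
      reannealInterval = as.integer(reannealInterval),
      stepScale = as.numeric(stepScale),
      acceptScale = as.numeric(acceptScale), rngSeed = as.integer(rngSeed))

#' Train DRF parameters by simulated annealing on the F-score
#'
#' Maximizes [objectiveFscore()] over `theta = (w, v)` with
#' temperature-scaled Gaussian proposals, exponential cooling, bound
#' handling by rejection (out-of-bound proposals are redrawn), and
#' best-ever bookkeeping: the returned parameters are never worse on the
#' training objective than the starting point. Reproducible under
#' `config@rngSeed`.
#'
#' @param training list of cases with `volume`, `mask`, `seed`.
#' @param config an [AnnealConfig-class].
#' @param model optional [IntensityModel-class]; fitted from `training`
#'   with [fitIntensityModel()] when NULL.
#' @param beta,deltaScale,pooled passed to [objectiveFscore()].
#' @param objective optional replacement objective `function(theta)`
#'   (used in tests and diagnostics to bypass inference); when supplied,
#'   `training` may be a placeholder and only the annealer runs.
#' @return A [TrainResult-class].
#' @export
trainDrf <- function(training, config = annealConfig(), model = NULL,
                     beta = 1, deltaScale = 1000, pooled = TRUE,
                     objective = NULL) {
  stopifnot(is(config, "AnnealConfig"))
  if (is.null(objective)) {
    if (length(training) == 0) stopfmt("empty training set")
    if (is.null(model)) model <- fitIntensityModel(training)
    cache <- trainingCache(training, model)
    obj <- function(th) objectiveFscore(th, cache, beta = beta,
                                        deltaScale = deltaScale,
                                        pooled = pooled)
  } else {
    obj <- objective
    if (is.null(model)) model <- intensityModel(0, 1, -1, 1)
  }
  nIt <- config@iterations
  trace <- data.frame(iteration = seq_len(nIt), w0 = NA_real_,
                      w1 = NA_real_, w2 = NA_real_, w3 = NA_real_,
                      v = NA_real_, fscore = NA_real_,
                      temperature = NA_real_, accepted = NA)
  withSeed(config@rngSeed, {
    theta <- config@initialParams
    f <- as.numeric(obj(theta))
    bestTheta <- theta; bestF <- f
    for (it in seq_len(nIt)) {
      sched <- if (config@reannealInterval > 0)
        (it - 1L) %% config@reannealInterval else it - 1L
      if (config@reannealInterval > 0 && it > 1L && sched == 0L) {
        # new hot cycle restarts from the incumbent best, so plateau
        # wandering in a previous cycle cannot strand the search
        theta <- bestTheta
        f <- bestF
      }
      temp <- config@initialTemperature * config@coolingRate^sched
      stepSd <- rep_len(config@stepScale, 5) * max(temp, 0.05)
      prop <- theta
      for (tries in 1:50) {
        prop <- theta + stats::rnorm(5, 0, stepSd)
        if (all(prop >= config@lower & prop <= config@upper)) break
      }
      prop <- pmin(pmax(prop, config@lower), config@upper)
      f2 <- as.numeric(obj(prop))
      accept <- f2 >= f ||
        stats::runif(1) < exp((f2 - f) * config@acceptScale / max(temp, 1e-8))
      if (accept) { theta <- prop; f <- f2 }
      if (f > bestF) { bestF <- f; bestTheta <- theta }
      trace[it, 2:6] <- theta
      trace[it, "fscore"] <- f
      trace[it, "temperature"] <- temp
      trace[it, "accepted"] <- accept
    }
    new("TrainResult",
        params = drfParams(w = bestTheta[1:4], v = bestTheta[5],
                           model = model, beta = beta,
                           deltaScale = deltaScale),
        bestFscore = bestF, trace = trace)
  })
}
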