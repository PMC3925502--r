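# Feature formulas, potentials, and the energy conversion.

featureFixture <- function(seed = 1, d = c(4, 4, 3)) {
  set.seed(seed)
  vol <- CtVolume(array(runif(prod(d), -900, 100), d), ctSpacing)
  mod <- intensityModel(-200, 150, -700, 50)
  geom <- new("NoduleGeometry", rInit = 3, center = (d - 1) * ctSpacing / 2,
              r = 3, sigmaLoc = 3 / ctSpacing,
              window = cbind(c(1L, 1L, 1L), d))
  list(vol = vol, mod = mod, geom = geom,
       feats = computeFeatures(vol, geom, mod))
}

test_that("feature arrays follow the model formulas", {
  fx <- featureFixture()
  n <- intensities(fx$vol)
  expect_equal(fx$feats@fg, (n + 200)^2 / 150^2)
  expect_equal(fx$feats@fu, array(1 - (n > -700 & n < 50), dim(n)))
  # location feature: 0 at the centre voxel, 1 one radius away, strict
  # thresholds at the window edges
  volc <- CtVolume(array(-200, c(5, 5, 5)), c(1, 1, 1))
  geo <- new("NoduleGeometry", rInit = 2, center = c(2, 2, 2), r = 2,
             sigmaLoc = c(2, 2, 2), window = cbind(rep(1L, 3), rep(5L, 3)))
  f <- computeFeatures(volc, geo, fx$mod)
  expect_equal(f@fl[3, 3, 3], 0)
  expect_equal(f@fl[5, 3, 3], 1)   # one radius (2 mm) along x
  volEdge <- CtVolume(array(50, c(2, 2, 2)), c(1, 1, 1))
  geo2 <- new("NoduleGeometry", rInit = 1, center = c(0.5, 0.5, 0.5), r = 1,
              sigmaLoc = c(1, 1, 1), window = cbind(rep(1L, 3), rep(2L, 3)))
  expect_true(all(computeFeatures(volEdge, geo2, fx$mod)@fu == 1))
})

test_that("association log-probabilities are normalized and stable", {
  # zero weights: both labels get log(1/2)
  expect_equal(associationLogProb(c(1, 2, 0, 1), +1, rep(0, 4)), log(0.5))
  expect_equal(associationLogProb(c(1, 2, 0, 1), -1, rep(0, 4)), log(0.5))
  # complement identity over random weights/features
  set.seed(9)
  for (k in 1:200) {
    h <- c(1, runif(3, 0, 10))
    w <- rnorm(4, 0, 3)
    s <- exp(associationLogProb(h, +1, w)) + exp(associationLogProb(h, -1, w))
    expect_lt(abs(s - 1), 1e-12)
  }
  # asymptotics: huge margins neither overflow nor lose the linear tail
  h <- c(1, 0, 0, 0)
  expect_gt(associationLogProb(h, +1, c(50, 0, 0, 0)), -1e-20)
  expect_equal(associationLogProb(h, -1, c(50, 0, 0, 0)), -50,
               tolerance = 1e-12)
  expect_lte(associationLogProb(h, +1, c(700, 0, 0, 0)), 0)
})

test_that("interaction potential implements the attenuated Ising form", {
  expect_equal(interactionPotential(0, 0, 1, 1, v = 2, beta = 1), 2)
  expect_equal(interactionPotential(0, 0, 1, -1, v = 2, beta = 1), -2)
  expect_equal(interactionPotential(0, 1000, 1, 1, v = 5, beta = 1), 0)
  expect_equal(interactionPotential(0, 2500, 1, -1, v = 5, beta = 1), 0)
  expect_equal(interactionPotential(0, 500, 1, 1, v = 1, beta = 1), 0.5)
  expect_equal(interactionPotential(0, 0, 1, 1, v = 3, beta = 0), 0)
  # symmetry under (i,j) swap and joint label flip
  set.seed(3)
  ni <- runif(50, -1000, 200); nj <- runif(50, -1000, 200)
  xi <- sample(c(-1, 1), 50, TRUE); xj <- sample(c(-1, 1), 50, TRUE)
  v <- 1.3
  expect_equal(interactionPotential(ni, nj, xi, xj, v),
               interactionPotential(nj, ni, xj, xi, v))
  expect_equal(interactionPotential(ni, nj, xi, xj, v),
               interactionPotential(ni, nj, -xi, -xj, v))
  # delta lies in [0,1] and is non-increasing in |ni - nj|
  dd <- seq(0, 3000, by = 100)
  delta <- interactionPotential(0, dd, 1, 1, v = 1)
  expect_true(all(delta >= 0 & delta <= 1))
  expect_true(all(diff(delta) <= 0))
})

test_that("total log-potential decomposes into unary and edge terms", {
  fx <- featureFixture(seed = 2)
  par <- drfParams(w = c(1, -0.5, -1, -0.8), v = 0.7, model = fx$mod)
  d <- dim(fx$vol)
  set.seed(11)
  lab <- BinaryMask(array(runif(prod(d)) < 0.5, d), ctSpacing)
  # v = 0: total equals the sum of per-voxel association terms
  par0 <- drfParams(w = par@w, v = 0, model = fx$mod)
  tot0 <- totalLogPotential(fx$vol, lab, par0, fx$feats)
  hs <- cbind(1, as.vector(fx$feats@fg), as.vector(fx$feats@fu),
              as.vector(fx$feats@fl))
  aSum <- sum(vapply(seq_len(prod(d)), function(i)
    associationLogProb(hs[i, ], as.vector(maskLabels(lab))[i], par@w),
    numeric(1)))
  expect_equal(tot0, aSum, tolerance = 1e-10)
  # flipping one voxel changes the total by its unary delta plus twice
  # the sum of its 6 edge deltas (brute-force recomputation)
  tot <- totalLogPotential(fx$vol, lab, par, fx$feats)
  i <- c(2L, 3L, 2L)
  lab2 <- lab
  lab2@labels[i[1], i[2], i[3]] <- -lab@labels[i[1], i[2], i[3]]
  tot2 <- totalLogPotential(fx$vol, lab2, par, fx$feats)
  n <- intensities(fx$vol)
  x <- maskLabels(lab); x2 <- maskLabels(lab2)
  dUn <- associationLogProb(c(1, fx$feats@fg[i[1], i[2], i[3]],
                              fx$feats@fu[i[1], i[2], i[3]],
                              fx$feats@fl[i[1], i[2], i[3]]),
                            x2[i[1], i[2], i[3]], par@w) -
    associationLogProb(c(1, fx$feats@fg[i[1], i[2], i[3]],
                         fx$feats@fu[i[1], i[2], i[3]],
                         fx$feats@fl[i[1], i[2], i[3]]),
                       x[i[1], i[2], i[3]], par@w)
  dEdge <- 0
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    j <- i + o
    if (any(j < 1) || any(j > dim(fx$vol))) next
    dEdge <- dEdge +
      interactionPotential(n[i[1], i[2], i[3]], n[j[1], j[2], j[3]],
                           x2[i[1], i[2], i[3]], x2[j[1], j[2], j[3]],
                           par@v) -
      interactionPotential(n[i[1], i[2], i[3]], n[j[1], j[2], j[3]],
                           x[i[1], i[2], i[3]], x[j[1], j[2], j[3]],
                           par@v)
  }
  expect_equal(tot2 - tot, dUn + 2 * dEdge, tolerance = 1e-10)
})

test_that("uniform volumes give the closed-form total log-potential", {
  d <- c(3, 4, 3)
  vol <- CtVolume(array(-300, d), c(1, 1, 1))
  mod <- intensityModel(-300, 100, -600, 0)
  geom <- new("NoduleGeometry", rInit = 1, center = c(1, 1, 1), r = 1,
              sigmaLoc = c(1, 1, 1), window = cbind(rep(1L, 3), d))
  feats <- computeFeatures(vol, geom, mod)
  par <- drfParams(w = rep(0, 4), v = 1.5, beta = 1, model = mod)
  lab <- BinaryMask(array(TRUE, d), c(1, 1, 1))
  nEdges <- 2 * 4 * 3 + 3 * 3 * 3 + 3 * 4 * 2   # x + y + z interior faces
  expect_equal(totalLogPotential(vol, lab, par, feats),
               prod(d) * log(0.5) + 2 * nEdges * 1.5, tolerance = 1e-10)
})

test_that("energy conversion is exactly the negated log-potential", {
  for (seed in 1:20) {
    en <- randomSubmodularEnergy(c(3, 3, 3), seed = seed)
    set.seed(seed + 100)
    d <- en@dim
    lab <- BinaryMask(array(runif(prod(d)) < 0.5, d), en@spacing)
    # reconstruct the generating DRF pieces to evaluate the log-potential
    set.seed(seed)
    n <- prod(d)
    vol <- CtVolume(array(runif(n, -800, 0), d), c(1, 1, 1))
    mod <- intensityModel(-400, 200, -800, 0)
    geom <- new("NoduleGeometry", rInit = 2, center = (d - 1) / 2, r = 2,
                sigmaLoc = c(2, 2, 2), window = cbind(rep(1L, 3), d))
    feats <- computeFeatures(vol, geom, mod)
    par <- drfParams(w = rnorm(4, 0, 2), v = runif(1, 0, 2), model = mod)
    expect_equal(energyOf(en, lab) +
                   totalLogPotential(vol, lab, par, feats), 0,
                 tolerance = 1e-8)
  }
})

test_that("Ising edge tables are submodular iff beta*v >= 0", {
  en <- randomSubmodularEnergy(seed = 5)
  ec <- en@edgeCosts
  expect_true(all(ec[, 2] + ec[, 3] - ec[, 1] - ec[, 4] >= 0))
  fx <- featureFixture()
  parBad <- drfParams(w = rep(0, 4), v = -1, model = fx$mod)
  expect_error(buildEnergy(fx$vol, parBad, fx$feats), "v >= 0")
  par0 <- drfParams(w = rep(0.5, 4), v = 0, model = fx$mod)
  en0 <- buildEnergy(fx$vol, par0, fx$feats)
  expect_true(all(en0@edgeCosts == 0))
})
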