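# Intensity-model fitting and the seven-step geometry chain.

test_that("intensity model pools mean, sd and min/max across cases", {
  d <- c(3, 3, 3)
  vol <- CtVolume(array(0, d), c(1, 1, 1))
  vol@intensities[1:3] <- c(-10, 0, 10)
  m <- array(FALSE, d); m[1:3] <- TRUE
  mod <- fitIntensityModel(list(list(volume = vol,
                                     mask = BinaryMask(m, c(1, 1, 1)))))
  expect_equal(mod@muInt, 0)
  expect_equal(mod@sigmaInt, sd(c(-10, 0, 10)))
  expect_equal(mod@tMin, -10)
  expect_equal(mod@tMax, 10)
  # identical positives: sigma/thresholds degenerate
  volc <- CtVolume(array(100, d), c(1, 1, 1))
  expect_error(fitIntensityModel(list(list(volume = volc,
                                           mask = BinaryMask(m, c(1, 1, 1))))),
               "degenerate")
  expect_error(fitIntensityModel(list(list(volume = vol,
                                           mask = BinaryMask(array(FALSE, d),
                                                             c(1, 1, 1))))),
               "no positive voxels")
  # CLT sanity on phantoms: pooled mean within 3 sd / sqrt(N) of noduleHu
  set <- makeTrainingSet(2, radius = c(6, 6), lumpiness = c(0, 0),
                         noiseSd = c(40, 40), psfSd = 0, rngSeed = 8)
  modp <- fitIntensityModel(set)
  npos <- sum(sapply(set, function(s) sum(maskArray(s$mask))))
  expect_lt(abs(modp@muInt), 3 * 40 / sqrt(npos))
})

test_that("thresholding smooths in-slice and applies strict bounds", {
  d <- c(9, 9, 3)
  mod <- intensityModel(0, 50, -100, 100)
  mid <- CtVolume(array(0, d), ctSpacing)
  expect_true(all(maskLabels(denoiseAndThreshold(mid, mod)) == 1L))
  atMax <- CtVolume(array(100, d), ctSpacing)
  expect_true(all(maskLabels(denoiseAndThreshold(atMax, mod)) == -1L))
  # single bright spike: compare against a direct 2D convolution oracle
  spike <- array(0, d)
  spike[5, 5, 2] <- 1100
  vol <- CtVolume(spike, ctSpacing)
  got <- maskArray(denoiseAndThreshold(vol, mod))
  k <- noduleDRF:::gaussKernel(1)
  r <- (length(k) - 1) / 2
  sm <- array(0, d)
  for (z in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    num <- 0; den <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
      wgt <- k[a + r + 1] * k[b + r + 1]
      num <- num + wgt * spike[ii, jj, z]
      den <- den + wgt
    }
    sm[i, j, z] <- num / den
  }
  expect_equal(got, sm > -100 & sm < 100)
  expect_false(got[5, 5, 2])  # the spike itself is attenuated but stays out
})

test_that("initial radius matches a brute-force box growth oracle", {
  ph <- spherePhantom(radius = 5)
  mod <- phantomModel()
  init <- denoiseAndThreshold(ph$volume, mod)
  rInit <- estimateInitialRadius(init, ph$seed)
  # independent oracle: literal physical box growth over the same mask
  pos <- maskArray(init)
  d <- dim(init); sp <- spacing(init)
  sPhys <- (seedIndex(ph$seed) - 1) * sp
  step <- min(sp)
  expected <- NA
  for (h in step * seq_len(200)) {
    lo <- pmax(1, ceiling((sPhys - h) / sp - 1e-9) + 1)
    hi <- pmin(d, floor((sPhys + h) / sp + 1e-9) + 1)
    box <- pos[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (1 - sum(box) / length(box) >= 0.75) { expected <- h; break }
  }
  expect_equal(rInit, expected)
  # analytic ballpark: a box around a 5 mm sphere is 25% full at edge
  # (4pi/3 * 125 / 0.25)^(1/3) ~ 12.8 mm, so rInit ~ 6.4 mm
  expect_lt(abs(rInit - 6.4), 1.5 * min(sp) + 0.7)
  expect_error(estimateInitialRadius(init, SeedPoint(c(1, 1, 1))),
               "not inside")
})

test_that("initial radius warns when the criterion is never met", {
  d <- c(10, 10, 6)
  full <- BinaryMask(array(TRUE, d), ctSpacing)
  expect_warning(r <- estimateInitialRadius(full, SeedPoint(c(5, 5, 3))),
                 "bounds")
  expect_equal(r, max((d - 1) * ctSpacing) / 2)
})

test_that("lung extraction removes the pleural wall but keeps the nodule", {
  ph <- makePhantom(phantomSpec(noduleRadius = 5, noiseSd = 0, psfSd = 0,
                                pleuralWall = list(thickness = 8)))
  mod <- phantomModel()
  init <- denoiseAndThreshold(ph$volume, mod)
  rInit <- estimateInitialRadius(init, ph$seed)
  lung <- extractLungMask(init, ph$seed, rInit)
  d <- dim(lung); sp <- spacing(lung)
  wallFrom <- (d[1] - 1) * sp[1] - 8
  expectedLung <- array(rep(noduleDRF:::axisCoords(d[1], sp[1]) < wallFrom,
                            d[2] * d[3]), d)
  inter <- sum(maskArray(lung) & expectedLung)
  dice <- 2 * inter / (sum(maskArray(lung)) + sum(expectedLung))
  expect_gte(dice, 0.95)
  # nodule voxels survive inside the lung mask
  expect_gt(mean(maskArray(lung)[maskArray(ph$mask)]), 0.95)
  # degenerate input: inverse all-positive still yields a non-empty mask
  allNeg <- BinaryMask(array(FALSE, c(12, 12, 8)), ctSpacing)
  lung2 <- extractLungMask(allNeg, SeedPoint(c(6, 6, 4)), 4)
  expect_gt(sum(maskArray(lung2)), 0)
})

test_that("lung masks are stable across voxel rasters of one geometry", {
  mkLung <- function(sp) {
    ph <- makePhantom(phantomSpec(noduleRadius = 5, noiseSd = 0, psfSd = 0,
                                  spacing = sp,
                                  pleuralWall = list(thickness = 8)))
    mod <- phantomModel()
    init <- denoiseAndThreshold(ph$volume, mod)
    lung <- extractLungMask(init, ph$seed,
                            estimateInitialRadius(init, ph$seed))
    sum(maskArray(lung)) * prod(sp)
  }
  vIso <- mkLung(c(1, 1, 1))
  vAniso <- mkLung(c(0.7, 0.7, 1.25))
  expect_lt(abs(vIso - vAniso) / vIso, 0.12)
})

test_that("seed-component filtering keeps exactly the seed's blob", {
  d <- c(12, 12, 6)
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:4] <- TRUE    # blob A
  m[8:11, 8:11, 2:5] <- TRUE  # blob B
  mask <- BinaryMask(m, ctSpacing)
  lungAll <- BinaryMask(array(TRUE, d), ctSpacing)
  keep <- filterToSeedComponent(mask, lungAll, SeedPoint(c(3, 3, 3)))
  expect_identical(maskArray(keep), array(m & !(m & (slice.index(m, 1) > 5)), d))
  # lung restriction can strip the seed
  lungNone <- BinaryMask(array(FALSE, d), ctSpacing)
  expect_error(filterToSeedComponent(mask, lungNone, SeedPoint(c(3, 3, 3))),
               "excluded")
  # an attached vessel inside the lung remains connected to the nodule
  phv <- makePhantom(phantomSpec(noduleRadius = 5, noiseSd = 0, psfSd = 0,
                                 vessel = list(radius = 1.5)))
  mod <- phantomModel()
  init <- denoiseAndThreshold(phv$volume, mod)
  lung <- extractLungMask(init, phv$seed,
                          estimateInitialRadius(init, phv$seed))
  filt <- filterToSeedComponent(init, lung, phv$seed)
  # the kept component extends along the vessel far beyond the nodule's
  # z range (the attached vessel stays connected to the seed component)
  zAny <- apply(maskArray(filt), 3, any)
  zTruth <- apply(maskArray(phv$mask), 3, any)
  expect_gt(sum(zAny), sum(zTruth) + 2)
})

test_that("centre refinement finds distance-transform peaks near the seed", {
  d <- c(21, 21, 3)
  sp <- c(1, 1, 2)
  mkDisk <- function(ci, cj, r) {
    outer(1:d[1], 1:d[2], function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
  }
  m <- array(FALSE, d)
  m[, , 2] <- mkDisk(10, 10, 6)
  mask <- BinaryMask(m, sp)
  ctr <- refineCenter(mask, SeedPoint(c(13, 8, 2)))
  expect_lte(max(abs(ctr[1:2] - c(9, 9))), 1)  # disk centre +-1 voxel
  expect_equal(ctr[3], 2)                      # physical z of the seed slice
  # single positive voxel: that voxel
  m2 <- array(FALSE, d); m2[4, 5, 2] <- TRUE
  ctr2 <- refineCenter(BinaryMask(m2, sp), SeedPoint(c(4, 5, 2)))
  expect_equal(ctr2[1:2], c(3, 4))
  # two equal disks: the one whose centre is nearer the seed wins
  m3 <- array(FALSE, d)
  m3[, , 2] <- mkDisk(6, 10, 4) | mkDisk(16, 10, 4)
  ctr3 <- refineCenter(BinaryMask(m3, sp), SeedPoint(c(7, 10, 2)))
  expect_lte(abs(ctr3[1] - 5), 1)
  expect_error(refineCenter(BinaryMask(array(FALSE, d), sp),
                            SeedPoint(c(2, 2, 1))), "no positive")
})

test_that("final radius recovers spheres and ignores detached voxels", {
  sp <- c(0.5, 0.5, 0.5)
  ph <- makePhantom(phantomSpec(noduleRadius = 5, spacing = sp,
                                noiseSd = 0, psfSd = 0))
  ctr <- ph$spec@noduleCenter
  r <- estimateFinalRadius(ph$mask, ctr)
  expect_lte(abs(r - 5), 0.5)
  # one detached distant voxel leaves the estimate unchanged
  m <- maskArray(ph$mask)
  m[2, 2, 2] <- TRUE
  expect_equal(estimateFinalRadius(BinaryMask(m, sp), ctr), r)
  # isolated voxel at the centre: one step
  d <- dim(ph$mask)
  m1 <- array(FALSE, d)
  m1[11, 11, 11] <- TRUE
  expect_equal(estimateFinalRadius(BinaryMask(m1, sp),
                                   (c(11, 11, 11) - 1) * sp), 0.5)
  expect_error(estimateFinalRadius(BinaryMask(array(FALSE, d), sp), ctr),
               "radius undefined")
})

test_that("full geometry chain recovers noiseless phantom geometry", {
  mod <- phantomModel()
  ph <- spherePhantom(radius = 6)
  g <- estimateGeometry(ph$volume, ph$seed, mod)
  sp <- spacing(ph$volume)
  expect_lte(abs(g@r - 6), min(sp) + 1e-9)
  expect_true(all(abs(g@center - ph$spec@noduleCenter) <= sp + 1e-9))
  expect_equal(g@sigmaLoc, g@r / sp)
  # lumpy nodule: r within the true radial extent range
  phl <- makePhantom(phantomSpec(noduleRadius = 6, lumpiness = 0.2,
                                 noiseSd = 0, psfSd = 0))
  gl <- estimateGeometry(phl$volume, phl$seed, mod)
  expect_gte(gl@r, 6 * 0.8 - min(sp))
  expect_lte(gl@r, 6 * 1.2 + min(sp))
  # juxtapleural: chain runs without error and stays near the truth
  phw <- makePhantom(phantomSpec(noduleRadius = 5, noiseSd = 0, psfSd = 0,
                                 pleuralWall = list(thickness = 8)))
  gw <- estimateGeometry(phw$volume, phw$seed, mod)
  expect_lt(abs(gw@r - 5), 2 * min(sp) + 1e-9)
})

test_that("geometry is invariant to joint intensity/model shifts", {
  ph <- makePhantom(phantomSpec(noduleRadius = 5, noiseSd = 20, rngSeed = 6))
  mod <- phantomModel()
  g1 <- estimateGeometry(ph$volume, ph$seed, mod)
  shift <- 400
  vol2 <- CtVolume(intensities(ph$volume) + shift, spacing(ph$volume))
  mod2 <- intensityModel(mod@muInt + shift, mod@sigmaInt,
                         mod@tMin + shift, mod@tMax + shift)
  g2 <- estimateGeometry(vol2, ph$seed, mod2)
  expect_equal(g1@rInit, g2@rInit)
  expect_equal(g1@r, g2@r)
  expect_equal(g1@center, g2@center)
})
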