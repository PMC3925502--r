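# noduleDRF

Semi-automatic 3D segmentation of solid pulmonary nodules in chest CT
volumes from a **single seed point**, for radiologists and imaging
researchers tracking nodule volumes across studies. The segmentation is
the exact maximum-a-posteriori labeling of a **discriminative random
field (DRF)** over the voxel 6-neighbourhood graph, and every parameter
of the model is learned from a handful of labelled training nodules.

## The model

Voxel labels $x_i \in \{-1, +1\}$ (nodule = $+1$) follow

$$\Pr(x \mid y) \propto \exp\Big(\sum_i A(x_i, y) + \sum_i \sum_{j \in N_i} I(x_i, x_j, y)\Big)$$

* **Association potential** — the log of a logistic model,
  $A(x_i, y) = \log \sigma(x_i\, w^\top h_i)$, over features
  $h_i = (1, f_g, f_u, f_l)$: squared standardized intensity deviation
  under a Gaussian nodule-intensity model, an intensity
  threshold-window indicator, and squared distance from the estimated
  nodule centre normalized by the estimated radius. Centre and radius
  come from a morphological pre-pass (in-slice smoothing and
  thresholding, bounding-box growth, 6 mm close/open lung extraction,
  seed-component filtering, 2D distance-transform centre refinement,
  sphere expansion) driven only by the seed point.
* **Interaction potential** — an Ising smoothing term attenuated by the
  neighbour intensity difference,
  $I = \beta\, x_i x_j\, v \max(1 - |n_i - n_j|/1000,\, 0)$.
* **Inference** — with $v \ge 0$ the energy is submodular and the exact
  MAP labeling is found by min-cut/max-flow (C++ Dinic solver; an
  exhaustive enumerator and an independent min-cut route verify it in
  the tests).
* **Learning** — simulated annealing directly on the F-score (= Dice)
  of full inference results on the training set, rather than a
  pseudo-likelihood surrogate.

A synthetic CT phantom generator (lumpy nodules at realistic Hounsfield
contrast, anisotropic voxels, partial-volume blur, Gaussian noise,
juxtavascular and juxtapleural variants) makes training, inference and
evaluation fully reproducible without clinical data. Volumes and masks
read and write as NIfTI (`.nii`, `.nii.gz`) and MetaImage
(`.mha`/`.mhd`).

## Worked example

Train on four phantoms (one juxtapleural, one juxtavascular, two plain)
and segment an unseen noisy phantom:

```r
library(noduleDRF)

train <- makeTrainingSet(4, radius = c(4, 7), vesselProb = 0.25,
                         wallProb = 0.25, stratify = TRUE, rngSeed = 42)
fit <- trainDrf(train, annealConfig(iterations = 500, rngSeed = 7))
fit
#> TrainResult: best F-score 0.9425 over 500 iterations
#> DrfParams: w = (7.72, -0.05165, -2.662, -4.75), v = 0.5396, beta = 1
#> IntensityModel: mu -50.42, sigma 83.09, window (-363.37, 139.92) HU

ph <- makePhantom(phantomSpec(noduleRadius = 6, noiseSd = 40, rngSeed = 99))
mask <- segmentNodule(ph$volume, ph$seed, fit@params)
print(computeMetrics(mask, ph$mask), digits = 3)
#>     tp fp  fn precision recall fscore volumeMm3 truthVolumeMm3
#> 1 1322  0 158         1  0.893  0.944       810            906
#>   relativeVolumeError
#> 1              -0.107
```

Reading the output: the trained weights penalize the three cost
features (negative `w1..w3`) against a positive bias, with a moderate
smoothing weight `v`; on the held-out 6 mm nodule the mask overlaps the
ground truth with Dice 0.944 — every predicted voxel is correct
(precision 1) and the missed 11% are partial-volume rim voxels, giving
a volume underestimate of the same order.

The same pipeline runs from the shell via the bundled script
(`inst/scripts/noduledrf`): subcommands `phantom`, `train`, `segment`
and `evaluate` over YAML configs, exit codes 0/1/2/3 for
success/usage/data/numerical errors.

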