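---
title: "Discriminative random field segmentation of lung nodules: model and methods"
author: "noduleDRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative random field segmentation of lung nodules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleDRF)
```

## The problem

Tracking small solid pulmonary nodules across CT studies requires volumes,
and volumes require segmentation. Manual voxel-wise delineation is slow and
inconsistent; fully automatic detection is a different problem. This package
implements a *semi-automatic* middle ground: a clinician (or a longitudinal
registration step) supplies one seed voxel per nodule, and the package
returns a full 3D mask via exact maximum-a-posteriori (MAP) inference in a
discriminative random field (DRF).

## The model

Voxels form the node set $S$ of a graph whose edges $E$ connect
6-neighbours. Each voxel $s_i$ has an observed (pre-smoothed) intensity
$n_i$, a position $p_i$, and a hidden label $x_i \in \{-1, +1\}$ (nodule =
$+1$). The posterior over labelings factorizes over unary and pairwise
terms:

$$\Pr(x \mid y) \;=\; \frac{1}{Z}\exp\Big(\sum_{i \in S} A(x_i, y)
  \;+\; \sum_{i \in S}\sum_{j \in N_i} I(x_i, x_j, y)\Big),$$

where the double sum visits every unordered edge twice. $Z$ is never
computed: MAP inference only needs the exponent.

### Association potential

Each voxel gets a feature vector $f_i = [f_g, f_u, f_l]$:

* $f_g = (n_i - \mu_\text{int})^2 / \sigma_\text{int}^2$ — squared
  standardized deviation under a Gaussian model of nodule intensity;
* $f_u = 0$ if $t_\min < n_i < t_\max$ (strict), else $1$ — a uniform
  (threshold-window) model;
* $f_l = \sum_k \big((p_{ik} - l_k)/\sigma_{\text{loc},k}\big)^2$ —
  squared distance from the estimated nodule centre $l$, normalized per
  axis by $\sigma_\text{loc} = r / v$ with $r$ the estimated radius and $v$
  the voxel size. Equivalently: squared physical distance over $r^2$, so a
  voxel one radius from the centre has $f_l = 1$.

With the bias-augmented vector $h_i = (1, f_i)$ (no kernel mapping: the
identity is used) and weights $w$, the association potential is the
log-logistic probability

$$A(x_i, y) = \log \frac{1}{1 + e^{-x_i\, w^\top h_i}},$$

evaluated with the usual overflow-safe `log1p` split so that
$e^{A(+1)} + e^{A(-1)} = 1$ holds to machine precision at any margin.

The four global constants $\mu_\text{int}, \sigma_\text{int}, t_\min,
t_\max$ are the mean, standard deviation, minimum and maximum of all
ground-truth nodule voxels pooled over the training volumes
(`fitIntensityModel()`). Because manually labelled nodule masks include
partial-volume rim voxels, the fitted window is wide (several hundred HU)
— substituting a "clean" nodule-core window here starves the model of rim
voxels and visibly undersegments.

### Interaction potential

Neighbouring labels are coupled by an Ising term attenuated by the
intensity difference:

$$\delta_{ij} = \max\!\Big(1 - \frac{|n_i - n_j|}{1000},\, 0\Big), \qquad
  I(x_i, x_j, y) = \beta\, x_i x_j\, v\, \delta_{ij}.$$

Equal labels are rewarded, most strongly where intensities agree; the
reward vanishes once neighbours differ by the full scale (1000 HU,
appropriate for the lung/soft-tissue contrast and exposed as
`deltaScale`). $\beta$ is kept as a pure on/off switch (default 1) and
excluded from learning; $v \ge 0$ is the learned smoothing strength.

### Exact inference

`buildEnergy()` negates the exponent into a minimize-form energy (unary
$-A$, pairwise $-2I$ per unordered edge, folding the directed double sum),
so energy plus log-potential is exactly zero for every labeling — a
property the tests assert. With $\beta v \ge 0$ every pairwise table is
submodular and the global minimizer is found by an s-t min-cut
(Kolmogorov–Zabih reparameterisation; Dinic max-flow in C++). Inference
refuses non-submodular energies rather than truncating them, so the
"exact MAP" claim is never silently weakened. Before inference the volume
is smoothed by a 3D Gaussian of one voxel standard deviation; features see
the smoothed volume ("one voxel" is read as sd = 1 voxel, matching the
in-slice filter used during geometry estimation).

Tie-breaking is deterministic: with equal unary costs and no coupling a
voxel takes label $-1$ (it is unreachable in the residual graph), and the
exhaustive reference solver returns the lexicographically smallest
minimizer. `segmentNodule()` with $v = 0$ therefore coincides bit-for-bit
with thresholding the per-voxel logistic probability at $0.5$.

## Geometry estimation

All location information enters through a morphological pre-pass
(`estimateGeometry()`), run on a subvolume of half-width
$\max(8\,r_\text{init}, 20\ \text{mm})$ around the seed:

1. **Initial segmentation** — every slice is smoothed with a 2D Gaussian
   of one voxel sd, then the strict window $(t_\min, t_\max)$ is applied.
2. **Initial radius** — a seed-centred box grows isotropically in physical
   units (one step = one voxel of the finest axis) until the fraction of
   box voxels *outside* the initial segmentation first reaches 0.75;
   $r_\text{init}$ is the box half-width at the stop. If the box hits the
   volume bounds first, half the largest reached edge is returned with a
   warning.
3. **Lung mask** — on the *inverse* of the initial segmentation: close
   then open with a 6 mm physical-radius ball (anisotropic in voxels,
   rasterized by voxel-centre inclusion; most non-nodule lung structures
   are thinner than 6 mm), fill a ball of radius $r_\text{init}/2$ at the
   seed, then close again (the final close reuses the 6 mm element, whose
   radius is otherwise unspecified).
4. **Component filter** — intersect with the initial segmentation and keep
   the 6-connected component containing the seed.
5. **Centre refinement** — on the seed's slice, the 2D Euclidean distance
   transform (physical in-slice units, exact Felzenszwalb–Huttenlocher)
   of the filtered mask; among 8-connected local maxima the one closest to
   the seed wins (ties: larger distance, then lexicographic index).
6. **Final radius** — a sphere grows from the refined centre in steps of
   the finest spacing; it stops at the first shell with no positive voxels
   or when the in-sphere positive fraction drops below 0.5, returning the
   last radius before the stop. Shells are half-open
   $[(k{-}1)s, ks)$, so a lone positive voxel at the centre yields $r$ =
   one step via the empty-shell rule.
7. $\sigma_\text{loc} = r / \text{spacing}$ componentwise. (The location
   scale is stated as distance over voxel size; reading its numerator as
   the estimated radius $r$ matches the accompanying "normalized by the
   estimated nodule radius" description, and is adopted.)

Steps 5–6 operate on the *filtered* mask (the seed's component), the
natural reading since unrelated structures should not shift the centre.

Border convention for the morphology: dilation treats out-of-volume
voxels as background; erosion only sees in-array background (faces do not
erode inward). The processing subvolume cuts through lung tissue, so faces
behave as if the tissue continued.

## Learning

Parameters $\theta = (w, v)$ are learned by maximizing the F-score
(equivalently, the Dice coefficient) of *full inference results* on the
training set — the evaluation metric is optimized directly rather than a
pseudo-likelihood surrogate. Counts (tp, fp, fn) are pooled across
training cases before the harmonic mean (a per-case average is available
via `pooled = FALSE`); pooling weights every voxel equally and is the
default. Precision of an empty prediction is defined as 0.

`trainDrf()` is a simulated annealer: Gaussian proposals with
per-iteration sd `stepScale * max(T, 0.05)`, exponential cooling
$T_i = T_0 c^{i-1}$, acceptance of worse moves with probability
$\exp((F' - F)\,a / T)$, bounds handled by rejection, and best-ever
bookkeeping (the returned $\theta$ is never worse than the start on the
training objective). Defaults: $\theta_0 = 0$, $T_0 = 1$, cooling 0.97,
500 iterations, `stepScale` $(2, 2, 2, 2, 0.5)$ (the interaction weight
lives on a smaller scale than the association weights), acceptance scale
$a = 50$, and **reannealing every 125 iterations with a restart from the
incumbent best**.

Two search-space choices deserve justification, because the objective is
exactly 0 on a wide plateau around the origin (a zero linear predictor
labels everything background) while the useful basin sits several units
away in $w$:

* *Sign bounds.* The default bounds are $w_1, w_2, w_3 \le 0$ and
  $v \ge 0$, with the bias $w_0$ unbounded. The three features are
  non-negative costs — a model that rewards a large intensity deviation
  or a large distance from the centre is never sensible — so the
  constraint removes half of each weight axis without excluding any
  defensible model. Empirically, a fully unbounded 500-iteration search
  strands on the zero plateau on a substantial fraction of seeds; the
  sign-constrained one does not.
* *Reannealing with restart.* On the plateau every proposal ties and is
  accepted, so a single cooling schedule can random-walk far from the
  origin and freeze there. Restarting each hot cycle from the best point
  found so far re-centres the walk (at worst, at the origin) and gives
  four effectively independent searches per 500 iterations.

Geometry and features are computed once per case and cached — $\theta$
does not affect them — so each objective evaluation costs one max-flow
solve per training case. A proposal with $v < 0$ scores 0 (flagged)
instead of raising, so the search can move away from it.

For the end-to-end reference runs, the 4-case training set is drawn
*stratified* from the same phantom population as the held-out set (one
juxtapleural, one juxtavascular, two plain at the 25%/25% population
rates; `makeTrainingSet(..., stratify = TRUE)`). A training set with no
wall-abutting example leaves the learned weights free to flood the
chest wall on juxtapleural cases — precisely the oversegmentation
failure known for this model family — and a four-case independent draw
misses the variant entirely a third of the time. Stratification keeps
the tiny training set representative and the runs reproducible.

## The phantom generator

`makePhantom()` builds the scenes the model is meant for: a solid
near-water-density nodule (default 0 HU) in low-density parenchyma
(−850 HU), on an anisotropic grid (default $0.7 \times 0.7 \times 1.25$
mm), blurred by a Gaussian point-spread function (default sd 0.5 voxel)
and corrupted by i.i.d. Gaussian noise (default sd 40 HU). Options add an
attached vessel cylinder (radius 1.5 mm, 50 HU) through the nodule centre
— the juxtavascular case — and a pleural wall slab (50 HU) at the high-x
face with the nodule abutting it — the juxtapleural case. The wall slab
defaults to 8 mm, deliberately thicker than the 6 mm structuring element,
as a real chest wall is; a sub-6 mm slab would be morphologically closed
into the lung and does not correspond to anatomy. Nodule shape can be
perturbed by a bounded low-order spherical-harmonic radial field
("lumpiness", a fraction of the radius); the perturbation is a
deterministic function of the geometry fields alone, so the ground-truth
mask never depends on the noise seed. Ground truth is the rasterization
of the solid *before* blur and noise, by voxel-centre inclusion — the
same convention the analytic sphere-volume checks use. The seed is the
voxel nearest the nodule centre. `makePair()` scales the radius by
$(1+g)^{1/3}$ for a known fractional volume change $g$, keeping the lumpy
shape; `makeTrainingSet()` draws spec fields uniformly from ranges, fully
reproducible from one integer seed.

What the phantoms do *not* emulate: parenchymal texture and vasculature
trees, reconstruction kernels and streak artifacts, ground-glass or
cavitating nodules, respiratory motion, and inter-reader ground-truth
variability. Passing the phantom-based checks therefore demonstrates that
the pipeline is internally correct and recovers known geometry under
realistic contrast, spacing and noise — not that clinical-grade accuracy
transfers to any particular scanner population.

## Numerical choices and conventions

* Arrays are indexed `(x, y, z)` with `z` the slice axis; voxel indices
  are 1-based and physical position is `(index - 1) * spacing + origin`.
  Seed files on disk use the same 1-based convention.
* Threshold comparisons are strict on both sides; a voxel exactly at
  $t_\max$ is outside the window.
* Gaussian smoothing uses a truncated (4 sd), border-renormalized
  separable kernel; constant volumes are exact fixed points.
* The distance transforms are exact Euclidean (no chamfer approximation),
  with physical spacing per axis.
* Masks serialize as 0/1 integer volumes (NIfTI uint8 / MetaImage uchar);
  the internal alphabet is $\{-1, +1\}$.
* First-crossing semantics everywhere a fraction criterion is tested
  ("reached 0.75", "dropped below 0.5"): checked after every step.
* The "radius 3–10 mm at spacing (0.7, 0.7, 1.25)" geometry sweep, the
  4-phantom/500-iteration training run and the 20-phantom held-out
  evaluation used in the test-suite and the verification script are the
  package's declared reference problem sizes.

## Known limitations

* The morphological chain assumes the seed lands inside the initial
  segmentation; heavily calcified or ground-glass nodules whose smoothed
  intensity leaves the fitted window will fail at the first stage (with a
  stage-named error rather than a wrong answer).
* An attached vessel that survives the lung-mask morphology stays in the
  seed's component by construction; the DRF's location feature, not the
  pre-pass, is what keeps the final mask from following it. Very long
  vascular attachments can still leak.
* F-score annealing is stochastic: different seeds give slightly
  different weights (the training objective typically varies by a few
  percent). The returned parameters are deterministic given the seed.
* Only binary labels are supported; there is no multi-label or
  probability-calibrated output beyond the association-probability map.
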