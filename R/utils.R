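# Internal numeric helpers: separable Gaussian smoothing, grid geometry,
# and Euclidean morphology built on the exact distance transform.

# Physical coordinate of each voxel centre along one axis (1-based index).
axisCoords <- function(n, sp, orig = 0) (seq_len(n) - 1) * sp + orig

# 1D Gaussian kernel, truncated at 4 sd, normalized.
gaussKernel <- function(sd) {
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(4 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k / sum(k)
}

# Shift a 3D array by `by` voxels along `axis`, zero-filling.
shiftArray <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- a[sx[[1]], sx[[2]], sx[[3]]]
  out
}

# Convolve along one axis with kernel k (odd length), zero padding.
convAxis <- function(a, axis, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (o in -r:r) out <- out + k[o + r + 1L] * shiftArray(a, axis, o)
  out
}

# Separable Gaussian smoothing with truncated-kernel renormalization at the
# borders (a constant array is a fixed point). `sd` in voxels, per axis.
gaussianSmooth <- function(a, sd, axes = 1:3) {
  sd <- rep_len(sd, 3)
  rng <- range(a)
  if (rng[1] == rng[2]) return(a)  # constants are exact fixed points
  num <- a
  den <- array(1, dim(a))
  for (ax in axes) {
    if (sd[ax] <= 0) next
    k <- gaussKernel(sd[ax])
    num <- convAxis(num, ax, k)
    den <- convAxis(den, ax, k)
  }
  num / den
}

# In-slice (2D, x/y) smoothing applied to every z slice.
gaussianSmoothSlices <- function(a, sd = 1) gaussianSmooth(a, sd, axes = 1:2)

# Unordered 6-neighbourhood edge list (linear indices) for a dims grid,
# in fixed axis order (x-edges, then y, then z).
gridEdges6 <- function(d) {
  idx <- array(seq_len(prod(d)), d)
  rbind(
    cbind(as.vector(idx[-d[1], , , drop = FALSE]),
          as.vector(idx[-1, , , drop = FALSE])),
    cbind(as.vector(idx[, -d[2], , drop = FALSE]),
          as.vector(idx[, -1, , drop = FALSE])),
    cbind(as.vector(idx[, , -d[3], drop = FALSE]),
          as.vector(idx[, , -1, drop = FALSE])))
}

# Squared physical distance (mm^2) of every voxel centre from point `p`.
distSquaredFrom <- function(d, sp, orig, p) {
  dx2 <- (axisCoords(d[1], sp[1], orig[1]) - p[1])^2
  dy2 <- (axisCoords(d[2], sp[2], orig[2]) - p[2])^2
  dz2 <- (axisCoords(d[3], sp[3], orig[3]) - p[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# ---- Euclidean morphology (physical-radius ball structuring elements,
# rasterized by voxel-centre inclusion; voxels outside the array are
# treated as background) ----

edtSq <- function(mask, sp) {
  d <- dim(mask)
  array(.edtSquared(as.vector(mask), as.integer(d), as.numeric(sp)), d)
}

maskDilate <- function(mask, radius, sp) {
  if (radius <= 0 || !any(mask)) return(mask)
  edtSq(mask, sp) <= radius^2 + 1e-9
}

maskErode <- function(mask, radius, sp) {
  if (radius <= 0) return(mask)
  bg <- !mask
  if (!any(bg)) return(mask)
  mask & (edtSq(bg, sp) > radius^2 + 1e-9)
}

maskClose <- function(mask, radius, sp)
  maskErode(maskDilate(mask, radius, sp), radius, sp)

maskOpen <- function(mask, radius, sp)
  maskDilate(maskErode(mask, radius, sp), radius, sp)

# Ball of physical radius r around physical point p, as a logical array.
ballMask <- function(d, sp, orig, p, r)
  distSquaredFrom(d, sp, orig, p) <= r^2 + 1e-9

# Crop window (3x2 lo/hi matrix) of half-width `hw` mm around a voxel index.
cropWindow <- function(d, sp, center, hw) {
  lo <- pmax(1L, as.integer(floor(center - hw / sp)))
  hi <- pmin(d, as.integer(ceiling(center + hw / sp)))
  cbind(lo, hi)
}

cropArray <- function(a, w)
  a[w[1, 1]:w[1, 2], w[2, 1]:w[2, 2], w[3, 1]:w[3, 2], drop = FALSE]

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopfmt <- function(...) stop(sprintf(...), call. = FALSE)
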