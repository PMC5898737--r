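#' Preprocessing configuration for network input
#'
#' @param targetShape network input grid, default (64, 64, 40); each axis
#'   must be divisible by the U-Net's pooling factor.
#' @param addGradient add the gradient magnitude to the image to reinforce
#'   contour definition (default on).
#' @param normalize z-score normalize each volume (default on).
#' @return List of class \code{"preprocessConfig"}.
#' @export
preprocessConfig <- function(targetShape = c(64, 64, 40), addGradient = TRUE,
                             normalize = TRUE) {
  stopifnot(length(targetShape) == 3, all(targetShape >= 2))
  structure(list(targetShape = as.integer(targetShape),
                 addGradient = addGradient, normalize = normalize),
            class = "preprocessConfig")
}

#' 3D affine augmentation parameter ranges
#'
#' One random affine per draw: rotation about a random grid axis,
#' translation as a fraction of each axis length, shear in a random axis
#' pair, and isotropic zoom, composed zoom -> shear -> rotate -> translate
#' about the volume centre.
#'
#' @param rotationDeg rotation range in degrees, default (-30, 30).
#' @param translationFrac translation range as a fraction of each axis
#'   length, default (-0.1, 0.1).
#' @param shearDeg shear angle range in degrees, default (-10, 10).
#' @param zoom isotropic zoom factor range, default (0.85, 1.15).
#' @return List of class \code{"augmentParams"}.
#' @export
augmentParams <- function(rotationDeg = c(-30, 30),
                          translationFrac = c(-0.1, 0.1),
                          shearDeg = c(-10, 10), zoom = c(0.85, 1.15)) {
  rng2 <- function(x) if (length(x) == 1) c(x, x) else as.numeric(x)
  p <- list(rotationDeg = rng2(rotationDeg),
            translationFrac = rng2(translationFrac),
            shearDeg = rng2(shearDeg), zoom = rng2(zoom))
  stopifnot(all(vapply(p, function(r) diff(r) >= 0, logical(1))),
            p$zoom[1] > 0)
  class(p) <- "augmentParams"
  p
}

#' Spatial gradient magnitude of a volume
#'
#' Per-voxel Euclidean norm of the 3D gradient, estimated with central
#' differences in the interior and one-sided differences at the
#' boundaries, in intensity units per voxel.
#'
#' @param v a \code{\linkS4class{BrainVolume}}.
#' @return A \code{BrainVolume} of gradient magnitudes.
#' @export
gradientMagnitude <- function(v) {
  stopifnot(is(v, "BrainVolume"))
  arr <- v@data
  g2 <- array(0, dim(arr))
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    lo <- pmax(seq_len(n) - 1L, 1L)
    hi <- pmin(seq_len(n) + 1L, n)
    denom <- hi - lo  # 2 interior, 1 at the two boundary slices
    take <- function(i) switch(ax, arr[i, , , drop = FALSE],
                               arr[, i, , drop = FALSE],
                               arr[, , i, drop = FALSE])
    diffs <- take(hi) - take(lo)
    dims <- dim(arr)
    dd <- switch(ax,
                 array(denom, dims),
                 array(rep(denom, each = dims[1]), dims),
                 array(rep(denom, each = dims[1] * dims[2]), dims))
    g2 <- g2 + (diffs / dd)^2
  }
  initialize(v, data = sqrt(g2), metadata = list())
}

#' Contour enhancement
#'
#' Adds the gradient magnitude to the volume voxelwise, reinforcing
#' contour definition against partial-volume blur.
#'
#' @param v a \code{BrainVolume}.
#' @return \code{v + gradientMagnitude(v)}.
#' @export
enhanceContours <- function(v) {
  g <- gradientMagnitude(v)
  initialize(v, data = v@data + g@data)
}

#' Z-score normalization
#'
#' Centers to mean 0 and scales to unit standard deviation over all
#' voxels.
#'
#' @param v a non-constant \code{BrainVolume}.
#' @return The normalized \code{BrainVolume}.
#' @export
zNormalize <- function(v) {
  stopifnot(is(v, "BrainVolume"))
  s <- sd(v@data)
  if (!is.finite(s) || s == 0) stop("cannot z-normalize a constant volume")
  initialize(v, data = (v@data - mean(v@data)) / s)
}

# Sample one affine from the parameter ranges and return the 3x4 matrix
# mapping output 0-based voxel indices to input voxel coordinates
# (the inverse transform, as needed for resampling).
sampleAffine <- function(d, params, seed) {
  withSeed(seed, function() {
    theta <- runif(1, params$rotationDeg[1], params$rotationDeg[2]) * pi / 180
    rotAxis <- sample(1:3, 1)
    trans <- runif(3, params$translationFrac[1], params$translationFrac[2]) * d
    shear <- tan(runif(1, params$shearDeg[1], params$shearDeg[2]) * pi / 180)
    shearPair <- sample(1:3, 2)  # row receives shear from column axis
    zoom <- runif(1, params$zoom[1], params$zoom[2])
    R <- diag(3)
    ij <- setdiff(1:3, rotAxis)
    R[ij[1], ij[1]] <- cos(theta); R[ij[1], ij[2]] <- -sin(theta)
    R[ij[2], ij[1]] <- sin(theta); R[ij[2], ij[2]] <- cos(theta)
    S <- diag(3)
    S[shearPair[1], shearPair[2]] <- shear
    Z <- diag(3) * zoom
    M <- R %*% S %*% Z          # forward: zoom, then shear, then rotate
    Minv <- solve(M)
    ctr <- (d - 1) / 2          # 0-based centre
    # forward maps p -> M (p - ctr) + ctr + trans; invert for resampling
    off <- ctr - Minv %*% (ctr + trans)
    cbind(Minv, off)
  })
}

#' Apply one random 3D affine to a volume/mask pair
#'
#' The same transform (sampled deterministically from \code{seed}) is
#' applied to both inputs: the volume with trilinear interpolation
#' (out-of-field filled with the volume minimum), the mask with
#' nearest-neighbour resampling and re-binarization (filled with 0).
#'
#' @param v a \code{BrainVolume}.
#' @param m a \code{BrainMask} on the same grid.
#' @param params an \code{\link{augmentParams}}.
#' @param seed integer seed for the parameter draw.
#' @return \code{list(volume, mask)}.
#' @export
augmentPair <- function(v, m, params = augmentParams(), seed = 1L) {
  stopifnot(is(v, "BrainVolume"), is(m, "BrainMask"))
  if (!identical(dim(v@data), dim(m@data)))
    stop("volume and mask must share a shape")
  d <- dim(v@data)
  A <- sampleAffine(d, params, seed)
  av <- cpp_affine_resample3d(as.numeric(v@data), d, A, FALSE, min(v@data))
  am <- cpp_affine_resample3d(as.numeric(m@data), d, A, TRUE, 0)
  list(volume = initialize(v, data = array(av, d)),
       mask = brainMask(array((am >= 0.5) * 1, d), spacing = m@spacing,
                        lrAxis = m@lrAxis))
}

#' Random train/validation split
#'
#' Uniform partition without replacement; the training side has
#' \code{round(fraction * n)} ids. Deterministic per seed.
#'
#' @param ids vector of subject identifiers (n >= 2).
#' @param fraction training fraction in (0, 1), default 0.70.
#' @param seed integer seed.
#' @return \code{list(trainIds, valIds, fraction, seed)}.
#' @examples
#' splitDataset(1:37, 0.7, seed = 1)  # 26 train / 11 validation
#' @export
splitDataset <- function(ids, fraction = 0.70, seed = 1L) {
  n <- length(ids)
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  nTrain <- round(fraction * n)
  if (nTrain == 0 || nTrain == n)
    stop("degenerate split: one side would be empty")
  tr <- withSeed(seed, function() sort(sample.int(n, nTrain)))
  list(trainIds = ids[tr], valIds = ids[-tr], fraction = fraction,
       seed = as.integer(seed))
}

#' Preprocess a volume to network input space
#'
#' Resize (trilinear) to the target shape, optionally enhance contours and
#' z-normalize — in that order, matching the training pipeline.
#'
#' @param v a \code{BrainVolume}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return The preprocessed \code{BrainVolume}.
#' @export
preprocessVolume <- function(v, cfg = preprocessConfig()) {
  out <- resizeLinear(v, cfg$targetShape)
  if (cfg$addGradient) out <- enhanceContours(out)
  if (cfg$normalize) out <- zNormalize(out)
  out
}
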