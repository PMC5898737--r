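#' Configuration of the semi-automatic reference segmentation
#'
#' The reference (ground-truth) biological tumor volume is obtained by
#' thresholding a generous region around the tumor at
#' \code{thresholdFactor} times the background, where the background is the
#' mean activity of a spherical VOI of \code{backgroundVoiVolumeCm3} cm^3
#' in the contralateral hemisphere.
#'
#' @param thresholdFactor dimensionless threshold multiplier, default 1.3.
#' @param backgroundVoiVolumeCm3 volume of the background sphere, default
#'   10 cm^3 (radius about 13.37 mm).
#' @param manualMarginMm dilation margin (mm) of the emulated manual
#'   envelope, default 10.
#' @return A validated list of class \code{"groundTruthConfig"}.
#' @export
groundTruthConfig <- function(thresholdFactor = 1.3,
                              backgroundVoiVolumeCm3 = 10,
                              manualMarginMm = 10) {
  stopifnot(thresholdFactor > 0, backgroundVoiVolumeCm3 > 0,
            manualMarginMm >= 0)
  structure(list(thresholdFactor = thresholdFactor,
                 backgroundVoiVolumeCm3 = backgroundVoiVolumeCm3,
                 manualMarginMm = manualMarginMm),
            class = "groundTruthConfig")
}

#' Emulate the manually drawn envelope around a lesion
#'
#' Dilates the lesion support by a Euclidean ball of radius \code{marginMm}
#' (converted to voxels through the spacing), clipped to the grid: a
#' generous region guaranteed to contain the lesion, standing in for a
#' human-drawn mask.
#'
#' @param truthLesion non-empty \code{\linkS4class{BrainMask}}.
#' @param marginMm dilation margin in mm.
#' @return A \code{BrainMask} superset of the input.
#' @export
makeManualRegion <- function(truthLesion, marginMm = 10) {
  stopifnot(is(truthLesion, "BrainMask"))
  if (sum(truthLesion@data) == 0) stop("lesion mask is empty")
  d <- dim(truthLesion@data)
  out <- cpp_ball_dilate(as.integer(truthLesion@data), d,
                         truthLesion@spacing, marginMm)
  brainMask(array(as.numeric(out), d), spacing = truthLesion@spacing,
            lrAxis = truthLesion@lrAxis)
}

# Positivity floor separating head from air: a fraction of the median of
# clearly positive voxels. Exact for constant volumes (support = all).
positivityFloor <- function(arr) {
  mx <- max(arr)
  if (mx <= 0) return(Inf)
  pos <- arr[arr > 0.05 * mx]
  0.25 * stats::median(pos)
}

#' Place the contralateral background VOI and measure its mean
#'
#' A sphere of the requested volume (radius \eqn{r = (3V/4\pi)^{1/3}}) is
#' centred at the centroid of the brain support restricted to the
#' hemisphere opposite the lesion, clipped to the brain support; the mean
#' activity inside it is the background estimate used for thresholding.
#'
#' @param volume the reference \code{\linkS4class{BrainVolume}} (typically
#'   the 20-40 min summation image).
#' @param lesionSide "left" or "right"; the sphere goes contralaterally.
#' @param voiVolumeCm3 sphere volume in cm^3, default 10.
#' @return \code{list(mask, backgroundMean)} where \code{mask} is a
#'   \code{BrainMask}.
#' @export
backgroundSphere <- function(volume, lesionSide, voiVolumeCm3 = 10) {
  stopifnot(is(volume, "BrainVolume"), lesionSide %in% c("left", "right"))
  arr <- volume@data
  d <- dim(arr)
  sx <- volume@spacing
  floorv <- positivityFloor(arr)
  supp <- arr >= floorv
  mid <- (d[volume@lrAxis] + 1) / 2
  co <- gridCoords(d)
  xc <- list(co$x, co$y, co$z)[[volume@lrAxis]]
  contra <- if (lesionSide == "left") xc > mid else xc < mid
  sel <- supp & contra
  if (!any(sel)) stop("no brain support in the contralateral hemisphere")
  cen <- c(mean(co$x[sel]), mean(co$y[sel]), mean(co$z[sel]))
  rMm <- (3 * voiVolumeCm3 * 1000 / (4 * pi))^(1 / 3)
  dist2 <- ((co$x - cen[1]) * sx[1])^2 + ((co$y - cen[2]) * sx[2])^2 +
    ((co$z - cen[3]) * sx[3])^2
  sphere <- dist2 <= rMm^2
  if (sum(sphere & supp) < 0.5 * sum(sphere))
    stop("background sphere would fall mostly outside the brain support")
  mask <- sphere & supp
  list(mask = brainMask(mask * 1, spacing = sx, lrAxis = volume@lrAxis),
       backgroundMean = mean(arr[mask]))
}

#' Threshold the manual region at a multiple of background
#'
#' The reference segmentation keeps the voxels of the manual region whose
#' activity is at least \code{factor} times the background mean (inclusive
#' comparison). An empty result is flagged on the output metadata
#' (\code{belowThreshold}) rather than raised as an error.
#'
#' @param volume reference \code{BrainVolume}.
#' @param manualRegion \code{BrainMask} envelope around the tumor.
#' @param backgroundMean positive background estimate (a.u.).
#' @param factor threshold multiplier, default 1.3.
#' @return The reference \code{BrainMask} T.
#' @export
semiAutoSegment <- function(volume, manualRegion, backgroundMean,
                            factor = 1.3) {
  stopifnot(is(volume, "BrainVolume"), is(manualRegion, "BrainMask"),
            backgroundMean > 0)
  if (!identical(dim(volume@data), dim(manualRegion@data)))
    stop("volume and manual region must share a grid")
  keep <- (manualRegion@data > 0) & (volume@data >= factor * backgroundMean)
  meta <- list(belowThreshold = !any(keep))
  brainMask(keep * 1, spacing = volume@spacing, lrAxis = volume@lrAxis,
            metadata = meta)
}

#' Full semi-automatic reference segmentation of a phantom subject
#'
#' Convenience wrapper chaining \code{\link{makeManualRegion}},
#' \code{\link{backgroundSphere}} and \code{\link{semiAutoSegment}} on the
#' subject's 20-40 min summation image.
#'
#' @param subject a \code{\linkS4class{PhantomSubject}}.
#' @param cfg a \code{\link{groundTruthConfig}}.
#' @return \code{list(mask, backgroundMean, manualRegion)}.
#' @export
groundTruthSegment <- function(subject, cfg = groundTruthConfig()) {
  stopifnot(is(subject, "PhantomSubject"))
  manual <- makeManualRegion(subject@truthLesion, cfg$manualMarginMm)
  bg <- backgroundSphere(subject@summation, subject@lesionSide,
                         cfg$backgroundVoiVolumeCm3)
  mask <- semiAutoSegment(subject@summation, manual, bg$backgroundMean,
                          cfg$thresholdFactor)
  list(mask = mask, backgroundMean = bg$backgroundMean, manualRegion = manual)
}
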