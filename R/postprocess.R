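#' Post-processing configuration
#'
#' The second stage of the two-step procedure: the predicted U-Net mask is
#' morphologically dilated (3x3x3 cube, 26-connectivity neighbourhood) and
#' then intersected with an adaptive intensity threshold of
#' \code{thresholdFactor} times the mean activity under the hemispheric
#' swap of the predicted mask — a subject-specific background estimate
#' mirroring the ground-truth procedure. The threshold is applied to the
#' raw (non-normalized) summation intensity on the prediction grid.
#'
#' @param thresholdFactor dimensionless multiplier, default 1.3.
#' @return List of class \code{"postprocessConfig"}.
#' @export
postprocessConfig <- function(thresholdFactor = 1.3) {
  stopifnot(thresholdFactor > 0)
  structure(list(thresholdFactor = thresholdFactor),
            class = "postprocessConfig")
}

#' Morphological dilation with the full 3x3x3 cube
#'
#' One iteration of binary dilation with the 26-connectivity cube
#' structuring element.
#'
#' @param m a \code{\linkS4class{BrainMask}}.
#' @return The dilated \code{BrainMask} (always a superset).
#' @export
dilateMask <- function(m) {
  stopifnot(is(m, "BrainMask"))
  d <- dim(m@data)
  out <- cpp_cube_dilate(as.integer(m@data), d)
  brainMask(array(as.numeric(out), d), spacing = m@spacing, lrAxis = m@lrAxis)
}

#' Background estimate from the hemispheric swap of the predicted mask
#'
#' Mean of the intensity over the predicted mask reflected across the
#' mid-sagittal plane, i.e. over homologous contralateral (healthy)
#' tissue.
#'
#' @param P non-empty predicted \code{BrainMask}.
#' @param intensity \code{BrainVolume} on the same grid (raw activity).
#' @return Scalar background estimate (a.u.).
#' @export
swapBackgroundMean <- function(P, intensity) {
  stopifnot(is(P, "BrainMask"), is(intensity, "BrainVolume"))
  if (!identical(dim(P@data), dim(intensity@data)))
    stop("mask and intensity must share a grid")
  if (sum(P@data) == 0) stop("predicted mask is empty")
  mir <- mirrorSagittal(P)
  if (sum(mir@data) == 0) stop("mirrored mask is empty")
  mean(intensity@data[mir@data > 0])
}

#' Refine a predicted mask by dilation and adaptive thresholding
#'
#' Returns \code{dilate(P)} intersected with the voxels whose intensity is
#' at least \code{thresholdFactor} times the hemispheric-swap background
#' mean of the un-dilated prediction.
#'
#' @param P predicted \code{BrainMask}.
#' @param intensity raw-activity \code{BrainVolume} on the same grid.
#' @param cfg a \code{\link{postprocessConfig}}.
#' @return The refined \code{BrainMask}.
#' @export
refineMask <- function(P, intensity, cfg = postprocessConfig()) {
  bg <- swapBackgroundMean(P, intensity)
  dil <- dilateMask(P)
  keep <- (dil@data > 0) & (intensity@data >= cfg$thresholdFactor * bg)
  brainMask(keep * 1, spacing = P@spacing, lrAxis = P@lrAxis)
}
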