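#' BrainVolume: a 3D scalar PET volume
#'
#' The unit of all image processing in the package: a 3D array of activity
#' values (SUV-like arbitrary units) with voxel spacing in mm and an
#' identified left-right (sagittal) grid axis. Volumes live on an MNI-like
#' grid with 2 mm isotropic voxels by default.
#'
#' @slot data 3D numeric array of voxel values; all values must be finite.
#' @slot spacing numeric(3), mm per voxel along each grid axis; strictly
#'   positive.
#' @slot lrAxis integer(1), which grid axis runs left-right. Fixed to the
#'   first axis for all volumes produced by this package; mirroring is
#'   about the grid midline of this axis.
#' @slot metadata named list of auxiliary flags (e.g. \code{belowThreshold}
#'   set by \code{\link{semiAutoSegment}}).
#' @seealso \code{\link{brainVolume}}, \code{\link{brainMask}}
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", lrAxis = "integer",
                 metadata = "list"),
  prototype(spacing = c(2, 2, 2), lrAxis = 1L, metadata = list()))

setValidity("BrainVolume", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array")
  if (!all(is.finite(object@data)))
    msgs <- c(msgs, "all voxel values must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values")
  if (length(object@lrAxis) != 1L || !(object@lrAxis %in% 1:3))
    msgs <- c(msgs, "lrAxis must be 1, 2 or 3")
  if (length(msgs)) msgs else TRUE
})

#' BrainMask: a binary voxel set on a volume grid
#'
#' A \code{\linkS4class{BrainVolume}} whose voxel values are restricted to
#' \{0, 1\}. Used for the ground-truth reference segmentation T and the
#' network prediction P.
#'
#' @seealso \code{\link{brainMask}}
#' @export
setClass("BrainMask", contains = "BrainVolume")

setValidity("BrainMask", function(object) {
  if (!all(object@data %in% c(0, 1)))
    "mask values must all be 0 or 1" else TRUE
})

#' DynamicSeries: an ordered set of dynamic PET frames
#'
#' Frames of a dynamic acquisition on a common grid; the default protocol
#' is 10 frames of 5 minutes (50 minutes total).
#'
#' @slot frames list of \code{BrainVolume}, all sharing shape and spacing.
#' @slot frameDurationMin minutes per frame.
#' @seealso \code{\link{dynamicSeries}}, \code{\link{sumFrames}}
#' @export
setClass("DynamicSeries",
  representation(frames = "list", frameDurationMin = "numeric"),
  prototype(frameDurationMin = 5))

setValidity("DynamicSeries", function(object) {
  if (length(object@frames) < 1L) return("at least one frame required")
  if (!all(vapply(object@frames, is, logical(1), "BrainVolume")))
    return("frames must all be BrainVolume objects")
  d0 <- dim(object@frames[[1]]@data)
  s0 <- object@frames[[1]]@spacing
  for (f in object@frames) {
    if (!identical(dim(f@data), d0)) return("frames must share a common shape")
    if (!isTRUE(all.equal(f@spacing, s0))) return("frames must share spacing")
  }
  if (length(object@frameDurationMin) != 1L || object@frameDurationMin <= 0)
    return("frameDurationMin must be a single positive number")
  TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D numeric array of finite voxel values.
#' @param spacing mm per voxel, length 3. Default 2 mm isotropic.
#' @param lrAxis grid axis running left-right (default first axis).
#' @param metadata optional named list of flags.
#' @return A \code{\linkS4class{BrainVolume}}.
#' @examples
#' v <- brainVolume(array(1, c(4, 4, 4)))
#' spacing(v)
#' @export
brainVolume <- function(data, spacing = c(2, 2, 2), lrAxis = 1L,
                        metadata = list()) {
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      lrAxis = as.integer(lrAxis), metadata = metadata)
}

#' Construct a BrainMask
#'
#' @param data 3D array of 0/1 (logical arrays are coerced).
#' @inheritParams brainVolume
#' @return A \code{\linkS4class{BrainMask}}.
#' @export
brainMask <- function(data, spacing = c(2, 2, 2), lrAxis = 1L,
                      metadata = list()) {
  storage.mode(data) <- "double"
  new("BrainMask", data = data, spacing = as.numeric(spacing),
      lrAxis = as.integer(lrAxis), metadata = metadata)
}

#' Construct a DynamicSeries
#'
#' @param frames list of \code{BrainVolume} on a common grid.
#' @param frameDurationMin minutes per frame (default 5).
#' @return A \code{\linkS4class{DynamicSeries}}.
#' @export
dynamicSeries <- function(frames, frameDurationMin = 5) {
  new("DynamicSeries", frames = frames,
      frameDurationMin = as.numeric(frameDurationMin))
}

#' PhantomSubject: one simulated dynamic FET-PET subject
#'
#' @slot series the simulated \code{DynamicSeries}.
#' @slot summation the 20-40 min summation \code{BrainVolume}.
#' @slot truthLesion the simulated lesion support (pre-blur) as a
#'   \code{BrainMask}.
#' @slot lesionSide "left" or "right" (lower or upper half of the
#'   left-right axis).
#' @slot spec the generating \code{phantomSpec} list.
#' @slot seed integer seed the subject was generated from.
#' @slot params realized random draws (lesion contrast, radii, centres,
#'   TAC slope, ...) for inspection in tests.
#' @export
setClass("PhantomSubject",
  representation(series = "DynamicSeries", summation = "BrainVolume",
                 truthLesion = "BrainMask", lesionSide = "character",
                 spec = "list", seed = "integer", params = "list"))

#' UNet3D: a 3-level volumetric U-Net
#'
#' Holds the architecture description and the weights of every
#' convolution. Weights of a k x k x k convolution with \code{cin} input and
#' \code{cout} output channels are stored as a (k^3 * cin) x cout matrix
#' plus a length-\code{cout} bias vector, matching the im2col layout used by
#' the C++ kernels.
#'
#' @slot config list from \code{\link{unetConfig}}.
#' @slot weights named list of \code{list(W, b, k)} per convolution, in
#'   network order.
#' @seealso \code{\link{buildUnet}}, \code{\link{trainUnet}},
#'   \code{\link{predictMask}}
#' @export
setClass("UNet3D", representation(config = "list", weights = "list"))
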