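#' Read a NIfTI volume or dynamic series
#'
#' Reads a 3D volume as a \code{\linkS4class{BrainVolume}} or a 4D file as
#' a \code{\linkS4class{DynamicSeries}}; voxel spacing is taken from the
#' header. The left-right axis is taken to be the first grid axis, the
#' package-wide convention for MNI-like grids.
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param frameDurationMin minutes per frame for 4D input; if the header
#'   carries a time step it takes precedence.
#' @return A \code{BrainVolume} (3D) or \code{DynamicSeries} (4D).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(brainVolume(array(1, c(4, 4, 4))), f)
#' readVolume(f)
#' @export
readVolume <- function(path, frameDurationMin = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  nd <- length(dim(arr))
  if (nd == 3L) {
    brainVolume(arr, spacing = pd[1:3])
  } else if (nd == 4L) {
    if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0)
      frameDurationMin <- pd[4]
    frames <- lapply(seq_len(dim(arr)[4]), function(i)
      brainVolume(arr[, , , i, drop = TRUE], spacing = pd[1:3]))
    dynamicSeries(frames, frameDurationMin = frameDurationMin)
  } else {
    stop("expected a 3D or 4D volume, got ", nd, " dimensions")
  }
}

#' Write a volume, mask or dynamic series to NIfTI
#'
#' Volumes are written as float32 (or float64 when needed), masks as
#' unsigned 8-bit. Data and spacing round-trip through
#' \code{\link{readVolume}}.
#'
#' @param v a \code{BrainVolume}, \code{BrainMask} or \code{DynamicSeries}.
#' @param path destination file path (.nii or .nii.gz); the parent
#'   directory must exist.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (is(v, "DynamicSeries")) {
    d <- dim(v@frames[[1]]@data)
    arr <- array(0, c(d, length(v@frames)))
    for (i in seq_along(v@frames)) arr[, , , i] <- v@frames[[i]]@data
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(spacing(v), v@frameDurationMin)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (is(v, "BrainMask")) {
    img <- RNifti::asNifti(v@data)
    RNifti::pixdim(img) <- v@spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (is(v, "BrainVolume")) {
    img <- RNifti::asNifti(v@data)
    RNifti::pixdim(img) <- v@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop("unsupported object of class ", class(v))
  invisible(path)
}

#' Resample a volume to a target grid shape
#'
#' Cell-centered (align-corners-false) resampling that preserves the
#' physical extent: spacing is rescaled by the shape ratio. Plain volumes
#' are interpolated trilinearly; masks are resampled nearest-neighbour and
#' re-binarized, so mask output is always strictly binary.
#'
#' @param v a \code{BrainVolume} or \code{BrainMask}.
#' @param targetShape integer(3), all entries >= 2.
#' @return Object of the same class on the target grid.
#' @examples
#' v <- brainVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)))
#' dim(resizeLinear(v, c(4, 4, 4)))
#' @export
resizeLinear <- function(v, targetShape) {
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape < 2L))
    stop("targetShape must be 3 integers, all >= 2")
  d <- dim(v@data)
  newSpacing <- v@spacing * d / targetShape
  nearest <- is(v, "BrainMask")
  out <- cpp_resize3d(as.numeric(v@data), d, targetShape, nearest)
  arr <- array(out, targetShape)
  if (nearest) {
    arr <- (arr >= 0.5) * 1
    brainMask(arr, spacing = newSpacing, lrAxis = v@lrAxis)
  } else {
    brainVolume(arr, spacing = newSpacing, lrAxis = v@lrAxis)
  }
}

#' Sum dynamic frames over a time window
#'
#' Voxelwise sum of the frames fully inside the half-open window
#' \code{[startMin, endMin)} minutes post-injection. The default 20-40 min
#' window sums frames 5-8 of a 10 x 5-min acquisition, the standard
#' reference image for FET-PET delineation.
#'
#' @param s a \code{\linkS4class{DynamicSeries}}.
#' @param startMin,endMin window bounds in minutes; must align with frame
#'   boundaries.
#' @return The summation \code{BrainVolume}.
#' @export
sumFrames <- function(s, startMin = 20, endMin = 40) {
  stopifnot(is(s, "DynamicSeries"))
  d <- s@frameDurationMin
  total <- length(s@frames) * d
  if (startMin < 0 || endMin > total || startMin >= endMin)
    stop("window must satisfy 0 <= start < end <= ", total, " minutes")
  if (startMin %% d != 0 || endMin %% d != 0)
    stop("window (", startMin, ", ", endMin, ") is not aligned to ",
         d, "-minute frame boundaries")
  idx <- seq.int(startMin / d + 1L, endMin / d)
  acc <- s@frames[[idx[1]]]@data
  for (i in idx[-1]) acc <- acc + s@frames[[i]]@data
  brainVolume(acc, spacing = spacing(s), lrAxis = s@frames[[1]]@lrAxis)
}

#' Mirror a volume or mask across the mid-sagittal plane
#'
#' Reflects the grid about the midline of the left-right axis (index i maps
#' to n - 1 - i, 0-based), the "hemispheric swap" used to sample homologous
#' contralateral tissue as background.
#'
#' @param v a \code{BrainVolume} or \code{BrainMask}.
#' @return Object of the same class, reflected.
#' @export
mirrorSagittal <- function(v) {
  stopifnot(is(v, "BrainVolume"))
  ax <- v@lrAxis
  if (is.na(ax) || !(ax %in% 1:3)) stop("left-right axis is not defined")
  idx <- rev(seq_len(dim(v@data)[ax]))
  arr <- switch(ax,
                v@data[idx, , , drop = FALSE],
                v@data[, idx, , drop = FALSE],
                v@data[, , idx, drop = FALSE])
  initialize(v, data = arr)
}
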