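#' Accessors for volume objects
#'
#' \code{voxelData} returns the raw 3D array, \code{spacing} the voxel size
#' in mm, \code{lrAxis} the left-right grid axis, and \code{nFrames} the
#' number of dynamic frames.
#'
#' @param x a \code{\linkS4class{BrainVolume}} or
#'   \code{\linkS4class{DynamicSeries}}.
#' @return See individual descriptions.
#' @name volume-accessors
#' @aliases voxelData spacing lrAxis nFrames
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname volume-accessors
#' @export
setGeneric("lrAxis", function(x) standardGeneric("lrAxis"))

#' @rdname volume-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@data)

#' @rdname volume-accessors
#' @export
setMethod("spacing", "BrainVolume", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("lrAxis", "BrainVolume", function(x) x@lrAxis)

#' @rdname volume-accessors
#' @export
setMethod("spacing", "DynamicSeries", function(x) x@frames[[1]]@spacing)

#' @rdname volume-accessors
#' @export
setMethod("nFrames", "DynamicSeries", function(x) length(x@frames))

#' @describeIn volume-accessors grid shape of a volume.
#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, LR axis %d\n", class(object),
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              object@lrAxis))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(object@data),
              max(object@data)))
  if (is(object, "BrainMask"))
    cat(sprintf("  %d foreground voxels\n", sum(object@data)))
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@frames[[1]]@data)
  cat(sprintf("DynamicSeries: %d frames of %g min, grid %dx%dx%d\n",
              length(object@frames), object@frameDurationMin,
              d[1], d[2], d[3]))
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject (seed %d): lesion on %s side, %d lesion voxels\n",
              object@seed, object@lesionSide, sum(object@truthLesion@data)))
})

setMethod("show", "UNet3D", function(object) {
  cfg <- object@config
  cat(sprintf("UNet3D: %d levels, base %d channels, %d -> %d channels\n",
              cfg$nLevels, cfg$baseChannels, cfg$inChannels, cfg$outChannels))
  cat(sprintf("  %d convolution layers, %d trainable parameters\n",
              countConvLayers(cfg), countParameters(cfg)))
})
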