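#' @importFrom grDevices hsv col2rgb
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Multi-channel microscope image
#'
#' An RGB frame on the 0-255 scale together with the folder entry it was read
#' from. \code{pixels} is an H x W x 3 numeric array (row = image row,
#' top-left origin); \code{entry} carries \code{numeric_id}, \code{path} and
#' \code{format} as produced by [scanAnalysisFolder()].
#'
#' @slot pixels H x W x 3 numeric array, values in 0..255.
#' @slot entry list with elements \code{numeric_id}, \code{path},
#'   \code{format}.
#' @export
setClass("MultiChannelImage",
  representation(pixels = "array", entry = "list"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[3] != 3)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 1 || d[2] < 1) return("image must be at least 1 x 1")
    if (min(object@pixels) < 0 || max(object@pixels) > 255)
      return("pixel values must lie in 0..255")
    TRUE
  })

#' Channel role assignment
#'
#' Maps the r/g/b planes of an RGB image to the roles the pipeline needs:
#' one or two axon-detection channels and, for automatic-ROI analysis, a
#' ROI-detection channel. Roles must name pairwise distinct channels.
#'
#' @slot axon1 "r", "g" or "b".
#' @slot axon2 second axon channel or \code{NA_character_}.
#' @slot roi ROI-detection channel or \code{NA_character_}.
#' @export
setClass("ChannelAssignment",
  representation(axon1 = "character", axon2 = "character", roi = "character"),
  prototype(axon1 = "g", axon2 = NA_character_, roi = NA_character_),
  validity = function(object) {
    chans <- c(object@axon1, object@axon2, object@roi)
    ok <- chans[!is.na(chans)]
    if (is.na(object@axon1)) return("axon1 channel is required")
    if (!all(ok %in% c("r", "g", "b")))
      return("channels must be one of 'r', 'g', 'b'")
    if (anyDuplicated(ok)) return("channel roles must be pairwise distinct")
    TRUE
  })

#' @rdname ChannelAssignment-class
#' @param axon1,axon2,roi channel letters ("r", "g", "b") or \code{NA}.
#' @return a \code{ChannelAssignment} object.
#' @examples
#' channelAssignment(axon1 = "g", roi = "r")
#' @export
channelAssignment <- function(axon1 = "g", axon2 = NA_character_,
                              roi = NA_character_) {
  new("ChannelAssignment", axon1 = axon1, axon2 = as.character(axon2),
      roi = as.character(roi))
}

#' ROI segmentation parameters
#'
#' Controls the morphological sequence that turns raw ROI-channel signal into
#' one continuous region: particle removal, hole filling, enlargement by
#' \code{enlargePx} (bridging gaps up to twice that width) and reduction by
#' \code{reducePx} (removing fragments of half-width below the difference),
#' followed by a user adjustment of \code{adjustPx} pixels in -255..255.
#'
#' @slot enlargePx dilation distance, default 60.
#' @slot reducePx erosion distance, default 90.
#' @slot minParticlePx components smaller than this are removed before hole
#'   filling, default 100.
#' @slot adjustPx final dilation (>0) or erosion (<0) distance, default 0.
#' @export
setClass("RoiParams",
  representation(enlargePx = "numeric", reducePx = "numeric",
                 minParticlePx = "numeric", adjustPx = "numeric"),
  prototype(enlargePx = 60, reducePx = 90, minParticlePx = 100, adjustPx = 0),
  validity = function(object) {
    if (object@enlargePx < 0) return("enlargePx must be >= 0")
    if (object@reducePx < 0) return("reducePx must be >= 0")
    if (object@minParticlePx < 0) return("minParticlePx must be >= 0")
    if (object@adjustPx < -255 || object@adjustPx > 255)
      return("adjustPx must lie in -255..255")
    TRUE
  })

#' @rdname RoiParams-class
#' @param enlargePx,reducePx,minParticlePx,adjustPx see slots.
#' @return a \code{RoiParams} object.
#' @export
roiParams <- function(enlargePx = 60, reducePx = 90, minParticlePx = 100,
                      adjustPx = 0) {
  new("RoiParams", enlargePx = enlargePx, reducePx = reducePx,
      minParticlePx = minParticlePx, adjustPx = adjustPx)
}

#' Axon detection parameters
#'
#' The user-tunable detection triple applied identically to every image of a
#' batch, plus the tissue-hole handling constants.
#'
#' \code{sensitivity} thresholds the ridge response after min-max
#' normalization to [0,1]: a pixel is detected when its response is at least
#' \code{1 - sensitivity} (and positive), so larger values detect fainter
#' axons. \code{cleanupPx} removes skeleton components whose pixel count is
#' not strictly above it. \code{derivativeScale} is the standard deviation
#' (pixels) of the Gaussian kernels used for the second-order derivative
#' ridge filters. Tissue holes are near-zero regions (intensity at most
#' \code{holeIntensityMax}, area at least \code{holeMinAreaPx}) that are
#' filled with the mean tissue intensity before ridge filtering so their
#' sharp edges do not masquerade as axons; \code{holeFill = FALSE} disables
#' that step.
#'
#' @slot sensitivity detection leniency in [0, 1], default 0.5.
#' @slot cleanupPx minimum surviving skeleton-component size, default 20.
#' @slot derivativeScale Gaussian scale in pixels, default 1.
#' @slot holeIntensityMax hole candidate intensity ceiling, default 5.
#' @slot holeMinAreaPx minimum hole area in pixels, default 500.
#' @slot holeFill logical, default \code{TRUE}.
#' @slot minRidgeContrast faintest ridge (intensity levels of a 1-px line)
#'   accepted as signal; planes whose strongest raw ridge response falls
#'   below it are reported as zero length. Default 32; 0 disables the
#'   guard.
#' @export
setClass("DetectionParams",
  representation(sensitivity = "numeric", cleanupPx = "numeric",
                 derivativeScale = "numeric", holeIntensityMax = "numeric",
                 holeMinAreaPx = "numeric", holeFill = "logical",
                 minRidgeContrast = "numeric"),
  prototype(sensitivity = 0.5, cleanupPx = 20, derivativeScale = 1,
            holeIntensityMax = 5, holeMinAreaPx = 500, holeFill = TRUE,
            minRidgeContrast = 32),
  validity = function(object) {
    if (object@sensitivity < 0 || object@sensitivity > 1)
      return("sensitivity must lie in [0, 1]")
    if (object@cleanupPx < 0) return("cleanupPx must be >= 0")
    if (object@derivativeScale <= 0) return("derivativeScale must be > 0")
    if (object@holeMinAreaPx < 0) return("holeMinAreaPx must be >= 0")
    if (object@minRidgeContrast < 0)
      return("minRidgeContrast must be >= 0")
    TRUE
  })

#' @rdname DetectionParams-class
#' @param sensitivity,cleanupPx,derivativeScale,holeIntensityMax,holeMinAreaPx,holeFill,minRidgeContrast
#'   see slots.
#' @return a \code{DetectionParams} object.
#' @export
detectionParams <- function(sensitivity = 0.5, cleanupPx = 20,
                            derivativeScale = 1, holeIntensityMax = 5,
                            holeMinAreaPx = 500, holeFill = TRUE,
                            minRidgeContrast = 32) {
  new("DetectionParams", sensitivity = sensitivity, cleanupPx = cleanupPx,
      derivativeScale = derivativeScale, holeIntensityMax = holeIntensityMax,
      holeMinAreaPx = holeMinAreaPx, holeFill = holeFill,
      minRidgeContrast = minRidgeContrast)
}

#' Region-of-interest mask
#'
#' A binary mask, the same shape as its source image, restricting where axons
#' are counted. \code{sourceMode} records how it was made: whole frame,
#' automatic segmentation of a ROI channel, or a user polygon.
#'
#' @slot mask logical H x W matrix.
#' @slot sourceMode "entire_image", "automatic" or "manual".
#' @export
setClass("RoiMask",
  representation(mask = "matrix", sourceMode = "character"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!object@sourceMode %in% c("entire_image", "automatic", "manual"))
      return("unknown sourceMode")
    TRUE
  })

#' @rdname RoiMask-class
#' @param mask logical matrix.
#' @param sourceMode provenance string.
#' @return a \code{RoiMask} object.
#' @export
roiMask <- function(mask, sourceMode = "manual") {
  new("RoiMask", mask = mask, sourceMode = sourceMode)
}

#' @describeIn RoiMask-class number of pixels inside the region.
#' @param object a \code{RoiMask}.
#' @export
setGeneric("roiArea", function(object) standardGeneric("roiArea"))

#' @rdname RoiMask-class
#' @export
setMethod("roiArea", "RoiMask", function(object) sum(object@mask))

#' Result of tracing one image plane
#'
#' Skeletonized axon traces inside a region of interest. The skeleton lives
#' in the cropped frame (tight bounding box of the ROI); \code{cropOffset}
#' gives the (row, col) of the crop origin in the source frame, 1-based.
#' \code{totalLengthPx} is the number of skeleton pixels -- the length
#' measure used throughout. \code{normalizedLength} is
#' \code{totalLengthPx / reference mean intensity} when normalization is on,
#' else \code{NULL}. In detail mode \code{axons} is a data frame with one row
#' per 8-connected skeleton component (\code{component_id},
#' \code{length_px}, \code{color}).
#'
#' @slot skeleton logical matrix in the cropped frame.
#' @slot cropOffset integer (row, col) crop origin, 1-based.
#' @slot totalLengthPx skeleton pixel count.
#' @slot normalizedLength numeric or \code{NULL}.
#' @slot axons data.frame or \code{NULL}.
#' @export
setClass("TraceResult",
  representation(skeleton = "matrix", cropOffset = "integer",
                 totalLengthPx = "numeric",
                 normalizedLength = "numericOrNULL", axons = "dfOrNULL"),
  validity = function(object) {
    if (!is.logical(object@skeleton)) return("skeleton must be logical")
    if (object@totalLengthPx != sum(object@skeleton))
      return("totalLengthPx must equal the number of skeleton pixels")
    if (!is.null(object@axons) &&
        nrow(object@axons) > 0 &&
        sum(object@axons$length_px) != object@totalLengthPx)
      return("per-axon lengths must sum to totalLengthPx")
    TRUE
  })

#' @describeIn TraceResult-class total traced length in skeleton pixels.
#' @param object a \code{TraceResult}.
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))

#' @rdname TraceResult-class
#' @export
setMethod("totalLength", "TraceResult", function(object) object@totalLengthPx)

#' @describeIn TraceResult-class skeleton mask (cropped frame).
#' @export
setGeneric("skeleton", function(object) standardGeneric("skeleton"))

#' @rdname TraceResult-class
#' @export
setMethod("skeleton", "TraceResult", function(object) object@skeleton)

#' @describeIn TraceResult-class per-axon records (detail mode) or
#'   \code{NULL}.
#' @export
setGeneric("axonTable", function(object) standardGeneric("axonTable"))

#' @rdname TraceResult-class
#' @export
setMethod("axonTable", "TraceResult", function(object) object@axons)

#' Batch run configuration
#'
#' Everything a folder run needs: the analysis mode, the channel assignment,
#' frozen detection and ROI parameters, normalization settings and (for the
#' manual modes) the polygon file per image id.
#'
#' Modes: \code{"entire_image"} analyzes the whole frame;
#' \code{"automatic_roi"} segments the ROI channel per image;
#' \code{"manual_roi_1ch"} and \code{"manual_roi_2ch"} rasterize a user
#' polygon, the latter quantifying two axon channels inside the same region.
#'
#' @slot mode one of the four mode strings above.
#' @slot assignment a [ChannelAssignment-class].
#' @slot detection a [DetectionParams-class].
#' @slot roiParams a [RoiParams-class].
#' @slot normalize logical; divide raw lengths by a reference mean intensity.
#' @slot normRoiPath polygon CSV for the normalization region
#'   (\code{NA_character_} when \code{normalize} is off).
#' @slot manualRoiPaths named character vector, image id -> polygon CSV.
#' @slot detail logical; per-axon records and multicolor tracings.
#' @slot writeImages logical; write the per-image result images.
#' @slot outputDir output folder (\code{NA_character_} = analysis folder).
#' @export
setClass("BatchConfig",
  representation(mode = "character", assignment = "ChannelAssignment",
                 detection = "DetectionParams", roiParams = "RoiParams",
                 normalize = "logical", normRoiPath = "character",
                 manualRoiPaths = "character", detail = "logical",
                 writeImages = "logical", outputDir = "character"),
  prototype(mode = "entire_image", normalize = FALSE,
            normRoiPath = NA_character_,
            manualRoiPaths = character(0), detail = FALSE,
            writeImages = TRUE, outputDir = NA_character_),
  validity = function(object) {
    modes <- c("entire_image", "automatic_roi", "manual_roi_1ch",
               "manual_roi_2ch")
    if (!object@mode %in% modes)
      return(paste("mode must be one of:", paste(modes, collapse = ", ")))
    if (object@mode == "automatic_roi" && is.na(object@assignment@roi))
      return("automatic_roi mode requires a ROI channel")
    if (object@mode == "manual_roi_2ch" && is.na(object@assignment@axon2))
      return("manual_roi_2ch mode requires two axon channels")
    if (object@normalize && is.na(object@normRoiPath))
      return("normalization requires normRoiPath")
    TRUE
  })

#' @rdname BatchConfig-class
#' @param mode,assignment,detection,roiParams,normalize,normRoiPath,manualRoiPaths,detail,writeImages,outputDir
#'   see slots.
#' @return a \code{BatchConfig} object.
#' @export
batchConfig <- function(mode = "entire_image",
                        assignment = channelAssignment(),
                        detection = detectionParams(),
                        roiParams = axontracer::roiParams(),
                        normalize = FALSE, normRoiPath = NA_character_,
                        manualRoiPaths = character(0), detail = FALSE,
                        writeImages = TRUE, outputDir = NA_character_) {
  new("BatchConfig", mode = mode, assignment = assignment,
      detection = detection, roiParams = roiParams, normalize = normalize,
      normRoiPath = as.character(normRoiPath),
      manualRoiPaths = manualRoiPaths, detail = detail,
      writeImages = writeImages, outputDir = as.character(outputDir))
}

#' Batch run result
#'
#' One row per input image (in ascending id order) with the region area and
#' the raw and, when enabled, normalized axon lengths; plus frozen copies of
#' the parameters every image was processed with.
#'
#' @slot rows data.frame of per-image results.
#' @slot paramsUsed list with elements \code{detection}, \code{roiParams},
#'   \code{mode}, \code{assignment}, \code{normalization}.
#' @export
setClass("BatchResult",
  representation(rows = "data.frame", paramsUsed = "list"))

#' @describeIn BatchResult-class per-image result table.
#' @param object a \code{BatchResult}.
#' @export
setGeneric("resultRows", function(object) standardGeneric("resultRows"))

#' @rdname BatchResult-class
#' @export
setMethod("resultRows", "BatchResult", function(object) object@rows)

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MultiChannelImage %d x %d (id %s, %s)\n", d[1], d[2],
              object@entry$numeric_id, object@entry$format))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask %d x %d, area %d px, source: %s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@sourceMode))
})

setMethod("show", "TraceResult", function(object) {
  cat(sprintf("TraceResult: %d skeleton px in %d x %d crop at (%d, %d)\n",
              object@totalLengthPx, nrow(object@skeleton),
              ncol(object@skeleton), object@cropOffset[1],
              object@cropOffset[2]))
  if (!is.null(object@normalizedLength))
    cat(sprintf("  normalized length: %.4f\n", object@normalizedLength))
  if (!is.null(object@axons))
    cat(sprintf("  %d individual axons\n", nrow(object@axons)))
})

setMethod("show", "BatchResult", function(object) {
  cat(sprintf("BatchResult: %d images, mode %s\n", nrow(object@rows),
              object@paramsUsed$mode))
})
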