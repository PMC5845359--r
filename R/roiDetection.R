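# Automatic ROI segmentation: contrast stretch, Otsu binarization, particle
# removal, hole filling, then a distance-based enlarge/reduce sequence that
# fuses fragmented signal (e.g. unevenly labeled cell grafts) into one
# continuous region.

# fraction of pixels saturated at each tail by the automatic contrast stretch
AUTO_CONTRAST_SATURATION <- 0.0035

# minimal stretch-window width (0-255 scale) for a plane to count as
# carrying ROI signal; below it, thresholding would only binarize noise
MIN_ROI_CONTRAST <- 32

#' Binarize a ROI channel
#'
#' Applies an automatic contrast stretch (a linear stretch saturating 0.35%
#' of pixels at each tail) followed by Otsu's global threshold; bright
#' pixels become foreground. Two degenerate cases are handled explicitly: a
#' constant plane is thresholded at the fixed mid-scale value 127 (so a
#' uniformly dark plane yields an empty mask and a uniformly saturated one a
#' full mask), and a near-constant plane -- stretch window narrower than 32
#' intensity levels -- is treated as carrying no ROI signal at all, since
#' any global threshold would merely binarize background noise.
#'
#' @param plane numeric H x W matrix on the 0-255 scale.
#' @return logical matrix.
#' @export
preprocessRoiChannel <- function(plane) {
  if (!is.matrix(plane)) stop("plane must be a single-channel matrix")
  q <- quantile(plane, c(AUTO_CONTRAST_SATURATION,
                         1 - AUTO_CONTRAST_SATURATION), names = FALSE)
  if (q[2] <= q[1]) return(plane > 127)
  if (q[2] - q[1] < MIN_ROI_CONTRAST)
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  stretched <- clamp255((plane - q[1]) / (q[2] - q[1]) * 255)
  thr <- EBImage::otsu(EBImage::Image(stretched), range = c(0, 255),
                       levels = 256)
  stretched > thr
}

#' Remove small particles and fill interior holes
#'
#' Drops 8-connected foreground components with area below
#' \code{minParticlePx} (debris), then fills interior holes (background
#' regions not connected to the image border) to make the region continuous.
#'
#' @param mask logical matrix.
#' @param minParticlePx minimum component area kept, in pixels.
#' @return logical matrix.
#' @export
cleanMask <- function(mask, minParticlePx) {
  stopIfNotMask(mask)
  if (!any(mask)) return(mask)
  kept <- filterComponents(mask, function(sz) sz >= minParticlePx)
  if (!any(kept)) return(kept)
  kept | interiorHoles(kept)
}

# background regions (4-connected, complementing the 8-connected foreground)
# that do not touch the image border
interiorHoles <- function(mask) {
  bg <- labelComponents(!mask, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  bg > 0L & !matrix(bg %in% border, nrow(bg), ncol(bg))
}

#' Merge fragments and prune small remnants
#'
#' The enlarge/reduce sequence: Euclidean-distance dilation by
#' \code{p@enlargePx} (default 60 px, bridging gaps up to twice that, i.e.
#' 120 px, between adjacent fragments), then Euclidean-distance erosion by
#' \code{p@reducePx} (default 90 px: 60 to counteract the enlargement plus a
#' net 30-px reduction that removes isolated fragments of half-width below
#' 30 px, which could not have been merged into anything larger). The mask is
#' padded during the sequence so that regions may transiently extend past
#' the frame, exactly as if the frame were a window on a larger plane.
#'
#' @param mask logical matrix.
#' @param p a [RoiParams-class].
#' @return logical matrix.
#' @export
mergeAndPrune <- function(mask, p = roiParams()) {
  stopIfNotMask(mask)
  margin <- as.integer(ceiling(p@enlargePx)) + 1L
  m <- padMatrix(mask, margin)
  m <- dilateByDistance(m, p@enlargePx)
  m <- erodeByDistance(m, p@reducePx)
  cropMatrix(m, margin)
}

#' Adjust a detected region by a signed distance
#'
#' Final user adjustment of the automatic region: positive values dilate,
#' negative values erode by the absolute distance, zero is the identity.
#'
#' @param mask logical matrix.
#' @param adjustPx integer in -255..255.
#' @return logical matrix.
#' @export
adjustRoi <- function(mask, adjustPx) {
  stopIfNotMask(mask)
  if (adjustPx < -255 || adjustPx > 255)
    stop("adjustPx must lie in -255..255")
  if (adjustPx == 0) return(mask)
  if (adjustPx > 0) {
    margin <- as.integer(ceiling(adjustPx)) + 1L
    return(cropMatrix(dilateByDistance(padMatrix(mask, margin), adjustPx),
                      margin))
  }
  erodeByDistance(mask, -adjustPx)
}

#' Automatic ROI detection
#'
#' Full segmentation of a ROI channel:
#' [preprocessRoiChannel()] -> [cleanMask()] -> [mergeAndPrune()] ->
#' [adjustRoi()]. An empty result is reported with a warning (the image is
#' later quantified with zero axon length, not skipped).
#'
#' @param plane numeric H x W matrix (the ROI channel) on the 0-255 scale.
#' @param p a [RoiParams-class].
#' @return a [RoiMask-class] with \code{sourceMode = "automatic"}.
#' @export
detectRoi <- function(plane, p = roiParams()) {
  m <- preprocessRoiChannel(plane)
  m <- cleanMask(m, p@minParticlePx)
  m <- mergeAndPrune(m, p)
  m <- adjustRoi(m, p@adjustPx)
  if (!any(m))
    warning("automatic ROI detection found no region; ",
            "image will be reported with zero axon length")
  roiMask(m, sourceMode = "automatic")
}

#' Select the parameter-tuning image
#'
#' The image whose ROI channel has the median mean intensity in the folder;
#' detection parameters tuned on it transfer best to the rest of the batch.
#' For an even number of images the lower median is taken; ties are broken
#' by the lowest id.
#'
#' @param entries data.frame from [scanAnalysisFolder()].
#' @param assign a [ChannelAssignment-class] with a ROI channel.
#' @return one-row data.frame (the selected entry).
#' @export
selectParameterImage <- function(entries, assign) {
  if (!nrow(entries)) stop("no entries")
  if (is.na(assign@roi)) stop("a ROI channel is required")
  means <- vapply(seq_len(nrow(entries)), function(i) {
    mean(splitChannels(loadImage(entries[i, ]), assign)$roi)
  }, numeric(1))
  ord <- order(means, entries$numeric_id)
  entries[ord[floor((length(ord) + 1) / 2)], , drop = FALSE]
}
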