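# Folder-level orchestration: mode dispatch, reference selection,
# normalization, per-image processing with frozen parameters, output files
# and the summary spreadsheet.

#' Select the normalization reference image
#'
#' The image with the highest mean intensity in the (first) axon channel;
#' its brightly labeled signal serves as the intensity reference that
#' corrects the whole folder for labeling efficiency. Ties go to the lowest
#' id.
#'
#' @param entries data.frame from [scanAnalysisFolder()].
#' @param assign a [ChannelAssignment-class].
#' @return one-row data.frame (the selected entry).
#' @export
selectNormalizationImage <- function(entries, assign) {
  if (!nrow(entries)) stop("no entries")
  means <- vapply(seq_len(nrow(entries)), function(i) {
    mean(splitChannels(loadImage(entries[i, ]), assign)$axon1)
  }, numeric(1))
  entries[order(-means, entries$numeric_id)[1], , drop = FALSE]
}

#' Compute the normalization reference intensity
#'
#' Arithmetic mean of the axon-channel pixels inside the user-supplied
#' polygon on the reference image. A zero mean cannot divide anything and
#' raises a normalization error.
#'
#' @param plane numeric H x W matrix (axon channel of the reference image).
#' @param polygonPath polygon CSV (see [readPolygonCsv()]).
#' @return mean intensity (numeric, > 0).
#' @export
computeNormalization <- function(plane, polygonPath) {
  v <- readPolygonCsv(polygonPath)
  mask <- rasterizePolygon(v, dim(plane))
  if (!any(mask)) stop("normalization polygon rasterizes to no pixels")
  m <- mean(plane[mask])
  if (m <= 0) stop("normalization region has zero mean intensity")
  m
}

#' Normalize a raw length
#'
#' \code{raw / meanIntensity}: raw skeleton pixel counts divided by the
#' reference mean intensity, making folders with different labeling
#' efficiency comparable.
#'
#' @param raw raw length in skeleton pixels.
#' @param meanIntensity reference mean intensity, > 0.
#' @return normalized length.
#' @export
normalizeLength <- function(raw, meanIntensity) {
  if (meanIntensity <= 0) stop("normalization mean intensity must be > 0")
  raw / meanIntensity
}

roiForImage <- function(img, planes, config) {
  dims <- dim(planes$axon1)
  switch(config@mode,
    entire_image = roiMask(matrix(TRUE, dims[1], dims[2]),
                           sourceMode = "entire_image"),
    automatic_roi = detectRoi(planes$roi, config@roiParams),
    {
      id <- as.character(img@entry$numeric_id)
      path <- config@manualRoiPaths[[id]]
      if (is.null(path) || is.na(path))
        stop("no manual ROI polygon for image ", id)
      loadManualRoi(path, dims)
    })
}

#' Run a batch analysis on a folder
#'
#' Processes every image of an analysis folder with identical, frozen
#' parameters: scan and order the images, establish the normalization
#' reference (when enabled), then per image build the region of interest for
#' the configured mode, trace the axon channel(s) and record one result row.
#' Per-image failures are recorded in their row and the batch continues.
#' Output images and the summary spreadsheet ("tracing data summary.csv")
#' are written unless disabled; two runs on identical inputs produce
#' byte-identical outputs (nothing in the pipeline is random).
#'
#' @param folder analysis folder (see [scanAnalysisFolder()]).
#' @param config a [BatchConfig-class].
#' @return a [BatchResult-class].
#' @export
runBatch <- function(folder, config) {
  validObject(config)
  entries <- scanAnalysisFolder(folder)
  outDir <- if (is.na(config@outputDir)) folder else config@outputDir
  tracedDir <- file.path(outDir, "traced images")
  detailDir <- file.path(outDir, "Traced Images Detailed Results")
  if (config@writeImages) {
    # fail before any processing if the destination is unwritable
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output folder: ", outDir)
    if (!dir.exists(tracedDir) &&
        !dir.create(tracedDir, showWarnings = FALSE))
      stop("cannot create output folder: ", tracedDir)
    if (config@detail && !dir.exists(detailDir) &&
        !dir.create(detailDir, showWarnings = FALSE))
      stop("cannot create output folder: ", detailDir)
    if (file.access(outDir, 2) != 0)
      stop("output folder is not writable: ", outDir)
  }
  normInfo <- NULL
  if (config@normalize) {
    ref <- selectNormalizationImage(entries, config@assignment)
    refPlanes <- splitChannels(loadImage(ref), config@assignment)
    meanInt <- computeNormalization(refPlanes$axon1, config@normRoiPath)
    normInfo <- list(entry = ref, meanIntensity = meanInt)
  }
  twoChannel <- config@mode == "manual_roi_2ch"
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    entry <- entries[i, ]
    row <- data.frame(numeric_id = entry$numeric_id, roi_area_px = NA_real_,
                      raw_length_px = NA_real_, stringsAsFactors = FALSE)
    if (config@normalize) row$normalized_length <- NA_real_
    if (twoChannel) {
      row$raw_length_px_2 <- NA_real_
      if (config@normalize) row$normalized_length_2 <- NA_real_
    }
    row$status <- "ok"
    tryCatch({
      img <- loadImage(entry)
      planes <- splitChannels(img, config@assignment)
      roi <- withCallingHandlers(
        roiForImage(img, planes, config),
        warning = function(w) invokeRestart("muffleWarning"))
      tr1 <- traceAxons(planes$axon1, roi, config@detection,
                        detail = config@detail)
      row$roi_area_px <- roiArea(roi)
      row$raw_length_px <- totalLength(tr1)
      if (config@normalize)
        row$normalized_length <- normalizeLength(totalLength(tr1),
                                                 normInfo$meanIntensity)
      tr2 <- NULL
      if (twoChannel) {
        tr2 <- traceAxons(planes$axon2, roi, config@detection,
                          detail = config@detail)
        row$raw_length_px_2 <- totalLength(tr2)
        if (config@normalize)
          row$normalized_length_2 <- normalizeLength(totalLength(tr2),
                                                     normInfo$meanIntensity)
      }
      if (config@writeImages)
        writeImageOutputs(img, planes, roi, tr1, tr2, tracedDir, detailDir,
                          config)
    }, error = function(e) {
      row$status <<- paste("error:", conditionMessage(e))
    })
    row
  })
  rows <- do.call(rbind, rows)
  paramsUsed <- list(mode = config@mode,
                     assignment = config@assignment,
                     detection = config@detection,
                     roiParams = config@roiParams,
                     normalization = normInfo)
  result <- new("BatchResult", rows = rows, paramsUsed = paramsUsed)
  if (config@writeImages)
    writeSummary(result, outDir)
  result
}

outputExtension <- function(format) {
  # overlays must stay lossless: JPEG inputs get PNG outputs
  if (format == "jpeg") "png" else format
}

writeImageOutputs <- function(img, planes, roi, tr1, tr2, tracedDir,
                              detailDir, config) {
  id <- img@entry$numeric_id
  ext <- outputExtension(img@entry$format)
  out <- function(letter) file.path(tracedDir,
                                    paste0(id, letter, ".", ext))
  # (a) original RGB with the ROI outlined in white
  outline <- maskOutline(roi@mask)
  writeRgbImage(renderOverlay(img@pixels, outline, c(1L, 1L),
                              c(255, 255, 255)), out("a"))
  empty <- !any(roi@mask)
  writePlaneOutputs <- function(plane, tr, letters) {
    if (empty) {
      writeGrayImage(plane * 0, out(letters[1]))
      writeRgbImage(grayToRgb(plane * 0), out(letters[2]))
      return(invisible())
    }
    cr <- applyRoiAndCrop(plane, roi)
    writeGrayImage(cr$plane, out(letters[1]))   # (b/d) cropped grayscale
    writeRgbImage(renderOverlay(cr$plane, skeleton(tr), c(1L, 1L),
                                c(255, 255, 0)), out(letters[2]))  # (c/e)
  }
  writePlaneOutputs(planes$axon1, tr1, c("b", "c"))
  if (!is.null(tr2))
    writePlaneOutputs(planes$axon2, tr2, c("d", "e"))
  if (config@detail) {
    writeDetailOutputs(planes$axon1, roi, tr1, id, detailDir, ext)
  }
}

writeDetailOutputs <- function(plane, roi, tr, id, detailDir, ext) {
  ax <- axonTable(tr)
  write.csv(ax, file.path(detailDir,
                          paste0(id, " Tracing Data Details.csv")),
            row.names = FALSE)
  if (any(roi@mask)) {
    cr <- applyRoiAndCrop(plane, roi)
    multicolor <- renderOverlay(cr$plane, skeleton(tr), c(1L, 1L), ax)
    writeRgbImage(multicolor,
                  file.path(detailDir,
                            paste0(id, " Tracing Data Details.png")))
  }
}

writeSummary <- function(result, outDir) {
  path <- file.path(outDir, "tracing data summary.csv")
  write.csv(resultRows(result), path, row.names = FALSE)
  invisible(path)
}
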