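IMAGE_EXTENSIONS <- c(tif = "tiff", tiff = "tiff", jpg = "jpeg",
                      jpeg = "jpeg", png = "png")

# output files the tool itself creates inside an analysis folder; a folder
# remains a valid analysis folder after a run
RESERVED_FILES <- c("tracing data summary.csv", "axontracer run.log")
RESERVED_DIRS <- c("traced images", "Traced Images Detailed Results")

#' Scan an analysis folder
#'
#' Validates and lists the images of an analysis folder: every file must be a
#' TIFF, PNG or JPEG whose name (before the extension) is a positive integer
#' with no leading zero; ids must be unique. Entries are returned sorted by
#' ascending id, which fixes the processing order of a batch. Dotfiles,
#' subfolders and the tool's own output files are ignored; any other
#' non-image file is an error.
#'
#' @param path directory containing the images.
#' @return data.frame with columns \code{numeric_id}, \code{path},
#'   \code{format}, ordered by \code{numeric_id}.
#' @examples
#' d <- tempfile(); dir.create(d)
#' file.create(file.path(d, c("3.png", "24.png")))
#' scanAnalysisFolder(d)$numeric_id
#' @export
scanAnalysisFolder <- function(path) {
  if (!dir.exists(path)) stop("analysis folder does not exist: ", path)
  all <- list.files(path, all.files = FALSE)   # all.files=FALSE drops dotfiles
  files <- all[!dir.exists(file.path(path, all))]
  files <- files[!tolower(files) %in% tolower(RESERVED_FILES)]
  if (!length(files)) stop("analysis folder contains no images: ", path)
  ext <- tolower(tools::file_ext(files))
  bad <- !(ext %in% names(IMAGE_EXTENSIONS))
  if (any(bad))
    stop("analysis folder contains non-image files: ",
         paste(files[bad], collapse = ", "))
  stem <- tools::file_path_sans_ext(files)
  okname <- grepl("^[1-9][0-9]*$", stem)
  if (any(!okname))
    stop("image filenames must be numeric without a leading zero: ",
         paste(files[!okname], collapse = ", "))
  ids <- as.integer(stem)
  if (anyDuplicated(ids))
    stop("duplicate numeric ids in analysis folder: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  data.frame(numeric_id = ids[ord],
             path = file.path(path, files[ord]),
             format = unname(IMAGE_EXTENSIONS[ext[ord]]),
             stringsAsFactors = FALSE)
}

#' Load one image entry
#'
#' Reads an image file into a [MultiChannelImage-class] on the 0-255 scale.
#' Grayscale sources are replicated to three identical planes. Sources with
#' more than 8 bits per channel are min-max rescaled to 0-255; an alpha
#' channel, if present, is dropped.
#'
#' @param entry one row of the data frame from [scanAnalysisFolder()], or a
#'   list with \code{numeric_id}, \code{path}, \code{format}.
#' @return a [MultiChannelImage-class].
#' @export
loadImage <- function(entry) {
  entry <- as.list(entry)
  img <- tryCatch(suppressWarnings(EBImage::readImage(entry$path)),
                  error = function(e)
                    stop("cannot decode image file ", entry$path, ": ",
                         conditionMessage(e)))
  a <- EBImage::imageData(img)             # W x H (x C), values in [0, 1]
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] >= 3) a <- a[, , 1:3, drop = FALSE]
  v255 <- a * 255
  if (max(abs(v255 - round(v255))) > 1e-6) {
    # deeper than 8 bits: min-max rescale
    rng <- range(a)
    if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng) else a <- a * 0
    v255 <- a * 255
  }
  v255 <- round(v255)
  if (dim(v255)[3] == 1) v255 <- v255[, , c(1, 1, 1)]
  # EBImage stores x (column) first; transpose to row-major H x W x 3
  pixels <- aperm(v255, c(2, 1, 3))
  new("MultiChannelImage", pixels = pixels,
      entry = entry[c("numeric_id", "path", "format")])
}

#' Split an RGB image into role planes
#'
#' Returns the color planes named by their role in the analysis, unmodified:
#' no rescaling, no copying artifacts. Roles must be assigned to distinct
#' channels (enforced by [ChannelAssignment-class]).
#'
#' @param img a [MultiChannelImage-class].
#' @param assign a [ChannelAssignment-class].
#' @return named list of H x W matrices: \code{axon1}, and \code{axon2} /
#'   \code{roi} when assigned.
#' @export
splitChannels <- function(img, assign) {
  stopifnot(is(img, "MultiChannelImage"), is(assign, "ChannelAssignment"))
  validObject(assign)
  chan <- c(r = 1L, g = 2L, b = 3L)
  pick <- function(ch) img@pixels[, , chan[[ch]]]
  out <- list(axon1 = pick(assign@axon1))
  if (!is.na(assign@axon2)) out$axon2 <- pick(assign@axon2)
  if (!is.na(assign@roi)) out$roi <- pick(assign@roi)
  out
}

#' Invert an 8-bit plane
#'
#' Pixelwise \code{255 - v}; applying it twice returns the original plane.
#'
#' @param plane numeric matrix on the 0-255 scale.
#' @return inverted matrix.
#' @export
invertPlane <- function(plane) 255 - plane

# ---- writers ------------------------------------------------------------

# grayscale H x W 0-255 matrix -> file (format by extension)
writeGrayImage <- function(plane, path) {
  EBImage::writeImage(EBImage::Image(t(plane) / 255), path)
  invisible(path)
}

# H x W x 3 0-255 array -> file
writeRgbImage <- function(arr, path) {
  EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3)) / 255,
                                     colormode = "Color"), path)
  invisible(path)
}

grayToRgb <- function(plane) {
  array(plane, c(dim(plane), 3L))
}
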