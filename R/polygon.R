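# Polygon handling for manual ROIs and the normalization region.
#
# Polygons are vertex lists in 0-based pixel coordinates, origin at the
# top-left, x = column, y = row -- the coordinate convention of the imaging
# platforms these files come from. Rasterization is inclusive: a pixel
# belongs to the region if its center is inside the polygon or exactly on
# its boundary, so an axis-aligned rectangle (10,10)-(20,20) covers
# 11 x 11 = 121 pixels.

#' Read a polygon vertex file
#'
#' One \code{x,y} vertex per line (0-based pixel coordinates, top-left
#' origin); an optional \code{x,y} header line is tolerated.
#'
#' @param path CSV file.
#' @return two-column numeric matrix of vertices.
#' @export
readPolygonCsv <- function(path) {
  if (!file.exists(path)) stop("polygon file does not exist: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^[a-zA-Z]", lines[1])) lines <- lines[-1]
  if (!length(lines)) stop("polygon file is empty: ", path)
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2))
    stop("polygon file must have one 'x,y' pair per line: ", path)
  v <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(v)) stop("non-numeric vertex in polygon file: ", path)
  colnames(v) <- c("x", "y")
  v
}

# inclusive point-in-polygon rasterization over an H x W pixel grid;
# vertices 0-based (x = col - 1, y = row - 1)
rasterizePolygon <- function(vertices, dims) {
  if (nrow(vertices) < 3)
    stop("a polygon needs at least 3 vertices")
  h <- dims[1]; w <- dims[2]
  vx <- pmin(pmax(vertices[, 1], 0), w - 1)   # clip to image bounds
  vy <- pmin(pmax(vertices[, 2], 0), h - 1)
  n <- length(vx)
  xmin <- max(0, floor(min(vx))); xmax <- min(w - 1, ceiling(max(vx)))
  ymin <- max(0, floor(min(vy))); ymax <- min(h - 1, ceiling(max(vy)))
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # even-odd crossing test
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint[crosses])
    }
    # boundary test: point within eps of segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      onedge <- onedge | d2 <= eps
    } else {
      onedge <- onedge | ((px - x1)^2 + (py - y1)^2 <= eps)
    }
    j <- i
  }
  keep <- inside | onedge
  mask <- matrix(FALSE, h, w)
  mask[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  mask
}

#' Load a manual ROI polygon
#'
#' Rasterizes a polygon vertex file into a [RoiMask-class] for the given
#' image dimensions. Vertices outside the image are clipped to its bounds.
#'
#' @param path polygon CSV (see [readPolygonCsv()]).
#' @param dims integer (H, W) of the target image.
#' @return a [RoiMask-class] with \code{sourceMode = "manual"}.
#' @export
loadManualRoi <- function(path, dims) {
  v <- readPolygonCsv(path)
  if (nrow(v) < 3)
    stop("manual ROI polygon needs at least 3 vertices: ", path)
  roiMask(rasterizePolygon(v, dims), sourceMode = "manual")
}
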