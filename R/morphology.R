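#' Distance-based dilation and erosion
#'
#' Grow or shrink a binary region by a Euclidean distance rather than by
#' iterating a structuring element. \code{dilateByDistance} adds every
#' background pixel whose Euclidean distance to the region is \code{<= r};
#' \code{erodeByDistance} keeps a region pixel only if its distance to the
#' background is \code{> r}. The frame border counts as background for
#' erosion (a region touching the border erodes from that side), while
#' dilation is clipped to the frame. With these inclusive conventions a
#' region enlarged by 60 px bridges gaps up to 120 px wide, and enlarging by
#' 60 then reducing by 90 removes isolated fragments of half-width < 30 px.
#'
#' @param mask logical matrix.
#' @param r distance in pixels, \code{>= 0}.
#' @return logical matrix of the same shape.
#' @seealso [mergeAndPrune()], [adjustRoi()]
#' @export
dilateByDistance <- function(mask, r) {
  stopIfNotMask(mask)
  if (r < 0) stop("r must be >= 0")
  if (r == 0 || !any(mask) || all(mask)) return(mask)
  bg <- 1 - mask * 1                       # foreground pixels are the zeros
  d <- EBImage::distmap(bg)
  d <= r
}

#' @rdname dilateByDistance
#' @export
erodeByDistance <- function(mask, r) {
  stopIfNotMask(mask)
  if (r < 0) stop("r must be >= 0")
  if (r == 0 || !any(mask)) return(mask)
  # 1-px background ring makes the frame border behave as background
  p <- padMatrix(mask, 1L)
  d <- EBImage::distmap(p * 1)
  cropMatrix(d > r, 1L)
}

# outline = region pixels adjacent to background (1-px wide)
maskOutline <- function(mask) {
  mask & !erodeByDistance(mask, 1)
}
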