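#' @import methods
#' @importFrom stats quantile rnorm runif
#' @importFrom utils write.csv read.csv
NULL

## Grayscale planes are numeric H x W matrices on the 0-255 scale
## (row = image row, top-left origin). RGB frames are H x W x 3 arrays.

# shift a logical/numeric matrix by (dr, dc), padding with `fill`
shiftMatrix <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

clamp255 <- function(x) { x[x < 0] <- 0; x[x > 255] <- 255; x }

# round-half-up to the nearest integer (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

padMatrix <- function(m, margin, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h + 2L * margin, w + 2L * margin)
  out[margin + seq_len(h), margin + seq_len(w)] <- m
  out
}

cropMatrix <- function(m, margin) {
  h <- nrow(m) - 2L * margin
  w <- ncol(m) - 2L * margin
  m[margin + seq_len(h), margin + seq_len(w), drop = FALSE]
}

stopIfNotMask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("expected a logical H x W matrix")
  invisible(mask)
}
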