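#' Label connected components in a binary mask
#'
#' Labels foreground components of a logical matrix. Foreground connectivity
#' defaults to 8 (edge- and corner-adjacent pixels belong to the same
#' component), the convention used throughout the tracing pipeline for both
#' region fragments and skeleton branches. Labels are assigned in raster-scan
#' order of each component's first pixel, so labelling is deterministic.
#'
#' @param mask logical matrix; \code{TRUE} = foreground.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(labelComponents(m))              # 1 under 8-connectivity
#' max(labelComponents(m, 4))           # 2 under 4-connectivity
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopIfNotMask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(length(mask))      # linear pixel index -> vertex id
  id[idx] <- seq_along(idx)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nb <- shiftMatrix(mask, -o[1], -o[2])   # neighbour at (+dr,+dc) exists
    both <- which(mask & nb)
    if (!length(both)) next
    nbidx <- both + o[1] + o[2] * nrow(mask)
    from <- c(from, id[both]); to <- c(to, id[nbidx])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber so that components appear in raster order of first occurrence
  first <- !duplicated(memb)
  ord <- integer(max(memb))
  ord[memb[first]] <- seq_len(sum(first))
  lab[idx] <- ord[memb]
  lab
}

# sizes of labelled components, as an integer vector indexed by label
componentSizes <- function(lab) {
  if (!any(lab > 0L)) return(integer(0))
  tabulate(lab[lab > 0L])
}

# drop components whose pixel count fails `keep` (a predicate on sizes)
filterComponents <- function(mask, predicate, connectivity = 8) {
  lab <- labelComponents(mask, connectivity)
  sz <- componentSizes(lab)
  if (!length(sz)) return(mask & FALSE)
  keep <- predicate(sz)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  sel <- lab > 0L
  out[sel] <- keep[lab[sel]]
  out
}
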