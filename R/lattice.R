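#' The six fold directions of the triangular lattice
#'
#' Direction symbols in counter-clockwise ring order starting at \code{R};
#' rotating a direction by one 60-degree step moves one position along this
#' ring. The symbols stand for right, right-up, left-up, left, left-down and
#' right-down steps between consecutive residues.
#'
#' @return Character vector of the six direction symbols.
#' @examples
#' latticeDirections()
#' @export
latticeDirections <- function() {
  c("R", "RU", "LU", "L", "LD", "RD")
}

# integer codes 0..5 shared with the C++ engine
.dirIndex <- function(d) {
  i <- match(d, latticeDirections())
  if (anyNA(i)) {
    bad <- unique(d[is.na(i)])
    stop("invalid direction symbol(s): ", paste(bad, collapse = ", "))
  }
  i - 1L
}

.dirStepX <- c(1L, 0L, -1L, -1L, 0L, 1L)
.dirStepY <- c(0L, 1L, 1L, 0L, -1L, -1L)

#' Unit step vector of a fold direction
#'
#' Axial integer coordinates are used throughout: \code{R = (1,0)},
#' \code{L = (-1,0)}, \code{RU = (0,1)}, \code{LD = (0,-1)},
#' \code{LU = (-1,1)}, \code{RD = (1,-1)}. Integer coordinates make
#' self-avoidance and contact tests exact.
#'
#' @param d Character vector of direction symbols.
#' @return For a single symbol, a named integer vector \code{c(x, y)}; for
#'   several, an integer matrix with one row per symbol.
#' @examples
#' directionVector("R")
#' colSums(directionVector(latticeDirections())) # zero by symmetry
#' @export
directionVector <- function(d) {
  i <- .dirIndex(d) + 1L
  m <- cbind(x = .dirStepX[i], y = .dirStepY[i])
  rownames(m) <- d
  if (length(d) == 1L) m[1L, ] else m
}

#' Test whether two lattice points are topological neighbours
#'
#' True iff the coordinate difference is one of the six unit step vectors.
#' A point is not its own neighbour.
#'
#' @param a,b Integer coordinate pairs \code{c(x, y)}, or matrices with one
#'   point per row (recycled row-wise against each other).
#' @return Logical vector.
#' @examples
#' areNeighbors(c(0, 0), c(1, 0))
#' areNeighbors(c(0, 0), c(1, 1))
#' @export
areNeighbors <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  dx <- b[, 1] - a[, 1]
  dy <- b[, 2] - a[, 2]
  out <- rep(FALSE, length(dx))
  for (k in 1:6) {
    out <- out | (dx == .dirStepX[k] & dy == .dirStepY[k])
  }
  unname(out)
}

#' Rotate a fold direction by multiples of 60 degrees
#'
#' Rotation is counter-clockwise along the ring
#' \code{R -> RU -> LU -> L -> LD -> RD -> R}; three steps give the opposite
#' direction and six steps the identity.
#'
#' @param d Character vector of direction symbols.
#' @param steps Single integer in \code{1..5}: rotation angle in units of 60
#'   degrees.
#' @return Character vector of rotated symbols.
#' @examples
#' rotateDirection("R", 3)  # "L"
#' rotateDirection("RU", 1) # "LU"
#' @export
rotateDirection <- function(d, steps) {
  if (length(steps) != 1L || is.na(steps) || steps != as.integer(steps) ||
      steps < 1L || steps > 5L) {
    stop("'steps' must be a single integer in 1..5")
  }
  latticeDirections()[(.dirIndex(d) + as.integer(steps)) %% 6L + 1L]
}

#' Opposite of a fold direction
#'
#' @param d Character vector of direction symbols.
#' @return The 180-degree rotation of each symbol.
#' @examples
#' oppositeDirection(c("L", "RU")) # "R", "LD"
#' @export
oppositeDirection <- function(d) {
  rotateDirection(d, 3L)
}

#' Map axial lattice coordinates to the Euclidean plane
#'
#' \code{(x, y)} maps to \code{(x + y/2, y * sqrt(3)/2)}; lattice neighbours
#' land at Euclidean distance 1. Used for plotting conformations.
#'
#' @param coords Integer coordinate pair \code{c(x, y)} or a matrix with one
#'   point per row.
#' @return Numeric pair or matrix of the same shape with columns
#'   \code{x, y}.
#' @examples
#' toEuclidean(c(0, 1)) # (0.5, sqrt(3)/2)
#' @export
toEuclidean <- function(coords) {
  single <- is.null(dim(coords))
  m <- rbind(coords)
  out <- cbind(x = m[, 1] + m[, 2] / 2, y = m[, 2] * sqrt(3) / 2)
  if (single) out[1L, ] else out
}
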