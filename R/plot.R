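#' Draw a conformation in the Euclidean plane
#'
#' Maps the decoded walk through \code{\link{toEuclidean}} and draws the
#' backbone with hydrophobic residues as filled dots, polar residues as open
#' circles, and H-H topological contacts as dashed segments.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param conf A matching \linkS4class{Conformation}.
#' @param main Plot title; defaults to the energy.
#' @param ... Further arguments passed to \code{plot}.
#' @return The Euclidean coordinate matrix, invisibly.
#' @examples
#' plotConformation(HPSequence("HHHH"), Conformation(c("R", "RU", "L")))
#' @export
plotConformation <- function(seq, conf, main = NULL, ...) {
  stopifnot(is(seq, "HPSequence"), is(conf, "Conformation"))
  walk <- decodeConformation(conf)
  xy <- toEuclidean(walk)
  isH <- .residueIsH(seq)
  if (is.null(main)) {
    main <- if (isSelfAvoiding(walk)) {
      sprintf("energy %d", hpEnergy(seq, conf))
    } else {
      "infeasible (self-colliding)"
    }
  }
  graphics::plot(xy, type = "n", asp = 1, xlab = "", ylab = "",
                 main = main, axes = FALSE, ...)
  # H-H contact segments behind the backbone
  H <- which(isH)
  if (length(H) >= 2) {
    pairs <- utils::combn(H, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (j - i > 1 && areNeighbors(walk[i, ], walk[j, ])) {
        graphics::segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2],
                           lty = 2, col = "grey60")
      }
    }
  }
  graphics::lines(xy, col = "grey30")
  graphics::points(xy[isH, , drop = FALSE], pch = 19, cex = 1.3)
  graphics::points(xy[!isH, , drop = FALSE], pch = 21, bg = "white",
                   cex = 1.3)
  invisible(xy)
}
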