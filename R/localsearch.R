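#' Local search I: single-direction hill climbing
#'
#' For each pass, visits every gene position in a random order and proposes
#' replacing that direction with a uniformly drawn different symbol; the
#' proposal is accepted iff it strictly improves the penalised fitness
#' (first-improvement hill climbing). The returned conformation never scores
#' worse than the input.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param conf A \linkS4class{Conformation} with n - 1 folds.
#' @param passes Non-negative integer number of passes (default 1; 0 is the
#'   identity).
#' @param penaltyPerCollision See \code{\link{hpFitness}}.
#' @param seed Optional integer seed.
#' @return The refined \linkS4class{Conformation}.
#' @export
localSearchOne <- function(seq, conf, passes = 1L,
                           penaltyPerCollision = NULL, seed = NULL) {
  stopifnot(is(seq, "HPSequence"), is(conf, "Conformation"))
  if (length(conf) != nResidues(seq) - 1L) {
    stop("conformation must have exactly n - 1 folds")
  }
  if (passes < 0L) stop("'passes' must be non-negative")
  penalty <- .resolvePenalty(penaltyPerCollision, nResidues(seq))
  res <- .cpp_local_search1(.residueIsH(seq), .foldsToCodes(conf@folds),
                            as.integer(passes), penalty, .drawSeed(seed))
  Conformation(.codesToFolds(res$folds))
}

#' Local search II: tail-segment rotation
#'
#' Picks a pivot gene position uniformly (so that the rotated suffix is a
#' proper tail of the chain), builds five neighbours by rotating every fold
#' from the pivot onward by 60, 120, 180, 240 and 300 degrees, and keeps the
#' best neighbour iff it strictly improves the fitness. Decoded, the five
#' neighbours are rigid rotations of the tail sub-walk about the pivot
#' residue. Chromosomes with fewer than two folds are returned unchanged.
#'
#' @inheritParams localSearchOne
#' @param trials Number of random pivots to try (default 1).
#' @param scanAll Logical: deterministically scan every pivot instead.
#' @param pivot Optional fixed pivot (gene index in \code{1..n-2}) replacing
#'   the random draw; useful for testing.
#' @return The refined \linkS4class{Conformation}.
#' @export
localSearchTwo <- function(seq, conf, trials = 1L, scanAll = FALSE,
                           penaltyPerCollision = NULL, seed = NULL,
                           pivot = NULL) {
  stopifnot(is(seq, "HPSequence"), is(conf, "Conformation"))
  if (length(conf) != nResidues(seq) - 1L) {
    stop("conformation must have exactly n - 1 folds")
  }
  if (length(conf) < 2L) return(conf)
  penalty <- .resolvePenalty(penaltyPerCollision, nResidues(seq))
  pv <- if (is.null(pivot)) -1L else as.integer(pivot)
  if (pv != -1L && (pv < 1L || pv > length(conf) - 1L)) {
    stop("'pivot' must lie in 1..n-2")
  }
  res <- .cpp_local_search2(.residueIsH(seq), .foldsToCodes(conf@folds),
                            as.integer(trials), isTRUE(scanAll), penalty,
                            .drawSeed(seed), pv)
  Conformation(.codesToFolds(res$folds))
}
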