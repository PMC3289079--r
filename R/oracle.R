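#' Exact minimum energy by exhaustive enumeration
#'
#' Ground-truth oracle for short chains: enumerates fold strings depth-first
#' with prefix self-avoidance pruning and returns the exact minimum free
#' energy together with one optimal conformation. With \code{symmetry = TRUE}
#' (default) the first step is fixed to \code{R} and the first off-axis step
#' is restricted to the upper half plane, quotienting out the 12-element
#' rotation/reflection group (~12x fewer walks; the minimum is unaffected
#' because the energy is invariant under rigid motions).
#'
#' The search space grows as 6^(n-1), so a guard refuses chains longer than
#' \code{maxN} explicitly rather than truncating silently.
#'
#' @param seq An \linkS4class{HPSequence}.
#' @param maxN Guard on the chain length (default 12).
#' @param symmetry Logical: apply the symmetry quotient (default
#'   \code{TRUE}); \code{FALSE} enumerates naively over all walks.
#' @return An \linkS4class{OracleResult}.
#' @examples
#' minEnergy(enumerateMinEnergy(HPSequence("HHHH"))) # -2
#' @export
enumerateMinEnergy <- function(seq, maxN = 12L, symmetry = TRUE) {
  stopifnot(is(seq, "HPSequence"))
  n <- nResidues(seq)
  if (n > maxN) {
    stop(sprintf(paste0("refusing to enumerate a %d-residue chain ",
                        "(guard maxN = %d); raise 'maxN' knowingly or use ",
                        "the GA instead"), n, maxN))
  }
  res <- .cpp_enumerate(.residueIsH(seq), isTRUE(symmetry))
  new("OracleResult",
      minEnergy = as.integer(res$minEnergy),
      optimalCount = as.numeric(res$optimalCount),
      optimum = Conformation(.codesToFolds(res$witness)))
}

#' @rdname OracleResult-class
#' @param x,object An \linkS4class{OracleResult}.
#' @export
setMethod("minEnergy", "OracleResult", function(x) x@minEnergy)

#' @rdname OracleResult-class
#' @export
setMethod("bestConformation", "OracleResult", function(x) x@optimum)

setMethod("show", "OracleResult", function(object) {
  cat(sprintf("OracleResult: minimum energy %d (%g optimal fold strings)\n",
              object@minEnergy, object@optimalCount))
  if (length(object@optimum) > 0) {
    cat("  witness:", foldString(object@optimum), "\n")
  }
})
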