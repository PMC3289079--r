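#' HPSequence: a hydrophobic-polar residue string
#'
#' An amino-acid chain reduced to its hydrophobicity pattern: each residue is
#' either \code{H} (hydrophobic) or \code{P} (polar). Construct with
#' \code{\link{HPSequence}} or \code{\link{parseHP}}.
#'
#' @slot residues Single character string over \code{{H, P}}.
#' @aliases HPSequence-class
#' @exportClass HPSequence
setClass("HPSequence", representation(residues = "character"))

setValidity("HPSequence", function(object) {
  r <- object@residues
  if (length(r) != 1L || is.na(r)) {
    return("'residues' must be a single non-NA string")
  }
  if (nchar(r) < 1L) {
    return("sequence must contain at least one residue")
  }
  if (grepl("[^HP]", r)) {
    return("sequence may contain only 'H' and 'P'")
  }
  TRUE
})

#' Conformation: a fold string on the triangular lattice
#'
#' The chromosome encoding of a lattice conformation: for an n-residue chain,
#' n-1 absolute step directions over \code{L, R, LU, LD, RU, RD}. Decoding
#' places the first residue at the origin and walks the steps; see
#' \code{\link{decodeConformation}}.
#'
#' @slot folds Character vector of direction symbols (possibly empty).
#' @aliases Conformation-class
#' @exportClass Conformation
setClass("Conformation", representation(folds = "character"))

setValidity("Conformation", function(object) {
  f <- object@folds
  if (length(f) > 0 && !all(f %in% latticeDirections())) {
    return("folds must be direction symbols L, R, LU, LD, RU or RD")
  }
  TRUE
})

#' GAConfig: tunables of the ERS-GA and HHGA
#'
#' All search parameters in one object; see \code{\link{gaConfig}} for
#' defaults and meanings.
#'
#' @slot populationSize Positive even integer.
#' @slot crossoverRate,mutationRate Probabilities in \code{[0, 1]}.
#' @slot maxGenerations Positive integer.
#' @slot penaltyPerCollision Positive number, or \code{NA} for the
#'   sequence-dependent default \code{4 * n}.
#' @slot runs Positive integer: independent runs in benchmark experiments.
#' @slot localSearch Logical: HHGA mode (hill climbing on every offspring).
#' @slot ls1Passes,ls2Trials Non-negative integers: local-search budgets.
#' @slot parentPool \code{"bottom_half"}, \code{"whole"} or \code{"top_half"}.
#' @slot mutationScope \code{"gene"} or \code{"chromosome"}.
#' @slot ls2ScanAll Logical: scan every pivot in local search II.
#' @aliases GAConfig-class
#' @exportClass GAConfig
setClass("GAConfig", representation(
  populationSize = "integer",
  crossoverRate = "numeric",
  mutationRate = "numeric",
  maxGenerations = "integer",
  penaltyPerCollision = "numeric",
  runs = "integer",
  localSearch = "logical",
  ls1Passes = "integer",
  ls2Trials = "integer",
  parentPool = "character",
  mutationScope = "character",
  ls2ScanAll = "logical"
))

setValidity("GAConfig", function(object) {
  p <- object@populationSize
  if (p < 2L || p %% 2L != 0L) {
    return("populationSize must be a positive even integer")
  }
  for (nm in c("crossoverRate", "mutationRate")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) return(paste(nm, "must lie in [0, 1]"))
  }
  if (object@maxGenerations < 1L) return("maxGenerations must be >= 1")
  if (!is.na(object@penaltyPerCollision) && object@penaltyPerCollision <= 0) {
    return("penaltyPerCollision must be positive (or NA for 4n)")
  }
  if (object@runs < 1L) return("runs must be >= 1")
  if (object@ls1Passes < 0L || object@ls2Trials < 0L) {
    return("local-search budgets must be non-negative")
  }
  if (!object@parentPool %in% c("bottom_half", "whole", "top_half")) {
    return("parentPool must be 'bottom_half', 'whole' or 'top_half'")
  }
  if (!object@mutationScope %in% c("gene", "chromosome")) {
    return("mutationScope must be 'gene' or 'chromosome'")
  }
  TRUE
})

#' HPPopulation: an evaluated, fitness-sorted GA population
#'
#' Rows of \code{folds} are chromosomes; \code{fitness} is kept sorted
#' ascending (best first).
#'
#' @slot sequence The \linkS4class{HPSequence} being folded.
#' @slot folds Character matrix, one chromosome per row.
#' @slot fitness Numeric vector, ascending.
#' @aliases HPPopulation-class
#' @exportClass HPPopulation
setClass("HPPopulation", representation(
  sequence = "HPSequence",
  folds = "matrix",
  fitness = "numeric"
))

setValidity("HPPopulation", function(object) {
  if (nrow(object@folds) != length(object@fitness)) {
    return("one fitness value per chromosome required")
  }
  if (is.unsorted(object@fitness)) {
    return("population must be sorted ascending by fitness")
  }
  TRUE
})

#' RunResult: outcome of one ERS-GA or HHGA run
#'
#' @slot sequence The folded \linkS4class{HPSequence}.
#' @slot bestConformation Best self-avoiding \linkS4class{Conformation} seen.
#' @slot bestEnergy Integer free energy of the best conformation.
#' @slot feasible Logical: whether any self-avoiding conformation was seen.
#' @slot generationLog Data frame with columns \code{generation},
#'   \code{best}, \code{mean} (population fitness per generation).
#' @slot seed Integer seed of the run.
#' @slot generationsRun Integer.
#' @slot wallTime Elapsed seconds.
#' @slot algorithm \code{"ersga"} or \code{"hhga"}.
#' @aliases RunResult-class
#' @exportClass RunResult
setClass("RunResult", representation(
  sequence = "HPSequence",
  bestConformation = "Conformation",
  bestEnergy = "integer",
  feasible = "logical",
  generationLog = "data.frame",
  seed = "integer",
  generationsRun = "integer",
  wallTime = "numeric",
  algorithm = "character"
))

#' OracleResult: exact optimum from exhaustive enumeration
#'
#' @slot minEnergy Integer: exact minimum free energy over all self-avoiding
#'   walks.
#' @slot optimalCount Numeric: number of optimal fold strings in the
#'   enumerated (symmetry-reduced, when enabled) space.
#' @slot optimum A witness \linkS4class{Conformation} attaining the minimum.
#' @aliases OracleResult-class
#' @exportClass OracleResult
setClass("OracleResult", representation(
  minEnergy = "integer",
  optimalCount = "numeric",
  optimum = "Conformation"
))
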