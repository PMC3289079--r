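#' @rdname HPSequence
#' @export
setGeneric("hpResidues", function(x) standardGeneric("hpResidues"))

#' @rdname HPSequence
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Conformation
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))

#' @rdname Conformation
#' @export
setGeneric("foldString", function(x) standardGeneric("foldString"))

#' @rdname RunResult-class
#' @export
setGeneric("bestConformation", function(x) standardGeneric("bestConformation"))

#' @rdname RunResult-class
#' @export
setGeneric("bestEnergy", function(x) standardGeneric("bestEnergy"))

#' @rdname RunResult-class
#' @export
setGeneric("generationLog", function(x) standardGeneric("generationLog"))

#' @rdname OracleResult-class
#' @export
setGeneric("minEnergy", function(x) standardGeneric("minEnergy"))
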