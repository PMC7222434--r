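#' @rdname APCGrid-class
#' @export
setGeneric("cases", function(x) standardGeneric("cases"))

#' @rdname APCGrid-class
#' @export
setGeneric("personYears", function(x) standardGeneric("personYears"))

#' @rdname APCGrid-class
#' @export
setGeneric("gridYears", function(x) standardGeneric("gridYears"))

#' @rdname APCGrid-class
#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))

#' @rdname APCGrid-class
#' @export
setGeneric("widthRatio", function(x) standardGeneric("widthRatio"))

#' @rdname APCGrid-class
#' @export
setGeneric("cohortIndexMap", function(x) standardGeneric("cohortIndexMap"))

#' @rdname AgeGrid-class
#' @export
setGeneric("nAgeGroups", function(x) standardGeneric("nAgeGroups"))

#' @rdname AgeGrid-class
#' @export
setGeneric("ageLowerBounds", function(x) standardGeneric("ageLowerBounds"))

#' @rdname AgeGrid-class
#' @export
setGeneric("ageLabels", function(x) standardGeneric("ageLabels"))

#' @rdname StandardPopulation-class
#' @export
setGeneric("standardWeights", function(x) standardGeneric("standardWeights"))

#' @rdname PosteriorDraws-class
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname PosteriorDraws-class
#' @export
setGeneric("effectDraws", function(x, block) standardGeneric("effectDraws"))

#' @rdname PosteriorDraws-class
#' @export
setGeneric("precisionDraws", function(x) standardGeneric("precisionDraws"))

#' @rdname TrueEffects-class
#' @export
setGeneric("trueLambda", function(x) standardGeneric("trueLambda"))
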