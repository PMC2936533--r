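#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the package's S4 containers: per-replicate homozygous and
#' heterozygous counts and the configuration of an [EnsembleResult-class];
#' heterozygous/fixed counts of a [LineState-class]; the underlying data.frame
#' of a [MatingAssayTable-class]; the grid and P-values of an
#' [UpperLimitScan-class]; the numeric rate of a [RateEstimate-class].
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("finalHom", function(object) standardGeneric("finalHom"))

#' @rdname accessors
#' @export
setGeneric("finalHet", function(object) standardGeneric("finalHet"))

#' @rdname accessors
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))

#' @rdname accessors
#' @export
setGeneric("nHet", function(object) standardGeneric("nHet"))

#' @rdname accessors
#' @export
setGeneric("nFixed", function(object) standardGeneric("nFixed"))

#' @rdname accessors
#' @export
setGeneric("assayCounts", function(object) standardGeneric("assayCounts"))

#' @rdname accessors
#' @export
setGeneric("multipliers", function(object) standardGeneric("multipliers"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("mutationRate", function(object) standardGeneric("mutationRate"))

#' Perkins map distance
#'
#' @param object a [TetradClassCounts-class] object (or see the numeric method
#'   built by [tetradClassCounts()]).
#' @export
setGeneric("perkinsDistance", function(object) standardGeneric("perkinsDistance"))
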