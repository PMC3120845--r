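#' @importFrom BiocGenerics counts
NULL

#' Accessors for hybridDMI result objects
#'
#' Small generics shared across the package's S4 classes: `nTotal()`
#' gives the number of (non-missing) individuals behind a count object,
#' `statistic()`, `dof()` and `pvalue()` extract test components,
#' `contributions()` the signed per-cell chi-square contributions,
#' `viabilities()` the per-locus Haldane relative viabilities of a model
#' prediction, and `jointFreq()`/`marginalFreq()` its frequency tables.
#'
#' @param x an object of the appropriate class.
#' @return the extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname accessors
#' @export
setGeneric("dof", function(x) standardGeneric("dof"))

#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' @rdname accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname accessors
#' @export
setGeneric("viabilities", function(x) standardGeneric("viabilities"))

#' @rdname accessors
#' @export
setGeneric("jointFreq", function(x) standardGeneric("jointFreq"))

#' @rdname accessors
#' @export
setGeneric("marginalFreq", function(x) standardGeneric("marginalFreq"))

#' @rdname accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
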