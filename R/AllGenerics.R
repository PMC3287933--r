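#' @name SnpSetTest-generics
#' @title Generics for SnpSetExperiment accessors and preprocessing
#' @param x object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname SnpSetTest-generics
#' @export
setGeneric("genoMatrix", function(x, ...) standardGeneric("genoMatrix"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("snpSets", function(x, ...) standardGeneric("snpSets"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("computeMaf", function(x, ...) standardGeneric("computeMaf"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("classifyVariantFrequency",
           function(x, ...) standardGeneric("classifyVariantFrequency"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("filterSingletonVariants",
           function(x, ...) standardGeneric("filterSingletonVariants"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("computePopulationPCs",
           function(x, ...) standardGeneric("computePopulationPCs"))

#' @rdname SnpSetTest-generics
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname SnpSetTest-generics
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)
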