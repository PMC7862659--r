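#' @name tuberstab-generics
#' @title Accessor generics for tuberstab result classes
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname tuberstab-generics
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname tuberstab-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname tuberstab-generics
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname tuberstab-generics
#' @export
setGeneric("otuTaxonomy", function(x) standardGeneric("otuTaxonomy"))

#' @rdname tuberstab-generics
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' @rdname tuberstab-generics
#' @export
setGeneric("retainedOtus", function(x) standardGeneric("retainedOtus"))

#' @rdname tuberstab-generics
#' @export
setGeneric("ruleLog", function(x) standardGeneric("ruleLog"))

#' @rdname tuberstab-generics
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname tuberstab-generics
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname tuberstab-generics
#' @export
setGeneric("selectedOtus", function(x) standardGeneric("selectedOtus"))

#' @rdname tuberstab-generics
#' @export
setGeneric("eliminationPath", function(x) standardGeneric("eliminationPath"))

#' @rdname tuberstab-generics
#' @export
setGeneric("importanceRanks", function(x) standardGeneric("importanceRanks"))
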