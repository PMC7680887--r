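#' @rdname genotypeCounts
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname caseControl
#' @export
setGeneric("caseControl", function(x) standardGeneric("caseControl"))

#' @rdname variantSubsets
#' @export
setGeneric("variantSubsets", function(x) standardGeneric("variantSubsets"))

#' @rdname variantSubsets
#' @export
setGeneric("variantSubsets<-",
    function(x, value) standardGeneric("variantSubsets<-"))

#' @rdname alleleFreq
#' @export
setGeneric("alleleFreq",
    function(x, group = c("case", "control")) standardGeneric("alleleFreq"))

#' @rdname vcStat
#' @export
setGeneric("vcStat", function(x, squared = FALSE) standardGeneric("vcStat"))

#' @rdname burdenStat
#' @export
setGeneric("burdenStat", function(x) standardGeneric("burdenStat"))
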