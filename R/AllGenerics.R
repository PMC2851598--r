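#' @rdname GeneAnnotation-class
#' @param x A \code{GeneAnnotation} or \code{NeighborPairs} object.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneAnnotation-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneAnnotation-class
#' @export
setGeneric("geneBiotypes", function(x) standardGeneric("geneBiotypes"))

#' @rdname NeighborPairs-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname NeighborPairs-class
#' @export
setGeneric("pairOrientation", function(x) standardGeneric("pairOrientation"))
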