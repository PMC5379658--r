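#' Extract the expression values of an ExpressionMatrix
#'
#' @param x an \linkS4class{ExpressionMatrix}
#' @return numeric gene-by-sample matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "values"))

#' Value kind of an ExpressionMatrix
#'
#' @param x an \linkS4class{ExpressionMatrix}
#' @return "count", "fpkm" or "log_fpkm"
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname valueKind
#' @export
setMethod("valueKind", "ExpressionMatrix", function(x) x@valueKind)

#' Gene identifiers
#'
#' @param x an \linkS4class{ExpressionMatrix} or \linkS4class{CentroidSet}
#' @return character vector of gene ids (row order)
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname geneIds
#' @export
setMethod("geneIds", "CentroidSet", function(x) rownames(x@values))

#' Sample identifiers
#'
#' @param x an \linkS4class{ExpressionMatrix}
#' @return character vector of sample ids (column order)
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' Subtype names of a CentroidSet
#'
#' @param x a \linkS4class{CentroidSet}
#' @return character vector of subtype names (column order)
#' @export
setGeneric("subtypeNames", function(x) standardGeneric("subtypeNames"))

#' @rdname subtypeNames
#' @export
setMethod("subtypeNames", "CentroidSet", function(x) colnames(x@values))

#' Centroid value matrix
#'
#' @param x a \linkS4class{CentroidSet}
#' @return numeric gene-by-subtype matrix
#' @export
setGeneric("centroidValues", function(x) standardGeneric("centroidValues"))

#' @rdname centroidValues
#' @export
setMethod("centroidValues", "CentroidSet", function(x) x@values)
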