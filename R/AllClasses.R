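#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata SimpleList DataFrame
NULL

.VALUE_KINDS <- c("count", "fpkm", "log_fpkm")

#' Gene-by-sample expression matrix with a value-kind tag
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one dense
#' assay (\code{"values"}) of genes in rows and samples in columns, tagged
#' with the kind of value stored: raw counts, FPKM (fragments per kilobase
#' of transcript per million mapped reads), or log2(FPKM + 1).
#'
#' Validity requires unique, non-empty gene and sample identifiers,
#' non-negative values when \code{valueKind == "count"}, and finite values
#' for the FPKM-derived kinds.
#'
#' @slot valueKind character(1); one of \code{"count"}, \code{"fpkm"},
#'   \code{"log_fpkm"}.
#' @seealso [ExpressionMatrix()] for the constructor, [exprValues()],
#'   [valueKind()], [geneIds()], [sampleIds()].
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(valueKind = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
        msg <- c(msg, sprintf("valueKind must be one of %s",
                              paste(.VALUE_KINDS, collapse = ", ")))
    g <- rownames(object)
    s <- colnames(object)
    if (is.null(g) || anyNA(g) || any(g == ""))
        msg <- c(msg, "gene identifiers must be present and non-empty")
    else if (anyDuplicated(g))
        msg <- c(msg, sprintf("duplicate gene identifier(s): %s",
                              paste(unique(g[duplicated(g)]), collapse = ", ")))
    if (is.null(s) || anyNA(s) || any(s == ""))
        msg <- c(msg, "sample identifiers must be present and non-empty")
    else if (anyDuplicated(s))
        msg <- c(msg, sprintf("duplicate sample identifier(s): %s",
                              paste(unique(s[duplicated(s)]), collapse = ", ")))
    if (length(assays(object)) >= 1L) {
        v <- assay(object, 1L)
        if (!is.numeric(v))
            msg <- c(msg, "values must be numeric")
        else if (identical(object@valueKind, "count") && any(v < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
        else if (object@valueKind %in% c("fpkm", "log_fpkm") && any(!is.finite(v)))
            msg <- c(msg, "fpkm/log_fpkm values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param valueKind one of \code{"count"}, \code{"fpkm"}, \code{"log_fpkm"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' ExpressionMatrix(m, "count")
#' @export
ExpressionMatrix <- function(values, valueKind = c("count", "fpkm", "log_fpkm")) {
    valueKind <- match.arg(valueKind)
    if (!is.matrix(values))
        values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = SimpleList(values = values))
    new("ExpressionMatrix", se, valueKind = valueKind)
}

#' @describeIn ExpressionMatrix show method
#' @param object an ExpressionMatrix
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
                object@valueKind, nrow(object), ncol(object)))
    callNextMethod()
})

#' Reference centroid profiles for nearest-centroid subtyping
#'
#' Genes in rows, subtypes in columns. A sample is classified by the
#' subtype whose centroid its expression profile correlates with most
#' strongly. Validity requires at least 2 genes and 2 subtypes, and unique
#' gene and subtype names.
#'
#' @slot values numeric gene-by-subtype matrix with dimnames.
#' @seealso [CentroidSet()], [subtypeCall()], [reduceCentroids()].
#' @exportClass CentroidSet
setClass("CentroidSet", representation(values = "matrix"))

setValidity("CentroidSet", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "centroid values must be numeric")
    if (nrow(v) < 2L) msg <- c(msg, "a CentroidSet needs >= 2 genes")
    if (ncol(v) < 2L) msg <- c(msg, "a CentroidSet needs >= 2 subtypes")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "gene names must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "subtype names must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CentroidSet
#'
#' @param values numeric matrix of reference profiles; rownames are gene
#'   ids, colnames are subtype names (e.g. BL1, BL2, M, LAR).
#' @return A \linkS4class{CentroidSet}.
#' @export
CentroidSet <- function(values) {
    if (!is.matrix(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("CentroidSet", values = values)
}

#' @describeIn CentroidSet show method
#' @param object a CentroidSet
#' @export
setMethod("show", "CentroidSet", function(object) {
    cat(sprintf("CentroidSet: %d genes x %d subtypes (%s)\n",
                nrow(object@values), ncol(object@values),
                paste(colnames(object@values), collapse = ", ")))
})

#' Single-sample subtype call
#'
#' Correlations of one sample to every centroid, the resulting call
#' (or \code{"UNCLASSIFIED"}), the prediction strength (correlation of the
#' called subtype) and the prediction confidence (difference between the
#' highest and second-highest subtype correlations).
#'
#' @slot sampleId character(1).
#' @slot correlations named numeric, one correlation per subtype.
#' @slot call character(1); a subtype name or \code{"UNCLASSIFIED"}.
#' @slot strength numeric(1); max correlation.
#' @slot confidence numeric(1); top minus second correlation, in [0, 2].
#' @slot nGenesUsed integer(1); centroid genes present in the sample.
#' @exportClass SubtypeResult
setClass("SubtypeResult",
    representation(sampleId = "character", correlations = "numeric",
                   call = "character", strength = "numeric",
                   confidence = "numeric", nGenesUsed = "integer"))

setValidity("SubtypeResult", function(object) {
    msg <- character()
    rho <- object@correlations
    if (is.null(names(rho)) || anyDuplicated(names(rho)))
        msg <- c(msg, "correlations must be uniquely named by subtype")
    if (object@confidence < -1e-12 || object@confidence > 2 + 1e-12)
        msg <- c(msg, "confidence must lie in [0, 2]")
    if (length(rho) && abs(object@strength - max(rho)) > 1e-12)
        msg <- c(msg, "strength must equal the maximum correlation")
    if (!identical(object@call, "UNCLASSIFIED") &&
        length(rho) && !object@call %in% names(rho))
        msg <- c(msg, "call must be a subtype name or UNCLASSIFIED")
    if (length(msg)) msg else TRUE
})

#' @describeIn SubtypeResult show method
#' @param object a SubtypeResult
#' @export
setMethod("show", "SubtypeResult", function(object) {
    cat(sprintf("SubtypeResult for %s: call=%s strength=%.3f confidence=%.3f (%d genes)\n",
                object@sampleId, object@call, object@strength,
                object@confidence, object@nGenesUsed))
    print(round(object@correlations, 3))
})

#' Paired subtype-call concordance report
#'
#' Agreement between paired subtype calls (e.g. FF vs FFPE members of the
#' same tumor) with a two-sided Clopper-Pearson exact binomial confidence
#' interval on the concordance rate.
#'
#' @slot nPairs integer(1); evaluable pairs.
#' @slot nConcordant integer(1).
#' @slot rate numeric(1); nConcordant / nPairs.
#' @slot ciLow,ciHigh numeric(1); exact two-sided bounds at \code{level}.
#' @slot level numeric(1); confidence level.
#' @slot excluded data.frame of excluded pairs with reasons.
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
    representation(nPairs = "integer", nConcordant = "integer",
                   rate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   level = "numeric", excluded = "data.frame"))

setValidity("ConcordanceReport", function(object) {
    msg <- character()
    if (object@nConcordant > object@nPairs)
        msg <- c(msg, "nConcordant cannot exceed nPairs")
    if (!(object@ciLow <= object@rate + 1e-12 &&
          object@rate <= object@ciHigh + 1e-12 &&
          object@ciLow >= -1e-12 && object@ciHigh <= 1 + 1e-12))
        msg <- c(msg, "must satisfy 0 <= ciLow <= rate <= ciHigh <= 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn ConcordanceReport show method
#' @param object a ConcordanceReport
#' @export
setMethod("show", "ConcordanceReport", function(object) {
    cat(sprintf("ConcordanceReport: %d/%d concordant = %.1f%% [CI %.1f%%, %.1f%%] (level %.2f)\n",
                object@nConcordant, object@nPairs, 100 * object@rate,
                100 * object@ciLow, 100 * object@ciHigh, object@level))
    if (nrow(object@excluded))
        cat(sprintf("  %d pair(s) excluded: %s\n", nrow(object@excluded),
                    paste(object@excluded$pair_id, collapse = ", ")))
})
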