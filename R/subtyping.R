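## Nearest-centroid molecular subtyping: FPKM normalization, per-sample
## centroid correlation with prediction strength/confidence, cohort-level
## calling with a subtype distribution, and centroid gene-set reduction.

#' Options controlling subtype calling
#'
#' @param correlationMethod correlation used against the centroids;
#'   \code{"spearman"} (default; rank-based, robust across platforms and
#'   normalizations) or \code{"pearson"}.
#' @param minStrength samples whose maximal centroid correlation falls
#'   below this are called \code{UNCLASSIFIED}; default 0.1.
#' @param minGeneOverlapFraction minimum fraction of centroid genes that
#'   must be present in the sample; default 0.5.
#' @param logTransform apply log2(x + 1) to the sample values before
#'   correlating (intended for FPKM input); default TRUE. Irrelevant for
#'   Spearman, which is rank-invariant.
#' @return a validated list of class \code{SubtypeCallOptions}.
#' @export
subtypeOptions <- function(correlationMethod = c("spearman", "pearson"),
                           minStrength = 0.1,
                           minGeneOverlapFraction = 0.5,
                           logTransform = TRUE) {
    correlationMethod <- match.arg(correlationMethod)
    stopifnot(is.numeric(minStrength), length(minStrength) == 1L,
              minStrength >= 0, minStrength < 1)
    stopifnot(is.numeric(minGeneOverlapFraction),
              length(minGeneOverlapFraction) == 1L,
              minGeneOverlapFraction > 0, minGeneOverlapFraction <= 1)
    structure(list(correlationMethod = correlationMethod,
                   minStrength = minStrength,
                   minGeneOverlapFraction = minGeneOverlapFraction,
                   logTransform = isTRUE(logTransform)),
              class = "SubtypeCallOptions")
}

#' FPKM-normalize a count matrix
#'
#' FPKM(g, s) = count(g, s) * 1e9 / (length(g) * totalCount(s)): reads per
#' kilobase of transcript per million mapped reads. Every gene must have a
#' positive transcript length in the annotation and every sample a positive
#' total count.
#'
#' @param counts \linkS4class{ExpressionMatrix} of kind \code{"count"}.
#' @param annotation annotation data.frame (see [readAnnotation()]) with a
#'   positive \code{transcript_length} for every gene in \code{counts}.
#' @return \linkS4class{ExpressionMatrix} of kind \code{"fpkm"}.
#' @export
fpkmNormalize <- function(counts, annotation) {
    stopifnot(is(counts, "ExpressionMatrix"))
    if (valueKind(counts) != "count")
        stop("fpkmNormalize expects raw counts, got ", valueKind(counts))
    m <- exprValues(counts)
    len <- annotation$transcript_length[match(rownames(m), annotation$gene_id)]
    miss <- rownames(m)[is.na(len) | len <= 0]
    if (length(miss))
        stop("no positive transcript length for gene(s): ",
             paste(utils::head(miss, 10L), collapse = ", "),
             if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L))
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-depth sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    fpkm <- sweep(m / len, 2L, tot, "/") * 1e9
    ExpressionMatrix(fpkm, "fpkm")
}

.prepareVector <- function(x, opts) {
    if (opts$logTransform) log2(x + 1) else x
}

#' Call the molecular subtype of one sample
#'
#' Correlates the sample's expression over the centroid genes (intersection
#' only) with every centroid column and calls the subtype with the highest
#' correlation. Prediction strength is that top correlation; prediction
#' confidence is the difference between the highest and second-highest
#' correlations. A sample whose top correlation falls below
#' \code{opts$minStrength} is called \code{UNCLASSIFIED}; a zero-variance
#' expression vector yields \code{UNCLASSIFIED} with all correlations 0 and
#' a warning. Ties in the top correlation break lexicographically by
#' subtype name (such calls have confidence 0 by construction).
#'
#' @param sampleExpr named numeric vector of expression over genes.
#' @param centroids a \linkS4class{CentroidSet}.
#' @param opts a [subtypeOptions()] list.
#' @param sampleId identifier stored in the result.
#' @return A \linkS4class{SubtypeResult}.
#' @export
subtypeCall <- function(sampleExpr, centroids, opts = subtypeOptions(),
                        sampleId = "sample") {
    stopifnot(is(centroids, "CentroidSet"), is.numeric(sampleExpr))
    if (is.null(names(sampleExpr)))
        stop("sampleExpr must be named by gene id")
    cg <- geneIds(centroids)
    shared <- intersect(cg, names(sampleExpr))
    frac <- length(shared) / length(cg)
    if (frac < opts$minGeneOverlapFraction)
        stop(sprintf(paste0("only %.1f%% of centroid genes present in sample %s ",
                            "(minimum %.1f%%)"),
                     100 * frac, sampleId, 100 * opts$minGeneOverlapFraction))
    x <- .prepareVector(sampleExpr[shared], opts)
    cm <- centroidValues(centroids)[shared, , drop = FALSE]
    subs <- colnames(cm)
    if (stats::sd(x) == 0) {
        warning("zero-variance expression vector for sample ", sampleId,
                "; returning UNCLASSIFIED")
        rho <- stats::setNames(rep(0, length(subs)), subs)
        return(new("SubtypeResult", sampleId = sampleId, correlations = rho,
                   call = "UNCLASSIFIED", strength = 0, confidence = 0,
                   nGenesUsed = length(shared)))
    }
    rho <- vapply(subs, function(s)
        stats::cor(x, cm[, s], method = opts$correlationMethod), numeric(1))
    ord <- order(-rho, subs)     # argmax; lexicographic tie-break
    strength <- rho[ord[1L]]
    confidence <- if (length(rho) >= 2L) strength - rho[ord[2L]] else 0
    call <- if (strength < opts$minStrength) "UNCLASSIFIED" else subs[ord[1L]]
    new("SubtypeResult", sampleId = sampleId, correlations = rho,
        call = call, strength = unname(strength),
        confidence = unname(confidence), nGenesUsed = length(shared))
}

.resultRow <- function(res) {
    row <- data.frame(sample_id = res@sampleId, stringsAsFactors = FALSE)
    for (s in names(res@correlations))
        row[[paste0("rho_", s)]] <- unname(res@correlations[s])
    row$call <- res@call
    row$strength <- res@strength
    row$confidence <- res@confidence
    row$n_genes_used <- res@nGenesUsed
    row
}

#' Subtype every sample of a cohort
#'
#' Applies [subtypeCall()] column-wise. Per-sample failures (e.g.
#' insufficient centroid-gene overlap) are collected into a \code{failed}
#' attribute instead of aborting the cohort.
#'
#' @param mat \linkS4class{ExpressionMatrix} (typically FPKM).
#' @param centroids a \linkS4class{CentroidSet}.
#' @param opts a [subtypeOptions()] list.
#' @return data.frame with one row per successfully called sample
#'   (\code{sample_id}, one \code{rho_<subtype>} column per subtype,
#'   \code{call}, \code{strength}, \code{confidence}, \code{n_genes_used});
#'   attributes: \code{distribution} (named fractions over calls including
#'   UNCLASSIFIED, summing to 1) and \code{failed} (data.frame of
#'   sample_id/error).
#' @export
subtypeCohort <- function(mat, centroids, opts = subtypeOptions()) {
    stopifnot(is(mat, "ExpressionMatrix"))
    if (ncol(mat) == 0L || nrow(mat) == 0L)
        stop("empty expression matrix")
    v <- exprValues(mat)
    rows <- list()
    failed <- data.frame(sample_id = character(), error = character(),
                         stringsAsFactors = FALSE)
    for (s in colnames(v)) {
        res <- tryCatch(
            subtypeCall(v[, s], centroids, opts, sampleId = s),
            error = function(e)
                structure(conditionMessage(e), class = "callError"))
        if (inherits(res, "callError")) {
            failed <- rbind(failed, data.frame(sample_id = s,
                                               error = unclass(res),
                                               stringsAsFactors = FALSE))
        } else {
            rows[[s]] <- .resultRow(res)
        }
    }
    out <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(sample_id = character(), stringsAsFactors = FALSE)
    lev <- c(subtypeNames(centroids), "UNCLASSIFIED")
    dist <- if (nrow(out)) {
        tab <- table(factor(out$call, levels = lev))
        as.numeric(tab) / nrow(out)
    } else rep(NA_real_, length(lev))
    names(dist) <- lev
    attr(out, "distribution") <- dist
    attr(out, "failed") <- failed
    out
}

#' Restrict a centroid set to a reduced gene set
#'
#' Drops the given genes from the centroid matrix, as when removing
#' transcripts that are differential between tissue preparations before
#' re-calling subtypes. Errors when fewer than \code{minSize} genes remain.
#'
#' @param centroids a \linkS4class{CentroidSet}.
#' @param excludeGeneIds character vector of gene ids to drop.
#' @param minSize minimum usable centroid size after reduction; default 50.
#' @return A reduced \linkS4class{CentroidSet} (subtype columns unchanged).
#' @export
reduceCentroids <- function(centroids, excludeGeneIds, minSize = 50L) {
    stopifnot(is(centroids, "CentroidSet"))
    keep <- setdiff(geneIds(centroids), excludeGeneIds)
    if (length(keep) < minSize)
        stop(sprintf("centroid reduction leaves %d genes, below the minimum of %d",
                     length(keep), minSize))
    CentroidSet(centroidValues(centroids)[keep, , drop = FALSE])
}
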