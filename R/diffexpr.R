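## Preparation-differential transcript identification: median-of-ratios
## size factors, a negative-binomial Wald test with method-of-moments
## dispersion, BH adjustment, threshold-based differential flags with
## direction, and the differential-gene-removal correlation experiment.

#' Options for differential-transcript identification
#'
#' @param fcThreshold minimum absolute fold change; default 2.
#' @param fdrThreshold maximum BH-adjusted p-value; default 0.05.
#' @param countThreshold minimum average normalized count; default 4.
#' @param dispersionFloor lower bound on the fitted NB dispersion;
#'   default 1e-8.
#' @return validated list of class \code{DEOptions}.
#' @export
deOptions <- function(fcThreshold = 2, fdrThreshold = 0.05,
                      countThreshold = 4, dispersionFloor = 1e-8) {
    stopifnot(fcThreshold > 0, fdrThreshold > 0, countThreshold > 0,
              dispersionFloor > 0)
    structure(list(fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
                   countThreshold = countThreshold,
                   dispersionFloor = dispersionFloor),
              class = "DEOptions")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples; genes with any zero
#' count are excluded from the reference set. Factors are rescaled to
#' geometric mean 1. When no gene is nonzero in every sample, falls back
#' to total-count ratios with a warning.
#'
#' @param counts \linkS4class{ExpressionMatrix} of counts, or a numeric
#'   matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
    m <- if (is(counts, "ExpressionMatrix")) exprValues(counts) else counts
    stopifnot(is.matrix(m), ncol(m) >= 1L)
    nz <- rowSums(m == 0) == 0L
    if (!any(nz)) {
        warning("no gene has nonzero counts in every sample; ",
                "falling back to total-count size factors")
        sf <- colSums(m)
        if (any(sf <= 0)) stop("sample(s) with zero total count")
    } else {
        ref <- m[nz, , drop = FALSE]
        logGeo <- rowMeans(log(ref))
        sf <- apply(ref, 2L, function(cnt) exp(stats::median(log(cnt) - logGeo)))
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i = min over p_j >= p_i of n * p_j / rank_j,
#' capped at 1, preserving the order of the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bhFdr <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

## Method-of-moments NB dispersion from normalized counts of one
## condition: alpha = (var - mu) / mu^2, floored.
.momDispersion <- function(mat, floor_) {
    mu <- rowMeans(mat)
    v <- apply(mat, 1L, stats::var)
    a <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    pmax(a, floor_)
}

#' Negative-binomial Wald test between two preparations
#'
#' Normalizes by median-of-ratios size factors, estimates a gene-level NB
#' dispersion by method of moments pooled within condition, and tests the
#' log2 fold change (second condition relative to first, pseudocount 0.5)
#' with a Wald z statistic whose standard error follows from the delta
#' method under NB(mu, alpha): Var(log2 mean_c) ~ (mu_c + alpha mu_c^2) /
#' (n_c (mu_c + 0.5)^2 ln(2)^2). Two-sided p from the normal tail, BH
#' q-values, and threshold-based differential flags with enrichment
#' direction.
#'
#' Genes with all-zero counts get p = 1, fold change 0 and a flag. Pairing
#' information is not used by the test itself (see
#' [removeAndRecorrelate()] for the paired correlation experiment).
#'
#' @param counts \linkS4class{ExpressionMatrix} of counts over both
#'   conditions' samples.
#' @param condition factor/character of length ncol(counts) with exactly
#'   two levels; the first level is the reference (FF), the second the
#'   test condition (FFPE): positive log2 fold changes mean enrichment in
#'   the second level. At least 2 samples per condition.
#' @param opts a [deOptions()] list.
#' @return data.frame: gene_id, base_mean, log2_fc, se, p_value, q_value,
#'   is_differential, enriched_in (first level, second level, or "none"),
#'   all_zero.
#' @export
nbWaldTest <- function(counts, condition, opts = deOptions()) {
    m <- if (is(counts, "ExpressionMatrix")) exprValues(counts) else counts
    condition <- as.factor(as.character(condition))
    if (nlevels(condition) != 2L)
        stop("condition must have exactly two levels")
    if (length(condition) != ncol(m))
        stop("condition length must match the number of samples")
    if (any(table(condition) < 2L))
        stop("need at least 2 samples per condition")
    lvl <- levels(condition)
    sf <- computeSizeFactors(m)
    norm <- sweep(m, 2L, sf, "/")
    g1 <- norm[, condition == lvl[1L], drop = FALSE]
    g2 <- norm[, condition == lvl[2L], drop = FALSE]
    n1 <- ncol(g1); n2 <- ncol(g2)
    mu1 <- rowMeans(g1); mu2 <- rowMeans(g2)
    a1 <- .momDispersion(g1, opts$dispersionFloor)
    a2 <- .momDispersion(g2, opts$dispersionFloor)
    alpha <- ((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2)
    lfc <- log2((mu2 + 0.5) / (mu1 + 0.5))
    ln2sq <- log(2)^2
    varTerm <- function(mu, a, n) (mu + a * mu^2) / (n * (mu + 0.5)^2 * ln2sq)
    se <- sqrt(varTerm(mu1, alpha, n1) + varTerm(mu2, alpha, n2))
    z <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    allZero <- mu1 == 0 & mu2 == 0
    p[allZero] <- 1
    lfc[allZero] <- 0
    q <- bhFdr(p)
    baseMean <- rowMeans(norm)
    isDiff <- q <= opts$fdrThreshold &
        abs(lfc) >= log2(opts$fcThreshold) &
        baseMean > opts$countThreshold
    enriched <- rep("none", nrow(m))
    enriched[isDiff & lfc > 0] <- lvl[2L]
    enriched[isDiff & lfc < 0] <- lvl[1L]
    data.frame(gene_id = rownames(m), base_mean = baseMean, log2_fc = lfc,
               se = se, p_value = p, q_value = q, is_differential = isDiff,
               enriched_in = enriched, all_zero = allZero,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired correlation before and after removing differential transcripts
#'
#' Computes per-pair Spearman correlations on all genes and again on the
#' complement of the differential set, reporting the per-pair deltas and a
#' Wilcoxon signed-rank test on them (two-sided). With a single pair the
#' deltas are reported and the significance is marked not computable.
#'
#' @param mat \linkS4class{ExpressionMatrix} over both members of each
#'   pair.
#' @param deTable [nbWaldTest()] result (columns gene_id,
#'   is_differential), or any data.frame with those columns.
#' @param design paired design data.frame.
#' @param minComplement minimum genes that must remain after removal;
#'   default 10.
#' @return list(perPair = data.frame(pair_id, rho_before, rho_after,
#'   delta), meanBefore, meanAfter, p_value (NA when not computable),
#'   nRemoved).
#' @export
removeAndRecorrelate <- function(mat, deTable, design, minComplement = 10L) {
    stopifnot(all(c("gene_id", "is_differential") %in% names(deTable)))
    diffGenes <- deTable$gene_id[deTable$is_differential]
    allGenes <- geneIds(mat)
    keep <- setdiff(allGenes, diffGenes)
    if (length(keep) < minComplement)
        stop(sprintf("only %d non-differential genes remain (minimum %d)",
                     length(keep), minComplement))
    before <- pairedExpressionCorrelation(mat, design)
    after <- pairedExpressionCorrelation(mat, design, geneSubset = keep)
    perPair <- data.frame(pair_id = before$pair_id,
                          rho_before = before$rho, rho_after = after$rho,
                          delta = after$rho - before$rho,
                          stringsAsFactors = FALSE)
    ok <- stats::complete.cases(perPair[, c("rho_before", "rho_after")])
    pv <- if (sum(ok) >= 2L && any(perPair$delta[ok] != 0)) {
        suppressWarnings(stats::wilcox.test(perPair$rho_after[ok],
                                            perPair$rho_before[ok],
                                            paired = TRUE))$p.value
    } else NA_real_
    list(perPair = perPair,
         meanBefore = mean(perPair$rho_before[ok]),
         meanAfter = mean(perPair$rho_after[ok]),
         p_value = pv,
         nRemoved = length(intersect(diffGenes, allGenes)))
}
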