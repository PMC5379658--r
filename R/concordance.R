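## Paired subtype-call agreement statistics: exact binomial intervals on
## the concordance rate, prediction-confidence vs accuracy curves, the
## confidence cutoff achieving a target accuracy, and paired expression
## correlations with a rank-based group comparison.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion by Beta-quantile
#' inversion of the binomial tails: with alpha = 1 - level, the lower
#' bound is qbeta(alpha/2; k, n - k + 1) (0 when k = 0) and the upper
#' bound qbeta(1 - alpha/2; k + 1, n - k) (1 when k = n).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level in (0, 1); default 0.95.
#' @return named numeric c(low, high).
#' @examples
#' clopperPearson(89, 98)   # c(0.833, 0.957) to 3 decimals
#' @export
clopperPearson <- function(k, n, level = 0.95) {
    stopifnot(length(k) == 1L, length(n) == 1L, length(level) == 1L)
    if (!is.finite(n) || n < 1 || n != round(n))
        stop("n must be a positive integer")
    if (!is.finite(k) || k < 0 || k > n || k != round(k))
        stop("k must be an integer in [0, n]")
    if (level <= 0 || level >= 1)
        stop("level must lie in (0, 1)")
    a <- 1 - level
    low <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
    high <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
    c(low = low, high = high)
}

.joinPairs <- function(resultsA, resultsB, design) {
    need <- c("sample_id", "call")
    for (nm in need) {
        if (!nm %in% names(resultsA) || !nm %in% names(resultsB))
            stop("result tables need columns sample_id and call")
    }
    ia <- match(design$sample_a_id, resultsA$sample_id)
    ib <- match(design$sample_b_id, resultsB$sample_id)
    bad <- is.na(ia) | is.na(ib)
    if (any(bad))
        stop("no result for pair(s): ",
             paste(design$pair_id[bad], collapse = ", "))
    data.frame(pair_id = design$pair_id,
               call_a = resultsA$call[ia],
               call_b = resultsB$call[ib],
               confidence_a = if ("confidence" %in% names(resultsA))
                   resultsA$confidence[ia] else NA_real_,
               confidence_b = if ("confidence" %in% names(resultsB))
                   resultsB$confidence[ib] else NA_real_,
               stringsAsFactors = FALSE)
}

#' Concordance of paired subtype calls
#'
#' A pair is concordant when its two members received an identical call.
#' By default pairs with \code{UNCLASSIFIED} on either side are excluded
#' from the evaluable set (and listed with reasons); with
#' \code{excludeUnclassified = FALSE} such pairs count as discordant unless
#' both members are \code{UNCLASSIFIED}.
#'
#' @param resultsA,resultsB [subtypeCohort()] result tables for the two
#'   preparations/platforms.
#' @param design paired design data.frame (see [readDesign()]).
#' @param excludeUnclassified exclude pairs with an UNCLASSIFIED member;
#'   default TRUE.
#' @param level confidence level of the exact interval; default 0.95.
#' @return A \linkS4class{ConcordanceReport}.
#' @export
concordance <- function(resultsA, resultsB, design,
                        excludeUnclassified = TRUE, level = 0.95) {
    design <- validateDesign(design)
    pairs <- .joinPairs(resultsA, resultsB, design)
    uncA <- pairs$call_a == "UNCLASSIFIED"
    uncB <- pairs$call_b == "UNCLASSIFIED"
    if (excludeUnclassified) {
        excl <- uncA | uncB
        excluded <- data.frame(
            pair_id = pairs$pair_id[excl],
            reason = ifelse(uncA[excl] & uncB[excl],
                            "both members UNCLASSIFIED",
                            ifelse(uncA[excl], "member A UNCLASSIFIED",
                                   "member B UNCLASSIFIED")),
            stringsAsFactors = FALSE)
        eval_ <- pairs[!excl, , drop = FALSE]
    } else {
        excluded <- data.frame(pair_id = character(), reason = character(),
                               stringsAsFactors = FALSE)
        eval_ <- pairs
    }
    n <- nrow(eval_)
    if (n == 0L) stop("no evaluable pairs")
    conc <- eval_$call_a == eval_$call_b
    k <- sum(conc)
    ci <- clopperPearson(k, n, level)
    new("ConcordanceReport", nPairs = as.integer(n),
        nConcordant = as.integer(k), rate = k / n,
        ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
        level = level, excluded = excluded)
}

#' Accuracy as a function of prediction confidence
#'
#' For every cutoff in the grid, restricts to pairs whose members both
#' have prediction confidence >= cutoff (a pair's confidence is the
#' minimum of its two members', the conservative combination) and reports
#' the concordant fraction among them. Cutoffs retaining no pairs are
#' reported with \code{NA} accuracy. Pairs with an UNCLASSIFIED member are
#' excluded throughout, so the cutoff-0 point reproduces the overall
#' [concordance()] rate.
#'
#' @param resultsA,resultsB result tables as in [concordance()].
#' @param design paired design data.frame.
#' @param cutoffGrid strictly increasing cutoffs within [0, 2];
#'   default seq(0, 1, 0.01).
#' @return data.frame (cutoff, n_pairs, n_concordant, accuracy); n_pairs is
#'   non-increasing in cutoff.
#' @export
accuracyVsConfidence <- function(resultsA, resultsB, design,
                                 cutoffGrid = seq(0, 1, by = 0.01)) {
    if (!length(cutoffGrid)) stop("empty cutoff grid")
    if (any(diff(cutoffGrid) <= 0) || any(cutoffGrid < 0 | cutoffGrid > 2))
        stop("cutoff grid must be strictly increasing within [0, 2]")
    design <- validateDesign(design)
    pairs <- .joinPairs(resultsA, resultsB, design)
    pairs <- pairs[pairs$call_a != "UNCLASSIFIED" &
                   pairs$call_b != "UNCLASSIFIED", , drop = FALSE]
    conf <- pmin(pairs$confidence_a, pairs$confidence_b)
    conc <- pairs$call_a == pairs$call_b
    out <- data.frame(cutoff = cutoffGrid,
                      n_pairs = NA_integer_,
                      n_concordant = NA_integer_,
                      accuracy = NA_real_)
    for (i in seq_along(cutoffGrid)) {
        sel <- conf >= cutoffGrid[i]
        out$n_pairs[i] <- sum(sel)
        out$n_concordant[i] <- sum(conc[sel])
        out$accuracy[i] <- if (any(sel)) mean(conc[sel]) else NA_real_
    }
    stopifnot(all(diff(out$n_pairs) <= 0))
    out
}

#' Smallest confidence cutoff reaching a target accuracy
#'
#' Scans a [accuracyVsConfidence()] curve for the smallest cutoff whose
#' accuracy is at least \code{target} while still retaining at least
#' \code{minPairs} pairs (near-empty strata are not trusted).
#'
#' @param curve data.frame from [accuracyVsConfidence()].
#' @param target target accuracy; default 0.95.
#' @param minPairs minimum pairs backing a valid curve point; default 5.
#' @return the cutoff, or \code{NA_real_} when never reached.
#' @export
minConfidenceForAccuracy <- function(curve, target = 0.95, minPairs = 5L) {
    if (!nrow(curve)) stop("empty curve")
    ok <- !is.na(curve$accuracy) & curve$accuracy >= target &
        curve$n_pairs >= minPairs
    if (!any(ok)) return(NA_real_)
    curve$cutoff[which(ok)[1L]]
}

#' Per-pair expression correlation
#'
#' Spearman rank correlation of the two members' expression vectors for
#' every design pair, optionally restricted to a gene subset. Pairs with a
#' zero-variance member get \code{NA} with a note.
#'
#' @param mat \linkS4class{ExpressionMatrix} holding both members of every
#'   pair.
#' @param design paired design data.frame.
#' @param geneSubset optional character vector of gene ids to restrict to.
#' @return data.frame (pair_id, rho, n_genes, note).
#' @export
pairedExpressionCorrelation <- function(mat, design, geneSubset = NULL) {
    stopifnot(is(mat, "ExpressionMatrix"))
    design <- validateDesign(design)
    v <- exprValues(mat)
    if (!is.null(geneSubset)) {
        keep <- intersect(rownames(v), geneSubset)
        v <- v[keep, , drop = FALSE]
    }
    if (nrow(v) < 3L)
        stop("need at least 3 shared genes, have ", nrow(v))
    miss <- setdiff(c(design$sample_a_id, design$sample_b_id), colnames(v))
    if (length(miss))
        stop("sample(s) absent from matrix: ", paste(miss, collapse = ", "))
    res <- data.frame(pair_id = design$pair_id, rho = NA_real_,
                      n_genes = nrow(v), note = "",
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(design))) {
        a <- v[, design$sample_a_id[i]]
        b <- v[, design$sample_b_id[i]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
            res$note[i] <- "zero-variance member; rho undefined"
            next
        }
        res$rho[i] <- stats::cor(a, b, method = "spearman")
    }
    res
}

#' Compare two groups of correlations by Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison, e.g. of per-pair
#' correlations between sequencing platforms or specimen age classes. Uses
#' the exact distribution when min(n1, n2) <= 8 and there are no ties, and
#' the normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors (NAs dropped); both must be nonempty.
#' @param exactMaxN largest min(n1, n2) for which the exact branch is
#'   taken; default 8.
#' @return list(statistic = U of the first sample, p_value, method).
#' @export
compareGroups <- function(x, y, exactMaxN = 8L) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("both groups must be nonempty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- min(length(x), length(y)) <= exactMaxN && !ties
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "exact" else "normal approximation with tie correction")
}
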