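## What kind of transcripts differ between preparations: class-wise
## accounting, transcript-length bias, exon-level 3' positional bias,
## hypergeometric gene-set overrepresentation, and read-category / rRNA
## summaries.

#' Class-wise accounting of differential transcripts
#'
#' Tabulates, per transcript class, the number of transcripts, the number
#' differential (and % of the class), and the split into FFPE-enriched and
#' FF-enriched (each as % of the class's differential transcripts). A
#' totals row is appended. Row identities (differential = FFPE + FF
#' enriched; column sums equal totals) are asserted on every call.
#'
#' @param deTable data.frame with columns gene_id, is_differential,
#'   enriched_in (values among the condition labels / "none").
#' @param annotation annotation data.frame covering every differential
#'   gene.
#' @param ffLabel,ffpeLabel values of \code{enriched_in} denoting FF- and
#'   FFPE-enrichment; defaults "FF" and "FFPE".
#' @return data.frame with one row per class plus a "Total" row: columns
#'   transcript_class, n_all, n_differential, pct_differential, n_ffpe,
#'   pct_ffpe, n_ff, pct_ff.
#' @export
classTable <- function(deTable, annotation, ffLabel = "FF", ffpeLabel = "FFPE") {
    idx <- match(deTable$gene_id, annotation$gene_id)
    un <- deTable$gene_id[is.na(idx) & deTable$is_differential]
    if (length(un))
        stop("unannotated differential gene(s): ",
             paste(utils::head(un, 10L), collapse = ", "),
             if (length(un) > 10L) sprintf(" (and %d more)", length(un) - 10L))
    cls <- annotation$transcript_class[idx]
    classes <- transcriptClasses()
    rows <- lapply(classes, function(cl) {
        sel <- !is.na(cls) & cls == cl
        nAll <- sum(sel)
        nDiff <- sum(sel & deTable$is_differential)
        nFFPE <- sum(sel & deTable$enriched_in == ffpeLabel)
        nFF <- sum(sel & deTable$enriched_in == ffLabel)
        data.frame(transcript_class = cl, n_all = nAll,
                   n_differential = nDiff,
                   pct_differential = if (nAll) 100 * nDiff / nAll else 0,
                   n_ffpe = nFFPE,
                   pct_ffpe = if (nDiff) 100 * nFFPE / nDiff else 0,
                   n_ff = nFF,
                   pct_ff = if (nDiff) 100 * nFF / nDiff else 0,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tot <- data.frame(transcript_class = "Total",
                      n_all = sum(tab$n_all),
                      n_differential = sum(tab$n_differential),
                      pct_differential = if (sum(tab$n_all))
                          100 * sum(tab$n_differential) / sum(tab$n_all) else 0,
                      n_ffpe = sum(tab$n_ffpe),
                      pct_ffpe = if (sum(tab$n_differential))
                          100 * sum(tab$n_ffpe) / sum(tab$n_differential) else 0,
                      n_ff = sum(tab$n_ff),
                      pct_ff = if (sum(tab$n_differential))
                          100 * sum(tab$n_ff) / sum(tab$n_differential) else 0,
                      stringsAsFactors = FALSE)
    out <- rbind(tab, tot)
    stopifnot(all(out$n_differential == out$n_ffpe + out$n_ff),
              tot$n_all == sum(tab$n_all),
              tot$n_differential == sum(tab$n_differential))
    out
}

#' Transcript-length bias of differential transcripts
#'
#' Summarizes transcript length (bp) for four groups — all genes in the DE
#' table, non-differential, FF-enriched and FFPE-enriched — and tests
#' FF-enriched vs FFPE-enriched lengths with a two-sided Mann-Whitney U
#' test on log10 length. When either enriched group has fewer than 3
#' genes the test is skipped with a notice.
#'
#' @inheritParams classTable
#' @return list(summary = data.frame(group, n, median_bp, mean_bp),
#'   p_value, note).
#' @export
lengthBias <- function(deTable, annotation, ffLabel = "FF", ffpeLabel = "FFPE") {
    len <- annotation$transcript_length[match(deTable$gene_id,
                                              annotation$gene_id)]
    if (anyNA(len))
        stop("length missing for gene(s): ",
             paste(utils::head(deTable$gene_id[is.na(len)], 10L),
                   collapse = ", "))
    groups <- list(all = rep(TRUE, nrow(deTable)),
                   non_differential = !deTable$is_differential,
                   ff_enriched = deTable$enriched_in == ffLabel,
                   ffpe_enriched = deTable$enriched_in == ffpeLabel)
    summary_ <- do.call(rbind, lapply(names(groups), function(g) {
        l <- len[groups[[g]]]
        data.frame(group = g, n = length(l),
                   median_bp = if (length(l)) stats::median(l) else NA_real_,
                   mean_bp = if (length(l)) mean(l) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    lff <- len[groups$ff_enriched]
    lffpe <- len[groups$ffpe_enriched]
    if (length(lff) < 3L || length(lffpe) < 3L) {
        return(list(summary = summary_, p_value = NA_real_,
                    note = "enriched group(s) below 3 genes; test skipped"))
    }
    cmp <- compareGroups(log10(lffpe), log10(lff))
    list(summary = summary_, p_value = cmp$p_value, note = "")
}

#' Exon-level 3' positional bias
#'
#' For every gene with at least \code{minExons} exons, the bias statistic
#' per sample group is the Spearman correlation between exon index (5' to
#' 3') and the group-mean normalized exon count; positive values mean
#' coverage piles toward the 3' end, the signature of poly-A selection on
#' partially degraded RNA. Each sample's exon counts are normalized to its
#' total before averaging, so the statistic is invariant to per-sample
#' scaling.
#'
#' @param exonCounts \linkS4class{ExpressionMatrix} over exon ids.
#' @param geneModel data.frame (gene_id, exon_id, exon_index) ordering
#'   exons 5' to 3' within each gene.
#' @param sampleGroups named list of character vectors of sample ids
#'   (e.g. list(FF = ..., FFPE = ...)).
#' @param minExons minimum exons per evaluated gene; default 4.
#' @return data.frame with one row per evaluated gene: gene_id, n_exons,
#'   one \code{bias_<group>} column per group, and \code{diff_<g1>_<g2>}
#'   for the first two groups; attribute \code{n_skipped} counts genes
#'   below the exon minimum.
#' @export
exonPositionBias <- function(exonCounts, geneModel, sampleGroups,
                             minExons = 4L) {
    stopifnot(is(exonCounts, "ExpressionMatrix"),
              all(c("gene_id", "exon_id", "exon_index") %in% names(geneModel)),
              is.list(sampleGroups), length(sampleGroups) >= 1L)
    v <- exprValues(exonCounts)
    tot <- colSums(v)
    if (any(tot <= 0))
        stop("sample(s) with zero exon counts: ",
             paste(colnames(v)[tot <= 0], collapse = ", "))
    normed <- sweep(v, 2L, tot, "/")
    genes <- split(geneModel, geneModel$gene_id)
    rows <- list()
    skipped <- 0L
    for (g in names(genes)) {
        gm <- genes[[g]][order(genes[[g]]$exon_index), , drop = FALSE]
        ex <- intersect(gm$exon_id, rownames(normed))
        if (length(ex) < minExons) { skipped <- skipped + 1L; next }
        gm <- gm[gm$exon_id %in% ex, , drop = FALSE]
        row <- data.frame(gene_id = g, n_exons = nrow(gm),
                          stringsAsFactors = FALSE)
        for (grp in names(sampleGroups)) {
            sel <- intersect(sampleGroups[[grp]], colnames(normed))
            if (!length(sel)) stop("no samples found for group ", grp)
            meanCnt <- rowMeans(normed[gm$exon_id, sel, drop = FALSE])
            row[[paste0("bias_", grp)]] <-
                if (stats::sd(meanCnt) == 0) 0
                else stats::cor(gm$exon_index, meanCnt, method = "spearman")
        }
        rows[[g]] <- row
    }
    out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else data.frame(gene_id = character(), n_exons = integer())
    if (length(sampleGroups) >= 2L && nrow(out)) {
        g1 <- names(sampleGroups)[1L]; g2 <- names(sampleGroups)[2L]
        out[[paste0("diff_", g1, "_", g2)]] <-
            out[[paste0("bias_", g1)]] - out[[paste0("bias_", g2)]]
    }
    attr(out, "n_skipped") <- skipped
    out
}

#' Gene-set overrepresentation by hypergeometric test
#'
#' For each named set, p = P(X >= k) where X is hypergeometric with
#' universe size N, set size K (after intersecting the set with the
#' universe) and query size n; k is the observed overlap. q-values are BH
#' across the sets of the collection; rows are sorted by p.
#'
#' @param queryGenes character vector; must be a subset of the universe.
#' @param collections named list of character vectors (gene sets).
#' @param universe character vector of all eligible genes.
#' @return data.frame (set_name, set_size, overlap_k, p_value, q_value)
#'   sorted by p_value.
#' @export
overlapEnrichment <- function(queryGenes, collections, universe) {
    universe <- unique(universe)
    queryGenes <- unique(queryGenes)
    if (!length(universe)) stop("empty universe")
    if (!length(queryGenes)) stop("empty query")
    if (!all(queryGenes %in% universe))
        stop("query genes outside the universe: ",
             paste(utils::head(setdiff(queryGenes, universe), 5L),
                   collapse = ", "))
    if (!length(collections) || is.null(names(collections)))
        stop("collections must be a named list of gene sets")
    N <- length(universe); n <- length(queryGenes)
    rows <- lapply(names(collections), function(nm) {
        set <- intersect(unique(collections[[nm]]), universe)
        K <- length(set)
        k <- length(intersect(set, queryGenes))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set_name = nm, set_size = K, overlap_k = k,
                   p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhFdr(out$p_value)
    out[order(out$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("GMT file is empty: ", path)
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
        if (length(f) < 3L)
            stop("GMT line with fewer than 3 fields: ", f[1L])
        unique(f[-(1:2)])
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    sets
}

#' Read-category percentages and FF vs FFPE comparison
#'
#' On-target, intronic and intergenic reads are expressed as percentages
#' of mapped reads; unmapped reads as a percentage of total reads
#' (mapped + unmapped). When a grouping is supplied, each category is
#' compared between the first two groups with a Mann-Whitney U test.
#'
#' @param categories data.frame with columns sample_id, on_target,
#'   intronic, intergenic, unmapped (non-negative counts).
#' @param groups optional named list of sample-id vectors (e.g.
#'   list(FF = ..., FFPE = ...)).
#' @return list(percentages = data.frame per sample, tests = data.frame
#'   (category, p_value) or NULL).
#' @export
readCategorySummary <- function(categories, groups = NULL) {
    need <- c("sample_id", "on_target", "intronic", "intergenic", "unmapped")
    miss <- setdiff(need, names(categories))
    if (length(miss))
        stop("categories missing column(s): ", paste(miss, collapse = ", "))
    cnt <- categories[, c("on_target", "intronic", "intergenic", "unmapped")]
    if (any(as.matrix(cnt) < 0)) stop("category counts must be non-negative")
    mapped <- categories$on_target + categories$intronic + categories$intergenic
    if (any(mapped <= 0))
        stop("zero mapped reads for sample(s): ",
             paste(categories$sample_id[mapped <= 0], collapse = ", "))
    total <- mapped + categories$unmapped
    pct <- data.frame(sample_id = categories$sample_id,
                      pct_on_target = 100 * categories$on_target / mapped,
                      pct_intronic = 100 * categories$intronic / mapped,
                      pct_intergenic = 100 * categories$intergenic / mapped,
                      pct_unmapped = 100 * categories$unmapped / total,
                      stringsAsFactors = FALSE)
    tests <- NULL
    if (!is.null(groups)) {
        if (length(groups) < 2L || is.null(names(groups)))
            stop("groups must be a named list with at least two entries")
        g1 <- pct[pct$sample_id %in% groups[[1L]], , drop = FALSE]
        g2 <- pct[pct$sample_id %in% groups[[2L]], , drop = FALSE]
        if (!nrow(g1) || !nrow(g2))
            stop("group(s) with no matching samples")
        cats <- c("pct_on_target", "pct_intronic", "pct_intergenic",
                  "pct_unmapped")
        tests <- do.call(rbind, lapply(cats, function(cc) {
            pv <- if (stats::sd(c(g1[[cc]], g2[[cc]])) == 0) 1
                  else compareGroups(g1[[cc]], g2[[cc]])$p_value
            data.frame(category = sub("^pct_", "", cc), p_value = pv,
                       stringsAsFactors = FALSE)
        }))
    }
    list(percentages = pct, tests = tests)
}

#' Fraction of counts in ribosomal-RNA genes
#'
#' Per-sample ratio of counts assigned to rRNA-class genes to total
#' counts, a measure of ribosomal-depletion efficiency.
#'
#' @param counts \linkS4class{ExpressionMatrix} of counts.
#' @param annotation annotation data.frame covering every counted gene.
#' @return named numeric vector in [0, 1], one value per sample.
#' @export
rrnaFraction <- function(counts, annotation) {
    stopifnot(is(counts, "ExpressionMatrix"))
    m <- exprValues(counts)
    cls <- annotation$transcript_class[match(rownames(m), annotation$gene_id)]
    if (anyNA(cls))
        stop("annotation missing for gene(s): ",
             paste(utils::head(rownames(m)[is.na(cls)], 10L), collapse = ", "))
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-depth sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    rr <- colSums(m[cls == "rRNA", , drop = FALSE])
    rr / tot
}
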