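## Readers and writers for the plain-text interchange formats: merged
## count/FPKM matrices, HTSeq-count per-sample files, gene annotation
## tables, centroid matrices and paired-sample design tables.

## HTSeq-count appends bookkeeping rows that are not genes.
.HTSEQ_SPECIAL <- c("__no_feature", "__ambiguous", "__too_low_aQual",
                    "__not_aligned", "__alignment_not_unique")

#' Transcript class vocabulary
#'
#' The fixed set of transcript classes used for class-wise accounting of
#' preparation-differential transcripts (ribosomal, small nuclear/nucleolar,
#' antisense, lincRNA, pseudogene, protein coding, ...). Annotation loaders
#' reject classes outside this vocabulary.
#'
#' @return character vector of the 15 class tokens.
#' @export
transcriptClasses <- function() {
    c("rRNA", "misc_RNA", "snoRNA", "snRNA", "sense_intronic",
      "three_prime_overlapping_ncRNA", "miRNA", "mt_RNA", "pseudogene",
      "antisense", "sense_overlapping", "lincRNA", "processed_transcript",
      "polymorphic_pseudogene", "protein_coding")
}

## Accepts human-readable variants ("protein coding", "3' overlapping
## ncRNA", "Misc RNA", "mt RNA") and normalizes to the canonical token.
.normalizeClass <- function(x) {
    y <- trimws(x)
    y <- gsub("[′']", "three_prime", y)
    y <- gsub("[ -]+", "_", y)
    y <- sub("^three_prime_?overlapping_?ncrna$", "three_prime_overlapping_ncRNA",
             y, ignore.case = TRUE)
    canon <- transcriptClasses()
    idx <- match(tolower(y), tolower(canon))
    out <- canon[idx]
    names(out) <- NULL
    bad <- is.na(out) & !is.na(x)
    if (any(bad))
        stop("unknown transcript class(es): ",
             paste(unique(x[bad]), collapse = ", "),
             "; allowed classes are: ", paste(canon, collapse = ", "))
    out
}

#' Default Ensembl gene_biotype to transcript-class mapping
#'
#' Maps Ensembl-style \code{gene_biotype} values (v75-era vocabulary) to
#' the class vocabulary of [transcriptClasses()]. Pseudogene flavours
#' collapse into \code{pseudogene}, mitochondrial rRNA/tRNA into
#' \code{mt_RNA}, and immunoglobulin/T-cell-receptor genes into
#' \code{protein_coding}. Override by passing a modified copy to
#' [annotationFromGTF()].
#'
#' @return named character vector: names are biotypes, values are classes.
#' @export
defaultBiotypeMap <- function() {
    c(rRNA = "rRNA",
      misc_RNA = "misc_RNA",
      snoRNA = "snoRNA",
      snRNA = "snRNA",
      sense_intronic = "sense_intronic",
      "3prime_overlapping_ncrna" = "three_prime_overlapping_ncRNA",
      miRNA = "miRNA",
      Mt_rRNA = "mt_RNA",
      Mt_tRNA = "mt_RNA",
      pseudogene = "pseudogene",
      processed_pseudogene = "pseudogene",
      unprocessed_pseudogene = "pseudogene",
      transcribed_processed_pseudogene = "pseudogene",
      transcribed_unprocessed_pseudogene = "pseudogene",
      unitary_pseudogene = "pseudogene",
      IG_C_pseudogene = "pseudogene",
      IG_J_pseudogene = "pseudogene",
      IG_V_pseudogene = "pseudogene",
      TR_J_pseudogene = "pseudogene",
      TR_V_pseudogene = "pseudogene",
      antisense = "antisense",
      sense_overlapping = "sense_overlapping",
      lincRNA = "lincRNA",
      processed_transcript = "processed_transcript",
      polymorphic_pseudogene = "polymorphic_pseudogene",
      protein_coding = "protein_coding",
      IG_C_gene = "protein_coding",
      IG_D_gene = "protein_coding",
      IG_J_gene = "protein_coding",
      IG_V_gene = "protein_coding",
      TR_C_gene = "protein_coding",
      TR_D_gene = "protein_coding",
      TR_J_gene = "protein_coding",
      TR_V_gene = "protein_coding")
}

.readTsv <- function(path, what) {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    if (file.size(path) == 0L) stop(what, " file is empty: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) stop(what, " file has no data rows: ", path)
    df
}

#' Read an expression matrix
#'
#' Reads either a merged tab-separated matrix (first column gene id, header
#' row of sample ids) or a directory of two-column HTSeq-count-style
#' per-sample files (no header; filename minus extension is the sample id).
#' Per-sample files are merged on the union of gene ids; genes absent from
#' a file are filled with 0 and a warning is emitted. HTSeq bookkeeping
#' rows (\code{__no_feature} etc.) are stripped and reported via a message.
#'
#' @param path file or directory path.
#' @param valueKind value kind tag for the result; per-sample directories
#'   must be \code{"count"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, valueKind = c("count", "fpkm", "log_fpkm")) {
    valueKind <- match.arg(valueKind)
    if (dir.exists(path)) {
        if (valueKind != "count")
            stop("per-sample count directories only hold raw counts")
        return(.readHTSeqDir(path))
    }
    df <- .readTsv(path, "expression")
    genes <- trimws(as.character(df[[1L]]))
    keep <- !genes %in% .HTSEQ_SPECIAL
    if (!all(keep)) {
        message("stripped ", sum(!keep), " HTSeq special row(s): ",
                paste(genes[!keep], collapse = ", "))
        df <- df[keep, , drop = FALSE]
        genes <- genes[keep]
    }
    if (anyDuplicated(genes))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        bad <- which(is.na(v) & !is.na(vals[[j]]) & trimws(vals[[j]]) != "NA")
        if (length(bad))
            stop(sprintf("non-numeric cell at row %d (gene %s), column '%s'",
                         bad[1L], genes[bad[1L]], names(vals)[j]))
        vals[[j]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
    ExpressionMatrix(m, valueKind)
}

.readHTSeqDir <- function(path) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (!length(files)) stop("no per-sample count files in ", path)
    tabs <- lapply(files, function(f) {
        df <- utils::read.delim(f, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE)
        if (ncol(df) != 2L)
            stop("per-sample count file must have two columns: ", f)
        g <- trimws(as.character(df[[1L]]))
        sp <- g %in% .HTSEQ_SPECIAL
        if (any(sp))
            message("stripped ", sum(sp), " HTSeq special row(s) from ",
                    basename(f))
        g <- g[!sp]
        if (anyDuplicated(g))
            stop("duplicate gene id(s) in ", f, ": ",
                 paste(unique(g[duplicated(g)]), collapse = ", "))
        v <- suppressWarnings(as.numeric(df[[2L]][!sp]))
        if (anyNA(v))
            stop("non-numeric count in ", f, " (gene ",
                 g[which(is.na(v))[1L]], ")")
        stats::setNames(v, g)
    })
    samples <- sub("\\.[^.]*$", "", basename(files))
    allGenes <- sort(unique(unlist(lapply(tabs, names))))
    m <- matrix(0, length(allGenes), length(tabs),
                dimnames = list(allGenes, samples))
    filled <- 0L
    for (j in seq_along(tabs)) {
        m[names(tabs[[j]]), j] <- tabs[[j]]
        filled <- filled + sum(!allGenes %in% names(tabs[[j]]))
    }
    if (filled > 0L)
        warning(filled, " gene/sample cell(s) absent from per-sample files ",
                "were filled with 0")
    ExpressionMatrix(m, "count")
}

#' Write an expression matrix or centroid set as TSV
#'
#' First column \code{gene_id}, remaining columns samples (or subtypes).
#' [readExpression()] / [readCentroids()] on the written file reproduce the
#' values exactly.
#'
#' @param x an \linkS4class{ExpressionMatrix} or \linkS4class{CentroidSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- if (is(x, "CentroidSet")) centroidValues(x) else exprValues(x)
    ## %.17g keeps doubles bit-exact through the text round trip
    txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    df <- data.frame(gene_id = rownames(m), txt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[-1L] <- colnames(m)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpression
#' @export
writeCentroids <- writeExpression

#' Read a gene annotation table
#'
#' Tab-separated with header columns \code{gene_id}, \code{transcript_class},
#' \code{transcript_length} and optionally \code{exon_lengths}
#' (comma-separated bp, 5' to 3'). Classes must belong to
#' [transcriptClasses()] (human-readable spellings such as
#' "protein coding" are normalized); lengths must be positive; when exon
#' lengths are present they must sum to the transcript length.
#'
#' @param path file path.
#' @return data.frame with columns \code{gene_id}, \code{transcript_class},
#'   \code{transcript_length} and list-column \code{exon_lengths} (NULL
#'   entries where absent).
#' @export
readAnnotation <- function(path) {
    df <- .readTsv(path, "annotation")
    need <- c("gene_id", "transcript_class", "transcript_length")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
    ann <- data.frame(gene_id = trimws(as.character(df$gene_id)),
                      transcript_class = .normalizeClass(df$transcript_class),
                      transcript_length = as.numeric(df$transcript_length),
                      stringsAsFactors = FALSE)
    if (anyDuplicated(ann$gene_id))
        stop("duplicate gene id(s) in annotation: ",
             paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
    if (anyNA(ann$transcript_length) || any(ann$transcript_length <= 0))
        stop("transcript_length must be a positive number for every gene")
    if ("exon_lengths" %in% names(df)) {
        ex <- lapply(as.character(df$exon_lengths), function(s) {
            if (is.na(s) || !nzchar(trimws(s))) return(NULL)
            as.numeric(strsplit(trimws(s), ",")[[1L]])
        })
        for (i in seq_along(ex)) {
            if (is.null(ex[[i]])) next
            if (anyNA(ex[[i]]) || any(ex[[i]] <= 0))
                stop("invalid exon_lengths for gene ", ann$gene_id[i])
            if (abs(sum(ex[[i]]) - ann$transcript_length[i]) > 1e-6)
                stop("exon_lengths of gene ", ann$gene_id[i],
                     " do not sum to transcript_length")
        }
        ann$exon_lengths <- ex
    } else {
        ann$exon_lengths <- vector("list", nrow(ann))
    }
    ann
}

#' Read a centroid matrix
#'
#' Tab-separated; first column gene id, one column per subtype. At least
#' two genes and two subtypes are required.
#'
#' @param path file path.
#' @return A \linkS4class{CentroidSet}.
#' @export
readCentroids <- function(path) {
    df <- .readTsv(path, "centroid")
    if (ncol(df) < 3L)
        stop("a centroid file needs >= 2 subtype columns, found ",
             ncol(df) - 1L)
    genes <- trimws(as.character(df[[1L]]))
    if (anyDuplicated(genes))
        stop("duplicate gene id(s) in centroid file: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("non-numeric centroid value in ", path)
    rownames(m) <- genes
    CentroidSet(m)
}

#' Read a paired-sample design table
#'
#' Tab-separated with header columns \code{pair_id}, \code{sample_a_id}
#' (FF or microarray member), \code{sample_b_id} (FFPE or RNA-seq member),
#' and optionally \code{platform_label} and \code{age_class}
#' (\code{new_lt4y}, \code{old_gt10y} or \code{unknown}).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readDesign <- function(path) {
    df <- .readTsv(path, "design")
    need <- c("pair_id", "sample_a_id", "sample_b_id")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("design file missing column(s): ", paste(miss, collapse = ", "))
    if (!"platform_label" %in% names(df)) df$platform_label <- "unknown"
    if (!"age_class" %in% names(df)) df$age_class <- "unknown"
    des <- data.frame(pair_id = trimws(as.character(df$pair_id)),
                      sample_a_id = trimws(as.character(df$sample_a_id)),
                      sample_b_id = trimws(as.character(df$sample_b_id)),
                      platform_label = as.character(df$platform_label),
                      age_class = as.character(df$age_class),
                      stringsAsFactors = FALSE)
    validateDesign(des)
}

#' Validate a paired design table
#'
#' @param des data.frame with pair_id, sample_a_id, sample_b_id and
#'   optional platform_label / age_class columns.
#' @return the validated data.frame (with defaults filled).
#' @export
validateDesign <- function(des) {
    if (!"platform_label" %in% names(des)) des$platform_label <- "unknown"
    if (!"age_class" %in% names(des)) des$age_class <- "unknown"
    if (anyDuplicated(des$pair_id))
        stop("duplicate pair id(s): ",
             paste(unique(des$pair_id[duplicated(des$pair_id)]), collapse = ", "))
    self <- des$sample_a_id == des$sample_b_id
    if (any(self))
        stop("pair(s) with identical members: ",
             paste(des$pair_id[self], collapse = ", "))
    ok <- c("new_lt4y", "old_gt10y", "unknown")
    if (!all(des$age_class %in% ok))
        stop("age_class must be one of: ", paste(ok, collapse = ", "))
    des
}

#' Derive a gene annotation table from a GTF file
#'
#' Extracts one record per gene from an Ensembl-dialect GTF: the transcript
#' class from the \code{gene_biotype} attribute via \code{biotypeMap}, and
#' the transcript length as the union of exon intervals (GTF coordinates
#' are 1-based inclusive, so each exon contributes end - start + 1 bp).
#' Requires the \pkg{rtracklayer} package.
#'
#' @param path GTF file path.
#' @param biotypeMap named character vector mapping biotypes to classes;
#'   defaults to [defaultBiotypeMap()].
#' @return annotation data.frame as from [readAnnotation()].
#' @export
annotationFromGTF <- function(path, biotypeMap = defaultBiotypeMap()) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("annotationFromGTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    md <- as.data.frame(S4Vectors::mcols(gr))
    if (!all(c("type", "gene_id") %in% names(md)))
        stop("GTF lacks type/gene_id attributes")
    ex <- gr[md$type == "exon"]
    if (!length(ex)) stop("GTF contains no exon records")
    exmd <- as.data.frame(S4Vectors::mcols(ex))
    byGene <- split(ex, exmd$gene_id)
    lens <- vapply(byGene, function(g)
        sum(BiocGenerics::width(GenomicRanges::reduce(g))), numeric(1))
    bt <- tapply(as.character(exmd$gene_biotype), exmd$gene_id,
                 function(x) x[1L])
    bt <- bt[names(lens)]
    unknown <- setdiff(unique(bt), names(biotypeMap))
    if (length(unknown))
        stop("no transcript-class mapping for biotype(s): ",
             paste(unknown, collapse = ", "))
    data.frame(gene_id = names(lens),
               transcript_class = unname(biotypeMap[bt]),
               transcript_length = unname(lens),
               exon_lengths = I(vector("list", length(lens))),
               stringsAsFactors = FALSE)
}
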