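## End-to-end orchestration: simulate (or load) -> FPKM -> subtype ->
## concordance -> differential transcripts -> removal/recorrelation ->
## class/length/3'-bias summaries -> one structured JSON report plus
## per-stage TSVs.

.loadRunInputs <- function(config) {
    if (!is.null(config$sim)) {
        simArgs <- config$sim
        if (!is.null(config$seed)) simArgs$seed <- config$seed
        cohort <- simulateCohort(do.call(simConfig, simArgs),
                                 depthRegime = config$depthRegime %||% "hiseq_like")
        return(cohort)
    }
    need <- c("countsFF", "countsFFPE", "annotation", "centroids", "design")
    miss <- need[!vapply(need, function(f) !is.null(config$paths[[f]]),
                         logical(1))]
    if (length(miss))
        stop("run config needs a 'sim' section or paths for: ",
             paste(miss, collapse = ", "))
    list(countsFF = readExpression(config$paths$countsFF, "count"),
         countsFFPE = readExpression(config$paths$countsFFPE, "count"),
         annotation = readAnnotation(config$paths$annotation),
         centroids = readCentroids(config$paths$centroids),
         design = readDesign(config$paths$design),
         exonCounts = NULL, exonModel = NULL, readCategories = NULL,
         truth = NULL, regime = "provided", config = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.combineCounts <- function(ff, ffpe) {
    stopifnot(identical(rownames(ff), rownames(ffpe)))
    ExpressionMatrix(cbind(exprValues(ff), exprValues(ffpe)), "count")
}

#' Run the full paired FF/FFPE subtyping-concordance experiment
#'
#' Stages: input (synthetic cohort or files), FPKM normalization and
#' subtyping of both preparations, paired concordance with exact CI and
#' the confidence-accuracy curve, NB Wald differential-transcript
#' identification, the differential-removal correlation experiment,
#' transcript-class/length/3'-bias summaries, rRNA and read-category
#' summaries, and a centroid-reduction re-call check. A stage failure is
#' recorded under \code{errors} and its dependents are skipped. Outputs
#' are a pure function of (config, seed).
#'
#' @param config a list, or path to a YAML file, with entries: either
#'   \code{sim} ([simConfig()] arguments) or \code{paths}
#'   (countsFF/countsFFPE/annotation/centroids/design TSVs); optional
#'   \code{seed} (overrides the sim seed), \code{depthRegime},
#'   \code{subtyping} ([subtypeOptions()] arguments), \code{de}
#'   ([deOptions()] arguments), \code{targetAccuracy} (default 0.95).
#' @param outDir directory for the JSON report and per-stage TSVs; NULL
#'   (default) writes nothing.
#' @return the report, an (invisible-friendly) nested list; also written
#'   to \code{outDir/report.json} when requested.
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    report <- list(options = list(
        subtyping = config$subtyping %||% list(),
        de = config$de %||% list(),
        targetAccuracy = config$targetAccuracy %||% 0.95,
        seed = config$seed %||% config$sim$seed,
        depthRegime = config$depthRegime %||% "hiseq_like"))
    errors <- list()
    note <- function(stage, e) {
        errors[[stage]] <<- conditionMessage(e)
        NULL
    }

    inputs <- tryCatch(.loadRunInputs(config), error = function(e) note("input", e))
    if (is.null(inputs)) {
        stop("input stage failed: ", errors$input)
    }
    sopts <- do.call(subtypeOptions, config$subtyping %||% list())
    dopts <- do.call(deOptions, config$de %||% list())

    ## subtyping
    resFF <- resFFPE <- NULL
    stage <- tryCatch({
        fpkmFF <- fpkmNormalize(inputs$countsFF, inputs$annotation)
        fpkmFFPE <- fpkmNormalize(inputs$countsFFPE, inputs$annotation)
        resFF <- subtypeCohort(fpkmFF, inputs$centroids, sopts)
        resFFPE <- subtypeCohort(fpkmFFPE, inputs$centroids, sopts)
        report$subtyping <- list(
            distribution_ff = as.list(attr(resFF, "distribution")),
            distribution_ffpe = as.list(attr(resFFPE, "distribution")),
            n_failed = nrow(attr(resFF, "failed")) +
                nrow(attr(resFFPE, "failed")))
        TRUE
    }, error = function(e) note("subtyping", e))

    ## concordance
    if (!is.null(stage)) {
        stage <- tryCatch({
            rep_ <- concordance(resFF, resFFPE, inputs$design)
            curve <- accuracyVsConfidence(resFF, resFFPE, inputs$design)
            cutoff <- minConfidenceForAccuracy(curve,
                                               report$options$targetAccuracy)
            report$concordance <- list(
                n_pairs = rep_@nPairs, n_concordant = rep_@nConcordant,
                rate = rep_@rate, ci_low = rep_@ciLow, ci_high = rep_@ciHigh,
                n_excluded = nrow(rep_@excluded),
                confidence_cutoff_for_target = cutoff)
            report$curve <- curve
            TRUE
        }, error = function(e) note("concordance", e))
    }

    ## differential transcripts
    de <- NULL
    deStage <- tryCatch({
        combined <- .combineCounts(inputs$countsFF, inputs$countsFFPE)
        cond <- rep(c("FF", "FFPE"),
                    c(ncol(inputs$countsFF), ncol(inputs$countsFFPE)))
        de <- nbWaldTest(combined, cond, dopts)
        report$de <- list(n_genes = nrow(de),
                          n_differential = sum(de$is_differential),
                          n_ffpe_enriched = sum(de$enriched_in == "FFPE"),
                          n_ff_enriched = sum(de$enriched_in == "FF"))
        TRUE
    }, error = function(e) note("de", e))

    if (!is.null(deStage)) {
        tryCatch({
            combined <- .combineCounts(inputs$countsFF, inputs$countsFFPE)
            rr <- removeAndRecorrelate(combined, de, inputs$design)
            report$recorrelation <- list(
                mean_rho_before = rr$meanBefore, mean_rho_after = rr$meanAfter,
                p_value = rr$p_value, n_removed = rr$nRemoved)
        }, error = function(e) note("recorrelation", e))
        tryCatch({
            ct <- classTable(de, inputs$annotation)
            lb <- lengthBias(de, inputs$annotation)
            report$classTable <- ct
            report$lengthBias <- list(summary = lb$summary,
                                      p_value = lb$p_value, note = lb$note)
        }, error = function(e) note("bias", e))
        ## centroid reduction re-call
        if (!is.null(stage)) tryCatch({
            reduced <- reduceCentroids(inputs$centroids,
                                       de$gene_id[de$is_differential])
            fpkmFF <- fpkmNormalize(inputs$countsFF, inputs$annotation)
            fpkmFFPE <- fpkmNormalize(inputs$countsFFPE, inputs$annotation)
            redFF <- subtypeCohort(fpkmFF, reduced, sopts)
            redFFPE <- subtypeCohort(fpkmFFPE, reduced, sopts)
            agree <- c(resFF$call == redFF$call, resFFPE$call == redFFPE$call)
            report$centroidReduction <- list(
                n_full = length(geneIds(inputs$centroids)),
                n_reduced = length(geneIds(reduced)),
                call_agreement = mean(agree))
        }, error = function(e) note("centroid_reduction", e))
    }

    ## exon-level 3' bias
    if (!is.null(inputs$exonCounts)) tryCatch({
        groups <- list(FF = grep("^FF_", sampleIds(inputs$exonCounts),
                                 value = TRUE),
                       FFPE = grep("^FFPE_", sampleIds(inputs$exonCounts),
                                   value = TRUE))
        eb <- exonPositionBias(inputs$exonCounts, inputs$exonModel, groups)
        report$exonBias <- list(n_genes = nrow(eb),
                                mean_bias_ff = mean(eb$bias_FF),
                                mean_bias_ffpe = mean(eb$bias_FFPE))
    }, error = function(e) note("exon_bias", e))

    ## read categories and rRNA fraction
    if (!is.null(inputs$readCategories)) tryCatch({
        groups <- list(FF = grep("^FF_", inputs$readCategories$sample_id,
                                 value = TRUE),
                       FFPE = grep("^FFPE_", inputs$readCategories$sample_id,
                                   value = TRUE))
        rc <- readCategorySummary(inputs$readCategories, groups)
        report$readCategories <- list(
            mean_pct = lapply(rc$percentages[-1L], mean),
            tests = rc$tests)
    }, error = function(e) note("read_categories", e))
    tryCatch({
        rrna <- rrnaFraction(.combineCounts(inputs$countsFF, inputs$countsFFPE),
                             inputs$annotation)
        report$rrna <- list(mean_fraction = mean(rrna), max_fraction = max(rrna))
    }, error = function(e) note("rrna", e))

    report$errors <- errors

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(resFF))
            utils::write.table(resFF, file.path(outDir, "subtypes_ff.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(resFFPE))
            utils::write.table(resFFPE, file.path(outDir, "subtypes_ffpe.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(de))
            utils::write.table(de, file.path(outDir, "differential.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows", na = "null")
    }
    report
}
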