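# Shared fixtures: tiny matrices, annotations and a down-sized simulation
# config for fast unit tests.

toyMatrix <- function(values, genes = NULL, samples = NULL,
                      kind = "count") {
    m <- as.matrix(values)
    if (!is.null(genes)) rownames(m) <- genes
    if (!is.null(samples)) colnames(m) <- samples
    ExpressionMatrix(m, kind)
}

toyAnnotation <- function(geneIds, lengths,
                          classes = rep("protein_coding", length(geneIds))) {
    data.frame(gene_id = geneIds, transcript_class = classes,
               transcript_length = lengths, stringsAsFactors = FALSE)
}

# small cohort: enough structure for end-to-end behavior, fast to draw
smallSimConfig <- function(seed, ...) {
    args <- list(nGenes = 1500L, nCentroidGenes = 200L, nPairs = 8L,
                 nOldPairs = 2L, nExonGenes = 10L, seed = seed)
    override <- list(...)
    args[names(override)] <- override
    do.call(simConfig, args)
}

subtypeFromSim <- function(sim, centroids = sim$centroids,
                           opts = subtypeOptions()) {
    list(ff = subtypeCohort(fpkmNormalize(sim$countsFF, sim$annotation),
                            centroids, opts),
         ffpe = subtypeCohort(fpkmNormalize(sim$countsFFPE, sim$annotation),
                              centroids, opts))
}

combinedCounts <- function(sim) {
    ExpressionMatrix(cbind(exprValues(sim$countsFF),
                           exprValues(sim$countsFFPE)), "count")
}

simCondition <- function(sim) {
    rep(c("FF", "FFPE"), c(ncol(sim$countsFF), ncol(sim$countsFFPE)))
}

truthAccuracy <- function(results, sim) {
    tr <- sim$truth$samples
    mean(results$call == tr$subtype[match(results$sample_id, tr$sample_id)])
}
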