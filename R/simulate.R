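## Synthetic paired FF/FFPE cohort generator. Emits count matrices with a
## known subtype structure, FFPE class-selective enrichment, FF poly-A
## length bias, exon-level 3' bias, two sequencing-depth regimes and
## age-dependent degradation noise, together with the truth tables needed
## to score every downstream stage.

## Table-1-style census of a 27,577-transcript transcriptome; used as the
## default class mixture.
.CLASS_CENSUS <- c(rRNA = 44, misc_RNA = 437, snoRNA = 326, snRNA = 410,
                   sense_intronic = 513, three_prime_overlapping_ncRNA = 8,
                   miRNA = 232, mt_RNA = 10, pseudogene = 3661,
                   antisense = 2881, sense_overlapping = 116, lincRNA = 1992,
                   processed_transcript = 300, polymorphic_pseudogene = 17,
                   protein_coding = 16630)

## Log-normal transcript-length parameters (bp) per class: medians chosen
## so protein-coding averages sit near 3.7 kb and small RNAs near their
## characteristic sizes.
.LENGTH_PARAMS <- list(
    rRNA = c(log(1500), 0.5), misc_RNA = c(log(200), 0.5),
    snoRNA = c(log(100), 0.3), snRNA = c(log(150), 0.3),
    sense_intronic = c(log(500), 0.6),
    three_prime_overlapping_ncRNA = c(log(800), 0.5),
    miRNA = c(log(85), 0.3), mt_RNA = c(log(1000), 0.4),
    pseudogene = c(log(1200), 0.8), antisense = c(log(800), 0.8),
    sense_overlapping = c(log(700), 0.6), lincRNA = c(log(1000), 0.8),
    processed_transcript = c(log(1500), 0.7),
    polymorphic_pseudogene = c(log(2000), 0.6),
    protein_coding = c(log(3000), 0.75))

#' Configuration of the synthetic paired cohort
#'
#' Defaults emulate the study conditions: a Table-1-like transcript-class
#' mixture; 21 FF/FFPE pairs of which 4 are old (>10 y) blocks; MiSeq-like
#' (1.3e7) and HiSeq-like (8e7) total aligned reads per sample, of which
#' FF libraries put ~84\% and FFPE libraries ~31\% on target; gene counts
#' scaled by nGenes/27577 so per-gene depth matches a full transcriptome
#' at those read totals; FFPE class-selective enrichment of non-poly-A
#' species; FF poly-A length bias (2-fold retention loss at 6 kb); FF
#' exon-level 3' weighting; and stronger multiplicative degradation noise
#' in old FFPE blocks.
#'
#' @param nGenes number of genes; default 5000.
#' @param classProportions named numeric over [transcriptClasses()];
#'   normalized to sum 1. Default: Table-1-like census.
#' @param nSubtypes,subtypeNames number/names of subtypes; default 4
#'   (BL1, BL2, M, LAR).
#' @param subtypeProportions named prevalence of each subtype among
#'   tumors; default the TCGA-like distribution (BL1 0.323, BL2 0.188,
#'   M 0.302, LAR 0.188).
#' @param nCentroidGenes centroid genes (sampled from protein-coding);
#'   default 500.
#' @param subtypeEffectSize log2 standard deviation of a subtype's
#'   signature: each subtype deviates from the shared baseline by
#'   independent N(0, subtypeEffectSize^2) log2 effects over the centroid
#'   genes; default 2.5. Zero gives identical centroids (chance-level
#'   recovery).
#' @param subtypePurityRange each tumor expresses a mixture
#'   w * ownSignature + (1 - w) * secondSignature with purity w drawn
#'   uniformly from this range; tumors near 0.5 are genuinely ambiguous
#'   (mixed subtype signals), the main source of low-confidence and
#'   discordant calls. Default c(0.5, 1).
#' @param tumorNoiseSd log2 sd of per-tumor gene-level deviations shared
#'   by the FF and FFPE members of a pair (intratumoral heterogeneity,
#'   stromal content); default 0.7.
#' @param baselineSdLog natural-log sd of the log-normal baseline
#'   abundance; default 3 (a bulk transcriptome spans several orders of
#'   magnitude, leaving many genes in the shot-noise regime at MiSeq-like
#'   depth).
#' @param nPairs number of FF/FFPE pairs; default 21.
#' @param nOldPairs pairs with age class old_gt10y; default 4.
#' @param depthMean named total-read depths per regime; default
#'   c(miseq_like = 1.3e7, hiseq_like = 8e7).
#' @param depthCV log-normal coefficient of variation of per-sample depth;
#'   default 0.2.
#' @param onTargetFraction named fractions of mapped reads on target,
#'   c(FF = 0.84, FFPE = 0.31).
#' @param nbDispersion central NB dispersion; default 0.05.
#' @param dispersionJitter gene dispersions are spread uniformly on the
#'   log scale within this factor of nbDispersion; default 2.
#' @param ffpeClassMultipliers named FFPE enrichment multipliers per
#'   class (ribosomal-depletion retention of non-poly-A species).
#' @param ffLengthBiasRate per-bp exponential FF retention decay;
#'   default log(2)/6000 (2-fold loss at 6 kb).
#' @param threePrimeDecayRate exon-level FF 3' weighting rate; default 2.
#' @param nExonGenes long protein-coding genes given exon models for the
#'   3'-bias analysis; default 30.
#' @param ffNoiseSd,ageNoiseSd multiplicative log2 noise sd for FF
#'   samples and for FFPE samples by age class.
#' @param seed mandatory integer RNG seed.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nGenes = 5000L,
                      classProportions = .CLASS_CENSUS,
                      nSubtypes = 4L,
                      subtypeNames = c("BL1", "BL2", "M", "LAR"),
                      subtypeProportions = c(BL1 = 0.323, BL2 = 0.188,
                                             M = 0.302, LAR = 0.188),
                      nCentroidGenes = 500L,
                      subtypeEffectSize = 2.5,
                      subtypePurityRange = c(0.5, 1),
                      tumorNoiseSd = 0.7,
                      baselineSdLog = 3,
                      nPairs = 21L,
                      nOldPairs = 4L,
                      depthMean = c(miseq_like = 1.3e7, hiseq_like = 8e7),
                      depthCV = 0.2,
                      onTargetFraction = c(FF = 0.84, FFPE = 0.31),
                      nbDispersion = 0.05,
                      dispersionJitter = 2,
                      ffpeClassMultipliers = c(
                          misc_RNA = 8, snoRNA = 8, snRNA = 8,
                          sense_intronic = 6,
                          three_prime_overlapping_ncRNA = 6, miRNA = 6,
                          rRNA = 4, pseudogene = 3, antisense = 3,
                          sense_overlapping = 2.5, lincRNA = 2.5,
                          processed_transcript = 2, mt_RNA = 1.5,
                          polymorphic_pseudogene = 1.5, protein_coding = 1),
                      ffLengthBiasRate = log(2) / 6000,
                      threePrimeDecayRate = 2,
                      nExonGenes = 30L,
                      ffNoiseSd = 0.1,
                      ageNoiseSd = c(new_lt4y = 0.15, old_gt10y = 0.6,
                                     unknown = 0.3),
                      seed) {
    if (missing(seed) || is.null(seed))
        stop("simConfig requires an explicit seed")
    stopifnot(nGenes >= 100, nPairs >= 1, nOldPairs >= 0, nOldPairs <= nPairs,
              nSubtypes >= 2, length(subtypeNames) == nSubtypes,
              nCentroidGenes >= nSubtypes,
              length(subtypePurityRange) == 2L,
              subtypePurityRange[1L] >= 0.5, subtypePurityRange[2L] <= 1,
              subtypePurityRange[1L] <= subtypePurityRange[2L],
              tumorNoiseSd >= 0, baselineSdLog > 0,
              subtypeEffectSize >= 0, nbDispersion > 0, dispersionJitter >= 1,
              depthCV >= 0, ffLengthBiasRate >= 0, threePrimeDecayRate >= 0,
              nExonGenes >= 0, ffNoiseSd >= 0, all(ageNoiseSd >= 0),
              all(depthMean > 0), all(onTargetFraction > 0 & onTargetFraction <= 1))
    cls <- transcriptClasses()
    miss <- setdiff(cls, names(classProportions))
    if (length(miss))
        stop("classProportions missing class(es): ", paste(miss, collapse = ", "))
    if (any(classProportions < 0) || sum(classProportions) <= 0)
        stop("classProportions must be non-negative and sum > 0")
    classProportions <- classProportions[cls] / sum(classProportions[cls])
    miss <- setdiff(subtypeNames, names(subtypeProportions))
    if (length(miss))
        stop("subtypeProportions missing subtype(s): ",
             paste(miss, collapse = ", "))
    if (any(subtypeProportions < 0) || sum(subtypeProportions) <= 0)
        stop("subtypeProportions must be non-negative and sum > 0")
    subtypeProportions <- subtypeProportions[subtypeNames] /
        sum(subtypeProportions[subtypeNames])
    miss <- setdiff(cls, names(ffpeClassMultipliers))
    if (length(miss))
        stop("ffpeClassMultipliers missing class(es): ",
             paste(miss, collapse = ", "))
    if (any(ffpeClassMultipliers <= 0))
        stop("ffpeClassMultipliers must be positive")
    structure(list(nGenes = as.integer(nGenes),
                   classProportions = classProportions,
                   nSubtypes = as.integer(nSubtypes),
                   subtypeNames = subtypeNames,
                   subtypeProportions = subtypeProportions,
                   nCentroidGenes = as.integer(nCentroidGenes),
                   subtypeEffectSize = subtypeEffectSize,
                   subtypePurityRange = subtypePurityRange,
                   tumorNoiseSd = tumorNoiseSd,
                   baselineSdLog = baselineSdLog,
                   nPairs = as.integer(nPairs),
                   nOldPairs = as.integer(nOldPairs),
                   depthMean = depthMean, depthCV = depthCV,
                   onTargetFraction = onTargetFraction,
                   nbDispersion = nbDispersion,
                   dispersionJitter = dispersionJitter,
                   ffpeClassMultipliers = ffpeClassMultipliers[cls],
                   ffLengthBiasRate = ffLengthBiasRate,
                   threePrimeDecayRate = threePrimeDecayRate,
                   nExonGenes = as.integer(nExonGenes),
                   ffNoiseSd = ffNoiseSd, ageNoiseSd = ageNoiseSd,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

## Deterministic (given the RNG state) construction of the cohort's
## underlying truth: gene census, baseline profile, subtype assignment,
## preparation biases, exon models.
.buildSimState <- function(cfg) {
    n <- cfg$nGenes
    cls <- sample(names(cfg$classProportions), n, replace = TRUE,
                  prob = cfg$classProportions)
    geneIds <- sprintf("G%05d", seq_len(n))
    len <- vapply(cls, function(cl) {
        p <- .LENGTH_PARAMS[[cl]]
        max(30, round(stats::rlnorm(1, p[1L], p[2L])))
    }, numeric(1))
    baseline <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$baselineSdLog)
    geneDisp <- cfg$nbDispersion *
        exp(stats::runif(n, -log(cfg$dispersionJitter),
                         log(cfg$dispersionJitter)))

    coding <- which(cls == "protein_coding")
    pool <- if (length(coding) >= cfg$nCentroidGenes) coding else seq_len(n)
    centroidIdx <- sort(sample(pool, cfg$nCentroidGenes))
    ## each subtype's signature: independent log2 deviations from the
    ## shared baseline over the centroid genes
    subtypeDelta <- matrix(stats::rnorm(cfg$nCentroidGenes * cfg$nSubtypes,
                                        0, cfg$subtypeEffectSize),
                           cfg$nCentroidGenes, cfg$nSubtypes,
                           dimnames = list(NULL, cfg$subtypeNames))

    pairSubtype <- sample(cfg$subtypeNames, cfg$nPairs, replace = TRUE,
                          prob = cfg$subtypeProportions)
    purity <- stats::runif(cfg$nPairs, cfg$subtypePurityRange[1L],
                           cfg$subtypePurityRange[2L])
    secondSubtype <- vapply(pairSubtype, function(s)
        sample(setdiff(cfg$subtypeNames, s), 1L), character(1))
    tumorDev <- matrix(stats::rnorm(n * cfg$nPairs, 0, cfg$tumorNoiseSd),
                       n, cfg$nPairs)
    age <- c(rep("old_gt10y", cfg$nOldPairs),
             rep("new_lt4y", cfg$nPairs - cfg$nOldPairs))
    age <- sample(age)

    ffRetention <- exp(-cfg$ffLengthBiasRate * len)
    ffpeMult <- unname(cfg$ffpeClassMultipliers[cls])
    ## identifiable truth: counts are relative abundances, so the fold
    ## change a composition-normalized analysis can recover is the raw
    ## FFPE/FF ratio centered on the median gene (the anchor of
    ## median-of-ratios normalization)
    rawLfc <- log2(ffpeMult / ffRetention)
    trueLfc <- rawLfc - stats::median(rawLfc)

    ## centroids: noiseless expected FPKM of a pure tumor of each
    ## subtype, free of preparation bias
    cvals <- vapply(cfg$subtypeNames, function(s) {
        prof <- baseline[centroidIdx] * 2^subtypeDelta[, s]
        fpkm <- prof / len[centroidIdx]
        1e6 * fpkm / sum(fpkm)
    }, numeric(length(centroidIdx)))
    rownames(cvals) <- geneIds[centroidIdx]

    ## exon models for long multi-exon coding genes
    exonModel <- NULL
    exonLengths <- vector("list", n)
    if (cfg$nExonGenes > 0L) {
        longCoding <- coding[order(-len[coding])]
        exonGenes <- utils::head(longCoding, cfg$nExonGenes)
        rowsEM <- list()
        for (gi in exonGenes) {
            ne <- sample(8:20, 1L)
            w <- stats::rlnorm(ne, 0, 0.5)
            el <- pmax(1, round(len[gi] * w / sum(w)))
            el[ne] <- el[ne] + (len[gi] - sum(el))
            if (el[ne] < 1) { el[ne] <- 1; len[gi] <- sum(el) }
            exonLengths[[gi]] <- el
            rowsEM[[length(rowsEM) + 1L]] <- data.frame(
                gene_id = geneIds[gi],
                exon_id = sprintf("%s:E%02d", geneIds[gi], seq_len(ne)),
                exon_index = seq_len(ne), exon_length = el,
                stringsAsFactors = FALSE)
        }
        exonModel <- do.call(rbind, rowsEM)
    }

    list(cfg = cfg, geneIds = geneIds, class = cls, length = len,
         baseline = baseline, geneDisp = geneDisp,
         centroidIdx = centroidIdx, subtypeDelta = subtypeDelta,
         centroids = CentroidSet(cvals),
         pairSubtype = pairSubtype, purity = purity,
         secondSubtype = secondSubtype, tumorDev = tumorDev, age = age,
         ffRetention = ffRetention, ffpeMult = ffpeMult,
         trueLfc = trueLfc, exonModel = exonModel)
}

## Expected (pre-noise) expression profile of one sample: baseline x
## purity-weighted subtype signature x shared tumor deviation x
## preparation bias.
.sampleProfile <- function(st, pair, prep) {
    prof <- st$baseline
    w <- st$purity[pair]
    dmix <- w * st$subtypeDelta[, st$pairSubtype[pair]] +
        (1 - w) * st$subtypeDelta[, st$secondSubtype[pair]]
    prof[st$centroidIdx] <- prof[st$centroidIdx] * 2^dmix
    prof <- prof * 2^st$tumorDev[, pair]
    if (prep == "FF") prof * st$ffRetention else prof * st$ffpeMult
}

## NB-sample the count matrix of one preparation at one depth regime.
.emitPrep <- function(st, prep, regime) {
    cfg <- st$cfg
    n <- cfg$nGenes
    m <- matrix(0, n, cfg$nPairs)
    for (j in seq_len(cfg$nPairs)) {
        prof <- .sampleProfile(st, j, prep)
        noiseSd <- if (prep == "FF") cfg$ffNoiseSd
                   else unname(cfg$ageNoiseSd[st$age[j]])
        if (noiseSd > 0)
            prof <- prof * 2^stats::rnorm(n, 0, noiseSd)
        depth <- cfg$depthMean[[regime]] *
            stats::rlnorm(1, -cfg$depthCV^2 / 2, cfg$depthCV)
        tot <- depth * cfg$onTargetFraction[[prep]] * n / 27577
        mu <- tot * prof / sum(prof)
        m[, j] <- stats::rnbinom(n, mu = mu, size = 1 / st$geneDisp)
    }
    rownames(m) <- st$geneIds
    colnames(m) <- sprintf("%s_P%02d", prep, seq_len(cfg$nPairs))
    ExpressionMatrix(m, "count")
}

## Exon-level counts: FF reweights exons toward the 3' end
## (exponentially in the exon's position along the transcript), FFPE is
## position-uniform; both weight by exon length.
.emitExonCounts <- function(st, regime) {
    cfg <- st$cfg
    em <- st$exonModel
    if (is.null(em)) return(NULL)
    samples <- c(sprintf("FF_P%02d", seq_len(cfg$nPairs)),
                 sprintf("FFPE_P%02d", seq_len(cfg$nPairs)))
    m <- matrix(0, nrow(em), length(samples),
                dimnames = list(em$exon_id, samples))
    byGene <- split(seq_len(nrow(em)), em$gene_id)
    for (g in names(byGene)) {
        rows <- byGene[[g]]
        el <- em$exon_length[rows]
        pos <- (cumsum(el) - el / 2) / sum(el)   # exon midpoint, 0=5' 1=3'
        wFF <- el * exp(cfg$threePrimeDecayRate * (pos - 1))
        wFFPE <- el
        for (j in seq_len(cfg$nPairs)) {
            ## fixed per-gene coverage (scaled by regime) so the bias
            ## statistic is well powered for every modeled gene
            base <- 2000 * cfg$depthMean[[regime]] / max(cfg$depthMean)
            totFF <- stats::rnbinom(1, mu = base, size = 1 / cfg$nbDispersion)
            totFFPE <- stats::rnbinom(1, mu = base, size = 1 / cfg$nbDispersion)
            m[rows, sprintf("FF_P%02d", j)] <-
                stats::rmultinom(1, totFF, wFF / sum(wFF))
            m[rows, sprintf("FFPE_P%02d", j)] <-
                stats::rmultinom(1, totFFPE, wFFPE / sum(wFFPE))
        }
    }
    ExpressionMatrix(m, "count")
}

## Read-category counts per sample (Fig-2-like composition).
.emitReadCategories <- function(st, regime) {
    cfg <- st$cfg
    rows <- list()
    comp <- list(FF = c(on = 0.84, intron = 0.13, inter = 0.03),
                 FFPE = c(on = 0.31, intron = 0.60, inter = 0.09))
    for (prep in c("FF", "FFPE")) {
        for (j in seq_len(cfg$nPairs)) {
            fr <- pmax(0.005, comp[[prep]] + stats::rnorm(3, 0, 0.02))
            fr <- fr / sum(fr)
            unm <- min(0.6, max(0.01, stats::rnorm(1,
                if (prep == "FFPE" && st$age[j] == "old_gt10y") 0.13 else 0.06,
                0.015)))
            depth <- cfg$depthMean[[regime]]
            mapped <- depth * (1 - unm)
            rows[[paste(prep, j)]] <- data.frame(
                sample_id = sprintf("%s_P%02d", prep, j),
                on_target = round(mapped * fr[1L]),
                intronic = round(mapped * fr[2L]),
                intergenic = round(mapped * fr[3L]),
                unmapped = round(depth * unm),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.emitCohort <- function(st, regime) {
    cfg <- st$cfg
    countsFF <- .emitPrep(st, "FF", regime)
    countsFFPE <- .emitPrep(st, "FFPE", regime)
    exonCounts <- .emitExonCounts(st, regime)
    readCategories <- .emitReadCategories(st, regime)
    ann <- data.frame(gene_id = st$geneIds, transcript_class = st$class,
                      transcript_length = st$length,
                      stringsAsFactors = FALSE)
    ann$exon_lengths <- vector("list", nrow(ann))
    if (!is.null(st$exonModel)) {
        for (g in unique(st$exonModel$gene_id))
            ann$exon_lengths[[match(g, ann$gene_id)]] <-
                st$exonModel$exon_length[st$exonModel$gene_id == g]
    }
    design <- data.frame(pair_id = sprintf("P%02d", seq_len(cfg$nPairs)),
                         sample_a_id = sprintf("FF_P%02d", seq_len(cfg$nPairs)),
                         sample_b_id = sprintf("FFPE_P%02d", seq_len(cfg$nPairs)),
                         platform_label = regime, age_class = st$age,
                         stringsAsFactors = FALSE)
    truthSamples <- rbind(
        data.frame(sample_id = design$sample_a_id, pair_id = design$pair_id,
                   prep = "FF", subtype = st$pairSubtype,
                   purity = st$purity, second_subtype = st$secondSubtype,
                   age_class = st$age, stringsAsFactors = FALSE),
        data.frame(sample_id = design$sample_b_id, pair_id = design$pair_id,
                   prep = "FFPE", subtype = st$pairSubtype,
                   purity = st$purity, second_subtype = st$secondSubtype,
                   age_class = st$age, stringsAsFactors = FALSE))
    truthGenes <- data.frame(
        gene_id = st$geneIds, transcript_class = st$class,
        transcript_length = st$length, baseline = st$baseline,
        true_log2_fc = st$trueLfc,
        is_differential = abs(st$trueLfc) >= 1,
        direction = ifelse(abs(st$trueLfc) < 1, "none",
                           ifelse(st$trueLfc > 0, "FFPE", "FF")),
        is_centroid_gene = seq_len(cfg$nGenes) %in% st$centroidIdx,
        stringsAsFactors = FALSE)
    list(countsFF = countsFF, countsFFPE = countsFFPE,
         exonCounts = exonCounts, exonModel = st$exonModel,
         readCategories = readCategories, annotation = ann,
         centroids = st$centroids, design = design,
         truth = list(samples = truthSamples, genes = truthGenes),
         regime = regime, config = cfg)
}

#' Generate a synthetic paired FF/FFPE cohort
#'
#' Fully reproducible under \code{config$seed}: identical configs give
#' bit-identical outputs. See [simConfig()] for what is emulated.
#'
#' @param config a [simConfig()] object.
#' @param depthRegime \code{"hiseq_like"} (default) or \code{"miseq_like"}.
#' @return list: \code{countsFF}, \code{countsFFPE} (count
#'   \linkS4class{ExpressionMatrix} over the cohort's pairs),
#'   \code{exonCounts} + \code{exonModel}, \code{readCategories},
#'   \code{annotation}, \code{centroids}, \code{design}, \code{truth}
#'   (per-sample subtype labels and per-gene differential status),
#'   \code{regime}, \code{config}.
#' @export
simulateCohort <- function(config, depthRegime = c("hiseq_like", "miseq_like")) {
    stopifnot(inherits(config, "SimConfig"))
    depthRegime <- match.arg(depthRegime)
    if (!depthRegime %in% names(config$depthMean))
        stop("depth regime not configured: ", depthRegime)
    set.seed(config$seed)
    st <- .buildSimState(config)
    .emitCohort(st, depthRegime)
}

#' Emit the same cohort at both depth regimes
#'
#' Builds one underlying cohort (identical expected expression, subtype
#' labels and biases) and samples counts independently at the MiSeq-like
#' and HiSeq-like depths, for depth-effect experiments.
#'
#' @param config a [simConfig()] object with both regimes in
#'   \code{depthMean}.
#' @return named list with one [simulateCohort()]-style cohort per regime.
#' @export
simulatePairedPlatform <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    need <- c("miseq_like", "hiseq_like")
    if (!all(need %in% names(config$depthMean)))
        stop("both depth regimes must be configured")
    set.seed(config$seed)
    st <- .buildSimState(config)
    out <- lapply(need, function(r) .emitCohort(st, r))
    names(out) <- need
    out
}
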