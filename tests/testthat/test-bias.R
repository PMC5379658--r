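test_that("class table identities hold and degenerate inputs are safe", {
    set.seed(31)
    n <- 600
    classes <- sample(transcriptClasses(), n, replace = TRUE)
    ann <- toyAnnotation(paste0("G", 1:n), rpois(n, 1000) + 50, classes)
    enr <- sample(c("none", "FF", "FFPE"), n, replace = TRUE,
                  prob = c(0.6, 0.1, 0.3))
    de <- data.frame(gene_id = ann$gene_id,
                     is_differential = enr != "none", enriched_in = enr)
    tab <- classTable(de, ann)
    body <- tab[tab$transcript_class != "Total", ]
    tot <- tab[tab$transcript_class == "Total", ]
    expect_equal(tot$n_all, sum(body$n_all))
    expect_equal(tot$n_differential, sum(body$n_differential))
    expect_equal(tab$n_differential, tab$n_ffpe + tab$n_ff)
    expect_equal(tot$pct_differential,
                 100 * tot$n_differential / tot$n_all)

    # empty differential set: all-zero rows, no division by zero
    de0 <- de; de0$is_differential <- FALSE; de0$enriched_in <- "none"
    tab0 <- classTable(de0, ann)
    expect_true(all(tab0$n_differential == 0))
    expect_true(all(is.finite(tab0$pct_ffpe)))

    dropIdx <- which(de$is_differential)[1]
    expect_error(classTable(de, ann[-dropIdx, ]), "unannotated differential")
})

test_that("length bias detects a planted 2x length shift and skips small groups", {
    set.seed(32)
    nPer <- 200
    lenFF <- rlnorm(nPer, log(2000), 0.5)
    lenFFPE <- rlnorm(nPer, log(4000), 0.5)     # 2x longer
    ids <- paste0("G", seq_len(2 * nPer))
    ann <- toyAnnotation(ids, c(lenFF, lenFFPE))
    de <- data.frame(gene_id = ids, is_differential = TRUE,
                     enriched_in = rep(c("FF", "FFPE"), each = nPer))
    lb <- lengthBias(de, ann)
    expect_lt(lb$p_value, 0.01)
    su <- lb$summary
    expect_gt(su$median_bp[su$group == "ffpe_enriched"],
              su$median_bp[su$group == "ff_enriched"])

    # identical distributions: no signal
    ann2 <- toyAnnotation(ids, rep(rlnorm(nPer, log(2000), 0.5), 2))
    lb2 <- lengthBias(de, ann2)
    expect_gt(lb2$p_value, 0.05)

    # a group below 3 genes: summaries only
    deSmall <- de; deSmall$enriched_in[deSmall$enriched_in == "FF"] <- "none"
    deSmall$enriched_in[1:2] <- "FF"
    deSmall$is_differential <- deSmall$enriched_in != "none"
    lb3 <- lengthBias(deSmall, ann)
    expect_true(is.na(lb3$p_value))
    expect_match(lb3$note, "skipped")
})

test_that("exon position bias: flat is 0, monotone is 1, scale invariant", {
    gm <- data.frame(gene_id = "TTN",
                     exon_id = sprintf("TTN:E%02d", 1:12),
                     exon_index = 1:12)
    flat <- toyMatrix(matrix(5, 12, 2), genes = gm$exon_id,
                      samples = c("FF_1", "FFPE_1"))
    groups <- list(FF = "FF_1", FFPE = "FFPE_1")
    ebFlat <- exonPositionBias(flat, gm, groups)
    expect_equal(ebFlat$bias_FF, 0)

    rising <- toyMatrix(cbind(2^(1:12), rep(4, 12)), genes = gm$exon_id,
                        samples = c("FF_1", "FFPE_1"))
    eb <- exonPositionBias(rising, gm, groups)
    expect_equal(eb$bias_FF, 1)
    expect_equal(eb$bias_FFPE, 0)
    expect_equal(eb$diff_FF_FFPE, 1)

    scaled <- toyMatrix(cbind(7 * 2^(1:12), rep(4, 12)),
                        genes = gm$exon_id, samples = c("FF_1", "FFPE_1"))
    expect_equal(exonPositionBias(scaled, gm, groups)$bias_FF, eb$bias_FF)

    # genes under the exon minimum are skipped and counted
    gm2 <- rbind(gm, data.frame(gene_id = "SHORT",
                                exon_id = sprintf("SHORT:E%02d", 1:3),
                                exon_index = 1:3))
    m2 <- toyMatrix(matrix(3, 15, 2), genes = gm2$exon_id,
                    samples = c("FF_1", "FFPE_1"))
    eb2 <- exonPositionBias(m2, gm2, groups)
    expect_equal(nrow(eb2), 1L)
    expect_equal(attr(eb2, "n_skipped"), 1L)
})

test_that("hypergeometric overrepresentation matches closed form and enumeration", {
    # query identical to a 5-gene set in a 100-gene universe
    uni <- paste0("G", 1:100)
    res <- overlapEnrichment(uni[1:5], list(hit = uni[1:5]), uni)
    expect_equal(res$p_value, 1 / choose(100, 5))

    # k = 0 has p = 1
    res0 <- overlapEnrichment(uni[1:5], list(disjoint = uni[6:10]), uni)
    expect_equal(res0$p_value, 1)

    # brute-force enumeration oracle for all small universes
    enumOracle <- function(N, K, n, k) {
        draws <- utils::combn(N, n)
        inSet <- seq_len(K)
        mean(apply(draws, 2, function(d) sum(d %in% inSet)) >= k)
    }
    # the documented N=10, K=4, n=3, k=2 case plus random ones
    uni10 <- paste0("g", 1:10)
    res2 <- overlapEnrichment(c("g1", "g2", "g5"),
                              list(s = paste0("g", 1:4)), uni10)
    expect_equal(res2$p_value, enumOracle(10, 4, 3, 2))
    set.seed(33)
    for (i in 1:10) {
        N <- sample(5:12, 1); K <- sample(2:(N - 1), 1)
        n <- sample(2:(N - 1), 1)
        uniN <- paste0("u", seq_len(N))
        query <- sample(uniN, n)
        set_ <- uniN[seq_len(K)]
        k <- length(intersect(query, set_))
        got <- overlapEnrichment(query, list(s = set_), uniN)
        expect_equal(got$p_value, enumOracle(N, K, n, k), tolerance = 1e-12)
        expect_lte(got$overlap_k, min(K, n))
    }

    expect_error(overlapEnrichment(character(), list(s = "a"), "a"), "empty query")
    expect_error(overlapEnrichment("b", list(s = "a"), "a"), "outside the universe")
})

test_that("GMT parsing returns named member lists", {
    f <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\turl\tG2\tG9"), f)
    sets <- readGMT(f)
    expect_equal(names(sets), c("setA", "setB"))
    expect_equal(sets$setB, c("G2", "G9"))
    writeLines("bad\tonlydesc", f)
    expect_error(readGMT(f), "fewer than 3")
})

test_that("read-category percentages use the documented denominators", {
    cats <- data.frame(sample_id = "s1", on_target = 80, intronic = 15,
                       intergenic = 5, unmapped = 10)
    rc <- readCategorySummary(cats)
    expect_equal(rc$percentages$pct_on_target, 80)
    expect_equal(rc$percentages$pct_intronic, 15)
    expect_equal(rc$percentages$pct_intergenic, 5)
    expect_equal(rc$percentages$pct_unmapped, 100 * 10 / 110, tolerance = 1e-12)

    # identical samples across groups: no between-group signal
    many <- do.call(rbind, lapply(1:6, function(i) {
        transform(cats, sample_id = paste0("s", i))
    }))
    rc2 <- readCategorySummary(many, groups = list(FF = paste0("s", 1:3),
                                                   FFPE = paste0("s", 4:6)))
    expect_true(all(rc2$tests$p_value == 1))

    bad <- data.frame(sample_id = "x", on_target = 0, intronic = 0,
                      intergenic = 0, unmapped = 5)
    expect_error(readCategorySummary(bad), "zero mapped")
})

test_that("rRNA fraction is a simple count ratio", {
    ids <- c("R1", "C1", "C2")
    ann <- toyAnnotation(ids, c(1500, 2000, 3000),
                         c("rRNA", "protein_coding", "protein_coding"))
    m <- toyMatrix(matrix(c(2, 100, 98), 3, 1), genes = ids, samples = "S1")
    expect_equal(unname(rrnaFraction(m, ann)), 0.01)

    mAll <- toyMatrix(matrix(c(50, 0, 0), 3, 1), genes = ids, samples = "S1")
    expect_equal(unname(rrnaFraction(mAll, ann)), 1)

    annNone <- toyAnnotation(ids, c(1500, 2000, 3000),
                             rep("protein_coding", 3))
    expect_equal(unname(rrnaFraction(m, annNone)), 0)
})
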