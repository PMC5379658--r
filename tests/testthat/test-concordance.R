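makeResults <- function(ids, calls, conf = rep(1, length(ids))) {
    data.frame(sample_id = ids, call = calls, confidence = conf,
               stringsAsFactors = FALSE)
}

makeDesign <- function(n, prefix = "P") {
    data.frame(pair_id = paste0(prefix, seq_len(n)),
               sample_a_id = paste0("A", seq_len(n)),
               sample_b_id = paste0("B", seq_len(n)),
               stringsAsFactors = FALSE)
}

test_that("Clopper-Pearson reproduces known intervals and boundary cases", {
    ci <- clopperPearson(89, 98, 0.95)
    expect_equal(round(unname(ci), 3), c(0.833, 0.957))
    expect_equal(unname(clopperPearson(0, 10)["low"]), 0)
    expect_equal(unname(clopperPearson(10, 10)["high"]), 1)
    expect_error(clopperPearson(5, 0), "positive integer")
    expect_error(clopperPearson(11, 10), "in \\[0, n\\]")
    expect_error(clopperPearson(5, 10, level = 1), "level")
})

test_that("Clopper-Pearson agrees with binomial tail-sum grid inversion", {
    # oracle: invert the binomial tails directly on a fine grid
    invertOracle <- function(k, n, level = 0.95) {
        a <- (1 - level) / 2
        grid <- seq(1e-6, 1 - 1e-6, by = 1e-5)
        upperTail <- function(p) sum(dbinom(k:n, n, p))     # P(X >= k)
        lowerTail <- function(p) sum(dbinom(0:k, n, p))     # P(X <= k)
        low <- if (k == 0) 0 else grid[which(vapply(grid, upperTail, 1) > a)[1]]
        hi <- if (k == n) 1 else {
            ok <- vapply(grid, lowerTail, 1) > a
            grid[rev(which(ok))[1]]
        }
        c(low, hi)
    }
    for (kn in list(c(5, 10), c(1, 12), c(89, 98))) {
        ours <- unname(clopperPearson(kn[1], kn[2]))
        oracle <- invertOracle(kn[1], kn[2])
        expect_equal(ours, oracle, tolerance = 1e-3)
    }
})

test_that("exact interval is conservative: empirical coverage >= nominal", {
    set.seed(2024)
    hits <- 0L; total <- 0L
    for (p in c(0.1, 0.5, 0.9)) {
        for (n in c(10, 100)) {
            k <- rbinom(2000, n, p)
            lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
            hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
            ours <- t(vapply(k, function(ki) clopperPearson(ki, n),
                             numeric(2)))
            expect_equal(unname(ours[, 1]), unname(lo))
            hits <- hits + sum(ours[, 1] <= p & p <= ours[, 2])
            total <- total + length(k)
        }
    }
    expect_gte(hits / total, 0.95)
})

test_that("concordance counts identical calls over evaluable pairs", {
    des <- makeDesign(9)
    a <- makeResults(des$sample_a_id, c(rep("BL1", 6), "M", "M", "LAR"))
    b <- makeResults(des$sample_b_id, c(rep("BL1", 6), "LAR", "BL2", "M"))
    rep_ <- concordance(a, b, des)
    expect_equal(rep_@nPairs, 9L)
    expect_equal(rep_@nConcordant, 6L)
    expect_equal(rep_@rate, 6 / 9)
    expect_equal(round(100 * rep_@rate), 67)

    # identical lists: rate 1, upper bound 1 at k = n
    full <- concordance(a, makeResults(des$sample_b_id, a$call), des)
    expect_equal(full@rate, 1)
    expect_equal(full@ciHigh, 1)
})

test_that("UNCLASSIFIED handling: exclusion, discordance, and empty sets", {
    des <- makeDesign(3)
    a <- makeResults(des$sample_a_id, c("BL1", "UNCLASSIFIED", "M"))
    b <- makeResults(des$sample_b_id, c("BL1", "BL2", "UNCLASSIFIED"))
    rep_ <- concordance(a, b, des)
    expect_equal(rep_@nPairs, 1L)
    expect_equal(nrow(rep_@excluded), 2L)

    inc <- concordance(a, b, des, excludeUnclassified = FALSE)
    expect_equal(inc@nPairs, 3L)
    expect_equal(inc@nConcordant, 1L)

    bothUnc <- concordance(
        makeResults(des$sample_a_id, rep("UNCLASSIFIED", 3)),
        makeResults(des$sample_b_id, rep("UNCLASSIFIED", 3)),
        des, excludeUnclassified = FALSE)
    expect_equal(bothUnc@rate, 1)

    allUnc <- makeResults(des$sample_a_id, rep("UNCLASSIFIED", 3))
    expect_error(concordance(allUnc,
                             makeResults(des$sample_b_id, rep("BL1", 3)),
                             des),
                 "no evaluable pairs")
    expect_error(concordance(a[-1, ], b, des), "no result for pair")
})

test_that("concordance is symmetric in the two result sets", {
    set.seed(7)
    des <- makeDesign(12)
    a <- makeResults(des$sample_a_id, sample(c("BL1", "M"), 12, TRUE))
    b <- makeResults(des$sample_b_id, sample(c("BL1", "M"), 12, TRUE))
    swapped <- des
    swapped$sample_a_id <- des$sample_b_id
    swapped$sample_b_id <- des$sample_a_id
    expect_equal(concordance(a, b, des)@rate,
                 concordance(b, a, swapped)@rate)
})

test_that("accuracy-vs-confidence curve restricts by the pair minimum", {
    des <- makeDesign(4)
    a <- makeResults(des$sample_a_id, c("BL1", "BL1", "M", "M"),
                     conf = c(0.5, 0.05, 0.5, 0.4))
    b <- makeResults(des$sample_b_id, c("BL1", "M", "M", "LAR"),
                     conf = c(0.4, 0.5, 0.3, 0.45))
    curve <- accuracyVsConfidence(a, b, des, cutoffGrid = c(0, 0.1, 0.35, 1.5))
    # cutoff 0 reproduces the overall rate (2 of 4 concordant)
    expect_equal(curve$accuracy[1], concordance(a, b, des)@rate)
    expect_true(all(diff(curve$n_pairs) <= 0))
    # cutoff above every pair confidence: undefined accuracy, no crash
    expect_true(is.na(curve$accuracy[4]))
    expect_equal(curve$n_pairs[4], 0L)
    # at 0.35 only pairs 1 (conf .4) and 3 (conf .3 < .35 -> out): pair 1
    # and pair 4 (min .4): 1 concordant of 2
    expect_equal(curve$n_pairs[3], 2L)
    expect_equal(curve$accuracy[3], 0.5)

    expect_error(accuracyVsConfidence(a, b, des, cutoffGrid = numeric()),
                 "empty")
    expect_error(accuracyVsConfidence(a, b, des, cutoffGrid = c(0.5, 0.1)),
                 "strictly increasing")
})

test_that("minimum confidence for a target accuracy scans the curve", {
    curve <- data.frame(cutoff = c(0, 0.1, 0.2), n_pairs = c(20, 10, 6),
                        accuracy = c(1, 1, 1))
    expect_equal(minConfidenceForAccuracy(curve, 0.95), 0)
    curve2 <- data.frame(cutoff = c(0, 0.1), n_pairs = c(20, 10),
                         accuracy = c(0.5, 0.5))
    expect_true(is.na(minConfidenceForAccuracy(curve2, 0.95)))
    # points backed by too few pairs are not trusted
    curve3 <- data.frame(cutoff = c(0, 0.3), n_pairs = c(20, 2),
                         accuracy = c(0.6, 1))
    expect_true(is.na(minConfidenceForAccuracy(curve3, 0.95)))
})

test_that("paired expression correlations behave at the extremes", {
    x <- rlnorm(30)
    m <- toyMatrix(cbind(x, x, max(x) + 1 - x, rep(1, 30)),
                   genes = paste0("G", 1:30),
                   samples = c("a1", "b1", "b2", "b3"), kind = "count")
    des <- data.frame(pair_id = c("P1", "P2", "P3"),
                      sample_a_id = c("a1", "a1", "a1"),
                      sample_b_id = c("b1", "b2", "b3"))
    pc <- pairedExpressionCorrelation(m, des)
    expect_equal(pc$rho[1], 1)
    expect_equal(pc$rho[2], -1)
    expect_true(is.na(pc$rho[3]))
    expect_match(pc$note[3], "zero-variance")
})

test_that("Mann-Whitney: exact textbook case and enumeration oracle", {
    cmp <- compareGroups(c(1, 2, 3), c(4, 5, 6))
    expect_equal(cmp$p_value, 0.1)
    expect_equal(cmp$method, "exact")

    # oracle: enumerate all C(n1+n2, n1) group assignments of the pooled
    # values and compute the two-sided p directly from the U distribution
    exactOracle <- function(x, y) {
        pooled <- c(x, y)
        n1 <- length(x)
        idx <- utils::combn(length(pooled), n1)
        r <- rank(pooled)
        uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        uAll <- apply(idx, 2, function(i)
            sum(r[i]) - n1 * (n1 + 1) / 2)
        mu <- n1 * length(y) / 2
        min(1, mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9))
    }
    set.seed(11)
    for (n1 in 2:5) for (n2 in 2:5) {
        x <- rnorm(n1); y <- rnorm(n2)
        expect_equal(compareGroups(x, y)$p_value, exactOracle(x, y),
                     tolerance = 1e-10)
    }
})

test_that("ties fall back to the corrected normal approximation", {
    x <- c(1, 2, 2, 3); y <- c(2, 3, 4, 4)
    cmp <- compareGroups(x, y)
    expect_match(cmp$method, "tie correction")
    expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
})
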