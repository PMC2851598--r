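mkCoex <- function(r, bp = NULL, d = NULL, orientation = "bidirectional") {
    data.frame(pair_id = sprintf("p%d", seq_along(r)),
               orientation = rep_len(orientation, length(r)),
               intergenic_bp = if (is.null(bp)) 0L else bp,
               n_intervening = if (is.null(d)) 0L else d,
               r = r, stringsAsFactors = FALSE)
}

test_that("the intervening-gene profile averages per distance with SEM", {
    coex <- mkCoex(c(0.1, 0.3, 0, 0.2), d = c(0, 0, 1, 1))
    prof <- profileByIntervening(coex, maxD = 1)
    expect_equal(prof$d, c(0, 1))
    expect_equal(prof$mean_r, c(0.2, 0.1))
    expect_equal(prof$n, c(2L, 2L))
    # SEM oracle: sd(c(0, 0.2))/sqrt(2) = 0.1
    expect_equal(prof$sem_r[2], 0.1)
    # maxD = 0: only the direct-neighbour bin
    prof0 <- profileByIntervening(coex, maxD = 0)
    expect_equal(prof0$d, 0)
    # empty intermediate bins are omitted with a message
    expect_message(p <- profileByIntervening(
        mkCoex(c(0.1, 0.2), d = c(0, 2)), maxD = 2), "omitted")
    expect_equal(p$d, c(0, 2))
})

test_that("bp binning is half-open with the boundary in the upper bin", {
    coex <- mkCoex(c(0.5, 0.7), bp = c(399L, 400L))
    prof <- profileByBp(coex, binWidth = 100, maxBp = 2000)
    expect_equal(prof$bin_lo[prof$mean_r == 0.5], 300)
    expect_equal(prof$bin_lo[prof$mean_r == 0.7], 400)
    # orientations absent from the input are absent from the profile
    expect_false("convergent" %in% prof$orientation)
    # overlapping pairs must not reach the bp profile
    expect_error(profileByBp(mkCoex(0.1, bp = -5L)), "negative")
})

test_that("weighted bin means reconstruct the global mean (conservation)", {
    set.seed(11)
    coex <- mkCoex(runif(500, -1, 1), bp = sample(0:1999, 500, TRUE),
                   d = sample(0:5, 500, TRUE),
                   orientation = sample(c("bidirectional", "unidirectional",
                                          "convergent"), 500, TRUE))
    prof <- profileByBp(coex, binWidth = 100, maxBp = 2000)
    expect_equal(sum(prof$mean_r * prof$n) / sum(prof$n), mean(coex$r),
                 tolerance = 1e-12)
    profI <- profileByIntervening(coex, maxD = 5)
    expect_equal(sum(profI$mean_r * profI$n) / sum(profI$n), mean(coex$r),
                 tolerance = 1e-12)
    gm <- groupMeans(coex, splitBp = 400)
    expect_equal(sum(gm$mean_r * gm$n) / sum(gm$n), mean(coex$r),
                 tolerance = 1e-12)
})

test_that("group means match a direct filtering oracle and handle edge splits", {
    set.seed(12)
    coex <- mkCoex(rnorm(300), bp = sample(0:1000, 300, TRUE),
                   orientation = sample(c("bidirectional", "unidirectional",
                                          "convergent"), 300, TRUE))
    gm <- groupMeans(coex, splitBp = 400)
    for (i in seq_len(nrow(gm))) {
        sel <- coex$orientation == gm$orientation[i] &
            (if (gm$distance_class[i] == "short") coex$intergenic_bp < 400
             else coex$intergenic_bp >= 400)
        expect_equal(gm$mean_r[i], mean(coex$r[sel]))
        expect_equal(gm$n[i], sum(sel))
    }
    # all pairs short
    shortOnly <- mkCoex(rnorm(10), bp = rep(10L, 10))
    gmS <- groupMeans(shortOnly, splitBp = 400)
    expect_equal(gmS$n[gmS$group_label == "bidirectional_long"], 0L)
    # splitBp = 0 puts every pair in the long class
    gm0 <- groupMeans(shortOnly, splitBp = 0)
    expect_equal(gm0$n[gm0$group_label == "bidirectional_short"], 0L)
    expect_equal(gm0$n[gm0$group_label == "bidirectional_long"], 10L)
    # splitBp = Inf reproduces single-group (orientation-only) means
    gmI <- groupMeans(coex, splitBp = Inf)
    expect_equal(nrow(gmI), 3L)
    for (ori in unique(coex$orientation))
        expect_equal(gmI$mean_r[gmI$orientation == ori],
                     mean(coex$r[coex$orientation == ori]))
})

test_that("the random background is reproducible and null-centred", {
    set.seed(13)
    mat <- matrix(rnorm(200 * 50), 200, 50,
                  dimnames = list(sprintf("g%03d", 1:200), NULL))
    b1 <- randomBackground(mat, nPairs = 1000, seed = 99)
    b2 <- randomBackground(mat, nPairs = 1000, seed = 99)
    expect_identical(b1$values, b2$values)
    expect_equal(b1$n_pairs, 1000L)
    # independent genes: mean within Monte-Carlo error of 0
    expect_lt(abs(b1$mean_r), 3 * b1$sem_r + 1e-9)
    # single draw works
    expect_length(randomBackground(mat, nPairs = 1, seed = 5)$values, 1L)
    # restricted to protein-coding genes of an annotation
    ann <- mkAnn(c("g001", "g002", "zzz"), "chr1",
                 start = c(1, 1001, 2001), end = c(500, 1500, 2500),
                 strand = "+", biotype = c("protein_coding",
                                           "protein_coding", "other"))
    b3 <- randomBackground(mat, ann, nPairs = 10, seed = 1)
    expect_length(b3$values, 10L)
    expect_error(randomBackground(mat[1, , drop = FALSE], nPairs = 5),
                 "at least 2")
})

test_that("rank-sum p-values match exact enumeration and asymptotics", {
    # exhaustive oracle: all 20 assignments of 6 ranks to sample A
    expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6)), 0.1)
    expect_equal(bruteRankSumP(c(1, 2, 3), c(4, 5, 6)), 0.1)
    # symmetric samples: exact two-sided p of 1
    expect_equal(rankSumTest(c(1, 4, 7), c(2, 5, 8)),
                 bruteRankSumP(c(1, 4, 7), c(2, 5, 8)))
    set.seed(21)
    for (k in 1:20) {
        na <- sample(2:5, 1); nb <- sample(2:5, 1)
        v <- sample(seq(0.01, 1, by = 0.01), na + nb)  # untied
        a <- v[seq_len(na)]; b <- v[-seq_len(na)]
        expect_equal(rankSumTest(a, b), bruteRankSumP(a, b),
                     tolerance = 1e-12)
        # one-sided tests mirror under swapping the samples
        expect_equal(rankSumTest(a, b, "greater"),
                     rankSumTest(b, a, "less"), tolerance = 1e-12)
    }
    # strongly shifted large normals: overwhelming evidence
    set.seed(22)
    expect_lt(rankSumTest(rnorm(200, 5), rnorm(200, 0)), 1e-10)
    expect_error(rankSumTest(numeric(), 1:3), "non-empty")
})

test_that("anti-correlated fraction and the transitive expectation", {
    expect_equal(anticorrelatedFraction(c(-0.1, 0.2, 0.3)), 1 / 3)
    expect_equal(anticorrelatedFraction(c(0.1, 0.2)), 0)
    expect_error(anticorrelatedFraction(numeric()), "no co-expression")
    # independent background: about half the pairs anti-correlated
    set.seed(23)
    mat <- matrix(rnorm(150 * 40), 150, 40,
                  dimnames = list(sprintf("g%03d", 1:150), NULL))
    bg <- randomBackground(mat, nPairs = 4000, seed = 3)
    expect_lt(abs(anticorrelatedFraction(bg$values) - 0.5),
              3 * sqrt(0.25 / 4000))
    # transitive expectation: R_ac^2 = R_ab^2 * R_bc^2 on the r scale
    expect_equal(transitiveExpectedR(0.1, 0.1), 0.01)
    expect_equal(transitiveExpectedR(1, 0.37), 0.37)
    expect_equal(transitiveExpectedR(0, 0.9), 0)
    expect_equal(transitiveExpectedR(-0.5, 0.4), -0.2)
    expect_error(transitiveExpectedR(1.2, 0.1), "\\[-1, 1\\]")
})
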