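grPair <- function(s1, e1, st1, s2, e2, st2) {
    list(GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1), st1),
         GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2), st2))
}

test_that("orientation follows the strand combination of the ordered pair", {
    g <- grPair(1, 100, "-", 500, 600, "+")
    expect_equal(classifyOrientation(g[[1]], g[[2]]), "bidirectional")
    g <- grPair(1, 100, "+", 500, 600, "-")
    expect_equal(classifyOrientation(g[[1]], g[[2]]), "convergent")
    g <- grPair(1, 100, "+", 500, 600, "+")
    expect_equal(classifyOrientation(g[[1]], g[[2]]), "unidirectional")
    # contract: same chromosome, genomic order
    expect_error(classifyOrientation(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+"),
        GenomicRanges::GRanges("chr2", IRanges::IRanges(500, 600), "+")),
        "chromosome")
})

test_that("overlap taxonomy distinguishes 3', 5' and contained geometries", {
    g <- grPair(1, 501, "+", 401, 901, "-")     # tails intersect
    expect_equal(classifyOverlap(g[[1]], g[[2]]), "overlap_3p")
    g <- grPair(1, 501, "-", 401, 901, "+")     # heads intersect
    expect_equal(classifyOverlap(g[[1]], g[[2]]), "overlap_5p")
    g <- grPair(1, 1001, "+", 201, 301, "-")    # nested
    expect_equal(classifyOverlap(g[[1]], g[[2]]), "contained")
    g <- grPair(1, 100, "+", 500, 600, "-")     # no intersection
    expect_equal(classifyOverlap(g[[1]], g[[2]]), "none")
})

test_that("overlap classification is symmetric under swapping gene order", {
    set.seed(42)
    for (k in 1:50) {
        s1 <- sample.int(1000, 1); e1 <- s1 + sample.int(800, 1)
        s2 <- sample.int(1000, 1); e2 <- s2 + sample.int(800, 1)
        st <- sample(c("+", "-"), 2, replace = TRUE)
        a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1), st[1])
        b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2), st[2])
        expect_identical(suppressWarnings(classifyOverlap(a, b)),
                         suppressWarnings(classifyOverlap(b, a)))
    }
})

test_that("same-strand overlaps are flagged unclassifiable with a warning", {
    g <- grPair(1, 500, "+", 400, 900, "+")
    expect_warning(cls <- classifyOverlap(g[[1]], g[[2]]), "unclassifiable")
    expect_true(is.na(cls))
})

test_that("direct neighbours skip pairs separated by non-coding genes", {
    ann <- mkAnn(c("A", "B", "C"), "chr1",
                 start = c(1, 1001, 2001), end = c(500, 1500, 2500),
                 strand = c("+", "+", "+"),
                 biotype = c("protein_coding", "other", "protein_coding"))
    pairs <- directNeighborPairs(ann)
    expect_equal(length(pairs), 0L)  # B intervenes between A and C
    annAll <- mkAnn(c("A", "B", "C"), "chr1",
                    start = c(1, 1001, 2001), end = c(500, 1500, 2500),
                    strand = c("+", "-", "+"))
    tab <- pairTable(directNeighborPairs(annAll))
    expect_equal(tab$pair_id, c("A|B", "B|C"))
    expect_equal(tab$orientation, c("convergent", "bidirectional"))
    expect_true(all(tab$n_intervening == 0L))
    # single-gene chromosome contributes nothing
    one <- mkAnn("solo", "chr9", 1, 100, "+")
    expect_equal(length(directNeighborPairs(one)), 0L)
})

test_that("all-chromosome pairs count interveners and respect the cutoff", {
    ann <- mkAnn(c("A", "B", "C", "D"), "chr1",
                 start = c(1, 1001, 2001, 3001),
                 end = c(500, 1500, 2500, 3500),
                 strand = c("+", "+", "-", "+"))
    tab <- pairTable(allChromosomePairs(ann, maxIntervening = 3))
    expect_equal(nrow(tab), 6L)
    expect_equal(sort(tab$n_intervening), c(0L, 0L, 0L, 1L, 1L, 2L))
    expect_equal(tab$n_intervening[tab$pair_id == "A|D"], 2L)
    # cutoff removes the distant pairs
    tab1 <- pairTable(allChromosomePairs(ann, maxIntervening = 0))
    expect_equal(sort(tab1$pair_id), c("A|B", "B|C", "C|D"))
    # consistency with direct adjacency on an all-coding annotation
    direct <- pairTable(directNeighborPairs(ann))
    expect_equal(tab1[order(tab1$pair_id), names(direct)],
                 direct[order(direct$pair_id), ],
                 ignore_attr = TRUE)
    # two chromosomes with one gene each: no same-chromosome pair
    two <- mkAnn(c("X", "Y"), c("chr1", "chr2"), c(1, 1),
                 c(100, 100), c("+", "-"))
    expect_equal(length(allChromosomePairs(two, maxIntervening = 5)), 0L)
})

test_that("the overlapping-gene filter removes pairs touching overlapped genes", {
    # B overlaps the non-coding gene N; pair A|B must go, pair C|D stays
    ann <- mkAnn(c("A", "B", "N", "C", "D"), "chr1",
                 start = c(1, 1001, 1400, 3001, 4001),
                 end = c(500, 1500, 1600, 3500, 4500),
                 strand = c("+", "+", "-", "+", "+"),
                 biotype = c("protein_coding", "protein_coding", "other",
                             "protein_coding", "protein_coding"))
    pairs <- directNeighborPairs(ann)
    kept <- pairTable(filterOverlappingGenes(pairs, ann))
    expect_false("A|B" %in% kept$pair_id)
    expect_true("C|D" %in% kept$pair_id)
    # annotation without overlaps: identity
    clean <- mkAnn(c("A", "B"), "chr1", c(1, 1001), c(500, 1500),
                   c("+", "-"))
    p2 <- directNeighborPairs(clean)
    expect_equal(pairTable(filterOverlappingGenes(p2, clean)),
                 pairTable(p2))
    # mutually overlapping pair members are themselves removed
    mut <- mkAnn(c("A", "B"), "chr1", c(1, 400), c(500, 900), c("+", "-"))
    p3 <- directNeighborPairs(mut)
    expect_equal(length(p3), 1L)
    expect_equal(length(filterOverlappingGenes(p3, mut)), 0L)
    # after the filter every retained pair has a non-negative gap
    expect_true(all(kept$intergenic_bp >= 0))
})

test_that("tandem-duplicate filtering applies the E-value threshold", {
    ann <- mkAnn(c("A", "B", "C", "D"), "chr1",
                 start = c(1, 1001, 2001, 3001),
                 end = c(500, 1500, 2500, 3500), strand = "+")
    pairs <- directNeighborPairs(ann)
    sim <- data.frame(id_a = c("B", "C"), id_b = c("A", "D"),
                      evalue = c(0.01, 0.5))
    kept <- pairTable(filterTandemDuplicates(pairs, sim, threshold = 0.2))
    expect_false("A|B" %in% kept$pair_id)  # E = 0.01 < 0.2, either order
    expect_true("C|D" %in% kept$pair_id)   # E = 0.5 kept
    # empty table is the identity
    expect_equal(pairTable(filterTandemDuplicates(
        pairs, data.frame(id_a = character(), id_b = character(),
                          evalue = numeric()))),
        pairTable(pairs))
    expect_warning(filterTandemDuplicates(
        pairs, data.frame(id_a = "ZZZ", id_b = "A", evalue = 0.01)),
        "not found")
})

test_that("gene-list exclusion removes pairs containing listed members", {
    ann <- mkAnn(c("A", "B", "C"), "chr1", c(1, 1001, 2001),
                 c(500, 1500, 2500), "+")
    pairs <- directNeighborPairs(ann)
    kept <- pairTable(excludeGeneList(pairs, "A"))
    expect_equal(kept$pair_id, "B|C")
    expect_equal(pairTable(excludeGeneList(pairs, character())),
                 pairTable(pairs))
    expect_warning(out <- excludeGeneList(pairs, "NOPE"), "none of")
    expect_equal(pairTable(out), pairTable(pairs))
})

test_that("emitted pairs re-validate their invariants on random annotations", {
    set.seed(101)
    for (k in 1:25) {
        frame <- randAnnFrame(nGenes = 40)
        ann <- GeneAnnotation(frame)
        pairs <- suppressMessages(directNeighborPairs(ann))
        expect_true(validObject(pairs))
        tab <- pairTable(pairs)
        # orientation partition covers every pair
        expect_equal(sum(tab$orientation %in%
                         c("bidirectional", "unidirectional", "convergent")),
                     nrow(tab))
        ap <- suppressMessages(allChromosomePairs(ann, maxIntervening = 2))
        expect_true(validObject(ap))
    }
})
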