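# End-to-end orchestration: annotation -> pairs -> filters -> co-expression
# -> profiles -> group means -> background -> tests -> decomposition, with
# one JSON-serialisable report collecting every headline number and all
# thresholds used.

#' Run the neighbouring-gene co-expression analysis
#'
#' Executes the full pipeline on an annotation and a log2 expression
#' matrix: extracts direct-neighbour pairs, separates overlapping pairs
#' (analysed by overlap class), filters genes overlapping other genes,
#' optionally removes tandem-duplicate pairs (similarity table, E-value
#' threshold) and listed genes, computes per-pair Pearson co-expression,
#' distance profiles (by intervening genes and by intergenic bp per
#' orientation), orientation and orientation-by-distance group means with
#' rank-sum tests against a random-pair background, anti-correlation
#' fractions, and the chromatin/promoter/interference decomposition.
#'
#' @param annotation A \code{GeneAnnotation} (or path to a GFF3 file).
#' @param mat Expression matrix (or path to a TSV readable by
#'   \code{\link{readExpressionMatrix}}).
#' @param splitBp Short/long distance split in bp (default 400; the
#'   boundary goes to the long class).
#' @param binWidth,maxBp Binning of the per-orientation distance profile
#'   (defaults 100 bp bins over [0, 2000)).
#' @param maxIntervening Range of the intervening-gene profile (default 10).
#' @param minObs Minimum complete experiments per pair (default 10).
#' @param nRandom Random background size (default 100000).
#' @param similarity Optional pairwise-similarity table for the tandem-
#'   duplicate filter (see \code{\link{filterTandemDuplicates}}).
#' @param evalueThreshold E-value cutoff of the tandem filter (default 0.2).
#' @param excludeIds Optional gene ids to exclude (e.g. bicistronic and
#'   fused monocistronic transcripts).
#' @param seed Seed for the random background (default 1).
#' @param rounding Rounding mode of the decomposition (default
#'   \code{"full"}).
#' @return A named list (the report); see the vignette for the field
#'   layout.  Serialise with \code{\link{writeReport}}.
#' @export
analyzeNeighbors <- function(annotation, mat,
                             splitBp = 400, binWidth = 100, maxBp = 2000,
                             maxIntervening = 10, minObs = 10,
                             nRandom = 100000,
                             similarity = NULL, evalueThreshold = 0.2,
                             excludeIds = NULL,
                             seed = 1, rounding = "full") {
    if (is.character(annotation)) annotation <- readGFF3(annotation)
    if (is.character(mat)) mat <- readExpressionMatrix(mat)
    bt <- geneBiotypes(annotation)
    direct <- directNeighborPairs(annotation)
    nDirect <- length(direct)
    # overlapping opposing-strand pairs, analysed by their overlap class
    dtab <- pairTable(direct)
    overlapPairs <- new("NeighborPairs",
                        table = dtab[!is.na(dtab$overlap_class) &
                                     dtab$overlap_class != "none", ,
                                     drop = FALSE])
    nonOv <- filterOverlappingGenes(direct, annotation)
    nNonOverlapping <- length(nonOv)
    if (!is.null(similarity))
        nonOv <- filterTandemDuplicates(nonOv, similarity,
                                        threshold = evalueThreshold)
    nAfterTandem <- length(nonOv)
    if (!is.null(excludeIds) && length(excludeIds))
        nonOv <- excludeGeneList(nonOv, excludeIds)
    nAfterExclusion <- length(nonOv)
    message("pairs: direct=", nDirect,
            " non-overlapping=", nNonOverlapping,
            " after-tandem=", nAfterTandem,
            " after-exclusion=", nAfterExclusion)
    coex <- coexpressPairs(mat, nonOv, minObs = minObs)
    background <- randomBackground(mat, annotation, nPairs = nRandom,
                                   seed = seed)
    table1 <- groupMeans(coex, splitBp = Inf, background = background)
    table1 <- table1[table1$n > 0, , drop = FALSE]
    table2 <- groupMeans(coex, splitBp = splitBp, background = background)
    profiles <- list(
        by_intervening = {
            all10 <- allChromosomePairs(annotation,
                                        maxIntervening = maxIntervening)
            all10 <- filterOverlappingGenes(all10, annotation)
            profileByIntervening(coexpressPairs(mat, all10,
                                                minObs = minObs),
                                 maxD = maxIntervening)
        },
        by_bp = profileByBp(coex, binWidth = binWidth, maxBp = maxBp))
    # overlap taxonomy (sense-antisense pairs): co-expression and abundance
    ovCoex <- coexpressPairs(mat, overlapPairs, minObs = minObs)
    table3 <- do.call(rbind, lapply(
        c("overlap_3p", "overlap_5p", "contained"), function(cls) {
            v <- ovCoex$r[ovCoex$overlap_class == cls & !is.na(ovCoex$r)]
            ids <- unique(unlist(ovCoex[ovCoex$overlap_class == cls,
                                        c("left_id", "right_id")]))
            ab <- if (length(ids))
                mean(meanAbundance(mat, ids[ids %in% rownames(mat)]))
            else NA_real_
            p <- if (length(v))
                rankSumTest(v, background$values) else NA_real_
            data.frame(overlap_class = cls, n = length(v),
                       mean_r = if (length(v)) mean(v) else NA_real_,
                       mean_abundance = ab, p_vs_random = p,
                       stringsAsFactors = FALSE)
        }))
    decomposition <- decomposeCoexpression(table2, background,
                                           rounding = rounding)
    oriCounts <- as.list(table(factor(pairTable(nonOv)$orientation,
                                      levels = ORIENTATIONS)))
    list(
        counts = list(
            genes = length(annotation),
            protein_coding = sum(bt == "protein_coding"),
            direct_pairs = nDirect,
            overlapping_pairs = length(overlapPairs),
            non_overlapping_pairs = nNonOverlapping,
            after_tandem_filter = nAfterTandem,
            after_exclusion = nAfterExclusion,
            orientation = lapply(oriCounts, as.integer),
            coexpression_drops = attr(coex, "drops")),
        table1 = table1,
        table2 = table2,
        table3 = table3,
        profiles = profiles,
        random_background = list(n_pairs = background$n_pairs,
                                 mean_r = background$mean_r,
                                 sem_r = background$sem_r,
                                 seed = background$seed),
        anticorrelated = list(
            neighbours = anticorrelatedFraction(coex$r),
            random = anticorrelatedFraction(background$values)),
        decomposition = decompositionAsList(decomposition),
        thresholds = list(split_bp = splitBp, bin_width = binWidth,
                          max_bp = maxBp, max_intervening = maxIntervening,
                          min_obs = minObs, n_random = nRandom,
                          evalue_threshold = evalueThreshold,
                          tandem_filter = !is.null(similarity),
                          exclusion_list = !is.null(excludeIds) &&
                              length(excludeIds) > 0,
                          rounding = rounding, seed = seed))
}

#' Serialise a pipeline report to JSON
#'
#' @param report Output of \code{\link{analyzeNeighbors}}.
#' @param path Output file path.
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
    invisible(path)
}
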