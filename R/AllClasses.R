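#' @import methods
#' @importFrom GenomicRanges GRanges granges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

ORIENTATIONS <- c("bidirectional", "unidirectional", "convergent")
OVERLAP_CLASSES <- c("none", "overlap_3p", "overlap_5p", "contained")
BIOTYPES <- c("protein_coding", "other")

PAIR_COLUMNS <- c("pair_id", "chrom", "left_id", "right_id",
                  "left_start", "left_end", "left_strand",
                  "right_start", "right_end", "right_strand",
                  "orientation", "overlap_class",
                  "intergenic_bp", "n_intervening")

#' Gene annotation container
#'
#' Holds one transcript-bearing record per gene as a \code{GRanges} (1-based,
#' closed intervals, the Bioconductor convention), sorted strictly by
#' (chromosome, start, end, gene_id).  Metadata columns \code{gene_id}
#' (unique) and \code{biotype} (\code{"protein_coding"} or \code{"other"})
#' are required.  The range of each gene spans its outermost transcript
#' boundaries (transcription start to transcription end).
#'
#' @slot genes A \code{GRanges} with mcols \code{gene_id} and \code{biotype}.
#' @export
setClass("GeneAnnotation", slots = c(genes = "GRanges"))

setValidity("GeneAnnotation", function(object) {
    gr <- object@genes
    mc <- mcols(gr)
    msgs <- character()
    if (!all(c("gene_id", "biotype") %in% colnames(mc)))
        return("mcols must contain 'gene_id' and 'biotype'")
    if (anyDuplicated(mc$gene_id))
        msgs <- c(msgs, "gene_id values must be unique")
    if (!all(mc$biotype %in% BIOTYPES))
        msgs <- c(msgs, "biotype must be 'protein_coding' or 'other'")
    if (length(gr) && !all(as.character(strand(gr)) %in% c("+", "-")))
        msgs <- c(msgs, "strand must be '+' or '-' for every gene")
    if (length(gr) > 1) {
        o <- order(as.factor(seqnames(gr)), start(gr), end(gr), mc$gene_id)
        if (!identical(o, seq_along(gr)))
            msgs <- c(msgs, "genes must be sorted by (chrom, start, end, gene_id)")
    }
    if (length(msgs)) msgs else TRUE
})

#' Collection of classified neighbouring gene pairs
#'
#' Each row is an ordered gene pair on one chromosome (left gene starts at or
#' before the right gene), carrying its orientation (\code{bidirectional},
#' \code{unidirectional}, \code{convergent}), its overlap class on opposing
#' strands (\code{none}, \code{overlap_3p}, \code{overlap_5p},
#' \code{contained}; \code{NA} for the unclassifiable same-strand overlap
#' geometry), the intergenic distance in bp between transcript boundaries
#' (negative when the transcripts overlap) and the number of intervening
#' annotated genes.
#'
#' @slot table A \code{data.frame} with the columns listed in
#'   \code{coexNeighbors:::PAIR_COLUMNS}.
#' @export
setClass("NeighborPairs", slots = c(table = "data.frame"))

setValidity("NeighborPairs", function(object) {
    tab <- object@table
    msgs <- character()
    if (!all(PAIR_COLUMNS %in% colnames(tab)))
        return(paste("pair table must contain columns:",
                     paste(setdiff(PAIR_COLUMNS, colnames(tab)), collapse = ", ")))
    if (nrow(tab)) {
        if (!all(tab$left_start <= tab$right_start))
            msgs <- c(msgs, "pairs must be in genomic order (left_start <= right_start)")
        if (!all(tab$orientation %in% ORIENTATIONS))
            msgs <- c(msgs, "invalid orientation label")
        if (!all(is.na(tab$overlap_class) | tab$overlap_class %in% OVERLAP_CLASSES))
            msgs <- c(msgs, "invalid overlap_class label")
        none <- !is.na(tab$overlap_class) & tab$overlap_class == "none"
        if (!all(tab$intergenic_bp[none] >= 0))
            msgs <- c(msgs, "overlap_class 'none' requires intergenic_bp >= 0")
        ov <- !is.na(tab$overlap_class) & tab$overlap_class != "none"
        if (!all(tab$intergenic_bp[ov] < 0))
            msgs <- c(msgs, "overlapping classes require intergenic_bp < 0")
        if (!all(tab$n_intervening >= 0))
            msgs <- c(msgs, "n_intervening must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' Decomposition of close-neighbour co-expression
#'
#' Result of separating the co-expression of direct gene neighbours into a
#' shared-chromatin component (estimated from distant divergent/convergent
#' pairs against the random background), the fraction of close bi-directional
#' co-expression attributable to promoter sharing, and the relative reduction
#' of chromatin-mediated co-expression in close convergent pairs
#' (transcriptional interference).  \code{variantInterferenceFraction} is the
#' baseline-consistent variant that subtracts the random mean from the close
#' convergent mean before forming the ratio.
#'
#' @slot chromatinEffect numeric(1).
#' @slot promoterFraction numeric(1).
#' @slot interferenceFraction numeric(1).
#' @slot variantInterferenceFraction numeric(1).
#' @slot inputsUsed named list of the five feeding quantities.
#' @slot rounding \code{"full"} or \code{"printed"}.
#' @slot se named list of delta-method standard errors (may be empty).
#' @export
setClass("DecompositionResult",
         slots = c(chromatinEffect = "numeric",
                   promoterFraction = "numeric",
                   interferenceFraction = "numeric",
                   variantInterferenceFraction = "numeric",
                   inputsUsed = "list",
                   rounding = "character",
                   se = "list"))

setValidity("DecompositionResult", function(object) {
    needed <- c("mean_bi_long", "mean_conv_long", "mean_bi_short",
                "mean_conv_short", "random_mean")
    if (!all(needed %in% names(object@inputsUsed)))
        return("inputsUsed must record all five feeding quantities")
    if (!object@rounding %in% c("full", "printed"))
        return("rounding must be 'full' or 'printed'")
    # promoterFraction <= 1 whenever the chromatin effect is non-negative
    if (!is.na(object@promoterFraction) &&
        !is.na(object@chromatinEffect) && object@chromatinEffect >= 0 &&
        object@promoterFraction > 1 + 1e-12)
        return("promoterFraction must be <= 1 for a non-negative chromatin effect")
    TRUE
})
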