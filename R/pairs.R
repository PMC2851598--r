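# Pair extraction and classification.
#
# All functions place the gene with the smaller start coordinate on the
# left; orientation is read from the strand combination of the ordered pair,
# intergenic distance is the number of bases strictly between the two
# transcript spans (start(right) - end(left) - 1, so abutting transcripts
# give 0 and overlapping transcripts a negative value).

.orientationFromStrands <- function(sl, sr) {
    ifelse(sl == "-" & sr == "+", "bidirectional",
    ifelse(sl == "+" & sr == "-", "convergent", "unidirectional"))
}

# vectorised overlap taxonomy for ordered pairs; NA = same-strand overlap
.overlapClassVec <- function(ls, le, rs, re, sl, sr) {
    isect <- pmin(le, re) - pmax(ls, rs) + 1L
    out <- rep("none", length(ls))
    ov <- isect > 0L
    opp <- sl != sr
    contained <- (rs >= ls & re <= le) | (ls >= rs & le <= re)
    out[ov & opp & contained] <- "contained"
    part <- ov & opp & !contained
    out[part & sl == "+"] <- "overlap_3p"
    out[part & sl == "-"] <- "overlap_5p"
    out[ov & !opp] <- NA_character_
    out
}

#' Classify the relative orientation of an ordered gene pair
#'
#' For genes in genomic order (left starts at or before right):
#' \code{(-,+)} is \code{bidirectional} (divergent, the 5' ends face each
#' other), \code{(+,-)} is \code{convergent} (3' ends face each other), and
#' equal strands are \code{unidirectional}.  Arguments are parallel
#' \code{GRanges}; pairs spanning different chromosomes are an error.
#'
#' @param left,right Parallel \code{GRanges} in genomic order.
#' @return Character vector of orientation labels.
#' @export
classifyOrientation <- function(left, right) {
    stopifnot(length(left) == length(right))
    if (!all(as.character(seqnames(left)) == as.character(seqnames(right))))
        stop("left and right genes must be on the same chromosome")
    if (any(start(left) > start(right)))
        stop("pairs must be in genomic order (left starts first)")
    .orientationFromStrands(as.character(strand(left)),
                            as.character(strand(right)))
}

#' Classify the overlap geometry of a gene pair
#'
#' Opposing-strand taxonomy: no coordinate intersection is \code{none}; one
#' transcript fully inside the other is \code{contained}; a partial
#' intersection of two 3' ends (convergent geometry) is \code{overlap_3p};
#' a partial intersection of two 5' ends (divergent geometry) is
#' \code{overlap_5p}.  Same-strand intersections fall outside the taxonomy
#' and return \code{NA} with a warning.  The result is invariant under
#' swapping the two arguments.
#'
#' @param left,right Parallel \code{GRanges} on one chromosome each.
#' @return Character vector of overlap classes (\code{NA} = unclassifiable).
#' @export
classifyOverlap <- function(left, right) {
    stopifnot(length(left) == length(right))
    if (!all(as.character(seqnames(left)) == as.character(seqnames(right))))
        stop("left and right genes must be on the same chromosome")
    swap <- start(left) > start(right) |
        (start(left) == start(right) & end(left) > end(right))
    ls <- ifelse(swap, start(right), start(left))
    le <- ifelse(swap, end(right), end(left))
    rs <- ifelse(swap, start(left), start(right))
    re <- ifelse(swap, end(left), end(right))
    sl <- ifelse(swap, as.character(strand(right)), as.character(strand(left)))
    sr <- ifelse(swap, as.character(strand(left)), as.character(strand(right)))
    out <- .overlapClassVec(ls, le, rs, re, sl, sr)
    if (anyNA(out))
        warning(sum(is.na(out)),
                " same-strand overlapping pair(s) are unclassifiable")
    out
}

#' Intergenic distance between transcript boundaries
#'
#' Number of base pairs strictly between the two transcript spans,
#' \code{start(right) - end(left) - 1}: abutting transcripts give 0,
#' intersecting transcripts a negative value.
#'
#' @param left,right Parallel \code{GRanges} in genomic order.
#' @return Integer vector of distances in bp.
#' @export
intergenicBp <- function(left, right) {
    stopifnot(length(left) == length(right))
    if (!all(as.character(seqnames(left)) == as.character(seqnames(right))))
        stop("left and right genes must be on the same chromosome")
    if (any(start(left) > start(right)))
        stop("pairs must be in genomic order (left starts first)")
    start(right) - end(left) - 1L
}

# assemble a NeighborPairs from an ordered (left, right) index selection of
# the annotation frame
.buildPairs <- function(frame, li, ri, nIntervening) {
    tab <- data.frame(
        pair_id = paste(frame$gene_id[li], frame$gene_id[ri], sep = "|"),
        chrom = frame$chrom[li],
        left_id = frame$gene_id[li],
        right_id = frame$gene_id[ri],
        left_start = frame$start[li], left_end = frame$end[li],
        left_strand = frame$strand[li],
        right_start = frame$start[ri], right_end = frame$end[ri],
        right_strand = frame$strand[ri],
        orientation = .orientationFromStrands(frame$strand[li],
                                              frame$strand[ri]),
        overlap_class = .overlapClassVec(frame$start[li], frame$end[li],
                                         frame$start[ri], frame$end[ri],
                                         frame$strand[li], frame$strand[ri]),
        intergenic_bp = frame$start[ri] - frame$end[li] - 1L,
        n_intervening = as.integer(nIntervening),
        stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    nUncls <- sum(is.na(tab$overlap_class))
    if (nUncls)
        message(nUncls, " same-strand overlapping pair(s) left unclassified")
    new("NeighborPairs", table = tab)
}

#' Direct chromosomal neighbour pairs
#'
#' Emits one pair per adjacent gene pair per chromosome, where adjacency is
#' over \emph{all} annotated genes (any biotype), but only
#' protein-coding/protein-coding pairs are returned: a protein-coding gene
#' whose immediate neighbour is non-coding forms no pair, because the
#' non-coding gene intervenes.  All pairs have \code{n_intervening = 0}.
#'
#' @param ann A \code{GeneAnnotation}.
#' @return A \code{NeighborPairs}.
#' @export
directNeighborPairs <- function(ann) {
    frame <- .annotationFrame(ann)
    li <- integer(0); ri <- integer(0)
    for (ch in unique(frame$chrom)) {
        idx <- which(frame$chrom == ch)
        if (length(idx) < 2) next
        a <- idx[-length(idx)]
        b <- idx[-1]
        keep <- frame$biotype[a] == "protein_coding" &
                frame$biotype[b] == "protein_coding"
        li <- c(li, a[keep]); ri <- c(ri, b[keep])
    }
    .buildPairs(frame, li, ri, rep(0L, length(li)))
}

#' All same-chromosome gene pairs up to a number of intervening genes
#'
#' Pairs every protein-coding gene with every other protein-coding gene on
#' the same chromosome.  \code{n_intervening} counts annotated genes of any
#' biotype whose transcript span lies strictly between the facing transcript
#' boundaries of the pair; pairs with more than \code{maxIntervening}
#' interveners are omitted for tractability.
#'
#' @param ann A \code{GeneAnnotation}.
#' @param maxIntervening Non-negative integer cutoff.
#' @return A \code{NeighborPairs}.
#' @export
allChromosomePairs <- function(ann, maxIntervening) {
    stopifnot(maxIntervening >= 0)
    frame <- .annotationFrame(ann)
    li <- integer(0); ri <- integer(0); nint <- integer(0)
    for (ch in unique(frame$chrom)) {
        idx <- which(frame$chrom == ch)
        G <- length(idx)
        if (G < 2) next
        st <- frame$start[idx]; en <- frame$end[idx]
        pc <- frame$biotype[idx] == "protein_coding"
        for (i in seq_len(G - 1)) {
            if (!pc[i]) next
            j <- (i + 1L):G
            j <- j[pc[j]]
            if (!length(j)) next
            eligEnds <- sort(en[st > en[i]])
            cnt <- findInterval(st[j] - 1L, eligEnds)
            keep <- cnt <= maxIntervening
            li <- c(li, rep(idx[i], sum(keep)))
            ri <- c(ri, idx[j[keep]])
            nint <- c(nint, cnt[keep])
        }
    }
    .buildPairs(frame, li, ri, nint)
}

#' Remove pairs involving genes that overlap any other gene
#'
#' Retains only pairs where neither member's transcript span intersects the
#' span of any other annotated gene (any biotype, either strand).  Pairs of
#' mutually overlapping genes are removed here and analysed separately via
#' their \code{overlap_class}.
#'
#' @param pairs A \code{NeighborPairs}.
#' @param ann The \code{GeneAnnotation} the pairs came from.
#' @return A filtered \code{NeighborPairs}.
#' @export
filterOverlappingGenes <- function(pairs, ann) {
    gr <- geneRanges(ann)
    nOv <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
    overlapping <- mcols(gr)$gene_id[nOv > 1]
    tab <- pairTable(pairs)
    keep <- !(tab$left_id %in% overlapping) & !(tab$right_id %in% overlapping)
    new("NeighborPairs", table = tab[keep, , drop = FALSE])
}

#' Remove putative tandem duplicate pairs by sequence similarity
#'
#' Drops pairs whose two members appear together (in either order) in the
#' provided pairwise-similarity table with an E-value below the threshold.
#' The similarity table is consumed, not computed: the first three columns
#' are taken as (id_a, id_b, evalue).
#'
#' @param pairs A \code{NeighborPairs}.
#' @param similarity A \code{data.frame} of pairwise hits; may have 0 rows,
#'   in which case the filter is the identity.
#' @param threshold E-value cutoff; hits strictly below it mark duplicates.
#' @return A filtered \code{NeighborPairs}.
#' @export
filterTandemDuplicates <- function(pairs, similarity, threshold = 0.2) {
    tab <- pairTable(pairs)
    if (is.null(similarity) || nrow(similarity) == 0)
        return(pairs)
    ida <- as.character(similarity[[1]])
    idb <- as.character(similarity[[2]])
    ev <- as.numeric(similarity[[3]])
    known <- unique(c(tab$left_id, tab$right_id))
    unknown <- unique(c(ida, idb)[!c(ida, idb) %in% known])
    if (length(unknown))
        warning(length(unknown),
                " similarity-table id(s) not found among pair members; ignored")
    hit <- ev < threshold
    dupKey <- paste(pmin(ida[hit], idb[hit]), pmax(ida[hit], idb[hit]))
    pairKey <- paste(pmin(tab$left_id, tab$right_id),
                     pmax(tab$left_id, tab$right_id))
    new("NeighborPairs", table = tab[!pairKey %in% dupKey, , drop = FALSE])
}

#' Remove pairs containing listed genes
#'
#' Used to exclude externally identified gene sets (e.g. bicistronic and
#' fused monocistronic transcripts) from the pair analysis.
#'
#' @param pairs A \code{NeighborPairs}.
#' @param excludeIds Character vector of gene ids.
#' @return A filtered \code{NeighborPairs}.
#' @export
excludeGeneList <- function(pairs, excludeIds) {
    tab <- pairTable(pairs)
    if (!length(excludeIds))
        return(pairs)
    present <- excludeIds %in% c(tab$left_id, tab$right_id)
    if (!any(present))
        warning("none of the excluded gene ids occur in the pair set")
    keep <- !(tab$left_id %in% excludeIds) & !(tab$right_id %in% excludeIds)
    new("NeighborPairs", table = tab[keep, , drop = FALSE])
}

#' @rdname NeighborPairs-class
#' @param x A \code{NeighborPairs}.
#' @export
setMethod("pairTable", "NeighborPairs", function(x) x@table)

#' @rdname NeighborPairs-class
#' @export
setMethod("pairOrientation", "NeighborPairs",
          function(x) x@table$orientation)

#' @rdname NeighborPairs-class
#' @export
setMethod("length", "NeighborPairs", function(x) nrow(x@table))

setMethod("show", "NeighborPairs", function(object) {
    tab <- object@table
    cat("NeighborPairs with", nrow(tab), "pairs\n")
    if (nrow(tab)) {
        cnt <- table(factor(tab$orientation, levels = ORIENTATIONS))
        cat("  orientation:",
            paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", "),
            "\n")
        cat("  overlapping:", sum(tab$intergenic_bp < 0), "\n")
    }
})

#' Write a pair table to TSV
#'
#' @param pairs A \code{NeighborPairs}.
#' @param path Output file path.
#' @export
writePairTable <- function(pairs, path) {
    cols <- c("pair_id", "chrom", "left_id", "right_id", "orientation",
              "overlap_class", "intergenic_bp", "n_intervening")
    utils::write.table(pairTable(pairs)[, cols], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
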