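#' Construct a GeneAnnotation
#'
#' Builds the sorted annotation container from either a \code{GRanges} with
#' mcols \code{gene_id} and \code{biotype}, or a \code{data.frame} with
#' columns \code{gene_id}, \code{chrom}, \code{start}, \code{end},
#' \code{strand}, and optionally \code{biotype} (default
#' \code{"protein_coding"}).  Coordinates are 1-based closed transcript
#' spans, as in GFF3.
#'
#' @param genes A \code{GRanges} or \code{data.frame} (see Details).
#' @return A \code{GeneAnnotation}.
#' @examples
#' ann <- GeneAnnotation(data.frame(
#'     gene_id = c("g1", "g2"), chrom = "chr1",
#'     start = c(1, 1001), end = c(600, 1800), strand = c("+", "-")))
#' geneIds(ann)
#' @export
GeneAnnotation <- function(genes = GenomicRanges::GRanges()) {
    if (is.data.frame(genes)) {
        if (!"biotype" %in% colnames(genes))
            genes$biotype <- "protein_coding"
        gr <- GenomicRanges::GRanges(
            seqnames = as.character(genes$chrom),
            ranges = IRanges::IRanges(start = genes$start, end = genes$end),
            strand = as.character(genes$strand))
        mcols(gr)$gene_id <- as.character(genes$gene_id)
        mcols(gr)$biotype <- as.character(genes$biotype)
        genes <- gr
    }
    if (length(genes)) {
        o <- order(as.factor(seqnames(genes)), start(genes), end(genes),
                   mcols(genes)$gene_id)
        genes <- genes[o]
    } else {
        mcols(genes)$gene_id <- character(0)
        mcols(genes)$biotype <- character(0)
    }
    new("GeneAnnotation", genes = genes)
}

#' Read a genome annotation from GFF3
#'
#' Imports gene features from a GFF3 file (1-based closed coordinates on
#' disk, kept 1-based closed in the returned \code{GRanges}) and infers each
#' gene's biotype.  Features of type \code{gene} are classified by their
#' \code{biotype}/\code{gene_biotype}/\code{locus_type} attribute when
#' present (anything other than \code{protein_coding} maps to \code{other});
#' a \code{gene} feature without such an attribute is taken as protein
#' coding.  Features of type \code{ncRNA_gene}, \code{pseudogene} or
#' \code{transposable_element_gene} become \code{other}.  All non-gene
#' features (mRNA, exon, CDS, ...) are ignored.  Genes without a \code{+} or
#' \code{-} strand are rejected with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A \code{GeneAnnotation}.
#' @export
readGFF3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(mcols(gr)$type)
    geneTypes <- c("gene", "ncRNA_gene", "pseudogene",
                   "transposable_element_gene")
    gr <- gr[type %in% geneTypes]
    if (!length(gr)) {
        warning("no gene features found in ", path)
        return(GeneAnnotation())
    }
    type <- as.character(mcols(gr)$type)
    bad <- !as.character(strand(gr)) %in% c("+", "-")
    if (any(bad)) {
        warning(sum(bad), " gene feature(s) without '+'/'-' strand rejected")
        gr <- gr[!bad]
        type <- type[!bad]
    }
    mc <- mcols(gr)
    ids <- if ("ID" %in% colnames(mc)) as.character(mc$ID) else NA_character_
    if ("Name" %in% colnames(mc))
        ids <- ifelse(is.na(ids), as.character(mc$Name), ids)
    if (anyNA(ids))
        stop("gene feature(s) without an ID/Name attribute")
    bt <- rep(NA_character_, length(gr))
    for (col in c("biotype", "gene_biotype", "locus_type"))
        if (col %in% colnames(mc))
            bt <- ifelse(is.na(bt), as.character(mc[[col]]), bt)
    biotype <- ifelse(type != "gene", "other",
               ifelse(is.na(bt) | bt == "protein_coding",
                      "protein_coding", "other"))
    out <- granges(gr)
    mcols(out) <- NULL
    mcols(out)$gene_id <- ids
    mcols(out)$biotype <- biotype
    GeneAnnotation(out)
}

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneRanges", "GeneAnnotation", function(x) x@genes)

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneIds", "GeneAnnotation",
          function(x) mcols(x@genes)$gene_id)

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneBiotypes", "GeneAnnotation", function(x) {
    bt <- mcols(x@genes)$biotype
    names(bt) <- mcols(x@genes)$gene_id
    bt
})

#' @rdname GeneAnnotation-class
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

setMethod("show", "GeneAnnotation", function(object) {
    bt <- mcols(object@genes)$biotype
    cat("GeneAnnotation with", length(object@genes), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "chromosome(s);", sum(bt == "protein_coding"), "protein coding\n")
})

# annotation as a plain per-chromosome data.frame (internal work-horse view)
.annotationFrame <- function(ann) {
    gr <- geneRanges(ann)
    data.frame(gene_id = mcols(gr)$gene_id,
               chrom = as.character(seqnames(gr)),
               start = start(gr), end = end(gr),
               strand = as.character(strand(gr)),
               biotype = mcols(gr)$biotype,
               stringsAsFactors = FALSE)
}
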