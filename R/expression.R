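# Expression matrix I/O and pairwise Pearson co-expression.
#
# The matrix holds log2-scale signal values, genes in rows, experiments in
# columns; missing cells are allowed and correlations use pairwise-complete
# experiments with a minimum-observation rule.

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of experiment ids and a first column of gene ids.
#' Empty cells become missing values.  Ragged rows and duplicated gene ids
#' are errors.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
readExpressionMatrix <- function(path) {
    nf <- utils::count.fields(path, sep = "\t", quote = "",
                              blank.lines.skip = FALSE)
    if (length(unique(nf)) > 1)
        stop("ragged expression table: line ",
             which(nf != nf[1])[1], " has ", nf[nf != nf[1]][1],
             " fields, expected ", nf[1])
    df <- utils::read.delim(path, check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated gene id(s) in expression matrix: ",
             paste(unique(dup), collapse = ", "))
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat))
        mat <- apply(df[, -1, drop = FALSE], 2, as.numeric)
    rownames(mat) <- ids
    mat
}

# standardise rows to zero mean / unit variance over non-missing entries;
# rows without variance get NA (flagged undefined downstream)
.rowStandardize <- function(mat) {
    mu <- rowMeans(mat)
    ctr <- mat - mu
    sd <- sqrt(rowSums(ctr^2) / (ncol(mat) - 1))
    z <- ctr / sd
    z[sd == 0, ] <- NA_real_
    z
}

# correlations for index pairs (li, ri) of a complete matrix, chunked to
# bound the memory of the row products
.pairCorComplete <- function(z, li, ri, chunk = 20000L) {
    n <- ncol(z)
    out <- numeric(length(li))
    for (lo in seq(1L, length(li), by = chunk)) {
        hi <- min(lo + chunk - 1L, length(li))
        out[lo:hi] <- rowSums(z[li[lo:hi], , drop = FALSE] *
                              z[ri[lo:hi], , drop = FALSE]) / (n - 1)
    }
    out
}

#' Pearson co-expression of one gene pair
#'
#' Correlation over the experiments where both genes have a value.  If fewer
#' than \code{minObs} complete experiments remain, or either vector has zero
#' variance over them, the value is flagged undefined (\code{r = NA},
#' \code{defined = FALSE}) rather than substituted.
#'
#' @param mat Expression matrix (genes x experiments, rownames = gene ids).
#' @param geneA,geneB Gene ids (must be rows of \code{mat}).
#' @param minObs Minimum number of complete experiments (default 10).
#' @return List with \code{r}, \code{nObs}, \code{defined}.
#' @export
pairPearson <- function(mat, geneA, geneB, minObs = 10) {
    for (g in c(geneA, geneB))
        if (!g %in% rownames(mat)) stop("gene not in matrix: ", g)
    x <- mat[geneA, ]; y <- mat[geneB, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < minObs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(list(r = NA_real_, nObs = n, defined = FALSE))
    list(r = stats::cor(x[ok], y[ok]), nObs = n, defined = TRUE)
}

#' Co-expression of a pair collection
#'
#' One Pearson correlation per pair with both genes measured.  Pairs with an
#' unmeasured gene are dropped; pairs with too few complete experiments or a
#' zero-variance vector are kept with \code{r = NA} so downstream stages can
#' report them.  Drop counts are attached as attribute \code{"drops"}
#' (\code{unmeasured}, \code{undefined}).
#'
#' @param mat Expression matrix.
#' @param pairs A \code{NeighborPairs}.
#' @param minObs Minimum complete experiments per pair (default 10).
#' @return \code{data.frame} with the pair metadata plus \code{r} and
#'   \code{n_obs}.
#' @export
coexpressPairs <- function(mat, pairs, minObs = 10) {
    tab <- pairTable(pairs)
    measured <- tab$left_id %in% rownames(mat) &
                tab$right_id %in% rownames(mat)
    out <- tab[measured, c("pair_id", "left_id", "right_id", "orientation",
                           "overlap_class", "intergenic_bp", "n_intervening"),
               drop = FALSE]
    if (nrow(out) == 0) {
        out$r <- numeric(0); out$n_obs <- integer(0)
        attr(out, "drops") <- list(unmeasured = sum(!measured), undefined = 0L)
        return(out)
    }
    li <- match(out$left_id, rownames(mat))
    ri <- match(out$right_id, rownames(mat))
    if (!anyNA(mat) && ncol(mat) >= minObs) {
        z <- .rowStandardize(mat)
        out$r <- .pairCorComplete(z, li, ri)
        out$n_obs <- rep(ncol(mat), nrow(out))
    } else {
        res <- mapply(function(a, b) {
            p <- pairPearson(mat, a, b, minObs = minObs)
            c(p$r, p$nObs)
        }, out$left_id, out$right_id)
        out$r <- res[1, ]
        out$n_obs <- as.integer(res[2, ])
    }
    rownames(out) <- NULL
    attr(out, "drops") <- list(unmeasured = sum(!measured),
                               undefined = sum(is.na(out$r)))
    out
}

#' Mean expression abundance per gene
#'
#' Mean of the log2 signal values across experiments (missing values
#' excluded).  Genes absent from the matrix are dropped with a warning.
#'
#' @param mat Expression matrix.
#' @param geneIds Character vector of gene ids.
#' @return Named numeric vector of mean log2 abundances.
#' @export
meanAbundance <- function(mat, geneIds) {
    present <- geneIds %in% rownames(mat)
    if (any(!present))
        warning(sum(!present), " gene(s) not in matrix dropped from abundance")
    ids <- geneIds[present]
    if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
    rowMeans(mat[ids, , drop = FALSE], na.rm = TRUE)
}
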