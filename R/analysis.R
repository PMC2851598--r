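# Aggregate statistics over pairwise co-expression values: distance
# profiles, orientation/distance group means, random-pair background,
# rank-sum tests, anti-correlation fraction and the transitive expectation.

.sem <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
}

#' Co-expression profile by number of intervening genes
#'
#' Averages co-expression over all pairs at the same distance, where
#' distance is the number of intervening annotated genes.  One bin per
#' integer distance in \code{[0, maxD]}; empty bins are omitted.
#'
#' @param coex Output of \code{\link{coexpressPairs}} (columns \code{r},
#'   \code{n_intervening}).
#' @param maxD Largest distance to report.
#' @return \code{data.frame} with \code{d}, \code{mean_r}, \code{sem_r},
#'   \code{n}.
#' @export
profileByIntervening <- function(coex, maxD) {
    coex <- coex[!is.na(coex$r) & coex$n_intervening <= maxD, , drop = FALSE]
    ds <- sort(unique(coex$n_intervening))
    empty <- setdiff(0:maxD, ds)
    if (length(empty))
        message(length(empty), " empty distance bin(s) omitted")
    out <- do.call(rbind, lapply(ds, function(d) {
        v <- coex$r[coex$n_intervening == d]
        data.frame(d = d, mean_r = mean(v), sem_r = .sem(v), n = length(v))
    }))
    rownames(out) <- NULL
    out
}

#' Per-orientation co-expression profile by intergenic distance
#'
#' Direct, non-overlapping neighbour pairs binned by intergenic distance
#' into half-open bins \code{[k*w, (k+1)*w)} of width \code{w} bp over
#' \code{[0, maxBp)}, separately per orientation.  Negative distances
#' (overlapping transcripts) are rejected: overlapping pairs are analysed
#' through their overlap class instead.
#'
#' @param coex Output of \code{\link{coexpressPairs}} for direct pairs.
#' @param binWidth Bin width in bp (default 100).
#' @param maxBp Upper end of the binned range in bp (default 2000).
#' @return \code{data.frame} with \code{orientation}, \code{bin_lo},
#'   \code{bin_hi}, \code{mean_r}, \code{sem_r}, \code{n}.
#' @export
profileByBp <- function(coex, binWidth = 100, maxBp = 2000) {
    coex <- coex[!is.na(coex$r), , drop = FALSE]
    if (any(coex$intergenic_bp < 0))
        stop("negative intergenic distances: route overlapping pairs ",
             "through their overlap class instead")
    coex <- coex[coex$intergenic_bp < maxBp, , drop = FALSE]
    bin <- coex$intergenic_bp %/% binWidth
    out <- do.call(rbind, lapply(ORIENTATIONS, function(ori) {
        sel <- coex$orientation == ori
        if (!any(sel)) return(NULL)
        do.call(rbind, lapply(sort(unique(bin[sel])), function(b) {
            v <- coex$r[sel & bin == b]
            data.frame(orientation = ori,
                       bin_lo = b * binWidth, bin_hi = (b + 1) * binWidth,
                       mean_r = mean(v), sem_r = .sem(v), n = length(v))
        }))
    }))
    rownames(out) <- NULL
    out
}

#' Orientation-by-distance group means
#'
#' Splits pairs into short (\code{intergenic_bp < splitBp}) and long
#' (\code{>= splitBp}) classes per orientation and reports mean
#' co-expression, SEM and count, plus a rank-sum p-value against the random
#' background when one is supplied (with a Benjamini-Hochberg adjusted
#' column alongside).  \code{splitBp = Inf} collapses to single per-
#' orientation groups (all short).
#'
#' @param coex Output of \code{\link{coexpressPairs}}.
#' @param splitBp Distance split in bp (default 400; the boundary value goes
#'   to the long class).
#' @param background Optional \code{\link{randomBackground}} result.
#' @param alternative Sidedness of the rank-sum tests.
#' @return \code{data.frame} with one row per orientation x distance class.
#' @export
groupMeans <- function(coex, splitBp = 400, background = NULL,
                       alternative = "two_sided") {
    coex <- coex[!is.na(coex$r), , drop = FALSE]
    classes <- if (is.infinite(splitBp)) "short" else c("short", "long")
    grid <- expand.grid(orientation = ORIENTATIONS, distance_class = classes,
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        ori <- grid$orientation[i]; cls <- grid$distance_class[i]
        sel <- coex$orientation == ori &
            (if (cls == "short") coex$intergenic_bp < splitBp
             else coex$intergenic_bp >= splitBp)
        v <- coex$r[sel]
        p <- if (length(v) && !is.null(background))
            rankSumTest(v, background$values, alternative = alternative)
        else NA_real_
        data.frame(group_label = paste(ori, cls, sep = "_"),
                   orientation = ori, distance_class = cls,
                   mean_r = if (length(v)) mean(v) else NA_real_,
                   sem_r = .sem(v), n = length(v), p_vs_random = p,
                   stringsAsFactors = FALSE)
    }))
    out$p_adj <- stats::p.adjust(out$p_vs_random, method = "BH")
    rownames(out) <- NULL
    out
}

#' Random-pair co-expression background
#'
#' Draws \code{nPairs} unordered pairs of distinct measured protein-coding
#' genes uniformly (with replacement across draws) and computes their
#' Pearson correlations; genes with zero expression variance are excluded up
#' front and reported.  Reproducible for a given seed.
#'
#' @param mat Expression matrix (complete, no missing values).
#' @param ann Optional \code{GeneAnnotation} restricting the draw to its
#'   protein-coding genes; by default all matrix rows are used.
#' @param nPairs Number of pairs to draw (default 100000).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return List with \code{n_pairs}, \code{seed}, \code{values},
#'   \code{mean_r}, \code{sem_r}, \code{n_dropped_genes}.
#' @export
randomBackground <- function(mat, ann = NULL, nPairs = 100000, seed = NULL) {
    ids <- rownames(mat)
    if (!is.null(ann)) {
        bt <- geneBiotypes(ann)
        ids <- intersect(ids, names(bt)[bt == "protein_coding"])
    }
    z <- .rowStandardize(mat[ids, , drop = FALSE])
    usable <- !is.na(z[, 1])
    nDropped <- sum(!usable)
    if (nDropped)
        message(nDropped, " zero-variance gene(s) excluded from background")
    z <- z[usable, , drop = FALSE]
    if (nrow(z) < 2)
        stop("need at least 2 measured genes with variance for a background")
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(seed)
    }
    i <- sample.int(nrow(z), nPairs, replace = TRUE)
    j <- sample.int(nrow(z), nPairs, replace = TRUE)
    while (any(i == j)) {
        clash <- i == j
        j[clash] <- sample.int(nrow(z), sum(clash), replace = TRUE)
    }
    vals <- .pairCorComplete(z, i, j)
    list(n_pairs = nPairs, seed = seed, values = vals,
         mean_r = mean(vals), sem_r = .sem(vals),
         n_dropped_genes = nDropped)
}

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' P-value for a difference in location between two samples: exact
#' enumeration for small untied samples, normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param sampleA,sampleB Numeric vectors (non-empty).
#' @param alternative \code{"two_sided"}, \code{"greater"} (A shifted above
#'   B) or \code{"less"}.
#' @return P-value.
#' @export
rankSumTest <- function(sampleA, sampleB,
                        alternative = c("two_sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    if (!length(sampleA) || !length(sampleB))
        stop("both samples must be non-empty")
    alt <- sub("two_sided", "two.sided", alternative)
    exact <- (length(sampleA) + length(sampleB)) <= 50 &&
        !anyDuplicated(c(sampleA, sampleB))
    stats::wilcox.test(sampleA, sampleB, alternative = alt,
                       exact = exact, correct = TRUE)$p.value
}

#' Fraction of anti-correlated pairs
#'
#' Share of co-expression values below zero.
#'
#' @param values Numeric vector of correlations (non-empty; NA removed).
#' @return Fraction in \code{[0, 1]}.
#' @export
anticorrelatedFraction <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values)) stop("no co-expression values")
    mean(values < 0)
}

#' Transitive co-expression expectation
#'
#' For consecutive genes A-B-C with no direct A-C interaction, the expected
#' correlation satisfies R_ac^2 = R_ab^2 * R_bc^2; on the correlation scale
#' this is \code{r_ab * r_bc} (sign = product of signs).
#'
#' @param rAb,rBc Correlations in \code{[-1, 1]}.
#' @return Expected A-C correlation.
#' @export
transitiveExpectedR <- function(rAb, rBc) {
    if (any(abs(c(rAb, rBc)) > 1))
        stop("correlations must lie in [-1, 1]")
    rAb * rBc
}
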