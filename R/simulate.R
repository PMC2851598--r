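# Synthetic annotation + expression generator with closed-form ground
# truth.
#
# The expression model is a latent-factor model realising the three
# mechanisms the decomposition separates:
#
#   * chromatin: gene i loads on a sliding window of `domainSpan`
#     consecutive latent chromatin factors (U_i, ..., U_{i+span-1}), with
#     the per-factor loading scaled so that every direct-neighbour pair has
#     expected chromatin correlation exactly `a`; the expectation decays
#     linearly to 0 beyond `domainSpan - 1` intervening genes.
#   * shared promoter: close (< closeThreshold bp) bi-directional direct
#     neighbours share an extra pair factor contributing `b` to their
#     expected correlation.
#   * interference: for close convergent or uni-directional pairs, the
#     downstream member's loadings on the factors it shares with its
#     partner are multiplied by (1 - delta), so the pair expectation
#     becomes a*(1-delta); the removed variance is returned to the gene's
#     private noise, keeping every gene at unit variance.
#
# Expected Pearson correlation of any pair is the inner product of the two
# genes' aligned chromatin loading vectors plus `b` for promoter-sharing
# pairs; `expectedPairCorrelation` evaluates it exactly from the stored
# loadings.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic genome and
#' expression generator.  Defaults describe the standard study conditions
#' used throughout the package's validation: a 5-chromosome genome of 5,000
#' genes with log-normal intergenic gaps (median 400 bp, so distance classes
#' are balanced around the 400 bp split), random strands, 1,000 experiments,
#' and mechanism strengths a = 0.04, b = 0.11, delta = 0.4 with a chromatin
#' window of 2 genes — chosen so the expected close bi-directional
#' correlation (a + b = 0.15), the long-range chromatin correlation (0.04)
#' and the close convergent correlation (a(1-delta) = 0.024) sit at
#' magnitudes typical of compact plant genomes.
#'
#' @param nChrom Number of chromosomes.
#' @param genesPerChrom Genes per chromosome.
#' @param geneLengthMean,geneLengthSd Normal parameters of gene (transcript
#'   span) length in bp; lengths are truncated below at 200 bp.
#' @param gapMeanlog,gapSdlog Log-normal parameters of the intergenic gap in
#'   bp; gaps are at least 1 bp, so simulated genes never overlap.
#' @param strandModel \code{"random"} (each strand +/- with probability
#'   1/2) or \code{"fixed_pattern"} (recycle \code{strandPattern}).
#' @param strandPattern Character vector or string of \code{+}/\code{-}
#'   used when \code{strandModel = "fixed_pattern"}.
#' @param nExperiments Number of expression experiments (columns).
#' @param a Expected chromatin correlation of direct-neighbour pairs, in
#'   \code{[0, 1)}.
#' @param b Promoter-factor correlation added to close bi-directional
#'   pairs, in \code{[0, 1 - a)}.
#' @param delta Interference strength in \code{[0, 1]}: close convergent /
#'   uni-directional pairs have expected correlation \code{a * (1 - delta)}.
#' @param domainSpan Chromatin window span in genes (>= 2 whenever
#'   \code{a > 0}).
#' @param closeThreshold Distance in bp below which pairs count as close
#'   (default 400).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nChrom = 5, genesPerChrom = 1000,
                      geneLengthMean = 2000, geneLengthSd = 500,
                      gapMeanlog = log(400), gapSdlog = 1.0,
                      strandModel = c("random", "fixed_pattern"),
                      strandPattern = NULL,
                      nExperiments = 1000,
                      a = 0.04, b = 0.11, delta = 0.4,
                      domainSpan = 2, closeThreshold = 400, seed = 1) {
    strandModel <- match.arg(strandModel)
    cfg <- list(nChrom = as.integer(nChrom),
                genesPerChrom = as.integer(genesPerChrom),
                geneLengthMean = geneLengthMean, geneLengthSd = geneLengthSd,
                gapMeanlog = gapMeanlog, gapSdlog = gapSdlog,
                strandModel = strandModel, strandPattern = strandPattern,
                nExperiments = as.integer(nExperiments),
                a = a, b = b, delta = delta,
                domainSpan = as.integer(domainSpan),
                closeThreshold = closeThreshold, seed = as.integer(seed))
    stopifnot(cfg$nChrom >= 1, cfg$genesPerChrom >= 1, cfg$nExperiments >= 2,
              cfg$a >= 0, cfg$b >= 0, cfg$a + cfg$b < 1,
              cfg$delta >= 0, cfg$delta <= 1,
              cfg$closeThreshold >= 0, cfg$geneLengthMean > 0)
    if (cfg$a > 0) {
        if (cfg$domainSpan < 2)
            stop("domainSpan must be >= 2 when a > 0")
        # variance share of the chromatin component per gene
        s <- cfg$a * cfg$domainSpan / (cfg$domainSpan - 1)
        if (s + cfg$b >= 1)
            stop("infeasible config: chromatin variance share ",
                 signif(s, 3), " plus b reaches 1")
    }
    if (strandModel == "fixed_pattern" && is.null(strandPattern))
        stop("strandPattern required for strandModel = 'fixed_pattern'")
    class(cfg) <- "SimConfig"
    cfg
}

.patternStrands <- function(pattern, n) {
    if (length(pattern) == 1 && nchar(pattern) > 1)
        pattern <- strsplit(pattern, "")[[1]]
    if (!all(pattern %in% c("+", "-")))
        stop("strandPattern must consist of '+' and '-'")
    rep_len(pattern, n)
}

#' Simulate a genome annotation
#'
#' Places genes left-to-right per chromosome with lengths ~ Normal
#' (truncated at 200 bp) and gaps ~ log-normal (at least 1 bp), strands per
#' the strand model.  Deterministic given \code{cfg$seed}.  The returned
#' geometry records, for every direct-neighbour pair, its orientation,
#' intergenic distance, and the mechanism assignment (promoter-shared /
#' interfered flags with the designated downstream member) that
#' \code{\link{simulateExpression}} will realise.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return List with \code{annotation} (a \code{GeneAnnotation}) and
#'   \code{geometry} (a \code{data.frame} over direct pairs).
#' @export
simulateGenome <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed)
    frames <- lapply(seq_len(cfg$nChrom), function(ci) {
        G <- cfg$genesPerChrom
        len <- pmax(200L, as.integer(round(
            stats::rnorm(G, cfg$geneLengthMean, cfg$geneLengthSd))))
        gap <- pmax(1L, as.integer(round(
            stats::rlnorm(G, cfg$gapMeanlog, cfg$gapSdlog))))
        strand <- if (cfg$strandModel == "random")
            sample(c("+", "-"), G, replace = TRUE)
        else .patternStrands(cfg$strandPattern, G)
        start <- cumsum(c(1L, (len + gap)[-G]))
        data.frame(gene_id = sprintf("SIM%dG%05d", ci, seq_len(G)),
                   chrom = sprintf("chr%d", ci),
                   start = start, end = start + len - 1L,
                   strand = strand, biotype = "protein_coding",
                   stringsAsFactors = FALSE)
    })
    frame <- do.call(rbind, frames)
    ann <- GeneAnnotation(frame)
    geometry <- .pairGeometry(frame, cfg)
    list(annotation = ann, geometry = geometry)
}

# mechanism assignment for direct-neighbour pairs of the simulated frame
# (frame is already sorted: generation is left-to-right per chromosome)
.pairGeometry <- function(frame, cfg) {
    geo <- do.call(rbind, lapply(unique(frame$chrom), function(ch) {
        idx <- which(frame$chrom == ch)
        G <- length(idx)
        if (G < 2) return(NULL)
        i <- seq_len(G - 1)
        data.frame(chrom = ch, left_idx = i, right_idx = i + 1L,
                   left_id = frame$gene_id[idx[i]],
                   right_id = frame$gene_id[idx[i + 1L]],
                   orientation = .orientationFromStrands(
                       frame$strand[idx[i]], frame$strand[idx[i + 1L]]),
                   intergenic_bp = frame$start[idx[i + 1L]] -
                       frame$end[idx[i]] - 1L,
                   stringsAsFactors = FALSE)
    }))
    rownames(geo) <- NULL
    close <- geo$intergenic_bp >= 0 & geo$intergenic_bp < cfg$closeThreshold
    geo$promoter_shared <- close & geo$orientation == "bidirectional"
    geo$interfered <- close & geo$orientation %in%
        c("convergent", "unidirectional") & cfg$delta > 0
    # downstream member: the gene the upstream polymerase runs into.  For
    # uni-directional pairs that is the right gene on "+" runs and the left
    # gene on "-" runs; for convergent pairs interference is mutual and the
    # right member is designated by convention (only the loading product
    # enters the pair expectation).
    geo$downstream <- ifelse(!geo$interfered, NA_character_,
        ifelse(geo$orientation == "unidirectional" &
               frame$strand[match(geo$left_id, frame$gene_id)] == "-",
               "left", "right"))
    geo
}

# per-chromosome chromatin loading matrices (genes x domainSpan), with
# interference dilution applied; loading k of gene i multiplies latent
# factor U_{i+k-1}
.chromatinLoadings <- function(geo, nGenesPerChrom, cfg) {
    w <- cfg$domainSpan
    if (cfg$a == 0)
        return(lapply(nGenesPerChrom, function(G) matrix(0, G, w)))
    s <- cfg$a * w / (w - 1)
    base <- sqrt(s / w)
    loadings <- lapply(nGenesPerChrom, function(G) matrix(base, G, w))
    if (any(geo$interfered)) {
        for (k in which(geo$interfered)) {
            ch <- geo$chrom[k]
            L <- loadings[[ch]]
            if (geo$downstream[k] == "right") {
                # right member's shared offsets are 1..(w-1)
                L[geo$right_idx[k], seq_len(w - 1)] <-
                    L[geo$right_idx[k], seq_len(w - 1)] * (1 - cfg$delta)
            } else {
                # left member's shared offsets are 2..w
                L[geo$left_idx[k], 2:w] <-
                    L[geo$left_idx[k], 2:w] * (1 - cfg$delta)
            }
            loadings[[ch]] <- L
        }
    }
    loadings
}

#' Simulate an expression matrix over a simulated genome
#'
#' Realises the latent-factor model (see the package vignette): unit-
#' variance gene expression vectors composed of a sliding-window chromatin
#' component, a pair-shared promoter factor for close bi-directional
#' neighbours, interference dilution for close convergent/uni-directional
#' pairs, and independent Gaussian noise.  Deterministic given
#' \code{cfg$seed} (which also seeded the genome).
#'
#' @param cfg The \code{\link{simConfig}} used for the genome.
#' @param annotation \code{GeneAnnotation} from \code{\link{simulateGenome}}.
#' @param geometry Geometry \code{data.frame} from
#'   \code{\link{simulateGenome}}.
#' @return List with \code{matrix} (genes x experiments, rownames = gene
#'   ids) and \code{groundTruth} (loadings and mechanism assignments;
#'   feeds \code{\link{expectedPairCorrelation}}).
#' @export
simulateExpression <- function(cfg, annotation, geometry) {
    stopifnot(inherits(cfg, "SimConfig"))
    frame <- .annotationFrame(annotation)
    chroms <- unique(frame$chrom)
    nPerChrom <- stats::setNames(
        vapply(chroms, function(ch) sum(frame$chrom == ch), integer(1)),
        chroms)
    loadings <- .chromatinLoadings(geometry, nPerChrom, cfg)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed + 1L)
    n <- cfg$nExperiments
    w <- cfg$domainSpan
    X <- matrix(0, nrow(frame), n,
                dimnames = list(frame$gene_id, sprintf("exp%04d", seq_len(n))))
    chromVar <- numeric(nrow(frame))
    for (ch in chroms) {
        idx <- which(frame$chrom == ch)
        G <- length(idx)
        L <- loadings[[ch]]
        if (cfg$a > 0) {
            U <- matrix(stats::rnorm((G + w - 1) * n), G + w - 1, n)
            comp <- matrix(0, G, n)
            for (k in seq_len(w))
                comp <- comp + L[, k] * U[k:(k + G - 1), , drop = FALSE]
            X[idx, ] <- comp
        }
        chromVar[idx] <- rowSums(L^2)
    }
    promVar <- numeric(nrow(frame))
    promPairs <- which(geometry$promoter_shared)
    if (cfg$b > 0 && length(promPairs)) {
        P <- matrix(stats::rnorm(length(promPairs) * n), length(promPairs), n)
        for (m in seq_along(promPairs)) {
            k <- promPairs[m]
            gl <- match(geometry$left_id[k], frame$gene_id)
            gr <- match(geometry$right_id[k], frame$gene_id)
            X[gl, ] <- X[gl, ] + sqrt(cfg$b) * P[m, ]
            X[gr, ] <- X[gr, ] + sqrt(cfg$b) * P[m, ]
            promVar[c(gl, gr)] <- promVar[c(gl, gr)] + cfg$b
        }
    }
    resid <- 1 - chromVar - promVar
    if (any(resid < 0))
        stop("infeasible config: factor variance exceeds 1 for some gene")
    X <- X + sqrt(resid) * matrix(stats::rnorm(nrow(frame) * n),
                                  nrow(frame), n)
    gt <- list(cfg = cfg, loadings = loadings, geometry = geometry,
               frame = frame[, c("gene_id", "chrom")],
               chromVar = chromVar, promVar = promVar)
    class(gt) <- "SimGroundTruth"
    list(matrix = X, groundTruth = gt)
}

#' Closed-form expected pair correlation under the simulator
#'
#' Evaluates the factor-model expectation exactly from the stored loadings:
#' the inner product of the two genes' chromatin loading vectors over the
#' latent factors they share, plus the promoter share for promoter-sharing
#' pairs.  Symmetric in the two genes; 0 for genes on different chromosomes
#' or further apart than the chromatin window.
#'
#' @param groundTruth \code{groundTruth} from
#'   \code{\link{simulateExpression}}.
#' @param geneA,geneB Simulated gene ids.
#' @return Expected Pearson correlation.
#' @export
expectedPairCorrelation <- function(groundTruth, geneA, geneB) {
    frame <- groundTruth$frame
    ia <- match(geneA, frame$gene_id); ib <- match(geneB, frame$gene_id)
    if (is.na(ia) || is.na(ib))
        stop("unknown simulated gene id")
    if (geneA == geneB) return(1)
    if (frame$chrom[ia] != frame$chrom[ib]) return(0)
    idx <- which(frame$chrom == frame$chrom[ia])
    pa <- match(ia, idx); pb <- match(ib, idx)
    if (pa > pb) { tmp <- pa; pa <- pb; pb <- tmp }
    L <- groundTruth$loadings[[frame$chrom[ia]]]
    w <- ncol(L)
    lag <- pb - pa
    r <- 0
    if (lag < w) {
        # gene pa offset k maps to factor pa+k-1; overlap with pb's window
        ka <- (lag + 1):w
        kb <- seq_len(w - lag)
        r <- sum(L[pa, ka] * L[pb, kb])
    }
    geo <- groundTruth$geometry
    hit <- geo$promoter_shared &
        ((geo$left_id == geneA & geo$right_id == geneB) |
         (geo$left_id == geneB & geo$right_id == geneA))
    if (any(hit)) r <- r + groundTruth$cfg$b
    r
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits \code{annotation.gff3} (gene features with ID and biotype
#' attributes), \code{expression.tsv} (header of experiment ids, first
#' column gene id) and \code{ground_truth.json} (config echo plus per-pair
#' mechanism assignments and expected correlations).  The files round-trip
#' losslessly through \code{\link{readGFF3}} /
#' \code{\link{readExpressionMatrix}}.
#'
#' @param annotation A \code{GeneAnnotation}.
#' @param mat Expression matrix.
#' @param dir Output directory (created if needed).
#' @param groundTruth Optional ground truth to serialise.
#' @return Invisibly, the named vector of file paths.
#' @export
writeFixture <- function(annotation, mat, dir, groundTruth = NULL) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    gff <- file.path(dir, "annotation.gff3")
    tsv <- file.path(dir, "expression.tsv")
    gr <- geneRanges(annotation)
    mcols(gr)$type <- "gene"
    mcols(gr)$ID <- mcols(gr)$gene_id
    rtracklayer::export(gr, gff, format = "gff3")
    df <- data.frame(gene_id = rownames(mat), mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(annotation = gff, expression = tsv)
    if (!is.null(groundTruth)) {
        gtPath <- file.path(dir, "ground_truth.json")
        geo <- groundTruth$geometry
        geo$expected_r <- vapply(seq_len(nrow(geo)), function(k)
            expectedPairCorrelation(groundTruth, geo$left_id[k],
                                    geo$right_id[k]), numeric(1))
        cfg <- groundTruth$cfg
        jsonlite::write_json(
            list(config = unclass(cfg)[!vapply(unclass(cfg), is.null,
                                               logical(1))],
                 pairs = geo),
            gtPath, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, ground_truth = gtPath)
    }
    invisible(paths)
}

#' Simulate and write a complete fixture
#'
#' Convenience wrapper: \code{\link{simulateGenome}} +
#' \code{\link{simulateExpression}} (+ optional \code{\link{writeFixture}}).
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param dir Optional output directory for fixture files.
#' @return List with \code{annotation}, \code{geometry}, \code{matrix},
#'   \code{groundTruth} and (if written) \code{paths}.
#' @export
simulateFixture <- function(cfg = simConfig(), dir = NULL) {
    gen <- simulateGenome(cfg)
    expr <- simulateExpression(cfg, gen$annotation, gen$geometry)
    out <- list(annotation = gen$annotation, geometry = gen$geometry,
                matrix = expr$matrix, groundTruth = expr$groundTruth)
    if (!is.null(dir))
        out$paths <- writeFixture(gen$annotation, expr$matrix, dir,
                                  groundTruth = expr$groundTruth)
    out
}
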