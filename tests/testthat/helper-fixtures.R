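# Builders and independent brute-force oracles used across the suite.

# quick annotation from vectors (1-based closed coordinates)
mkAnn <- function(ids, chrom, start, end, strand, biotype = "protein_coding") {
    GeneAnnotation(data.frame(gene_id = ids, chrom = chrom, start = start,
                              end = end, strand = strand, biotype = biotype,
                              stringsAsFactors = FALSE))
}

# random annotation: genes with random spans, possibly overlapping
randAnnFrame <- function(nGenes = 50, nChrom = 2, pNoncoding = 0.2,
                         span = 30000) {
    chrom <- sort(sample(sprintf("chr%d", seq_len(nChrom)), nGenes,
                         replace = TRUE))
    start <- sample.int(span, nGenes, replace = TRUE)
    len <- sample(50:2000, nGenes, replace = TRUE)
    data.frame(gene_id = sprintf("G%03d", seq_len(nGenes)),
               chrom = chrom, start = start, end = start + len - 1L,
               strand = sample(c("+", "-"), nGenes, replace = TRUE),
               biotype = sample(c("protein_coding", "other"), nGenes,
                                replace = TRUE,
                                prob = c(1 - pNoncoding, pNoncoding)),
               stringsAsFactors = FALSE)
}

# non-overlapping variant (genes laid end to end with positive gaps)
randAnnFrameNonOv <- function(nGenes = 50, nChrom = 2) {
    perChrom <- table(sort(sample.int(nChrom, nGenes, replace = TRUE)))
    frames <- lapply(seq_along(perChrom), function(ci) {
        G <- as.integer(perChrom[ci])
        len <- sample(50:2000, G, replace = TRUE)
        gap <- sample(1:1500, G, replace = TRUE)
        start <- cumsum(c(1L, (len + gap)[-G]))
        data.frame(chrom = sprintf("chr%d", ci), start = start,
                   end = start + len - 1L,
                   strand = sample(c("+", "-"), G, replace = TRUE),
                   biotype = sample(c("protein_coding", "other"), G,
                                    replace = TRUE, prob = c(0.8, 0.2)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, frames)
    out <- cbind(gene_id = sprintf("G%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    out
}

# ---- brute-force oracles (scalar logic, independent of the package) ----

bruteSortFrame <- function(frame) {
    frame[order(frame$chrom, frame$start, frame$end, frame$gene_id), ,
          drop = FALSE]
}

bruteClassifyOrientation <- function(sl, sr) {
    if (sl == "-" && sr == "+") return("bidirectional")
    if (sl == "+" && sr == "-") return("convergent")
    "unidirectional"
}

bruteClassifyOverlap <- function(ls, le, rs, re, sl, sr) {
    noIntersect <- le < rs || re < ls
    if (noIntersect) return("none")
    if (sl == sr) return(NA_character_)
    inside <- (rs >= ls && re <= le) || (ls >= rs && le <= re)
    if (inside) return("contained")
    if (sl == "+") "overlap_3p" else "overlap_5p"
}

# per-pair record computed with plain scalar arithmetic
brutePairRecord <- function(f, i, j) {
    data.frame(left_id = f$gene_id[i], right_id = f$gene_id[j],
               orientation = bruteClassifyOrientation(f$strand[i],
                                                      f$strand[j]),
               overlap_class = bruteClassifyOverlap(f$start[i], f$end[i],
                                                    f$start[j], f$end[j],
                                                    f$strand[i], f$strand[j]),
               intergenic_bp = f$start[j] - f$end[i] - 1L,
               stringsAsFactors = FALSE)
}

bruteDirectPairs <- function(frame) {
    f <- bruteSortFrame(frame)
    out <- NULL
    for (ch in unique(f$chrom)) {
        idx <- which(f$chrom == ch)
        if (length(idx) < 2) next
        for (k in seq_len(length(idx) - 1)) {
            i <- idx[k]; j <- idx[k + 1]
            if (f$biotype[i] == "protein_coding" &&
                f$biotype[j] == "protein_coding")
                out <- rbind(out, brutePairRecord(f, i, j))
        }
    }
    out
}

bruteAllPairs <- function(frame, maxIntervening) {
    f <- bruteSortFrame(frame)
    out <- NULL
    for (ch in unique(f$chrom)) {
        idx <- which(f$chrom == ch)
        if (length(idx) < 2) next
        for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
            i <- idx[a]; j <- idx[b]
            if (f$biotype[i] != "protein_coding" ||
                f$biotype[j] != "protein_coding") next
            nInt <- sum(f$start[idx] > f$end[i] & f$end[idx] < f$start[j])
            if (nInt > maxIntervening) next
            rec <- brutePairRecord(f, i, j)
            rec$n_intervening <- nInt
            out <- rbind(out, rec)
        }
    }
    out
}

# direct correlation formula (covariance over product of standard deviations)
brutePearson <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exact two-sided rank-sum p by exhaustive enumeration of all assignments
# of the pooled ranks to sample A (doubled smaller tail, capped at 1)
bruteRankSumP <- function(a, b) {
    pooled <- c(a, b)
    rk <- rank(pooled)
    na <- length(a)
    obs <- sum(rk[seq_len(na)])
    combos <- utils::combn(length(pooled), na)
    sums <- apply(combos, 2, function(ix) sum(rk[ix]))
    lower <- mean(sums <= obs)
    upper <- mean(sums >= obs)
    min(1, 2 * min(lower, upper))
}

# tiny expression matrix with named genes
mkMat <- function(..., experiments = NULL) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    rownames(m) <- names(rows)
    colnames(m) <- if (is.null(experiments))
        sprintf("e%d", seq_len(ncol(m))) else experiments
    m
}

# GFF3 writer for hand-made fixtures
writeGFF3Lines <- function(lines, path = tempfile(fileext = ".gff3")) {
    writeLines(c("##gff-version 3", lines), path)
    path
}
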