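#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag countBam
#' @importFrom GenomicAlignments readGAlignments coverage cigarWidthAlongReferenceSpace
#' @importFrom S4Vectors runValue runLength Rle mcols
NULL

# ---- depth construction --------------------------------------------------

#' Per-base stranded depth from a SAM alignment file
#'
#' Builds strand-specific per-base depth from alignments against the genome.
#' Unmapped, secondary and supplementary records are skipped (their count is
#' reported via attribute `"skipped"`). Depth counts reference-consuming
#' aligned bases (CIGAR M/=/X); deletions and skips do not increment depth.
#' Positions inside the genome's masked intervals are set to zero: reads
#' overlapping a masked interval contribute only at unmasked positions.
#'
#' The template (transcribed) strand is derived from the mate orientation.
#' The default, `"read2-sense"`, matches TruSeq stranded chemistry (read 2
#' carries the sense of the RNA); `"read1-sense"` is the reverse; unpaired
#' reads are taken at face value (alignment strand = template strand).
#'
#' @param sam_path SAM (or BAM) file aligned to `genome`.
#' @param genome a \linkS4class{MitoGenome}.
#' @param orientation strandedness of the library (see Details).
#' @param min_mapq optional mapping-quality floor (default none).
#' @param apply_mask zero out masked positions (default `TRUE`).
#' @return a \linkS4class{StrandedDepth}; attribute `"skipped"` holds the
#'   number of records dropped, attribute `"aligned_bases"` the total aligned
#'   (M/=/X) bases of retained reads before masking.
#' @export
depthFromAlignments <- function(sam_path, genome,
                                orientation = c("read2-sense", "read1-sense"),
                                min_mapq = NA, apply_mask = TRUE) {
    .checkFileExists(sam_path, "SAM file")
    orientation <- match.arg(orientation)
    bam <- .asBamFile(sam_path)
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE)
    param <- ScanBamParam(flag = flag, what = "flag",
        mapqFilter = if (is.na(min_mapq)) NA_integer_ else as.integer(min_mapq))
    aln <- readGAlignments(bam, param = param)
    n_total <- countBam(bam)$records
    n_skipped <- n_total - length(aln)

    L <- genomeLength(genome)
    plus <- numeric(L); minus <- numeric(L)
    aligned_bases <- 0
    if (length(aln)) {
        refs <- unique(as.character(seqnames(aln)))
        if (!genomeName(genome) %in% refs)
            stop("alignments are against ", paste(refs, collapse = ","),
                 ", not '", genomeName(genome), "'")
        aln <- aln[as.character(seqnames(aln)) == genomeName(genome)]
        if (max(end(aln)) > L)
            stop("alignment beyond the ", L, "-bp genome")
        fl <- mcols(aln)$flag
        paired <- bitwAnd(fl, 1L) > 0L
        second <- bitwAnd(fl, 128L) > 0L
        read_minus <- as.character(strand(aln)) == "-"
        sense_is_read <- !paired |
            (if (orientation == "read2-sense") second else !second)
        tmpl_minus <- xor(read_minus, !sense_is_read)
        for (s in c(FALSE, TRUE)) {
            sel <- which(tmpl_minus == s)
            if (!length(sel)) next
            cov <- coverage(aln[sel], drop.D.ranges = TRUE,
                            width = stats::setNames(L, genomeName(genome)))
            v <- as.numeric(cov[[genomeName(genome)]])
            if (s) minus <- v else plus <- v
        }
        aligned_bases <- sum(plus) + sum(minus)
    }
    if (apply_mask && length(maskRanges(genome))) {
        m <- maskedPositions(genome)
        plus[m] <- 0; minus[m] <- 0
    }
    out <- StrandedDepth(genome, plus, minus)
    attr(out, "skipped") <- n_skipped
    attr(out, "aligned_bases") <- aligned_bases
    out
}

.asBamFile <- function(sam_path) {
    if (grepl("\\.bam$", sam_path, ignore.case = TRUE)) return(sam_path)
    dest <- tempfile(fileext = "")
    asBam(sam_path, destination = dest, overwrite = TRUE,
          indexDestination = FALSE)
}

#' Per-base stranded depth from a pair of bedGraph tracks
#'
#' @param plus_path,minus_path bedGraph files (0-based half-open on disk)
#'   with the per-base depth of the plus and minus strands.
#' @param genome a \linkS4class{MitoGenome}.
#' @return a \linkS4class{StrandedDepth}. Positions absent from a track have
#'   depth 0. Overlapping intervals within one track are an error.
#' @export
depthFromBedgraph <- function(plus_path, minus_path, genome) {
    StrandedDepth(genome,
                  plus = .bedgraphVector(plus_path, genome),
                  minus = .bedgraphVector(minus_path, genome))
}

.bedgraphVector <- function(path, genome) {
    .checkFileExists(path, "bedGraph file")
    gr <- import(path, format = "bedGraph")
    L <- genomeLength(genome)
    v <- numeric(L)
    if (!length(gr)) return(v)
    if (min(start(gr)) < 1L || max(end(gr)) > L)
        stop("bedGraph interval outside the ", L, "-bp genome in ", path)
    s <- start(gr); e <- end(gr); sc <- mcols(gr)$score
    o <- order(s)
    if (length(s) > 1L && any(s[o][-1L] <= e[o][-length(e)]))
        stop("overlapping bedGraph intervals in ", path)
    w <- e - s + 1L
    v[sequence(w) + rep(s - 1L, w)] <- rep(sc, w)
    v
}

#' Write a StrandedDepth as a pair of bedGraph tracks
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param plus_path,minus_path output files (0-based half-open bedGraph).
#' @param keep_zero write zero-depth runs too (default drops them).
#' @export
writeBedgraph <- function(depth, plus_path, minus_path, keep_zero = FALSE) {
    for (s in c("+", "-")) {
        path <- if (s == "+") plus_path else minus_path
        r <- Rle(strandDepth(depth, s))
        ends <- cumsum(runLength(r))
        starts <- ends - runLength(r) + 1L
        keep <- if (keep_zero) seq_along(ends) else which(runValue(r) != 0)
        df <- data.frame(chrom = genomeName(depthGenome(depth)),
                         start = starts[keep] - 1L,  # bedGraph is 0-based
                         end = ends[keep],
                         score = runValue(r)[keep])
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(c(plus_path, minus_path))
}

# ---- summaries -----------------------------------------------------------

#' Genome-wide transcription summary of a stranded depth track
#'
#' Computes, over unmasked positions and counting the two strands
#' separately (denominator `2 x` unmasked genome length):
#' the mean and maximum depth, the mean depth outside annotated exons
#' (strand-aware: a position is intergenic on a strand when no exon of a
#' gene on that strand covers it), the fraction of strand-positions with
#' depth at or above each threshold, and a histogram assigning each
#' `window`-bp window (per strand) to the depth interval containing its mean.
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param genes named list of \linkS4class{GeneFeature} (used for the
#'   intergenic mean; may be empty).
#' @param thresholds ascending integer depth thresholds.
#' @param window window size in bp for the depth histogram.
#' @param breaks interval break points for the histogram
#'   (right-open at the top via `Inf`).
#' @return a list of class `"CoverageSummary"` with elements
#'   `mean_depth_both`, `max_depth`, `mean_depth_intergenic`, `frac_ge`
#'   (named numeric) and `window_hist` (named integer).
#' @export
summarizeCoverage <- function(depth, genes = list(),
                              thresholds = c(1, 2, 5), window = 100,
                              breaks = c(0, 1, 10, 50, 100, 1000, Inf)) {
    genome <- depthGenome(depth)
    if (genomeLength(genome) == 0L) stop("empty genome")
    if (is.unsorted(thresholds))
        stop("thresholds must be sorted ascending")
    unmasked <- !maskedPositions(genome)
    p <- depthPlus(depth)[unmasked]
    m <- depthMinus(depth)[unmasked]
    both <- c(p, m)
    n <- length(both)

    frac_ge <- vapply(thresholds, function(t) sum(both >= t) / n, numeric(1))
    names(frac_ge) <- as.character(thresholds)

    exonic <- .exonicPositions(genome, genes)
    ip <- depthPlus(depth)[unmasked & !exonic$plus]
    im <- depthMinus(depth)[unmasked & !exonic$minus]
    mean_intergenic <- .safeMean(c(ip, im))

    hist_counts <- integer(length(breaks) - 1L)
    lab <- paste0("(", breaks[-length(breaks)], ",", breaks[-1L], "]")
    names(hist_counts) <- lab
    for (s in c("+", "-")) {
        v <- strandDepth(depth, s)
        w <- .anchoredWindows(1L, genomeLength(genome), window, window,
                              anchor = "start")
        for (k in seq_len(nrow(w))) {
            idx <- w[k, 1L]:w[k, 2L]
            idx <- idx[unmasked[idx]]
            if (!length(idx)) next
            mu <- mean(v[idx])
            # bins are (b[i], b[i+1]]; a mean at the lower edge goes to bin 1
            bin <- findInterval(mu, breaks, left.open = TRUE)
            bin <- min(max(bin, 1L), length(hist_counts))
            hist_counts[bin] <- hist_counts[bin] + 1L
        }
    }

    structure(list(mean_depth_both = mean(both),
                   max_depth = max(both),
                   mean_depth_intergenic = mean_intergenic,
                   frac_ge = frac_ge,
                   window_hist = hist_counts),
              class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
    cat("CoverageSummary: mean depth (both strands)",
        signif(x$mean_depth_both, 4), "; max", x$max_depth,
        "; intergenic mean", signif(x$mean_depth_intergenic, 4), "\n")
    cat("fraction of strand-positions with depth >= t:\n")
    print(round(x$frac_ge, 4))
    invisible(x)
}

.exonicPositions <- function(genome, genes) {
    L <- genomeLength(genome)
    plus <- logical(L); minus <- logical(L)
    for (g in genes) {
        ex <- geneExons(g)
        for (k in seq_along(ex)) {
            idx <- start(ex)[k]:end(ex)[k]
            if (geneStrand(g) == "+") plus[idx] <- TRUE else minus[idx] <- TRUE
        }
    }
    list(plus = plus, minus = minus)
}

#' Maximal low-coverage intervals per strand
#'
#' Finds the maximal runs of positions with depth at or below `max_depth`
#' on each strand, excluding masked positions (a masked interval terminates
#' any run).
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param max_depth depth ceiling defining "low" (0 = zero coverage).
#' @return data.frame with columns `strand`, `start`, `end` (1-based
#'   closed), sorted by strand then start.
#' @export
zeroCoverageIntervals <- function(depth, max_depth = 0) {
    stopifnot(max_depth >= 0)
    genome <- depthGenome(depth)
    unmasked <- !maskedPositions(genome)
    out <- list()
    for (s in c("+", "-")) {
        low <- strandDepth(depth, s) <= max_depth & unmasked
        r <- Rle(low)
        ends <- cumsum(runLength(r))
        starts <- ends - runLength(r) + 1L
        keep <- which(runValue(r))
        if (length(keep))
            out[[s]] <- data.frame(strand = s, start = starts[keep],
                                   end = ends[keep])
    }
    if (!length(out))
        return(data.frame(strand = character(0), start = integer(0),
                          end = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$strand, res$start), , drop = FALSE]
}
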