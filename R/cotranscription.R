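# Co-transcription classification of neighbouring same-strand gene pairs.

#' Candidate co-transcribed gene pairs
#'
#' All ordered (by genomic position) same-strand gene pairs whose coding
#' regions are separated by at most `max_distance` bp, plus overlapping
#' same-strand pairs, whose separation is reported as the negative overlap
#' length.
#'
#' @param genes named list of \linkS4class{GeneFeature}.
#' @param max_distance maximum intergenic separation in bp.
#' @return data.frame with columns `gene_a`, `gene_b`, `separation`
#'   (bp between nearest coding ends; negative = overlap), sorted by the
#'   genomic start of `gene_a`.
#' @export
candidatePairs <- function(genes, max_distance = 2000) {
    genes <- unname(genes)
    n <- length(genes)
    rows <- list()
    if (n >= 2L) {
        starts <- vapply(genes, function(g) start(geneRange(g)), integer(1))
        ends <- vapply(genes, function(g) end(geneRange(g)), integer(1))
        strands <- vapply(genes, geneStrand, character(1))
        o <- order(starts)
        for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
            a <- o[i]; b <- o[j]
            if (strands[a] != strands[b]) next
            sep <- starts[b] - ends[a] - 1L
            if (sep < 0L)  # overlap length (negative separation)
                sep <- -(min(ends[a], ends[b]) - starts[b] + 1L)
            if (sep <= max_distance)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_a = geneId(genes[[a]]), gene_b = geneId(genes[[b]]),
                    separation = as.integer(sep), stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          separation = integer(0)))
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}

#' Classify a same-strand gene pair from its intergenic coverage
#'
#' Overlapping pairs are `excluded_overlapping`; pairs closer than
#' `min_separation` bp are `excluded_too_close` (their elevated read depths
#' overlap, so continuity carries no information) - both are still reported
#' with their depth statistics, only the co-transcription classification is
#' withheld. Otherwise the minimum of `window`-bp windowed mean depths
#' across the intergenic span is compared with `tau x` the lower of the two
#' gene-body mean depths: at or above the threshold the pair is
#' `continuous` (co-transcription-like), below it `drop` (independent
#' transcription).
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param gene_a,gene_b \linkS4class{GeneFeature}s on the same strand,
#'   `gene_a` the genomically left one.
#' @param min_separation exclusion threshold in bp.
#' @param tau continuity threshold on the depth ratio.
#' @param window window size for the intergenic minimum.
#' @return one-row data.frame: `gene_a`, `gene_b`, `separation`,
#'   `classification`, `intergenic_min_depth`, `reference_depth`,
#'   `depth_ratio`.
#' @export
classifyPair <- function(depth, gene_a, gene_b, min_separation = 150,
                         tau = 0.5, window = 50) {
    if (geneStrand(gene_a) != geneStrand(gene_b))
        stop("pair must be on the same strand")
    if (start(geneRange(gene_a)) > start(geneRange(gene_b))) {
        tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp
    }
    ra <- geneRange(gene_a); rb <- geneRange(gene_b)
    sep <- start(rb) - end(ra) - 1L
    if (sep < 0L) sep <- -(min(end(ra), end(rb)) - start(rb) + 1L)
    v <- strandDepth(depth, geneStrand(gene_a))
    body <- function(g) {
        ex <- geneExons(g)
        mean(unlist(lapply(seq_along(ex), function(k)
            v[start(ex)[k]:end(ex)[k]])))
    }
    ref <- min(body(gene_a), body(gene_b))
    inter_min <- NA_real_
    if (sep > 0L) {
        span <- (end(ra) + 1L):(start(rb) - 1L)
        if (length(span) <= window) {
            inter_min <- mean(v[span])
        } else {
            w <- .anchoredWindows(span[1L], span[length(span)], window,
                                  window, anchor = "start")
            inter_min <- min(vapply(seq_len(nrow(w)), function(k)
                mean(v[w[k, 1L]:w[k, 2L]]), numeric(1)))
        }
    }
    ratio <- if (is.na(inter_min) || ref == 0) NA_real_ else inter_min / ref
    classification <-
        if (sep < 0L) "excluded_overlapping"
        else if (sep < min_separation) "excluded_too_close"
        else if (!is.na(ratio) && ratio >= tau) "continuous"
        else "drop"
    data.frame(gene_a = geneId(gene_a), gene_b = geneId(gene_b),
               separation = as.integer(sep), classification = classification,
               intergenic_min_depth = inter_min, reference_depth = ref,
               depth_ratio = ratio, stringsAsFactors = FALSE)
}

#' Classify all candidate pairs of an annotation
#'
#' @inheritParams classifyPair
#' @param genes named list of \linkS4class{GeneFeature}.
#' @param max_distance passed to \code{\link{candidatePairs}}.
#' @return data.frame of \code{\link{classifyPair}} rows, one per candidate
#'   pair.
#' @export
classifyAllPairs <- function(depth, genes, max_distance = 2000,
                             min_separation = 150, tau = 0.5, window = 50) {
    pairs <- candidatePairs(genes, max_distance)
    ids <- vapply(genes, geneId, character(1))
    rows <- lapply(seq_len(nrow(pairs)), function(k)
        classifyPair(depth,
                     genes[[which(ids == pairs$gene_a[k])[1L]]],
                     genes[[which(ids == pairs$gene_b[k])[1L]]],
                     min_separation = min_separation, tau = tau,
                     window = window))
    if (!length(rows))
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          separation = integer(0),
                          classification = character(0),
                          intergenic_min_depth = numeric(0),
                          reference_depth = numeric(0),
                          depth_ratio = numeric(0)))
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
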