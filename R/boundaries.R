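#' @importFrom Biostrings DNAString matchPattern reverseComplement
NULL

#' Windowed depth slopes upstream of a gene
#'
#' Tiles the region upstream of the gene's transcription start with
#' `window`-bp windows every `stride` bp (strand-aware: "upstream" follows
#' the gene's strand; windows are anchored at the gene-proximal end so the
#' window adjacent to the gene is always full) and computes in each window
#' the least-squares slope of per-base depth versus position, sign-oriented
#' so that a positive slope means depth increasing toward the gene.
#'
#' With the default `stride = window` the windows tile the span without
#' overlap. A step in depth falling exactly on a tile boundary is invisible
#' to within-window slopes; pass `stride = window / 2` when maximal
#' sensitivity to arbitrarily placed steps is needed.
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param gene a \linkS4class{GeneFeature}.
#' @param upstream_span bp of upstream sequence to scan (truncated at the
#'   genome edge, flagged via the `truncated` element).
#' @param window window size in bp.
#' @param stride distance between successive window starts.
#' @return a list of class `"SlopeProfile"`: `gene_id`, `windows` (a
#'   data.frame with genomic `start`, `end`, `midpoint`, `slope`,
#'   `dist_to_gene`, ordered gene-proximal first), `upstream_span`,
#'   `window`, `stride`, `truncated`.
#' @export
slopeProfile <- function(depth, gene, upstream_span = 2000, window = 50,
                         stride = window) {
    if (window > upstream_span) stop("window larger than upstream span")
    genome <- depthGenome(depth)
    v <- strandDepth(depth, geneStrand(gene))
    ts <- txStart(gene)
    if (geneStrand(gene) == "+") {
        from <- max(1L, ts - upstream_span)
        to <- ts - 1L
        truncated <- (ts - upstream_span) < 1L
    } else {
        from <- ts + 1L
        to <- min(genomeLength(genome), ts + upstream_span)
        truncated <- (ts + upstream_span) > genomeLength(genome)
    }
    if (to < from || to - from + 1L < window) {
        win <- data.frame(start = integer(0), end = integer(0),
                          midpoint = numeric(0), slope = numeric(0),
                          dist_to_gene = integer(0))
        return(structure(list(gene_id = geneId(gene), windows = win,
                              upstream_span = upstream_span, window = window,
                              stride = stride, truncated = TRUE),
                         class = "SlopeProfile"))
    }
    anchor <- if (geneStrand(gene) == "+") "end" else "start"
    w <- .anchoredWindows(from, to, window, stride, anchor = anchor)
    slope <- numeric(nrow(w))
    for (k in seq_len(nrow(w))) {
        y <- v[w[k, 1L]:w[k, 2L]]
        s <- .lsSlope(y)
        slope[k] <- if (geneStrand(gene) == "+") s else -s
    }
    mid <- (w[, 1L] + w[, 2L]) / 2
    dist <- if (geneStrand(gene) == "+") ts - w[, 2L] else w[, 1L] - ts
    win <- data.frame(start = w[, 1L], end = w[, 2L], midpoint = mid,
                      slope = slope, dist_to_gene = as.integer(dist))
    structure(list(gene_id = geneId(gene), windows = win,
                   upstream_span = upstream_span, window = window,
                   stride = stride, truncated = truncated),
              class = "SlopeProfile")
}

#' @export
print.SlopeProfile <- function(x, ...) {
    cat("SlopeProfile for", x$gene_id, "-", nrow(x$windows), "windows of",
        x$window, "bp (stride", x$stride, ") over", x$upstream_span,
        "bp upstream", if (x$truncated) "(truncated)", "\n")
    if (nrow(x$windows)) {
        top <- x$windows[order(-x$windows$slope)[seq_len(min(3, nrow(x$windows)))], ]
        cat("top slopes:\n"); print(top, row.names = FALSE)
    }
    invisible(x)
}

#' Call putative transcription start sites from a slope profile
#'
#' The `top_n` windows with the highest slope (ties broken toward the
#' gene-proximal window) become putative TSS calls. A call is `matched`
#' when a known TSS of the gene lies within `match_radius` bp of the window
#' midpoint (radius 50 reproduces the conventional 100-bp matching window);
#' `inside_upstream_gene` when the window overlaps the exons of another
#' gene on the same strand; `upstream_of_known` when the window lies 5' of
#' every known TSS of the gene; otherwise `unmatched`.
#'
#' @param profile a `"SlopeProfile"` from \code{\link{slopeProfile}}.
#' @param known boundaries data.frame (see \code{\link{readBoundaries}});
#'   only `kind == "tss"` rows for this gene are used.
#' @param genes named list of all \linkS4class{GeneFeature}s (context for
#'   the `inside_upstream_gene` label); may be empty.
#' @param top_n number of candidate windows to report.
#' @param match_radius bp each side of the window midpoint.
#' @param slope_floor drop candidate windows with slope below this value.
#' @return data.frame with one row per call: `gene_id`, `start`, `end`,
#'   `midpoint`, `slope`, `rank`, `match_status`, `matched_position`,
#'   `matched_label`.
#' @export
callTss <- function(profile, known = emptyBoundaries(), genes = list(),
                    top_n = 3, match_radius = 50, slope_floor = -Inf) {
    win <- profile$windows
    gene_id <- profile$gene_id
    empty <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), midpoint = numeric(0),
                        slope = numeric(0), rank = integer(0),
                        match_status = character(0),
                        matched_position = integer(0),
                        matched_label = character(0))
    if (!nrow(win)) return(empty)
    o <- order(-win$slope, win$dist_to_gene)
    o <- o[win$slope[o] >= slope_floor]
    o <- o[seq_len(min(top_n, length(o)))]
    if (!length(o)) return(empty)
    sel <- win[o, , drop = FALSE]

    ktss <- known[known$kind == "tss" & known$gene_id == gene_id, ,
                  drop = FALSE]
    this_gene <- NULL
    for (g in genes)
        if (geneId(g) == gene_id) this_gene <- g
    status <- character(nrow(sel))
    mpos <- rep(NA_integer_, nrow(sel))
    mlab <- rep(NA_character_, nrow(sel))
    for (k in seq_len(nrow(sel))) {
        mid <- sel$midpoint[k]
        if (nrow(ktss)) {
            d <- abs(ktss$position - mid)
            j <- which.min(d)
            if (d[j] <= match_radius) {
                status[k] <- "matched"
                mpos[k] <- ktss$position[j]
                mlab[k] <- as.character(ktss$label[j])
                next
            }
        }
        inside <- FALSE
        for (g in genes) {
            if (geneId(g) == gene_id) next
            if (!is.null(this_gene) &&
                geneStrand(g) != geneStrand(this_gene)) next
            ex <- geneExons(g)
            if (any(sel$start[k] <= end(ex) & sel$end[k] >= start(ex))) {
                inside <- TRUE; break
            }
        }
        if (inside) { status[k] <- "inside_upstream_gene"; next }
        if (nrow(ktss)) {
            upstream_all <- if (!is.null(this_gene) &&
                                geneStrand(this_gene) == "-")
                all(mid > ktss$position) else all(mid < ktss$position)
            if (is.null(this_gene))
                upstream_all <- all(mid < ktss$position)
            if (upstream_all) { status[k] <- "upstream_of_known"; next }
        }
        status[k] <- "unmatched"
    }
    data.frame(gene_id = gene_id, start = sel$start, end = sel$end,
               midpoint = sel$midpoint, slope = sel$slope,
               rank = seq_len(nrow(sel)), match_status = status,
               matched_position = mpos, matched_label = mlab,
               stringsAsFactors = FALSE)
}

#' Detect the 3' transcript terminus as a downstream coverage drop
#'
#' Scans `window`-bp windows downstream of the gene end (strand-aware) and
#' reports the first window whose mean depth falls below
#' `drop_fraction x` the gene-body mean depth. If, before any drop, a
#' window overlaps the exons of another same-strand gene, the terminus is
#' reported as `obscured_by_downstream_gene`. When known 3' termini are
#' supplied, a detected drop within `match_radius` bp of one is `matched`,
#' otherwise `unmatched` (as is the absence of any drop).
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param gene a \linkS4class{GeneFeature}.
#' @param known boundaries data.frame; `kind == "terminus_3p"` rows used.
#' @param genes named list of all genes (context for obscuring).
#' @param downstream_span bp to scan past the gene end.
#' @param window window size in bp.
#' @param drop_fraction drop threshold as a fraction of gene-body mean.
#' @param match_radius bp tolerance when matching known termini.
#' @return one-row data.frame: `gene_id`, `drop_position`, `depth_before`,
#'   `depth_after`, `match_status`, `matched_position`.
#' @export
callTerminus <- function(depth, gene, known = emptyBoundaries(),
                         genes = list(), downstream_span = 2000,
                         window = 50, drop_fraction = 0.5,
                         match_radius = 50) {
    genome <- depthGenome(depth)
    v <- strandDepth(depth, geneStrand(gene))
    body <- mean(unlist(lapply(seq_along(geneExons(gene)), function(k) {
        ex <- geneExons(gene)
        v[start(ex)[k]:end(ex)[k]]
    })))
    te <- txEnd(gene)
    if (geneStrand(gene) == "+") {
        from <- te + 1L
        to <- min(genomeLength(genome), te + downstream_span)
        anchor <- "start"
    } else {
        from <- max(1L, te - downstream_span)
        to <- te - 1L
        anchor <- "end"
    }
    res <- function(pos, before, after, status, mpos = NA_integer_)
        data.frame(gene_id = geneId(gene), drop_position = pos,
                   depth_before = before, depth_after = after,
                   match_status = status, matched_position = mpos,
                   stringsAsFactors = FALSE)
    if (to < from || to - from + 1L < window)
        return(res(NA_integer_, body, NA_real_, "unmatched"))
    w <- .anchoredWindows(from, to, window, window, anchor = anchor)
    kter <- known[known$kind == "terminus_3p" & known$gene_id == geneId(gene),
                  , drop = FALSE]
    prev_mean <- body
    for (k in seq_len(nrow(w))) {
        # obscured: another same-strand gene's exons under the scan window
        for (g in genes) {
            if (geneId(g) == geneId(gene) ||
                geneStrand(g) != geneStrand(gene)) next
            ex <- geneExons(g)
            if (any(w[k, 1L] <= end(ex) & w[k, 2L] >= start(ex)))
                return(res(NA_integer_, prev_mean, NA_real_,
                           "obscured_by_downstream_gene"))
        }
        mu <- mean(v[w[k, 1L]:w[k, 2L]])
        if (mu < drop_fraction * body) {
            pos <- if (geneStrand(gene) == "+") w[k, 1L] else w[k, 2L]
            status <- "unmatched"; mpos <- NA_integer_
            if (nrow(kter)) {
                d <- abs(kter$position - pos)
                j <- which.min(d)
                if (d[j] <= match_radius) {
                    status <- "matched"; mpos <- kter$position[j]
                }
            }
            return(res(as.integer(pos), prev_mean, mu, status, mpos))
        }
        prev_mean <- mu
    }
    res(NA_integer_, prev_mean, NA_real_, "unmatched")
}

#' Exact-match scan of promoter sequences against both genome strands
#'
#' Finds every exact occurrence of each promoter sequence on the plus
#' strand and of its reverse complement (reported as a minus-strand hit) on
#' the genome. Positions are 1-based starts of the matching plus-strand
#' interval.
#'
#' @param genome a \linkS4class{MitoGenome} with its sequence present.
#' @param promoter_seqs named character vector (names = promoter labels) of
#'   A/C/G/T sequences, or a data.frame with columns `label`, `seq`.
#' @return data.frame with columns `label`, `strand`, `start`, sorted by
#'   label then position.
#' @export
scanPromoterSequences <- function(genome, promoter_seqs) {
    if (!nzchar(genomeSequence(genome)))
        stop("genome sequence required for promoter scanning")
    if (is.data.frame(promoter_seqs)) {
        seqs <- stats::setNames(as.character(promoter_seqs$seq),
                                promoter_seqs$label)
    } else seqs <- promoter_seqs
    if (!length(seqs) || any(!nzchar(seqs)))
        stop("promoter sequences must be non-empty")
    if (any(grepl("[^ACGTacgt]", seqs)))
        stop("ambiguous or non-ACGT bases in promoter sequences")
    subject <- DNAString(genomeSequence(genome))
    out <- list()
    for (lab in names(seqs)) {
        q <- DNAString(toupper(seqs[[lab]]))
        hp <- matchPattern(q, subject)
        hm <- matchPattern(reverseComplement(q), subject)
        if (length(hp))
            out[[length(out) + 1L]] <- data.frame(label = lab, strand = "+",
                                                  start = start(hp))
        if (length(hm))
            out[[length(out) + 1L]] <- data.frame(label = lab, strand = "-",
                                                  start = start(hm))
    }
    if (!length(out))
        return(data.frame(label = character(0), strand = character(0),
                          start = integer(0)))
    res <- do.call(rbind, out)
    res <- res[order(res$label, res$start, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}
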