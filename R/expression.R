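# Per-gene read counting and RPKM normalisation.

#' Count reads (fragments) per gene
#'
#' Two input modes. (1) A named character vector of per-gene SAM files,
#' each holding the alignments of the library against that gene's own
#' (100-bp-extended) reference: retained alignments are counted, with read
#' pairs collapsed to one fragment unless `count_mates = TRUE`. A read is
#' counted for every gene reference it aligns to (multi-reporting
#' alignments are not deduplicated across genes). (2) A
#' \linkS4class{StrandedDepth} plus the gene models: counts are estimated
#' as total exonic aligned bases on the gene's strand divided by
#' `read_length` (the study-scale approximation when only a depth track is
#' available).
#'
#' @param x named character vector of SAM paths (names = gene ids) or a
#'   \linkS4class{StrandedDepth}.
#' @param genes named list of \linkS4class{GeneFeature}.
#' @param count_mates count each mate separately instead of per fragment.
#' @param read_length read length used by the depth-based estimate.
#' @return named numeric vector of counts, one per gene in `genes`.
#' @export
countReadsPerGene <- function(x, genes, count_mates = FALSE,
                              read_length = 89) {
    ids <- vapply(genes, geneId, character(1))
    if (is(x, "StrandedDepth")) {
        counts <- vapply(genes, function(g) {
            v <- strandDepth(x, geneStrand(g))
            ex <- geneExons(g)
            bases <- sum(vapply(seq_along(ex), function(k)
                sum(v[start(ex)[k]:end(ex)[k]]), numeric(1)))
            bases / read_length
        }, numeric(1))
        names(counts) <- ids
        return(counts)
    }
    if (!is.character(x) || is.null(names(x)))
        stop("'x' must be a StrandedDepth or a named vector of SAM paths")
    missing <- setdiff(ids, names(x))
    if (length(missing))
        stop("no alignment file for gene(s): ", paste(missing, collapse = ", "))
    counts <- stats::setNames(numeric(length(ids)), ids)
    for (id in ids) {
        .checkFileExists(x[[id]], paste0("SAM file for ", id))
        bam <- .asBamFile(x[[id]])
        flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                       isSecondaryAlignment = FALSE,
                                       isSupplementaryAlignment = FALSE)
        aln <- GenomicAlignments::readGAlignments(bam,
            param = Rsamtools::ScanBamParam(flag = flag, what = "qname"))
        counts[id] <- if (count_mates) length(aln)
                      else length(unique(S4Vectors::mcols(aln)$qname))
    }
    counts
}

#' RPKM from counts and transcript lengths
#'
#' `rpkm[g] = counts[g] * 1e9 / (lengths[g] * sum(counts))`. The caller
#' chooses the universe of the denominator; for the conventional
#' plant-mitochondrial normalisation it is the reads mapped to
#' protein-coding genes only (restrict `counts` to those genes, e.g. with
#' \code{\link{proteinCodingIds}}). For intron-containing genes, pass the
#' spliced transcript length (sum of exon widths).
#'
#' @param counts named numeric vector of per-gene read counts.
#' @param lengths named numeric vector of transcript lengths in bp.
#' @return named numeric vector of RPKM values.
#' @export
rpkmValues <- function(counts, lengths) {
    if (is.null(names(counts)) || is.null(names(lengths)))
        stop("'counts' and 'lengths' must be named")
    lengths <- lengths[names(counts)]
    if (anyNA(lengths)) stop("missing transcript length for some genes")
    if (any(lengths <= 0)) stop("all transcript lengths must be positive")
    total <- sum(counts)
    if (total <= 0) stop("zero total count: RPKM undefined")
    counts * 1e9 / (lengths * total)
}

#' Gene ids of protein-coding features
#'
#' @param genes named list of \linkS4class{GeneFeature}.
#' @return character vector of ids with `featureClass == "protein"`.
#' @export
proteinCodingIds <- function(genes) {
    ids <- vapply(genes, geneId, character(1))
    ids[vapply(genes, featureClass, character(1)) == "protein"]
}

#' Mean depth of each exon of a gene
#'
#' @param depth a \linkS4class{StrandedDepth}.
#' @param gene a \linkS4class{GeneFeature}.
#' @return numeric vector of per-exon mean depths on the gene's strand,
#'   ordered as in the transcript (reversed genomic order for minus-strand
#'   genes).
#' @export
exonLevelDepth <- function(depth, gene) {
    v <- strandDepth(depth, geneStrand(gene))
    ex <- geneExons(gene)
    means <- vapply(seq_along(ex), function(k)
        mean(v[start(ex)[k]:end(ex)[k]]), numeric(1))
    if (geneStrand(gene) == "-") means <- rev(means)
    names(means) <- paste0(geneId(gene), "e", seq_along(means))
    means
}

#' Per-gene expression table
#'
#' Convenience wrapper assembling counts, spliced transcript lengths and
#' RPKM (denominator restricted to protein-coding genes) into one table.
#'
#' @inheritParams countReadsPerGene
#' @param depth optional \linkS4class{StrandedDepth} for exon-level means.
#' @return data.frame with columns `gene_id`, `reads_mapped`,
#'   `transcript_length`, `rpkm`.
#' @export
geneExpressionTable <- function(x, genes, depth = NULL, count_mates = FALSE,
                                read_length = 89) {
    counts <- countReadsPerGene(x, genes, count_mates = count_mates,
                                read_length = read_length)
    lengths <- vapply(genes, transcriptLength, numeric(1))
    names(lengths) <- names(counts)
    pc <- proteinCodingIds(genes)
    rk <- rep(NA_real_, length(counts))
    names(rk) <- names(counts)
    if (length(pc) && sum(counts[pc]) > 0)
        rk[pc] <- rpkmValues(counts[pc], lengths[pc])
    data.frame(gene_id = names(counts),
               reads_mapped = as.numeric(counts),
               transcript_length = as.integer(lengths),
               rpkm = as.numeric(rk),
               stringsAsFactors = FALSE)
}
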