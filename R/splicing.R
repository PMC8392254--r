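# Junction-read counting, splicing efficiency and group comparisons.

#' Junction coordinates of a cis intron on its per-gene references
#'
#' Maps an intron's genomic donor/acceptor coordinates onto the
#' `extension`-bp-extended unspliced reference of its gene and computes the
#' exon-exon junction coordinate on the spliced reference. A junction is
#' identified by the reference coordinate of its last upstream base, i.e. a
#' read supports junction `j` when it covers both `j` and `j + 1`.
#'
#' @param gene the parent \linkS4class{GeneFeature}.
#' @param intron an \linkS4class{IntronFeature} with genomic coordinates.
#' @param extension bp of flanking sequence included in the references.
#' @return list with `ei5`, `i3e` (unspliced reference) and `ee` (spliced
#'   reference) junction coordinates.
#' @export
junctionPositions <- function(gene, intron, extension = 100) {
    if (is.na(intron@donorPos) || is.na(intron@acceptorPos))
        stop("intron '", intronId(intron),
             "' has no genomic junction coordinates (trans-spliced?)")
    st <- geneStrand(gene)
    r <- geneRange(gene)
    toRef <- function(p)
        if (st == "+") p - (start(r) - extension) + 1L
        else (end(r) + extension) - p + 1L
    ei5 <- toRef(intron@donorPos)
    i3e <- toRef(intron@acceptorPos) - 1L
    ex <- geneExons(gene)
    if (st == "+") {
        upstream_exons <- which(end(ex) <= intron@donorPos)
        ee <- extension + sum(width(ex)[upstream_exons])
    } else {
        upstream_exons <- which(start(ex) >= intron@donorPos)
        ee <- extension + sum(width(ex)[upstream_exons])
    }
    list(ei5 = as.integer(ei5), i3e = as.integer(i3e), ee = as.integer(ee))
}

#' Count reads supporting the three junctions of an intron
#'
#' Counts reads crossing the exon/5'-intron (EI5') and 3'-intron/exon
#' (I3'E) junctions in the alignments against the unspliced reference, and
#' reads crossing the exon-exon (EE) junction in the alignments against the
#' spliced reference. A read supports a junction when its aligned interval
#' covers at least one base on each side of the junction point; the
#' `flank`-bp figure bounds the evaluation windows around each junction,
#' not a minimum overhang. Each read (by name) is counted at most once per
#' junction. Counting is refused when a flanking exon is shorter than
#' `flank`, since the junction windows would not fit inside the exon.
#'
#' @param unspliced_sam,spliced_sam SAM files of alignments against the
#'   unspliced and spliced per-gene references.
#' @param intron an \linkS4class{IntronFeature} (for id, metadata and the
#'   short-exon refusal); junction coordinates are taken from `positions`
#'   when supplied, else derived via \code{\link{junctionPositions}}.
#' @param gene the parent \linkS4class{GeneFeature}; needed only when
#'   `positions` is not supplied.
#' @param positions optional list with `ei5`, `i3e`, `ee` coordinates.
#' @param flank bp evaluated on each side of a junction.
#' @param extension passed to \code{\link{junctionPositions}}.
#' @return one-row data.frame: `intron_id`, `n_ei5`, `n_i3e`, `n_ee`.
#' @export
countJunctionReads <- function(unspliced_sam, spliced_sam, intron,
                               gene = NULL, positions = NULL, flank = 30,
                               extension = 100) {
    stopifnot(flank > 0)
    fl <- flankingExonLengths(intron)
    if (!anyNA(fl) && any(fl < flank))
        stop("intron '", intronId(intron), "' not analyzed: flanking exon (",
             min(fl), " bp) shorter than the ", flank, "-bp junction window")
    if (is.null(positions))
        positions <- junctionPositions(gene, intron, extension)
    un <- .readRefAlignments(unspliced_sam)
    sp <- .readRefAlignments(spliced_sam)
    .check_inside <- function(aln, j, what) {
        if (length(aln$start) && j < 1L)
            stop("junction '", what, "' outside the reference for intron '",
                 intronId(intron), "'")
    }
    .check_inside(un, positions$ei5, "ei5")
    .check_inside(un, positions$i3e, "i3e")
    .check_inside(sp, positions$ee, "ee")
    data.frame(intron_id = intronId(intron),
               n_ei5 = .countCrossing(un, positions$ei5),
               n_i3e = .countCrossing(un, positions$i3e),
               n_ee = .countCrossing(sp, positions$ee),
               stringsAsFactors = FALSE)
}

.readRefAlignments <- function(sam_path) {
    .checkFileExists(sam_path, "SAM file")
    bam <- .asBamFile(sam_path)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    aln <- GenomicAlignments::readGAlignments(bam,
        param = Rsamtools::ScanBamParam(flag = flag, what = "qname"))
    list(start = start(aln), end = end(aln),
         qname = S4Vectors::mcols(aln)$qname)
}

# reads whose aligned span covers positions j and j+1; one count per name
.countCrossing <- function(aln, j) {
    hit <- aln$start <= j & aln$end >= j + 1L
    length(unique(aln$qname[hit]))
}

#' Splicing efficiency and junction-count ratio of one intron
#'
#' `SE = N_EE / (N_EE + 0.5 N_EI5' + 0.5 N_I3'E)`: the fraction of junction
#' evidence supporting the mature, spliced form, where the two unspliced
#' junction counts are halved because a single unspliced precursor molecule
#' carries both of them. The I3'E/EI5' ratio is `NA` when `N_EI5'` is zero
#' (undefined, not infinite). All-zero counts are an error.
#'
#' @param n_ei5,n_i3e,n_ee junction read counts.
#' @return list with `se` and `ratio` (unrounded).
#' @export
splicingEfficiency <- function(n_ei5, n_i3e, n_ee) {
    stopifnot(length(n_ei5) == 1L, length(n_i3e) == 1L, length(n_ee) == 1L)
    if (any(c(n_ei5, n_i3e, n_ee) < 0))
        stop("junction counts must be non-negative")
    total <- n_ee + 0.5 * n_ei5 + 0.5 * n_i3e
    if (total == 0)
        stop("all junction counts are zero: splicing efficiency undefined")
    list(se = n_ee / total,
         ratio = if (n_ei5 == 0) NA_real_ else n_i3e / n_ei5)
}

#' Splicing-efficiency table for a set of introns
#'
#' Applies \code{\link{splicingEfficiency}} to each row of a junction-count
#' table, carrying along splice-type and mechanism metadata.
#'
#' @param counts data.frame with columns `intron_id`, `n_ei5`, `n_i3e`,
#'   `n_ee` and optionally `splice_type`, `mechanism`.
#' @return the input with `ratio_i3e_ei5` and `se` columns appended
#'   (unrounded; \code{\link{writeResultsTable}} renders them at 2
#'   decimals).
#' @export
splicingTable <- function(counts) {
    need <- c("intron_id", "n_ei5", "n_i3e", "n_ee")
    if (!all(need %in% names(counts)))
        stop("counts table must have columns ", paste(need, collapse = ", "))
    se <- numeric(nrow(counts)); ratio <- numeric(nrow(counts))
    for (k in seq_len(nrow(counts))) {
        r <- splicingEfficiency(counts$n_ei5[k], counts$n_i3e[k],
                                counts$n_ee[k])
        se[k] <- r$se; ratio[k] <- r$ratio
    }
    counts$ratio_i3e_ei5 <- ratio
    counts$se <- se
    counts
}

#' Junction read counts of the 21 analyzed Arabidopsis mtDNA introns
#'
#' The published per-intron junction read counts (EI5', I3'E, EE) for the
#' 21 cis- and trans-spliced group II introns analyzed in the Arabidopsis
#' mitochondrial genome, with their splice type and splicing mechanism.
#' The two trans-spliced introns of nad5 are absent: the intervening exon 3
#' is shorter than the 30-bp junction window.
#'
#' @return data.frame with columns `intron_id`, `splice_type`, `mechanism`,
#'   `n_ei5`, `n_i3e`, `n_ee`.
#' @export
paperJunctionCounts <- function() {
    path <- system.file("extdata", "arabidopsis_mt_junction_counts.tsv",
                        package = "mitoscape", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
}

#' One-way ANOVA of splicing efficiency across groups
#'
#' Compares SE values across the levels of a grouping column (splice type
#' or splicing mechanism) with a standard one-way analysis of variance,
#' `F = MS_between / MS_within`. A degenerate case with zero within-group
#' variance but distinct group means is reported as `F = Inf`, `p = 0`.
#'
#' @param records data.frame with an `se` column and the grouping column.
#' @param grouping name of the grouping column, `"splice_type"` or
#'   `"mechanism"`.
#' @return list with `f`, `p`, `df` (numerator, denominator), and
#'   `group_means`.
#' @export
compareGroups <- function(records, grouping = c("splice_type", "mechanism")) {
    grouping <- match.arg(grouping)
    if (!grouping %in% names(records) || !"se" %in% names(records))
        stop("records must have columns 'se' and '", grouping, "'")
    g <- factor(records[[grouping]])
    y <- records$se
    if (nlevels(g) < 2L)
        stop("need at least two groups")
    if (max(table(g)) < 2L)
        stop("need at least one group with two or more records")
    k <- nlevels(g); n <- length(y)
    means <- tapply(y, g, mean)
    ss_between <- sum(table(g) * (means - mean(y))^2)
    ss_within <- sum((y - means[g])^2)
    df1 <- k - 1L; df2 <- n - k
    if (ss_within == 0) {
        if (ss_between == 0) {
            f <- 0; p <- 1
        } else {
            f <- Inf; p <- 0
        }
    } else {
        fit <- stats::anova(stats::lm(y ~ g))
        f <- fit$`F value`[1L]
        p <- fit$`Pr(>F)`[1L]
    }
    list(f = f, p = p, df = c(df1, df2), group_means = means)
}
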