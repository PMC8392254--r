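#' @import methods
#' @importFrom IRanges IRanges reduce start end width findOverlaps overlapsAny
#' @importFrom S4Vectors isSorted queryHits subjectHits
NULL

#' Reference genome for a mitochondrial (or other small) replicon
#'
#' Holds the reference name, its length, optionally its nucleotide sequence,
#' and a set of masked intervals (e.g. plastid-like regions of a plant
#' mitochondrial genome) that are excluded from all depth statistics.
#' Coordinates are 1-based closed throughout the package; conversion to the
#' 0-based conventions of BED/bedGraph happens only at I/O boundaries.
#'
#' @slot name single reference name.
#' @slot seqlength genome length in bp.
#' @slot sequence nucleotide string (possibly empty when unknown).
#' @slot mask an \link[IRanges]{IRanges} of masked intervals, stored reduced
#'   (sorted, non-overlapping).
#' @export
setClass("MitoGenome",
    slots = c(name = "character", seqlength = "integer",
              sequence = "character", mask = "IRanges"))

setValidity("MitoGenome", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@seqlength) != 1L || is.na(object@seqlength) ||
        object@seqlength <= 0L)
        msg <- c(msg, "'seqlength' must be a single positive integer")
    if (length(object@sequence) != 1L)
        msg <- c(msg, "'sequence' must be a single string (possibly empty)")
    else if (nzchar(object@sequence) &&
             nchar(object@sequence) != object@seqlength)
        msg <- c(msg, "sequence length disagrees with 'seqlength'")
    if (length(object@mask)) {
        if (min(start(object@mask)) < 1L ||
            max(end(object@mask)) > object@seqlength)
            msg <- c(msg, "masked intervals outside [1, seqlength]")
        red <- reduce(object@mask)
        if (length(red) != length(object@mask) ||
            !all(start(red) == start(object@mask)))
            msg <- c(msg, "masked intervals must be reduced (non-overlapping, sorted)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MitoGenome
#'
#' @param name reference name.
#' @param length genome length in bp. May be omitted when `sequence` is given.
#' @param sequence optional nucleotide string (A/C/G/T/N).
#' @param mask optional \link[IRanges]{IRanges} (or 2-column matrix of
#'   1-based closed start/end) of intervals to exclude from statistics.
#' @return a \linkS4class{MitoGenome}.
#' @examples
#' MitoGenome("mt", length = 1000, mask = IRanges::IRanges(101, 200))
#' @export
MitoGenome <- function(name, length = NULL, sequence = "", mask = IRanges()) {
    sequence <- toupper(as.character(sequence))
    if (is.null(length)) {
        if (!nzchar(sequence))
            stop("either 'length' or 'sequence' must be supplied")
        length <- nchar(sequence)
    }
    if (is.matrix(mask))
        mask <- IRanges(start = mask[, 1L], end = mask[, 2L])
    new("MitoGenome", name = as.character(name),
        seqlength = as.integer(length), sequence = sequence,
        mask = reduce(mask))
}

#' @describeIn MitoGenome genome length in bp.
#' @param x a \linkS4class{MitoGenome}.
#' @export
genomeLength <- function(x) x@seqlength

#' @describeIn MitoGenome reference name.
#' @export
genomeName <- function(x) x@name

#' @describeIn MitoGenome nucleotide sequence (`""` when absent).
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn MitoGenome masked intervals as an IRanges.
#' @export
maskRanges <- function(x) x@mask

#' Logical vector marking masked positions
#'
#' @param x a \linkS4class{MitoGenome}.
#' @return logical of length `genomeLength(x)`; `TRUE` at masked positions.
#' @export
maskedPositions <- function(x) {
    m <- logical(x@seqlength)
    if (length(x@mask))
        for (i in seq_along(x@mask))
            m[start(x@mask)[i]:end(x@mask)[i]] <- TRUE
    m
}

setMethod("show", "MitoGenome", function(object) {
    cat("MitoGenome '", object@name, "': ", object@seqlength, " bp; ",
        length(object@mask), " masked interval(s)",
        if (nzchar(object@sequence)) "; sequence present" else "",
        "\n", sep = "")
})

#' Strand-specific per-base read depth
#'
#' Per-base read-depth vectors for the plus and minus strands of one
#' reference. Positions falling in the genome's masked intervals are kept in
#' the arrays (coordinates stay stable) but are excluded from every summary
#' statistic.
#'
#' @slot genome the \linkS4class{MitoGenome} the depths refer to.
#' @slot plus,minus numeric depth vectors of length `genomeLength(genome)`.
#' @export
setClass("StrandedDepth",
    slots = c(genome = "MitoGenome", plus = "numeric", minus = "numeric"))

setValidity("StrandedDepth", function(object) {
    msg <- NULL
    L <- object@genome@seqlength
    if (length(object@plus) != L || length(object@minus) != L)
        msg <- c(msg, "depth vectors must have length genomeLength(genome)")
    if (anyNA(object@plus) || anyNA(object@minus) ||
        min(object@plus, object@minus, 0) < 0)
        msg <- c(msg, "depths must be non-negative and non-missing")
    if (is.null(msg)) TRUE else msg
})

#' Construct a StrandedDepth
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param plus,minus per-base depth vectors (recycled scalars allowed).
#' @return a \linkS4class{StrandedDepth}.
#' @export
StrandedDepth <- function(genome, plus = 0, minus = 0) {
    L <- genomeLength(genome)
    new("StrandedDepth", genome = genome,
        plus = rep_len(as.numeric(plus), L),
        minus = rep_len(as.numeric(minus), L))
}

#' @describeIn StrandedDepth plus-strand depth vector.
#' @param x a \linkS4class{StrandedDepth}.
#' @export
depthPlus <- function(x) x@plus

#' @describeIn StrandedDepth minus-strand depth vector.
#' @export
depthMinus <- function(x) x@minus

#' @describeIn StrandedDepth the underlying \linkS4class{MitoGenome}.
#' @export
depthGenome <- function(x) x@genome

#' Depth vector of one strand
#'
#' @param x a \linkS4class{StrandedDepth}.
#' @param strand `"+"` or `"-"`.
#' @export
strandDepth <- function(x, strand) {
    strand <- match.arg(strand, c("+", "-"))
    if (strand == "+") x@plus else x@minus
}

setMethod("show", "StrandedDepth", function(object) {
    cat("StrandedDepth on '", object@genome@name, "' (",
        object@genome@seqlength, " bp): mean depth + ",
        signif(mean(object@plus), 4), ", - ",
        signif(mean(object@minus), 4), "\n", sep = "")
})

#' A gene or coding-unit region with exon structure
#'
#' Gene regions of trans-spliced genes (e.g. the separate exon blocks of
#' nad1) and co-annotated dicistrons are modelled as separate GeneFeature
#' records sharing a `codingUnitId`.
#'
#' @slot geneId gene (or gene-region) identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot featureClass one of `"protein"`, `"rRNA"`, `"tRNA"`, `"orf"`.
#' @slot exons \link[IRanges]{IRanges} of exons, sorted, non-overlapping.
#' @slot codingUnitId identifier grouping gene regions into coding units.
#' @export
setClass("GeneFeature",
    slots = c(geneId = "character", strand = "character",
              featureClass = "character", exons = "IRanges",
              codingUnitId = "character"))

setValidity("GeneFeature", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (!object@featureClass %in% c("protein", "rRNA", "tRNA", "orf"))
        msg <- c(msg, "featureClass must be protein/rRNA/tRNA/orf")
    if (length(object@exons) == 0L)
        msg <- c(msg, "exons must be non-empty")
    else {
        if (!isSorted(start(object@exons)))
            msg <- c(msg, "exons must be sorted by start")
        if (length(object@exons) > 1L &&
            any(start(object@exons)[-1L] <=
                end(object@exons)[-length(object@exons)]))
            msg <- c(msg, "exons must be non-overlapping")
        if (min(start(object@exons)) < 1L)
            msg <- c(msg, "exon coordinates must be >= 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneFeature
#'
#' @param gene_id identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons an \link[IRanges]{IRanges} or 2-column matrix of 1-based
#'   closed exon intervals.
#' @param feature_class `"protein"` (default), `"rRNA"`, `"tRNA"` or `"orf"`.
#' @param coding_unit_id defaults to `gene_id`.
#' @return a \linkS4class{GeneFeature}.
#' @examples
#' GeneFeature("atp1", "+", cbind(101, 1600))
#' @export
GeneFeature <- function(gene_id, strand, exons, feature_class = "protein",
                        coding_unit_id = gene_id) {
    if (is.matrix(exons))
        exons <- IRanges(start = exons[, 1L], end = exons[, 2L])
    exons <- exons[order(start(exons))]
    new("GeneFeature", geneId = as.character(gene_id), strand = strand,
        featureClass = feature_class, exons = exons,
        codingUnitId = as.character(coding_unit_id))
}

#' @describeIn GeneFeature gene identifier.
#' @param x a \linkS4class{GeneFeature}.
#' @export
geneId <- function(x) x@geneId

#' @describeIn GeneFeature gene strand.
#' @export
geneStrand <- function(x) x@strand

#' @describeIn GeneFeature exon IRanges.
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneFeature feature class.
#' @export
featureClass <- function(x) x@featureClass

#' @describeIn GeneFeature coding-unit identifier.
#' @export
codingUnitId <- function(x) x@codingUnitId

#' @describeIn GeneFeature genomic span (first exon start to last exon end).
#' @export
geneRange <- function(x) range(x@exons)

#' @describeIn GeneFeature position of transcription start (strand-aware).
#' @export
txStart <- function(x)
    if (x@strand == "+") min(start(x@exons)) else max(end(x@exons))

#' @describeIn GeneFeature position of transcription end (strand-aware).
#' @export
txEnd <- function(x)
    if (x@strand == "+") max(end(x@exons)) else min(start(x@exons))

#' @describeIn GeneFeature spliced transcript length (sum of exon widths).
#' @export
transcriptLength <- function(x) sum(width(x@exons))

setMethod("show", "GeneFeature", function(object) {
    r <- range(object@exons)
    cat("GeneFeature ", object@geneId, " (", object@featureClass, ", ",
        object@strand, ") ", start(r), "-", end(r), ", ",
        length(object@exons), " exon(s), unit ", object@codingUnitId,
        "\n", sep = "")
})

#' A group II intron with splicing metadata
#'
#' @slot intronId identifier, e.g. `"nad4i2"`.
#' @slot geneId parent gene.
#' @slot spliceType `"cis"` or `"trans"`.
#' @slot mechanism `"branching"`, `"hydrolytic"` or `"both"`.
#' @slot donorPos genomic coordinate of the last exonic base upstream of the
#'   intron (exon/5'-intron boundary, strand-aware).
#' @slot acceptorPos genomic coordinate of the first exonic base downstream
#'   of the intron (3'-intron/exon boundary, strand-aware).
#' @slot flankingExonLengths upstream and downstream flanking exon lengths
#'   in bp.
#' @export
setClass("IntronFeature",
    slots = c(intronId = "character", geneId = "character",
              spliceType = "character", mechanism = "character",
              donorPos = "integer", acceptorPos = "integer",
              flankingExonLengths = "integer"))

setValidity("IntronFeature", function(object) {
    msg <- NULL
    if (!object@spliceType %in% c("cis", "trans"))
        msg <- c(msg, "spliceType must be 'cis' or 'trans'")
    if (!object@mechanism %in% c("branching", "hydrolytic", "both"))
        msg <- c(msg, "mechanism must be branching/hydrolytic/both")
    if (length(object@flankingExonLengths) != 2L ||
        any(!is.na(object@flankingExonLengths) &
            object@flankingExonLengths < 0L))
        msg <- c(msg, "flankingExonLengths must be two non-negative lengths")
    if (is.null(msg)) TRUE else msg
})

#' Construct an IntronFeature
#'
#' @param intron_id,gene_id identifiers.
#' @param splice_type `"cis"` or `"trans"`.
#' @param mechanism `"branching"`, `"hydrolytic"` or `"both"`.
#' @param donor_pos,acceptor_pos genomic junction coordinates (see class
#'   slots); may be `NA` for trans-spliced introns whose halves lie on
#'   different precursors.
#' @param flanking_exon_lengths upstream/downstream flanking exon lengths.
#' @return an \linkS4class{IntronFeature}.
#' @export
IntronFeature <- function(intron_id, gene_id, splice_type, mechanism,
                          donor_pos = NA_integer_, acceptor_pos = NA_integer_,
                          flanking_exon_lengths = c(NA_integer_, NA_integer_)) {
    new("IntronFeature", intronId = as.character(intron_id),
        geneId = as.character(gene_id), spliceType = splice_type,
        mechanism = mechanism, donorPos = as.integer(donor_pos),
        acceptorPos = as.integer(acceptor_pos),
        flankingExonLengths = as.integer(flanking_exon_lengths))
}

#' @describeIn IntronFeature intron identifier.
#' @param x an \linkS4class{IntronFeature}.
#' @export
intronId <- function(x) x@intronId

#' @describeIn IntronFeature splice type (`"cis"`/`"trans"`).
#' @export
spliceType <- function(x) x@spliceType

#' @describeIn IntronFeature splicing mechanism.
#' @export
spliceMechanism <- function(x) x@mechanism

#' @describeIn IntronFeature flanking exon lengths (upstream, downstream).
#' @export
flankingExonLengths <- function(x) x@flankingExonLengths

setMethod("show", "IntronFeature", function(object) {
    cat("IntronFeature ", object@intronId, " in ", object@geneId, " (",
        object@spliceType, ", ", object@mechanism, "), donor ",
        object@donorPos, ", acceptor ", object@acceptorPos, "\n", sep = "")
})
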