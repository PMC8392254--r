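#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges seqnames strand start end width mcols
#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

# ---- reading -------------------------------------------------------------

#' Read a genome annotation with known boundaries
#'
#' Reads gene structures from GFF3 (genes with `ID`, optional
#' `feature_class` and `coding_unit` attributes; exons with `Parent`;
#' introns with `ID`, `Parent`, `splice_type`, `mechanism`) or from BED12
#' (blocks become exons; feature class defaults to `"protein"`), plus an
#' optional TSV of experimentally known transcription start sites and 3'
#' termini. All coordinates are 1-based closed internally; BED input is
#' converted from its on-disk 0-based half-open convention by the importer.
#'
#' The genome length is taken from `fasta_path` when given, else from
#' `genome_length`, else from a `##sequence-region` pragma in the GFF3.
#' Annotations must be linear(ized): features spanning the circular origin
#' of a circular-mapping genome are not supported.
#'
#' @param path GFF3 or BED12 annotation file.
#' @param boundary_path optional TSV with columns
#'   `gene_id`, `kind` (`tss`/`terminus_3p`), `position` (1-based), `label`.
#' @param fasta_path optional genome FASTA (first record used).
#' @param genome_length genome length in bp when no FASTA is given.
#' @param mask optional \link[IRanges]{IRanges} (or 2-column matrix) of
#'   masked intervals, e.g. plastid-like regions.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return list with elements `genome` (\linkS4class{MitoGenome}), `genes`
#'   (named list of \linkS4class{GeneFeature}), `introns` (named list of
#'   \linkS4class{IntronFeature}) and `boundaries` (data.frame).
#' @export
readAnnotation <- function(path, boundary_path = NULL, fasta_path = NULL,
                           genome_length = NULL, mask = IRanges(),
                           format = c("auto", "gff3", "bed")) {
    .checkFileExists(path, "annotation file")
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gff3"

    sequence <- ""
    if (!is.null(fasta_path)) {
        .checkFileExists(fasta_path, "FASTA file")
        seqs <- readDNAStringSet(fasta_path)
        sequence <- as.character(seqs[[1L]])
        genome_length <- nchar(sequence)
        ref_name <- sub("\\s.*", "", names(seqs)[1L])
    } else ref_name <- NA_character_

    gr <- tryCatch(import(path, format = if (format == "bed") "bed" else "gff3"),
                   error = function(e)
                       stop("malformed ", format, " file '", path, "': ",
                            conditionMessage(e), call. = FALSE))
    if (length(gr) == 0L)
        stop("annotation file '", path, "' contains no features")
    seqname <- as.character(seqnames(gr)[1L])
    if (is.na(ref_name)) ref_name <- seqname
    if (is.null(genome_length)) {
        genome_length <- .sequenceRegionLength(path, seqname)
        if (is.null(genome_length)) {
            genome_length <- max(end(gr))
            warning("genome length not declared; using max feature end (",
                    genome_length, " bp)")
        }
    }
    genome <- MitoGenome(ref_name, length = genome_length,
                         sequence = sequence, mask = mask)

    parsed <- if (format == "bed") .genesFromBed(gr)
              else .genesFromGff(gr)
    genes <- parsed$genes
    introns <- parsed$introns

    for (g in genes)
        if (max(end(geneExons(g))) > genome_length)
            stop("gene '", geneId(g), "' extends beyond the ",
                 genome_length, "-bp genome")
    for (g in genes) validObject(g)
    for (i in introns) validObject(i)

    boundaries <- if (is.null(boundary_path)) emptyBoundaries()
                  else readBoundaries(boundary_path, genome)

    list(genome = genome, genes = genes, introns = introns,
         boundaries = boundaries)
}

.sequenceRegionLength <- function(path, seqname) {
    hdr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
    for (h in hdr) {
        f <- strsplit(trimws(h), "\\s+")[[1L]]
        if (length(f) >= 4L && f[2L] == seqname)
            return(as.integer(f[4L]))
    }
    if (length(hdr)) {
        f <- strsplit(trimws(hdr[1L]), "\\s+")[[1L]]
        if (length(f) >= 4L) return(as.integer(f[4L]))
    }
    NULL
}

.gffAttr <- function(gr, name, default) {
    if (name %in% names(mcols(gr))) {
        v <- as.character(mcols(gr)[[name]])
        ifelse(is.na(v) | !nzchar(v), default, v)
    } else rep(default, length(gr))
}

.genesFromGff <- function(gr) {
    type <- as.character(mcols(gr)$type)
    gene_rows <- which(type == "gene")
    if (!length(gene_rows))
        stop("no 'gene' features in GFF3")
    ids <- .gffAttr(gr, "ID", NA_character_)[gene_rows]
    if (anyNA(ids)) stop("gene feature without ID attribute")
    fclass <- .gffAttr(gr, "feature_class", "protein")[gene_rows]
    cunit <- .gffAttr(gr, "coding_unit", NA_character_)[gene_rows]
    cunit <- ifelse(is.na(cunit), ids, cunit)

    parent <- .gffAttr(gr, "Parent", NA_character_)
    exon_rows <- which(type == "exon")
    genes <- vector("list", length(gene_rows))
    names(genes) <- ids
    for (k in seq_along(gene_rows)) {
        i <- gene_rows[k]
        ex <- exon_rows[parent[exon_rows] == ids[k]]
        exons <- if (length(ex))
            IRanges(start = start(gr)[ex], end = end(gr)[ex])
        else IRanges(start = start(gr)[i], end = end(gr)[i])
        genes[[k]] <- GeneFeature(ids[k],
                                  strand = as.character(strand(gr)[i]),
                                  exons = exons,
                                  feature_class = fclass[k],
                                  coding_unit_id = cunit[k])
    }

    intron_rows <- which(type == "intron")
    introns <- list()
    for (i in intron_rows) {
        iid <- .gffAttr(gr, "ID", NA_character_)[i]
        gid <- parent[i]
        if (is.na(iid) || is.na(gid))
            stop("intron feature without ID or Parent")
        st <- as.character(strand(gr)[i])
        donor <- if (st == "+") start(gr)[i] - 1L else end(gr)[i] + 1L
        acceptor <- if (st == "+") end(gr)[i] + 1L else start(gr)[i] - 1L
        flanks <- c(NA_integer_, NA_integer_)
        if (gid %in% names(genes)) {
            ex <- geneExons(genes[[gid]])
            up <- which(end(ex) == start(gr)[i] - 1L)
            dn <- which(start(ex) == end(gr)[i] + 1L)
            w_left <- if (length(up)) width(ex)[up[1L]] else NA_integer_
            w_right <- if (length(dn)) width(ex)[dn[1L]] else NA_integer_
            flanks <- if (st == "+") c(w_left, w_right) else c(w_right, w_left)
        }
        introns[[iid]] <- IntronFeature(
            iid, gid,
            splice_type = .gffAttr(gr, "splice_type", "cis")[i],
            mechanism = .gffAttr(gr, "mechanism", "branching")[i],
            donor_pos = donor, acceptor_pos = acceptor,
            flanking_exon_lengths = flanks)
    }
    list(genes = genes, introns = introns)
}

.genesFromBed <- function(gr) {
    ids <- if ("name" %in% names(mcols(gr))) as.character(mcols(gr)$name)
           else paste0("feature", seq_along(gr))
    genes <- vector("list", length(gr))
    names(genes) <- ids
    has_blocks <- "blocks" %in% names(mcols(gr))
    for (k in seq_along(gr)) {
        exons <- if (has_blocks && length(mcols(gr)$blocks[[k]])) {
            b <- mcols(gr)$blocks[[k]]  # 1-based, relative to feature start
            IRanges(start = start(gr)[k] + start(b) - 1L,
                    end = start(gr)[k] + end(b) - 1L)
        } else IRanges(start = start(gr)[k], end = end(gr)[k])
        st <- as.character(strand(gr)[k])
        if (!st %in% c("+", "-"))
            stop("BED record '", ids[k], "' lacks a strand")
        genes[[k]] <- GeneFeature(ids[k], strand = st, exons = exons)
    }
    list(genes = genes, introns = list())
}

#' Read a table of known transcription boundaries
#'
#' @param path TSV with columns `gene_id`, `kind`, `position`, `label`.
#'   `kind` is `tss` or `terminus_3p`; `position` is 1-based genomic.
#' @param genome optional \linkS4class{MitoGenome} used for bounds checking.
#' @return data.frame with those four columns.
#' @export
readBoundaries <- function(path, genome = NULL) {
    .checkFileExists(path, "boundary table")
    b <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "kind", "position")
    if (!all(need %in% names(b)))
        stop("boundary table must have columns gene_id, kind, position")
    if (!"label" %in% names(b)) b$label <- ""
    bad <- which(!b$kind %in% c("tss", "terminus_3p"))
    if (length(bad))
        stop("boundary table line ", bad[1L] + 1L,
             ": unknown kind '", b$kind[bad[1L]], "'")
    b$position <- as.integer(b$position)
    if (anyNA(b$position))
        stop("boundary table: non-numeric position (line ",
             which(is.na(b$position))[1L] + 1L, ")")
    if (!is.null(genome)) {
        bad <- which(b$position < 1L | b$position > genomeLength(genome))
        if (length(bad))
            stop("boundary table line ", bad[1L] + 1L,
                 ": position outside the genome")
    }
    b[, c("gene_id", "kind", "position", "label")]
}

#' @rdname readBoundaries
#' @export
emptyBoundaries <- function()
    data.frame(gene_id = character(0), kind = character(0),
               position = integer(0), label = character(0),
               stringsAsFactors = FALSE)

# ---- writing -------------------------------------------------------------

#' Write an annotation back to GFF3
#'
#' Emits the package's GFF3 dialect (see \code{\link{readAnnotation}}),
#' including a `##sequence-region` pragma, so that reading the file back
#' reproduces the annotation field for field.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param genes named list of \linkS4class{GeneFeature}.
#' @param introns named list of \linkS4class{IntronFeature} (optional).
#' @param path output file.
#' @export
writeAnnotation <- function(genome, genes, introns = list(), path) {
    lines <- c("##gff-version 3",
               paste("##sequence-region", genomeName(genome), 1,
                     genomeLength(genome)))
    esc <- function(x) gsub("[;=\t]", "_", x)
    for (g in genes) {
        r <- geneRange(g)
        lines <- c(lines, paste(genomeName(genome), "mitoscape", "gene",
            start(r), end(r), ".", geneStrand(g), ".",
            sprintf("ID=%s;feature_class=%s;coding_unit=%s",
                    esc(geneId(g)), featureClass(g), esc(codingUnitId(g))),
            sep = "\t"))
        ex <- geneExons(g)
        for (k in seq_along(ex))
            lines <- c(lines, paste(genomeName(genome), "mitoscape", "exon",
                start(ex)[k], end(ex)[k], ".", geneStrand(g), ".",
                sprintf("ID=%s.e%d;Parent=%s", esc(geneId(g)), k,
                        esc(geneId(g))), sep = "\t"))
    }
    for (i in introns) {
        if (is.na(i@donorPos) || is.na(i@acceptorPos)) next
        st <- if (i@donorPos < i@acceptorPos) "+" else "-"
        istart <- min(i@donorPos, i@acceptorPos) + 1L
        iend <- max(i@donorPos, i@acceptorPos) - 1L
        lines <- c(lines, paste(genomeName(genome), "mitoscape", "intron",
            istart, iend, ".", st, ".",
            sprintf("ID=%s;Parent=%s;splice_type=%s;mechanism=%s",
                    esc(intronId(i)), esc(i@geneId), spliceType(i),
                    spliceMechanism(i)), sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname readBoundaries
#' @param boundaries data.frame as returned by `readBoundaries`.
#' @export
writeBoundaries <- function(boundaries, path) {
    write.table(boundaries, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write a results table as TSV with fixed numeric precision
#'
#' Fractional numeric columns are rendered with a fixed number of decimals
#' (half-up), the precision splicing-efficiency and ratio tables are
#' conventionally printed at; integer-valued columns are left untouched. An
#' empty record list yields a header-only file.
#'
#' @param records a data.frame (possibly zero-row).
#' @param path output file.
#' @param digits decimals for fractional numeric columns.
#' @export
writeResultsTable <- function(records, path, digits = 2) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    for (j in seq_along(records)) {
        v <- records[[j]]
        if (is.double(v) && nrow(records) &&
            !all(is.na(v) | v == floor(v) | is.infinite(v)))
            records[[j]] <- formatC(roundHalfUp(v, digits), format = "f",
                                    digits = digits)
    }
    con <- file(path, "w")
    on.exit(close(con))
    write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
    .checkFileExists(path, "results table")
    read.delim(path, stringsAsFactors = FALSE)
}
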