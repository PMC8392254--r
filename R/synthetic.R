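# Synthetic-data generator: toy mitochondrial genomes with known ground
# truth for every pipeline stage (no downloads, no external aligner).

#' Specification for a synthetic mitochondrial transcriptional landscape
#'
#' The generated world emulates the structure of a pervasively transcribed
#' plant mitochondrial genome: low background transcription on both
#' strands, elevated plateaus over gene bodies starting with a step at each
#' promoter and ending with a drop at the 3' terminus, co-transcribed units
#' covered by one continuous plateau, and per-base Poisson count noise.
#'
#' @param genome_length genome length in bp.
#' @param n_genes number of genes laid out automatically (ignored when
#'   `gene_table` is given).
#' @param background_depth mean depth of pervasive background transcription
#'   (both strands).
#' @param gene_depth_range range of gene-body plateau depths; drawn
#'   uniformly per gene. The default keeps signal-to-background at 5 or
#'   more, the regime in which slope-based TSS recovery is expected to
#'   work.
#' @param gene_length gene length in bp for the automatic layout.
#' @param gap_min minimum intergenic gap in the automatic layout (kept
#'   above 2 kb so automatically laid-out genes form no candidate pairs).
#' @param promoter_offsets vector of possible TSS offsets upstream of the
#'   gene start; one offset is drawn per promoter.
#' @param n_promoters promoters per gene (first is the strongest).
#' @param terminus_utr bp of 3' UTR between gene end and the terminus drop.
#' @param noise `"poisson"` (default) or `"none"`.
#' @param gene_table optional explicit layout: data.frame with columns
#'   `gene_id`, `strand`, `start`, `end`, `depth`, optional `unit` (shared
#'   values mark co-transcribed units), optional `promoter_offset`.
#' @param motif_length length of the promoter motif planted at each
#'   primary TSS in the genome sequence.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return a list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(genome_length = 60000, n_genes = 8,
                          background_depth = 20,
                          gene_depth_range = c(100, 600),
                          gene_length = 1500, gap_min = 2200,
                          promoter_offsets = 200:1500, n_promoters = 1,
                          terminus_utr = 100,
                          noise = c("poisson", "none"),
                          gene_table = NULL, motif_length = 16,
                          seed = 1) {
    noise <- match.arg(noise)
    stopifnot(genome_length > 0, background_depth >= 0,
              background_depth < min(gene_depth_range))
    structure(list(genome_length = as.integer(genome_length),
                   n_genes = n_genes, background_depth = background_depth,
                   gene_depth_range = gene_depth_range,
                   gene_length = gene_length, gap_min = gap_min,
                   promoter_offsets = promoter_offsets,
                   n_promoters = n_promoters, terminus_utr = terminus_utr,
                   noise = noise, gene_table = gene_table,
                   motif_length = motif_length, seed = seed),
              class = "SyntheticSpec")
}

#' Generate a synthetic annotated genome with stranded coverage
#'
#' Builds the genome sequence (i.i.d. uniform nucleotides with a promoter
#' motif planted at each primary TSS), the gene models, the true-boundary
#' table, the noiseless expected depth and its Poisson-noised realisation,
#' and a ground-truth record. Deterministic for a given spec (seeded).
#'
#' @param spec a `"SyntheticSpec"` from \code{\link{syntheticSpec}}.
#' @return list with `genome` (\linkS4class{MitoGenome}), `genes` (named
#'   list of \linkS4class{GeneFeature}), `boundaries` (true TSS/termini as
#'   a boundaries data.frame), `depth` (\linkS4class{StrandedDepth}),
#'   `expected_depth` (noiseless \linkS4class{StrandedDepth}) and `truth`
#'   (list with per-gene `tss` (ordered strongest first), `terminus`,
#'   `plateau_depth`, per-unit membership, and planted `promoter_seqs`).
#' @export
generateSynthetic <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    set.seed(spec$seed)
    gt <- spec$gene_table
    if (is.null(gt)) {
        starts <- integer(spec$n_genes)
        pos <- 1L
        for (k in seq_len(spec$n_genes)) {
            pos <- pos + spec$gap_min +
                sample(0:500, 1L)  # jitter keeps layouts varied
            starts[k] <- pos
            pos <- pos + spec$gene_length
        }
        need <- pos + spec$gap_min
        if (need > spec$genome_length)
            stop("genome_length too small for ", spec$n_genes, " genes (need ",
                 need, " bp)")
        gt <- data.frame(gene_id = sprintf("g%02d", seq_len(spec$n_genes)),
                         strand = "+", start = starts,
                         end = starts + spec$gene_length - 1L,
                         depth = round(stats::runif(spec$n_genes,
                                                    spec$gene_depth_range[1],
                                                    spec$gene_depth_range[2])),
                         unit = sprintf("g%02d", seq_len(spec$n_genes)),
                         stringsAsFactors = FALSE)
    }
    if (is.null(gt$unit)) gt$unit <- gt$gene_id
    if (is.null(gt$promoter_offset)) gt$promoter_offset <- NA_integer_
    L <- spec$genome_length
    if (max(gt$end) > L) stop("gene_table extends beyond the genome")

    # same-strand overlap is only legitimate inside a declared unit
    for (i in seq_len(nrow(gt))) for (j in seq_len(nrow(gt))) {
        if (j <= i || gt$strand[i] != gt$strand[j]) next
        if (gt$start[j] <= gt$end[i] && gt$end[j] >= gt$start[i] &&
            gt$unit[i] != gt$unit[j])
            stop("genes '", gt$gene_id[i], "' and '", gt$gene_id[j],
                 "' overlap on one strand but are not co-transcribed")
    }

    genes <- list()
    for (k in seq_len(nrow(gt)))
        genes[[gt$gene_id[k]]] <- GeneFeature(gt$gene_id[k], gt$strand[k],
            cbind(gt$start[k], gt$end[k]), coding_unit_id = gt$unit[k])

    exp_plus <- rep(spec$background_depth, L)
    exp_minus <- rep(spec$background_depth, L)
    truth <- list(tss = list(), terminus = list(), plateau_depth = list(),
                  units = split(gt$gene_id, gt$unit),
                  promoter_seqs = character(0))
    bnd <- list()

    for (u in unique(gt$unit)) {
        rows <- gt[gt$unit == u, , drop = FALSE]
        st <- rows$strand[1L]
        unit_depth <- max(rows$depth)
        u_start <- min(rows$start); u_end <- max(rows$end)
        lead_gene <- if (st == "+") rows$gene_id[which.min(rows$start)]
                     else rows$gene_id[which.max(rows$end)]
        offs <- rows$promoter_offset[rows$gene_id == lead_gene]
        n_p <- spec$n_promoters
        offsets <- if (!is.na(offs)) offs
                   else sort(sample(spec$promoter_offsets, n_p))
        # strongest promoter is the most gene-proximal one
        strengths <- unit_depth * rev(seq_len(length(offsets))) /
            sum(seq_len(length(offsets)))
        if (st == "+") {
            tss <- u_start - offsets
            term <- min(L, u_end + spec$terminus_utr)
        } else {
            tss <- u_end + offsets
            term <- max(1L, u_start - spec$terminus_utr)
        }
        bad <- tss < 1L | tss > L
        tss <- tss[!bad]; strengths <- strengths[!bad]
        for (p in seq_along(tss)) {
            span <- if (st == "+") tss[p]:term else term:tss[p]
            if (st == "+") exp_plus[span] <- exp_plus[span] + strengths[p]
            else exp_minus[span] <- exp_minus[span] + strengths[p]
        }
        o <- order(-strengths)
        for (gid in rows$gene_id) {
            truth$tss[[gid]] <- tss[o]
            truth$terminus[[gid]] <- term
            truth$plateau_depth[[gid]] <- unit_depth
        }
        for (p in o)
            bnd[[length(bnd) + 1L]] <- data.frame(
                gene_id = lead_gene, kind = "tss", position = tss[p],
                label = sprintf("p%s-%d", lead_gene, offsets[p]))
        bnd[[length(bnd) + 1L]] <- data.frame(
            gene_id = rows$gene_id[if (st == "+") which.max(rows$end)
                                   else which.min(rows$start)],
            kind = "terminus_3p", position = term, label = "")
    }

    sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
    for (u in unique(gt$unit)) {
        gid <- truth$units[[u]][1L]
        tss1 <- truth$tss[[gid]][1L]
        if (tss1 + spec$motif_length - 1L <= L) {
            motif <- paste(sample(c("A", "C", "G", "T"), spec$motif_length,
                                  replace = TRUE), collapse = "")
            substr(sequence, tss1, tss1 + spec$motif_length - 1L) <- motif
            truth$promoter_seqs[paste0("p", gid)] <- motif
        }
    }

    if (spec$noise == "poisson") {
        plus <- stats::rpois(L, exp_plus)
        minus <- stats::rpois(L, exp_minus)
    } else {
        plus <- exp_plus; minus <- exp_minus
    }
    genome <- MitoGenome("synthmt", length = L, sequence = sequence)
    boundaries <- do.call(rbind, bnd)
    list(genome = genome, genes = genes,
         boundaries = boundaries,
         depth = StrandedDepth(genome, plus, minus),
         expected_depth = StrandedDepth(genome, exp_plus, exp_minus),
         truth = truth)
}

#' Write a generated bundle to disk
#'
#' Emits FASTA, GFF3, the true-boundary TSV and the stranded bedGraph pair
#' for a bundle from \code{\link{generateSynthetic}}. Byte-identical for
#' identical spec and seed.
#'
#' @param sim list from \code{\link{generateSynthetic}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the emitted file paths.
#' @export
writeSyntheticBundle <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "genome.fa"),
               gff = file.path(dir, "annotation.gff3"),
               boundaries = file.path(dir, "boundaries.tsv"),
               bedgraph_plus = file.path(dir, "depth_plus.bedGraph"),
               bedgraph_minus = file.path(dir, "depth_minus.bedGraph"))
    seqs <- Biostrings::DNAStringSet(genomeSequence(sim$genome))
    names(seqs) <- genomeName(sim$genome)
    Biostrings::writeXStringSet(seqs, paths["fasta"], width = 70L)
    writeAnnotation(sim$genome, sim$genes, path = paths["gff"])
    writeBoundaries(sim$boundaries, paths["boundaries"])
    writeBedgraph(sim$depth, paths["bedgraph_plus"], paths["bedgraph_minus"])
    paths
}

#' Write a minimal single-end SAM file
#'
#' Utility for emitting small synthetic alignments (all reads mapped,
#' primary, MAPQ 60) against one reference.
#'
#' @param path output SAM path.
#' @param ref reference name.
#' @param ref_len reference length for the `@SQ` header.
#' @param reads data.frame with columns `qname`, `pos` (1-based leftmost),
#'   optional `flag` (default 0) and `cigar` (default `"<len>M"`).
#' @param read_length read length used for default CIGARs and SEQ fields.
#' @export
writeMinimalSam <- function(path, ref, ref_len, reads, read_length = 89) {
    if (is.null(reads$flag)) reads$flag <- rep(0L, nrow(reads))
    if (is.null(reads$cigar))
        reads$cigar <- rep(paste0(read_length, "M"), nrow(reads))
    seqlen <- vapply(reads$cigar, function(cg) {
        ops <- regmatches(cg, gregexpr("[0-9]+[MIS=X]", cg))[[1L]]
        sum(as.integer(sub("[MIS=X]", "", ops)))
    }, numeric(1))
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", ref, "\tLN:", ref_len))
    if (nrow(reads))
        lines <- c(lines, paste(reads$qname, reads$flag, ref, reads$pos,
                                60L, reads$cigar, "*", 0L, 0L,
                                strrep("A", seqlen), "*", sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Simulate junction reads for one intron at a known splicing fraction
#'
#' Molecule-level model: of `n_molecules` precursor molecules,
#' `K ~ Binomial(n, s)` are spliced and each yields one read crossing the
#' exon-exon junction of the spliced reference; each of the `n - K`
#' unspliced molecules carries both unspliced junctions and yields one read
#' crossing EI5' and one crossing I3'E on the unspliced reference. Read
#' starts are uniform over the `flank`-bp window upstream of each junction,
#' so every read crosses its junction with at least one base on each side.
#' Under this model the splicing-efficiency estimator equals `K / n`:
#' unbiased for `s` with binomial standard error `sqrt(s (1 - s) / n)`.
#'
#' @param intron_id identifier used in read names and reference names.
#' @param s true splicing fraction in `[0, 1]`.
#' @param n_molecules number of precursor molecules.
#' @param dir directory for the two SAM files.
#' @param exon_length,intron_length reference geometry in bp.
#' @param read_length read length in bp.
#' @param flank junction window used for read placement.
#' @return list with `unspliced_sam`, `spliced_sam`, `positions` (junction
#'   coordinates for \code{\link{countJunctionReads}}), `intron` (an
#'   \linkS4class{IntronFeature}) and `truth` (`s`, `n`, `k_spliced`).
#' @export
simulateJunctionReads <- function(intron_id, s, n_molecules, dir = tempdir(),
                                  exon_length = 200, intron_length = 400,
                                  read_length = 89, flank = 30) {
    stopifnot(s >= 0, s <= 1, n_molecules > 0,
              exon_length >= max(flank, read_length - intron_length))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    un_len <- 2L * exon_length + intron_length
    sp_len <- 2L * exon_length
    j_ei5 <- exon_length
    j_i3e <- exon_length + intron_length
    j_ee <- exon_length

    k <- stats::rbinom(1L, n_molecules, s)
    draw <- function(j, n) if (n) sample((j - flank + 1L):j, n, replace = TRUE)
                           else integer(0)
    sp_reads <- data.frame(qname = sprintf("%s_sp_%d", intron_id,
                                           seq_len(k)),
                           pos = draw(j_ee, k))
    n_un <- n_molecules - k
    un_reads <- data.frame(
        qname = c(sprintf("%s_ei5_%d", intron_id, seq_len(n_un)),
                  sprintf("%s_i3e_%d", intron_id, seq_len(n_un))),
        pos = c(draw(j_ei5, n_un), draw(j_i3e, n_un)))

    un_path <- file.path(dir, paste0(intron_id, "_unspliced.sam"))
    sp_path <- file.path(dir, paste0(intron_id, "_spliced.sam"))
    writeMinimalSam(un_path, paste0(intron_id, "_unspliced"), un_len,
                    un_reads, read_length)
    writeMinimalSam(sp_path, paste0(intron_id, "_spliced"), sp_len,
                    sp_reads, read_length)
    intron <- IntronFeature(intron_id, paste0(intron_id, "_gene"),
                            splice_type = "cis", mechanism = "branching",
                            flanking_exon_lengths = c(exon_length,
                                                      exon_length))
    list(unspliced_sam = un_path, spliced_sam = sp_path,
         positions = list(ei5 = j_ei5, i3e = j_i3e, ee = j_ee),
         intron = intron,
         truth = list(s = s, n = n_molecules, k_spliced = k))
}

#' Fixture reproducing the published study geometry
#'
#' Returns (a) the printed junction-count table of the 21 analyzed introns
#' (for direct splicing-efficiency reproduction) and (b) a synthetic genome
#' whose same-strand gene-pair geometry mirrors the published analysis: 11
#' candidate pairs within 2 kb, of which one pair overlaps, two are closer
#' than 150 bp (all three excluded), and the remaining 8 evaluable pairs
#' split into 3 co-transcribed (continuous coverage) and 5 independently
#' transcribed (intergenic drop) pairs.
#'
#' @param seed RNG seed for the Poisson noise on the fixture's coverage.
#' @return list with `junction_counts`, plus the `generateSynthetic` bundle
#'   elements (`genome`, `genes`, `depth`, `truth`, ...); `truth` addition-
#'   ally holds `continuous_pairs`, `drop_pairs` and `excluded_pairs`.
#' @export
paperFixture <- function(seed = 1) {
    glen <- 1800L
    clusters <- list(  # within-cluster gaps; 2500-bp gaps between clusters
        list(ids = c("rps3", "rpl16", "nad9", "nad5e4e5"),
             gaps = c(-20L, 400L, 600L),
             units = c("rps3_rpl16_nad9", "rps3_rpl16_nad9",
                       "rps3_rpl16_nad9", "nad5e4e5")),
        list(ids = c("rps4", "nad2e12"), gaps = 600L,
             units = c("rps4", "nad2e12")),
        list(ids = c("rpl5rps14", "cob"), gaps = 400L,
             units = c("rpl5rps14_cob", "rpl5rps14_cob")),
        list(ids = c("rpl2", "mttb"), gaps = 600L,
             units = c("rpl2", "mttb")),
        list(ids = c("atp8", "nad7"), gaps = 700L,
             units = c("atp8", "nad7")),
        list(ids = c("nad5e3", "nad4L", "atp4"), gaps = c(800L, 300L),
             units = c("nad5e3", "nad4L_atp4", "nad4L_atp4")),
        list(ids = c("nad3", "rps12"), gaps = 100L,
             units = c("nad3_rps12", "nad3_rps12")),
        list(ids = c("nad1e4e5", "nad5e1e2"), gaps = 120L,
             units = c("nad1e4e5", "nad5e1e2")))
    depths <- c(rps3 = 300, rpl16 = 300, nad9 = 300, nad5e4e5 = 150,
                rps4 = 200, nad2e12 = 250, rpl5rps14 = 400, cob = 400,
                rpl2 = 180, mttb = 220, atp8 = 350, nad7 = 260,
                nad5e3 = 140, nad4L = 320, atp4 = 320,
                nad3 = 240, rps12 = 240, nad1e4e5 = 160, nad5e1e2 = 190)
    rows <- list(); pos <- 2500L
    for (cl in clusters) {
        for (k in seq_along(cl$ids)) {
            if (k > 1L) pos <- pos + cl$gaps[k - 1L]
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = cl$ids[k], strand = "+", start = pos,
                end = pos + glen - 1L, depth = depths[[cl$ids[k]]],
                unit = cl$units[k],
                promoter_offset = if (cl$ids[k] %in% c("nad5e1e2", "rps12"))
                    60L else 200L,
                stringsAsFactors = FALSE)
            pos <- pos + glen
        }
        pos <- pos + 2500L
    }
    gt <- do.call(rbind, rows)
    # one antisense gene: never pairs with the plus-strand chain
    gt <- rbind(gt, data.frame(gene_id = "orfX", strand = "-",
                               start = 200L, end = 1400L, depth = 120,
                               unit = "orfX", promoter_offset = 200L,
                               stringsAsFactors = FALSE))
    spec <- syntheticSpec(genome_length = as.integer(pos + 2500L),
                          background_depth = 20, gene_depth_range = c(100, 600),
                          terminus_utr = 100, gene_table = gt, seed = seed)
    sim <- generateSynthetic(spec)
    sim$junction_counts <- paperJunctionCounts()
    sim$truth$continuous_pairs <- list(c("rpl16", "nad9"),
                                       c("rpl5rps14", "cob"),
                                       c("nad4L", "atp4"))
    sim$truth$drop_pairs <- list(c("nad9", "nad5e4e5"),
                                 c("rps4", "nad2e12"),
                                 c("rpl2", "mttb"),
                                 c("atp8", "nad7"),
                                 c("nad5e3", "nad4L"))
    sim$truth$excluded_pairs <- list(c("rps3", "rpl16"),
                                     c("nad3", "rps12"),
                                     c("nad1e4e5", "nad5e1e2"))
    sim
}
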