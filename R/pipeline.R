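# End-to-end orchestration: coverage -> expression -> boundaries ->
# co-transcription -> splicing, with per-stage TSVs and a run report.

#' Validate a pipeline run configuration
#'
#' @param annotation GFF3/BED annotation path.
#' @param bedgraph_plus,bedgraph_minus stranded depth tracks; alternatively
#'   give `sam` (alignments against the genome).
#' @param sam optional genome-level SAM path.
#' @param boundaries optional known-boundary TSV.
#' @param fasta optional genome FASTA (needed for the promoter scan).
#' @param junctions optional data.frame with one row per intron:
#'   `intron_id`, `unspliced_sam`, `spliced_sam`, `ei5`, `i3e`, `ee`,
#'   optional `splice_type`, `mechanism`, `flank_up`, `flank_down`.
#' @param promoter_seqs optional promoter sequences for the exact-match
#'   scan (named character vector).
#' @param out_dir output directory.
#' @param params named list of stage parameters overriding the defaults
#'   (`thresholds`, `window`, `upstream_span`, `tss_window`, `stride`,
#'   `top_n`, `match_radius`, `drop_fraction`, `max_distance`,
#'   `min_separation`, `tau`, `flank`, `seed`).
#' @return validated config (list of class `"RunConfig"`).
#' @export
runConfig <- function(annotation, bedgraph_plus = NULL, bedgraph_minus = NULL,
                      sam = NULL, boundaries = NULL, fasta = NULL,
                      junctions = NULL, promoter_seqs = NULL,
                      out_dir = tempfile("mitoscape_run_"),
                      params = list()) {
    defaults <- list(thresholds = c(1, 2, 5), window = 100,
                     upstream_span = 2000, tss_window = 50, stride = 50,
                     top_n = 3, match_radius = 50, drop_fraction = 0.5,
                     max_distance = 2000, min_separation = 150, tau = 0.5,
                     flank = 30, seed = 1)
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    params <- utils::modifyList(defaults, params)
    for (p in c(annotation, bedgraph_plus, bedgraph_minus, sam, boundaries,
                fasta))
        if (!is.null(p)) .checkFileExists(p)
    if (is.null(sam) && (is.null(bedgraph_plus) || is.null(bedgraph_minus)))
        stop("either 'sam' or both bedGraph tracks are required")
    if (!is.null(junctions))
        for (p in c(junctions$unspliced_sam, junctions$spliced_sam))
            .checkFileExists(p, "junction SAM")
    structure(list(annotation = annotation, bedgraph_plus = bedgraph_plus,
                   bedgraph_minus = bedgraph_minus, sam = sam,
                   boundaries = boundaries, fasta = fasta,
                   junctions = junctions, promoter_seqs = promoter_seqs,
                   out_dir = out_dir, params = params),
              class = "RunConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes coverage, expression, TSS/terminus inference, co-transcription
#' classification and (when junction inputs are configured) splicing
#' efficiency, writing one TSV per stage plus a plain-text report that
#' embeds the resolved parameters and seed. Stage outputs are pure
#' functions of the inputs, parameters and seed.
#'
#' @param config a `"RunConfig"` from \code{\link{runConfig}}.
#' @return (invisibly) a list with the per-stage results and the report
#'   path.
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    p <- config$params
    set.seed(p$seed)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)

    ann <- .stage("annotation", readAnnotation(config$annotation,
        boundary_path = config$boundaries, fasta_path = config$fasta))
    depth <- .stage("depth",
        if (!is.null(config$sam))
            depthFromAlignments(config$sam, ann$genome)
        else depthFromBedgraph(config$bedgraph_plus, config$bedgraph_minus,
                               ann$genome))

    covsum <- .stage("coverage", summarizeCoverage(depth, ann$genes,
        thresholds = p$thresholds, window = p$window))
    writeResultsTable(data.frame(statistic = c("mean_depth_both", "max_depth",
                                               "mean_depth_intergenic",
                                               paste0("frac_ge_",
                                                      names(covsum$frac_ge))),
                                 value = c(covsum$mean_depth_both,
                                           covsum$max_depth,
                                           covsum$mean_depth_intergenic,
                                           unname(covsum$frac_ge))),
                      out("coverage_summary.tsv"), digits = 4)

    expr <- .stage("expression", geneExpressionTable(depth, ann$genes))
    writeResultsTable(expr, out("expression.tsv"))

    tss <- .stage("tss", {
        do.call(rbind, lapply(ann$genes, function(g)
            callTss(slopeProfile(depth, g, upstream_span = p$upstream_span,
                                 window = p$tss_window, stride = p$stride),
                    known = ann$boundaries, genes = ann$genes,
                    top_n = p$top_n, match_radius = p$match_radius)))
    })
    writeResultsTable(tss, out("tss_calls.tsv"))

    term <- .stage("terminus", do.call(rbind, lapply(ann$genes, function(g)
        callTerminus(depth, g, known = ann$boundaries, genes = ann$genes,
                     downstream_span = p$upstream_span,
                     window = p$tss_window,
                     drop_fraction = p$drop_fraction,
                     match_radius = p$match_radius))))
    writeResultsTable(term, out("terminus_calls.tsv"))

    pairs <- .stage("cotranscription", classifyAllPairs(depth, ann$genes,
        max_distance = p$max_distance, min_separation = p$min_separation,
        tau = p$tau))
    writeResultsTable(pairs, out("gene_pairs.tsv"))

    splicing <- NULL
    if (!is.null(config$junctions)) {
        splicing <- .stage("splicing", {
            j <- config$junctions
            counts <- do.call(rbind, lapply(seq_len(nrow(j)), function(k) {
                intr <- IntronFeature(j$intron_id[k], j$intron_id[k],
                    splice_type = if ("splice_type" %in% names(j))
                        j$splice_type[k] else "cis",
                    mechanism = if ("mechanism" %in% names(j))
                        j$mechanism[k] else "branching",
                    flanking_exon_lengths =
                        if (all(c("flank_up", "flank_down") %in% names(j)))
                            c(j$flank_up[k], j$flank_down[k])
                        else c(NA_integer_, NA_integer_))
                cbind(countJunctionReads(j$unspliced_sam[k], j$spliced_sam[k],
                        intr, positions = list(ei5 = j$ei5[k], i3e = j$i3e[k],
                                               ee = j$ee[k]),
                        flank = p$flank),
                      splice_type = spliceType(intr),
                      mechanism = spliceMechanism(intr))
            }))
            splicingTable(counts)
        })
        writeResultsTable(splicing, out("splicing.tsv"))
    }

    scan <- NULL
    if (!is.null(config$promoter_seqs) && nzchar(genomeSequence(ann$genome))) {
        scan <- .stage("promoter_scan",
                       scanPromoterSequences(ann$genome, config$promoter_seqs))
        writeResultsTable(scan, out("promoter_scan.tsv"))
    }

    report <- out("report.txt")
    n_match <- sum(tss$rank == 1 & tss$match_status == "matched")
    lines <- c("mitoscape run report",
               paste0("package_version: ",
                      as.character(utils::packageVersion("mitoscape"))),
               paste0("date: ", format(Sys.time(), "%Y-%m-%d")),
               paste0("seed: ", p$seed),
               "parameters:",
               paste0("  ", names(p), " = ",
                      vapply(p, function(v) paste(v, collapse = ","),
                             character(1))),
               "summary:",
               sprintf("  mean depth (both strands): %.3f",
                       covsum$mean_depth_both),
               sprintf("  intergenic mean depth: %.3f",
                       covsum$mean_depth_intergenic),
               sprintf("  frac_ge: %s",
                       paste(names(covsum$frac_ge), "->",
                             signif(covsum$frac_ge, 4), collapse = "; ")),
               sprintf("  genes: %d; rank-1 TSS matched: %d",
                       length(ann$genes), n_match),
               sprintf("  termini matched: %d",
                       sum(term$match_status == "matched")),
               sprintf("  gene pairs: %d (continuous %d, drop %d, excluded %d)",
                       nrow(pairs),
                       sum(pairs$classification == "continuous"),
                       sum(pairs$classification == "drop"),
                       sum(grepl("^excluded", pairs$classification))),
               if (!is.null(splicing))
                   sprintf("  splicing: %d introns, mean SE %.2f",
                           nrow(splicing), mean(splicing$se)))
    writeLines(lines, report)

    invisible(list(annotation = ann, depth = depth, coverage = covsum,
                   expression = expr, tss = tss, terminus = term,
                   pairs = pairs, splicing = splicing,
                   promoter_scan = scan, report = report,
                   out_dir = config$out_dir))
}
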