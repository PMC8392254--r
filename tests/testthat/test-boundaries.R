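test_that("slope profile reproduces closed forms", {
    genome <- flatGenome(5000)
    gene <- GeneFeature("g", "+", cbind(3001, 4000))

    # constant depth -> all slopes zero
    d <- StrandedDepth(genome, plus = 8, minus = 8)
    pr <- slopeProfile(d, gene)
    expect_equal(nrow(pr$windows), 40L)
    expect_true(all(pr$windows$slope == 0))

    # linear ramp of gradient g over the span -> every window slope == g
    grad <- 0.3
    v <- rep(0, 5000); v[1001:3000] <- grad * seq_len(2000)
    dr <- StrandedDepth(genome, plus = v, minus = 0)
    pr <- slopeProfile(dr, gene)
    expect_equal(pr$windows$slope, rep(grad, 40), tolerance = 1e-12)

    # step of height h centred in a window -> that window has the top slope
    h <- 60
    vs <- rep(5, 5000); vs[2525:4100] <- 5 + h
    ds <- StrandedDepth(genome, plus = vs, minus = 0)
    prs <- slopeProfile(ds, gene)
    top <- prs$windows[which.max(prs$windows$slope), ]
    expect_true(top$start <= 2525 && top$end >= 2525)
    far <- prs$windows[prs$windows$end < 2400, "slope"]
    expect_true(all(abs(far) < 1e-9))

    # linearity: scaling depth by c scales slopes by c
    d3 <- StrandedDepth(genome, plus = 3 * vs, minus = 0)
    expect_equal(slopeProfile(d3, gene)$windows$slope,
                 3 * prs$windows$slope, tolerance = 1e-12)

    expect_error(slopeProfile(d, gene, upstream_span = 40, window = 50),
                 "window")
})

test_that("slopes are strand-aware: positive means rising toward the gene", {
    genome <- flatGenome(5000)
    gneg <- GeneFeature("n", "-", cbind(1001, 2000))
    # depth rises in transcription direction (right to left) past the gene end
    v <- rep(2, 5000); v[1001:2625] <- 80
    d <- StrandedDepth(genome, minus = v, plus = 0)
    pr <- slopeProfile(d, gneg)
    top <- pr$windows[which.max(pr$windows$slope), ]
    expect_true(top$start <= 2625 && top$end >= 2625)
    expect_gt(top$slope, 0)
})

test_that("TSS calls rank windows and label matches against known sites", {
    genome <- flatGenome(6000)
    gene <- GeneFeature("g", "+", cbind(4001, 5000))
    tss_true <- 3120L
    v <- rep(10, 6000); v[tss_true:5100] <- 110
    d <- StrandedDepth(genome, plus = v, minus = 0)
    known <- data.frame(gene_id = "g", kind = "tss", position = tss_true,
                        label = "pg-880")
    calls <- callTss(slopeProfile(d, gene, stride = 25), known)
    expect_equal(calls$match_status[1], "matched")
    expect_lte(abs(calls$midpoint[1] - tss_true), 50)
    expect_equal(calls$matched_position[1], tss_true)

    # two promoters (strong then weak): both among the top-2 calls
    v2 <- rep(10, 6000); v2[2620:5100] <- 40; v2[3620:5100] <- 140
    d2 <- StrandedDepth(genome, plus = v2, minus = 0)
    known2 <- data.frame(gene_id = "g", kind = "tss",
                         position = c(2620L, 3620L), label = c("p1", "p2"))
    calls2 <- callTss(slopeProfile(d2, gene), known2, top_n = 2)
    expect_setequal(calls2$match_status, "matched")
    expect_setequal(calls2$matched_position, c(2620L, 3620L))

    # flat profile with no known sites: zero slopes, unmatched
    flat <- callTss(slopeProfile(StrandedDepth(genome, 4, 4), gene))
    expect_true(all(flat$slope == 0))
    expect_true(all(flat$match_status == "unmatched"))
})

test_that("TSS windows overlapping an upstream gene are labelled as such", {
    genome <- flatGenome(6000)
    gene <- GeneFeature("g", "+", cbind(4001, 5000))
    upstream <- GeneFeature("u", "+", cbind(2500, 3300))
    v <- rep(10, 6000)
    v[2800:5100] <- 110  # step inside the upstream gene's exon
    d <- StrandedDepth(genome, plus = v, minus = 0)
    calls <- callTss(slopeProfile(d, gene, stride = 25),
                     genes = list(g = gene, u = upstream))
    expect_equal(calls$match_status[1], "inside_upstream_gene")
})

test_that("candidate windows 5' of every known TSS are labelled upstream_of_known", {
    genome <- flatGenome(6000)
    gene <- GeneFeature("g", "+", cbind(4001, 5000))
    v <- rep(10, 6000); v[2300:5100] <- 110
    d <- StrandedDepth(genome, plus = v, minus = 0)
    known <- data.frame(gene_id = "g", kind = "tss", position = 3800L,
                        label = "pknown")
    calls <- callTss(slopeProfile(d, gene, stride = 25), known,
                     genes = list(g = gene))
    expect_equal(calls$match_status[1], "upstream_of_known")
})

test_that("terminus detection finds drops, matches and obscured cases", {
    genome <- flatGenome(6000)
    gene <- GeneFeature("g", "+", cbind(1001, 2000))

    # step down to background right after the gene
    v <- rep(3, 6000); v[800:2000] <- 100
    d <- StrandedDepth(genome, plus = v, minus = 0)
    known <- data.frame(gene_id = "g", kind = "terminus_3p",
                        position = 2001L, label = "")
    call <- callTerminus(d, gene, known)
    expect_equal(call$match_status, "matched")
    expect_equal(call$drop_position, 2001L)
    expect_gt(call$depth_before, call$depth_after)

    # programmed terminus 130 bp past the stop: within one window
    v2 <- rep(3, 6000); v2[800:2130] <- 100
    call2 <- callTerminus(StrandedDepth(genome, plus = v2, minus = 0), gene)
    expect_lte(abs(call2$drop_position - 2131), 50)

    # continued elevated depth through a downstream gene -> obscured
    v3 <- rep(3, 6000); v3[800:3500] <- 100
    downstream <- GeneFeature("d", "+", cbind(2200, 3200))
    call3 <- callTerminus(StrandedDepth(genome, plus = v3, minus = 0), gene,
                          genes = list(g = gene, d = downstream))
    expect_equal(call3$match_status, "obscured_by_downstream_gene")
    expect_true(is.na(call3$drop_position))

    # no drop inside the scan -> unmatched, no position
    v4 <- rep(3, 6000); v4[800:4500] <- 100
    call4 <- callTerminus(StrandedDepth(genome, plus = v4, minus = 0), gene)
    expect_equal(call4$match_status, "unmatched")
})

test_that("terminus detection is strand-aware", {
    genome <- flatGenome(6000)
    gene <- GeneFeature("g", "-", cbind(4001, 5000))
    v <- rep(3, 6000); v[3900:5200] <- 100  # 3' UTR extends left to 3900
    d <- StrandedDepth(genome, minus = v, plus = 0)
    call <- callTerminus(d, gene)
    expect_lte(abs(call$drop_position - 3899), 50)
})

test_that("promoter scanning equals the naive sliding-window oracle", {
    set.seed(23)
    seqchars <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
    sequence <- paste(seqchars, collapse = "")
    genome <- MitoGenome("mt", sequence = sequence)

    # query equal to a genomic substring -> plus-strand hit at its start
    q <- substr(sequence, 1001, 1020)
    hits <- scanPromoterSequences(genome, c(p1 = q))
    expect_true(any(hits$strand == "+" & hits$start == 1001))

    # reverse complement of a substring -> minus-strand hit
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(substr(sequence, 2001, 2018),
                                    "")[[1]]), collapse = ""))
    hits_rc <- scanPromoterSequences(genome, c(p2 = rc))
    expect_true(any(hits_rc$strand == "-" & hits_rc$start == 2001))

    # random short queries: exact agreement with the naive oracle
    for (i in 1:5) {
        qlen <- sample(6:9, 1)
        qs <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
                    collapse = "")
        got <- scanPromoterSequences(genome, c(q = qs))
        want <- oracleStringScan(sequence, qs)
        got <- got[order(got$start, got$strand), c("strand", "start")]
        want <- want[order(want$start, want$strand), ]
        expect_equal(got, want, ignore_attr = TRUE)
    }

    expect_error(scanPromoterSequences(genome, c(p = "ACGN")), "ambiguous")
    expect_error(scanPromoterSequences(flatGenome(100), c(p = "ACGT")),
                 "sequence required")
})
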