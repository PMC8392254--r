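test_that("SAM depth counts aligned template-strand bases per position", {
    genome <- flatGenome(400)
    sam <- tempfile(fileext = ".sam")

    # one 89-bp forward single-end read at 1-based position 100
    writeMinimalSam(sam, "mt", 400, data.frame(qname = "r1", pos = 100L))
    d <- depthFromAlignments(sam, genome)
    expect_equal(depthPlus(d)[100:188], rep(1, 89))
    expect_equal(sum(depthPlus(d)), 89)
    expect_equal(sum(depthMinus(d)), 0)

    # empty SAM -> all-zero arrays
    writeMinimalSam(sam, "mt", 400, data.frame(qname = character(0),
                                               pos = integer(0)))
    d0 <- depthFromAlignments(sam, genome)
    expect_equal(sum(depthPlus(d0)) + sum(depthMinus(d0)), 0)

    # two overlapping reads on opposite strands: per-strand 1, pooled 2
    writeMinimalSam(sam, "mt", 400,
                    data.frame(qname = c("f", "r"), pos = c(50L, 100L),
                               flag = c(0L, 16L)))
    d2 <- depthFromAlignments(sam, genome)
    overlap <- 100:138  # brute force: f spans 50..138, r spans 100..188
    expect_equal(depthPlus(d2)[overlap], rep(1, 39))
    expect_equal(depthMinus(d2)[overlap], rep(1, 39))
    expect_equal(depthPlus(d2)[overlap] + depthMinus(d2)[overlap], rep(2, 39))

    # conservation: array total equals aligned bases of retained reads
    expect_equal(sum(depthPlus(d2)) + sum(depthMinus(d2)),
                 attr(d2, "aligned_bases"))
    expect_equal(attr(d2, "aligned_bases"), 2 * 89)
})

test_that("paired-end template strand follows the library chemistry", {
    genome <- flatGenome(400)
    sam <- tempfile(fileext = ".sam")
    # proper pair: read1 on + at 50, read2 on - at 100
    writeMinimalSam(sam, "mt", 400,
        data.frame(qname = c("p", "p"), pos = c(50L, 100L),
                   flag = c(1L + 64L, 1L + 128L + 16L)))
    d <- depthFromAlignments(sam, genome)  # read2-sense: template is minus
    expect_equal(sum(depthPlus(d)), 0)
    expect_equal(sum(depthMinus(d)), 178)
    d1 <- depthFromAlignments(sam, genome, orientation = "read1-sense")
    expect_equal(sum(depthPlus(d1)), 178)
})

test_that("deletions do not add depth and masked positions are zeroed", {
    genome <- flatGenome(400, mask = IRanges::IRanges(60, 70))
    sam <- tempfile(fileext = ".sam")
    writeMinimalSam(sam, "mt", 400,
                    data.frame(qname = "d", pos = 50L, cigar = "10M5D10M"))
    d <- depthFromAlignments(sam, genome, apply_mask = FALSE)
    expect_equal(which(depthPlus(d) == 1), c(50:59, 65:74))
    dm <- depthFromAlignments(sam, genome)
    expect_equal(which(depthPlus(dm) == 1), c(50:59, 71:74))
})

test_that("SAM against the wrong reference is refused", {
    genome <- flatGenome(400)
    sam <- tempfile(fileext = ".sam")
    writeMinimalSam(sam, "other", 400, data.frame(qname = "r", pos = 1L))
    expect_error(depthFromAlignments(sam, genome), "other")
})

test_that("bedGraph depth import obeys the 0-based half-open convention", {
    genome <- flatGenome(50)
    p <- tempfile(); m <- tempfile()
    writeLines("mt\t0\t10\t5", p)   # covers 1-based positions 1..10
    writeLines(character(0), m)
    d <- depthFromBedgraph(p, m, genome)
    expect_equal(depthPlus(d)[1:10], rep(5, 10))
    expect_equal(depthPlus(d)[11], 0)
    expect_equal(sum(depthMinus(d)), 0)

    writeLines(c("mt\t0\t10\t5", "mt\t5\t15\t2"), p)
    expect_error(depthFromBedgraph(p, m, genome), "overlap")
    writeLines("mt\t40\t60\t1", p)
    expect_error(depthFromBedgraph(p, m, genome), "outside")
})

test_that("bedGraph tracks round-trip through write and read", {
    genome <- flatGenome(300)
    set.seed(41)
    d <- randomDepth(genome, max_depth = 4)
    p <- tempfile(); m <- tempfile()
    writeBedgraph(d, p, m)
    back <- depthFromBedgraph(p, m, genome)
    expect_equal(depthPlus(back), depthPlus(d))
    expect_equal(depthMinus(back), depthMinus(d))
})

test_that("coverage summary matches closed forms on flat tracks", {
    genome <- flatGenome(1000)
    d5 <- StrandedDepth(genome, plus = 5, minus = 5)
    s <- summarizeCoverage(d5, thresholds = c(1, 2, 5, 6))
    expect_equal(unname(s$frac_ge), c(1, 1, 1, 0))
    expect_equal(s$mean_depth_both, 5)
    expect_equal(s$max_depth, 5)

    # depth 1 on the plus strand only: half the strand-positions covered
    d1 <- StrandedDepth(genome, plus = 1, minus = 0)
    expect_equal(unname(summarizeCoverage(d1, thresholds = 1)$frac_ge), 0.5)
})

test_that("coverage summary equals the per-position oracle; masks and genes respected", {
    set.seed(7)
    genome <- flatGenome(400, mask = IRanges::IRanges(101, 150))
    d <- randomDepth(genome)
    thresholds <- c(1, 3, 5, 8)
    s <- summarizeCoverage(d, thresholds = thresholds)
    expect_equal(s$frac_ge, oracleFracGe(d, thresholds))

    # intergenic mean excludes exonic positions on the gene's strand
    genes <- list(g = GeneFeature("g", "+", cbind(201, 300)))
    sg <- summarizeCoverage(d, genes, thresholds = 1)
    keep <- !maskedPositions(genome)
    expect_equal(sg$mean_depth_intergenic,
                 mean(c(depthPlus(d)[keep & !(seq_len(400) %in% 201:300)],
                        depthMinus(d)[keep])))
    expect_error(summarizeCoverage(d, thresholds = c(5, 1)), "sorted")
})

test_that("frac_ge is non-increasing in the threshold on random tracks", {
    set.seed(11)
    genome <- flatGenome(200)
    for (i in 1:20) {
        d <- randomDepth(genome, max_depth = sample(2:12, 1))
        s <- summarizeCoverage(d, thresholds = 0:10)
        expect_true(all(diff(s$frac_ge) <= 1e-12))
        expect_true(all(s$frac_ge >= 0 & s$frac_ge <= 1))
    }
})

test_that("low-coverage intervals match a linear-scan oracle", {
    genome <- flatGenome(120)
    zero <- StrandedDepth(genome, 0, 0)
    z <- zeroCoverageIntervals(zero, 0)
    expect_equal(nrow(z), 2L)            # one full-genome run per strand
    expect_equal(unique(z$start), 1L)
    expect_equal(unique(z$end), 120L)

    one <- StrandedDepth(genome, plus = c(rep(0, 59), 1, rep(0, 60)),
                         minus = 1)
    z1 <- zeroCoverageIntervals(one, 0)
    expect_equal(z1[z1$strand == "+", c("start", "end")],
                 data.frame(start = c(1L, 61L), end = c(59L, 120L)),
                 ignore_attr = TRUE)

    set.seed(5)
    for (i in 1:10) {
        d <- randomDepth(genome, max_depth = 2)
        md <- sample(0:1, 1)
        expect_equal(zeroCoverageIntervals(d, md), oracleLowRuns(d, md),
                     ignore_attr = TRUE)
    }
    # masked positions break and are excluded from runs
    gm <- flatGenome(100, mask = IRanges::IRanges(41, 60))
    zm <- zeroCoverageIntervals(StrandedDepth(gm, 0, 0), 0)
    expect_equal(zm[zm$strand == "+", "start"], c(1L, 61L))
    expect_equal(zm[zm$strand == "+", "end"], c(40L, 100L))
})
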