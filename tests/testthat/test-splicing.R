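test_that("splicing efficiency reproduces its closed forms", {
    # published cox2 and rpl2 intron rows
    cox2 <- splicingEfficiency(129, 282, 12433)
    expect_equal(roundHalfUp(cox2$se, 2), 0.98)
    expect_equal(roundHalfUp(cox2$ratio, 2), 2.19)
    rpl2 <- splicingEfficiency(122, 685, 465)
    expect_equal(roundHalfUp(rpl2$se, 2), 0.54)
    expect_equal(roundHalfUp(rpl2$ratio, 2), 5.61)

    # fully spliced limit and symmetric case
    lim <- splicingEfficiency(0, 0, 7)
    expect_equal(lim$se, 1)
    expect_true(is.na(lim$ratio))
    expect_equal(splicingEfficiency(11, 11, 11)$se, 0.5)

    expect_error(splicingEfficiency(0, 0, 0), "zero")
    expect_error(splicingEfficiency(-1, 0, 5), "non-negative")
})

test_that("SE is scale-invariant and monotone in its counts", {
    set.seed(13)
    for (i in 1:20) {
        a <- sample(0:500, 1); b <- sample(0:500, 1); e <- sample(1:5000, 1)
        base <- splicingEfficiency(a, b, e)$se
        expect_equal(splicingEfficiency(3 * a, 3 * b, 3 * e)$se, base)
        expect_gte(splicingEfficiency(a, b, e + 10)$se, base)
        expect_lte(splicingEfficiency(a + 10, b, e)$se, base)
        expect_lte(splicingEfficiency(a, b + 10, e)$se, base)
        expect_true(base >= 0 && base <= 1)
    }
})

test_that("junction-read counting follows the crossing rule", {
    dir <- tempdir()
    intr <- IntronFeature("ti", "tg", "cis", "branching",
                          flanking_exon_lengths = c(200L, 200L))
    pos <- list(ei5 = 200L, i3e = 600L, ee = 200L)
    un <- file.path(dir, "un.sam"); sp <- file.path(dir, "sp.sam")
    # spliced ref: one read spanning EE with 40 bp each side; one read
    # ending exactly at the junction point (must not count)
    writeMinimalSam(sp, "sp", 400,
                    data.frame(qname = c("span", "abut"),
                               pos = c(161L, 112L)), read_length = 89)
    writeMinimalSam(un, "un", 800,
                    data.frame(qname = c("e1", "e2", "i1"),
                               pos = c(150L, 595L, 300L)), read_length = 89)
    cnt <- countJunctionReads(un, sp, intr, positions = pos)
    expect_equal(cnt$n_ee, 1L)        # 'abut' covers ...200 but not 201
    expect_equal(cnt$n_ei5, 1L)       # e1 spans 150..238
    expect_equal(cnt$n_i3e, 1L)       # e2 spans 595..683
})

test_that("junction counts equal the brute-force membership oracle", {
    set.seed(17)
    dir <- tempdir()
    intr <- IntronFeature("tr", "tg", "cis", "branching",
                          flanking_exon_lengths = c(200L, 200L))
    pos <- list(ei5 = 200L, i3e = 600L, ee = 200L)
    rl <- 89L
    un_starts <- sample(1:700, 300, replace = TRUE)
    sp_starts <- sample(1:300, 150, replace = TRUE)
    un_q <- sprintf("u%03d", seq_along(un_starts))
    sp_q <- sprintf("s%03d", seq_along(sp_starts))
    un <- file.path(dir, "un2.sam"); sp <- file.path(dir, "sp2.sam")
    writeMinimalSam(un, "un", 800, data.frame(qname = un_q, pos = un_starts),
                    read_length = rl)
    writeMinimalSam(sp, "sp", 400, data.frame(qname = sp_q, pos = sp_starts),
                    read_length = rl)
    cnt <- countJunctionReads(un, sp, intr, positions = pos)
    expect_equal(cnt$n_ei5, oracleJunctionCount(un_starts, un_q, rl, 200L))
    expect_equal(cnt$n_i3e, oracleJunctionCount(un_starts, un_q, rl, 600L))
    expect_equal(cnt$n_ee, oracleJunctionCount(sp_starts, sp_q, rl, 200L))
})

test_that("introns with too-short flanking exons are refused with a reason", {
    intr <- IntronFeature("nad5i2", "nad5", "trans", "branching",
                          flanking_exon_lengths = c(22L, 200L))
    expect_error(countJunctionReads("x.sam", "y.sam", intr,
                                    positions = list(ei5 = 1, i3e = 2, ee = 1)),
                 "shorter than the 30-bp junction window")
})

test_that("cis junction coordinates map onto the extended references", {
    gene <- GeneFeature("g", "+", cbind(c(1001, 1501), c(1200, 1700)))
    intr <- IntronFeature("gi1", "g", "cis", "branching",
                          donor_pos = 1200L, acceptor_pos = 1501L,
                          flanking_exon_lengths = c(200L, 200L))
    pos <- junctionPositions(gene, intr, extension = 100)
    expect_equal(pos$ei5, 300L)   # 100 ext + 200 exon1
    expect_equal(pos$i3e, 600L)   # last intron base on the unspliced ref
    expect_equal(pos$ee, 300L)    # 100 ext + 200 exon1 on the spliced ref

    gneg <- GeneFeature("n", "-", cbind(c(1001, 1501), c(1200, 1700)))
    ineg <- IntronFeature("ni1", "n", "cis", "branching",
                          donor_pos = 1501L, acceptor_pos = 1200L,
                          flanking_exon_lengths = c(200L, 200L))
    pneg <- junctionPositions(gneg, ineg, extension = 100)
    expect_equal(pneg$ei5, 300L)
    expect_equal(pneg$i3e, 600L)
    expect_equal(pneg$ee, 300L)
})

test_that("one-way ANOVA handles ordinary and degenerate groupings", {
    # identical SE lists in both groups -> F = 0, p = 1
    rec <- data.frame(se = c(0.6, 0.8, 0.9, 0.6, 0.8, 0.9),
                      splice_type = rep(c("cis", "trans"), each = 3))
    r <- compareGroups(rec, "splice_type")
    expect_equal(r$f, 0)
    expect_equal(r$p, 1)

    # complete separation with zero within-group variance
    sep <- data.frame(se = c(0, 0, 0, 1, 1, 1),
                      mechanism = rep(c("branching", "hydrolytic"), each = 3))
    rs <- compareGroups(sep, "mechanism")
    expect_true(is.infinite(rs$f))
    expect_equal(rs$p, 0)

    # random SE values: F equals the sums-of-squares oracle
    set.seed(29)
    rnd <- data.frame(se = runif(18),
                      splice_type = sample(c("cis", "trans"), 18,
                                           replace = TRUE))
    rr <- compareGroups(rnd, "splice_type")
    expect_equal(rr$f, oracleAnovaF(rnd$se, rnd$splice_type),
                 tolerance = 1e-10)
    expect_equal(unname(rr$df), c(1L, 16L))

    expect_error(compareGroups(data.frame(se = 1:3 / 4,
                                          mechanism = c("a", "a", "a")),
                               "mechanism"), "two groups")
})

test_that("the published junction-count table is shaped as expected", {
    tab <- paperJunctionCounts()
    expect_equal(nrow(tab), 21L)
    expect_setequal(unique(tab$splice_type), c("cis", "trans"))
    expect_setequal(unique(tab$mechanism), c("branching", "hydrolytic", "both"))
    expect_true(all(tab$n_ei5 >= 0 & tab$n_i3e >= 0 & tab$n_ee >= 0))
    st <- splicingTable(tab)
    expect_true(all(st$se >= 0 & st$se <= 1))
})
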