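# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (per-position / per-read scans) and stay
# independent of the implementation paths they check.

flatGenome <- function(L = 200, name = "mt", sequence = "", mask = NULL) {
    if (is.null(mask)) mask <- IRanges::IRanges()
    MitoGenome(name, length = L, sequence = sequence, mask = mask)
}

randomDepth <- function(genome, max_depth = 10) {
    L <- genomeLength(genome)
    StrandedDepth(genome,
                  plus = sample(0:max_depth, L, replace = TRUE),
                  minus = sample(0:max_depth, L, replace = TRUE))
}

# per-position tally of strand-positions with depth >= t, over unmasked
# positions, denominator 2 x unmasked length
oracleFracGe <- function(depth, thresholds) {
    keep <- !maskedPositions(depthGenome(depth))
    vals <- c(depthPlus(depth)[keep], depthMinus(depth)[keep])
    out <- vapply(thresholds, function(t) {
        n <- 0L
        for (v in vals) if (v >= t) n <- n + 1L
        n / length(vals)
    }, numeric(1))
    names(out) <- as.character(thresholds)
    out
}

# linear left-to-right scan for maximal runs with depth <= max_depth
oracleLowRuns <- function(depth, max_depth) {
    keep <- !maskedPositions(depthGenome(depth))
    rows <- list()
    for (s in c("+", "-")) {
        v <- strandDepth(depth, s)
        run_start <- NA_integer_
        for (i in seq_along(v)) {
            low <- keep[i] && v[i] <= max_depth
            if (low && is.na(run_start)) run_start <- i
            if (!low && !is.na(run_start)) {
                rows[[length(rows) + 1L]] <-
                    data.frame(strand = s, start = run_start, end = i - 1L)
                run_start <- NA_integer_
            }
        }
        if (!is.na(run_start))
            rows[[length(rows) + 1L]] <-
                data.frame(strand = s, start = run_start, end = length(v))
    }
    if (!length(rows))
        return(data.frame(strand = character(0), start = integer(0),
                          end = integer(0)))
    out <- do.call(rbind, rows)
    out[order(out$strand, out$start), , drop = FALSE]
}

# sliding-window exact string scan on both strands, 1-based starts
oracleStringScan <- function(sequence, query) {
    rc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, "")[[1]]), collapse = ""))
    hits <- list()
    n <- nchar(sequence); m <- nchar(query)
    for (strand in c("+", "-")) {
        q <- if (strand == "+") query else rc(query)
        for (i in seq_len(n - m + 1L))
            if (substr(sequence, i, i + m - 1L) == q)
                hits[[length(hits) + 1L]] <-
                    data.frame(strand = strand, start = i)
    }
    if (!length(hits))
        return(data.frame(strand = character(0), start = integer(0)))
    out <- do.call(rbind, hits)
    out[order(out$start), , drop = FALSE]
}

# textbook two-pass one-way ANOVA F from explicit sums of squares
oracleAnovaF <- function(values, groups) {
    g <- factor(groups)
    grand <- mean(values)
    means <- tapply(values, g, mean)
    ss_b <- sum(table(g) * (means - grand)^2)
    ss_w <- sum((values - means[g])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(values) - nlevels(g)
    (ss_b / df1) / (ss_w / df2)
}

# per-read junction membership: unique read names whose span covers j, j+1
oracleJunctionCount <- function(starts, qnames, read_length, j) {
    supporting <- character(0)
    for (i in seq_along(starts)) {
        if (starts[i] <= j && starts[i] + read_length - 1L >= j + 1L)
            supporting <- union(supporting, qnames[i])
    }
    length(supporting)
}

# a depth track with one elevated plateau per gene over flat background
plateauDepth <- function(genome, genes, background = 5, heights = NULL) {
    L <- genomeLength(genome)
    plus <- rep(background, L); minus <- rep(background, L)
    for (k in seq_along(genes)) {
        g <- genes[[k]]
        h <- if (is.null(heights)) 50 else heights[k]
        r <- geneRange(g)
        idx <- start(r):end(r)
        if (geneStrand(g) == "+") plus[idx] <- plus[idx] + h
        else minus[idx] <- minus[idx] + h
    }
    StrandedDepth(genome, plus, minus)
}
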