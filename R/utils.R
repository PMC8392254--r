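# shared numeric helpers

#' Round half away from zero
#'
#' Fixed-precision table output uses conventional half-up rounding (0.675 ->
#' 0.68) rather than R's round-half-even, matching how splicing-efficiency
#' tables are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# least-squares slope of y against 1..length(y); 0 for constant y
.lsSlope <- function(y) {
    n <- length(y)
    if (n < 2L) return(0)
    x <- seq_len(n)
    xc <- x - mean(x)
    sum(xc * y) / sum(xc * xc)
}

# windows tiling [from, to] with given width/stride, anchored at `anchor_end`
# so the window nearest the anchored end is always full. Returns matrix with
# columns start,end (1-based closed, genomic), ordered from the anchored end
# outward. Windows extending beyond `from` are dropped.
.anchoredWindows <- function(from, to, width, stride, anchor = c("end", "start")) {
    anchor <- match.arg(anchor)
    if (to - from + 1L < width) return(cbind(start = integer(0), end = integer(0)))
    if (anchor == "end") {
        ends <- seq.int(to, from + width - 1L, by = -stride)
        cbind(start = ends - width + 1L, end = ends)
    } else {
        starts <- seq.int(from, to - width + 1L, by = stride)
        cbind(start = starts, end = starts + width - 1L)
    }
}

.checkFileExists <- function(path, what = "file") {
    if (!is.character(path) || length(path) != 1L || !file.exists(path))
        stop(what, " not found: ", path, call. = FALSE)
    invisible(path)
}

# mean that returns NA (not NaN warnings) on empty input
.safeMean <- function(x) if (length(x)) mean(x) else NA_real_
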