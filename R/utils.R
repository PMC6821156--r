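## Internal helpers.

## round-half-up; base round() is banker's rounding, chi-squared tabulation
## wants the deterministic "0.5 goes up" convention
.roundHalfUp <- function(x) floor(x + 0.5)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## sum of depths over 0-based half-open intervals, zero-padded beyond the
## stored Rle length; `ir` is an IRanges in 1-based coordinates
.sumDepth <- function(rle, ir) {
    if (is.null(rle) || length(ir) == 0L) return(0)
    n <- length(rle)
    s <- pmax(IRanges::start(ir), 1L)
    e <- pmin(IRanges::end(ir), n)
    keep <- s <= e
    if (!any(keep)) return(0)
    v <- IRanges::Views(rle, IRanges::IRanges(s[keep], e[keep]))
    sum(as.numeric(IRanges::viewSums(v)))
}

## mean depth over 0-based half-open intervals given as two integer vectors
.meanDepth0 <- function(covList, chrom, start0, end0) {
    w <- sum(end0 - start0)
    if (w <= 0L) return(NA_real_)
    rle <- covList[[chrom]]
    if (is.null(rle)) return(0)
    .sumDepth(rle, IRanges::IRanges(start0 + 1L, end0)) / w
}

## key=value config file (one pair per line, '#' comments); values stay
## character, callers coerce
.readKVConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- vapply(kv, length, 0L) < 2L
    if (any(bad))
        stop("config line without '=': ", lines[which(bad)[1]])
    vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), "")
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
    as.list(vals)
}

## stable hash of a canonicalized config string (md5 via tools, no extra deps)
.configHash <- function(x) {
    txt <- paste(names(x), unlist(lapply(x, paste, collapse = ",")),
                 sep = "=", collapse = ";")
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(txt, tf)
    unname(tools::md5sum(tf))
}

.pkgVersion <- function()
    as.character(utils::packageVersion("spliceQuant"))

## header comment stamped into every output table
.tableHeader <- function(confHash)
    sprintf("# spliceQuant %s; config=%s", .pkgVersion(), confHash)

.writeTSV <- function(df, path, confHash = NULL) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!is.null(confHash)) writeLines(.tableHeader(confHash), con)
    utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.readTSV <- function(path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
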