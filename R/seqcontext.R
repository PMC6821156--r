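#' Acceptor context window geometry
#'
#' The default window covers positions -35..+5 around the 3' splice site:
#' 33 intronic bases (-35..-3), the AG dinucleotide (-2,-1), and 5 exonic
#' bases (+1..+5).  There is no position 0.
#'
#' @param upstream intronic bases before the AG (default 33).
#' @param downstream exonic bases after the splice site (default 5).
#' @return A list with \code{upstream}, \code{downstream}, \code{width}
#'   and the integer \code{positions} labels.
#' @examples
#' contextWindow()$width  # 40
#' @export
contextWindow <- function(upstream = 33, downstream = 5) {
    upstream <- as.integer(upstream); downstream <- as.integer(downstream)
    stopifnot(upstream >= 1L, downstream >= 1L)
    list(upstream = upstream, downstream = downstream,
         width = upstream + 2L + downstream,
         positions = c(seq.int(-(upstream + 2L), -1L),
                       seq_len(downstream)))
}

#' Extract strand-aware acceptor-context windows
#'
#' For each event the window is anchored at its 3' splice site so that
#' positions -2,-1 are the intronic AG immediately preceding the affected
#' exon's strand-aware start; minus-strand windows are
#' reverse-complemented.  Windows running off the contig are skipped with
#' a warning.  Windows without AG at -2,-1 are kept (annotations contain
#' non-canonical acceptors) but counted, and flagged in the result's
#' \code{ag} metadata column.
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param genome a \code{DNAStringSet} (named by chromosome) or path to a
#'   FASTA file.
#' @param window a [contextWindow()].
#' @return A \code{DNAStringSet} of equal-length uppercase windows, named
#'   by event id, with metadata column \code{ag}.
#' @export
extractAcceptorContext <- function(eventSet, genome,
                                   window = contextWindow()) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ev <- events(eventSet)
    up <- window$upstream + 2L; dn <- window$downstream
    seqs <- character(0); ids <- character(0); skipped <- 0L
    for (i in seq_len(nrow(ev))) {
        ch <- as.character(ev$chrom[i])
        if (!ch %in% names(genome)) { skipped <- skipped + 1L; next }
        clen <- Biostrings::width(genome[ch])
        acc <- ev$acceptor_pos[i]
        if (ev$strand[i] == "+") {
            s0 <- acc - up; e0 <- acc + dn
        } else {
            s0 <- acc - dn; e0 <- acc + up
        }
        if (s0 < 0L || e0 > clen) { skipped <- skipped + 1L; next }
        s <- Biostrings::subseq(genome[[ch]], s0 + 1L, e0)
        if (ev$strand[i] == "-")
            s <- Biostrings::reverseComplement(s)
        seqs <- c(seqs, toupper(as.character(s)))
        ids <- c(ids, as.character(ev$event_id[i]))
    }
    if (skipped)
        warning(skipped, " event(s) skipped: window outside contig bounds",
                " or chromosome missing from genome")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    agPos <- window$upstream + c(1L, 2L)
    ag <- if (length(out))
        as.character(Biostrings::subseq(out, agPos[1], agPos[2])) == "AG"
    else logical(0)
    nonAG <- sum(!ag)
    if (nonAG)
        message(nonAG, " of ", length(out),
                " windows lack AG at positions -2,-1")
    S4Vectors::mcols(out)$ag <- ag
    out
}

#' Position-wise nucleotide frequency and certainty matrices
#'
#' Tallies equal-length windows column-wise into A/C/G/T fractions
#' (ambiguous bases are excluded per column), then applies the certainty
#' transform (see [certainty()]) and the standard information content
#' \code{clamp(2 + log2(freq), 0, 2)}.
#'
#' @param seqs a \code{DNAStringSet} or character vector of equal-length
#'   sequences, e.g. from [extractAcceptorContext()].
#' @param window the [contextWindow()] supplying position labels; pass
#'   \code{NULL} to label positions 1..width.
#' @param background background frequency in percent (default 2.4).
#' @return A \linkS4class{ContextMatrix}.
#' @export
frequencyMatrix <- function(seqs, window = contextWindow(),
                            background = 2.4) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    if (length(seqs) == 0L) stop("no sequences to tally")
    if (length(unique(Biostrings::width(seqs))) != 1L)
        stop("sequences must all have the same length")
    w <- Biostrings::width(seqs)[1]
    cm <- Biostrings::consensusMatrix(seqs)[, seq_len(w), drop = FALSE]
    bases <- c("A", "C", "G", "T")
    cnt <- matrix(0, 4, w, dimnames = list(bases, NULL))
    for (b in bases)
        if (b %in% rownames(cm)) cnt[b, ] <- cm[b, ]
    tot <- colSums(cnt)
    freq <- sweep(cnt, 2, pmax(tot, 1), "/")
    positions <- if (is.null(window)) seq_len(w) else window$positions
    if (length(positions) != w)
        stop("window does not match sequence length ", w)
    colnames(freq) <- as.character(positions)
    cert <- matrix(certainty(freq, background), 4, w,
                   dimnames = dimnames(freq))
    bits <- .clamp(2 + log2(freq), 0, 2)
    bits[freq == 0] <- 0
    nNonAG <- if (!is.null(window) &&
                  !is.null(S4Vectors::mcols(seqs)$ag))
        sum(!S4Vectors::mcols(seqs)$ag) else 0L
    new("ContextMatrix", freq = freq, certainty = cert, bits = bits,
        positions = as.integer(positions),
        nSequences = length(seqs), nNonAG = as.integer(nNonAG),
        background = background)
}

#' Certainty transform of a nucleotide frequency
#'
#' \code{certainty = clamp(log10(100 * freq / background), 0, 1.5)}: the
#' frequency is expressed in percent, divided by a 2.4 percent background
#' floor, log10-transformed and clamped to [0, 1.5].  A frequency of
#' 2.4 percent maps to 0, 24 percent to 1, and 100 percent clamps at 1.5.
#' Monotone non-decreasing in \code{freq}.
#'
#' @param freq frequency (fraction in [0, 1]); vectorized.
#' @param background background frequency in percent (default 2.4).
#' @return Certainty in bits, in [0, 1.5].
#' @examples
#' certainty(c(0.024, 0.24, 1))  # 0, 1, 1.5
#' @export
certainty <- function(freq, background = 2.4) {
    if (any(!is.na(freq) & (freq < 0 | freq > 1)))
        stop("freq must lie in [0, 1]")
    out <- suppressWarnings(log10(100 * freq / background))
    out[!is.finite(out)] <- 0
    .clamp(out, 0, 1.5)
}

#' Per-position pyrimidine (C+T) profile
#'
#' @param cm a \linkS4class{ContextMatrix}.
#' @param tractRange positions summarized as the polypyrimidine-tract
#'   mean (default -20..-3).
#' @return Numeric vector of C+T fractions named by position, with the
#'   tract mean in attribute \code{"tract_mean"}.
#' @export
pyrimidineProfile <- function(cm, tractRange = c(-20L, -3L)) {
    fr <- freqMatrix(cm)
    prof <- fr["C", ] + fr["T", ]
    pos <- contextPositions(cm)
    names(prof) <- as.character(pos)
    sel <- pos >= tractRange[1] & pos <= tractRange[2]
    attr(prof, "tract_mean") <- if (any(sel)) mean(prof[sel]) else NA_real_
    prof
}

#' Write a context matrix as TSV
#'
#' Rows A/C/G/T of the frequency matrix, then of the certainty matrix,
#' long format: \code{metric}, \code{base}, one column per position.
#'
#' @param cm a \linkS4class{ContextMatrix}.
#' @param path output path.
#' @param confHash optional config hash for the header comment.
#' @export
writeContextTSV <- function(cm, path, confHash = NULL) {
    f <- as.data.frame(freqMatrix(cm)); c2 <- as.data.frame(certaintyMatrix(cm))
    b <- as.data.frame(bitsMatrix(cm))
    df <- cbind(metric = rep(c("freq", "certainty", "bits"), each = 4),
                base = rep(rownames(freqMatrix(cm)), 3),
                rbind(f, c2, b))
    colnames(df)[-(1:2)] <- as.character(contextPositions(cm))
    .writeTSV(df, path, confHash)
}
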