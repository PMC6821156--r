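#' Per-base coverage from a sorted, indexed BAM file
#'
#' Depth counts every aligned base (CIGAR M/=/X) of every read that is
#' mapped, primary and not duplicate-flagged; N gaps of split reads and
#' deletions contribute no depth.
#'
#' @param path path to a coordinate-sorted BAM with a .bai index.
#' @param label condition label stored on the track.
#' @return A \linkS4class{CoverageTrack}.
#' @export
coverageFromBam <- function(path, label = basename(path)) {
    if (!file.exists(path)) stop("BAM file not found: ", path)
    idx <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
    if (!any(file.exists(idx)))
        stop("no index found for ", path,
             "; index it first (e.g. samtools index, or Rsamtools::indexBam)")
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE)
    aln <- GenomicAlignments::readGAlignments(
        path, param = Rsamtools::ScanBamParam(flag = flags))
    cov <- GenomicAlignments::coverage(aln, drop.D.ranges = TRUE)
    new("CoverageTrack", cov = cov, label = label)
}

#' Per-base coverage from a bedGraph file
#'
#' Intervals must be 0-based half-open and non-overlapping per
#' chromosome; depth is reconstructed exactly.
#'
#' @param path path to a bedGraph file.
#' @param label condition label stored on the track.
#' @return A \linkS4class{CoverageTrack}.  An empty file yields an empty
#'   track.
#' @export
coverageFromBedgraph <- function(path, label = basename(path)) {
    if (!file.exists(path)) stop("bedGraph file not found: ", path)
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L)
        return(new("CoverageTrack", cov = RleList(compress = FALSE),
                   label = label))
    if (length(gr)) {
        hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                            drop.redundant = TRUE)
        if (length(hits))
            stop("overlapping bedGraph intervals in ", path,
                 ": first offending interval is record ",
                 min(S4Vectors::queryHits(hits)))
    }
    cov <- GenomicRanges::coverage(gr, weight = gr$score)
    new("CoverageTrack", cov = cov, label = label)
}

#' Build a coverage track from in-memory depth vectors
#'
#' @param depths named list (by chromosome) of non-negative integer
#'   vectors, one entry per base starting at genomic 0-based position 0.
#' @param label condition label.
#' @return A \linkS4class{CoverageTrack}.
#' @examples
#' coverageTrack(list(chr1 = c(0, 0, 5, 5, 5)), "A")
#' @export
coverageTrack <- function(depths, label = "track") {
    cov <- RleList(lapply(depths, S4Vectors::Rle), compress = FALSE)
    new("CoverageTrack", cov = cov, label = label)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted; [coverageFromBedgraph()] reconstructs the
#' identical track (positions never written read back as depth 0).
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedgraph <- function(track, path) {
    cov <- coverageRle(track)
    grs <- lapply(names(cov), function(ch) {
        r <- cov[[ch]]
        len <- S4Vectors::runLength(r); val <- S4Vectors::runValue(r)
        e <- cumsum(len); s <- e - len + 1L
        keep <- val != 0
        GRanges(ch, IRanges(s[keep], e[keep]), score = val[keep])
    })
    gr <- if (length(grs)) suppressWarnings(do.call(c, grs)) else
        GRanges(score = numeric())
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Mean depth over a genomic interval
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Mean per-base depth (bases beyond the track count as 0).
#' @export
meanDepth <- function(track, chrom, start, end)
    .meanDepth0(coverageRle(track), chrom, as.integer(start),
                as.integer(end))
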