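#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges RleList
#' @importFrom GenomicRanges GRanges GRangesList
NULL

## Internal coordinate convention: all event/exon coordinates stored in
## DataFrame columns are 0-based half-open [start, end).  Bioconductor
## containers (GRanges, RleList views) are converted at the boundary.

#' Gene models: transcripts, exons and CDS bounds
#'
#' Container for the transcript structures of one annotation: an exon
#' \linkS4class{GRangesList} (one element per transcript, exons sorted by
#' genomic start) plus a per-transcript table with gene assignment and the
#' genomic CDS bounds (0-based half-open, \code{NA} for non-coding
#' transcripts).
#'
#' @slot exons \code{GRangesList} of exons, named by transcript id.
#' @slot txInfo \code{DataFrame} with columns \code{tx_id}, \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{cds_start}, \code{cds_end}.
#'
#' @seealso [readGeneModels()], [enumerateASEvents()]
#' @export
setClass("TranscriptModels",
         representation(exons = "GRangesList", txInfo = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    info <- object@txInfo
    need <- c("tx_id", "gene_id", "chrom", "strand", "cds_start", "cds_end")
    if (!all(need %in% colnames(info)))
        return(paste("txInfo must have columns:", paste(need, collapse = ", ")))
    if (!identical(as.character(names(object@exons)),
                   as.character(info$tx_id)))
        return("names(exons) must equal txInfo$tx_id (same order)")
    if (any(!as.character(info$strand) %in% c("+", "-")))
        return("strand must be '+' or '-'")
    nEx <- lengths(object@exons)
    if (any(nEx == 0L))
        return(sprintf("transcript '%s' has no exons",
                       info$tx_id[which(nEx == 0L)[1]]))
    ## vectorized per-transcript structure checks (no per-element [[)
    ue <- unlist(object@exons, use.names = FALSE)
    grp <- rep.int(seq_along(nEx), nEx)
    s <- GenomicRanges::start(ue); e <- GenomicRanges::end(ue)
    n <- length(s)
    if (n > 1L) {
        sameTx <- grp[-1] == grp[-n]
        bad <- sameTx & s[-1] <= e[-n]
        if (any(bad))
            return(sprintf(
                "exons of transcript '%s' must be non-overlapping and strictly increasing",
                info$tx_id[grp[which(bad)[1] + 1L]]))
    }
    cs <- info$cds_start; ce <- info$cds_end
    coding <- !is.na(cs)
    if (any(coding)) {
        if (any(is.na(ce[coding]) | cs[coding] >= ce[coding]))
            return(sprintf("bad CDS bounds for '%s'",
                           info$tx_id[which(coding &
                               (is.na(ce) | cs >= ce))[1]]))
        gf <- factor(grp, levels = seq_along(nEx))
        txMin <- vapply(split(s, gf), min, 0L)
        txMax <- vapply(split(e, gf), max, 0L)
        out <- coding & (cs < txMin - 1L | ce > txMax)
        if (any(out))
            return(sprintf("CDS bounds of '%s' outside exonic span",
                           info$tx_id[which(out)[1]]))
    }
    TRUE
})

#' Catalogue of alternative-splicing events
#'
#' One row per deduplicated event.  Column semantics (coordinates 0-based
#' half-open): \code{a1_start}/\code{a1_end} the affected exon (for MXE the
#' genomically first of the pair, with the partner in \code{a2_*});
#' \code{fu_start}/\code{fu_end} and \code{fd_start}/\code{fd_end} the
#' genomically upstream and downstream flanking exons; \code{fu_end} and
#' \code{fd_start} are the shared splice-junction coordinates that define
#' the event; \code{acceptor_pos} the strand-aware genomic coordinate of
#' the affected exon's 3' splice site (the first exonic base on the plus
#' strand, the past-the-end coordinate on the minus strand, so that the AG
#' dinucleotide occupies the two intronic bases immediately 5' of it in
#' transcript orientation).
#'
#' @slot events \code{DataFrame}, one row per event.
#' @export
setClass("ASEventSet", representation(events = "DataFrame"))

.EVENT_COLS <- c("event_id", "etype", "gene_id", "chrom", "strand",
                 "a1_start", "a1_end", "a2_start", "a2_end",
                 "fu_start", "fu_end", "fd_start", "fd_end",
                 "host_inc", "host_exc", "acceptor_pos")

setValidity("ASEventSet", function(object) {
    ev <- object@events
    if (!all(.EVENT_COLS %in% colnames(ev)))
        return(paste("events must have columns:",
                     paste(.EVENT_COLS, collapse = ", ")))
    if (anyDuplicated(ev$event_id))
        return("event_id values must be unique")
    if (any(!ev$etype %in% c("SE", "MXE", "A5SS", "A3SS")))
        return("etype must be one of SE, MXE, A5SS, A3SS")
    if (nrow(ev)) {
        if (any(ev$a1_start >= ev$a1_end))
            return("affected intervals must have start < end")
        if (any(ev$a1_start < ev$fu_end | ev$a1_end > ev$fd_start))
            return("affected interval must lie between the flank junctions")
        mxe <- ev$etype == "MXE"
        if (any(mxe & (is.na(ev$a2_start) | is.na(ev$a2_end))))
            return("MXE events need a second affected interval")
        if (any(mxe & !is.na(ev$a2_start) & ev$a2_start < ev$a1_end))
            return("MXE affected pair must be ordered and non-overlapping")
    }
    TRUE
})

#' Per-base read coverage of one library
#'
#' Wraps an integer \code{RleList} (one run-length vector per chromosome;
#' Rle position i is genomic 0-based position i-1) with a condition label.
#' Positions beyond the stored length are read as depth 0.
#'
#' @slot cov \code{RleList} of per-base depths.
#' @slot label condition name, e.g. \code{"A"}.
#' @export
setClass("CoverageTrack",
         representation(cov = "RleList", label = "character"))

setValidity("CoverageTrack", function(object) {
    if (length(object@label) != 1L) return("label must be a single string")
    if (length(object@cov) && any(vapply(object@cov, function(r)
        min(S4Vectors::runValue(r), 0) < 0, logical(1))))
        return("coverage depths must be >= 0")
    TRUE
})

#' Significance thresholds for the two-condition comparison
#'
#' Defaults follow the filtering rule used throughout the package: a
#' candidate event is significant when its chi-squared P-value is at most
#' \code{pMax} (0.1) and the absolute difference of inclusion ratios
#' exceeds \code{dratioMin} (0.1).
#'
#' @slot pMax P-value ceiling, in (0, 1].
#' @slot dratioMin minimum absolute inclusion-ratio difference, in [0, 1).
#' @export
setClass("ComparisonThresholds",
         representation(pMax = "numeric", dratioMin = "numeric"))

setValidity("ComparisonThresholds", function(object) {
    if (!(length(object@pMax) == 1L && object@pMax > 0 && object@pMax <= 1))
        return("pMax must be a single value in (0, 1]")
    if (!(length(object@dratioMin) == 1L &&
          object@dratioMin >= 0 && object@dratioMin < 1))
        return("dratioMin must be a single value in [0, 1)")
    TRUE
})

#' @rdname ComparisonThresholds-class
#' @param pMax P-value ceiling.
#' @param dratioMin minimum absolute inclusion-ratio difference.
#' @return A \code{ComparisonThresholds} object.
#' @examples
#' comparisonThresholds()
#' @export
comparisonThresholds <- function(pMax = 0.1, dratioMin = 0.1)
    new("ComparisonThresholds", pMax = pMax, dratioMin = dratioMin)

#' Acceptor-context frequency/certainty matrices
#'
#' Column-wise nucleotide composition of equal-length windows anchored at
#' 3' splice sites.  \code{freq} holds per-position fractions of A/C/G/T
#' (ambiguous bases excluded from the denominator), \code{certainty} the
#' transform \code{clamp(log10(100 * freq / background), 0, 1.5)} with
#' background 2.4 (percent), and \code{bits} the standard information
#' content \code{clamp(2 + log2(freq), 0, 2)}.
#'
#' @slot freq,certainty,bits 4 x width numeric matrices (rows A,C,G,T).
#' @slot positions integer position labels (-35..-1, +1..+5 by default;
#'   there is no position 0, the AG sits at -2,-1).
#' @slot nSequences number of windows tallied.
#' @slot nNonAG windows whose -2,-1 dinucleotide was not AG.
#' @slot background background frequency in percent (2.4).
#' @export
setClass("ContextMatrix",
         representation(freq = "matrix", certainty = "matrix",
                        bits = "matrix", positions = "integer",
                        nSequences = "integer", nNonAG = "integer",
                        background = "numeric"))

setValidity("ContextMatrix", function(object) {
    if (!identical(rownames(object@freq), c("A", "C", "G", "T")))
        return("freq rows must be A, C, G, T")
    if (ncol(object@freq) != length(object@positions))
        return("positions must label the freq columns")
    cs <- colSums(object@freq)
    if (any(abs(cs[cs > 0] - 1) > 1e-9))
        return("freq columns must each sum to 1")
    if (any(object@certainty < 0 | object@certainty > 1.5))
        return("certainty values must lie in [0, 1.5]")
    TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator.  See [simConfig()] for
#' field semantics and defaults, and the package vignette for the
#' rationale behind the default study conditions.
#'
#' @export
setClass("SimConfig",
         representation(seed = "numeric", nGenes = "integer",
                        exonLen = "integer", intronLen = "integer",
                        extLen = "integer", depth = "numeric",
                        psiA = "numeric", psiB = "numeric",
                        noise = "numeric", plantMotif = "ANY",
                        utr = "list", bam = "logical"))

setValidity("SimConfig", function(object) {
    if (object@depth <= 0) return("depth must be > 0")
    if (any(object@psiA < 0 | object@psiA > 1) ||
        any(object@psiB < 0 | object@psiB > 1))
        return("psi values must lie in [0, 1]")
    if (!identical(sort(names(object@nGenes)),
                   sort(c("SE", "MXE", "A5SS", "A3SS"))))
        return("nGenes must be named SE, MXE, A5SS, A3SS")
    if (object@noise < 0) return("noise must be >= 0")
    TRUE
})
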