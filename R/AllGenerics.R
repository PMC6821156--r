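#' @include AllClasses.R
NULL

#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @export
setGeneric("txInfo", function(x) standardGeneric("txInfo"))
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))
#' @export
setGeneric("eventTypes", function(x) standardGeneric("eventTypes"))
#' @export
setGeneric("eventRanges", function(x) standardGeneric("eventRanges"))
#' @export
setGeneric("coverageRle", function(x) standardGeneric("coverageRle"))
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))
#' @export
setGeneric("certaintyMatrix", function(x) standardGeneric("certaintyMatrix"))
#' @export
setGeneric("bitsMatrix", function(x) standardGeneric("bitsMatrix"))
#' @export
setGeneric("contextPositions", function(x) standardGeneric("contextPositions"))

## ---- TranscriptModels ----

#' @describeIn TranscriptModels-class exon GRangesList, named by transcript.
#' @param x a \code{TranscriptModels} object.
#' @export
setMethod("txExons", "TranscriptModels", function(x) x@exons)

#' @describeIn TranscriptModels-class per-transcript DataFrame.
#' @export
setMethod("txInfo", "TranscriptModels", function(x) x@txInfo)

#' @describeIn TranscriptModels-class unique gene identifiers.
#' @export
setMethod("geneIds", "TranscriptModels",
          function(x) unique(as.character(x@txInfo$gene_id)))

#' @describeIn TranscriptModels-class transcript identifiers.
#' @export
setMethod("txIds", "TranscriptModels",
          function(x) as.character(x@txInfo$tx_id))

setMethod("length", "TranscriptModels", function(x) length(x@exons))

setMethod("show", "TranscriptModels", function(object) {
    info <- object@txInfo
    cat(sprintf("TranscriptModels: %d transcripts in %d genes (%d coding)\n",
                nrow(info), length(unique(info$gene_id)),
                sum(!is.na(info$cds_start))))
    cat("  chromosomes:",
        paste(unique(as.character(info$chrom)), collapse = ", "), "\n")
})

## ---- ASEventSet ----

#' @describeIn ASEventSet-class the event DataFrame.
#' @param x an \code{ASEventSet}.
#' @export
setMethod("events", "ASEventSet", function(x) x@events)

#' @describeIn ASEventSet-class event identifiers.
#' @export
setMethod("eventIds", "ASEventSet",
          function(x) as.character(x@events$event_id))

#' @describeIn ASEventSet-class event types (SE/MXE/A5SS/A3SS).
#' @export
setMethod("eventTypes", "ASEventSet",
          function(x) as.character(x@events$etype))

#' @describeIn ASEventSet-class affected intervals as a (1-based) GRanges;
#'   MXE contributes two ranges sharing one event_id.
#' @export
setMethod("eventRanges", "ASEventSet", function(x) {
    ev <- x@events
    if (!nrow(ev)) return(GRanges())
    mxe <- !is.na(ev$a2_start)
    gr1 <- GRanges(ev$chrom, IRanges(ev$a1_start + 1L, ev$a1_end),
                   strand = ev$strand, event_id = ev$event_id,
                   etype = ev$etype)
    if (!any(mxe)) return(gr1)
    gr2 <- GRanges(ev$chrom[mxe],
                   IRanges(ev$a2_start[mxe] + 1L, ev$a2_end[mxe]),
                   strand = ev$strand[mxe], event_id = ev$event_id[mxe],
                   etype = ev$etype[mxe])
    sort(c(gr1, gr2))
})

setMethod("length", "ASEventSet", function(x) nrow(x@events))

setMethod("[", "ASEventSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@events$event_id)
    new("ASEventSet", events = x@events[i, , drop = FALSE])
})

setMethod("show", "ASEventSet", function(object) {
    ev <- object@events
    cat(sprintf("ASEventSet with %d events\n", nrow(ev)))
    if (nrow(ev)) {
        tab <- table(factor(ev$etype, c("SE", "MXE", "A5SS", "A3SS")))
        cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "),
            "\n", sep = "")
        cat(sprintf("  %d genes\n", length(unique(ev$gene_id))))
    }
})

#' Coerce an ASEventSet to a base data.frame
#'
#' @param x an \code{ASEventSet}.
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.ASEventSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...)
    as.data.frame(x@events)

## ---- CoverageTrack ----

#' @describeIn CoverageTrack-class the underlying RleList.
#' @param x a \code{CoverageTrack}.
#' @export
setMethod("coverageRle", "CoverageTrack", function(x) x@cov)

#' @describeIn CoverageTrack-class condition label.
#' @export
setMethod("trackLabel", "CoverageTrack", function(x) x@label)

setMethod("show", "CoverageTrack", function(object) {
    tot <- sum(vapply(object@cov, function(r) sum(as.numeric(r)), 0))
    cat(sprintf("CoverageTrack '%s': %d chromosome(s), %.3g covered bases\n",
                object@label, length(object@cov),
                sum(vapply(object@cov,
                           function(r) sum(as.numeric(r > 0)), 0))))
    cat(sprintf("  total depth mass: %.4g\n", tot))
})

## ---- ContextMatrix ----

#' @describeIn ContextMatrix-class per-position nucleotide fractions.
#' @param x a \code{ContextMatrix}.
#' @export
setMethod("freqMatrix", "ContextMatrix", function(x) x@freq)

#' @describeIn ContextMatrix-class certainty (bit) matrix.
#' @export
setMethod("certaintyMatrix", "ContextMatrix", function(x) x@certainty)

#' @describeIn ContextMatrix-class information-content matrix.
#' @export
setMethod("bitsMatrix", "ContextMatrix", function(x) x@bits)

#' @describeIn ContextMatrix-class integer position labels.
#' @export
setMethod("contextPositions", "ContextMatrix", function(x) x@positions)

setMethod("show", "ContextMatrix", function(object) {
    cat(sprintf(
        "ContextMatrix: %d positions (%+d..%+d), %d sequences (%d non-AG)\n",
        length(object@positions), min(object@positions),
        max(object@positions), object@nSequences, object@nNonAG))
})

setMethod("show", "ComparisonThresholds", function(object)
    cat(sprintf("ComparisonThresholds: P <= %g and |dratio| > %g\n",
                object@pMax, object@dratioMin)))

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  seed %d, depth %g, noise %g\n",
                as.integer(object@seed), object@depth, object@noise))
    cat(sprintf("  genes per event type: %s\n",
                paste(sprintf("%s=%d", names(object@nGenes), object@nGenes),
                      collapse = " ")))
    cat(sprintf("  psi A/B: %s / %s\n",
                paste(object@psiA, collapse = ","),
                paste(object@psiB, collapse = ",")))
    cat(sprintf("  5'UTR genes %d, 3'UTR genes %d, background genes %d\n",
                object@utr$nUTR5, object@utr$nUTR3, object@utr$nBackground))
})
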