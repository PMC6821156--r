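#' Quantify events from a coverage track
#'
#' For each event, \code{n} is the mean per-base depth of the affected
#' exon (for MXE, of the genomically first exon of the pair) and \code{N}
#' the mean depth over the exon union of the inclusion-form host
#' transcript minus all affected intervals (for MXE both tandem exons are
#' excluded, keeping \code{n} and \code{N} disjoint).  The inclusion
#' ratio is \code{n / (n + N)} (or \code{n / N} with
#' \code{ratioDef = "n_over_N"}); it is recorded as \code{NA} when the
#' denominator is zero.
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param models the \linkS4class{TranscriptModels} the events came from.
#' @param track a \linkS4class{CoverageTrack}.
#' @param ratioDef \code{"inclusion"} for the bounded ratio
#'   \code{n/(n+N)} (default) or \code{"n_over_N"}.
#' @return A \code{DataFrame} with one row per event: \code{event_id},
#'   \code{n}, \code{N}, \code{ratio}, \code{affected_len},
#'   \code{rest_len}.  Events whose host transcript has no exons left
#'   outside the affected interval(s) are skipped with a warning
#'   (\code{NA} row).
#' @export
quantifyEvents <- function(eventSet, models, track,
                           ratioDef = c("inclusion", "n_over_N")) {
    ratioDef <- match.arg(ratioDef)
    ev <- events(eventSet)
    info <- txInfo(models)
    cov <- coverageRle(track)

    miss <- setdiff(unique(as.character(ev$chrom)), names(cov))
    if (length(miss) && nrow(ev))
        warning("chromosomes absent from coverage track '",
                trackLabel(track), "': ", paste(miss, collapse = ", "))

    n <- N <- ratio <- rep(NA_real_, nrow(ev))
    alen <- rlen <- rep(NA_integer_, nrow(ev))
    skipped <- character()
    allMats <- if (nrow(ev)) .allExonMatrices(models) else list()
    for (i in seq_len(nrow(ev))) {
        m <- match(ev$host_inc[i], info$tx_id)
        if (is.na(m))
            stop("host transcript of event '", ev$event_id[i],
                 "' not found in models")
        exm <- allMats[[as.character(ev$host_inc[i])]]
        exIR <- IRanges::reduce(IRanges(exm[, 1] + 1L, exm[, 2]))
        aff <- IRanges(ev$a1_start[i] + 1L, ev$a1_end[i])
        excl <- aff
        if (!is.na(ev$a2_start[i]))
            excl <- c(excl, IRanges(ev$a2_start[i] + 1L, ev$a2_end[i]))
        rest <- IRanges::setdiff(exIR, excl)
        if (sum(IRanges::width(rest)) == 0L) {
            skipped <- c(skipped, as.character(ev$event_id[i]))
            next
        }
        ch <- as.character(ev$chrom[i])
        alen[i] <- sum(IRanges::width(aff))
        rlen[i] <- sum(IRanges::width(rest))
        rle <- cov[[ch]]
        n[i] <- if (is.null(rle)) 0 else .sumDepth(rle, aff) / alen[i]
        N[i] <- if (is.null(rle)) 0 else .sumDepth(rle, rest) / rlen[i]
        ratio[i] <- switch(ratioDef,
            inclusion = if (n[i] + N[i] > 0) n[i] / (n[i] + N[i])
                        else NA_real_,
            n_over_N = if (N[i] > 0) n[i] / N[i] else NA_real_)
    }
    if (length(skipped))
        warning("skipped events with empty rest-exon set: ",
                paste(skipped, collapse = ", "))
    DataFrame(event_id = ev$event_id, n = n, N = N, ratio = ratio,
              affected_len = alen, rest_len = rlen)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Canonical (no continuity correction) Pearson test with one degree of
#' freedom.  A table with any zero row or column margin carries no
#' evidence and returns statistic 0, P-value 1.
#'
#' @param a,b,c,d non-negative cell counts, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return Named list with \code{chi2} and \code{pvalue}.
#' @examples
#' chiSquare2x2(10, 90, 30, 70)  # chi2 = 12.5
#' @export
chiSquare2x2 <- function(a, b, c, d) {
    x <- c(a, b, c, d)
    if (any(is.na(x)) || any(x < 0))
        stop("cell counts must be non-negative numbers")
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
        return(list(chi2 = 0, pvalue = 1))
    ht <- suppressWarnings(
        stats::chisq.test(matrix(x, nrow = 2, byrow = TRUE),
                          correct = FALSE))
    list(chi2 = unname(ht$statistic), pvalue = ht$p.value)
}

#' Compare one event between two conditions
#'
#' Rounds the four mean coverages half-up to integers, tabulates
#' \code{rbind(c(n_a, N_a), c(n_b, N_b))}, tests with [chiSquare2x2()],
#' and applies the significance filters: P-value at most \code{pMax} and
#' absolute inclusion-ratio difference above \code{dratioMin}.  If either
#' ratio is undefined the event is flagged \code{low_coverage} and never
#' significant.
#'
#' @param quantA,quantB single-event rows as produced by
#'   [quantifyEvents()] (anything list-like with \code{n}, \code{N},
#'   \code{ratio}).
#' @param thresholds a \linkS4class{ComparisonThresholds}.
#' @param labels condition labels used for the \code{direction} field.
#' @return Named list: \code{chi2}, \code{pvalue}, \code{dratio}
#'   (ratio A minus ratio B), \code{significant}, \code{direction},
#'   \code{low_coverage}.
#' @export
compareEvent <- function(quantA, quantB,
                         thresholds = comparisonThresholds(),
                         labels = c("A", "B")) {
    ra <- quantA$ratio; rb <- quantB$ratio
    if (is.na(ra) || is.na(rb))
        return(list(chi2 = NA_real_, pvalue = NA_real_,
                    dratio = NA_real_, significant = FALSE,
                    direction = "none", low_coverage = TRUE))
    ht <- chiSquare2x2(.roundHalfUp(quantA$n), .roundHalfUp(quantA$N),
                       .roundHalfUp(quantB$n), .roundHalfUp(quantB$N))
    dr <- ra - rb
    sig <- ht$pvalue <= thresholds@pMax && abs(dr) > thresholds@dratioMin
    dir <- if (dr > 0) labels[1] else if (dr < 0) labels[2] else "none"
    list(chi2 = ht$chi2, pvalue = ht$pvalue, dratio = dr,
         significant = sig, direction = dir, low_coverage = FALSE)
}

#' Run the two-condition comparison over an event catalogue
#'
#' Quantifies every event in both tracks, tests each with the 2x2
#' chi-squared statistic and applies the significance filters.  Output
#' rows are ordered by event id, so repeated runs on identical inputs are
#' bit-identical.
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param models the matching \linkS4class{TranscriptModels}.
#' @param trackA,trackB \linkS4class{CoverageTrack}s for the two
#'   conditions.
#' @param thresholds a \linkS4class{ComparisonThresholds}.
#' @param ratioDef ratio definition, see [quantifyEvents()].
#' @param adjust \code{"none"} (default; the raw P-value rule) or
#'   \code{"BH"} for Benjamini-Hochberg adjustment, in which case the
#'   adjusted P-value is filtered against \code{pMax}.
#' @return A \code{DataFrame} with columns \code{event_id}, \code{etype},
#'   \code{gene_id}, \code{region}, \code{n_a}, \code{N_a},
#'   \code{ratio_a}, \code{n_b}, \code{N_b}, \code{ratio_b}, \code{chi2},
#'   \code{pvalue} (\code{padj} when adjusted), \code{dratio},
#'   \code{significant}, \code{direction}, \code{low_coverage}.
#' @export
runComparison <- function(eventSet, models, trackA, trackB,
                          thresholds = comparisonThresholds(),
                          ratioDef = c("inclusion", "n_over_N"),
                          adjust = c("none", "BH")) {
    ratioDef <- match.arg(ratioDef)
    adjust <- match.arg(adjust)
    ev <- events(eventSet)
    labels <- c(trackLabel(trackA), trackLabel(trackB))
    if (labels[1] == labels[2]) labels <- c("A", "B")
    region <- if (nrow(ev)) classifyEventRegion(eventSet, models)
              else character()
    qa <- quantifyEvents(eventSet, models, trackA, ratioDef)
    qb <- quantifyEvents(eventSet, models, trackB, ratioDef)
    res <- lapply(seq_len(nrow(ev)), function(i)
        compareEvent(as.list(qa[i, ]), as.list(qb[i, ]), thresholds,
                     labels))
    num <- function(f) vapply(res, function(r) as.numeric(r[[f]]), 0)
    out <- DataFrame(
        event_id = ev$event_id, etype = ev$etype, gene_id = ev$gene_id,
        region = unname(region),
        n_a = qa$n, N_a = qa$N, ratio_a = qa$ratio,
        n_b = qb$n, N_b = qb$N, ratio_b = qb$ratio,
        chi2 = num("chi2"), pvalue = num("pvalue"),
        dratio = num("dratio"),
        significant = vapply(res, `[[`, TRUE, "significant"),
        direction = vapply(res, `[[`, "", "direction"),
        low_coverage = vapply(res, `[[`, TRUE, "low_coverage"))
    if (adjust == "BH" && nrow(out)) {
        out$padj <- stats::p.adjust(out$pvalue, method = "BH")
        out$significant <- !is.na(out$padj) & out$padj <= thresholds@pMax &
            !is.na(out$dratio) & abs(out$dratio) > thresholds@dratioMin
    }
    out[order(out$event_id), , drop = FALSE]
}

#' Summarize a comparison table
#'
#' @param cmp output of [runComparison()].
#' @return List with \code{n_events}, \code{n_significant},
#'   \code{n_genes_significant}, and \code{by_type} /
#'   \code{by_direction} / \code{by_region} count tables over the
#'   significant events.
#' @export
summarizeComparisons <- function(cmp) {
    sig <- cmp[!is.na(cmp$significant) & cmp$significant, , drop = FALSE]
    list(n_events = nrow(cmp),
         n_significant = nrow(sig),
         n_genes_significant = length(unique(sig$gene_id)),
         by_type = table(factor(sig$etype,
                                c("SE", "MXE", "A5SS", "A3SS"))),
         by_direction = table(factor(sig$direction,
                                     unique(c(cmp$direction, "none")))),
         by_region = table(factor(sig$region,
                                  c("5UTR", "CDS", "3UTR", "noncoding"))))
}

#' @rdname runComparison
#' @param cmp a comparison table.
#' @param path output TSV path.
#' @param confHash optional config hash stamped into the file header.
#' @export
writeComparisonTSV <- function(cmp, path, confHash = NULL)
    .writeTSV(cmp, path, confHash)

#' @rdname runComparison
#' @export
readComparisonTSV <- function(path)
    .readTSV(path)
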