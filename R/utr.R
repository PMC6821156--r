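## 5'-UTR exon pieces (0-based matrix) of one coding transcript,
## strand-aware: on '+' everything upstream of cds_start, on '-'
## everything downstream of cds_end.
.utrExons <- function(models, tx) {
    info <- txInfo(models)
    m <- match(tx, info$tx_id)
    if (is.na(m)) stop("transcript '", tx, "' not found in models")
    cs <- info$cds_start[m]; ce <- info$cds_end[m]
    if (is.na(cs)) stop("transcript '", tx, "' has no CDS")
    ex <- .exonMatrix(models, tx)
    if (info$strand[m] == "+") {
        keep <- ex[, 1] < cs
        out <- cbind(ex[keep, 1], pmin(ex[keep, 2], cs))
    } else {
        keep <- ex[, 2] > ce
        out <- cbind(pmax(ex[keep, 1], ce), ex[keep, 2])
    }
    out[out[, 1] < out[, 2], , drop = FALSE]
}

## spliced sequence of 0-based exon pieces, in transcript orientation
.spliceSeq <- function(genome, chrom, mat, strand) {
    if (nrow(mat) == 0L) return("")
    pieces <- vapply(seq_len(nrow(mat)), function(i)
        as.character(Biostrings::subseq(genome[[chrom]],
                                        mat[i, 1] + 1L, mat[i, 2])), "")
    s <- paste(pieces, collapse = "")
    if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
    toupper(s)
}

#' Reconstruct alternative 5'-UTR isoform sequences
#'
#' For each 5'-UTR-classified event, assembles the spliced 5'-UTR of the
#' inclusion-form host transcript (exonic sequence upstream of the CDS
#' start, in transcript orientation) and the exclusion form obtained by
#' removing the affected interval(s).  By construction
#' \code{utr_len_included = utr_len_excluded + alt_exon_len}.
#'
#' @param eventSet an \linkS4class{ASEventSet}; every event must classify
#'   as \code{5UTR} (an affected exon overlapping the CDS start is a
#'   misrouted CDS-class event and raises an error).
#' @param models the matching \linkS4class{TranscriptModels}.
#' @param genome a \code{DNAStringSet} or FASTA path.
#' @return \code{DataFrame} with columns \code{event_id}, \code{gene_id},
#'   \code{tx_id}, \code{seq_included}, \code{seq_excluded},
#'   \code{utr_len_included}, \code{utr_len_excluded},
#'   \code{alt_exon_len}, \code{alt_fraction}.
#' @export
buildUTRVariants <- function(eventSet, models, genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ev <- events(eventSet)
    region <- classifyEventRegion(eventSet, models)
    out <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
        if (region[i] != "5UTR")
            stop("event '", ev$event_id[i], "' classifies as ", region[i],
                 ", not 5UTR (misrouted)")
        tx <- as.character(ev$host_inc[i])
        ch <- as.character(ev$chrom[i])
        st <- as.character(ev$strand[i])
        utr <- .utrExons(models, tx)
        aff <- IRanges(ev$a1_start[i] + 1L, ev$a1_end[i])
        if (!is.na(ev$a2_start[i]))
            aff <- c(aff, IRanges(ev$a2_start[i] + 1L, ev$a2_end[i]))
        utrIR <- IRanges(utr[, 1] + 1L, utr[, 2])
        inAff <- IRanges::intersect(utrIR, aff)
        if (sum(IRanges::width(inAff)) !=
            sum(ev$a1_end[i] - ev$a1_start[i],
                ev$a2_end[i] - ev$a2_start[i], na.rm = TRUE))
            stop("affected interval of event '", ev$event_id[i],
                 "' extends beyond the 5'-UTR (misrouted)")
        exclIR <- IRanges::setdiff(utrIR, aff)
        toMat <- function(ir) cbind(IRanges::start(ir) - 1L,
                                    IRanges::end(ir))
        seqInc <- .spliceSeq(genome, ch, toMat(utrIR), st)
        seqExc <- .spliceSeq(genome, ch, toMat(exclIR), st)
        altLen <- sum(IRanges::width(inAff))
        out[[i]] <- data.frame(
            event_id = as.character(ev$event_id[i]),
            gene_id = as.character(ev$gene_id[i]), tx_id = tx,
            seq_included = seqInc, seq_excluded = seqExc,
            utr_len_included = nchar(seqInc),
            utr_len_excluded = nchar(seqExc),
            alt_exon_len = altLen,
            alt_fraction = altLen / nchar(seqInc),
            stringsAsFactors = FALSE)
    }
    DataFrame(do.call(rbind, out))
}

#' Scan a 5'-UTR for upstream open reading frames
#'
#' Every ATG wholly within the 5'-UTR starts a candidate; triplets are
#' read in its frame until a stop codon (TAA/TAG/TGA).  A stop ending at
#' or before the CDS start yields a terminated uORF whose length runs
#' from the ATG through the stop inclusive; ORFs that read into the CDS
#' (or off the end of the sequence) are reported as non-terminated
#' N-terminal extension candidates with \code{length_nt = NA}.
#' Overlapping uORFs are each counted from their own ATG.  Reported
#' terminated uORFs must span at least \code{minCodons} codons before the
#' stop (default 2, i.e. 9 nt minimum).
#'
#' @param seq character string or \code{DNAString} (A/C/G/T/N,
#'   uppercased internally).
#' @param cdsStartOffset 0-based offset of the annotated CDS start within
#'   \code{seq}; defaults to just past the end (the whole sequence is
#'   UTR).
#' @param minCodons minimum codons (including the ATG) before the stop.
#' @return \code{data.frame} with columns \code{start_offset} (0-based),
#'   \code{length_nt}, \code{terminated}.
#' @examples
#' findUORFs("CCATGAAATAACC")  # one uORF: start 2, length 9
#' @export
findUORFs <- function(seq, cdsStartOffset = NULL, minCodons = 2L) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    if (is.null(cdsStartOffset)) cdsStartOffset <- n
    stops <- c("TAA", "TAG", "TGA")
    starts <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
    if (starts[1] == -1L)
        return(data.frame(start_offset = integer(),
                          length_nt = integer(), terminated = logical()))
    res <- list(); k <- 0L
    for (s1 in starts) {              # s1 is 1-based match position
        s0 <- s1 - 1L                 # 0-based ATG offset
        if (s0 + 3L > cdsStartOffset) next
        pos <- s0 + 3L
        terminated <- FALSE; len <- NA_integer_
        while (pos + 3L <= n) {
            codon <- substr(seq, pos + 1L, pos + 3L)
            if (codon %in% stops) {
                if (pos + 3L <= cdsStartOffset) {
                    terminated <- TRUE
                    len <- pos + 3L - s0
                }
                break
            }
            pos <- pos + 3L
        }
        if (terminated && len < 3L * (minCodons + 1L)) next
        k <- k + 1L
        res[[k]] <- data.frame(start_offset = s0, length_nt = len,
                               terminated = terminated)
    }
    if (k == 0L)
        return(data.frame(start_offset = integer(),
                          length_nt = integer(), terminated = logical()))
    do.call(rbind, res)
}

#' 5'-TOP signature test
#'
#' A transcript carries a terminal oligopyrimidine signature when its
#' 5' end starts with C followed by at least four consecutive
#' pyrimidines.  Reported for completeness; not part of the uORF
#' statistics.
#'
#' @param seq character vector of 5'-UTR sequences (transcript
#'   orientation, position 1 = transcript 5' end).
#' @return Logical vector.
#' @export
detectFiveTOP <- function(seq)
    grepl("^C[CT]{4}", toupper(as.character(seq)))

#' Summarize region distribution and 5'-UTR reconfiguration
#'
#' Computes (i) the distribution of significant events across mRNA
#' regions, (ii) mean spliced 5'-UTR length of coding transcripts with
#' vs without catalogued events, (iii) the mean proportion of the
#' 5'-UTR contributed by the alternative exon, and (iv) per-gene uORF
#' count and mean-length differences between the inclusion and exclusion
#' 5'-UTR forms (with the 5'-TOP tally).
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param cmp a [runComparison()] table for the same events, or
#'   \code{NULL} to treat every event as selected.
#' @param models the matching \linkS4class{TranscriptModels}.
#' @param genome a \code{DNAStringSet} or FASTA path.
#' @param minCodons passed to [findUORFs()].
#' @return A list: \code{region_distribution} (percentages over
#'   5UTR/CDS/3UTR, summing to 100), \code{utr_lengths},
#'   \code{utr_variants}, \code{uorf_deltas}, \code{n_genes_utr5},
#'   \code{n_genes_uorf_reconfigured}, \code{five_top}.
#' @export
summarizeUTR <- function(eventSet, cmp = NULL, models, genome,
                         minCodons = 2L) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ev <- events(eventSet)
    region <- classifyEventRegion(eventSet, models)

    sel <- rep(TRUE, nrow(ev))
    if (!is.null(cmp) && any(!is.na(cmp$significant) & cmp$significant)) {
        sigIds <- cmp$event_id[!is.na(cmp$significant) & cmp$significant]
        sel <- ev$event_id %in% sigIds
    }
    selRegion <- region[sel]
    coding <- selRegion[selRegion %in% c("5UTR", "CDS", "3UTR")]
    dist <- if (length(coding))
        100 * table(factor(coding, c("5UTR", "CDS", "3UTR"))) /
            length(coding)
    else table(factor(character(), c("5UTR", "CDS", "3UTR"))) * NA

    ## spliced 5'-UTR length of every coding transcript, split by whether
    ## the transcript hosts any catalogued event
    info <- txInfo(models)
    hostTx <- unique(c(as.character(ev$host_inc),
                       as.character(ev$host_exc)))
    codingTx <- as.character(info$tx_id[!is.na(info$cds_start)])
    utrLen <- vapply(codingTx, function(tx) {
        m <- .utrExons(models, tx)
        sum(m[, 2] - m[, 1])
    }, 0)
    withEv <- codingTx %in% hostTx
    utrLengths <- list(
        mean_with_events = if (any(withEv)) mean(utrLen[withEv]) else NA,
        mean_without_events = if (any(!withEv)) mean(utrLen[!withEv])
                              else NA,
        n_with = sum(withEv), n_without = sum(!withEv))

    ## 5'-UTR variants and uORF reconfiguration for selected 5UTR events
    utr5 <- which(sel & region == "5UTR")
    variants <- NULL; deltas <- NULL; fiveTop <- 0L; nReconf <- 0L
    if (length(utr5)) {
        variants <- buildUTRVariants(eventSet[utr5], models, genome)
        fiveTop <- sum(detectFiveTOP(variants$seq_included))
        deltas <- do.call(rbind, lapply(seq_len(nrow(variants)),
                                        function(i) {
            ui <- findUORFs(variants$seq_included[i],
                            minCodons = minCodons)
            ue <- findUORFs(variants$seq_excluded[i],
                            minCodons = minCodons)
            ti <- ui[ui$terminated, , drop = FALSE]
            te <- ue[ue$terminated, , drop = FALSE]
            data.frame(
                event_id = variants$event_id[i],
                gene_id = variants$gene_id[i],
                n_uorf_included = nrow(ti), n_uorf_excluded = nrow(te),
                mean_len_included = if (nrow(ti)) mean(ti$length_nt)
                                    else NA_real_,
                mean_len_excluded = if (nrow(te)) mean(te$length_nt)
                                    else NA_real_,
                stringsAsFactors = FALSE)
        }))
        changed <- deltas$n_uorf_included != deltas$n_uorf_excluded |
            (!is.na(deltas$mean_len_included) &
             !is.na(deltas$mean_len_excluded) &
             deltas$mean_len_included != deltas$mean_len_excluded) |
            xor(is.na(deltas$mean_len_included),
                is.na(deltas$mean_len_excluded))
        nReconf <- length(unique(deltas$gene_id[changed]))
    }
    list(region_distribution = dist,
         utr_lengths = utrLengths,
         utr_variants = variants,
         uorf_deltas = deltas,
         n_genes_utr5 = length(unique(ev$gene_id[region == "5UTR"])),
         n_genes_uorf_reconfigured = nReconf,
         five_top = fiveTop)
}
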