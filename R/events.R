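#' Enumerate alternative-splicing events from gene models
#'
#' Compares every pair of transcripts of each gene and emits the four
#' classical event categories:
#' \describe{
#'   \item{SE}{a cassette exon of one transcript is absent (as an exact
#'     interval) from another whose corresponding flanking exons form the
#'     same splice junctions (matching upstream-exon end and
#'     downstream-exon start).}
#'   \item{MXE}{two transcripts carry different middle exons between
#'     identical flanking junctions; the middle exons are non-overlapping
#'     and each absent from the other transcript.}
#'   \item{A5SS/A3SS}{two exons share one boundary but differ at the
#'     other, with the adjacent exon across the variable boundary sharing
#'     its splice junction; the affected interval is the differential
#'     extension, and the donor/acceptor label is assigned strand-aware.}
#' }
#' Events are deduplicated on (type, affected coordinates, flank-junction
#' coordinates, strand); the representative host transcript pair is the
#' lexicographically smallest, which makes the catalogue deterministic and
#' independent of transcript order.
#'
#' @param models a \linkS4class{TranscriptModels} object.
#' @return An \linkS4class{ASEventSet}.  Genes with a single transcript
#'   contribute no events.
#' @examples
#' m <- transcriptModels(
#'   list(t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
#'        t2 = cbind(c(0, 400), c(100, 500))),
#'   geneId = "g1")
#' enumerateASEvents(m)
#' @export
enumerateASEvents <- function(models) {
    info <- txInfo(models)
    allMats <- .allExonMatrices(models)
    rows <- list()
    for (g in unique(as.character(info$gene_id))) {
        idx <- which(info$gene_id == g)
        if (length(idx) < 2L) next
        txs <- as.character(info$tx_id[idx])
        mats <- allMats[txs]
        rows[[g]] <- .enumGene(mats,
                               chrom = as.character(info$chrom[idx[1]]),
                               strand = as.character(info$strand[idx[1]]),
                               gene = g)
    }
    rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    .newEventSet(rows)
}

.newEventSet <- function(rows) {
    if (is.null(rows) || nrow(rows) == 0L) {
        ev <- DataFrame(event_id = character(), etype = character(),
                        gene_id = character(), chrom = character(),
                        strand = character(),
                        a1_start = integer(), a1_end = integer(),
                        a2_start = integer(), a2_end = integer(),
                        fu_start = integer(), fu_end = integer(),
                        fd_start = integer(), fd_end = integer(),
                        host_inc = character(), host_exc = character(),
                        acceptor_pos = integer())
        return(new("ASEventSet", events = ev))
    }
    key <- with(rows, paste(etype, chrom,
                            a1_start, a1_end,
                            ifelse(is.na(a2_start), ".", a2_start),
                            ifelse(is.na(a2_end), ".", a2_end),
                            fu_end, fd_start, strand, sep = ":"))
    ord <- order(key, rows$host_inc, rows$host_exc)
    rows <- rows[ord, , drop = FALSE]
    rows <- rows[!duplicated(key[ord]), , drop = FALSE]
    rows$event_id <- sprintf(
        "%s:%s:%d-%d%s:%d^%d:%s", rows$etype, rows$chrom,
        rows$a1_start, rows$a1_end,
        ifelse(is.na(rows$a2_start), "",
               sprintf("/%d-%d", rows$a2_start, rows$a2_end)),
        rows$fu_end, rows$fd_start, rows$strand)
    rows$acceptor_pos <- ifelse(rows$strand == "+",
                                rows$a1_start, rows$a1_end)
    rows <- rows[order(rows$event_id), , drop = FALSE]
    rownames(rows) <- NULL
    new("ASEventSet", events = DataFrame(rows[, .EVENT_COLS]))
}

.hasIv <- function(m, s, e) any(m[, 1] == s & m[, 2] == e)

.enumGene <- function(mats, chrom, strand, gene) {
    txs <- names(mats)
    acc <- list(); k <- 0L
    add <- function(etype, a1, a2, fu, fd, hinc, hexc) {
        k <<- k + 1L
        acc[[k]] <<- data.frame(
            event_id = "", etype = etype, gene_id = gene, chrom = chrom,
            strand = strand,
            a1_start = a1[1], a1_end = a1[2],
            a2_start = if (is.null(a2)) NA_integer_ else a2[1],
            a2_end = if (is.null(a2)) NA_integer_ else a2[2],
            fu_start = fu[1], fu_end = fu[2],
            fd_start = fd[1], fd_end = fd[2],
            host_inc = hinc, host_exc = hexc,
            acceptor_pos = NA_integer_, stringsAsFactors = FALSE)
    }

    ## SE: ordered pairs (inclusion form X, exclusion form Y)
    for (p in seq_along(txs)) for (q in seq_along(txs)) {
        if (p == q) next
        X <- mats[[p]]; Y <- mats[[q]]
        if (nrow(X) < 3L || nrow(Y) < 2L) next
        for (i in 2:(nrow(X) - 1L)) {
            u <- X[i - 1L, ]; a <- X[i, ]; d <- X[i + 1L, ]
            if (.hasIv(Y, a[1], a[2])) next
            for (j in which(Y[, 2] == u[2])) {
                if (j < nrow(Y) && Y[j + 1L, 1] == d[1]) {
                    add("SE", a, NULL, u, d, txs[p], txs[q])
                    break
                }
            }
        }
    }

    ## MXE: unordered pairs, both middle exons flanked by identical junctions
    if (length(txs) >= 2L)
        for (p in 1:(length(txs) - 1L)) for (q in (p + 1L):length(txs)) {
            X <- mats[[p]]; Y <- mats[[q]]
            if (nrow(X) < 3L || nrow(Y) < 3L) next
            for (i in 2:(nrow(X) - 1L)) for (j in 2:(nrow(Y) - 1L)) {
                a <- X[i, ]; b <- Y[j, ]
                if (X[i - 1L, 2] != Y[j - 1L, 2]) next
                if (X[i + 1L, 1] != Y[j + 1L, 1]) next
                if (.hasIv(Y, a[1], a[2]) || .hasIv(X, b[1], b[2])) next
                if (!(a[2] <= b[1] || b[2] <= a[1])) next  # must not overlap
                if (a[1] < b[1]) {
                    add("MXE", a, b, X[i - 1L, ], X[i + 1L, ],
                        txs[p], txs[q])
                } else {
                    add("MXE", b, a, Y[j - 1L, ], Y[j + 1L, ],
                        txs[q], txs[p])
                }
            }
        }

    ## Alternative donor/acceptor, variable boundary on the genomic right:
    ## exons share their start, differ at their end, and the next exon
    ## shares its splice junction.  On '+' the right boundary is the donor
    ## (A5SS); on '-' it is the acceptor (A3SS).
    if (length(txs) >= 2L)
        for (p in 1:(length(txs) - 1L)) for (q in (p + 1L):length(txs)) {
            X <- mats[[p]]; Y <- mats[[q]]
            if (nrow(X) < 2L || nrow(Y) < 2L) next
            for (i in 1:(nrow(X) - 1L)) for (j in 1:(nrow(Y) - 1L)) {
                e1 <- X[i, ]; e2 <- Y[j, ]
                if (e1[1] == e2[1] && e1[2] != e2[2] &&
                    X[i + 1L, 1] == Y[j + 1L, 1]) {
                    if (e1[2] > e2[2]) {
                        long <- e1; short <- e2
                        hin <- txs[p]; hex <- txs[q]; fd <- X[i + 1L, ]
                    } else {
                        long <- e2; short <- e1
                        hin <- txs[q]; hex <- txs[p]; fd <- Y[j + 1L, ]
                    }
                    add(if (strand == "+") "A5SS" else "A3SS",
                        c(short[2], long[2]), NULL, short, fd, hin, hex)
                }
            }
            ## variable boundary on the genomic left ('+': acceptor); the
            ## variable exon may be the transcript's last exon
            for (i in 2:nrow(X)) for (j in 2:nrow(Y)) {
                f1 <- X[i, ]; f2 <- Y[j, ]
                if (f1[2] == f2[2] && f1[1] != f2[1] &&
                    X[i - 1L, 2] == Y[j - 1L, 2]) {
                    if (f1[1] < f2[1]) {
                        long <- f1; short <- f2
                        hin <- txs[p]; hex <- txs[q]; fu <- X[i - 1L, ]
                    } else {
                        long <- f2; short <- f1
                        hin <- txs[q]; hex <- txs[p]; fu <- Y[j - 1L, ]
                    }
                    add(if (strand == "+") "A3SS" else "A5SS",
                        c(long[1], short[1]), NULL, fu, short, hin, hex)
                }
            }
        }
    if (k == 0L) return(NULL)
    do.call(rbind, acc)
}

#' Classify an event's position within its host mRNA
#'
#' Labels each event by where its affected interval(s) fall relative to
#' the CDS bounds of the inclusion-form host transcript, strand-aware: on
#' the minus strand the 5'-UTR is genomically downstream of the CDS.  An
#' affected exon overlapping a CDS boundary is classified \code{CDS}; a
#' host transcript without CDS yields \code{noncoding}.
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param models the \linkS4class{TranscriptModels} the events came from.
#' @return Character vector of labels in
#'   \code{c("5UTR", "CDS", "3UTR", "noncoding")}, named by event id.
#' @export
classifyEventRegion <- function(eventSet, models) {
    ev <- events(eventSet)
    info <- txInfo(models)
    out <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
        m <- match(ev$host_inc[i], info$tx_id)
        if (is.na(m))
            stop("host transcript of event '", ev$event_id[i],
                 "' not found in models")
        cs <- info$cds_start[m]; ce <- info$cds_end[m]
        if (is.na(cs)) { out[i] <- "noncoding"; next }
        s <- c(ev$a1_start[i], ev$a2_start[i])
        e <- c(ev$a1_end[i], ev$a2_end[i])
        keep <- !is.na(s); s <- s[keep]; e <- e[keep]
        if (any(s < ce & e > cs)) { out[i] <- "CDS"; next }
        left <- all(e <= cs); right <- all(s >= ce)
        if (!left && !right) { out[i] <- "CDS"; next }  # straddles the CDS
        plus <- ev$strand[i] == "+"
        out[i] <- if (left == plus) "5UTR" else "3UTR"
    }
    names(out) <- ev$event_id
    out
}

#' Write and read event catalogues
#'
#' Events are exported as 6-column BED (one line per affected interval;
#' an MXE contributes two lines sharing the event id) together with a TSV
#' sidecar holding the full event table.
#'
#' @param eventSet an \linkS4class{ASEventSet}.
#' @param bedPath,tsvPath output paths.
#' @param confHash optional config hash stamped into the TSV header.
#' @return Invisibly, the paths written.
#' @export
writeEventsBED <- function(eventSet, bedPath) {
    gr <- eventRanges(eventSet)
    if (length(gr)) {
        names(gr) <- gr$event_id
        gr$score <- 0L
        gr$event_id <- NULL; gr$etype <- NULL
    }
    rtracklayer::export(gr, bedPath, format = "bed")
    invisible(bedPath)
}

#' @rdname writeEventsBED
#' @param path a BED file written by [writeEventsBED()].
#' @export
readEventsBED <- function(path)
    rtracklayer::import(path, format = "bed")

#' @rdname writeEventsBED
#' @export
writeEventsTSV <- function(eventSet, tsvPath, confHash = NULL)
    .writeTSV(as.data.frame(eventSet), tsvPath, confHash)

#' @rdname writeEventsBED
#' @export
readEventsTSV <- function(path) {
    df <- .readTSV(path)
    for (col in c("a2_start", "a2_end"))
        df[[col]] <- as.integer(df[[col]])
    new("ASEventSet", events = DataFrame(df[, .EVENT_COLS]))
}
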