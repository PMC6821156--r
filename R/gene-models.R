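#' Read gene models from a GTF annotation
#'
#' Parses a GTF file (attribute keys \code{gene_id} and
#' \code{transcript_id} are mandatory on exon features) into a
#' \linkS4class{TranscriptModels} object.  GTF's 1-based closed
#' coordinates are converted to the package's internal 0-based half-open
#' convention; when CDS features are present the genomic CDS bounds are
#' recorded per transcript.
#'
#' @param path path to a GTF file.
#' @return A \linkS4class{TranscriptModels} object.  An empty file yields
#'   an empty model set with a warning.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsrc\texon\t101\t200\t.\t+\t.",
#'                  'gene_id "g1"; transcript_id "t1";'), gtf)
#' readGeneModels(gtf)
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "#") & nzchar(trimws(lines))
    nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
    if (any(nf < 8L))
        stop("malformed GTF line ", which(body)[nf < 8L][1],
             " in ", path, " (fewer than 8 tab-separated fields)")
    if (!any(body)) {
        warning("empty annotation: ", path)
        return(.emptyModels())
    }
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- S4Vectors::mcols(gr)
    if (!all(c("gene_id", "transcript_id") %in% colnames(mc)))
        stop("GTF must carry gene_id and transcript_id attributes")
    ex <- gr[mc$type == "exon"]
    if (length(ex) == 0L) {
        warning("annotation has no exon features: ", path)
        return(.emptyModels())
    }
    if (any(is.na(ex$gene_id)) || any(is.na(ex$transcript_id)))
        stop("exon feature missing gene_id or transcript_id attribute")

    ## flat vector representation; grouping by transcript without
    ## per-transcript S4 subsetting
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
        strand = as.character(GenomicRanges::strand(ex)),
        gene = as.character(ex$gene_id),
        tx = as.character(ex$transcript_id), stringsAsFactors = FALSE)
    df <- df[order(df$tx, df$start, df$end), ]
    df <- df[!duplicated(df[c("tx", "chrom", "start", "end",
                              "strand")]), ]
    txid <- unique(df$tx)
    first <- match(txid, df$tx)
    mixed <- tapply(paste(df$chrom, df$strand), df$tx,
                    function(x) length(unique(x)))[txid]
    if (any(mixed > 1L))
        stop("transcript '", txid[which(mixed > 1L)[1]],
             "' has exons on mixed chromosomes/strands: rejected")

    cds <- gr[mc$type == "CDS"]
    cs <- rep(NA_integer_, length(txid))
    ce <- rep(NA_integer_, length(txid))
    if (length(cds)) {
        cds <- cds[as.character(cds$transcript_id) %in% txid]
    }
    if (length(cds)) {
        ctx <- as.character(cds$transcript_id)
        m <- match(unique(ctx), txid)
        cs[m] <- as.integer(tapply(GenomicRanges::start(cds), ctx,
                                   min)[txid[m]]) - 1L
        ce[m] <- as.integer(tapply(GenomicRanges::end(cds), ctx,
                                   max)[txid[m]])
    }

    info <- data.frame(tx_id = txid, gene_id = df$gene[first],
                       chrom = df$chrom[first],
                       strand = df$strand[first],
                       cds_start = cs, cds_end = ce,
                       stringsAsFactors = FALSE)
    ord <- order(info$gene_id, info$tx_id)
    info <- info[ord, ]
    exGR <- GRanges(df$chrom, IRanges(df$start, df$end),
                    strand = df$strand)
    grl <- S4Vectors::split(exGR, factor(df$tx, levels = info$tx_id))
    new("TranscriptModels", exons = grl,
        txInfo = DataFrame(info, row.names = NULL))
}

.emptyModels <- function()
    new("TranscriptModels", exons = GRangesList(),
        txInfo = DataFrame(tx_id = character(), gene_id = character(),
                           chrom = character(), strand = character(),
                           cds_start = integer(), cds_end = integer()))

#' Build gene models programmatically
#'
#' Constructor used by the simulator and by tests: exon coordinates are
#' given directly in the internal 0-based half-open convention.
#'
#' @param exons named list (by transcript id) of two-column matrices of
#'   0-based half-open exon intervals, rows sorted by start.
#' @param geneId character vector (recycled) of parent gene ids.
#' @param chrom,strand chromosome and strand per transcript (recycled).
#' @param cdsStart,cdsEnd optional genomic CDS bounds per transcript,
#'   0-based half-open; \code{NA} for non-coding.
#' @return A \linkS4class{TranscriptModels} object.
#' @examples
#' transcriptModels(list(t1 = cbind(c(0, 200), c(100, 300))), geneId = "g1")
#' @export
transcriptModels <- function(exons, geneId, chrom = "chr1", strand = "+",
                             cdsStart = NA_integer_, cdsEnd = NA_integer_) {
    n <- length(exons)
    if (is.null(names(exons)) || anyDuplicated(names(exons)))
        stop("exons must be a uniquely named list of interval matrices")
    geneId <- rep_len(geneId, n); chrom <- rep_len(chrom, n)
    strand <- rep_len(strand, n)
    cdsStart <- rep_len(as.integer(cdsStart), n)
    cdsEnd <- rep_len(as.integer(cdsEnd), n)
    nEx <- vapply(exons, nrow, 0L)
    allIv <- do.call(rbind, exons)
    gr <- GRanges(rep.int(chrom, nEx),
                  IRanges(as.integer(allIv[, 1]) + 1L,
                          as.integer(allIv[, 2])),
                  strand = rep.int(strand, nEx))
    grl <- S4Vectors::split(gr, factor(rep.int(names(exons), nEx),
                                       levels = names(exons)))
    new("TranscriptModels", exons = grl,
        txInfo = DataFrame(tx_id = names(exons), gene_id = geneId,
                           chrom = chrom, strand = strand,
                           cds_start = cdsStart, cds_end = cdsEnd))
}

## 0-based half-open exon matrix of one transcript
.exonMatrix <- function(models, tx) {
    e <- models@exons[[tx]]
    cbind(start = GenomicRanges::start(e) - 1L, end = GenomicRanges::end(e))
}

## all transcripts at once: one unlist instead of per-transcript [[,
## which matters on thousand-transcript annotations
.allExonMatrices <- function(models) {
    nEx <- lengths(models@exons)
    ue <- unlist(models@exons, use.names = FALSE)
    s <- GenomicRanges::start(ue) - 1L
    e <- GenomicRanges::end(ue)
    gf <- factor(rep.int(seq_along(nEx), nEx),
                 levels = seq_along(nEx))
    idx <- split(seq_along(gf), gf)
    out <- lapply(idx, function(i) cbind(start = s[i], end = e[i]))
    names(out) <- names(models@exons)
    out
}
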