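test_that("cassette (SE) events are detected with junction-matched flanks", {
    ev <- as.data.frame(enumerateASEvents(toySEModels()))
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$etype, "SE")
    expect_identical(c(ev$a1_start, ev$a1_end), c(200L, 300L))
    expect_identical(c(ev$fu_start, ev$fu_end), c(0L, 100L))
    expect_identical(c(ev$fd_start, ev$fd_end), c(400L, 500L))
    expect_identical(ev$host_inc, "t1")
    expect_identical(ev$host_exc, "t2")
    expect_identical(ev$acceptor_pos, 200L)

    ## flank matching is on junction coordinates, not full exon identity:
    ## t2's outer boundaries differ but the junctions agree
    m2 <- transcriptModels(
        list(t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
             t2 = cbind(c(20, 400), c(100, 480))), geneId = "g1")
    expect_identical(eventTypes(enumerateASEvents(m2)), "SE")

    ## single-transcript genes yield nothing
    m1 <- transcriptModels(list(t1 = cbind(c(0, 200), c(100, 300))),
                           geneId = "g1")
    expect_identical(length(enumerateASEvents(m1)), 0L)
})

test_that("MXE requires identical flanking junctions and non-overlap", {
    m <- transcriptModels(
        list(t1 = cbind(c(0, 200, 500), c(100, 300, 600)),
             t2 = cbind(c(0, 350, 500), c(100, 450, 600))), geneId = "g1")
    ev <- as.data.frame(enumerateASEvents(m))
    expect_identical(ev$etype, "MXE")
    expect_identical(c(ev$a1_start, ev$a1_end), c(200L, 300L))
    expect_identical(c(ev$a2_start, ev$a2_end), c(350L, 450L))

    ## overlapping middle exons are not MXE
    mo <- transcriptModels(
        list(t1 = cbind(c(0, 200, 500), c(100, 300, 600)),
             t2 = cbind(c(0, 250, 500), c(100, 450, 600))), geneId = "g1")
    expect_false("MXE" %in% eventTypes(enumerateASEvents(mo)))
})

test_that("alternative donor/acceptor events are strand-aware", {
    ## shared start, variable right boundary, shared downstream junction
    m <- transcriptModels(
        list(t1 = cbind(c(0, 200), c(150, 300)),
             t2 = cbind(c(0, 200), c(100, 300))), geneId = "g1")
    ev <- as.data.frame(enumerateASEvents(m))
    expect_identical(ev$etype, "A5SS")
    expect_identical(c(ev$a1_start, ev$a1_end), c(100L, 150L))
    expect_identical(ev$host_inc, "t1")

    mneg <- transcriptModels(
        list(t1 = cbind(c(0, 200), c(150, 300)),
             t2 = cbind(c(0, 200), c(100, 300))), geneId = "g1",
        strand = "-")
    evn <- as.data.frame(enumerateASEvents(mneg))
    expect_identical(evn$etype, "A3SS")
    expect_identical(evn$acceptor_pos, 150L)  # strand-aware 3'ss

    ## shared end, variable left boundary ('+': acceptor); the variable
    ## exon here is the terminal exon
    m3 <- transcriptModels(
        list(t1 = cbind(c(0, 200), c(100, 300)),
             t2 = cbind(c(0, 250), c(100, 300))), geneId = "g1")
    ev3 <- as.data.frame(enumerateASEvents(m3))
    expect_identical(ev3$etype, "A3SS")
    expect_identical(c(ev3$a1_start, ev3$a1_end), c(200L, 250L))
    expect_identical(ev3$acceptor_pos, 200L)
})

test_that("enumeration is symmetric and deduplicated deterministically", {
    ## three transcripts, two of which support the same cassette event
    m <- transcriptModels(
        list(tA = cbind(c(0, 200, 400), c(100, 300, 500)),
             tB = cbind(c(0, 400), c(100, 500)),
             tC = cbind(c(0, 400), c(100, 520))), geneId = "g1")
    ev <- as.data.frame(enumerateASEvents(m))
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$host_exc, "tB")  # lexicographically smallest pair

    ## transcript order never changes the result
    set.seed(421)
    for (rep in 1:5) {
        m1 <- randomToyModels(8)
        perm <- sample(length(txExons(m1)))
        exl <- lapply(txExons(m1)[perm], function(e)
            cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e)))
        info <- as.data.frame(txInfo(m1))[perm, ]
        m2 <- transcriptModels(exl, geneId = info$gene_id,
                               chrom = info$chrom, strand = info$strand)
        expect_identical(as.data.frame(enumerateASEvents(m1)),
                         as.data.frame(enumerateASEvents(m2)))
    }
})

test_that("enumeration matches the brute-force oracle on random genes", {
    set.seed(1003)
    for (rep in 1:4) {
        m <- randomToyModels(20)
        expect_identical(eventSetKeys(enumerateASEvents(m)),
                         bruteForceEventKeys(m))
    }
})

test_that("affected intervals are exonic in one host and absent from the other", {
    set.seed(77)
    m <- randomToyModels(25)
    ev <- as.data.frame(enumerateASEvents(m))
    hasIv <- function(tx, s, e) {
        em <- spliceQuant:::.exonMatrix(m, tx)
        any(em[, 1] == s & em[, 2] == e)
    }
    for (i in seq_len(nrow(ev))) {
        if (ev$etype[i] %in% c("SE", "MXE")) {
            expect_true(hasIv(ev$host_inc[i], ev$a1_start[i],
                              ev$a1_end[i]))
            expect_false(hasIv(ev$host_exc[i], ev$a1_start[i],
                               ev$a1_end[i]))
        } else {
            ## boundary events: the affected extension is covered by an
            ## exon of the inclusion host only
            em <- spliceQuant:::.exonMatrix(m, ev$host_inc[i])
            expect_true(any(em[, 1] <= ev$a1_start[i] &
                            em[, 2] >= ev$a1_end[i]))
        }
        expect_true(ev$a1_start[i] >= ev$fu_end[i])
        expect_true(ev$a1_end[i] <= ev$fd_start[i])
    }
})

test_that("event BED/TSV round trips preserve intervals and metadata", {
    m <- transcriptModels(
        list(t1 = cbind(c(0, 200, 500), c(100, 300, 600)),
             t2 = cbind(c(0, 350, 500), c(100, 450, 600)),
             t3 = cbind(c(0, 500), c(100, 600))), geneId = "g1")
    ev <- enumerateASEvents(m)
    bed <- withr::local_tempfile(fileext = ".bed")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeEventsBED(ev, bed)
    gr <- readEventsBED(bed)
    asdf <- function(g) {
        d <- as.data.frame(g)[, c("seqnames", "start", "end", "strand")]
        d[] <- lapply(d, as.character)
        rownames(d) <- NULL
        d
    }
    expect_identical(asdf(gr), asdf(eventRanges(ev)))
    writeEventsTSV(ev, tsv)
    ev2 <- readEventsTSV(tsv)
    expect_identical(as.data.frame(ev), as.data.frame(ev2))
})

test_that("event regions are classified strand-aware against the CDS", {
    mk <- function(strand, cds)
        transcriptModels(
            list(t1 = cbind(c(0, 100, 220, 840), c(60, 200, 820, 950)),
                 t2 = cbind(c(0, 220, 840), c(60, 820, 950))),
            geneId = "g1", strand = strand,
            cdsStart = cds[1], cdsEnd = cds[2])
    ## '+' strand: affected exon (100,200) upstream of CDS (250,800)
    mplus <- mk("+", c(250, 800))
    evp <- enumerateASEvents(mplus)
    expect_identical(unname(classifyEventRegion(evp, mplus)), "5UTR")
    ## mirrored call on '-' strand: genomically left of the CDS is 3'UTR
    mminus <- mk("-", c(250, 800))
    expect_identical(unname(classifyEventRegion(enumerateASEvents(mminus),
                                                mminus)), "3UTR")
    ## affected exon overlapping a CDS boundary is CDS
    mcds <- mk("+", c(150, 800))
    expect_identical(unname(classifyEventRegion(enumerateASEvents(mcds),
                                                mcds)), "CDS")
    ## genomically right of the CDS, minus strand: 5'UTR
    mk2 <- transcriptModels(
        list(t1 = cbind(c(0, 400, 850, 980), c(300, 800, 950, 1000)),
             t2 = cbind(c(0, 400, 980), c(300, 800, 1000))),
        geneId = "g1", strand = "-", cdsStart = 250, cdsEnd = 800)
    expect_identical(unname(classifyEventRegion(enumerateASEvents(mk2),
                                                mk2)), "5UTR")
    ## no CDS at all
    mnc <- transcriptModels(
        list(t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
             t2 = cbind(c(0, 400), c(100, 500))), geneId = "g1")
    expect_identical(unname(classifyEventRegion(enumerateASEvents(mnc),
                                                mnc)), "noncoding")
})
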