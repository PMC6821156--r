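## toy coding gene with a cassette exon wholly inside the 5'-UTR:
## UTR exons (0,50) + (100,150), CDS starts exactly at exon (200,300)
utr5Toy <- function(strand = "+") {
    if (strand == "+")
        transcriptModels(
            list(t1 = cbind(c(0, 100, 200), c(50, 150, 300)),
                 t2 = cbind(c(0, 200), c(50, 300))),
            geneId = "g1", cdsStart = 200, cdsEnd = 280)
    else
        ## mirrored in a 300-base chromosome
        transcriptModels(
            list(t1 = cbind(c(0, 150, 250), c(100, 200, 300)),
                 t2 = cbind(c(0, 250), c(100, 300))),
            geneId = "g1", strand = "-", cdsStart = 20, cdsEnd = 100)
}

test_that("5'-UTR variant pairs satisfy the length identity", {
    g <- Biostrings::DNAStringSet(setNames(
        paste(rep("ACGT", 75), collapse = ""), "chr1"))
    m <- utr5Toy()
    ev <- enumerateASEvents(m)
    v <- buildUTRVariants(ev, m, g)
    expect_identical(v$utr_len_included, 100L)
    expect_identical(v$utr_len_excluded, 50L)
    expect_identical(v$alt_exon_len, 100L - 50L)
    expect_equal(v$alt_fraction, 0.5)
    expect_identical(v$utr_len_included,
                     v$utr_len_excluded + v$alt_exon_len)
    ## sequences are the spliced exon pieces upstream of the CDS
    expect_identical(v$seq_included,
                     paste0(substr(as.character(g[[1]]), 1, 50),
                            substr(as.character(g[[1]]), 101, 150)))
    expect_identical(v$seq_excluded,
                     substr(as.character(g[[1]]), 1, 50))
})

test_that("minus-strand UTR variants are reverse-complemented mirrors", {
    set.seed(5)
    fwd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    gPlus <- Biostrings::DNAStringSet(setNames(fwd, "chr1"))
    gMinus <- Biostrings::DNAStringSet(setNames(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(fwd))),
        "chr1"))
    vP <- buildUTRVariants(enumerateASEvents(utr5Toy("+")), utr5Toy("+"),
                           gPlus)
    vM <- buildUTRVariants(enumerateASEvents(utr5Toy("-")), utr5Toy("-"),
                           gMinus)
    expect_identical(vP$utr_len_included, vM$utr_len_included)
    expect_identical(vP$utr_len_excluded, vM$utr_len_excluded)
    expect_identical(vP$seq_included, vM$seq_included)
    expect_identical(vP$seq_excluded, vM$seq_excluded)
})

test_that("events touching the CDS are rejected as misrouted", {
    g <- Biostrings::DNAStringSet(setNames(strrep("ACGT", 100), "chr1"))
    m <- transcriptModels(
        list(t1 = cbind(c(0, 100, 200), c(50, 150, 300)),
             t2 = cbind(c(0, 200), c(50, 300))),
        geneId = "g1", cdsStart = 120, cdsEnd = 280)
    expect_error(buildUTRVariants(enumerateASEvents(m), m, g),
                 "misrouted|not 5UTR")
})

test_that("uORF scanning follows the triplet definition", {
    u <- findUORFs("CCATGAAATAACC")
    expect_identical(u$start_offset, 2L)
    expect_identical(u$length_nt, 9L)
    expect_true(u$terminated)

    expect_identical(nrow(findUORFs("CCCCCCCCCC")), 0L)

    ## too short (ATG directly followed by a stop) is not reported
    expect_identical(nrow(findUORFs("ATGTAACCCCCC")), 0L)

    ## an ORF reading into the CDS is a non-terminated candidate
    u2 <- findUORFs("CCATGAAAAAATAA", cdsStartOffset = 8)
    expect_false(u2$terminated)
    expect_true(is.na(u2$length_nt))

    ## overlapping ATGs each start their own uORF
    u3 <- findUORFs("ATGATGCCCTAACC")
    expect_identical(u3$start_offset, c(0L, 3L))
    expect_identical(u3$length_nt, c(12L, 9L))
})

test_that("uORF scanning equals the brute-force scanner on random input", {
    set.seed(202)
    for (i in 1:40) {
        s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                   collapse = "")
        cds <- sample(c(400, sample(50:400, 3)), 1)
        expect_equal(findUORFs(s, cds), bruteUORFs(s, cds),
                     ignore_attr = TRUE, info = paste("seq", i))
    }
})

test_that("uORF offsets shift by the alternative exon length", {
    ## included = prefix + alt + suffix; excluded = prefix + suffix, with
    ## all uORFs in the suffix
    prefix <- strrep("C", 30)
    alt <- strrep("G", 24)
    suffix <- "CCATGCCCTAACCATGAAAGGGTGACC"
    inc <- paste0(prefix, alt, suffix)
    exc <- paste0(prefix, suffix)
    ui <- findUORFs(inc); ue <- findUORFs(exc)
    expect_identical(ui$start_offset, ue$start_offset + nchar(alt))
    expect_identical(ui$length_nt, ue$length_nt)
})

test_that("5'-TOP signature detection", {
    expect_true(detectFiveTOP("CCTCTAGG"))
    expect_true(detectFiveTOP("CTTTTAAA"))
    expect_false(detectFiveTOP("ACTTTT"))
    expect_false(detectFiveTOP("CATTTT"))
})

test_that("the UTR summary recovers planted structure from simulation", {
    dir <- withr::local_tempdir()
    res <- simulateDataset(
        simConfig(seed = 13, nGenes = c(SE = 7, MXE = 0, A5SS = 0,
                                        A3SS = 0),
                  utr = list(nUTR5 = 2, nUTR3 = 1, nBackground = 5,
                             lenWithEvents = 500, lenWithout = 200,
                             jitter = 0)),
        dir)
    m <- readGeneModels(res$gtf)
    ev <- enumerateASEvents(m)
    genome <- Biostrings::readDNAStringSet(res$genome)
    s <- summarizeUTR(ev, NULL, m, genome)

    ## 10 events: 7 CDS, 2 5'UTR, 1 3'UTR
    expect_equal(as.numeric(s$region_distribution),
                 c(20, 70, 10), tolerance = 1e-12)
    expect_equal(sum(s$region_distribution), 100)

    ## planted mean 5'-UTR lengths: ~500 with events (inclusion forms;
    ## exclusion forms are shorter by the alt exon), 200 without
    expect_equal(s$utr_lengths$mean_without_events, 200, tolerance = 0.01)
    expect_gt(s$utr_lengths$mean_with_events, 400)
    expect_lt(s$utr_lengths$mean_with_events, 520)

    ## alt exon proportion as configured (30%)
    expect_equal(mean(s$utr_variants$alt_fraction), 0.3, tolerance = 0.01)

    ## the planted uORF appears in the inclusion form only
    expect_identical(s$uorf_deltas$n_uorf_included, c(1L, 1L))
    expect_identical(s$uorf_deltas$n_uorf_excluded, c(0L, 0L))
    expect_identical(s$n_genes_uorf_reconfigured, 2L)

    truth <- res$truth
    pl <- truth[!is.na(truth$uorf_start), ]
    v <- s$utr_variants
    for (i in seq_len(nrow(pl))) {
        vv <- v[v$event_id == pl$event_id[i], ]
        u <- findUORFs(vv$seq_included)
        expect_true(any(u$start_offset == pl$uorf_start[i] &
                        u$length_nt == pl$uorf_len[i]))
        expect_identical(nrow(findUORFs(vv$seq_excluded)), 0L)
    }
})
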