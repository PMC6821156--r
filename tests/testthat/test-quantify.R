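## helper: one-gene cassette with chosen depths on affected/rest exons
seTrackModels <- function(affDepth, restDepth, label = "A") {
    m <- toySEModels()
    d <- numeric(600)
    d[(0 + 1):100] <- restDepth; d[(400 + 1):500] <- restDepth
    d[(200 + 1):300] <- affDepth
    list(models = m, ev = enumerateASEvents(m),
         track = coverageTrack(list(chr1 = d), label))
}

test_that("n, N and the inclusion ratio follow the coverage means", {
    x <- seTrackModels(30, 60)
    q <- quantifyEvents(x$ev, x$models, x$track)
    expect_equal(q$n, 30)
    expect_equal(q$N, 60)
    expect_equal(q$ratio, 30 / 90)
    expect_identical(q$affected_len, 100L)
    expect_identical(q$rest_len, 200L)

    ## alternative unbounded definition behind the flag
    q2 <- quantifyEvents(x$ev, x$models, x$track, ratioDef = "n_over_N")
    expect_equal(q2$ratio, 0.5)

    ## zero coverage everywhere: ratio undefined
    x0 <- seTrackModels(0, 0)
    q0 <- quantifyEvents(x0$ev, x0$models, x0$track)
    expect_equal(q0$n, 0)
    expect_true(is.na(q0$ratio))
})

test_that("MXE excludes both tandem exons from the rest set", {
    m <- transcriptModels(
        list(t1 = cbind(c(0, 200, 500), c(100, 300, 600)),
             t2 = cbind(c(0, 350, 500), c(100, 450, 600))), geneId = "g1")
    ev <- enumerateASEvents(m)
    d <- numeric(700)
    d[1:100] <- 60; d[501:600] <- 60     # constitutive
    d[201:300] <- 45                     # first tandem exon (quantified)
    d[351:450] <- 15                     # partner: must not leak into N
    q <- quantifyEvents(ev, m, coverageTrack(list(chr1 = d)))
    expect_equal(q$n, 45)
    expect_equal(q$N, 60)
    expect_identical(q$rest_len, 200L)
})

test_that("events with no rest exons are skipped with a warning", {
    ev <- spliceQuant:::.newEventSet(data.frame(
        event_id = "", etype = "SE", gene_id = "g1", chrom = "chr1",
        strand = "+", a1_start = 100L, a1_end = 200L,
        a2_start = NA_integer_, a2_end = NA_integer_,
        fu_start = 0L, fu_end = 100L, fd_start = 200L, fd_end = 300L,
        host_inc = "t1", host_exc = "t2", acceptor_pos = 100L,
        stringsAsFactors = FALSE))
    m <- transcriptModels(list(t1 = cbind(100L, 200L),
                               t2 = cbind(400L, 500L)), geneId = "g1")
    expect_warning(q <- quantifyEvents(ev, m, flatTrack(600, 10)),
                   "rest-exon")
    expect_true(is.na(q$ratio))
})

test_that("chiSquare2x2 agrees with the closed form and handles degeneracy", {
    expect_equal(chiSquare2x2(50, 50, 50, 50), list(chi2 = 0, pvalue = 1))
    ht <- chiSquare2x2(10, 90, 30, 70)
    expect_equal(ht$chi2, 12.5, tolerance = 1e-12)
    expect_equal(ht$chi2, oracleChi2(10, 90, 30, 70), tolerance = 1e-12)
    expect_equal(ht$pvalue, 4.06952e-4, tolerance = 1e-4)
    ## zero margins carry no evidence
    expect_equal(chiSquare2x2(0, 0, 5, 7), list(chi2 = 0, pvalue = 1))
    expect_equal(chiSquare2x2(0, 5, 0, 7), list(chi2 = 0, pvalue = 1))
    expect_error(chiSquare2x2(-1, 2, 3, 4), "non-negative")
})

test_that("chiSquare2x2 is margin-symmetric and scales linearly", {
    set.seed(42)
    for (i in 1:20) {
        x <- sample(0:200, 4, replace = TRUE)
        base <- chiSquare2x2(x[1], x[2], x[3], x[4])$chi2
        expect_equal(chiSquare2x2(x[3], x[4], x[1], x[2])$chi2, base)
        expect_equal(chiSquare2x2(x[2], x[1], x[4], x[3])$chi2, base)
        expect_equal(chiSquare2x2(3 * x[1], 3 * x[2], 3 * x[3],
                                  3 * x[4])$chi2, 3 * base,
                     tolerance = 1e-12)
    }
    ## p is monotone decreasing in the statistic, with p(0) = 1
    xs <- c(0, 0.5, 1, 2, 5, 10, 25)
    ps <- stats::pchisq(xs, df = 1, lower.tail = FALSE)
    expect_identical(ps[1], 1)
    expect_true(all(diff(ps) < 0))
})

test_that("compareEvent applies both significance filters", {
    mk <- function(n, N) list(n = n, N = N, ratio = n / (n + N))
    ## clearly separated inclusion: significant
    r <- compareEvent(mk(80, 100), mk(20, 100))
    expect_equal(r$chi2, 25, tolerance = 1e-12)
    expect_equal(r$pvalue, 5.73e-7, tolerance = 1e-2)
    expect_equal(r$dratio, 80 / 180 - 20 / 120)
    expect_true(r$significant)
    expect_identical(r$direction, "A")
    ## identical quantifications: not significant
    r0 <- compareEvent(mk(50, 50), mk(50, 50))
    expect_equal(r0$dratio, 0)
    expect_equal(r0$pvalue, 1)
    expect_false(r0$significant)
    ## tiny P but small effect: the ratio-difference filter rejects
    r1 <- compareEvent(mk(500, 500), mk(5000, 7000))
    expect_lt(r1$pvalue, 0.05)
    expect_lt(abs(r1$dratio), 0.1)
    expect_false(r1$significant)
    ## missing ratio: flagged, never significant
    r2 <- compareEvent(mk(0, 0), mk(10, 10))
    expect_true(r2$low_coverage)
    expect_false(r2$significant)
})

test_that("runComparison is deterministic and honours thresholds", {
    x <- seTrackModels(80, 100, "A")
    y <- seTrackModels(20, 100, "B")
    cmp <- runComparison(x$ev, x$models, x$track, y$track)
    expect_identical(nrow(cmp), 1L)
    expect_true(cmp$significant)
    expect_identical(cmp$direction, "A")
    expect_identical(cmp$region, "noncoding")

    ## self-comparison finds nothing
    self <- runComparison(x$ev, x$models, x$track, x$track)
    expect_false(any(self$significant))

    ## empty catalogue gives an empty table with zero summaries
    e0 <- enumerateASEvents(transcriptModels(
        list(t1 = cbind(0L, 100L)), geneId = "g"))
    cmp0 <- runComparison(e0, x$models, x$track, y$track)
    expect_identical(nrow(cmp0), 0L)
    expect_identical(summarizeComparisons(cmp0)$n_significant, 0L)

    ## a stricter P ceiling can veto the same table
    strict <- runComparison(x$ev, x$models, x$track, y$track,
                            thresholds = comparisonThresholds(
                                pMax = 1e-9))
    expect_false(any(strict$significant))

    ## repeated runs are bit-identical
    expect_identical(as.data.frame(cmp),
                     as.data.frame(runComparison(x$ev, x$models,
                                                 x$track, y$track)))
})

test_that("mean-coverage tabulation is conservative under a pipeline null", {
    ## equal inclusion in both conditions: averaging over exons of ~100+
    ## bases shrinks the cell variance far below Poisson, so the false
    ## positive rate must not exceed the nominal level
    dir <- withr::local_tempdir()
    res <- simulateDataset(
        simConfig(seed = 99, nGenes = c(SE = 40, MXE = 0, A5SS = 0,
                                        A3SS = 0), depth = 50,
                  psiA = 0.5, psiB = 0.5,
                  utr = list(nUTR5 = 0, nUTR3 = 0, nBackground = 0)),
        dir)
    m <- readGeneModels(res$gtf)
    ev <- enumerateASEvents(m)
    cmp <- runComparison(ev, m,
                         coverageFromBedgraph(res$coverage[["A"]], "A"),
                         coverageFromBedgraph(res$coverage[["B"]], "B"))
    expect_lte(mean(cmp$pvalue <= 0.1), 0.1)
    expect_false(any(cmp$significant))
})

test_that("Benjamini-Hochberg adjustment is opt-in and conservative", {
    dir <- withr::local_tempdir()
    res <- simulateDataset(
        simConfig(seed = 11, nGenes = c(SE = 4, MXE = 2, A5SS = 2,
                                        A3SS = 2),
                  utr = list(nUTR5 = 0, nUTR3 = 0, nBackground = 0)),
        dir)
    m <- readGeneModels(res$gtf)
    ev <- enumerateASEvents(m)
    ta <- coverageFromBedgraph(res$coverage[["A"]], "A")
    tb <- coverageFromBedgraph(res$coverage[["B"]], "B")
    raw <- runComparison(ev, m, ta, tb)
    bh <- runComparison(ev, m, ta, tb, adjust = "BH")
    expect_true(all(bh$padj >= bh$pvalue - 1e-12))
    expect_true(sum(bh$significant) <= sum(raw$significant))
})
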