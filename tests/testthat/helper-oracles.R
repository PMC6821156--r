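## Independent oracles used by the unit and acceptance tests.  These are
## deliberately written from the definitions themselves (closed forms,
## exhaustive scans), not by calling back into the package internals.

## closed-form 2x2 Pearson statistic: T (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
oracleChi2 <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)   # margins overflow 32-bit ints
    c <- as.numeric(c); d <- as.numeric(d)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
        return(0)
    T <- a + b + c + d
    T * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
}

## upper-tail 1-df chi-squared probability by adaptive quadrature of the
## density (independent of pchisq)
oracleChi2P <- function(x) {
    if (x <= 0) return(1)
    ## roundoff warnings at extreme tail values are expected and benign
    suppressWarnings(stats::integrate(
        function(t) stats::dchisq(t, df = 1), lower = x, upper = Inf,
        rel.tol = 1e-12, abs.tol = 1e-14)$value)
}

## ---- brute-force event enumerator --------------------------------------
## Exhaustively tests every exon / exon pair of every transcript pair
## against the four event definitions and returns a character set of keys
## (etype|affected|flank junctions|strand).  No deduplication shortcuts,
## no early exits.

.bfKey <- function(etype, chrom, a1, a2, juncU, juncD, strand) {
    a2s <- if (is.null(a2)) "." else sprintf("%d-%d", a2[1], a2[2])
    sprintf("%s|%s|%d-%d|%s|%d^%d|%s", etype, chrom, a1[1], a1[2], a2s,
            juncU, juncD, strand)
}

bruteForceEventKeys <- function(models) {
    info <- as.data.frame(txInfo(models))
    keys <- character()
    for (g in unique(info$gene_id)) {
        sub <- info[info$gene_id == g, ]
        if (nrow(sub) < 2) next
        strand <- sub$strand[1]; chrom <- sub$chrom[1]
        mats <- lapply(sub$tx_id, function(t) {
            e <- txExons(models)[[t]]
            cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e))
        })
        exact <- function(m, iv)
            any(m[, 1] == iv[1] & m[, 2] == iv[2])
        nt <- length(mats)
        for (p in seq_len(nt)) for (q in seq_len(nt)) {
            if (p == q) next
            A <- mats[[p]]; B <- mats[[q]]
            ## SE: interior exon of A absent from B, flanks junction-match
            ## a consecutive pair of B
            if (nrow(A) >= 3) for (i in seq(2, nrow(A) - 1)) {
                e <- A[i, ]
                if (exact(B, e)) next
                u <- A[i - 1, ]; d <- A[i + 1, ]
                hit <- FALSE
                if (nrow(B) >= 2) for (j in seq_len(nrow(B) - 1))
                    if (B[j, 2] == u[2] && B[j + 1, 1] == d[1])
                        hit <- TRUE
                if (hit)
                    keys <- c(keys, .bfKey("SE", chrom, e, NULL,
                                           u[2], d[1], strand))
            }
            if (p < q) {
                ## MXE over every interior exon pair
                if (nrow(A) >= 3 && nrow(B) >= 3)
                    for (i in seq(2, nrow(A) - 1))
                        for (j in seq(2, nrow(B) - 1)) {
                            a <- A[i, ]; b <- B[j, ]
                            ok <- A[i - 1, 2] == B[j - 1, 2] &&
                                A[i + 1, 1] == B[j + 1, 1] &&
                                !exact(B, a) && !exact(A, b) &&
                                (a[2] <= b[1] || b[2] <= a[1])
                            if (ok) {
                                first <- if (a[1] < b[1]) a else b
                                second <- if (a[1] < b[1]) b else a
                                keys <- c(keys, .bfKey(
                                    "MXE", chrom, first, second,
                                    A[i - 1, 2], A[i + 1, 1], strand))
                            }
                        }
                ## alternative boundary, genomic right side variable
                for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
                    a <- A[i, ]; b <- B[j, ]
                    if (a[1] == b[1] && a[2] != b[2] &&
                        i < nrow(A) && j < nrow(B) &&
                        A[i + 1, 1] == B[j + 1, 1]) {
                        lo <- min(a[2], b[2]); hi <- max(a[2], b[2])
                        keys <- c(keys, .bfKey(
                            if (strand == "+") "A5SS" else "A3SS",
                            chrom, c(lo, hi), NULL, lo, A[i + 1, 1],
                            strand))
                    }
                    ## genomic left side variable
                    if (a[2] == b[2] && a[1] != b[1] &&
                        i > 1 && j > 1 &&
                        A[i - 1, 2] == B[j - 1, 2]) {
                        lo <- min(a[1], b[1]); hi <- max(a[1], b[1])
                        keys <- c(keys, .bfKey(
                            if (strand == "+") "A3SS" else "A5SS",
                            chrom, c(lo, hi), NULL, A[i - 1, 2], hi,
                            strand))
                    }
                }
            }
        }
    }
    sort(unique(keys))
}

## the same key encoding applied to an ASEventSet, for comparison
eventSetKeys <- function(eventSet) {
    ev <- as.data.frame(eventSet)
    if (!nrow(ev)) return(character())
    sort(unique(vapply(seq_len(nrow(ev)), function(i) {
        a2 <- if (is.na(ev$a2_start[i])) NULL
              else c(ev$a2_start[i], ev$a2_end[i])
        .bfKey(ev$etype[i], ev$chrom[i],
               c(ev$a1_start[i], ev$a1_end[i]), a2,
               ev$fu_end[i], ev$fd_start[i], ev$strand[i])
    }, "")))
}

## ---- brute-force uORF scanner ------------------------------------------
## plain position-by-position triplet scan over every ATG
bruteUORFs <- function(seq, cds = nchar(seq), minCodons = 2) {
    seq <- toupper(seq)
    n <- nchar(seq)
    ch <- strsplit(seq, "")[[1]]
    rows <- list()
    for (s in seq_len(max(n - 2, 0))) {        # 1-based ATG position
        if (paste(ch[s:(s + 2)], collapse = "") != "ATG") next
        if ((s - 1) + 3 > cds) next
        pos <- s + 3                            # 1-based codon start
        term <- FALSE; len <- NA_integer_
        while (pos + 2 <= n) {
            codon <- paste(ch[pos:(pos + 2)], collapse = "")
            if (codon %in% c("TAA", "TAG", "TGA")) {
                if ((pos + 2) <= cds) {
                    term <- TRUE
                    len <- pos + 2 - s + 1
                }
                break
            }
            pos <- pos + 3
        }
        if (term && len < 3 * (minCodons + 1)) next
        rows[[length(rows) + 1]] <-
            data.frame(start_offset = s - 1, length_nt = len,
                       terminated = term)
    }
    if (!length(rows))
        return(data.frame(start_offset = integer(), length_nt = integer(),
                          terminated = logical()))
    do.call(rbind, rows)
}
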