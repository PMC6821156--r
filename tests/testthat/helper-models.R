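## Random toy gene models for property tests: each gene is a master exon
## chain plus 2-3 transcript variants derived by dropping an internal
## exon, substituting a non-overlapping alternative exon, or shifting a
## donor/acceptor boundary.  Draws come from the caller's RNG state.

randomToyModels <- function(nGenes = 20, chrom = "chrT") {
    exl <- list(); gid <- character(); strands <- character()
    for (g in seq_len(nGenes)) {
        strand <- sample(c("+", "-"), 1)
        m <- sample(3:5, 1)
        pos <- sample(0:50, 1)
        chain <- matrix(0L, m, 2)
        for (i in seq_len(m)) {
            pos <- pos + sample(80:200, 1)     # intron
            chain[i, 1] <- pos
            pos <- pos + sample(50:150, 1)     # exon
            chain[i, 2] <- pos
        }
        ntx <- sample(2:3, 1)
        for (t in seq_len(ntx)) {
            ex <- chain
            op <- sample(c("id", "drop", "alt", "right", "left"), 1)
            if (op == "drop") {
                ex <- ex[-sample(2:(m - 1), 1), , drop = FALSE]
            } else if (op == "alt") {
                i <- sample(2:(m - 1), 1)
                room <- ex[i + 1, 1] - ex[i, 2]
                if (room >= 40) {
                    s <- ex[i, 2] + sample(5:10, 1)
                    e <- min(ex[i + 1, 1] - 5L, s + sample(20:60, 1))
                    if (e > s) ex[i, ] <- c(s, e)
                }
            } else if (op == "right") {
                i <- sample(seq_len(m - 1), 1)
                newe <- ex[i, 2] - sample(10:40, 1)
                if (newe > ex[i, 1]) ex[i, 2] <- newe
            } else if (op == "left") {
                i <- sample(2:m, 1)
                news <- ex[i, 1] + sample(10:40, 1)
                if (news < ex[i, 2]) ex[i, 1] <- news
            }
            nm <- sprintf("rg%03d.t%d", g, t)
            exl[[nm]] <- ex
            gid <- c(gid, sprintf("rg%03d", g))
            strands <- c(strands, strand)
        }
    }
    transcriptModels(exl, geneId = gid, chrom = chrom, strand = strands)
}

## minimal cassette gene used in several files: t1 includes exon
## (200,300), t2 skips it
toySEModels <- function(strand = "+", cds = c(NA, NA))
    transcriptModels(list(t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
                          t2 = cbind(c(0, 400), c(100, 500))),
                     geneId = "g1", strand = strand,
                     cdsStart = cds[1], cdsEnd = cds[2])

## deterministic flat-depth track over one chromosome
flatTrack <- function(len, depth, label = "flat", chrom = "chr1")
    coverageTrack(setNames(list(rep(depth, len)), chrom), label)

## write a tiny SAM and convert to an indexed BAM; reads is a data.frame
## with columns pos (1-based), cigar, seq
writeToyBam <- function(reads, chrom = "chr1", chromLen = 1000,
                        dir = tempfile("bam")) {
    dir.create(dir)
    sam <- file.path(dir, "toy.sam")
    lines <- c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen),
               sprintf("r%03d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       seq_len(nrow(reads)), chrom, reads$pos,
                       reads$cigar, reads$seq,
                       strrep("I", nchar(reads$seq))))
    writeLines(lines, sam)
    Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                     indexDestination = TRUE)
}
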