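#' Default planted acceptor motif
#'
#' Per-position nucleotide probabilities over the -35..+5 acceptor window
#' used by the simulator: a polypyrimidine tract (C/T probability 0.85)
#' over -20..-5, a C-biased -3 position, an invariant AG at -2,-1, a
#' G-biased +1, and uniform background elsewhere.
#'
#' @param upstream,downstream window geometry, see [contextWindow()].
#' @param tract C+T probability inside the polypyrimidine tract.
#' @return 4 x width probability matrix (rows A, C, G, T; columns labelled
#'   by window position), each column summing to 1.
#' @export
acceptorMotifDefault <- function(upstream = 33, downstream = 5,
                                 tract = 0.85) {
    win <- contextWindow(upstream, downstream)
    m <- matrix(0.25, 4, win$width,
                dimnames = list(c("A", "C", "G", "T"),
                                as.character(win$positions)))
    pos <- win$positions
    inTract <- pos >= -20 & pos <= -5
    m[, inTract] <- c((1 - tract) / 2, tract / 2, (1 - tract) / 2,
                      tract / 2)
    m[, pos == -3] <- c(0.1, 0.7, 0.1, 0.1)
    m[, pos == -2] <- c(1, 0, 0, 0)
    m[, pos == -1] <- c(0, 0, 1, 0)
    m[, pos == 1] <- c(1, 1, 3, 1) / 6
    m
}

.UTR_DEFAULTS <- list(nUTR5 = 12L, nUTR3 = 3L, nBackground = 10L,
                      lenWithEvents = 528L, lenWithout = 227L,
                      jitter = 40L, altFraction = 0.30,
                      plantUORF = TRUE, uorfCodons = 4L)

#' Simulation configuration constructor
#'
#' Defines the study conditions of the synthetic dataset: a toy plus-strand
#' genome carrying multi-isoform genes of all four event types, planted
#' acceptor motifs, 5'-UTR/3'-UTR event genes and no-event background
#' genes, with two-condition per-base Poisson coverage at known inclusion
#' levels.  Defaults (see the package vignette for rationale): 8 CDS-region
#' genes per event type, 12 5'-UTR and 3 3'-UTR cassette genes, 10
#' background genes; constitutive depth 50; inclusion levels 0.5 (A) vs
#' 0.2 (B); event-bearing transcripts get ~528 nt 5'-UTRs against ~227 nt
#' for background genes, with the alternative exon contributing ~30% of
#' the inclusion-form UTR.
#'
#' @param seed RNG seed; identical configs produce byte-identical output
#'   files.
#' @param nGenes named integer vector: genes per event type
#'   (\code{SE}, \code{MXE}, \code{A5SS}, \code{A3SS}), all CDS-region.
#' @param exonLen,intronLen,extLen sampling ranges (bases) for exon
#'   lengths, intron lengths and A5SS/A3SS extensions.
#' @param depth mean per-base coverage of constitutive exons (reads).
#' @param psiA,psiB inclusion levels in [0, 1]; scalar or one value per
#'   event (recycled over CDS events then UTR events).
#' @param noise intron/background Poisson contamination rate (0 = clean).
#' @param plantMotif 4 x 40 acceptor motif probability matrix, or
#'   \code{NULL} to leave acceptor contexts as random background.
#' @param utr list overriding any of: \code{nUTR5}, \code{nUTR3},
#'   \code{nBackground}, \code{lenWithEvents}, \code{lenWithout},
#'   \code{jitter}, \code{altFraction}, \code{plantUORF},
#'   \code{uorfCodons}.
#' @param bam also emit per-condition BAM files whose coverage equals the
#'   bedGraph tracks exactly.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(seed = 7, depth = 50)
#' @export
simConfig <- function(seed = 1,
                      nGenes = c(SE = 8L, MXE = 8L, A5SS = 8L, A3SS = 8L),
                      exonLen = c(80L, 200L), intronLen = c(150L, 400L),
                      extLen = c(40L, 80L), depth = 50, psiA = 0.5,
                      psiB = 0.2, noise = 0,
                      plantMotif = acceptorMotifDefault(),
                      utr = list(), bam = FALSE) {
    u <- .UTR_DEFAULTS
    if (length(utr)) {
        bad <- setdiff(names(utr), names(u))
        if (length(bad)) stop("unknown utr field(s): ",
                              paste(bad, collapse = ", "))
        u[names(utr)] <- utr
    }
    new("SimConfig", seed = seed,
        nGenes = setNames(as.integer(nGenes), names(nGenes)),
        exonLen = as.integer(exonLen), intronLen = as.integer(intronLen),
        extLen = as.integer(extLen), depth = depth, psiA = psiA,
        psiB = psiB, noise = noise, plantMotif = plantMotif, utr = u,
        bam = bam)
}

## ---- gene plan constructors (all plus strand) -------------------------
## A plan is a list: gene_id, txs (named list of exon matrices), cds
## (c(start, end) or NA), cover (list of c(start, end, kind) with kind
## 1=constitutive, 2=psi, 3=1-psi), introns (matrix), truth fields,
## motifAcc (acceptor to plant, or NA), sanitize (list of regions),
## uorf (c(pos, len) genomic, or NULL), cursorNext.

.rng <- function(rg) if (rg[1] >= rg[2]) rg[1] else
    sample(seq.int(rg[1], rg[2]), 1L)

.planGene <- function(kind, cursor, cfg, gid, psi) {
    exL <- cfg@exonLen; inL <- cfg@intronLen; u <- cfg@utr
    jit <- function(l) l + .rng(c(-u$jitter, u$jitter))
    uw <- if (kind == "BG") jit(u$lenWithout) else jit(u$lenWithEvents)
    gap <- 500L
    p <- list(gene_id = gid, kind = kind, motifAcc = NA_integer_,
              sanitize = list(), uorf = NULL, psi = psi,
              utr_inc = NA_integer_, utr_exc = NA_integer_,
              alt_len = NA_integer_)
    if (kind %in% c("SE", "MXE", "A5SS", "A3SS", "SE3", "BG"))
        uw <- max(uw, 60L)  # CDS start must stay inside the first exon

    if (kind == "SE" || kind == "BG") {
        e1 <- c(cursor, cursor + uw + 60L)
        if (kind == "SE") {
            as <- e1[2] + .rng(inL); ae <- as + .rng(exL)
            e2 <- c(ae + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 100L
            p$txs <- list(t1 = rbind(e1, c(as, ae), e2), t2 = rbind(e1, e2))
            p$cover <- list(c(e1, 1L), c(as, ae, 2L), c(e2, 1L))
            p$introns <- rbind(c(e1[2], as), c(ae, e2[1]))
            p$truth <- list(etype = "SE", a1 = c(as, ae), a2 = NULL,
                            fu = e1, fd = e2, region = "CDS")
            p$motifAcc <- as
        } else {
            e2 <- c(e1[2] + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 100L
            p$txs <- list(t1 = rbind(e1, e2))
            p$cover <- list(c(e1, 1L), c(e2, 1L))
            p$introns <- rbind(c(e1[2], e2[1]))
            p$truth <- NULL
        }
        p$cds <- c(e1[1] + uw, e2[2] - 40L)
        cursor <- e2[2] + gap
    } else if (kind == "MXE") {
        e1 <- c(cursor, cursor + uw + 60L)
        as <- e1[2] + .rng(inL); ae <- as + .rng(exL)
        bs <- ae + .rng(inL); be <- bs + .rng(exL)
        e2 <- c(be + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 100L
        p$txs <- list(t1 = rbind(e1, c(as, ae), e2),
                      t2 = rbind(e1, c(bs, be), e2))
        p$cover <- list(c(e1, 1L), c(as, ae, 2L), c(bs, be, 3L),
                        c(e2, 1L))
        p$introns <- rbind(c(e1[2], as), c(ae, bs), c(be, e2[1]))
        p$truth <- list(etype = "MXE", a1 = c(as, ae), a2 = c(bs, be),
                        fu = e1, fd = e2, region = "CDS")
        p$motifAcc <- as
        p$cds <- c(e1[1] + uw, e2[2] - 40L)
        cursor <- e2[2] + gap
    } else if (kind == "A5SS") {
        s <- cursor; shortE <- s + uw + 60L
        ext <- .rng(cfg@extLen); longE <- shortE + ext
        e2 <- c(longE + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 100L
        p$txs <- list(t1 = rbind(c(s, longE), e2),
                      t2 = rbind(c(s, shortE), e2))
        p$cover <- list(c(s, shortE, 1L), c(shortE, longE, 2L),
                        c(e2, 1L))
        p$introns <- rbind(c(longE, e2[1]))
        p$truth <- list(etype = "A5SS", a1 = c(shortE, longE), a2 = NULL,
                        fu = c(s, shortE), fd = e2, region = "CDS")
        p$cds <- c(s + uw, e2[2] - 40L)
        cursor <- e2[2] + gap
    } else if (kind == "A3SS") {
        e1 <- c(cursor, cursor + uw + 60L)
        sL <- e1[2] + .rng(inL); ext <- .rng(cfg@extLen)
        sS <- sL + ext; e2e <- sS + .rng(exL) + 100L
        p$txs <- list(t1 = rbind(e1, c(sL, e2e)),
                      t2 = rbind(e1, c(sS, e2e)))
        p$cover <- list(c(e1, 1L), c(sL, sS, 2L), c(sS, e2e, 1L))
        p$introns <- rbind(c(e1[2], sL))
        p$truth <- list(etype = "A3SS", a1 = c(sL, sS), a2 = NULL,
                        fu = e1, fd = c(sS, e2e), region = "CDS")
        p$motifAcc <- sL
        p$cds <- c(e1[1] + uw, e2e - 40L)
        cursor <- e2e + gap
    } else if (kind == "SE5") {
        altLen <- as.integer(round(u$altFraction * uw))
        e2utr <- 30L
        e1 <- c(cursor, cursor + uw - altLen - e2utr)
        as <- e1[2] + .rng(inL); ae <- as + altLen
        e2 <- c(ae + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 120L
        e3 <- c(e2[2] + .rng(inL), 0L); e3[2] <- e3[1] + .rng(exL) + 80L
        p$txs <- list(t1 = rbind(e1, c(as, ae), e2, e3),
                      t2 = rbind(e1, e2, e3))
        p$cover <- list(c(e1, 1L), c(as, ae, 2L), c(e2, 1L), c(e3, 1L))
        p$introns <- rbind(c(e1[2], as), c(ae, e2[1]), c(e2[2], e3[1]))
        p$truth <- list(etype = "SE", a1 = c(as, ae), a2 = NULL,
                        fu = e1, fd = e2, region = "5UTR")
        p$motifAcc <- as
        p$cds <- c(e2[1] + e2utr, e3[2] - 40L)
        p$utr_inc <- uw; p$utr_exc <- uw - altLen; p$alt_len <- altLen
        if (isTRUE(u$plantUORF)) {
            ulen <- 3L * (u$uorfCodons + 2L)
            p$uorf <- c(as + 12L, ulen)   # genomic position, length
            p$uorf_offset <- (e1[2] - e1[1]) + 12L  # offset in included UTR
            p$sanitize <- list(e1, c(as, as + 12L),
                               c(as + 12L + ulen, ae),
                               c(e2[1], e2[1] + e2utr))
        } else {
            p$sanitize <- list(e1, c(as, ae), c(e2[1], e2[1] + e2utr))
        }
        p$junctionC <- c(e1[2] - 1L, as, ae - 1L, e2[1])
        cursor <- e3[2] + gap
    } else if (kind == "SE3") {
        e1 <- c(cursor, cursor + uw + 60L)
        e2 <- c(e1[2] + .rng(inL), 0L); e2[2] <- e2[1] + .rng(exL) + 100L
        as <- e2[2] + .rng(inL); ae <- as + .rng(exL)
        e3 <- c(ae + .rng(inL), 0L); e3[2] <- e3[1] + 60L
        p$txs <- list(t1 = rbind(e1, e2, c(as, ae), e3),
                      t2 = rbind(e1, e2, e3))
        p$cover <- list(c(e1, 1L), c(e2, 1L), c(as, ae, 2L), c(e3, 1L))
        p$introns <- rbind(c(e1[2], e2[1]), c(e2[2], as), c(ae, e3[1]))
        p$truth <- list(etype = "SE", a1 = c(as, ae), a2 = NULL,
                        fu = e2, fd = e3, region = "3UTR")
        p$motifAcc <- as
        p$cds <- c(e1[1] + uw, e2[2] - 40L)
        cursor <- e3[2] + gap
    } else stop("unknown gene kind: ", kind)
    p$cursorNext <- cursor
    p
}

.SAFE_CODONS <- c("GCA", "GCC", "CTT", "CCT", "GAA", "CAA")

#' Generate a self-contained synthetic splicing dataset
#'
#' Writes, under \code{outdir}: \code{genome.fa}, \code{annotation.gtf},
#' \code{coverage_A.bedGraph}, \code{coverage_B.bedGraph},
#' \code{truth.tsv} and (optionally) \code{reads_A.bam} /
#' \code{reads_B.bam} with indices.  Coverage over each affected exon is
#' per-base Poisson at \code{psi * depth} (the MXE partner exon at
#' \code{(1 - psi) * depth}), constitutive exons Poisson(\code{depth}),
#' introns 0 (or Poisson(\code{noise})).  Acceptor windows of SE, MXE and
#' A3SS events are drawn from the planted motif.  Identical configs
#' (including seed) produce byte-identical files.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir output directory, created if missing.
#' @return Invisibly, a list with the output paths, the truth
#'   \code{data.frame} and the planned event count.
#' @export
simulateDataset <- function(config, outdir) {
    stopifnot(is(config, "SimConfig"))
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    set.seed(as.integer(config@seed))
    u <- config@utr

    kinds <- c(rep("SE", config@nGenes["SE"]),
               rep("MXE", config@nGenes["MXE"]),
               rep("A5SS", config@nGenes["A5SS"]),
               rep("A3SS", config@nGenes["A3SS"]),
               rep("SE5", u$nUTR5), rep("SE3", u$nUTR3),
               rep("BG", u$nBackground))
    nEvents <- sum(kinds != "BG")
    psiA <- rep_len(config@psiA, nEvents)
    psiB <- rep_len(config@psiB, nEvents)

    plans <- vector("list", length(kinds))
    cursor <- 1000L; ei <- 0L
    for (i in seq_along(kinds)) {
        psi <- if (kinds[i] == "BG") c(NA, NA) else {
            ei <- ei + 1L
            c(psiA[ei], psiB[ei])
        }
        gid <- sprintf("g%04d", i)
        plans[[i]] <- .planGene(kinds[i], cursor, config, gid, psi)
        cursor <- plans[[i]]$cursorNext
    }
    chromLen <- cursor + 600L
    chrom <- "chrS"

    ## genome, planted motifs, UTR sanitation, planted uORFs
    chars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
    motif <- config@plantMotif
    if (!is.null(motif)) {
        up2 <- 35L  # motif window is [acc-35, acc+5)
        for (p in plans) {
            if (is.na(p$motifAcc)) next
            idx <- (p$motifAcc - up2 + 1L):(p$motifAcc + 5L)
            for (k in seq_along(idx))
                chars[idx[k]] <- sample(rownames(motif), 1L,
                                        prob = motif[, k])
        }
    }
    stripATG <- function(region) {
        idx <- (region[1] + 1L):region[2]
        s <- paste(chars[idx], collapse = "")
        while (grepl("ATG", s, fixed = TRUE))
            s <- sub("ATG", "ACG", s, fixed = TRUE)
        chars[idx] <<- strsplit(s, "")[[1]]
    }
    for (p in plans) {
        if (p$kind != "SE5") next
        for (r in p$sanitize) if (r[2] > r[1]) stripATG(r)
        chars[p$junctionC + 1L] <- "C"
        if (!is.null(p$uorf)) {
            body <- sample(.SAFE_CODONS, u$uorfCodons, replace = TRUE)
            useq <- strsplit(paste0("ATG", paste(body, collapse = ""),
                                    "TAA"), "")[[1]]
            chars[(p$uorf[1] + 1L):(p$uorf[1] + p$uorf[2])] <- useq
            ## block a spanning ATG forming across the stop codon's A
            chars[p$uorf[1] + p$uorf[2] + 1L] <- "C"
        }
    }
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- chrom
    genomePath <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(genome, genomePath, width = 70L)

    ## annotation
    exons <- list(); geneId <- character(); cdsS <- integer()
    cdsE <- integer()
    for (p in plans) for (t in names(p$txs)) {
        nm <- paste0(p$gene_id, ".", t)
        m <- p$txs[[t]]
        dimnames(m) <- NULL
        exons[[nm]] <- m
        geneId <- c(geneId, p$gene_id)
        cdsS <- c(cdsS, p$cds[1]); cdsE <- c(cdsE, p$cds[2])
    }
    models <- transcriptModels(exons, geneId = geneId, chrom = chrom,
                               strand = "+", cdsStart = cdsS,
                               cdsEnd = cdsE)
    gtfPath <- file.path(outdir, "annotation.gtf")
    .writeGTF(models, gtfPath)

    ## two-condition coverage
    tracks <- list()
    for (cond in 1:2) {
        d <- integer(chromLen)
        for (p in plans) {
            psi <- p$psi[cond]
            for (cv in p$cover) {
                w <- cv[2] - cv[1]
                lambda <- switch(cv[3], config@depth, psi * config@depth,
                                 (1 - psi) * config@depth)
                d[(cv[1] + 1L):cv[2]] <- stats::rpois(w, lambda)
            }
            if (config@noise > 0 && !is.null(p$introns))
                for (j in seq_len(nrow(p$introns))) {
                    iv <- p$introns[j, ]
                    d[(iv[1] + 1L):iv[2]] <- stats::rpois(iv[2] - iv[1],
                                                          config@noise)
                }
        }
        lab <- c("A", "B")[cond]
        tracks[[lab]] <- list(depth = d,
                              track = coverageTrack(
                                  setNames(list(d), chrom), lab))
    }
    covPaths <- c(A = file.path(outdir, "coverage_A.bedGraph"),
                  B = file.path(outdir, "coverage_B.bedGraph"))
    writeBedgraph(tracks$A$track, covPaths["A"])
    writeBedgraph(tracks$B$track, covPaths["B"])

    ## ground truth
    truth <- do.call(rbind, lapply(plans[kinds != "BG"], function(p) {
        tr <- p$truth
        mx <- !is.null(tr$a2)
        eid <- sprintf("%s:%s:%d-%d%s:%d^%d:+", tr$etype, chrom,
                       tr$a1[1], tr$a1[2],
                       if (mx) sprintf("/%d-%d", tr$a2[1], tr$a2[2])
                       else "",
                       tr$fu[2], tr$fd[1])
        data.frame(event_id = eid, etype = tr$etype,
                   gene_id = p$gene_id, strand = "+",
                   region = tr$region,
                   psi_a = p$psi[1], psi_b = p$psi[2],
                   depth = config@depth,
                   exp_n_a = p$psi[1] * config@depth,
                   exp_N_a = config@depth,
                   exp_n_b = p$psi[2] * config@depth,
                   exp_N_b = config@depth,
                   exp_ratio_a = p$psi[1] / (1 + p$psi[1]),
                   exp_ratio_b = p$psi[2] / (1 + p$psi[2]),
                   utr_len_included = p$utr_inc,
                   utr_len_excluded = p$utr_exc,
                   alt_exon_len = p$alt_len,
                   uorf_start = if (is.null(p$uorf)) NA_integer_
                                else p$uorf_offset,
                   uorf_len = if (is.null(p$uorf)) NA_integer_
                              else p$uorf[2],
                   stringsAsFactors = FALSE)
    }))
    truthPath <- file.path(outdir, "truth.tsv")
    writeTruth(truth, truthPath)

    bamPaths <- NULL
    if (isTRUE(config@bam)) {
        bamPaths <- c(A = file.path(outdir, "reads_A.bam"),
                      B = file.path(outdir, "reads_B.bam"))
        .emitBam(tracks$A$depth, chars, chrom, bamPaths["A"])
        .emitBam(tracks$B$depth, chars, chrom, bamPaths["B"])
    }

    invisible(list(dir = outdir, genome = genomePath, gtf = gtfPath,
                   coverage = covPaths, truth_path = truthPath,
                   truth = truth, bam = bamPaths, n_events = nEvents))
}

## GTF writer: exon features plus per-exon CDS pieces; the rtracklayer
## "##date" comment is stripped so identical configs give identical bytes
.writeGTF <- function(models, path) {
    info <- txInfo(models)
    nEx <- lengths(txExons(models))
    ue <- unlist(txExons(models), use.names = FALSE)
    i <- rep.int(seq_len(nrow(info)), nEx)     # txInfo row per exon
    s0 <- GenomicRanges::start(ue) - 1L
    e0 <- GenomicRanges::end(ue)
    ## per-exon CDS pieces clipped to the transcript CDS bounds
    cs <- info$cds_start[i]; ce <- info$cds_end[i]
    cls <- pmax(s0, cs); cle <- pmin(e0, ce)
    keep <- !is.na(cs) & cls < cle
    df <- data.frame(
        chrom = c(as.character(info$chrom[i]),
                  as.character(info$chrom[i[keep]])),
        start = c(s0 + 1L, cls[keep] + 1L),
        end = c(e0, cle[keep]),
        strand = c(as.character(info$strand[i]),
                   as.character(info$strand[i[keep]])),
        type = rep(c("exon", "CDS"), c(length(i), sum(keep))),
        tx = c(as.character(info$tx_id[i]),
               as.character(info$tx_id[i[keep]])),
        gene = c(as.character(info$gene_id[i]),
                 as.character(info$gene_id[i[keep]])),
        stringsAsFactors = FALSE)
    df <- df[order(df$tx, df$type == "CDS", df$start), ]
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                  type = df$type, gene_id = df$gene,
                  transcript_id = df$tx)
    suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
    lines <- readLines(path)
    writeLines(lines[!startsWith(lines, "##date")], path)
    invisible(path)
}

## Emit a BAM whose per-base coverage equals `depth` exactly: the depth
## field is peeled into layers of maximal positive runs, each layer run
## becoming one perfect-match read.
.emitBam <- function(depth, chars, chrom, bamPath) {
    reads <- list(); k <- 0L
    d <- depth
    while (any(d > 0L)) {
        r <- rle(d > 0L)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
            k <- k + 1L
            reads[[k]] <- c(starts[j], ends[j])
        }
        d <- pmax(d - 1L, 0L)
    }
    sam <- tempfile(fileext = ".sam")
    con <- file(sam, "wt")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(depth))), con)
    for (j in seq_along(reads)) {
        s <- reads[[j]][1]; e <- reads[[j]][2]
        seq <- paste(chars[s:e], collapse = "")
        writeLines(sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                           j, chrom, s, e - s + 1L, seq,
                           strrep("I", e - s + 1L)), con)
    }
    close(con)
    dest <- sub("\\.bam$", "", bamPath)
    Rsamtools::asBam(sam, dest, overwrite = TRUE,
                     indexDestination = TRUE)
    unlink(sam)
    invisible(bamPath)
}

#' Write / read simulator ground truth
#'
#' Plain TSV round trip of the truth table emitted by
#' [simulateDataset()].
#'
#' @param truth a truth \code{data.frame}.
#' @param path TSV path.
#' @export
writeTruth <- function(truth, path) {
    out <- truth
    for (col in colnames(out))   # full double precision survives the trip
        if (is.double(out[[col]]))
            out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                                 sprintf("%.17g", out[[col]]))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    for (col in c("psi_a", "psi_b", "depth", "exp_n_a", "exp_N_a",
                  "exp_n_b", "exp_N_b", "exp_ratio_a", "exp_ratio_b"))
        if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
    for (col in c("utr_len_included", "utr_len_excluded", "alt_exon_len",
                  "uorf_start", "uorf_len"))
        if (col %in% colnames(df)) df[[col]] <- as.integer(df[[col]])
    df
}
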