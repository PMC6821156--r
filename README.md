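# spliceQuant

Differential alternative splicing from RNA-seq coverage, for analysts
who want a transparent, annotation-driven alternative to read-level
isoform deconvolution: every call traces back to two mean coverages
and one 2x2 table.

## The method

Candidate events of the four classical types — skipped exon (SE),
mutually exclusive exons (MXE), alternative 5′ and 3′ splice sites
(A5SS/A3SS) — are catalogued by pairwise transcript comparison on a
GTF annotation, matching exact splice-junction coordinates. Each
event in each condition is summarized by

- *n* — mean per-base read coverage of the affected exon,
- *N* — mean coverage of the remaining exons of its transcript,
- inclusion ratio *r* = *n*/(*n*+*N*); under inclusion level ψ and
  constitutive depth *d*, E[*r*] ≈ ψ/(1+ψ).

Two conditions are compared per event with a canonical 2x2 Pearson
chi-squared test (1 df, no continuity correction) on the table
[[*n*_A, *N*_A], [*n*_B, *N*_B]] of rounded coverages. An event is
called significant when **P ≤ 0.1 and |Δr| > 0.1** (both
thresholds configurable; Benjamini–Hochberg adjustment optional).

Around the core: strand-aware −35..+5 acceptor-context matrices with
the certainty transform clamp(log10(100·f/2.4), 0, 1.5), 5′-UTR
isoform reconstruction with uORF scanning, and a seeded simulator
(genome FASTA, GTF, two-condition bedGraph/BAM coverage with known ψ)
that makes the whole pipeline testable offline. See the vignette
`vignettes/splicing-quantitation.Rmd` for the model, parameter
rationale and limitations.

## Worked example

```r
library(spliceQuant)

dir <- tempfile()
res <- simulateDataset(simConfig(seed = 1), dir)   # default conditions
models <- readGeneModels(res$gtf)
ev <- enumerateASEvents(models)
ev
#> ASEventSet with 47 events
#>   SE: 23  MXE: 8  A5SS: 8  A3SS: 8
#>   47 genes

cmp <- runComparison(ev, models,
                     coverageFromBedgraph(res$coverage[["A"]], "A"),
                     coverageFromBedgraph(res$coverage[["B"]], "B"))
summarizeComparisons(cmp)$n_significant
#> [1] 47
head(as.data.frame(cmp)[, c("event_id", "ratio_a", "ratio_b",
                            "pvalue", "dratio", "significant")], 1)
#>                              event_id   ratio_a   ratio_b     pvalue
#> 1 A3SS:chrS:50023-50080:49647^50080:+ 0.3286714 0.1636927 0.03701989
#>      dratio significant
#> 1 0.1649787        TRUE
```

All 47 simulated events carry a true inclusion shift (ψ 0.5 vs 0.2),
and all pass the filters; the estimated ratios sit at the closed-form
expectations 0.5/1.5 ≈ 0.333 and 0.2/1.2 ≈ 0.167. The same pipeline
runs from the shell:

```sh
Rscript inst/cli/splicequant all --gtf annotation.gtf --genome genome.fa \
    --cov-a coverage_A.bedGraph --cov-b coverage_B.bedGraph --outdir out/
```

writing `events.bed`/`events.tsv`, `comparison.tsv`, `summary.tsv`,
acceptor-logo TSVs and the 5′-UTR/uORF report, deterministically.

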