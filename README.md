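# exon5uc

Classification and splicing analysis of internal exons that carry the
translation initiation site.

## The problem

Internal (neither first nor last) exons of protein-coding genes can be
partitioned by their coding composition: exons entirely within the 5′UTR
(Type 1), exons spanning the 5′UTR–CDS boundary — i.e. containing the start
codon — (**5UC**, Type 2), exons fully inside the CDS (Type 3), exons
spanning the CDS–3′UTR boundary (Type 4), and exons entirely within the
3′UTR (Type 5). A surprising subset of the 5UC exons are *cassette exons*
(alternatively skipped exons, ASEs): their skipping deletes the start codon
and converts the mRNA into an untranslatable isoform, so **5UC-ASEs** act
as a post-transcriptional off-switch for protein output. Splicing of these
exons is repressed by RNA-binding proteins (RBPs) such as MATR3 that bind
the upstream intron, and it is distinctly regulated in brain, muscle and
testis.

`exon5uc` implements the complete computational workflow for studying this
exon class, for R users working with GENCODE/Ensembl annotations, GTEx-style
junction counts, and eCLIP-style coverage tracks:

* **Classification** — unique internal exons of protein-coding genes are
  assigned a coding type (Types 1–5) and a splice class (constitutive,
  ASE, splice-site-shifted/SSE, other alternative), with explicit audit
  flags for every ambiguous case.
* **Exon features** — per-type length distributions and in-frame codon
  usage (the 5UC class stands out by its large median length and its
  methionine codon).
* **Splicing quantification** — SUPPA-style skipped-exon (SE) events and
  junction-read PSI:

  `PSI = (u + d) / (u + d + 2 s)`

  where `u`, `d`, `s` are upstream-inclusion, downstream-inclusion and
  skipping junction reads (an included transcript spans two junctions, a
  skipping transcript one — hence the factor 2), with a read-total
  threshold (`u + d + s > 50`) below which PSI is `NA`. Tissue matrices,
  tissue-ΔPSI (deviation from the cross-tissue median), moderate-PSI
  fractions (0.3 < PSI < 0.75) and two-condition ΔPSI groups
  (ΔPSI ≥ 0.2 / ≤ −0.2) build on it.
* **Coverage comparison** — strand-aware meta-coverage matrices
  (500 nt upstream / length-scaled body / 500 nt downstream at 10 nt bins),
  region-wise enrichment volcanoes (median fold-change + exact Wilcoxon
  signed-rank p, cut-off log₂FC > 0.4 and −log₁₀p > 6), and Steel–Dwass
  all-pairs comparison of upstream binding across ΔPSI groups.
* **Evolution** — per-species 5UC-ASE counts, ortholog-sharing
  (symmetrised Jaccard) distances between species gene sets, and Ward
  dendrograms with Newick export.
* **Synthetic data** — a fully seeded generator that emits annotation
  (GTF + FASTA), junction counts (GCT), coverage (bedGraph), knockdown TPM
  tables and species gene sets with planted ground truth, so the entire
  pipeline is testable without external downloads.

## Worked example

```r
library(exon5uc)

cfg <- sim_config(seed = 42, quotas = c("TYPE2_5UC:ASE" = 8,
                                        "TYPE3_CDS:ASE" = 8,
                                        "TYPE3_CDS:CONSTITUTIVE" = 4))
sim <- simulate_annotation(cfg, out_dir = "demo")
cls <- classify_all(sim$models)
cls$summary
#>   coding_type total ase sse other_alt constitutive
#> 1  TYPE1_5UTR     0   0   0         0            0
#> 2   TYPE2_5UC     8   8   0         0            0
#> 3   TYPE3_CDS    12   8   0         0            4
#> 4   TYPE4_C3U     0   0   0         0            0
#> 5  TYPE5_3UTR     0   0   0         0            0
```

The summary reproduces the planted design exactly: eight 5UC cassette
exons, eight CDS-internal cassette exons, four constitutive CDS exons.
Junction-based PSI per tissue (rows are SE event ids, low values = mostly
skipped):

```r
ev  <- generate_se_events(sim$models, cls$exons)
jc  <- simulate_junction_counts(sim$events, cfg)
psi <- event_psi_matrix(ev, jc$counts)
round(tissue_psi_matrix(psi, jc$samples)[1:3, 1:4], 3)
#>                                          tissue01 tissue02 tissue03 tissue04
#> SYNG0001;SE:chrS01:833-1834:1992-2993:+     0.206     0.00    0.189    0.046
#> SYNG0002;SE:chrS01:4003-5004:5315-6316:-    0.130     0.00    0.000    0.068
#> SYNG0003;SE:chrS01:7182-8183:8342-9343:-    0.122     0.03    0.123    0.104

compute_psi(u = 30, d = 30, s = 10)   # direct use of the PSI formula
#> [1] 0.75
```

RBP binding around the 5UC cassette set versus the CDS-internal cassette
background (the generator plants upstream binding on the 5UC set):

```r
trk <- simulate_coverage(sim$truth, cfg)
t2 <- subset(sim$truth, coding_type == "TYPE2_5UC")
t3 <- subset(sim$truth, coding_type == "TYPE3_CDS" & splice_class == "ASE")
mk <- function(s) data.frame(chrom = s$chrom, start = s$start,
                             end = s$end, strand = s$strand)
volcano_table(build_coverage_matrix(trk, mk(t2)),
              build_coverage_matrix(trk, mk(t3)), "RBP")
#>   factor     region     log2_fc      p_value neg_log10_p n_bins passes_cutoff
#> 1    RBP   UPSTREAM  0.46646739 1.054209e-09  8.97707310     50          TRUE
#> 2    RBP       EXON -0.12593811 2.324219e-01  0.63372300     10         FALSE
#> 3    RBP DOWNSTREAM -0.03206512 8.506593e-01  0.07024436     50         FALSE
```

Only the upstream region clears the volcano cut-off — the planted
(MATR3-like) upstream-intron binding signature.

Real data drop in at the same boundaries: `read_gtf()` +
`filter_swissprot()` for GENCODE annotations, `read_junction_gct()` for
GTEx junction tables, `read_bedgraph()` for coverage tracks converted from
eCLIP BAMs, and `run_full(run_config(...))` to orchestrate every stage.

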