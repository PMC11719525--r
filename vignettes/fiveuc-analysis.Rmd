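---
title: "Classifying and quantifying start-codon-containing cassette exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and quantifying start-codon-containing cassette exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: what each stage
computes, which conventions were chosen where the underlying definitions
are genuinely open, and what the synthetic benchmarks do and do not
demonstrate.

## Exon classification

All interval arithmetic is done on 0-based half-open coordinates; the GTF
reader/writer converts at the boundary, so no internal step carries an
off-by-one correction. A *unique internal exon* is a deduplicated
(chrom, start, end, strand) interval that is neither first nor last in at
least one transcript with ≥ 3 exons. Exons that are internal in one
isoform but terminal in another are included and flagged
`mixed_terminal`; the alternative (exclusion) would silently shrink the
exon universe in heavily annotated genes.

**Coding type.** Within each coding containing transcript, the exon is
compared against the CDS span in transcript orientation: entirely 5′ of
the CDS → Type 1; containing the CDS start strictly inside → Type 2 (5UC);
inside the CDS → Type 3; containing the CDS end strictly inside → Type 4;
entirely 3′ → Type 5. Two conventions close the gaps the definition leaves
open:

* an exon containing *both* CDS ends is called Type 2 and flagged
  `both_cds_ends` — the initiation site is the feature of interest, and
  such single-exon-CDS cases are rare;
* when coding isoforms disagree (e.g. an alternative start codon makes an
  exon 5UC in one isoform and fully coding in another), the fixed priority
  Type 2 > Type 4 > Type 1 > Type 5 > Type 3 decides and the exon is
  flagged `type_conflict`. The priority prefers boundary-containing calls
  because they are the informative ones; the flag keeps every such
  resolution auditable.

Exons contained only in non-coding isoforms of a coding gene have no
UTR/CDS composition; they are excluded from the typed table and reported
in a separate audit list rather than dropped silently.

**Splice class.** *Covering* transcripts are those whose genomic span
contains the exon — the natural reading of "isoforms covering the exon
region". The rules apply in order: exact presence in all covering
isoforms → constitutive; an overlapping exon with a different 5′ or 3′
*splice-site* boundary in any covering isoform → SSE; complete absence
from some covering isoform → ASE (cassette exon); otherwise → other
alternative. Two details matter:

* SSE is tested before ASE, so a boundary-variant exon that is also
  skipped in a third isoform counts once, as SSE — the count table must
  partition, and boundary variation is the more specific signal;
* a differing boundary only counts toward SSE when it is a genuine splice
  site of the overlapping exon. The outermost boundaries of a transcript
  are its TSS and polyA end, not splice sites; overlaps that differ only
  at such terminal boundaries fall through to the "other alternative"
  class. Without this refinement the rule system has no reachable "other"
  state at all, while with it the class captures exactly the
  alternative-terminal-exon overlaps it is meant to describe.

## Exon features

Length summaries use `end − start` with standard quartiles and 1.5 × IQR
whiskers. Codon usage is counted per coding type from a representative
containing transcript (longest annotated CDS, ties broken
lexicographically — deterministic and biased toward the principal ORF).
The reading frame of an exon's CDS portion is derived from the cumulative
CDS length upstream of the exon in that transcript; only complete codons
whose three bases lie inside the exon are counted, because codons split
across junctions cannot be attributed to a single exon without double
counting. Frequencies are normalised over the pooled codon count of each
type (per-exon normalisation would overweight short exons). Sequence
comes from a genome FASTA; length statistics never require sequence.

## Splicing quantification

Skipped-exon events follow the SUPPA SE convention: one event per
(gene, skipped exon, flank pair) with an isoform joining the flanks
directly, identical donor and acceptor required. Junction PSI is

\[ \psi = \frac{u + d}{u + d + 2s} \]

with the factor 2 reflecting that an included transcript contributes two
junction reads where a skipping transcript contributes one. The read
threshold is interpreted as the *unweighted* total `u + d + s > 50`
(`min_total` is a parameter): the threshold is about evidence, and raw
read counts are the evidence. Per-tissue PSI is the median over the
tissue's samples — robust to depth outliers; the aggregation is a
convention, not a derived quantity. Tissue-ΔPSI subtracts the per-event
median across tissues; events with fewer than three informative tissues
are excluded as uninformative about deviation. The moderate band
(0.3, 0.75) is open on both sides, and the two-condition ΔPSI bands
(± 0.2) are closed, both matching their stated definitions; band
comparisons carry a 1e-9 guard so a difference that is exactly ± 0.2 up to
floating-point representation lands on the inclusive side.

Two-condition ΔPSI is a point estimate from TPM-based PSIs; an empirical
significance calibration for ΔPSI is deliberately out of scope.

## Coverage comparison

Meta-coverage matrices use 500 nt upstream, a body rescaled to 100 nt and
500 nt downstream at 10 nt bins (110 columns), oriented 5′→3′ so that
minus-strand rows are column-reversed after assembly; all-zero rows are
dropped (skip-zeros semantics, applied after orientation). Body rescaling
assigns each base to `floor(pos · 10 / L)` and averages — exact for the
uniform tracks used in validation and within half a bin otherwise.

Region enrichment collapses each matrix to its per-bin median profile
within the region, pairs the two profiles by bin, and reports
`log2(median of per-bin ratios)` (zero-denominator bins excluded; the
ratio-of-medians alternative is available behind a flag) with an exact
Wilcoxon signed-rank p-value on the paired profiles. The volcano cut-off
is log₂FC > 0.4 with −log₁₀p > 6, the y-axis being −log₁₀p.

The signed-rank test computes the exact null distribution by convolution
over ranks — mathematically identical to enumerating all \(2^n\) sign
assignments — whenever `n ≤ 25` and the absolute differences are untied,
and otherwise falls back to a normal approximation with tie-corrected
variance and continuity correction; the output records which path ran.
The two-sided exact p is \(P(|W - \mu| \ge |w - \mu|)\), which equals the
doubled smaller tail under the symmetric null.

The Steel–Dwass all-pairs procedure midranks each pooled pair,
standardises the rank sum with the tie-corrected two-sample variance, and
refers \(|t|\sqrt{2}\) to the studentized range with `k` groups and
infinite degrees of freedom. With two groups this reduces exactly to the
two-sample rank-sum normal approximation, which the tests verify. Exact
small-sample permutation is out of scope.

For the ΔPSI-group comparison of upstream binding, each exon's upstream
window is re-binned to 50 nt bins and the *pooled* exon × bin values form
each group's sample; per-bin group medians are returned separately for
profile plots. Using the ten per-bin medians themselves as the test
sample was considered and rejected: with three groups and ten values per
group the studentized-range tail cannot reach the significance levels the
comparison is meant to resolve (the best attainable p is ≈ 5 × 10⁻⁴), so
the medians are a visualisation, not a test sample.

## Evolutionary comparison

Per-species counts run the same classifier and event generator on each
annotation. The round-robin species comparison uses a symmetrised
Jaccard distance: `shared(A,B)` counts genes in A's 5UC-ASE set with an
ortholog in B's set, the two directions are averaged, and
`d = 1 − shared/(|A| + |B| − shared)`. Raw shared counts are returned
alongside so any alternative metric can be recomputed. Clustering is
Ward's minimum-variance method on the squared-distance (ward.D2)
convention with Newick export.

A structural caveat, verified on exact expected distances: Ward's merge
cost carries a cluster-size factor \(\sqrt{2 n_A n_B / (n_A + n_B)}\), so
on ladder-like (caterpillar) topologies the next singleton outgroup can
be cheaper to merge with another singleton than with the large true
clade. A Ward dendrogram therefore cannot represent successive-outgroup
phylogenies even without sampling noise, and topology-recovery benchmarks
in this package use balanced planted trees (`balanced_species_tree()`);
the realistic vertebrate ladder remains the default generator tree and
documents this limitation of dendrogram-based phylogenetics.

## The synthetic-data generator

The generator is first-class, tested code. Design choices, fixed once:

* **Templates.** Each gene is a 3-exon template whose middle exon is the
  planted unique internal exon; cassette genes add a skipping isoform,
  SSE genes a 5′-extended variant (planting a second SSE exon), "other"
  genes an isoform terminating inside the downstream intron. Introns are
  1000 nt so the full 500 nt flanking windows stay intragenic.
* **Lengths.** Planted exon lengths are log-normal with medians 161 nt
  (5UC) and 122 nt (other types) — the observed medians of the real exon
  landscape — and sdlog 0.35. At these spreads the median of 500 drawn
  5UC exons has a sampling s.e. of ≈ 3 nt, which is what the recovery
  tolerances in the tests reflect.
* **Junction counts.** Reads are drawn per event and sample as
  \((u, d, s) \sim \text{Multinomial}(n;\ \pi, \pi, 1-\pi)\) normalised,
  with \(n \sim \text{Poisson}(\text{depth})\), depth 200 by default, so
  the doubled-skip-read estimator is unbiased for the transcript-level
  inclusion \(\pi\) — the sampling model is chosen to be consistent with
  the estimator's own junction-count logic.
* **Inclusion landscape.** Event-level \(\pi\) is bimodal (peaks near 0
  and 1) with a planted 15% moderate fraction; 30 tissues, of which the
  first three are "divergent" (inclusion shifts with s.d. 0.15 vs 0.02),
  emulating the brain/muscle/testis pattern; 5 samples per tissue.
* **Binding and knockdown.** A configurable fraction (default 0.5) of the
  5UC cassette exons is bound; bound exons skew to low inclusion (a
  repressor's targets) while keeping the 15% moderate share, and their
  upstream window (500 nt, fold 2 by default over a Poisson background of
  5 per 10 nt bin) is enriched. Knockdown raises bound events' inclusion
  by 0.3; 10% of unbound events respond in the opposite direction,
  emulating indirect effects and populating the DOWN group.
* **Species sets.** An ancestral pool of 300 genes evolves down the
  planted tree; survival per branch is
  \((1-\text{loss})^{\text{branch length}}\) on clock-scaled ultrametric
  trees, so ortholog sharing decays with divergence time. Ortholog maps
  are identity on shared ancestral genes.
* **Determinism.** Every artifact draws from its own RNG stream derived
  from the master seed by a fixed label; adding artifacts never perturbs
  existing ones, and fixed seeds give byte-identical files.

**What passing tests show — and what they do not.** The generator
produces clean annotations (no overlapping genes, no chained
multi-isoform complexity beyond the templates), junction counts without
mapping bias, coverage without crosslink-site artefacts, and identity
orthology without paralog ambiguity. Recovery on these inputs validates
the *implementations* — the classifier's rule system, the estimator's
arithmetic, the tests' distributions, the clustering — not the biological
fidelity of any real dataset. Real-annotation idiosyncrasies (fragment
isoforms, non-canonical biotypes, chromosome naming) and real-signal
noise structure are exercised only at the format level.

## Problem sizes

The shipped test and acceptance runs use scaled-down sizes chosen to keep
statistical claims meaningful at interactive runtimes: 200 genes
(10 per type × class cell) for classification recovery, 300 exons per set
and 50 replicates for enrichment detection at the volcano cut-off,
1000 random cases for the exact-test enumeration check, 100 seeds for
species-tree recovery, and a 1:100 scaling of the published count table
for the synthetic study in `scripts/acceptance.R`.

## Known limitations

* SSE detection is boundary-based and does not model coordinated 5′/3′
  shifts as separate sub-classes.
* TPM-based ΔPSI carries no significance calibration by design.
* The Steel–Dwass implementation targets the asymptotic studentized-range
  reference; very small groups (n < ~8 per group) are better served by
  exact permutation, which is not provided.
* bigWig input is not read natively; tracks are consumed as bedGraph.
* Ward dendrograms on ortholog-sharing distances are a grouping device,
  not a consistent phylogeny estimator (see above); for additive-tree
  reconstruction use neighbour-joining on the same distance matrix.
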