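# Shared fixtures, built once per test run.

# default-condition synthetic study: 10 genes in each (type, class) cell
SIM_CFG <- sim_config(seed = 101L)
SIM <- simulate_annotation(SIM_CFG)

# build a gene_models object from a compact transcript spec:
# list(T1 = list(gene = "G1", chrom = "chr1", strand = "+",
#                exons = list(c(0, 100), ...), cds = list(c(50, 100), ...)))
toy_models <- function(spec) {
  ex <- list(); cds <- list(); tr <- list()
  for (tid in names(spec)) {
    s <- spec[[tid]]
    for (e in s$exons) {
      ex[[length(ex) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = s$gene, chrom = s$chrom,
        start = e[1], end = e[2], strand = s$strand)
    }
    for (cc in s$cds %||% list()) {
      cds[[length(cds) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = s$gene, chrom = s$chrom,
        start = cc[1], end = cc[2], strand = s$strand)
    }
    tr[[length(tr) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = s$gene,
      coding = length(s$cds %||% list()) > 0)
  }
  exd <- do.call(rbind, ex)
  exd <- exd[order(exd$transcript_id, exd$start), ]
  exd$exon_rank <- stats::ave(
    exd$start, exd$transcript_id,
    FUN = function(v) seq_along(v))
  # rank in transcript orientation
  for (tid in unique(exd$transcript_id)) {
    sel <- exd$transcript_id == tid
    if (exd$strand[sel][1] == "-") {
      exd$exon_rank[sel] <- rev(seq_len(sum(sel)))
    }
  }
  genes <- unique(exd[, c("gene_id", "chrom", "strand")])
  genes$gene_name <- genes$gene_id
  genes$swissprot_validated <- FALSE
  cdd <- if (length(cds)) do.call(rbind, cds) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  gene_models(genes, do.call(rbind, tr), exd, cdd)
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "exon5uc")
  if (nzchar(p)) p else file.path("../../inst/extdata", f)
}
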