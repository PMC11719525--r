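#' Gene-model container
#'
#' Internal representation of a parsed annotation: four linked tables, all
#' coordinates 0-based half-open (conversion from the GTF's 1-based inclusive
#' convention happens at the I/O boundary, so interval arithmetic inside the
#' package never needs off-by-one corrections).
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `swissprot_validated`.
#' @param transcripts data.frame with `transcript_id`, `gene_id`, `coding`.
#' @param exons data.frame with `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `exon_rank` (1 = 5'-most exon in transcript orientation).
#' @param cds like `exons` without `exon_rank`; empty for non-coding isoforms.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons, cds) {
  obj <- structure(
    list(
      genes = data.table::as.data.table(genes),
      transcripts = data.table::as.data.table(transcripts),
      exons = data.table::as.data.table(exons),
      cds = data.table::as.data.table(cds)
    ),
    class = "gene_models"
  )
  validate_gene_models(obj)
  obj
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes, %d transcripts (%d coding), %d exon records\n",
    nrow(x$genes), nrow(x$transcripts), sum(x$transcripts$coding),
    nrow(x$exons)
  ))
  invisible(x)
}

validate_gene_models <- function(obj) {
  ex <- obj$exons
  if (nrow(ex)) {
    bad <- ex$start >= ex$end
    if (any(bad)) {
      stopf("invalid exon interval (start >= end) in transcript %s",
            ex$transcript_id[which(bad)[1]])
    }
    # exons of a transcript must not overlap each other
    data.table::setorder(ex, transcript_id, start)
    ov <- ex[, any(start[-1] < end[-.N]), by = "transcript_id"]
    if (nrow(ov) && any(ov$V1)) {
      stopf("overlapping exons in transcript %s",
            ov$transcript_id[which(ov$V1)[1]])
    }
  }
  cds <- obj$cds
  if (nrow(cds)) {
    # every CDS segment must lie inside exactly one exon of its transcript
    hit <- cds[ex, on = c("transcript_id"), allow.cartesian = TRUE,
               nomatch = 0L][start >= i.start & end <= i.end]
    n_hit <- hit[, .N, by = c("transcript_id", "start", "end")]
    chk <- cds[, .(transcript_id, start, end)]
    miss <- chk[!n_hit, on = c("transcript_id", "start", "end")]
    if (nrow(miss)) {
      stopf("CDS segment not contained in any exon of transcript %s",
            miss$transcript_id[1])
    }
  }
  invisible(TRUE)
}

#' Read a GTF gene annotation into a gene-model set
#'
#' Parses a GENCODE- or Ensembl-dialect GTF, keeping protein-coding genes
#' only. When any transcript carries a `tag "basic"` attribute, the basic
#' transcript set is used; otherwise all transcripts are kept. Coordinates
#' are converted to 0-based half-open and exons are ranked 5' to 3' in
#' transcript orientation.
#'
#' Repeated `tag` attributes on one row defeat generic attribute parsers
#' (only the last value survives), so basic-tag membership is recovered by a
#' direct scan of the attribute column.
#'
#' @param path GTF file path.
#' @param dialect `"auto"` (default) detects `gene_type` (GENCODE) vs
#'   `gene_biotype` (Ensembl); or force one.
#' @return a [gene_models] object.
#' @export
read_gtf <- function(path, dialect = c("auto", "gencode", "ensembl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("GTF file not found: %s", path)

  raw <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                           col.names = paste0("V", 1:9), fill = TRUE,
                           skip = "\t")
  if (!nrow(raw)) stopf("empty GTF: %s", path)
  bad <- which(!is.na(raw$V4) & !is.na(raw$V5) & raw$V5 < raw$V4)
  if (length(bad)) {
    stopf("GTF parse error at line %d: end (%s) < start (%s)",
          bad[1], raw$V5[bad[1]], raw$V4[bad[1]])
  }
  need_attr <- raw$V3 %in% c("exon", "CDS")
  no_tid <- need_attr & !grepl("transcript_id", raw$V9, fixed = TRUE)
  no_gid <- need_attr & !grepl("gene_id", raw$V9, fixed = TRUE)
  if (any(no_tid | no_gid)) {
    stopf("GTF parse error at line %d: malformed attribute string (missing %s)",
          which(no_tid | no_gid)[1],
          if (any(no_tid)) "transcript_id" else "gene_id")
  }

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  biotype_col <- if (dialect == "gencode") "gene_type"
    else if (dialect == "ensembl") "gene_biotype"
    else intersect(c("gene_type", "gene_biotype"), colnames(mc))[1]
  if (is.na(biotype_col) || is.null(biotype_col) ||
      !biotype_col %in% colnames(mc)) {
    stopf("GTF has neither gene_type nor gene_biotype attributes")
  }

  df <- data.table::data.table(
    type = as.character(mc$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(mc$gene_id),
    transcript_id = if ("transcript_id" %in% colnames(mc))
      as.character(mc$transcript_id) else NA_character_,
    biotype = as.character(mc[[biotype_col]]),
    gene_name = if ("gene_name" %in% colnames(mc))
      as.character(mc$gene_name) else NA_character_
  )

  pc_genes <- unique(df[type == "gene" & biotype == "protein_coding", gene_id])
  if (!length(pc_genes)) {
    # annotation without gene-level rows: fall back to transcript/exon biotype
    pc_genes <- unique(df[biotype == "protein_coding" & !is.na(gene_id),
                          gene_id])
  }
  df <- df[gene_id %in% pc_genes & strand %in% c("+", "-")]

  # basic-tag transcript set, recovered from the raw attribute column
  basic_tids <- character(0)
  has_basic <- grepl('tag "basic"', raw$V9, fixed = TRUE)
  if (any(has_basic)) {
    basic_tids <- unique(sub('.*transcript_id "([^"]+)".*', "\\1",
                             raw$V9[has_basic & grepl("transcript_id",
                                                      raw$V9, fixed = TRUE)]))
  }

  ex <- df[type == "exon" & !is.na(transcript_id)]
  cds <- df[type == "CDS" & !is.na(transcript_id)]
  if (length(basic_tids)) {
    ex <- ex[transcript_id %in% basic_tids]
    cds <- cds[transcript_id %in% basic_tids]
  }
  if (!nrow(ex)) stopf("no protein-coding exon rows in %s", path)

  # rank exons 5'->3' in transcript orientation
  data.table::setorder(ex, transcript_id, start)
  ex[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = "transcript_id"]

  tr <- ex[, .(gene_id = gene_id[1]), by = "transcript_id"]
  tr[, coding := transcript_id %in% unique(cds$transcript_id)]

  gmeta <- df[type == "gene" & gene_id %in% unique(tr$gene_id),
              .(gene_name = gene_name[1]), by = "gene_id"]
  genes <- ex[, .(chrom = chrom[1], strand = strand[1]), by = "gene_id"]
  genes <- merge(genes, gmeta, by = "gene_id", all.x = TRUE)
  genes[is.na(gene_name), gene_name := gene_id]
  genes[, swissprot_validated := FALSE]
  data.table::setcolorder(genes, c("gene_id", "gene_name", "chrom", "strand",
                                   "swissprot_validated"))

  gene_models(
    genes = genes,
    transcripts = tr[, .(transcript_id, gene_id, coding)],
    exons = ex[, .(transcript_id, gene_id, chrom, start, end, strand,
                   exon_rank)],
    cds = cds[, .(transcript_id, gene_id, chrom, start, end, strand)]
  )
}

#' Write a gene-model set back to GTF
#'
#' Inverse of [read_gtf()]: emits gene/transcript/exon/CDS rows with 1-based
#' inclusive coordinates and GENCODE-style attributes (including a
#' `tag "basic"` on every transcript). Round-tripping preserves all exon and
#' CDS coordinate sets.
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  cds <- models$cds
  tr <- models$transcripts
  genes <- models$genes

  fmt_row <- function(chrom, feat, start0, end0, strand, attr) {
    sprintf("%s\texon5uc\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end0, strand, attr)
  }
  gattr <- function(gid, gname) {
    sprintf('gene_id "%s"; gene_type "protein_coding"; gene_name "%s";',
            gid, gname)
  }
  tattr <- function(gid, gname, tid) {
    sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                   'gene_type "protein_coding"; gene_name "%s"; tag "basic";'),
            gid, tid, gname)
  }

  tspan <- ex[, .(start = min(start), end = max(end), chrom = chrom[1],
                  strand = strand[1]), by = c("transcript_id", "gene_id")]
  gspan <- tspan[, .(start = min(start), end = max(end), chrom = chrom[1],
                     strand = strand[1]), by = "gene_id"]
  gspan <- merge(gspan, genes[, c("gene_id", "gene_name")], by = "gene_id")
  tspan <- merge(tspan, genes[, c("gene_id", "gene_name")], by = "gene_id")

  lines <- character(0)
  lines <- c(lines, fmt_row(gspan$chrom, "gene", gspan$start, gspan$end,
                            gspan$strand, gattr(gspan$gene_id,
                                                gspan$gene_name)))
  lines <- c(lines, fmt_row(tspan$chrom, "transcript", tspan$start, tspan$end,
                            tspan$strand,
                            tattr(tspan$gene_id, tspan$gene_name,
                                  tspan$transcript_id)))
  exm <- merge(ex, genes[, c("gene_id", "gene_name")], by = "gene_id")
  lines <- c(lines, fmt_row(exm$chrom, "exon", exm$start, exm$end, exm$strand,
                            tattr(exm$gene_id, exm$gene_name,
                                  exm$transcript_id)))
  if (nrow(cds)) {
    cdm <- merge(cds, genes[, c("gene_id", "gene_name")], by = "gene_id")
    lines <- c(lines, fmt_row(cdm$chrom, "CDS", cdm$start, cdm$end,
                              cdm$strand,
                              tattr(cdm$gene_id, cdm$gene_name,
                                    cdm$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Unique internal exons of each gene
#'
#' An exon counts as internal when it is neither the first nor the last exon
#' in at least one transcript with three or more exons; identical genomic
#' coordinates are collapsed to one record per gene. Exons that are internal
#' in one isoform but terminal in another are kept and flagged
#' `mixed_terminal` for audit.
#'
#' @param models a [gene_models] object.
#' @param gene_ids optional subset of genes.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `mixed_terminal`.
#' @export
unique_internal_exons <- function(models, gene_ids = NULL) {
  ex <- models$exons
  if (!is.null(gene_ids)) ex <- ex[gene_id %in% gene_ids]
  empty <- data.table::data.table(
    gene_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), mixed_terminal = logical(0))
  if (!nrow(ex)) return(as.data.frame(empty))
  ex <- data.table::copy(ex)
  ex[, n_ex := .N, by = "transcript_id"]
  internal <- ex[n_ex >= 3L & exon_rank > 1L & exon_rank < n_ex]
  if (!nrow(internal)) return(as.data.frame(empty))
  uniq <- unique(internal[, .(gene_id, chrom, start, end, strand)])
  terminal <- unique(ex[exon_rank == 1L | exon_rank == n_ex,
                        .(gene_id, chrom, start, end, strand)])
  uniq[, mixed_terminal := FALSE]
  uniq[terminal, on = c("gene_id", "chrom", "start", "end", "strand"),
       mixed_terminal := TRUE]
  data.table::setorder(uniq, gene_id, chrom, start, end)
  as.data.frame(uniq)
}

#' Flag and filter genes by Swiss-Prot-validated coding status
#'
#' @param models a [gene_models] object.
#' @param metadata path to a headerless two-column TSV
#'   (transcript_id, accession) or an equivalent data.frame. Transcript ids
#'   are compared after version stripping.
#' @param keep_only if `TRUE` (default) drop genes with no Swiss-Prot-mapped
#'   transcript; otherwise only set the `swissprot_validated` flag.
#' @return a filtered/flagged [gene_models] object.
#' @export
filter_swissprot <- function(models, metadata, keep_only = TRUE) {
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stopf("metadata file not found: %s", metadata)
    md <- tryCatch(
      utils::read.delim(metadata, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) data.frame())
  } else {
    md <- as.data.frame(metadata)
  }
  if (!nrow(md) || ncol(md) < 2L) {
    warnf("empty Swiss-Prot metadata; flagging all genes FALSE")
    models$genes$swissprot_validated <- FALSE
    return(models)
  }
  mapped_tids <- strip_version(as.character(md[[1]]))
  mapped_tids <- mapped_tids[!is.na(md[[2]]) & nzchar(as.character(md[[2]]))]
  tr <- models$transcripts
  hit_genes <- unique(tr$gene_id[strip_version(tr$transcript_id) %in%
                                   mapped_tids])
  models$genes$swissprot_validated <- models$genes$gene_id %in% hit_genes
  if (keep_only) {
    keep <- models$genes$gene_id[models$genes$swissprot_validated]
    models$genes <- models$genes[models$genes$gene_id %in% keep, ]
    models$transcripts <- models$transcripts[
      models$transcripts$gene_id %in% keep, ]
    models$exons <- models$exons[models$exons$gene_id %in% keep, ]
    models$cds <- models$cds[models$cds$gene_id %in% keep, ]
  }
  models
}
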