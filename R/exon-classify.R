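CODING_TYPES <- c("TYPE1_5UTR", "TYPE2_5UC", "TYPE3_CDS", "TYPE4_C3U",
                  "TYPE5_3UTR")
SPLICE_CLASSES <- c("ASE", "SSE", "OTHER_ALT", "CONSTITUTIVE")

# priority used to resolve isoform-dependent coding composition; exons whose
# coding isoforms disagree get the highest-priority type and a conflict flag
TYPE_PRIORITY <- c(TYPE2_5UC = 1, TYPE4_C3U = 2, TYPE1_5UTR = 3,
                   TYPE5_3UTR = 4, TYPE3_CDS = 5)

# ---- per-exon core (vectorised over all genes) -----------------------------

# one row per (unique internal exon x containing transcript), with the
# coding-composition call of each coding containing transcript
.containing_calls <- function(models, ui) {
  ex <- models$exons
  cont <- ex[ui, on = c("gene_id", "chrom", "start", "end", "strand"),
             nomatch = 0L, allow.cartesian = TRUE]
  if (!nrow(models$cds)) {
    cont[, c("ct", "both_ends") := list(NA_character_, FALSE)]
    return(cont)
  }
  cdsspan <- models$cds[, .(cs = min(start), ce = max(end)),
                        by = "transcript_id"]
  cont <- merge(cont, cdsspan, by = "transcript_id", all.x = TRUE)
  # orient so that comparisons read 5'->3' regardless of genomic strand
  cont[, `:=`(
    o_s = data.table::fifelse(strand == "+", as.numeric(start), -as.numeric(end)),
    o_e = data.table::fifelse(strand == "+", as.numeric(end), -as.numeric(start)),
    o_lo = data.table::fifelse(strand == "+", as.numeric(cs), -as.numeric(ce)),
    o_hi = data.table::fifelse(strand == "+", as.numeric(ce), -as.numeric(cs))
  )]
  cont[, ct := data.table::fcase(
    is.na(cs), NA_character_,
    o_e <= o_lo, "TYPE1_5UTR",
    o_s >= o_hi, "TYPE5_3UTR",
    o_s < o_lo & o_lo < o_e, "TYPE2_5UC",
    o_s < o_hi & o_hi < o_e, "TYPE4_C3U",
    default = "TYPE3_CDS"
  )]
  cont[, both_ends := !is.na(cs) & o_s < o_lo & o_lo < o_e &
         o_s < o_hi & o_hi < o_e]
  cont[, c("o_s", "o_e", "o_lo", "o_hi") := NULL]
  cont
}

# splice-class statistics per (unique internal exon x covering transcript)
.covering_stats <- function(models, ui) {
  ex <- models$exons
  tspan <- ex[, .(t_start = min(start), t_end = max(end),
                  gene_id = gene_id[1]), by = "transcript_id"]
  cov <- tspan[ui, on = "gene_id", allow.cartesian = TRUE][
    t_start <= start & t_end >= end]
  # mark which exon boundaries are genuine splice sites: the genomically
  # outermost boundaries of a transcript are TSS/polyA ends, not splice sites
  exb <- data.table::copy(ex)
  exb[, `:=`(lmost = start == min(start), rmost = end == max(end)),
      by = "transcript_id"]
  ov <- exb[cov[, .(exon_key, transcript_id, start, end)],
            on = "transcript_id", allow.cartesian = TRUE][
    start < i.end & end > i.start]
  pt <- ov[, .(
    present = any(start == i.start & end == i.end),
    sse = any((start != i.start & !lmost) | (end != i.end & !rmost))
  ), by = c("exon_key", "transcript_id")]
  covstat <- merge(cov[, .(exon_key, transcript_id)], pt,
                   by = c("exon_key", "transcript_id"), all.x = TRUE)
  covstat[, no_overlap := is.na(present)]
  covstat[is.na(present), `:=`(present = FALSE, sse = FALSE)]
  covstat
}

#' Coding composition of one exon within one transcript
#'
#' From the transcript's CDS span, in transcript orientation: an exon
#' entirely upstream of the CDS is `TYPE1_5UTR`; an exon containing the CDS
#' start strictly inside is `TYPE2_5UC` (the "5UC" class, harbouring the
#' translation initiation site); an exon inside the CDS is `TYPE3_CDS`; an
#' exon containing the CDS end strictly inside is `TYPE4_C3U`; an exon
#' entirely downstream is `TYPE5_3UTR`. An exon containing both CDS ends is
#' called `TYPE2_5UC` (initiation site takes precedence).
#'
#' @param models a [gene_models] object.
#' @param transcript_id transcript that must contain the exon exactly.
#' @param start,end exon coordinates (0-based half-open).
#' @return type string, or `NA` for a non-coding transcript.
#' @export
coding_composition <- function(models, transcript_id, start, end) {
  tid <- transcript_id
  s0 <- start; e0 <- end
  ex <- models$exons[models$exons$transcript_id == tid &
                       models$exons$start == s0 & models$exons$end == e0, ]
  if (!nrow(ex)) stopf("exon [%d,%d) not found in transcript %s", s0, e0, tid)
  ui <- data.table::data.table(
    gene_id = ex$gene_id[1], chrom = ex$chrom[1], start = s0, end = e0,
    strand = ex$strand[1], exon_key = "q")
  calls <- .containing_calls(models, ui)
  calls$ct[calls$transcript_id == tid][1]
}

#' Resolve the coding type of a unique internal exon across its isoforms
#'
#' All coding transcripts containing the exon (exact coordinates) vote; on
#' disagreement the priority TYPE2 > TYPE4 > TYPE1 > TYPE5 > TYPE3 decides
#' and the exon is flagged. Exons contained only in non-coding isoforms have
#' no coding composition and yield `NA`.
#'
#' @inheritParams coding_composition
#' @param gene_id gene owning the exon.
#' @return list with `coding_type` (or `NA`) and `conflict`.
#' @export
assign_coding_type <- function(models, gene_id, start, end) {
  gid <- gene_id; s0 <- start; e0 <- end
  ex <- models$exons[models$exons$gene_id == gid &
                       models$exons$start == s0 & models$exons$end == e0, ]
  if (!nrow(ex)) stopf("exon [%d,%d) not found in gene %s", s0, e0, gid)
  ui <- data.table::data.table(
    gene_id = gid, chrom = ex$chrom[1], start = s0, end = e0,
    strand = ex$strand[1], exon_key = "q")
  calls <- .containing_calls(models, ui)
  types <- unique(calls$ct[!is.na(calls$ct)])
  if (!length(types)) return(list(coding_type = NA_character_,
                                  conflict = FALSE))
  list(coding_type = types[which.min(TYPE_PRIORITY[types])],
       conflict = length(types) > 1L)
}

#' Splice class of a unique internal exon
#'
#' Covering transcripts are those whose genomic span contains the exon.
#' Rules, in order: present (exact coordinates) in all covering transcripts
#' -> `CONSTITUTIVE`; some covering transcript has an exon overlapping this
#' one with a different 5' or 3' splice-site boundary -> `SSE`; some covering
#' transcript has no overlapping exon at all -> `ASE` (cassette exon); else
#' -> `OTHER_ALT`. A boundary only counts toward `SSE` when it is a true
#' splice site of the overlapping exon — transcript-terminal TSS/polyA ends
#' do not, which is what routes alternative-terminal-exon overlaps into
#' `OTHER_ALT`.
#'
#' @inheritParams assign_coding_type
#' @return one of `"CONSTITUTIVE"`, `"SSE"`, `"ASE"`, `"OTHER_ALT"`.
#' @export
assign_splice_class <- function(models, gene_id, start, end) {
  gid <- gene_id; s0 <- start; e0 <- end
  ex <- models$exons[models$exons$gene_id == gid &
                       models$exons$start == s0 & models$exons$end == e0, ]
  if (!nrow(ex)) stopf("exon [%d,%d) not found in gene %s", s0, e0, gid)
  ui <- data.table::data.table(
    gene_id = gid, chrom = ex$chrom[1], start = s0, end = e0,
    strand = ex$strand[1], exon_key = "q")
  covstat <- .covering_stats(models, ui)
  if (all(covstat$present)) return("CONSTITUTIVE")
  if (any(covstat$sse)) return("SSE")
  if (any(covstat$no_overlap)) return("ASE")
  "OTHER_ALT"
}

#' Classify every unique internal exon of a gene-model set
#'
#' Runs the coding-composition and splice-class assignment over all unique
#' internal exons of multi-exon protein-coding genes. Exons contained only
#' in non-coding isoforms carry no UTR/CDS composition and are excluded from
#' the typed table; they are returned separately for audit.
#'
#' @param models a [gene_models] object.
#' @return list with
#'   \describe{
#'     \item{exons}{data.frame of classified exons: coordinates, `length`,
#'       `coding_type`, `splice_class`, audit flags (`type_conflict`,
#'       `both_cds_ends`, `mixed_terminal`) and the containing/covering
#'       transcript id lists.}
#'     \item{summary}{5 x 4 count table from [classification_summary()].}
#'     \item{dropped}{audit data.frame of internal exons without a coding
#'       containing transcript.}
#'   }
#' @export
classify_all <- function(models) {
  ui <- data.table::as.data.table(unique_internal_exons(models))
  if (!nrow(ui)) {
    empty <- data.frame(
      gene_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), length = integer(0),
      coding_type = character(0), splice_class = character(0),
      type_conflict = logical(0), both_cds_ends = logical(0),
      mixed_terminal = logical(0), containing_transcripts = character(0),
      covering_transcripts = character(0))
    return(list(exons = empty, summary = classification_summary(empty),
                dropped = empty[0, 1:5]))
  }
  ui[, exon_key := paste(gene_id, chrom, start, end, strand, sep = "|")]

  calls <- .containing_calls(models, ui)
  tt <- calls[!is.na(ct),
              .(types = list(unique(ct)), both_cds_ends = any(both_ends)),
              by = "exon_key"]
  tt[, coding_type := vapply(types, function(v)
    v[which.min(TYPE_PRIORITY[v])], character(1))]
  tt[, type_conflict := lengths(types) > 1L]
  tt[, types := NULL]

  cont_ids <- calls[, .(containing_transcripts =
                          paste(sort(transcript_id), collapse = ",")),
                    by = "exon_key"]

  covstat <- .covering_stats(models, ui)
  cls <- covstat[, .(
    all_present = all(present), any_sse = any(sse),
    any_skip = any(no_overlap),
    covering_transcripts = paste(sort(transcript_id), collapse = ",")
  ), by = "exon_key"]
  cls[, splice_class := data.table::fcase(
    all_present, "CONSTITUTIVE",
    any_sse, "SSE",
    any_skip, "ASE",
    default = "OTHER_ALT")]

  out <- merge(ui, tt, by = "exon_key", all.x = TRUE)
  out <- merge(out, cls[, .(exon_key, splice_class, covering_transcripts)],
               by = "exon_key")
  out <- merge(out, cont_ids, by = "exon_key", all.x = TRUE)
  out[, length := end - start]

  dropped <- out[is.na(coding_type),
                 .(gene_id, chrom, start, end, strand)]
  out <- out[!is.na(coding_type)]
  out[is.na(both_cds_ends), both_cds_ends := FALSE]
  data.table::setorder(out, gene_id, chrom, start, end)
  exons <- as.data.frame(out[, .(
    gene_id, chrom, start, end, strand, length, coding_type, splice_class,
    type_conflict, both_cds_ends, mixed_terminal,
    containing_transcripts, covering_transcripts)])
  list(exons = exons, summary = classification_summary(exons),
       dropped = as.data.frame(dropped))
}

#' Tabulate classified exons as a coding-type by splice-class count table
#'
#' @param classified data.frame of classified exons (the `exons` element of
#'   [classify_all()]).
#' @return data.frame with one row per coding type (all five always present)
#'   and columns `total`, `ase`, `sse`, `other_alt`, `constitutive`.
#' @export
classification_summary <- function(classified) {
  ct <- factor(classified$coding_type, levels = CODING_TYPES)
  sc <- factor(classified$splice_class, levels = SPLICE_CLASSES)
  tab <- table(ct, sc)
  data.frame(
    coding_type = CODING_TYPES,
    total = as.integer(rowSums(tab)),
    ase = as.integer(tab[, "ASE"]),
    sse = as.integer(tab[, "SSE"]),
    other_alt = as.integer(tab[, "OTHER_ALT"]),
    constitutive = as.integer(tab[, "CONSTITUTIVE"]),
    stringsAsFactors = FALSE)
}

#' Desk arithmetic over a classification summary table
#'
#' @param summary a table in [classification_summary()] layout (or read from
#'   TSV with [read_classification_summary()]).
#' @return list with `grand_total` (all unique internal exons),
#'   `utr5_total` (Type 1 + Type 2, exons containing 5'UTR), `utr3_total`
#'   (Type 4 + Type 5), `total_ase` (all cassette exons), `fiveuc_ase`
#'   (Type 2 cassette exons) and `fiveuc_ase_share` (their fraction of all
#'   cassette exons).
#' @export
classification_totals <- function(summary) {
  stopifnot(all(c("coding_type", "total", "ase") %in% colnames(summary)))
  rownames(summary) <- NULL
  idx <- match(CODING_TYPES, summary$coding_type)
  tot <- summary$total[idx]
  ase <- summary$ase[idx]
  list(
    grand_total = sum(tot),
    utr5_total = tot[1] + tot[2],
    utr3_total = tot[4] + tot[5],
    total_ase = sum(ase),
    fiveuc_ase = ase[2],
    fiveuc_ase_share = ase[2] / sum(ase)
  )
}

#' Read a classification summary table from TSV
#'
#' @param path TSV with the [classification_summary()] columns.
#' @return data.frame.
#' @export
read_classification_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write classified exons as BED6 (+ annotation columns)
#'
#' First six columns are BED-compatible: chrom, start, end,
#' `gene_id|coding_type|splice_class`, 0, strand.
#'
#' @param classified classified exon data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classified_bed <- function(classified, path) {
  bed <- data.frame(
    chrom = classified$chrom,
    start = classified$start,
    end = classified$end,
    name = paste(classified$gene_id, classified$coding_type,
                 classified$splice_class, sep = "|"),
    score = 0L,
    strand = classified$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genes carrying at least one 5UC cassette exon
#'
#' @param classified classified exon data.frame.
#' @return character vector of gene ids with >= 1 `TYPE2_5UC` exon of splice
#'   class `ASE`.
#' @export
fiveuc_ase_genes <- function(classified) {
  sort(unique(classified$gene_id[
    classified$coding_type == "TYPE2_5UC" &
      classified$splice_class == "ASE"]))
}
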