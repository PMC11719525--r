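# Per-type exon length distributions and in-frame codon usage.

.five_num <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = lo, whisker_hi = hi)
}

#' Exon length summaries per coding type
#'
#' Lengths are `end - start` in nt. Summaries (n, median, quartiles and the
#' 1.5 x IQR whisker extremes) are reported per coding type — optionally
#' split by splice class — plus an `ALL` row over every classified internal
#' exon.
#'
#' @param classified classified exon table from [classify_all()].
#' @param group_by `"coding_type"` (default) or
#'   `"coding_type_splice_class"`.
#' @return data.frame of group summaries; empty groups appear with `n = 0`.
#' @export
length_stats <- function(classified,
                         group_by = c("coding_type",
                                      "coding_type_splice_class")) {
  group_by <- match.arg(group_by)
  grp <- if (group_by == "coding_type") classified$coding_type else
    paste(classified$coding_type, classified$splice_class, sep = ":")
  levels_all <- if (group_by == "coding_type") CODING_TYPES else
    as.vector(outer(CODING_TYPES, SPLICE_CLASSES, paste, sep = ":"))
  rows <- lapply(c("ALL", levels_all), function(g) {
    x <- if (g == "ALL") classified$length else classified$length[grp == g]
    if (!length(x)) {
      return(data.frame(group = g, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_))
    }
    s <- .five_num(x)
    data.frame(group = g, n = as.integer(s["n"]), median = s["median"],
               q1 = s["q1"], q3 = s["q3"], whisker_lo = s["whisker_lo"],
               whisker_hi = s["whisker_hi"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"), paste0))

#' In-frame codon usage of classified exons, per coding type
#'
#' For each exon, a representative containing transcript is chosen (longest
#' annotated CDS; ties by lexicographic transcript id), the exon's CDS
#' portion is extracted from the genome (reverse-complemented on the minus
#' strand) and its reading frame derived from the cumulative CDS length
#' upstream of the exon in that transcript. Only complete codons whose
#' three bases all lie inside the exon's CDS portion are counted; counts
#' are pooled per coding type and normalised to frequencies.
#'
#' @param classified classified exon table.
#' @param models the [gene_models] the classification came from.
#' @param genome `Biostrings::DNAStringSet` or FASTA path.
#' @param types coding types to tabulate (those with CDS content).
#' @return data.frame `coding_type`, `codon`, `count`, `frequency` (64 rows
#'   per type; frequencies sum to 1 per type when any codon was counted).
#' @export
codon_usage <- function(classified, models, genome,
                        types = c("TYPE2_5UC", "TYPE3_CDS", "TYPE4_C3U")) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cds <- data.table::as.data.table(models$cds)
  if (!nrow(cds)) stopf("annotation has no CDS features")
  cds_len <- cds[, .(cds_total = sum(end - start)), by = "transcript_id"]
  ex <- data.table::as.data.table(models$exons)

  cl <- data.table::as.data.table(classified)[coding_type %in% types]
  counts <- lapply(setNames(types, types), function(t)
    setNames(integer(length(ALL_CODONS)), ALL_CODONS))

  for (i in seq_len(nrow(cl))) {
    # representative transcript: longest CDS among coding containing isoforms
    cand <- ex[gene_id == cl$gene_id[i] & start == cl$start[i] &
                 end == cl$end[i], transcript_id]
    cand <- cand[cand %in% cds_len$transcript_id]
    if (!length(cand)) next
    lens <- cds_len[match(cand, transcript_id), cds_total]
    rep_t <- sort(cand[lens == max(lens)])[1]
    seg <- cds[transcript_id == rep_t & start < cl$end[i] &
                 end > cl$start[i]]
    if (!nrow(seg)) next
    ps <- max(seg$start[1], cl$start[i]); pe <- min(seg$end[1], cl$end[i])
    if (pe - ps < 3L) next
    st <- cl$strand[i]
    others <- cds[transcript_id == rep_t &
                    !(start < cl$end[i] & end > cl$start[i])]
    upstream_len <- if (st == "+") sum(pmax(0L, others$end[others$end <= ps] -
                                              others$start[others$end <= ps]))
                    else sum(pmax(0L, others[start >= pe, end - start]))
    offset <- (3L - upstream_len %% 3L) %% 3L
    sq <- Biostrings::subseq(genome[[cl$chrom[i]]], ps + 1L, pe)
    if (st == "-") sq <- Biostrings::reverseComplement(sq)
    s <- as.character(sq)
    n_cod <- (nchar(s) - offset) %/% 3L
    if (n_cod < 1L) next
    starts <- offset + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(s, starts, starts + 2L)
    tb <- table(cods)
    ty <- cl$coding_type[i]
    counts[[ty]][names(tb)] <- counts[[ty]][names(tb)] + as.integer(tb)
  }

  do.call(rbind, lapply(types, function(t) {
    cnt <- counts[[t]]
    tot <- sum(cnt)
    data.frame(coding_type = t, codon = names(cnt),
               count = as.integer(cnt),
               frequency = if (tot > 0) cnt / tot else rep(0, length(cnt)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
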