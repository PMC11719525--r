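# Cassette-exon (skipped-exon) event generation and junction-based PSI.

#' Enumerate exon-skipping events from a gene-model set
#'
#' One event is emitted per (gene, skipped exon, flank pair) where some
#' isoform splices flank A -> exon -> flank B and another isoform joins
#' A -> B directly with the identical A-side donor and B-side acceptor.
#' Event ids follow the SUPPA SE convention
#' `gene;SE:chrom:e1end-e2start:e2end-e3start:strand` (1-based, genomic
#' order).
#'
#' @param models a [gene_models] object.
#' @param classified optional classified exon table; when given, events
#'   whose skipped exon is typed get `coding_type`/`splice_class` columns
#'   (the `TYPE2_5UC` subset being the 5UC cassette events).
#' @return data.frame of events with genomic junction intervals (0-based
#'   half-open introns: `up_*` = transcript-upstream, `down_*` =
#'   transcript-downstream, `skip_*`) and comma-joined
#'   inclusion/exclusion transcript lists.
#' @export
generate_se_events <- function(models, classified = NULL) {
  ex <- data.table::copy(models$exons)
  data.table::setorder(ex, transcript_id, start)
  ex[, idx := seq_len(.N), by = "transcript_id"]
  ex[, n_ex := .N, by = "transcript_id"]

  # all junctions (genomic intron intervals) of every transcript
  jx <- ex[n_ex >= 2L, .(
    js = end[-.N], je = start[-1], gene_id = gene_id[1],
    chrom = chrom[1], strand = strand[1]), by = "transcript_id"]

  # candidate triplets around each genomically-internal exon
  tri <- ex[n_ex >= 3L & idx > 1L & idx < n_ex]
  left <- ex[, .(transcript_id, idx = idx + 1L, l_end = end)]
  right <- ex[, .(transcript_id, idx = idx - 1L, r_start = start)]
  tri <- merge(tri, left, by = c("transcript_id", "idx"))
  tri <- merge(tri, right, by = c("transcript_id", "idx"))

  empty <- data.frame(
    event_id = character(0), gene_id = character(0), chrom = character(0),
    strand = character(0), exon_start = integer(0), exon_end = integer(0),
    up_start = integer(0), up_end = integer(0), down_start = integer(0),
    down_end = integer(0), skip_start = integer(0), skip_end = integer(0),
    inclusion_transcripts = character(0), exclusion_transcripts = character(0))
  if (!nrow(tri)) return(empty)

  # unique (gene, exon, flank pair) candidates
  cand <- unique(tri[, .(gene_id, chrom, strand, exon_start = start,
                         exon_end = end, l_end, r_start)])
  # exclusion isoforms: same gene, junction l_end -> r_start
  excl <- jx[cand, on = c(gene_id = "gene_id", js = "l_end", je = "r_start"),
             nomatch = 0L, allow.cartesian = TRUE]
  if (!nrow(excl)) return(empty)
  excl_ids <- excl[, .(exclusion_transcripts =
                         paste(sort(unique(transcript_id)), collapse = ",")),
                   by = .(gene_id, chrom = i.chrom, strand = i.strand,
                          exon_start, exon_end, l_end = js, r_start = je)]

  # inclusion isoforms: transcripts carrying both flanking junctions
  incl <- tri[, .(transcript_id, gene_id, exon_start = start,
                  exon_end = end, l_end, r_start)]
  incl_ids <- incl[, .(inclusion_transcripts =
                         paste(sort(unique(transcript_id)), collapse = ",")),
                   by = .(gene_id, exon_start, exon_end, l_end, r_start)]

  ev <- merge(excl_ids, incl_ids,
              by = c("gene_id", "exon_start", "exon_end", "l_end", "r_start"))
  ev[, event_id := sprintf("%s;SE:%s:%d-%d:%d-%d:%s", gene_id, chrom,
                           l_end, exon_start + 1L, exon_end, r_start + 1L,
                           strand)]
  # orient junctions: upstream = 5' side in transcript orientation
  ev[, `:=`(
    up_start = data.table::fifelse(strand == "+", l_end, exon_end),
    up_end = data.table::fifelse(strand == "+", exon_start, r_start),
    down_start = data.table::fifelse(strand == "+", exon_end, l_end),
    down_end = data.table::fifelse(strand == "+", r_start, exon_start),
    skip_start = l_end, skip_end = r_start)]
  out <- ev[, .(event_id, gene_id, chrom, strand, exon_start, exon_end,
                up_start, up_end, down_start, down_end, skip_start,
                skip_end, inclusion_transcripts, exclusion_transcripts)]
  data.table::setorder(out, gene_id, chrom, exon_start)
  if (!is.null(classified)) {
    cl <- data.table::as.data.table(classified)[
      , .(gene_id, exon_start = start, exon_end = end,
          coding_type, splice_class)]
    out <- merge(out, cl, by = c("gene_id", "exon_start", "exon_end"),
                 all.x = TRUE, sort = FALSE)
  }
  as.data.frame(out)
}

#' Junction-read PSI
#'
#' `psi = (u + d) / (u + d + 2 s)` where `u`/`d` are upstream/downstream
#' inclusion-junction reads and `s` skipping-junction reads; the skip count
#' is doubled because one included transcript spans two junctions while one
#' skipping transcript spans a single junction. Events whose raw total
#' `u + d + s` does not exceed `min_total` are reported `NA`.
#'
#' @param u,d,s non-negative read counts (vectorised).
#' @param min_total raw-count threshold; PSI requires `u + d + s > min_total`.
#' @return numeric PSI in `[0, 1]` or `NA`.
#' @export
compute_psi <- function(u, d, s, min_total = 50) {
  if (any(c(u, d, s) < 0, na.rm = TRUE)) stopf("negative junction counts")
  val <- (u + d) / (u + d + 2 * s)
  val[u + d + s <= min_total] <- NA_real_
  val[u + d + 2 * s == 0] <- NA_real_
  val
}

#' Per-sample PSI matrix for skipped-exon events
#'
#' Looks up the three junctions of each event in a junction-count table by
#' exact genomic coordinates (absent junctions count 0 reads) and applies
#' [compute_psi()].
#'
#' @param events event table from [generate_se_events()].
#' @param junctions junction-count table: columns `chrom`, `start`, `end`
#'   (0-based half-open intron) plus one numeric column per sample, as
#'   returned by [read_junction_gct()] or [simulate_junction_counts()].
#' @param min_total see [compute_psi()].
#' @return numeric matrix events x samples, rownames = event ids.
#' @export
event_psi_matrix <- function(events, junctions, min_total = 50) {
  jc <- data.table::as.data.table(junctions)
  sample_cols <- setdiff(colnames(jc), c("chrom", "start", "end"))
  if (!length(sample_cols)) stopf("junction table has no sample columns")
  if (any(vapply(jc[, ..sample_cols], function(x) any(x < 0), logical(1)))) {
    stopf("negative junction counts")
  }
  ev <- data.table::as.data.table(events)
  lookup <- function(cs, ce) {
    key <- data.table::data.table(chrom = ev$chrom, start = cs, end = ce)
    m <- jc[key, on = c("chrom", "start", "end")]
    mat <- as.matrix(m[, ..sample_cols])
    mat[is.na(mat)] <- 0
    mat
  }
  u <- lookup(ev$up_start, ev$up_end)
  d <- lookup(ev$down_start, ev$down_end)
  s <- lookup(ev$skip_start, ev$skip_end)
  psi <- matrix(compute_psi(as.vector(u), as.vector(d), as.vector(s),
                            min_total = min_total),
                nrow = nrow(ev),
                dimnames = list(ev$event_id, sample_cols))
  psi
}

#' TPM-based PSI of one or more events
#'
#' `psi = sum(TPM inclusion) / (sum(TPM inclusion) + sum(TPM exclusion))`;
#' transcripts absent from the table count 0, an all-zero denominator gives
#' `NA`.
#'
#' @param events event table.
#' @param tpm named numeric vector of transcript TPMs, or a data.frame with
#'   columns `transcript_id` and `tpm`.
#' @return numeric PSI per event (named by event id).
#' @export
psi_from_tpm <- function(events, tpm) {
  if (is.data.frame(tpm)) tpm <- setNames(tpm$tpm, tpm$transcript_id)
  if (any(tpm < 0)) stopf("negative TPM values")
  get_sum <- function(ids) {
    vapply(strsplit(ids, ",", fixed = TRUE), function(v)
      sum(tpm[v], na.rm = TRUE), numeric(1))
  }
  inc <- get_sum(events$inclusion_transcripts)
  exc <- get_sum(events$exclusion_transcripts)
  val <- inc / (inc + exc)
  val[inc + exc == 0] <- NA_real_
  setNames(val, events$event_id)
}

#' Aggregate a per-sample PSI matrix to tissues
#'
#' Per-tissue PSI is the median of the tissue's non-`NA` per-sample PSIs
#' (robust to depth outliers); all-`NA` tissues stay `NA`.
#'
#' @param psi events x samples matrix from [event_psi_matrix()].
#' @param tissue_map data.frame with `sample_id` and `tissue`.
#' @return events x tissues matrix.
#' @export
tissue_psi_matrix <- function(psi, tissue_map) {
  missing <- setdiff(tissue_map$sample_id, colnames(psi))
  if (length(missing)) {
    stopf("sample(s) in tissue map absent from PSI matrix: %s",
          paste(missing, collapse = ", "))
  }
  tissues <- unique(tissue_map$tissue)
  out <- vapply(tissues, function(ti) {
    cols <- tissue_map$sample_id[tissue_map$tissue == ti]
    apply(psi[, cols, drop = FALSE], 1, function(v)
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  }, numeric(nrow(psi)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(psi),
                                                       tissues))
  out
}

#' Tissue-delta-PSI
#'
#' Per (event, tissue): the difference between the tissue's PSI and the
#' median of the event's PSI over all tissues. Events with fewer than
#' `min_tissues` non-`NA` tissue values are excluded.
#'
#' @param tissue_psi events x tissues matrix.
#' @param min_tissues minimum non-`NA` tissues per event.
#' @return list with `delta` (events x tissues matrix) and `abs_by_tissue`
#'   (long data.frame `event_id`, `tissue`, `delta`, `abs_delta` for
#'   boxplotting and group tests).
#' @export
tissue_delta_psi <- function(tissue_psi, min_tissues = 3L) {
  keep <- rowSums(!is.na(tissue_psi)) >= min_tissues
  m <- tissue_psi[keep, , drop = FALSE]
  med <- apply(m, 1, median, na.rm = TRUE)
  delta <- m - med
  long <- data.frame(
    event_id = rep(rownames(m), ncol(m)),
    tissue = rep(colnames(m), each = nrow(m)),
    delta = as.vector(delta))
  long <- long[!is.na(long$delta), ]
  long$abs_delta <- abs(long$delta)
  list(delta = delta, abs_by_tissue = long)
}

#' Fraction of events at moderate inclusion
#'
#' @param psis numeric PSI values (`NA` allowed and excluded).
#' @param lo,hi open interval bounds; values strictly inside count.
#' @return fraction in `[0, 1]`, or `NA` if no non-`NA` input.
#' @export
moderate_fraction <- function(psis, lo = 0.3, hi = 0.75) {
  v <- psis[!is.na(psis)]
  if (!length(v)) return(NA_real_)
  mean(v > lo & v < hi)
}

#' Two-condition delta-PSI with the three-band grouping
#'
#' `dpsi = psi_kd - psi_ctrl`; `UP` when `dpsi >= band`, `DOWN` when
#' `dpsi <= -band`, else `NEUTRAL`. Events with an `NA` PSI in either
#' condition are excluded.
#'
#' @param psi_kd,psi_ctrl named numeric PSI vectors (knockdown, control).
#' @param band group boundary (default 0.2, boundary values inclusive).
#' @return data.frame `event_id`, `psi_ctrl`, `psi_kd`, `dpsi`, `group`.
#' @export
delta_psi_condition <- function(psi_kd, psi_ctrl, band = 0.2) {
  ids <- intersect(names(psi_kd), names(psi_ctrl))
  kd <- psi_kd[ids]; ct <- psi_ctrl[ids]
  ok <- !is.na(kd) & !is.na(ct)
  dpsi <- kd[ok] - ct[ok]
  group <- dpsi_group(dpsi, band)
  data.frame(event_id = ids[ok], psi_ctrl = unname(ct[ok]),
             psi_kd = unname(kd[ok]), dpsi = unname(dpsi),
             group = unname(group), stringsAsFactors = FALSE)
}

# band comparison with a numeric guard so that a delta of exactly +-band
# (up to representation error) lands on the boundary-inclusive side
dpsi_group <- function(dpsi, band = 0.2, tol = 1e-9) {
  ifelse(dpsi >= band - tol, "UP",
         ifelse(dpsi <= -band + tol, "DOWN", "NEUTRAL"))
}

#' Read a GCT-like junction count table
#'
#' Accepts the GTEx junction layout: optional `#`/version and dimension
#' header lines, then a header row whose first column holds junction ids
#' `chrom_start_end` (1-based inclusive intron coordinates, converted here
#' to 0-based half-open) and remaining columns samples. A `Description`
#' column, when present, is dropped.
#'
#' @param path file path.
#' @return data.table `chrom`, `start`, `end` + one column per sample.
#' @export
read_junction_gct <- function(path) {
  head_lines <- readLines(path, n = 10L)
  first_field <- vapply(strsplit(head_lines, "\t"), `[`, character(1), 1)
  data_at <- which(grepl("_[0-9]+_[0-9]+$", first_field))[1]
  if (is.na(data_at)) stopf("no junction-id rows found in %s", path)
  # the header row sits immediately above the first data row
  dt <- data.table::fread(path, skip = max(0L, data_at - 2L),
                          header = TRUE, sep = "\t")
  id_col <- colnames(dt)[1]
  drop <- intersect(c("Description", "Name2"), colnames(dt))
  if (length(drop)) dt[, (drop) := NULL]
  parts <- data.table::tstrsplit(dt[[id_col]], "_")
  n <- length(parts)
  dt[, chrom := do.call(paste, c(parts[1:(n - 2)], sep = "_"))]
  dt[, start := as.integer(parts[[n - 1]]) - 1L]
  dt[, end := as.integer(parts[[n]])]
  dt[, (id_col) := NULL]
  data.table::setcolorder(dt, c("chrom", "start", "end"))
  dt[]
}

#' Write events in SUPPA-compatible ioe layout
#'
#' Columns: `seqname`, `gene_id`, `event_id`,
#' `alternative_transcripts` (inclusion set), `total_transcripts`.
#'
#' @param events event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ioe <- function(events, path) {
  total <- mapply(function(a, b)
    paste(sort(unique(c(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]]))),
          collapse = ","),
    events$inclusion_transcripts, events$exclusion_transcripts)
  df <- data.frame(seqname = events$chrom, gene_id = events$gene_id,
                   event_id = events$event_id,
                   alternative_transcripts = events$inclusion_transcripts,
                   total_transcripts = unname(total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
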