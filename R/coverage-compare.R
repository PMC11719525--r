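# Strand-aware meta-coverage matrices around exon sets and region-wise
# enrichment testing between two exon classes.

#' Coverage track container
#'
#' Per-chromosome base-resolution signal stored run-length encoded. Tracks
#' are built from bedGraph files ([read_bedgraph()]) or from binned values
#' ([track_from_bins()], the output of [simulate_coverage()]).
#'
#' @param rle_list named list of [S4Vectors::Rle] vectors (one per
#'   chromosome, base resolution).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(rle_list) {
  stopifnot(is.list(rle_list), !is.null(names(rle_list)))
  structure(list(signal = rle_list), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s): %s\n",
              length(x$signal),
              paste(utils::head(names(x$signal), 5), collapse = ", ")))
  invisible(x)
}

#' @rdname coverage_track
#' @param bins named list of per-chromosome numeric vectors of bin values.
#' @param bin_size bin width in nt.
#' @export
track_from_bins <- function(bins, bin_size = 10L) {
  coverage_track(lapply(bins, function(v)
    S4Vectors::Rle(rep(as.numeric(v), each = bin_size))))
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @return a [coverage_track].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = "score")
  coverage_track(as.list(cov))
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$signal)) {
    r <- track$signal[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep],
                         ends[keep], vals[keep]), con)
    }
  }
  invisible(path)
}

.track_window <- function(rle, start, end) {
  len <- length(rle)
  lo <- max(start, 0L); hi <- min(end, len)
  core <- if (hi > lo) as.numeric(S4Vectors::window(rle, lo + 1L, hi))
          else numeric(0)
  c(rep(0, max(0L, lo - start)), core, rep(0, max(0L, end - hi)))
}

# rescale an arbitrary-length vector to n_bins by length-weighted averaging
.bin_means <- function(v, n_bins) {
  if (length(v) < n_bins) v <- rep(v, each = ceiling(n_bins / length(v)))
  grp <- floor((seq_along(v) - 1) * n_bins / length(v))
  as.numeric(tapply(v, factor(grp, levels = 0:(n_bins - 1)), mean))
}

#' Build a strand-aware meta-coverage matrix around exons
#'
#' For each exon: `up/bin_size` upstream bins, `body/bin_size` bins over the
#' exon body rescaled by length-weighted averaging, and `down/bin_size`
#' downstream bins, oriented 5' to 3' (minus-strand rows are
#' column-reversed, so column 1 is always the 5'-most upstream bin). Rows
#' with all-zero signal are dropped (skip-zeros semantics); exons on
#' chromosomes absent from the track are dropped with a warning.
#'
#' @param track a [coverage_track].
#' @param exons data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally an id column (first non-coordinate column used as rowname,
#'   else coordinates).
#' @param up,body,down window sizes in nt (defaults 500/100/500).
#' @param bin_size bin width; must divide `up`, `body` and `down`.
#' @return numeric matrix exons x bins with a `regions` attribute labelling
#'   columns `UPSTREAM`/`EXON`/`DOWNSTREAM`.
#' @export
build_coverage_matrix <- function(track, exons, up = 500L, body = 100L,
                                  down = 500L, bin_size = 10L) {
  if (up %% bin_size || down %% bin_size || body %% bin_size) {
    stopf("bin_size must divide up, body and down window sizes")
  }
  nb_up <- up %/% bin_size; nb_body <- body %/% bin_size
  nb_down <- down %/% bin_size
  ids <- if ("exon_id" %in% colnames(exons)) exons$exon_id else
    paste0(exons$chrom, ":", exons$start, "-", exons$end, ":", exons$strand)
  present <- exons$chrom %in% names(track$signal)
  if (!all(present)) {
    warnf("dropping %d exon(s) on chromosomes absent from track",
          sum(!present))
  }
  exons <- exons[present, , drop = FALSE]; ids <- ids[present]
  rows <- matrix(0, nrow(exons), nb_up + nb_body + nb_down)
  for (i in seq_len(nrow(exons))) {
    r <- track$signal[[exons$chrom[i]]]
    s <- exons$start[i]; e <- exons$end[i]
    left <- .track_window(r, s - up, s)
    bodyv <- .track_window(r, s, e)
    right <- .track_window(r, e, e + down)
    vals <- c(colMeans(matrix(left, nrow = bin_size)),
              .bin_means(bodyv, nb_body),
              colMeans(matrix(right, nrow = bin_size)))
    if (exons$strand[i] == "-") vals <- rev(vals)
    rows[i, ] <- vals
  }
  rownames(rows) <- ids
  keep <- rowSums(rows) > 0
  rows <- rows[keep, , drop = FALSE]
  attr(rows, "regions") <- c(rep("UPSTREAM", nb_up), rep("EXON", nb_body),
                             rep("DOWNSTREAM", nb_down))
  attr(rows, "bin_size") <- bin_size
  rows
}

#' Region-wise coverage enrichment between two exon sets
#'
#' Within the chosen region, each matrix is collapsed to its per-bin median
#' profile over exons; the fold-change is the median over bins of the
#' per-bin ratio `profile_a / profile_b` (zero-denominator bins excluded),
#' reported as log2, and the p-value comes from the exact Wilcoxon
#' signed-rank test on the paired bin profiles.
#'
#' @param matrix_a,matrix_b matrices from [build_coverage_matrix()] with
#'   identical window parameters (e.g. the 5UC cassette set vs the
#'   CDS-internal cassette background).
#' @param region `"UPSTREAM"`, `"EXON"` or `"DOWNSTREAM"`.
#' @param fc_cutoff,p_cutoff volcano cut-offs: enrichment requires
#'   `log2_fc > fc_cutoff` and `-log10(p) > p_cutoff`.
#' @param fc_method `"median_ratio"` (median over bins of the per-bin
#'   ratio, default) or `"ratio_of_medians"`.
#' @return one-row data.frame: `region`, `log2_fc`, `p_value`,
#'   `neg_log10_p`, `n_bins`, `passes_cutoff`, `p_method`.
#' @export
region_enrichment <- function(matrix_a, matrix_b,
                              region = c("UPSTREAM", "EXON", "DOWNSTREAM"),
                              fc_cutoff = 0.4, p_cutoff = 6,
                              fc_method = c("median_ratio",
                                            "ratio_of_medians")) {
  region <- match.arg(region)
  fc_method <- match.arg(fc_method)
  ra <- attr(matrix_a, "regions"); rb <- attr(matrix_b, "regions")
  if (is.null(ra) || is.null(rb) || !identical(ra, rb)) {
    stopf("matrices must come from build_coverage_matrix with identical windows")
  }
  cols <- which(ra == region)
  pa <- apply(matrix_a[, cols, drop = FALSE], 2, median)
  pb <- apply(matrix_b[, cols, drop = FALSE], 2, median)
  ok <- pb > 0
  if (!any(ok)) stopf("no bins with non-zero background profile in %s",
                      region)
  fc <- if (fc_method == "median_ratio") median(pa[ok] / pb[ok])
        else median(pa[ok]) / median(pb[ok])
  log2_fc <- log2(fc)
  wt <- exact_wilcoxon_signed_rank(pa, pb)
  data.frame(
    region = region, log2_fc = log2_fc, p_value = wt$p_value,
    neg_log10_p = -log10(wt$p_value), n_bins = sum(ok),
    passes_cutoff = log2_fc > fc_cutoff & -log10(wt$p_value) > p_cutoff,
    p_method = wt$method, stringsAsFactors = FALSE)
}

#' Volcano table over all three regions
#'
#' @inheritParams region_enrichment
#' @param factor_name label column (e.g. the RBP assayed).
#' @return data.frame with one row per region.
#' @export
volcano_table <- function(matrix_a, matrix_b, factor_name = "factor",
                          fc_cutoff = 0.4, p_cutoff = 6) {
  out <- do.call(rbind, lapply(c("UPSTREAM", "EXON", "DOWNSTREAM"),
                               function(rg)
    region_enrichment(matrix_a, matrix_b, rg, fc_cutoff, p_cutoff)))
  cbind(factor = factor_name, out)
}

#' Upstream coverage across delta-PSI groups
#'
#' Re-bins each exon's upstream window into coarse bins (default 50 nt, ten
#' bins over the 500 nt window), then compares the pooled per-exon bin
#' values of the delta-PSI groups with the Steel-Dwass all-pairs test.
#' Per-bin group medians are also returned for profile plotting.
#'
#' @param matrix a [build_coverage_matrix()] matrix.
#' @param groups data.frame with `exon_id` and `group`, or a named vector
#'   mapping exon id to group label.
#' @param bin_nt coarse bin width in nt.
#' @return list: `test` ([steel_dwass()] table), `group_values` (named list
#'   of pooled bin values per group), `bin_medians` (groups x bins matrix).
#' @export
stratified_upstream_coverage <- function(matrix, groups, bin_nt = 50L) {
  if (is.data.frame(groups)) groups <- setNames(groups$group,
                                                groups$exon_id)
  bin_size <- attr(matrix, "bin_size") %||% 10L
  cols <- which(attr(matrix, "regions") == "UPSTREAM")
  if (bin_nt %% bin_size) stopf("bin_nt must be a multiple of bin_size")
  fold <- bin_nt %/% bin_size
  upm <- matrix[, cols, drop = FALSE]
  nb <- ncol(upm) %/% fold
  coarse <- sapply(seq_len(nb), function(j)
    rowMeans(upm[, ((j - 1) * fold + 1):(j * fold), drop = FALSE]))
  if (is.null(dim(coarse))) coarse <- matrix(coarse, nrow = 1)
  rownames(coarse) <- rownames(upm)
  g <- groups[rownames(coarse)]
  labs <- unique(stats::na.omit(g))
  vals <- lapply(labs, function(l)
    as.vector(coarse[which(g == l), , drop = FALSE]))
  names(vals) <- labs
  small <- lengths(vals) < 2 * nb
  if (any(small)) {
    warnf("excluding group(s) with < 2 exons: %s",
          paste(labs[small], collapse = ", "))
    vals <- vals[!small]
  }
  if (length(vals) < 2) stopf("need >= 2 non-empty groups")
  med <- t(sapply(names(vals), function(l)
    apply(coarse[which(g == l), , drop = FALSE], 2, median)))
  list(test = steel_dwass(vals), group_values = vals, bin_medians = med)
}
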