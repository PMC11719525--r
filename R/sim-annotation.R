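# Synthetic annotation generator: plants one unique internal exon (two for
# SSE genes) of known coding type and splice class per gene, using 3-exon
# gene templates whose isoform structure forces the intended splice class.

.rand_len <- function(n, med, sdlog, lo, hi) {
  pmin(hi, pmax(lo, round(exp(rnorm(n, log(med), sdlog)))))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build one gene in local transcript-oriented coordinates (0 = first base of
# exon 1). Returns exon/cds rows per isoform, planted-exon truth rows and
# cassette-event junction intervals, all local.
.plant_gene <- function(ty, cl, l1, l2, l3, intron) {
  e1 <- c(0L, l1)
  e2 <- c(l1 + intron, l1 + intron + l2)
  e3 <- c(e2[2] + intron, e2[2] + intron + l3)
  gene_len <- e3[2]

  off1 <- max(12L, l1 %/% 2L)            # CDS start offset inside exon 1
  off2 <- min(max(6L, round(l2 * 0.4)), l2 - 6L)  # offset inside planted exon
  r0 <- 60L                               # CDS tail inside exon 3

  cds_a <- switch(ty,
    TYPE1_5UTR = {
      list(c(e3[1] + 12L, e3[1] + 72L))
    },
    TYPE2_5UC = {
      r <- r0 + (3L - (l2 - off2 + r0) %% 3L) %% 3L
      list(c(e2[1] + off2, e2[2]), c(e3[1], e3[1] + r))
    },
    TYPE3_CDS = {
      r <- r0 + (3L - (l1 - off1 + l2 + r0) %% 3L) %% 3L
      list(c(e1[1] + off1, e1[2]), e2, c(e3[1], e3[1] + r))
    },
    TYPE4_C3U = {
      o <- off2 + (3L - (l1 - off1 + off2) %% 3L) %% 3L
      list(c(e1[1] + off1, e1[2]), c(e2[1], e2[1] + o))
    },
    TYPE5_3UTR = {
      o <- min(off1, l1 - 66L)
      list(c(e1[1] + o, e1[1] + o + 60L))
    },
    stopf("unknown coding type %s", ty))

  iso <- list(A = list(exons = list(e1, e2, e3), cds = cds_a))
  truth_exons <- list(e2)

  if (cl == "ASE") {
    iso$B <- list(exons = list(e1, e3), cds = list())
  } else if (cl == "SSE") {
    ext <- 30L
    e2x <- c(e2[1] - ext, e2[2])
    cds_b <- switch(ty,
      TYPE1_5UTR = cds_a,
      TYPE2_5UC = cds_a,
      TYPE3_CDS = {
        r <- cds_a[[3]][2] - e3[1]
        list(c(e1[1] + off1, e1[2]), e2x, c(e3[1], e3[1] + r))
      },
      TYPE4_C3U = {
        o <- cds_a[[2]][2] - e2[1]
        list(c(e1[1] + off1, e1[2]), c(e2x[1], e2[1] + o))
      },
      TYPE5_3UTR = cds_a)
    iso$B <- list(exons = list(e1, e2x, e3), cds = cds_b)
    truth_exons <- list(e2, e2x)
  } else if (cl == "OTHER_ALT") {
    # variant isoform ends inside intron 2: its last exon shares the planted
    # exon's acceptor but reads through the donor (non-splice 3' end)
    e2l <- c(e2[1], e2[2] + 40L)
    iso$B <- list(exons = list(e1, e2l), cds = list())
  } # CONSTITUTIVE: single isoform

  event <- NULL
  if (cl == "ASE") {
    event <- list(up = c(e1[2], e2[1]), down = c(e2[2], e3[1]),
                  skip = c(e1[2], e3[1]))
  }
  list(iso = iso, truth_exons = truth_exons, event = event,
       gene_len = gene_len, cds_marks = cds_a)
}

.map_local <- function(lo, hi, off, gene_len, strand) {
  if (strand == "+") c(off + lo, off + hi)
  else c(off + gene_len - hi, off + gene_len - lo)
}

#' Generate a synthetic annotation with planted exon classes
#'
#' Emits a gene-model set (and optionally GTF + genome FASTA files) in which
#' every unique internal exon has a known coding type and splice class.
#' Each gene follows a 3-exon template; cassette (ASE) genes carry a
#' skipping isoform, SSE genes a boundary-shifted isoform (which plants a
#' second SSE exon), OTHER_ALT genes an isoform terminating inside the
#' downstream intron. Planted exon lengths are drawn log-normally with a
#' larger median for the 5UC type. The genome sequence is uniform random
#' ACGT with splice-site dinucleotides, start (ATG) and stop (TAA) codons
#' planted at the annotated positions.
#'
#' @param config a [sim_config] object.
#' @param out_dir if non-`NULL`, write `annotation.gtf`, `genome.fa` and
#'   `truth_exons.tsv` there.
#' @param emit_fasta generate the genome sequence (needed only for codon
#'   analyses; skipping it makes large simulations faster).
#' @return list with `models` ([gene_models]), `truth` (data.frame of
#'   planted exons: coordinates, `coding_type`, `splice_class`, `bound`
#'   flag), `events` (planted cassette events with genomic junction
#'   coordinates and inclusion/exclusion transcripts), `genome`
#'   (`DNAStringSet` or `NULL`) and any file paths written.
#' @export
simulate_annotation <- function(config = sim_config(), out_dir = NULL,
                                emit_fasta = TRUE) {
  set.seed(derive_seed(config$seed, "annotation"))
  quotas <- config$quotas
  quotas <- quotas[quotas > 0]
  if (!length(quotas)) stopf("no genes requested in quotas")
  cells <- do.call(rbind, strsplit(names(quotas), ":", fixed = TRUE))
  if (ncol(cells) != 2 || !all(cells[, 1] %in% CODING_TYPES) ||
      !all(cells[, 2] %in% SPLICE_CLASSES)) {
    stopf("quota names must be '<coding_type>:<splice_class>'")
  }
  plan <- data.table::data.table(
    ty = rep(cells[, 1], quotas), cl = rep(cells[, 2], quotas))
  n_genes <- nrow(plan)
  plan[, gene_id := sprintf("SYNG%04d", seq_len(n_genes))]
  plan[, strand := sample(c("+", "-"), n_genes, replace = TRUE)]
  med <- config$type_median_length
  plan[, l1 := .rand_len(n_genes, 150, config$length_sdlog, 100L, 400L)]
  plan[, l2 := .rand_len(.N, med[ty], config$length_sdlog, 45L, 1200L),
       by = "ty"]
  plan[, l3 := .rand_len(n_genes, 250, config$length_sdlog, 120L, 500L)]

  genes_per_chrom <- 50L
  flank <- 700L
  gap <- 400L

  exon_rows <- list(); cds_rows <- list(); truth_rows <- list()
  event_rows <- list(); tr_rows <- list(); gene_rows <- list()
  seq_parts <- list(); chrom_of <- character(0)

  offset <- flank; chrom_i <- 1L
  chrom_seqs <- list(); cur_parts <- list(); cur_pos <- 0L

  for (i in seq_len(n_genes)) {
    gid <- plan$gene_id[i]; st <- plan$strand[i]
    chrom <- sprintf("chrS%02d", chrom_i)
    g <- .plant_gene(plan$ty[i], plan$cl[i], plan$l1[i], plan$l2[i],
                     plan$l3[i], config$intron_length)

    for (iso_name in names(g$iso)) {
      tid <- paste0(gid, ".", iso_name)
      iso <- g$iso[[iso_name]]
      for (e in iso$exons) {
        m <- .map_local(e[1], e[2], offset, g$gene_len, st)
        exon_rows[[length(exon_rows) + 1L]] <- data.table::data.table(
          transcript_id = tid, gene_id = gid, chrom = chrom,
          start = m[1], end = m[2], strand = st)
      }
      for (cc in iso$cds) {
        m <- .map_local(cc[1], cc[2], offset, g$gene_len, st)
        cds_rows[[length(cds_rows) + 1L]] <- data.table::data.table(
          transcript_id = tid, gene_id = gid, chrom = chrom,
          start = m[1], end = m[2], strand = st)
      }
      tr_rows[[length(tr_rows) + 1L]] <- data.table::data.table(
        transcript_id = tid, gene_id = gid,
        coding = length(iso$cds) > 0L)
    }

    for (e in g$truth_exons) {
      m <- .map_local(e[1], e[2], offset, g$gene_len, st)
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        gene_id = gid, chrom = chrom, start = m[1], end = m[2], strand = st,
        coding_type = plan$ty[i], splice_class = plan$cl[i])
    }

    if (!is.null(g$event)) {
      ju <- .map_local(g$event$up[1], g$event$up[2], offset, g$gene_len, st)
      jd <- .map_local(g$event$down[1], g$event$down[2], offset,
                       g$gene_len, st)
      js <- .map_local(g$event$skip[1], g$event$skip[2], offset,
                       g$gene_len, st)
      m2 <- .map_local(g$iso$A$exons[[2]][1], g$iso$A$exons[[2]][2],
                       offset, g$gene_len, st)
      # genomic-order junctions (left/right of the skipped exon)
      jl <- if (st == "+") ju else jd
      jr <- if (st == "+") jd else ju
      event_rows[[length(event_rows) + 1L]] <- data.table::data.table(
        event_id = sprintf("%s;SE:%s:%d-%d:%d-%d:%s", gid, chrom,
                           jl[1], jl[2] + 1L, jr[1], jr[2] + 1L, st),
        gene_id = gid, chrom = chrom, strand = st,
        exon_start = m2[1], exon_end = m2[2],
        up_start = ju[1], up_end = ju[2],
        down_start = jd[1], down_end = jd[2],
        skip_start = js[1], skip_end = js[2],
        inclusion_transcripts = paste0(gid, ".A"),
        exclusion_transcripts = paste0(gid, ".B"))
    }

    if (emit_fasta) {
      s <- strsplit(.random_dna(g$gene_len), "")[[1]]
      # splice sites of the primary isoform's introns
      exA <- g$iso$A$exons
      for (k in 1:2) {
        is_ <- exA[[k]][2]; ie_ <- exA[[k + 1]][1]
        s[is_ + 1L] <- "G"; s[is_ + 2L] <- "T"
        s[ie_ - 1L] <- "A"; s[ie_] <- "G"
      }
      cds_all <- g$cds_marks
      cs <- cds_all[[1]][1]; ce <- cds_all[[length(cds_all)]][2]
      s[(cs + 1L):(cs + 3L)] <- c("A", "T", "G")
      s[(ce - 2L):ce] <- c("T", "A", "A")
      local_seq <- paste(s, collapse = "")
      if (st == "-") {
        local_seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(local_seq)))
      }
      pre_gap <- offset - cur_pos
      cur_parts[[length(cur_parts) + 1L]] <- .random_dna(pre_gap)
      cur_parts[[length(cur_parts) + 1L]] <- local_seq
      cur_pos <- offset + g$gene_len
    }

    offset <- offset + g$gene_len + gap
    if (i %% genes_per_chrom == 0L && i < n_genes) {
      if (emit_fasta) {
        cur_parts[[length(cur_parts) + 1L]] <- .random_dna(flank)
        chrom_seqs[[chrom]] <- paste(unlist(cur_parts), collapse = "")
        cur_parts <- list(); cur_pos <- 0L
      }
      chrom_i <- chrom_i + 1L
      offset <- flank
    }
  }
  if (emit_fasta) {
    cur_parts[[length(cur_parts) + 1L]] <- .random_dna(flank)
    chrom_seqs[[sprintf("chrS%02d", chrom_i)]] <-
      paste(unlist(cur_parts), collapse = "")
  }

  ex <- data.table::rbindlist(exon_rows)
  data.table::setorder(ex, transcript_id, start)
  ex[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = "transcript_id"]
  tr <- data.table::rbindlist(tr_rows)
  genes <- unique(ex[, .(gene_id, chrom, strand)])
  genes[, gene_name := gene_id]
  genes[, swissprot_validated := FALSE]
  data.table::setcolorder(genes, c("gene_id", "gene_name", "chrom", "strand",
                                   "swissprot_validated"))
  cds <- if (length(cds_rows)) data.table::rbindlist(cds_rows) else
    data.table::data.table(transcript_id = character(0),
                           gene_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  models <- gene_models(genes, tr, ex, cds)

  truth <- data.table::rbindlist(truth_rows)
  # RBP binding: a configurable fraction of the 5UC cassette exons is bound;
  # bound events sit at intermediate inclusion so knockdown has headroom
  truth[, bound := FALSE]
  is_target <- truth$coding_type == "TYPE2_5UC" & truth$splice_class == "ASE"
  idx <- which(is_target)
  if (length(idx)) {
    n_bound <- round(config$bound_fraction * length(idx))
    truth$bound[sample(idx, n_bound)] <- TRUE
  }
  events <- if (length(event_rows)) data.table::rbindlist(event_rows) else
    data.table::data.table()
  if (nrow(events)) {
    events <- merge(events,
                    truth[, .(gene_id, coding_type, splice_class, bound)],
                    by = "gene_id", sort = FALSE)
    events[, psi_true := .draw_psi(.N, bound, config)]
    data.table::setorder(events, gene_id)
  }

  res <- list(models = models, truth = as.data.frame(truth),
              events = as.data.frame(events),
              genome = if (emit_fasta)
                Biostrings::DNAStringSet(unlist(chrom_seqs)) else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res$gtf_path <- file.path(out_dir, "annotation.gtf")
    write_gtf(models, res$gtf_path)
    if (emit_fasta) {
      res$fasta_path <- file.path(out_dir, "genome.fa")
      Biostrings::writeXStringSet(res$genome, res$fasta_path)
    }
    utils::write.table(res$truth, file.path(out_dir, "truth_exons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(events)) {
      utils::write.table(res$events, file.path(out_dir, "truth_events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}

# bimodal inclusion landscape with a planted moderate fraction. Bound
# (repressed) exons skew low and stay below 0.65, so a knockdown shift of
# +kd_effect keeps them inside [0, 1]; their moderate share matches the
# global planted fraction
.draw_psi <- function(n, bound, config) {
  psi <- numeric(n)
  u <- runif(n)
  mod <- config$psi_moderate_frac
  lo_frac <- (1 - mod) / 2
  psi[u < lo_frac] <- runif(sum(u < lo_frac), 0.02, 0.15)
  hi <- u >= lo_frac & u < 2 * lo_frac
  psi[hi] <- runif(sum(hi), 0.85, 0.98)
  mid <- u >= 2 * lo_frac
  psi[mid] <- runif(sum(mid), 0.35, 0.70)
  nb <- sum(bound)
  if (nb) {
    low <- runif(nb) >= mod
    psi[bound] <- ifelse(low, runif(nb, 0.02, 0.15), runif(nb, 0.35, 0.65))
  }
  psi
}
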