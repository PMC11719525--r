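# End-to-end orchestration: classify -> features -> events/PSI -> coverage
# comparison, with stages skipped when their inputs are absent.

#' Pipeline run configuration
#'
#' All thresholds default to the analysis' canonical values: junction-read
#' total > 50 for a PSI call, the moderate-PSI band (0.3, 0.75), the
#' delta-PSI grouping band 0.2, volcano cut-offs log2FC > 0.4 and
#' -log10 p > 6, and 500/100/500 nt coverage windows at 10 nt bins.
#'
#' @param gtf annotation path (or a [gene_models] via `models`).
#' @param models optional pre-parsed [gene_models]; overrides `gtf`.
#' @param swissprot optional transcript-to-accession TSV; genes without a
#'   mapped transcript are flagged (not dropped).
#' @param genome_fasta optional genome FASTA enabling codon analysis.
#' @param junctions optional GCT-like junction count table path.
#' @param sample_attrs optional sample-to-tissue TSV (columns `sample_id`,
#'   `tissue`).
#' @param tpm_ctrl,tpm_kd optional transcript TPM TSVs (columns
#'   `transcript_id`, `tpm`) for the two-condition delta-PSI stage.
#' @param tracks optional named character vector of bedGraph paths.
#' @param out_dir output directory (created); `NULL` disables file output.
#' @param min_total,psi_lo,psi_hi,dpsi_band,fc_cutoff,p_cutoff,up,body,down,bin_size
#'   thresholds and window parameters.
#' @param seed integer seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(gtf = NULL, models = NULL, swissprot = NULL,
                       genome_fasta = NULL, junctions = NULL,
                       sample_attrs = NULL, tpm_ctrl = NULL, tpm_kd = NULL,
                       tracks = NULL, out_dir = NULL,
                       min_total = 50, psi_lo = 0.3, psi_hi = 0.75,
                       dpsi_band = 0.2, fc_cutoff = 0.4, p_cutoff = 6,
                       up = 500L, body = 100L, down = 500L,
                       bin_size = 10L, seed = 1L) {
  stopifnot(min_total >= 0, psi_lo < psi_hi, dpsi_band > 0, dpsi_band <= 1)
  structure(as.list(environment()), class = "run_config")
}

.save_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: annotation parsing, exon classification,
#' length/codon features, skipped-exon event generation, junction PSI and
#' tissue statistics, two-condition delta-PSI, and coverage-enrichment
#' comparison of the 5UC cassette set against the CDS-internal cassette
#' background. Stages whose inputs are absent are skipped with a message;
#' a stage failure aborts with the stage name.
#'
#' @param config a [run_config].
#' @return named list of stage results (also written as TSVs under
#'   `config$out_dir` when set).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  models <- stage("annotation", {
    m <- config$models %||% read_gtf(config$gtf)
    if (!is.null(config$swissprot)) {
      m <- filter_swissprot(m, config$swissprot, keep_only = FALSE)
    }
    m
  })
  res$models <- models

  res$classification <- stage("classification", classify_all(models))
  .save_tsv(res$classification$exons, config$out_dir, "classified_exons.tsv")
  .save_tsv(res$classification$summary, config$out_dir,
            "classification_summary.tsv")
  if (!is.null(config$out_dir)) {
    write_classified_bed(res$classification$exons,
                         file.path(config$out_dir, "classified_exons.bed"))
  }

  res$length_stats <- stage("features",
                            length_stats(res$classification$exons))
  .save_tsv(res$length_stats, config$out_dir, "length_stats.tsv")
  if (!is.null(config$genome_fasta)) {
    res$codon_usage <- stage("features", codon_usage(
      res$classification$exons, models, config$genome_fasta))
    .save_tsv(res$codon_usage, config$out_dir, "codon_usage.tsv")
  } else {
    message("no genome FASTA: codon analysis skipped")
  }

  res$events <- stage("events",
                      generate_se_events(models, res$classification$exons))
  if (!is.null(config$out_dir) && nrow(res$events)) {
    write_ioe(res$events, file.path(config$out_dir, "events.ioe"))
  }

  if (!is.null(config$junctions) && nrow(res$events)) {
    res$psi <- stage("psi", {
      jc <- read_junction_gct(config$junctions)
      event_psi_matrix(res$events, jc, min_total = config$min_total)
    })
    .save_tsv(data.frame(event_id = rownames(res$psi), res$psi,
                         check.names = FALSE),
              config$out_dir, "psi_samples.tsv")
    if (!is.null(config$sample_attrs)) {
      res$tissue_psi <- stage("tissue_psi", {
        sa <- utils::read.delim(config$sample_attrs,
                                stringsAsFactors = FALSE)
        tissue_psi_matrix(res$psi, sa)
      })
      res$tissue_delta <- stage("tissue_psi",
                                tissue_delta_psi(res$tissue_psi))
      res$moderate <- stage("tissue_psi", apply(
        res$tissue_psi, 2, moderate_fraction,
        lo = config$psi_lo, hi = config$psi_hi))
      .save_tsv(data.frame(event_id = rownames(res$tissue_psi),
                           res$tissue_psi, check.names = FALSE),
                config$out_dir, "psi_tissues.tsv")
      .save_tsv(data.frame(tissue = names(res$moderate),
                           moderate_fraction = unname(res$moderate)),
                config$out_dir, "moderate_fraction.tsv")
    }
  } else {
    message("no junction counts: PSI stage skipped")
  }

  if (!is.null(config$tpm_ctrl) && !is.null(config$tpm_kd) &&
      nrow(res$events)) {
    res$dpsi <- stage("dpsi", {
      ctrl <- utils::read.delim(config$tpm_ctrl, stringsAsFactors = FALSE)
      kd <- utils::read.delim(config$tpm_kd, stringsAsFactors = FALSE)
      delta_psi_condition(psi_from_tpm(res$events, kd),
                          psi_from_tpm(res$events, ctrl),
                          band = config$dpsi_band)
    })
    .save_tsv(res$dpsi, config$out_dir, "delta_psi.tsv")
  } else {
    message("no TPM tables: delta-PSI stage skipped")
  }

  if (!is.null(config$tracks) && nrow(res$events)) {
    res$volcano <- stage("coverage", {
      cl <- res$events
      set_a <- cl[!is.na(cl$coding_type) & cl$coding_type == "TYPE2_5UC", ]
      set_b <- cl[!is.na(cl$coding_type) & cl$coding_type == "TYPE3_CDS", ]
      if (!nrow(set_a) || !nrow(set_b)) {
        stopf("need both 5UC and CDS-internal cassette sets")
      }
      mk_set <- function(s) data.frame(
        chrom = s$chrom, start = s$exon_start, end = s$exon_end,
        strand = s$strand, exon_id = s$event_id)
      do.call(rbind, lapply(names(config$tracks), function(nm) {
        trk <- read_bedgraph(config$tracks[[nm]])
        ma <- build_coverage_matrix(trk, mk_set(set_a), up = config$up,
                                    body = config$body, down = config$down,
                                    bin_size = config$bin_size)
        mb <- build_coverage_matrix(trk, mk_set(set_b), up = config$up,
                                    body = config$body, down = config$down,
                                    bin_size = config$bin_size)
        volcano_table(ma, mb, factor_name = nm,
                      fc_cutoff = config$fc_cutoff,
                      p_cutoff = config$p_cutoff)
      }))
    })
    .save_tsv(res$volcano, config$out_dir, "volcano.tsv")
  } else {
    message("no coverage tracks: enrichment stage skipped")
  }

  invisible(res)
}
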