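# Simulators for the assays consumed downstream: junction read counts over
# tissues, RBP coverage tracks, and knockdown/control TPM tables.

#' Simulate junction read counts for planted cassette events
#'
#' Per event and sample, a junction read budget `n ~ Poisson(depth)` is
#' split between the upstream, downstream and skipping junctions with
#' probabilities proportional to `(psi, psi, 1 - psi)` — an included
#' transcript spans two junctions while a skipping transcript spans one, so
#' under this sampling the doubled-skip-read PSI estimator is unbiased for
#' the transcript-level inclusion fraction `psi`. The first three tissues
#' are "divergent" (large per-tissue inclusion shifts, emulating
#' brain/muscle/testis); the rest move little.
#'
#' @param events event truth table from [simulate_annotation()] (needs
#'   `psi_true` and junction coordinates).
#' @param config a [sim_config].
#' @return list: `counts` (junction x sample table consumable by
#'   [event_psi_matrix()]), `samples` (sample-to-tissue map),
#'   `tissue_psi_true` (events x tissues matrix of true inclusion levels).
#' @export
simulate_junction_counts <- function(events, config = sim_config()) {
  set.seed(derive_seed(config$seed, "junctions"))
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) stopf("no events to simulate")
  n_ev <- nrow(ev)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  tau <- rep(config$tissue_tau_other, config$n_tissues)
  n_div <- min(3L, config$n_tissues)
  tau[seq_len(n_div)] <- config$tissue_tau_divergent
  names(tissues) <- NULL

  psi_t <- sapply(seq_len(config$n_tissues), function(ti)
    pmin(1, pmax(0, ev$psi_true + if (tau[ti] > 0)
      rnorm(n_ev, 0, tau[ti]) else 0)))
  dimnames(psi_t) <- list(ev$event_id, tissues)

  samples <- data.frame(
    sample_id = sprintf("%s_s%d", rep(tissues,
                                      each = config$samples_per_tissue),
                        rep(seq_len(config$samples_per_tissue),
                            config$n_tissues)),
    tissue = rep(tissues, each = config$samples_per_tissue),
    stringsAsFactors = FALSE)

  cnt <- matrix(0L, nrow = 3L * n_ev, ncol = nrow(samples))
  for (j in seq_len(nrow(samples))) {
    p <- psi_t[, samples$tissue[j]]
    n <- rpois(n_ev, config$depth)
    s <- rbinom(n_ev, n, (1 - p) / (1 + p))
    u <- rbinom(n_ev, n - s, 0.5)
    d <- n - s - u
    cnt[, j] <- as.integer(rbind(u, d, s))
  }
  colnames(cnt) <- samples$sample_id
  keys <- data.table::data.table(
    chrom = rep(ev$chrom, each = 3L),
    start = as.integer(rbind(ev$up_start, ev$down_start, ev$skip_start)),
    end = as.integer(rbind(ev$up_end, ev$down_end, ev$skip_end)))
  counts <- cbind(keys, data.table::as.data.table(cnt))
  list(counts = counts, samples = samples, tissue_psi_true = psi_t)
}

#' Write simulated junction counts in GCT-like layout
#'
#' @param counts the `counts` element of [simulate_junction_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_gct <- function(counts, path) {
  dt <- data.table::as.data.table(counts)
  sample_cols <- setdiff(colnames(dt), c("chrom", "start", "end"))
  out <- data.table::data.table(
    Name = sprintf("%s_%d_%d", dt$chrom, dt$start + 1L, dt$end),
    Description = "junction")
  out <- cbind(out, dt[, ..sample_cols])
  lines <- c("#1.2", sprintf("%d\t%d", nrow(out), length(sample_cols)))
  writeLines(lines, path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Simulate an RBP coverage track with planted upstream enrichment
#'
#' Background signal is Poisson per bin; for exons flagged `bound`, the
#' bins covering the window from `enrich_width` nt upstream of the exon's
#' 5' splice site to the site itself (strand-aware) draw from a
#' `fold`-scaled intensity.
#'
#' @param truth planted-exon table from [simulate_annotation()] (columns
#'   `chrom`, `start`, `end`, `strand`, `bound`).
#' @param config a [sim_config].
#' @param chrom_lengths optional named lengths; defaults to the largest
#'   coordinate plus a margin.
#' @param stream label suffix so independent tracks can be drawn for the
#'   same truth.
#' @return a [coverage_track].
#' @export
simulate_coverage <- function(truth, config = sim_config(),
                              chrom_lengths = NULL, stream = "coverage") {
  set.seed(derive_seed(config$seed, stream))
  bs <- config$cov_bin_size
  tr <- data.table::as.data.table(truth)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tr[, .(len = max(end) + 700L), by = "chrom"]
    chrom_lengths <- setNames(chrom_lengths$len, chrom_lengths$chrom)
  }
  bins <- lapply(chrom_lengths, function(L)
    rpois(ceiling(L / bs), config$lambda_bg))
  bound <- tr[bound == TRUE]
  if (nrow(bound) && config$fold > 1) {
    for (i in seq_len(nrow(bound))) {
      w <- if (bound$strand[i] == "+")
        c(bound$start[i] - config$enrich_width, bound$start[i])
      else c(bound$end[i], bound$end[i] + config$enrich_width)
      b0 <- max(0L, w[1] %/% bs); b1 <- ceiling(w[2] / bs)
      idx <- (b0 + 1L):b1
      bins[[bound$chrom[i]]][idx] <-
        rpois(length(idx), config$lambda_bg * config$fold)
    }
  }
  track_from_bins(bins, bin_size = bs)
}

#' Simulate control and knockdown transcript TPM tables
#'
#' Control TPMs reproduce each event's true inclusion `psi`; under
#' knockdown of the simulated repressor, bound events' inclusion rises by
#' `kd_effect` (clamped to `[0, 1]`). Multiplicative log-normal noise with
#' `tpm_sdlog` is applied per transcript.
#'
#' @param events event truth table (needs `psi_true`, `bound`,
#'   inclusion/exclusion transcript ids).
#' @param config a [sim_config].
#' @return list: `ctrl`, `kd` (data.frames `transcript_id`, `tpm`),
#'   `truth_group` (planted delta-PSI group per event).
#' @export
simulate_knockdown <- function(events, config = sim_config()) {
  if (abs(config$kd_effect) > 1) stopf("kd_effect outside [-1, 1]")
  set.seed(derive_seed(config$seed, "knockdown"))
  ev <- data.table::as.data.table(events)
  shift <- ifelse(ev$bound, config$kd_effect, 0)
  # indirect responders: unbound events moving opposite to the direct targets
  unb <- which(!ev$bound)
  n_down <- round(config$kd_down_fraction * length(unb))
  if (n_down > 0) {
    down_idx <- sample(unb, n_down)
    shift[down_idx] <- -config$kd_effect
  }
  psi_kd <- pmin(1, pmax(0, ev$psi_true + shift))
  mk <- function(psi) {
    noise <- function(n) exp(rnorm(n, 0, config$tpm_sdlog))
    data.frame(
      transcript_id = c(ev$inclusion_transcripts,
                        ev$exclusion_transcripts),
      tpm = c(config$base_tpm * psi * noise(nrow(ev)),
              config$base_tpm * (1 - psi) * noise(nrow(ev))),
      stringsAsFactors = FALSE)
  }
  dpsi_planted <- psi_kd - ev$psi_true
  list(
    ctrl = mk(ev$psi_true),
    kd = mk(psi_kd),
    truth_group = data.frame(
      event_id = ev$event_id,
      dpsi_planted = dpsi_planted,
      group = dpsi_group(dpsi_planted),
      stringsAsFactors = FALSE))
}
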