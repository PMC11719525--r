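# Independent oracles shared by unit and acceptance tests.

# literal enumeration of all 2^n sign assignments of the signed-rank test
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# greedy minimum-variance agglomeration from the Lance-Williams recurrence,
# written independently of hclust; returns the sorted merge heights
ward_oracle_heights <- function(d) {
  d2 <- d^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in active) for (j in active) if (i < j && d2[i, j] < bestv) {
      bestv <- d2[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      upd <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                nk * bestv) / (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- upd
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    d2[j, ] <- d2[, j] <- Inf
  }
  heights
}

# detection of planted upstream enrichment: one annotation, fresh coverage
# noise per seed; returns the fraction of seeds passing the volcano cut-off
enrichment_detection_rate <- function(fold, n_seeds, n_exons = 300L,
                                      seed0 = 9000L) {
  cfg <- sim_config(seed = seed0,
                    quotas = c("TYPE2_5UC:ASE" = n_exons,
                               "TYPE3_CDS:ASE" = n_exons),
                    bound_fraction = 1, fold = fold)
  sim <- simulate_annotation(cfg, emit_fasta = FALSE)
  t2 <- subset(sim$truth, coding_type == "TYPE2_5UC")
  t3 <- subset(sim$truth, coding_type == "TYPE3_CDS")
  mk <- function(s) data.frame(chrom = s$chrom, start = s$start,
                               end = s$end, strand = s$strand)
  hits <- vapply(seq_len(n_seeds), function(s) {
    trk <- simulate_coverage(sim$truth, cfg,
                             stream = sprintf("cov%d", s))
    ma <- build_coverage_matrix(trk, mk(t2))
    mb <- build_coverage_matrix(trk, mk(t3))
    region_enrichment(ma, mb, "UPSTREAM")$passes_cutoff
  }, logical(1))
  mean(hits)
}
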