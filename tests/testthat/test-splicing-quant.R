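test_that("skipping events need both inclusion and exclusion isoforms", {
  base <- list(gene = "G1", chrom = "chr1", strand = "+",
               exons = list(c(0, 60), c(100, 200), c(300, 400)),
               cds = list(c(20, 60), c(100, 200), c(300, 330)))
  skip_iso <- list(gene = "G1", chrom = "chr1", strand = "+",
                   exons = list(c(0, 60), c(300, 400)))
  ev <- generate_se_events(toy_models(list(A = base, B = skip_iso)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_id, "G1;SE:chr1:60-101:200-301:+")
  expect_equal(ev$inclusion_transcripts, "A")
  expect_equal(ev$exclusion_transcripts, "B")
  # no exclusion isoform -> no event
  expect_equal(nrow(generate_se_events(toy_models(list(A = base)))), 0L)
})

test_that("event generation matches a brute-force oracle on small genes", {
  # random multi-isoform genes over a shared 6-exon scaffold
  set.seed(77)
  scaffold <- list(c(0, 80), c(200, 260), c(400, 480), c(600, 700),
                   c(900, 960), c(1100, 1200))
  for (rep in 1:15) {
    n_iso <- sample(2:4, 1)
    spec <- list()
    for (k in seq_len(n_iso)) {
      keep <- sort(unique(c(1, 6, which(runif(6) > 0.35))))
      spec[[paste0("T", k)]] <- list(
        gene = "G1", chrom = "chr1",
        strand = sample(c("+", "-"), 1)[1],
        exons = scaffold[keep])
    }
    strand <- spec[[1]]$strand
    for (k in seq_along(spec)) spec[[k]]$strand <- strand
    m <- toy_models(spec)
    ev <- generate_se_events(m)

    # oracle: enumerate all (isoform, internal exon, isoform') triples
    found <- character(0)
    for (ti in names(spec)) {
      exs <- spec[[ti]]$exons
      if (length(exs) < 3) next
      for (i in 2:(length(exs) - 1)) {
        a <- exs[[i - 1]]; e <- exs[[i]]; b <- exs[[i + 1]]
        for (tj in setdiff(names(spec), ti)) {
          exj <- spec[[tj]]$exons
          for (j in seq_len(length(exj) - 1)) {
            if (exj[[j]][2] == a[2] && exj[[j + 1]][1] == b[1]) {
              found <- c(found, sprintf("%d-%d:%d-%d", a[2], e[1], e[2],
                                        b[1]))
            }
          }
        }
      }
    }
    oracle_keys <- sort(unique(found))
    got_keys <- sort(sprintf("%d-%d:%d-%d", ev$skip_start, ev$exon_start,
                             ev$exon_end, ev$skip_end))
    expect_identical(got_keys, oracle_keys)
  }
})

test_that("synthetic cassette events are recovered exactly", {
  cls <- classify_all(SIM$models)
  ev <- generate_se_events(SIM$models, cls$exons)
  expect_setequal(ev$event_id, SIM$events$event_id)
  expect_equal(sum(ev$coding_type == "TYPE2_5UC"),
               sum(SIM$events$coding_type == "TYPE2_5UC"))
})

test_that("PSI formula, threshold and scale invariance", {
  expect_equal(compute_psi(30, 30, 10), 0.75)
  expect_equal(compute_psi(40, 40, 0), 1.0)
  # total exactly 50 fails the strict threshold
  expect_true(is.na(compute_psi(20, 20, 10)))
  expect_equal(compute_psi(20, 20, 10, min_total = 49), 2 / 3)
  # scale invariance (threshold permitting)
  for (k in c(2, 5, 10)) {
    expect_equal(compute_psi(30 * k, 30 * k, 10 * k),
                 compute_psi(30, 30, 10))
  }
  expect_error(compute_psi(-1, 5, 5), "negative")
})

test_that("TPM-based PSI sums isoform abundances", {
  ev <- data.frame(event_id = c("e1", "e2", "e3"),
                   inclusion_transcripts = c("i1", "i1,i2,i3", "i9"),
                   exclusion_transcripts = c("x1", "x1", "x9"))
  tpm <- c(i1 = 8, x1 = 2, i2 = 2, i3 = 3)
  v <- psi_from_tpm(ev, tpm)
  expect_equal(unname(v["e1"]), 0.8)
  # inclusion 1+2+3 = 6? here 8+2+3 = 13 vs 2 -> 13/15
  expect_equal(unname(v["e2"]), 13 / 15)
  expect_true(is.na(v["e3"]))
  v2 <- psi_from_tpm(data.frame(event_id = "e",
                                inclusion_transcripts = "i1,i2,i3",
                                exclusion_transcripts = "x1"),
                     c(i1 = 1, i2 = 2, i3 = 3, x1 = 4))
  expect_equal(unname(v2), 0.6)
  expect_error(psi_from_tpm(ev, c(i1 = -1)), "negative")
})

test_that("per-tissue aggregation is the median of sample PSIs", {
  psi <- matrix(c(0.4, 0.6, NA, NA), nrow = 1,
                dimnames = list("e1", paste0("s", 1:4)))
  tm <- data.frame(sample_id = paste0("s", 1:4),
                   tissue = c("a", "a", "b", "b"))
  out <- tissue_psi_matrix(psi, tm)
  expect_equal(out["e1", "a"], 0.5)
  expect_true(is.na(out["e1", "b"]))
  expect_error(tissue_psi_matrix(psi, data.frame(sample_id = "zz",
                                                 tissue = "a")), "zz")
})

test_that("junction-simulated tissue PSI tracks the true inclusion level", {
  cfg <- sim_config(seed = 55L, n_tissues = 1L, tissue_tau_divergent = 0,
                    tissue_tau_other = 0, samples_per_tissue = 20L,
                    depth = 200)
  ev <- SIM$events
  ev$psi_true <- 0.7
  jc <- simulate_junction_counts(ev, cfg)
  psi <- event_psi_matrix(ev, jc$counts)
  tp <- tissue_psi_matrix(psi, jc$samples)
  expect_true(all(abs(tp[, 1] - 0.7) < 0.03))
})

test_that("tissue-delta-PSI centres each event at its median", {
  m <- matrix(c(0.5, 0.5, 0.5, 0.2, 0.5, 0.8), nrow = 2, byrow = TRUE,
              dimnames = list(c("e1", "e2"), c("t1", "t2", "t3")))
  td <- tissue_delta_psi(m)
  expect_equal(unname(td$delta["e1", ]), c(0, 0, 0))
  expect_equal(unname(td$delta["e2", ]), c(-0.3, 0, 0.3))
  # median of deltas is zero per event (odd tissue count, no NA)
  expect_equal(unname(apply(td$delta, 1, median)), c(0, 0))
  # events with < 3 informative tissues are excluded
  m2 <- rbind(m, e3 = c(0.5, NA, NA))
  expect_equal(nrow(tissue_delta_psi(m2)$delta), 2L)
})

test_that("divergent tissues show the largest inclusion shifts", {
  jc <- simulate_junction_counts(SIM$events, SIM_CFG)
  psi <- event_psi_matrix(SIM$events, jc$counts)
  tp <- tissue_psi_matrix(psi, jc$samples)
  td <- tissue_delta_psi(tp)
  med <- aggregate(abs_delta ~ tissue, td$abs_by_tissue, median)
  top3 <- med$tissue[order(-med$abs_delta)][1:3]
  expect_setequal(top3, c("tissue01", "tissue02", "tissue03"))
})

test_that("moderate-PSI fraction uses the open interval", {
  expect_equal(moderate_fraction(c(0.1, 0.5, 0.9, 1.0)), 0.25)
  expect_equal(moderate_fraction(c(0.3, 0.5, 0.75)), 1 / 3)
  expect_true(is.na(moderate_fraction(c(NA_real_, NA_real_))))
  expect_true(is.na(moderate_fraction(numeric(0))))
})

test_that("delta-PSI grouping includes the band boundary", {
  kd <- c(e1 = 0.9, e2 = 0.5, e3 = 0.7, e4 = 0.1, e5 = NA)
  ct <- c(e1 = 0.6, e2 = 0.5, e3 = 0.5, e4 = 0.5, e5 = 0.5)
  d <- delta_psi_condition(kd, ct)
  expect_equal(d$group[d$event_id == "e1"], "UP")
  expect_equal(d$group[d$event_id == "e2"], "NEUTRAL")
  expect_equal(d$group[d$event_id == "e3"], "UP")   # exactly +0.2
  expect_equal(d$group[d$event_id == "e4"], "DOWN")
  expect_false("e5" %in% d$event_id)
})

test_that("GCT junction tables round-trip through write/read", {
  jc <- simulate_junction_counts(SIM$events, SIM_CFG)
  path <- tempfile(fileext = ".gct")
  write_junction_gct(jc$counts, path)
  back <- read_junction_gct(path)
  orig <- data.table::as.data.table(jc$counts)
  data.table::setorder(orig, chrom, start, end)
  data.table::setorder(back, chrom, start, end)
  expect_equal(as.data.frame(back), as.data.frame(orig))
})
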