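flat_track <- function(value, len = 6000, chrom = "chr1") {
  coverage_track(setNames(list(S4Vectors::Rle(value, len)), chrom))
}

test_that("coverage matrix geometry: uniform, zero and peaked tracks", {
  exons <- data.frame(chrom = "chr1", start = 2000L, end = 2100L,
                      strand = "+", exon_id = "e1")
  m <- build_coverage_matrix(flat_track(1), exons)
  expect_equal(dim(m), c(1L, 110L))
  expect_true(all(m == 1))
  expect_equal(attr(m, "regions"),
               c(rep("UPSTREAM", 50), rep("EXON", 10), rep("DOWNSTREAM", 50)))

  # all-zero track: every row skipped
  expect_equal(nrow(build_coverage_matrix(flat_track(0), exons)), 0L)

  # rectangular peak at -300..-200 relative to the exon start lands in
  # upstream bins 21..30 (1-based)
  r <- S4Vectors::Rle(0, 6000)
  r[(2000 - 300 + 1):(2000 - 200)] <- 5
  trk <- coverage_track(list(chr1 = r))
  mp <- build_coverage_matrix(trk, exons)
  expect_true(all(mp[1, 21:30] == 5))
  expect_true(all(mp[1, -(21:30)] == 0))

  expect_error(build_coverage_matrix(flat_track(1), exons, bin_size = 7),
               "bin_size")
})

test_that("minus-strand rows are mirrored so column 1 is 5'-most", {
  # peak downstream (genomically right) of a minus-strand exon's 3' end,
  # i.e. in its transcriptional upstream window
  r <- S4Vectors::Rle(0, 6000)
  r[(2100 + 200 + 1):(2100 + 300)] <- 7
  trk <- coverage_track(list(chr1 = r))
  exons_m <- data.frame(chrom = "chr1", start = 2000L, end = 2100L,
                        strand = "-", exon_id = "e1")
  m <- build_coverage_matrix(trk, exons_m)
  expect_true(all(m[1, 21:30] == 7))
  expect_true(all(m[1, -(21:30)] == 0))
})

test_that("strand symmetry: mirroring the locus leaves the matrix unchanged", {
  set.seed(8)
  L <- 6000L
  vals <- rpois(L, 3)
  trk_p <- coverage_track(list(chr1 = S4Vectors::Rle(vals)))
  ex_p <- data.frame(chrom = "chr1", start = 2000L, end = 2130L,
                     strand = "+", exon_id = "e")
  trk_m <- coverage_track(list(chr1 = S4Vectors::Rle(rev(vals))))
  ex_m <- data.frame(chrom = "chr1", start = L - 2130L, end = L - 2000L,
                     strand = "-", exon_id = "e")
  expect_equal(build_coverage_matrix(trk_p, ex_p),
               build_coverage_matrix(trk_m, ex_m))
})

test_that("region enrichment: identity, doubling and error cases", {
  set.seed(21)
  m <- matrix(rpois(40 * 110, 5) + 1, nrow = 40)
  attr(m, "regions") <- c(rep("UPSTREAM", 50), rep("EXON", 10),
                          rep("DOWNSTREAM", 50))
  attr(m, "bin_size") <- 10L
  m2 <- m * 2
  attributes(m2) <- attributes(m)

  same <- region_enrichment(m, m, "UPSTREAM")
  expect_equal(same$log2_fc, 0)
  expect_equal(same$p_value, 1)

  dbl <- region_enrichment(m2, m, "UPSTREAM")
  expect_equal(dbl$log2_fc, 1)
  # all 50 paired bins shifted the same way: the smallest p the bin count
  # allows under the continuity-corrected normal tail
  expect_lt(dbl$p_value, 1e-8)

  z <- m; z[] <- 0; attributes(z) <- attributes(m)
  expect_error(region_enrichment(m, z, "EXON"), "non-zero")
  bad <- m[, 1:100]
  expect_error(region_enrichment(m, bad, "EXON"), "identical windows")
})

test_that("planted upstream enrichment is localised to the upstream region", {
  cfg <- sim_config(seed = 60L,
                    quotas = c("TYPE2_5UC:ASE" = 60L, "TYPE3_CDS:ASE" = 60L),
                    bound_fraction = 1, fold = 2)
  sim <- simulate_annotation(cfg, emit_fasta = FALSE)
  trk <- simulate_coverage(sim$truth, cfg)
  mk <- function(s) data.frame(chrom = s$chrom, start = s$start,
                               end = s$end, strand = s$strand)
  ma <- build_coverage_matrix(trk,
                              mk(subset(sim$truth,
                                        coding_type == "TYPE2_5UC")))
  mb <- build_coverage_matrix(trk,
                              mk(subset(sim$truth,
                                        coding_type == "TYPE3_CDS")))
  v <- volcano_table(ma, mb, "RBP1")
  expect_true(v$passes_cutoff[v$region == "UPSTREAM"])
  expect_false(v$passes_cutoff[v$region == "EXON"])
  expect_false(v$passes_cutoff[v$region == "DOWNSTREAM"])
})

test_that("delta-PSI group comparison of upstream binding", {
  set.seed(9)
  mk_rows <- function(n, lambda) matrix(rpois(n * 110, lambda), nrow = n)
  m <- rbind(mk_rows(30, 10), mk_rows(30, 5), mk_rows(10, 5))
  rownames(m) <- paste0("e", seq_len(nrow(m)))
  attr(m, "regions") <- c(rep("UPSTREAM", 50), rep("EXON", 10),
                          rep("DOWNSTREAM", 50))
  attr(m, "bin_size") <- 10L
  grp <- setNames(rep(c("UP", "NEUTRAL", "DOWN"), c(30, 30, 10)),
                  rownames(m))
  st <- stratified_upstream_coverage(m, grp)
  expect_equal(ncol(st$bin_medians), 10L)
  p <- function(a, b) st$test$p_value[
    (st$test$group1 == a & st$test$group2 == b) |
      (st$test$group1 == b & st$test$group2 == a)]
  expect_lt(p("UP", "NEUTRAL"), 1e-4)
  expect_lt(p("UP", "DOWN"), 1e-4)
  expect_gt(p("NEUTRAL", "DOWN"), 0.05)

  # three identical groups: nothing significant
  m0 <- rbind(mk_rows(20, 5), mk_rows(20, 5), mk_rows(20, 5))
  rownames(m0) <- paste0("e", seq_len(nrow(m0)))
  attributes(m0)[c("regions", "bin_size")] <-
    attributes(m)[c("regions", "bin_size")]
  g0 <- setNames(rep(c("UP", "NEUTRAL", "DOWN"), each = 20), rownames(m0))
  expect_gt(min(stratified_upstream_coverage(m0, g0)$test$p_value), 0.01)
})

test_that("bedGraph tracks round-trip", {
  set.seed(4)
  bins <- list(chrA = rpois(200, 3), chrB = rpois(150, 2))
  trk <- track_from_bins(bins, bin_size = 10L)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(trk, path)
  back <- read_bedgraph(path)
  for (ch in names(bins)) {
    a <- as.numeric(trk$signal[[ch]])
    b <- as.numeric(back$signal[[ch]])
    expect_equal(b, a[seq_along(b)])
    expect_true(all(a[-seq_along(b)] == 0))
  }
})
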