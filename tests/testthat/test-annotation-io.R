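test_that("GTF reading converts coordinates and respects the basic tag", {
  m <- read_gtf(extdata("gencode_mini.gtf"))
  expect_setequal(m$genes$gene_id,
                  c("ENSG00000000001.1", "ENSG00000000002.2",
                    "ENSG00000000003.1"))
  # non-basic isoform ENST...103 must be excluded even though its rows carry
  # no tag (other transcripts do)
  expect_false("ENST00000000103.1" %in% m$transcripts$transcript_id)
  expect_equal(sum(m$transcripts$gene_id == "ENSG00000000001.1"), 2L)
  # 1-based inclusive 101..200 becomes 0-based half-open [100, 200)
  e1 <- m$exons[m$exons$transcript_id == "ENST00000000101.3" &
                  m$exons$exon_rank == 1, ]
  expect_equal(c(e1$start, e1$end), c(100L, 200L))
  # minus-strand exon ranks run 5' -> 3' (highest coordinates first)
  eb <- m$exons[m$exons$transcript_id == "ENST00000000201.1", ]
  expect_equal(eb$start[eb$exon_rank == 1], 1400L)
  expect_equal(eb$start[eb$exon_rank == 3], 1000L)
  # per-transcript exon counts match the hand-enumerated manifest
  cnt <- table(m$exons$transcript_id)
  expect_equal(as.integer(cnt[c("ENST00000000101.3", "ENST00000000102.1")]),
               c(3L, 2L))
})

test_that("malformed GTF rows raise parse errors naming the line", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t100\t200\t.\t+\t.\tgene_id "G1"; gene_type "protein_coding";',
    'chr1\tx\texon\t300\t250\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    bad)
  expect_error(read_gtf(bad), "line 2")
  bad2 <- tempfile(fileext = ".gtf")
  writeLines(
    'chr1\tx\texon\t100\t200\t.\t+\t.\tsomething_else "G1";', bad2)
  expect_error(read_gtf(bad2), "malformed attribute")
})

test_that("CDS outside its transcript's exons fails validation", {
  expect_error(
    toy_models(list(T1 = list(
      gene = "G1", chrom = "chr1", strand = "+",
      exons = list(c(0, 100), c(200, 300)),
      cds = list(c(120, 180))))),
    "CDS segment.*T1")
})

test_that("unique internal exons: dedup, terminal exclusion, mixed flag", {
  # 3-exon single-isoform gene: exactly the middle exon
  m <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 100), c(200, 300), c(400, 500)),
    cds = list(c(50, 100), c(200, 300), c(400, 450)))))
  ui <- unique_internal_exons(m)
  expect_equal(nrow(ui), 1L)
  expect_equal(c(ui$start, ui$end), c(200L, 300L))

  # 2-exon gene: no internal exon possible
  m2 <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 100), c(200, 300)))))
  expect_equal(nrow(unique_internal_exons(m2)), 0L)

  # internal in isoform A, terminal (first) in isoform B: included once,
  # flagged mixed_terminal
  m3 <- toy_models(list(
    A = list(gene = "G1", chrom = "chr1", strand = "+",
             exons = list(c(0, 100), c(200, 300), c(400, 500))),
    B = list(gene = "G1", chrom = "chr1", strand = "+",
             exons = list(c(200, 300), c(400, 500)))))
  ui3 <- unique_internal_exons(m3)
  expect_equal(nrow(ui3), 1L)
  expect_true(ui3$mixed_terminal)
})

test_that("internal exon count on synthetic annotation equals planted count", {
  ui <- unique_internal_exons(SIM$models)
  expect_equal(nrow(ui), nrow(SIM$truth))
  expect_true(all(!ui$mixed_terminal))
})

test_that("GTF round-trip preserves exon and CDS coordinate sets", {
  path <- tempfile(fileext = ".gtf")
  write_gtf(SIM$models, path)
  m2 <- read_gtf(path)
  key <- function(df) sort(paste(df$transcript_id, df$chrom, df$start,
                                 df$end, df$strand))
  expect_identical(key(m2$exons), key(SIM$models$exons))
  expect_identical(key(m2$cds), key(SIM$models$cds))
})

test_that("Swiss-Prot filtering strips versions and flags genes", {
  m <- read_gtf(extdata("gencode_mini.gtf"))
  # metadata carries .N suffixes; match after version stripping either way
  md <- data.frame(V1 = c("ENST00000000101.99"), V2 = "Q12345")
  f <- filter_swissprot(m, md, keep_only = TRUE)
  expect_equal(f$genes$gene_id, "ENSG00000000001.1")
  expect_true(all(f$genes$swissprot_validated))

  f2 <- filter_swissprot(m, extdata("swissprot_mini.tsv"), keep_only = FALSE)
  expect_equal(sum(f2$genes$swissprot_validated), 2L)

  # empty metadata: warning, everything flagged FALSE
  empty <- tempfile(); file.create(empty)
  expect_warning(f3 <- filter_swissprot(m, empty), "empty")
  expect_false(any(f3$genes$swissprot_validated))
})
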