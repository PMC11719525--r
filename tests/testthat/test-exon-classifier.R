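# Gene templates used repeatedly: a 3-exon isoform with configurable CDS,
# plus variant isoforms that force each splice class.

test_that("coding composition follows the CDS span, strand-aware", {
  m <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 60), c(100, 200), c(300, 400)),
    cds = list(c(150, 200), c(300, 360)))))
  # CDS starts at 150, strictly inside [100, 200) -> start-codon exon
  expect_equal(coding_composition(m, "T1", 100, 200), "TYPE2_5UC")

  m2 <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 60), c(100, 200), c(300, 400)),
    cds = list(c(20, 60), c(100, 200), c(300, 360)))))
  expect_equal(coding_composition(m2, "T1", 100, 200), "TYPE3_CDS")

  # minus strand: exon numerically downstream of the CDS is 5' of it
  m3 <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "-",
    exons = list(c(0, 100), c(200, 300), c(400, 500)),
    cds = list(c(20, 100)))))
  expect_equal(coding_composition(m3, "T1", 200, 300), "TYPE1_5UTR")

  # exon absent from transcript -> error
  expect_error(coding_composition(m, "T1", 101, 200), "not found")
})

test_that("an exon containing the whole CDS is called 5UC and flagged", {
  m <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 60), c(100, 400), c(500, 600)),
    cds = list(c(150, 300)))))
  cls <- classify_all(m)
  expect_equal(cls$exons$coding_type, "TYPE2_5UC")
  expect_true(cls$exons$both_cds_ends)
})

test_that("isoform-dependent composition resolves by priority with a flag", {
  # isoform A: alternative (later) start codon inside the exon -> TYPE2;
  # isoform B: CDS from exon 1 -> exon fully coding, TYPE3
  m <- toy_models(list(
    A = list(gene = "G1", chrom = "chr1", strand = "+",
             exons = list(c(0, 60), c(100, 200), c(300, 400)),
             cds = list(c(150, 200), c(300, 360))),
    B = list(gene = "G1", chrom = "chr1", strand = "+",
             exons = list(c(0, 60), c(100, 200), c(300, 400)),
             cds = list(c(20, 60), c(100, 200), c(300, 330)))))
  r <- assign_coding_type(m, "G1", 100, 200)
  expect_equal(r$coding_type, "TYPE2_5UC")
  expect_true(r$conflict)

  # agreement (both isoforms end their CDS inside [300,400)): no conflict
  r2 <- assign_coding_type(m, "G1", 300, 400)
  expect_equal(r2$coding_type, "TYPE4_C3U")
  expect_false(r2$conflict)

  # only non-coding containing isoforms: no composition
  m3 <- toy_models(list(
    A = list(gene = "G1", chrom = "chr1", strand = "+",
             exons = list(c(0, 60), c(100, 200), c(300, 400)))))
  expect_true(is.na(assign_coding_type(m3, "G1", 100, 200)$coding_type))
  expect_equal(nrow(classify_all(m3)$dropped), 1L)
})

test_that("splice classes follow the covering-isoform rules in order", {
  base <- list(gene = "G1", chrom = "chr1", strand = "+",
               exons = list(c(0, 60), c(100, 200), c(300, 400)),
               cds = list(c(20, 60), c(100, 200), c(300, 330)))
  # present in all covering isoforms -> constitutive
  m <- toy_models(list(A = base, B = base))
  expect_equal(assign_splice_class(m, "G1", 100, 200), "CONSTITUTIVE")

  # completely absent from a covering isoform -> cassette exon
  skip_iso <- list(gene = "G1", chrom = "chr1", strand = "+",
                   exons = list(c(0, 60), c(300, 400)))
  m2 <- toy_models(list(A = base, B = skip_iso))
  expect_equal(assign_splice_class(m2, "G1", 100, 200), "ASE")

  # overlapping internal exon with a shifted 5' boundary -> SSE
  shift_iso <- list(gene = "G1", chrom = "chr1", strand = "+",
                    exons = list(c(0, 60), c(80, 200), c(300, 400)))
  m3 <- toy_models(list(A = base, B = shift_iso))
  expect_equal(assign_splice_class(m3, "G1", 100, 200), "SSE")

  # SSE is evaluated before ASE: with both a boundary-variant and a
  # skipping isoform the exon counts once, as SSE
  m4 <- toy_models(list(A = base, B = shift_iso, C = skip_iso))
  expect_equal(assign_splice_class(m4, "G1", 100, 200), "SSE")

  # overlap only with a transcript-terminal boundary -> other alternative
  readthrough <- list(gene = "G1", chrom = "chr1", strand = "+",
                      exons = list(c(0, 60), c(100, 240)))
  m5 <- toy_models(list(A = base, B = readthrough))
  expect_equal(assign_splice_class(m5, "G1", 100, 200), "OTHER_ALT")
})

test_that("classification recovers all planted labels and the quota table", {
  cls <- classify_all(SIM$models)
  truth <- SIM$truth
  expect_gte(length(unique(truth$gene_id)), 200L)
  got <- cls$exons[, c("gene_id", "start", "end", "coding_type",
                       "splice_class")]
  m <- merge(truth, got, by = c("gene_id", "start", "end"),
             suffixes = c(".planted", ""))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(nrow(cls$exons), nrow(truth))
  expect_identical(m$coding_type, m$coding_type.planted)
  expect_identical(m$splice_class, m$splice_class.planted)

  # partition: summary cells sum to the number of classified exons
  expect_equal(sum(cls$summary$total), nrow(cls$exons))
  expect_equal(cls$summary$total,
               with(cls$summary, ase + sse + other_alt + constitutive))

  # planted quota table reproduced exactly
  tab <- table(truth$coding_type, truth$splice_class)
  for (ty in rownames(tab)) {
    row <- cls$summary[cls$summary$coding_type == ty, ]
    expect_equal(row$ase, unname(tab[ty, "ASE"]))
    expect_equal(row$constitutive, unname(tab[ty, "CONSTITUTIVE"]))
  }
})

test_that("classification is independent of transcript input order", {
  m <- SIM$models
  perm <- sample(nrow(m$exons))
  m2 <- gene_models(m$genes[sample(nrow(m$genes)), ],
                    m$transcripts[sample(nrow(m$transcripts)), ],
                    m$exons[perm, ], m$cds[sample(nrow(m$cds)), ])
  # exon_rank must be rebuilt from coordinates to test true order freedom
  ex <- m2$exons
  data.table::setorder(ex, transcript_id, start)
  ex[, exon_rank := if (strand[1] == "+") seq_len(.N) else
    rev(seq_len(.N)), by = "transcript_id"]
  c1 <- classify_all(SIM$models)
  c2 <- classify_all(m2)
  expect_equal(c1$summary, c2$summary)
  o1 <- c1$exons[order(c1$exons$gene_id, c1$exons$start), ]
  o2 <- c2$exons[order(c2$exons$gene_id, c2$exons$start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("degenerate inputs: empty set and single-isoform genes", {
  m <- toy_models(list(T1 = list(
    gene = "G1", chrom = "chr1", strand = "+",
    exons = list(c(0, 60), c(100, 200), c(300, 400)),
    cds = list(c(20, 60), c(100, 200), c(300, 330)))))
  cls <- classify_all(m)
  expect_true(all(cls$exons$splice_class == "CONSTITUTIVE"))

  empty <- gene_models(
    m$genes[0, ], m$transcripts[0, ], m$exons[0, ], m$cds[0, ])
  cls0 <- classify_all(empty)
  expect_equal(nrow(cls0$exons), 0L)
  expect_equal(sum(cls0$summary$total), 0L)
})
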