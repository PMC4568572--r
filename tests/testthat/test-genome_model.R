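# genome annotation parsing, extension arithmetic and interval queries

two_gene_ann <- function(extension_nt = 50L) {
  make_annotation(list(
    list(strand = "+", start = 1001L, end = 2000L, cds = c(1101L, 1800L)),
    list(strand = "-", start = 5001L, end = 6000L, cds = c(5201L, 5800L))),
    chrom_len = c(chrS1 = 10000L), extension_nt = extension_nt)
}

test_that("3' extension is applied in transcription direction and clipped", {
  ann <- two_gene_ann()
  g <- ann$genes
  expect_equal(g$ext_end[g$strand == "+"], 2050L)   # 2000 + 50
  expect_equal(g$ext_start[g$strand == "+"], 1001L) # 5' end untouched
  expect_equal(g$ext_start[g$strand == "-"], 4951L) # 5001 - 50
  expect_equal(g$ext_end[g$strand == "-"], 6000L)

  ann0 <- two_gene_ann(extension_nt = 0L)
  expect_equal(ann0$genes$ext_start, ann0$genes$tx_start)
  expect_equal(ann0$genes$ext_end, ann0$genes$tx_end)

  # clipping at the chromosome end
  annc <- make_annotation(list(
    list(strand = "+", start = 901L, end = 980L, cds = c(910L, 960L))),
    chrom_len = c(chrS1 = 1000L))
  expect_equal(annc$genes$ext_end, 1000L)
})

test_that("intergenic intervals complement same-strand extended spans", {
  # two + genes [1,100], [201,300] on a 400-nt chromosome, no extension
  ann <- make_annotation(list(
    list(strand = "+", start = 1L, end = 100L),
    list(strand = "+", start = 201L, end = 300L)),
    chrom_len = c(chrS1 = 400L), extension_nt = 0L)
  iv <- intergenic_intervals(ann, "+")
  expect_equal(iv$start, c(101L, 301L))
  expect_equal(iv$end, c(200L, 400L))
  # the strand without genes is one full gap
  ivm <- intergenic_intervals(ann, "-")
  expect_equal(ivm$start, 1L)
  expect_equal(ivm$end, 400L)

  # overlapping same-strand genes emit no gap between them
  anno <- make_annotation(list(
    list(strand = "+", start = 50L, end = 150L),
    list(strand = "+", start = 100L, end = 250L)),
    chrom_len = c(chrS1 = 400L), extension_nt = 0L)
  ivo <- intergenic_intervals(anno, "+")
  expect_equal(ivo$start, c(1L, 251L))
  expect_equal(ivo$end, c(49L, 400L))

  expect_error(intergenic_intervals(ann, "+", chroms = "nope"),
               "unknown chromosome")
})

test_that("extended spans and intergenic intervals tile each strand", {
  sim <- acceptance_sim()
  ann <- sim$ann
  for (s in c("+", "-")) {
    for (chrom in names(ann$chrom_lengths)) {
      g <- ann$genes[ann$genes$strand == s & ann$genes$chrom == chrom, ]
      iv <- intergenic_intervals(ann, s, chroms = chrom)
      all_iv <- IRanges::reduce(c(
        IRanges::IRanges(g$ext_start, g$ext_end),
        IRanges::IRanges(iv$start, iv$end)))
      expect_equal(IRanges::start(all_iv), 1L)
      expect_equal(IRanges::end(all_iv), ann$chrom_lengths[[chrom]])
      # and no overlap: widths add up exactly
      expect_equal(sum(g$ext_end - g$ext_start + 1) +
                     sum(iv$end - iv$start + 1),
                   ann$chrom_lengths[[chrom]])
    }
  }
})

test_that("gene_boundary honors anchors and strand", {
  ann <- two_gene_ann()
  expect_equal(gene_boundary(ann, "g1", "stop_codon"), 1800L)
  expect_equal(gene_boundary(ann, "g2", "stop_codon"), 5201L)
  expect_equal(gene_boundary(ann, "g1", "tx_end_extended"), 2050L)
  expect_equal(gene_boundary(ann, "g2", "tx_end_extended"), 4951L)
  expect_equal(gene_boundary(ann, "g1", "tx_start"), 1001L)
  expect_equal(gene_boundary(ann, "g2", "tx_start"), 6000L)

  annn <- make_annotation(list(
    list(strand = "+", start = 100L, end = 400L, biotype = "ncRNA")),
    chrom_len = c(chrS1 = 1000L))
  expect_error(gene_boundary(annn, "g1", "stop_codon"),
               class = "missing_anchor")
  expect_error(gene_boundary(ann, "nope"), "unknown gene")
})

test_that("round trip through GFF3 preserves the gene set", {
  ann <- two_gene_ann()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  ann2 <- load_annotation(path, extension_nt = 50L)
  expect_equal(ann2$genes, ann$genes)
  expect_equal(ann2$chrom_lengths, ann$chrom_lengths)
  # feature derivation is reproduced too
  expect_equal(sort(as.character(ann2$features$type)),
               sort(as.character(ann$features$type)))
})

test_that("strand mirror reflects intergenic intervals", {
  len <- 10000L
  genes <- list(
    list(strand = "+", start = 1001L, end = 2000L, cds = c(1101L, 1800L)),
    list(strand = "-", start = 5001L, end = 6000L, cds = c(5201L, 5800L)))
  mirror <- lapply(genes, function(g) {
    list(strand = if (g$strand == "+") "-" else "+",
         start = len - g$end + 1L, end = len - g$start + 1L,
         cds = c(len - g$cds[2] + 1L, len - g$cds[1] + 1L))
  })
  ann <- make_annotation(genes, chrom_len = c(chrS1 = len))
  annm <- make_annotation(mirror, chrom_len = c(chrS1 = len))
  for (s in c("+", "-")) {
    iv <- intergenic_intervals(ann, s)
    ivm <- intergenic_intervals(annm, if (s == "+") "-" else "+")
    expect_equal(sort(len - iv$end + 1L), sort(ivm$start))
    expect_equal(sort(len - iv$start + 1L), sort(ivm$end))
  }
})

test_that("malformed input is rejected with informative errors", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrS1\tx\tgene\t10\t20"), bad)
  expect_error(load_annotation(bad), "line 2")

  degenerate <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chrS1 1 1000",
               "chrS1\tx\tgene\t500\t500\t.\t+\t.\tID=g1"), degenerate)
  expect_error(load_annotation(degenerate), "end <= start")
})
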