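# neighbor distances and normalized positions

nb_ann <- function() {
  # + genes at [1001,2000] (stop 1800, ext end 2050) and [8001,9000];
  # - gene at [4001,5000] (ext start 3951)
  make_annotation(list(
    list(id = "up", strand = "+", start = 1001L, end = 2000L,
         cds = c(1101L, 1800L)),
    list(id = "anti", strand = "-", start = 4001L, end = 5000L,
         cds = c(4201L, 4800L)),
    list(id = "down", strand = "+", start = 8001L, end = 9000L,
         cds = c(8101L, 8800L))),
    chrom_len = c(chrS1 = 20000L))
}

ipac_at <- function(pos, strand = "+") {
  p <- make_pac(dominant_site = pos, strand = strand)
  p$category <- "INTERGENIC"
  p
}

test_that("distances anchor at the stop codon and gene starts", {
  ann <- nb_ann()
  ctx <- neighbor_contexts(ipac_at(2922L), ann)
  # stop codon at 1800 -> d5s = 1122; "122 nt past a stop at 1000" geometry
  expect_equal(ctx$d5s, 1122)
  expect_equal(ctx$gene5s, "up")
  expect_equal(ctx$d3s, 8001 - 2922)
  expect_equal(ctx$gene3s, "down")
  # antisense gene [3951,5000]: left of it -> d3a on + orientation
  expect_equal(ctx$d3a, 3951 - 2922)
  expect_true(is.na(ctx$d5a)) # no antisense gene upstream of the site

  ext <- neighbor_contexts(ipac_at(2922L), ann,
                           sense_anchor = "tx_end_extended")
  expect_equal(ext$d5s, 2922 - 2050)
  expect_equal(ext$intergenic_len, ext$d5s + ext$d3s) # additivity
  expect_equal(ext$rel_pos, ext$d5s / ext$intergenic_len)
})

test_that("the strand-mirrored configuration gives identical distances", {
  len <- 20000L
  ann <- nb_ann()
  mirror <- make_annotation(list(
    list(id = "up", strand = "-", start = len - 2000L + 1L,
         end = len - 1001L + 1L, cds = c(len - 1800L + 1L, len - 1101L + 1L)),
    list(id = "anti", strand = "+", start = len - 5000L + 1L,
         end = len - 4001L + 1L, cds = c(len - 4800L + 1L, len - 4201L + 1L)),
    list(id = "down", strand = "-", start = len - 9000L + 1L,
         end = len - 8001L + 1L, cds = c(len - 8800L + 1L, len - 8101L + 1L))),
    chrom_len = c(chrS1 = len))
  a <- neighbor_contexts(ipac_at(2922L), ann)
  b <- neighbor_contexts(ipac_at(len - 2922L + 1L, strand = "-"), mirror)
  expect_equal(b$d5s, a$d5s)
  expect_equal(b$d3s, a$d3s)
  expect_equal(b$d5a, a$d5a)
  expect_equal(b$d3a, a$d3a)
  expect_equal(b$intergenic_len, a$intergenic_len)
})

test_that("absent neighbors give NA distances, not zero", {
  ann <- make_annotation(list(
    list(strand = "+", start = 1001L, end = 2000L, cds = c(1101L, 1800L))),
    chrom_len = c(chrS1 = 20000L))
  ctx <- neighbor_contexts(ipac_at(5000L), ann)
  expect_false(is.na(ctx$d5s))
  expect_true(is.na(ctx$d3s))       # no downstream sense gene
  expect_true(is.na(ctx$d5a))       # no antisense genes at all
  expect_true(is.na(ctx$d3a))
  expect_true(is.na(ctx$intergenic_len))
})

test_that("an overlapping antisense gene yields zero antisense distance", {
  ann <- nb_ann()
  ctx <- neighbor_contexts(ipac_at(4500L), ann)
  expect_equal(ctx$d5a, 0)
  expect_equal(ctx$d3a, 0)
})

test_that("shifting an IPAC moves d5s and d3s in lockstep", {
  ann <- nb_ann()
  for (k in c(10L, 137L, 1000L)) {
    a <- neighbor_contexts(ipac_at(3000L), ann,
                           sense_anchor = "tx_end_extended")
    b <- neighbor_contexts(ipac_at(3000L + k), ann,
                           sense_anchor = "tx_end_extended")
    expect_equal(b$d5s, a$d5s + k)
    expect_equal(b$d3s, a$d3s - k)
    expect_equal(b$intergenic_len, a$intergenic_len)
  }
})

test_that("additivity holds for every simulated IPAC with two neighbors", {
  run <- acceptance_run()
  ctx <- neighbor_contexts(run$ipacs, run$ann,
                           sense_anchor = "tx_end_extended")
  both <- !is.na(ctx$d5s) & !is.na(ctx$d3s)
  expect_gt(sum(both), 50)
  expect_equal(ctx$d5s[both] + ctx$d3s[both], ctx$intergenic_len[both])
  expect_true(all(ctx$rel_pos[both] >= 0 & ctx$rel_pos[both] <= 1))
})

test_that("rel_pos histogram reports the first-decile fraction", {
  # all mass in the first decile
  all_low <- make_ctx()[rep(1, 5), ]
  all_low$rel_pos <- 0.05
  h <- rel_position_histogram(all_low)
  expect_equal(h$frac_first_decile, 1)
  expect_equal(sum(h$histogram$count), 5L)

  # 8020 of 16567 at or below 0.1 -> 48.41 %
  ctx <- make_ctx()[rep(1, 16567), ]
  ctx$rel_pos <- c(rep(0.08, 8020), rep(0.6, 16567 - 8020))
  h2 <- rel_position_histogram(ctx)
  expect_equal(h2$frac_first_decile, 8020 / 16567)
  expect_equal(round(100 * h2$frac_first_decile, 2), 48.41)
  expect_equal(h2$n, 16567L)

  # uniform rel_pos -> about 10% per decile
  set.seed(1)
  u <- make_ctx()[rep(1, 20000), ]
  u$rel_pos <- runif(20000)
  hu <- rel_position_histogram(u)
  dec <- tapply(hu$histogram$count,
                rep(1:10, each = 10), sum) / 20000
  expect_true(all(abs(dec - 0.1) < 0.01))
})
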