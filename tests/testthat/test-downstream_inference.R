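# SO clustering, evidence association, correlations, cross-sample matching

so_rec <- function(pac_id, pos, chrom = "c1", strand = "+", tags = 5L) {
  p <- make_pac(pac_id = pac_id, chrom = chrom, dominant_site = pos,
                strand = strand, total_tags = tags)
  p$ipac_class <- "SO"
  p
}

far_ctx <- function(n = 1L) {
  make_ctx(d5s = 5000, d3s = 5000, d5a = 5000, d3a = 5000)[rep(1, n), ]
}

test_that("inter-PAC distance reproduces the published arithmetic", {
  expect_equal(inter_pac_distance(935, 2.17), 431)
  expect_equal(inter_pac_distance(100, 1), 100)
  expect_equal(inter_pac_distance(0, 2), 0)
  expect_error(inter_pac_distance(100, 0), "mean_pacs_per_utr")
  expect_error(inter_pac_distance(-1, 1), "mean_utr_len")
})

test_that("SO clustering excludes near-gene sites then chains the rest", {
  rec <- rbind(so_rec("a", 1000L), so_rec("b", 1400L), so_rec("c", 5000L))
  out <- cluster_so(rec, far_ctx(3), linkage_nt = 431L)
  expect_equal(out$n_excluded, 0L)
  expect_equal(nrow(out$clusters), 2L)
  expect_equal(out$clusters$n_members, c(2L, 1L))

  # all within 2000 nt of a gene -> everything excluded
  near <- make_ctx(d5s = 900, d3s = 5000, d5a = 5000, d3a = 5000)[rep(1, 3), ]
  out2 <- cluster_so(rec, near)
  expect_equal(out2$n_excluded, 3L)
  expect_equal(nrow(out2$clusters), 0L)

  single <- cluster_so(so_rec("solo", 9000L), far_ctx(1))
  expect_equal(nrow(single$clusters), 1L)
  expect_equal(single$clusters$n_members, 1L)
})

test_that("cluster representatives are the max-tag members", {
  rec <- rbind(so_rec("a", 1000L, tags = 2L), so_rec("b", 1300L, tags = 9L))
  out <- cluster_so(rec, far_ctx(2))
  expect_equal(out$clusters$dominant_pac, "b")
  expect_equal(out$clusters$dominant_site, 1300L)
  # tie breaks toward the smaller coordinate
  tie <- rbind(so_rec("a", 1000L, tags = 5L), so_rec("b", 1300L, tags = 5L))
  expect_equal(cluster_so(tie, far_ctx(2))$clusters$dominant_pac, "a")
})

test_that("SO clustering equals brute-force components", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:50, 1)
    rec <- do.call(rbind, lapply(seq_len(n), function(i) {
      so_rec(sprintf("p%02d", i), sample(1:20000, 1),
             chrom = sample(c("c1", "c2"), 1),
             strand = sample(c("+", "-"), 1))
    }))
    rec <- rec[!duplicated(rec[c("chrom", "strand", "dominant_site")]), ]
    out <- cluster_so(rec, far_ctx(nrow(rec)), linkage_nt = 431L)
    member_lists <- strsplit(out$clusters$members, ",")
    got_labels <- rep(seq_along(member_lists), lengths(member_lists))
    got_idx <- match(unlist(member_lists), rec$pac_id)
    got_key <- paste(rec$chrom[got_idx], rec$strand[got_idx],
                     rec$dominant_site[got_idx])
    want <- brute_cluster(rec$dominant_site, rec$chrom, rec$strand, 431L)
    want_key <- paste(rec$chrom, rec$strand, rec$dominant_site)
    expect_identical(partition_sets(got_labels, got_key),
                     partition_sets(want, want_key))
  }
})

test_that("evidence verification honors the three anchor modes", {
  # point mode: |site - anchor| <= window
  est <- evidence_set("est", data.frame(chrom = "c1", start = 10000L,
                                        end = 10000L),
                      anchor_mode = "point", window_nt = 500L)
  items <- data.frame(chrom = "c1", pos = c(10300L, 10501L))
  expect_equal(verify_against_evidence(items, est), c(TRUE, FALSE))

  # interval mode with a 200-nt margin: 201 nt away fails
  nv <- evidence_set("novel", data.frame(chrom = "c1", start = 5000L,
                                         end = 6000L),
                     anchor_mode = "interval", window_nt = 200L)
  iv_items <- data.frame(chrom = "c1", pos = c(6200L, 6201L, 5500L))
  expect_equal(verify_against_evidence(iv_items, nv), c(TRUE, FALSE, TRUE))

  # directional: downstream of the interval end in its strand direction
  orf <- evidence_set("orf", data.frame(chrom = "c1", start = 2000L,
                                        end = 2300L, strand = "+"),
                      anchor_mode = "directional", window_nt = 2000L)
  d_items <- data.frame(chrom = "c1", pos = c(3800L, 4301L, 1900L))
  expect_equal(verify_against_evidence(d_items, orf),
               c(TRUE, FALSE, FALSE))
  orf_m <- evidence_set("orf", data.frame(chrom = "c1", start = 2000L,
                                          end = 2300L, strand = "-"),
                        anchor_mode = "directional", window_nt = 2000L)
  expect_equal(verify_against_evidence(data.frame(chrom = "c1", pos = 500L),
                                       orf_m), TRUE)
})

test_that("enlarging the window never unverifies an item", {
  set.seed(4)
  iv <- data.frame(chrom = "c1", start = sample(1:50000, 20), end = NA)
  iv$end <- iv$start + sample(100:500, 20)
  items <- data.frame(chrom = "c1", pos = sample(1:50000, 100))
  prev <- rep(FALSE, 100)
  for (w in c(0L, 100L, 500L, 2000L)) {
    cur <- verify_against_evidence(
      items, evidence_set("x", iv, anchor_mode = "interval",
                          window_nt = w))
    expect_true(all(cur | !prev))
    prev <- cur
  }
})

test_that("malformed evidence BED is rejected", {
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100"), bad)
  expect_error(read_evidence_bed(bad), "malformed BED")
  good <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t200\tx\t0\t+"), good)
  ev <- read_evidence_bed(good, window_nt = 10L)
  expect_equal(ev$intervals$start, 100L)
  expect_equal(ev$intervals$strand, "+")
})

test_that("expression correlation behaves like Pearson's r", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(expression_correlation(x, x)$r, 1)
  expect_equal(expression_correlation(x, -x)$r, -1)
  expect_error(expression_correlation(x, rep(2, 5)), "zero variance")
  expect_error(expression_correlation(1:2, 1:2), "length >= 3")
  set.seed(10)
  n <- 1000
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  r <- expression_correlation(a, b)
  expect_lt(abs(r$r - 0.5), 0.06)
  expect_lt(r$p_value, 1e-10)
})

test_that("cross-sample matching applies the 50-nt one-to-one rule", {
  a <- do.call(rbind, lapply(1:10, function(i) {
    make_pac(pac_id = sprintf("a%d", i), chrom = "c1",
             dominant_site = 1000L * i, total_tags = i)
  }))
  ident <- cross_sample_match(a, a)
  expect_equal(ident$shared_fraction, 1)
  expect_equal(ident$count_correlation$r, 1)

  b_far <- a
  b_far$chrom <- "c9"
  expect_equal(cross_sample_match(a, b_far)$shared_fraction, 0)

  b50 <- a
  b50$dominant_site <- a$dominant_site + 50L
  expect_equal(cross_sample_match(a, b50)$shared_fraction, 1)
  b51 <- a
  b51$dominant_site <- a$dominant_site + 51L
  expect_equal(cross_sample_match(a, b51)$shared_fraction, 0)

  # strand must match
  b_strand <- a
  b_strand$strand <- "-"
  expect_equal(cross_sample_match(a, b_strand)$shared_fraction, 0)

  # asymmetric by definition: fraction is relative to the first set
  expect_equal(cross_sample_match(a[1:4, ], a)$shared_fraction, 1)
  expect_equal(cross_sample_match(a, a[1:4, ])$shared_fraction, 0.4)

  # one-to-one: two A sites cannot share one B site
  a2 <- rbind(make_pac(pac_id = "x", dominant_site = 100L),
              make_pac(pac_id = "y", dominant_site = 140L))
  b1 <- make_pac(pac_id = "z", dominant_site = 120L)
  m <- cross_sample_match(a2, b1)
  expect_equal(m$n_shared, 1L)
})
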