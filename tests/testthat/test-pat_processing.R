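# cleavage-site clustering, support filtering, internal-priming filter

mk_sites <- function(pos, n_tags = rep(3L, length(pos)), chrom = "c1",
                     strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             n_tags = as.integer(n_tags), stringsAsFactors = FALSE)
}

test_that("single-linkage chaining joins sites within the gap", {
  one <- cluster_sites(mk_sites(c(100, 120, 140)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 100L)
  expect_equal(one$end, 140L)
  expect_equal(one$total_tags, 9L)

  two <- cluster_sites(mk_sites(c(100, 130)))
  expect_equal(nrow(two), 2L)

  # exactly 24 joins, 25 does not
  expect_equal(nrow(cluster_sites(mk_sites(c(100, 124)))), 1L)
  expect_equal(nrow(cluster_sites(mk_sites(c(100, 125)))), 2L)

  expect_equal(nrow(cluster_sites(mk_sites(integer(0)))), 0L)
  expect_error(cluster_sites(mk_sites(100), max_gap = -1), "max_gap")
  expect_error(cluster_sites(mk_sites(c(100, 100))), "duplicate")
})

test_that("strands and chromosomes never mix", {
  s <- rbind(mk_sites(c(100, 110), strand = "+"),
             mk_sites(c(105, 115), strand = "-"),
             mk_sites(c(100, 110), chrom = "c2"))
  pacs <- cluster_sites(s)
  expect_equal(nrow(pacs), 3L)
})

test_that("dominant site is the max-tag member, distal on ties", {
  p <- cluster_sites(mk_sites(c(100, 110, 120), c(2, 9, 4)))
  expect_equal(p$dominant_site, 110L)
  tie_plus <- cluster_sites(mk_sites(c(100, 120), c(5, 5)))
  expect_equal(tie_plus$dominant_site, 120L)
  tie_minus <- cluster_sites(mk_sites(c(100, 120), c(5, 5), strand = "-"))
  expect_equal(tie_minus$dominant_site, 100L)
})

test_that("clustering matches the brute-force component oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:50, 1)
    s <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      pos = sample(1:2000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      n_tags = sample(1:9, n, replace = TRUE))
    s <- s[!duplicated(s[c("chrom", "pos", "strand")]), ]
    pacs <- cluster_sites(s, max_gap = 24L)
    # expand members back out of the PAC table
    got_labels <- rep(seq_len(nrow(pacs)),
                      vapply(pacs$sites, nrow, 1L))
    got_key <- unlist(lapply(seq_len(nrow(pacs)), function(i) {
      paste(pacs$chrom[i], pacs$strand[i], pacs$sites[[i]]$pos)
    }))
    want_labels <- brute_cluster(s$pos, s$chrom, s$strand, 24L)
    want_key <- paste(s$chrom, s$strand, s$pos)
    expect_identical(partition_sets(got_labels, got_key),
                     partition_sets(want_labels, want_key))
  }
})

test_that("clustering is idempotent, order-free and conserves tags", {
  set.seed(42)
  s <- data.frame(chrom = "c1", pos = sample(1:5000, 200),
                  strand = sample(c("+", "-"), 200, replace = TRUE),
                  n_tags = sample(1:20, 200, replace = TRUE))
  s <- s[!duplicated(s[c("chrom", "pos", "strand")]), ]
  pacs <- cluster_sites(s)
  expect_equal(sum(pacs$total_tags), sum(s$n_tags)) # conservation
  # permutation invariance
  perm <- cluster_sites(s[sample(nrow(s)), ])
  expect_equal(perm[, c("chrom", "strand", "start", "end", "total_tags")],
               pacs[, c("chrom", "strand", "start", "end", "total_tags")])
  # idempotence: re-cluster the member sites
  members <- do.call(rbind, lapply(seq_len(nrow(pacs)), function(i) {
    cbind(chrom = pacs$chrom[i], pacs$sites[[i]], strand = pacs$strand[i])
  }))
  again <- cluster_sites(members[, c("chrom", "pos", "strand", "n_tags")])
  expect_equal(again[, c("chrom", "strand", "start", "end", "total_tags")],
               pacs[, c("chrom", "strand", "start", "end", "total_tags")])
})

test_that("support filter keeps >= min_tags and preserves order", {
  pacs <- cluster_sites(mk_sites(c(100, 200, 300), c(3, 2, 7)))
  kept <- filter_min_support(pacs, 3L)
  expect_equal(kept$total_tags, c(3L, 7L))
  expect_equal(filter_min_support(pacs, 1L), pacs) # identity
  expect_error(filter_min_support(pacs, 0L), "min_tags")
})

test_that("priming filter applies strict thresholds to the downstream 20-mer", {
  mkg <- function(win) {
    # site at position 10 on +: downstream window is bases 11..30
    make_genome(c1 = paste0(strrep("C", 10), win, strrep("C", 10)))
  }
  pac <- make_pac(chrom = "c1", dominant_site = 10L)
  run <- function(win) {
    internal_priming_filter(pac, mkg(win))
  }
  # 11 A (55% A) -> discard
  expect_false(run(paste0(strrep("A", 11), strrep("T", 9)))$keep)
  # 10 A + 2 G: A = 50%, A+G = 60%, neither strictly exceeded -> keep
  expect_true(run(paste0(strrep("A", 10), "GG", strrep("T", 8)))$keep)
  # 8 A + 5 G: A+G = 65% -> discard
  expect_false(run(paste0(strrep("A", 8), strrep("G", 5),
                          strrep("T", 7)))$keep)
  # minus strand reads the reverse complement: 11 T upstream -> 11 A downstream
  gm <- make_genome(c1 = paste0(strrep("G", 10), strrep("T", 11),
                                strrep("G", 20)))
  pm <- make_pac(chrom = "c1", dominant_site = 22L, strand = "-")
  expect_false(internal_priming_filter(pm, gm)$keep)
})

test_that("windows truncated at the chromosome end are flagged", {
  g <- make_genome(c1 = paste0(strrep("C", 30), strrep("A", 10)))
  pac <- make_pac(chrom = "c1", dominant_site = 30L)
  r <- internal_priming_filter(pac, g)
  expect_true(r$truncated)
  expect_false(r$keep) # 10/10 A in the available window
  # nothing downstream at all -> keep, flagged
  pac_end <- make_pac(chrom = "c1", dominant_site = 40L)
  r2 <- internal_priming_filter(pac_end, g)
  expect_true(r2$truncated)
  expect_true(r2$keep)
})

test_that("BED round trip merges duplicate sites", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t100\ts1\t3\t+",
               "c1\t99\t100\ts2\t2\t+",
               "c1\t199\t200\ts3\t4\t-"), path)
  s <- read_cleavage_sites(path)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_tags[s$pos == 100L], 5L)
})
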