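# Downstream inference: SO-IPAC clustering into candidate novel
# transcripts, association with external evidence intervals, expression
# correlation of antisense events, and cross-sample IPAC comparison.

#' Expected distance between poly(A) sites of one gene
#'
#' The average 3'-UTR length divided by the average number of PACs per
#' 3'-UTR gives the typical spacing of alternative poly(A) sites within a
#' gene, used as the linkage distance when clustering orphan IPACs.
#'
#' @param mean_utr_len Mean (extended) 3'-UTR length in nt.
#' @param mean_pacs_per_utr Mean number of PACs per 3'-UTR.
#' @return Distance in nt, rounded to the nearest integer.
#' @export
inter_pac_distance <- function(mean_utr_len, mean_pacs_per_utr) {
  if (mean_utr_len < 0 || mean_pacs_per_utr <= 0) {
    stop("mean_utr_len must be >= 0 and mean_pacs_per_utr > 0")
  }
  round(mean_utr_len / mean_pacs_per_utr)
}

#' Cluster SO-IPACs into candidate novel transcripts
#'
#' SO-IPACs within `near_gene_exclusion_nt` of any neighbouring gene
#' (minimum over the four context distances, either strand) are excluded
#' first as likely extensions or false positives; the remainder is
#' single-linkage clustered at `linkage_nt` per chromosome and strand. Each
#' cluster's representative is its dominant (max-tag) member.
#'
#' @param so_records [classify_ipacs()] rows labeled `SO`.
#' @param contexts Matching [neighbor_contexts()] rows (1:1).
#' @param near_gene_exclusion_nt Exclusion radius (default 2000).
#' @param linkage_nt Single-linkage distance (default 431, see
#'   [inter_pac_distance()]).
#' @return A list with `clusters` (data.frame: `cluster_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_members`, `dominant_site`,
#'   `dominant_pac`, `total_tags`, `members`), `n_excluded` and `retained`
#'   (the clustered subset of `so_records`).
#' @export
cluster_so <- function(so_records, contexts, near_gene_exclusion_nt = 2000L,
                       linkage_nt = 431L) {
  so <- so_records$ipac_class == "SO"
  rec <- so_records[so, , drop = FALSE]
  ctx <- contexts[so, , drop = FALSE]
  dmin <- suppressWarnings(
    pmin(ctx$d5s, ctx$d3s, ctx$d5a, ctx$d3a, na.rm = TRUE))
  dmin[is.infinite(dmin)] <- NA_real_
  excl <- !is.na(dmin) & dmin < near_gene_exclusion_nt
  kept <- rec[!excl, , drop = FALSE]
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      dominant_site = integer(), dominant_pac = character(),
                      total_tags = integer(), members = character())
  if (nrow(kept) == 0L) {
    return(list(clusters = empty, n_excluded = sum(excl), retained = kept))
  }
  dt <- data.table::as.data.table(
    kept[, c("pac_id", "chrom", "strand", "dominant_site", "total_tags")])
  data.table::setorder(dt, chrom, strand, dominant_site)
  dt[, gap_break := c(TRUE, diff(dominant_site) > linkage_nt),
     by = c("chrom", "strand")]
  dt[, cl := cumsum(gap_break)]
  agg <- dt[, {
    imax <- which(total_tags == max(total_tags))
    dom <- min(dominant_site[imax]) # tie -> smaller coordinate
    list(start = min(dominant_site), end = max(dominant_site),
         n_members = .N, dominant_site = dom,
         dominant_pac = pac_id[dominant_site == dom][1L],
         total_tags = sum(total_tags),
         members = paste(pac_id, collapse = ","))
  }, by = c("chrom", "strand", "cl")]
  agg[, cl := NULL]
  data.table::setorder(agg, chrom, start)
  clusters <- as.data.frame(agg)
  clusters <- cbind(cluster_id = sprintf("SOC%04d", seq_len(nrow(clusters))),
                    clusters, stringsAsFactors = FALSE)
  list(clusters = clusters, n_excluded = sum(excl), retained = kept)
}

#' Define an evidence interval set
#'
#' @param name Label of the evidence source (e.g. `"EST"`, `"rnaseq"`).
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `strand`.
#' @param window_nt Association window in nt.
#' @param anchor_mode `"point"` (anchor = interval midpoint, |site - anchor|
#'   <= window), `"interval"` (site within the interval widened by window on
#'   both sides) or `"directional"` (site within window nt downstream of the
#'   interval end, in the interval's strand direction).
#' @return A list of class `evidence_set`.
#' @export
evidence_set <- function(name, intervals,
                         anchor_mode = c("point", "interval", "directional"),
                         window_nt = 0L) {
  anchor_mode <- match.arg(anchor_mode)
  if (window_nt < 0) stop("window_nt must be >= 0")
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (anchor_mode == "directional" && is.null(intervals$strand)) {
    stop("directional evidence requires a strand column")
  }
  structure(list(name = name, intervals = intervals,
                 anchor_mode = anchor_mode, window_nt = window_nt),
            class = "evidence_set")
}

#' Read an evidence BED file
#'
#' @param path BED file (3+ columns; strand read from column 6 when
#'   present).
#' @param name,anchor_mode,window_nt Passed to [evidence_set()]; `name`
#'   defaults to the file name.
#' @return An `evidence_set`.
#' @export
read_evidence_bed <- function(path, name = basename(path),
                              anchor_mode = "interval", window_nt = 0L) {
  bed <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed BED '%s': %s", path,
                                     conditionMessage(e))))
  if (ncol(bed) < 3L) stop(sprintf("malformed BED '%s': fewer than 3 columns",
                                   path))
  iv <- data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]) + 1L,
                   end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  if (ncol(bed) >= 6L) iv$strand <- bed[[6]]
  evidence_set(name, iv, anchor_mode = anchor_mode, window_nt = window_nt)
}

#' Flag items supported by an evidence set
#'
#' @param items data.frame with `chrom`, `pos` (e.g. cluster dominant sites
#'   or IPAC dominant sites).
#' @param ev An [evidence_set()].
#' @return Logical vector aligned with `items`.
#' @export
verify_against_evidence <- function(items, ev) {
  stopifnot(inherits(ev, "evidence_set"))
  iv <- ev$intervals
  w <- ev$window_nt
  out <- logical(nrow(items))
  for (i in seq_len(nrow(items))) {
    sel <- iv$chrom == items$chrom[i]
    if (!any(sel)) next
    s <- iv[sel, , drop = FALSE]
    pos <- items$pos[i]
    out[i] <- switch(ev$anchor_mode,
      point = any(abs(pos - floor((s$start + s$end) / 2)) <= w),
      interval = any(pos >= s$start - w & pos <= s$end + w),
      directional = any(ifelse(s$strand == "-",
                               s$start - pos >= 0 & s$start - pos <= w,
                               pos - s$end >= 0 & pos - s$end <= w)))
  }
  out
}

#' Pearson correlation of paired expression levels
#'
#' @param x_counts,y_counts Paired numeric vectors (length >= 3), e.g. tag
#'   counts of A-IPACs and of their target antisense genes.
#' @return A list with `r`, `p_value`, `n`.
#' @export
expression_correlation <- function(x_counts, y_counts) {
  if (length(x_counts) != length(y_counts) || length(x_counts) < 3L) {
    stop("need paired vectors of length >= 3")
  }
  if (stats::sd(x_counts) == 0 || stats::sd(y_counts) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x_counts, y_counts, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x_counts))
}

#' Match IPACs across two samples
#'
#' An IPAC of sample A is shared when a same-strand IPAC of sample B has its
#' dominant site within `match_window` nt. Matching is one-to-one greedy by
#' distance (ties broken toward the smaller coordinate), so each B IPAC
#' supports at most one A IPAC. The shared fraction is relative to |A|
#' (asymmetric by definition); the count correlation is Pearson's r over
#' the matched pairs' total tag counts.
#'
#' @param ipacs_a,ipacs_b data.frames with `pac_id`, `chrom`, `strand`,
#'   `dominant_site`, `total_tags`.
#' @param match_window Maximum dominant-site distance (default 50 nt).
#' @return A list with `pairs` (matched table), `n_a`, `n_shared`,
#'   `shared_fraction` and `count_correlation` (`NULL` when fewer than 3
#'   pairs or degenerate counts).
#' @export
cross_sample_match <- function(ipacs_a, ipacs_b, match_window = 50L) {
  gr_a <- GenomicRanges::GRanges(
    ipacs_a$chrom,
    IRanges::IRanges(ipacs_a$dominant_site - match_window,
                     ipacs_a$dominant_site + match_window),
    strand = ipacs_a$strand)
  gr_b <- GenomicRanges::GRanges(
    ipacs_b$chrom,
    IRanges::IRanges(ipacs_b$dominant_site, ipacs_b$dominant_site),
    strand = ipacs_b$strand)
  # disjoint chromosome sets are a legitimate (empty) comparison
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_a, gr_b, ignore.strand = FALSE))
  cand <- data.frame(a = S4Vectors::queryHits(hits),
                     b = S4Vectors::subjectHits(hits))
  cand$dist <- abs(ipacs_a$dominant_site[cand$a] -
                     ipacs_b$dominant_site[cand$b])
  cand <- cand[order(cand$dist, ipacs_a$dominant_site[cand$a]), ,
               drop = FALSE]
  used_a <- logical(nrow(ipacs_a)); used_b <- logical(nrow(ipacs_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$a[k]] && !used_b[cand$b[k]]) {
      keep[k] <- TRUE
      used_a[cand$a[k]] <- TRUE
      used_b[cand$b[k]] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- data.frame(
    pac_a = ipacs_a$pac_id[pairs$a], pac_b = ipacs_b$pac_id[pairs$b],
    dist = pairs$dist,
    tags_a = ipacs_a$total_tags[pairs$a],
    tags_b = ipacs_b$total_tags[pairs$b], stringsAsFactors = FALSE)
  corr <- if (nrow(pairs) >= 3L && stats::sd(pairs$tags_a) > 0 &&
              stats::sd(pairs$tags_b) > 0) {
    expression_correlation(pairs$tags_a, pairs$tags_b)
  } else NULL
  list(pairs = pairs, n_a = nrow(ipacs_a), n_shared = nrow(pairs),
       shared_fraction = if (nrow(ipacs_a)) nrow(pairs) / nrow(ipacs_a)
                         else NA_real_,
       count_correlation = corr)
}
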