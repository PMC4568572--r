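# Poly(A)-tag processing: cleavage sites -> poly(A) site clusters (PACs).
# Single-linkage chaining at 24 nt absorbs cleavage microheterogeneity; the
# 3-tag support filter and the internal-priming sequence filter follow.

#' Read cleavage sites from a BED6 file
#'
#' One row per cleavage site, score column = tag count. The BED `end`
#' coordinate is taken as the 1-based cleavage position. Duplicate
#' (chrom, pos, strand) entries are merged by summing counts.
#'
#' @param path BED6 file path.
#' @return A data.frame with `chrom`, `pos`, `strand`, `n_tags`.
#' @export
read_cleavage_sites <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop(sprintf("'%s' is not BED6", path))
  sites <- data.frame(chrom = bed[[1]], pos = as.integer(bed[[3]]),
                      strand = bed[[6]], n_tags = as.integer(bed[[5]]),
                      stringsAsFactors = FALSE)
  if (any(sites$n_tags < 1L)) stop("tag counts must be >= 1")
  sites <- stats::aggregate(n_tags ~ chrom + pos + strand, sites, sum)
  sites[order(sites$chrom, sites$strand, sites$pos), ]
}

#' Cluster cleavage sites into PACs
#'
#' Single-linkage chaining per chromosome and strand: consecutive sorted
#' sites at most `max_gap` nt apart join the same cluster. Each PAC records
#' its span, member sites, total tag count and the dominant (max-tag)
#' representative site.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`, `n_tags`
#'   (duplicates pre-merged; see [read_cleavage_sites()]).
#' @param max_gap Maximum distance between neighbouring member sites
#'   (default 24 nt).
#' @return A data.frame of PACs sorted by (chrom, start): `pac_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_sites`, `total_tags`, `dominant_site`,
#'   `dominant_tags`, plus a `sites` list-column of member data.frames.
#' @export
cluster_sites <- function(sites, max_gap = 24L) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  cols <- c("chrom", "pos", "strand", "n_tags")
  if (nrow(sites) == 0L) {
    return(data.frame(pac_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      total_tags = integer(), dominant_site = integer(),
                      dominant_tags = integer()))
  }
  stopifnot(all(cols %in% names(sites)))
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, strand) sites: pre-merge counts first")
  }
  dt <- data.table::as.data.table(sites[, cols])
  data.table::setorder(dt, chrom, strand, pos)
  dt[, gap_break := c(TRUE, diff(pos) > max_gap),
     by = c("chrom", "strand")]
  dt[, cluster := cumsum(gap_break)]
  agg <- dt[, {
    imax <- which(n_tags == max(n_tags))
    # tie-break: the more distal member in transcription direction
    dom <- if (strand[1] == "+") max(pos[imax]) else min(pos[imax])
    list(start = min(pos), end = max(pos), n_sites = .N,
         total_tags = sum(n_tags), dominant_site = dom,
         dominant_tags = max(n_tags),
         sites = list(data.frame(pos = pos, n_tags = n_tags)))
  }, by = c("chrom", "strand", "cluster")]
  agg[, cluster := NULL]
  data.table::setorder(agg, chrom, start)
  pacs <- as.data.frame(agg)
  pacs <- cbind(pac_id = sprintf("PAC%05d", seq_len(nrow(pacs))), pacs,
                stringsAsFactors = FALSE)
  pacs
}

#' Drop PACs below the minimum tag support
#'
#' @param pacs PAC data.frame from [cluster_sites()].
#' @param min_tags Minimum total tag count to retain a PAC (default 3).
#' @return The retained subset in the original order.
#' @export
filter_min_support <- function(pacs, min_tags = 3L) {
  if (min_tags < 1) stop("min_tags must be >= 1")
  pacs[pacs$total_tags >= min_tags, , drop = FALSE]
}

#' Internal-priming sequence filter
#'
#' Examines the genomic 20-mer immediately downstream (3', in the PAC's
#' strand direction) of each dominant site. A PAC is discarded when the
#' window holds strictly more than 50 % A, or strictly more than 60 % A+G --
#' the signature of oligo(dT) priming within an A-rich tract rather than a
#' true poly(A) tail. Windows truncated by the chromosome end are evaluated
#' over the available length and flagged.
#'
#' @param pacs PAC data.frame (needs `chrom`, `strand`, `dominant_site`).
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param window_nt Downstream window length (default 20).
#' @param a_frac Maximum tolerated A fraction (strict; default 0.50).
#' @param ag_frac Maximum tolerated A+G fraction (strict; default 0.60).
#' @return A data.frame with `keep` (logical), `frac_a`, `frac_ag`,
#'   `truncated`, aligned with `pacs` rows.
#' @export
internal_priming_filter <- function(pacs, genome, window_nt = 20L,
                                    a_frac = 0.50, ag_frac = 0.60) {
  genome <- .as_genome(genome)
  n <- nrow(pacs)
  out <- data.frame(keep = logical(n), frac_a = numeric(n),
                    frac_ag = numeric(n), truncated = logical(n))
  for (i in seq_len(n)) {
    s <- downstream_seq(genome, pacs$chrom[i], pacs$dominant_site[i],
                        pacs$strand[i], window_nt)
    len <- nchar(s)
    out$truncated[i] <- len < window_nt
    if (len == 0L) { # nothing downstream: cannot look A-rich
      out$keep[i] <- TRUE
      next
    }
    counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                          c("A", "G"))
    out$frac_a[i] <- counts[["A"]] / len
    out$frac_ag[i] <- (counts[["A"]] + counts[["G"]]) / len
    out$keep[i] <- !(out$frac_a[i] > a_frac || out$frac_ag[i] > ag_frac)
  }
  out
}

.as_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  genome
}

#' Oriented downstream genomic sequence of a cleavage site
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,pos,strand Site coordinates.
#' @param window_nt Window length.
#' @return Character sequence read 5'->3' on the site's strand, truncated at
#'   the chromosome boundary.
#' @export
downstream_seq <- function(genome, chrom, pos, strand, window_nt = 20L) {
  len <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    s <- min(pos + 1L, len + 1L); e <- min(pos + window_nt, len)
    if (s > e) return("")
    as.character(Biostrings::subseq(genome[[chrom]], s, e))
  } else {
    s <- max(pos - window_nt, 1L); e <- max(pos - 1L, 0L)
    if (s > e) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], s, e)))
  }
}

#' Write a PAC table as TSV
#'
#' Flat BED-like table: chrom, start, end, pac_id, total_tags, strand,
#' dominant_site, n_sites.
#'
#' @param pacs PAC data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pacs <- function(pacs, path) {
  utils::write.table(
    pacs[, c("chrom", "start", "end", "pac_id", "total_tags", "strand",
             "dominant_site", "n_sites")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
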