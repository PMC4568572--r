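# Neighbor geometry of intergenic PACs: distances to the nearest sense and
# antisense genes on both sides, the containing same-strand intergenic gap,
# and positions normalized by gap length.

#' Neighbor context of intergenic PACs
#'
#' For every IPAC, computes the four distances to its neighbouring genes in
#' the IPAC's own strand orientation: `d5s` to the upstream sense gene
#' (anchored at its stop codon or extended 3' end), `d3s` to the downstream
#' sense gene's transcription start, and `d5a`/`d3a` to the nearest
#' opposite-strand gene boundary on either side (0 when an antisense gene
#' overlaps the site). `intergenic_len` is the distance between the flanking
#' extended sense boundaries, so that `d5s + d3s = intergenic_len` holds
#' exactly when `sense_anchor = "tx_end_extended"`; `rel_pos` is the
#' extended-anchor `d5s` divided by `intergenic_len`. Distances are `NA`
#' (absent), not zero, when no gene exists on the corresponding side.
#'
#' @param ipacs Annotated PAC data.frame (INTERGENIC rows).
#' @param ann An `ExtendedAnnotation`.
#' @param sense_anchor `"stop_codon"` (default; non-coding upstream genes
#'   fall back to the extended end) or `"tx_end_extended"`.
#' @return A data.frame aligned with `ipacs`: `d5s`, `d3s`, `d5a`, `d3a`,
#'   `intergenic_len`, `rel_pos`, `gene5s`, `gene3s`.
#' @export
neighbor_contexts <- function(ipacs, ann,
                              sense_anchor = c("stop_codon",
                                               "tx_end_extended")) {
  sense_anchor <- match.arg(sense_anchor)
  stopifnot(inherits(ann, "ExtendedAnnotation"))
  n <- nrow(ipacs)
  out <- data.frame(d5s = rep(NA_real_, n), d3s = NA_real_, d5a = NA_real_,
                    d3a = NA_real_, intergenic_len = NA_real_,
                    rel_pos = NA_real_, gene5s = NA_character_,
                    gene3s = NA_character_, stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  g <- ann$genes
  for (i in seq_len(n)) {
    chrom <- ipacs$chrom[i]; pos <- ipacs$dominant_site[i]
    strand <- ipacs$strand[i]
    same <- g[g$chrom == chrom & g$strand == strand, ]
    opp <- g[g$chrom == chrom & g$strand != strand, ]
    if (strand == "+") {
      up <- same[same$ext_end <= pos, ]
      if (nrow(up)) {
        k <- which.max(up$ext_end)
        out$gene5s[i] <- up$gene_id[k]
        d5x <- pos - up$ext_end[k]
        out$d5s[i] <- if (sense_anchor == "stop_codon" &&
                          !is.na(up$stop_codon_pos[k])) {
          pos - up$stop_codon_pos[k]
        } else d5x
        d5s_ext <- d5x
      } else d5s_ext <- NA_real_
      dn <- same[same$tx_start >= pos, ]
      if (nrow(dn)) {
        k <- which.min(dn$tx_start)
        out$gene3s[i] <- dn$gene_id[k]
        out$d3s[i] <- dn$tx_start[k] - pos
      }
      if (!is.na(d5s_ext) && !is.na(out$d3s[i])) {
        out$intergenic_len[i] <- d5s_ext + out$d3s[i]
        out$rel_pos[i] <- d5s_ext / out$intergenic_len[i]
      }
      a_over <- nrow(opp) > 0 && any(opp$ext_start <= pos & opp$ext_end >= pos)
      if (a_over) {
        out$d5a[i] <- 0; out$d3a[i] <- 0
      } else {
        l <- opp[opp$ext_end <= pos, ]
        r <- opp[opp$ext_start >= pos, ]
        if (nrow(l)) out$d5a[i] <- pos - max(l$ext_end)
        if (nrow(r)) out$d3a[i] <- min(r$ext_start) - pos
      }
    } else {
      up <- same[same$ext_start >= pos, ]
      if (nrow(up)) {
        k <- which.min(up$ext_start)
        out$gene5s[i] <- up$gene_id[k]
        d5x <- up$ext_start[k] - pos
        out$d5s[i] <- if (sense_anchor == "stop_codon" &&
                          !is.na(up$stop_codon_pos[k])) {
          up$stop_codon_pos[k] - pos
        } else d5x
        d5s_ext <- d5x
      } else d5s_ext <- NA_real_
      dn <- same[same$tx_end <= pos, ]
      if (nrow(dn)) {
        k <- which.max(dn$tx_end)
        out$gene3s[i] <- dn$gene_id[k]
        out$d3s[i] <- pos - dn$tx_end[k]
      }
      if (!is.na(d5s_ext) && !is.na(out$d3s[i])) {
        out$intergenic_len[i] <- d5s_ext + out$d3s[i]
        out$rel_pos[i] <- d5s_ext / out$intergenic_len[i]
      }
      a_over <- nrow(opp) > 0 && any(opp$ext_start <= pos & opp$ext_end >= pos)
      if (a_over) {
        out$d5a[i] <- 0; out$d3a[i] <- 0
      } else {
        l <- opp[opp$ext_end <= pos, ] # genomic left = 3' side on minus
        r <- opp[opp$ext_start >= pos, ]
        if (nrow(r)) out$d5a[i] <- min(r$ext_start) - pos
        if (nrow(l)) out$d3a[i] <- pos - max(l$ext_end)
      }
    }
  }
  out
}

#' Histogram of normalized IPAC positions
#'
#' Bins `rel_pos` (position within the containing intergenic gap, 0 = at the
#' upstream sense gene) on a uniform grid over [0, 1] and reports the
#' fraction of IPACs in the first tenth of their gaps.
#'
#' @param contexts Output of [neighbor_contexts()] (rows with `NA`
#'   `rel_pos` are dropped).
#' @param n_bins Number of uniform bins (default 100).
#' @return A list with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`), `n`, and `frac_first_decile` (fraction with rel_pos <= 0.1).
#' @export
rel_position_histogram <- function(contexts, n_bins = 100L) {
  x <- contexts$rel_pos
  x <- x[!is.na(x)]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(x, edges, include.lowest = TRUE)))
  list(histogram = data.frame(bin_start = edges[-(n_bins + 1L)],
                              bin_end = edges[-1L], count = counts),
       n = length(x),
       frac_first_decile = if (length(x)) mean(x <= 0.1) else NA_real_)
}
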