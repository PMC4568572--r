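# Sequence context of cleavage sites: per-position base composition and
# poly(A)-signal (NUE) hexamer classification.

#' The 18 single-nucleotide variants of AATAAA
#'
#' @return Character vector of the hexamers at Hamming distance exactly 1
#'   from the canonical AATAAA signal.
#' @export
pas_variants <- function() {
  canon <- strsplit("AATAAA", "")[[1]]
  out <- character(0)
  for (i in seq_along(canon)) {
    for (b in setdiff(c("A", "C", "G", "T"), canon[i])) {
      v <- canon
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Position-by-position base composition around cleavage sites
#'
#' Extracts the oriented window `-up .. +down` around each site (position 0
#' is the cleavage site itself; minus-strand windows are
#' reverse-complemented so "upstream" is transcription-upstream) and tallies
#' A/C/G/T fractions per position. Sites whose window runs over a chromosome
#' edge contribute only the available positions; `n_obs` records per-position
#' coverage.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand` (e.g. dominant
#'   sites of a PAC class).
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param up,down Window extent in nt (defaults 300 upstream, 100
#'   downstream).
#' @return A data.frame with `position` (-up..down), `fA`, `fC`, `fG`, `fT`
#'   and `n_obs`; fractions are `NA` where no site covers the position.
#' @export
composition_profile <- function(sites, genome, up = 300L, down = 100L) {
  genome <- .as_genome(genome)
  width <- up + down + 1L
  counts <- matrix(0L, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  n_obs <- integer(width)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    plus <- sites$strand[i] == "+"
    g_lo <- if (plus) pos - up else pos - down
    g_hi <- if (plus) pos + down else pos + up
    s <- max(1L, g_lo); e <- min(chrom_len[[chrom]], g_hi)
    if (s > e) next
    seqc <- strsplit(as.character(
      Biostrings::subseq(genome[[chrom]], s, e)), "")[[1]]
    if (!plus) seqc <- .rc_chars(seqc)
    # window-local columns covered by the available sequence
    off_lo <- if (plus) s - g_lo else g_hi - e
    cols <- seq(off_lo + 1L, off_lo + length(seqc))
    for (b in c("A", "C", "G", "T")) {
      hitcols <- cols[seqc == b]
      counts[b, hitcols] <- counts[b, hitcols] + 1L
    }
    n_obs[cols] <- n_obs[cols] + 1L
  }
  freq <- sweep(counts, 2L, pmax(n_obs, 1L), "/")
  freq[, n_obs == 0L] <- NA_real_
  data.frame(position = seq(-up, down), fA = freq["A", ], fC = freq["C", ],
             fG = freq["G", ], fT = freq["T", ], n_obs = n_obs)
}

#' Classify the poly(A) signal upstream of a cleavage site
#'
#' Scans the oriented upstream window for the canonical AATAAA hexamer
#' first; failing that, for any hexamer at Hamming distance 1. The canonical
#' match takes priority regardless of position; within a class the leftmost
#' match is reported. Windows truncated at the chromosome start are scanned
#' over the available portion.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param window Scan window relative to the site, default `c(-50, -1)`.
#' @return A data.frame with `pas_class` (`AATAAA`, `VARIANT_1NT`, `NOPAS`),
#'   `hexamer` and `offset` (window-relative position of the match start, NA
#'   for NOPAS).
#' @export
classify_pas <- function(sites, genome, window = c(-50L, -1L)) {
  genome <- .as_genome(genome)
  variants <- pas_variants()
  n <- nrow(sites)
  out <- data.frame(pas_class = rep("NOPAS", n),
                    hexamer = NA_character_, offset = NA_integer_,
                    stringsAsFactors = FALSE)
  w_lo <- window[1]; w_hi <- window[2]
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(n)) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    plus <- sites$strand[i] == "+"
    g_lo <- if (plus) pos + w_lo else pos - w_hi
    g_hi <- if (plus) pos + w_hi else pos - w_lo
    s <- max(1L, g_lo); e <- min(chrom_len[[chrom]], g_hi)
    if (s > e) next
    seqs <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
    if (!plus) {
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs)))
    }
    # offset of the first window-local character relative to the site
    lead_trunc <- if (plus) s - g_lo else g_hi - e
    hit <- regexpr("AATAAA", seqs, fixed = TRUE)
    if (hit > 0L) {
      out$pas_class[i] <- "AATAAA"
      out$hexamer[i] <- "AATAAA"
      out$offset[i] <- w_lo + lead_trunc + as.integer(hit) - 1L
      next
    }
    best <- NA_integer_; best_hex <- NA_character_
    for (v in variants) {
      hv <- regexpr(v, seqs, fixed = TRUE)
      if (hv > 0L && (is.na(best) || hv < best)) {
        best <- as.integer(hv); best_hex <- v
      }
    }
    if (!is.na(best)) {
      out$pas_class[i] <- "VARIANT_1NT"
      out$hexamer[i] <- best_hex
      out$offset[i] <- w_lo + lead_trunc + best - 1L
    }
  }
  out
}

#' Write a composition profile as TSV
#'
#' @param profile Result of [composition_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
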