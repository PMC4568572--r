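# Ordered classification of IPACs into SE / A / SO and the two proximal
# leftover categories, with the internal-priming filter applied to A
# candidates.

IPAC_CLASSES <- c("SE", "A", "SO", "SENSE_PROMOTER", "ANTISENSE_PROXIMAL",
                  "FILTERED_IP")

#' Classification configuration
#'
#' Distance cutoffs and priming-filter parameters with their published
#' defaults. `se_cutoff_nt` is conventionally the output of
#' [select_cutoff()] (700 nt at FDR < 0.1); `antisense_proximal_cutoff_nt`
#' is the 200-nt rule (FDR 0.01) applied to both antisense sides;
#' `so_antisense_cutoff_nt` optionally raises the 3'-antisense exclusion to
#' the 700-nt variant mentioned alongside it (default: equal to the 200-nt
#' rule, i.e. off).
#'
#' @param se_cutoff_nt Distance below which an IPAC is a 3'-UTR extension
#'   (default 700).
#' @param antisense_proximal_cutoff_nt Proximity cutoff to antisense gene
#'   boundaries (default 200).
#' @param sense_promoter_cutoff_nt Proximity cutoff to the downstream sense
#'   gene start (default 700).
#' @param so_antisense_cutoff_nt Optional stricter 3'-antisense exclusion
#'   for SO candidates (default `NULL`: use
#'   `antisense_proximal_cutoff_nt`).
#' @param priming_window_nt,priming_a_frac,priming_ag_frac Parameters of
#'   [internal_priming_filter()].
#' @param sense_anchor Anchor of the upstream sense distance:
#'   `"stop_codon"` (default) or `"tx_end_extended"`.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(se_cutoff_nt = 700L,
                                  antisense_proximal_cutoff_nt = 200L,
                                  sense_promoter_cutoff_nt = 700L,
                                  so_antisense_cutoff_nt = NULL,
                                  priming_window_nt = 20L,
                                  priming_a_frac = 0.50,
                                  priming_ag_frac = 0.60,
                                  sense_anchor = c("stop_codon",
                                                   "tx_end_extended")) {
  sense_anchor <- match.arg(sense_anchor)
  stopifnot(se_cutoff_nt >= 0, antisense_proximal_cutoff_nt >= 0,
            sense_promoter_cutoff_nt >= 0)
  structure(list(se_cutoff_nt = se_cutoff_nt,
                 antisense_proximal_cutoff_nt = antisense_proximal_cutoff_nt,
                 sense_promoter_cutoff_nt = sense_promoter_cutoff_nt,
                 so_antisense_cutoff_nt = so_antisense_cutoff_nt,
                 priming_window_nt = priming_window_nt,
                 priming_a_frac = priming_a_frac,
                 priming_ag_frac = priming_ag_frac,
                 sense_anchor = sense_anchor),
            class = "classification_config")
}

#' Classify IPACs by the ordered distance rules
#'
#' The rules fire in a fixed order, so the class labels partition the input:
#' (1) upstream sense distance `d5s` below `se_cutoff_nt` -> `SE`;
#' (2) else an antisense gene overlaps the dominant site: the
#'     internal-priming filter decides `FILTERED_IP` (discard) vs `A`;
#' (3) else nearest antisense boundary below
#'     `antisense_proximal_cutoff_nt` -> `ANTISENSE_PROXIMAL`;
#' (4) else downstream sense distance `d3s` below
#'     `sense_promoter_cutoff_nt` -> `SENSE_PROMOTER`;
#' (5) else `SO`.
#' This ordering draws A candidates from the non-SE IPACs and applies the
#' proximity screens only to the remainder, which is the only ordering
#' consistent with the published class counts.
#'
#' @param ipacs Annotated IPAC data.frame ([select_ipacs()]).
#' @param contexts Matching [neighbor_contexts()] rows (1:1 with `ipacs`,
#'   computed with `cfg$sense_anchor`).
#' @param cfg A [classification_config()].
#' @param genome A [Biostrings::DNAStringSet] or FASTA path (priming
#'   filter).
#' @return `ipacs` with added columns `ipac_class`, `rule`, the four
#'   distances, and `priming_frac_a`/`priming_frac_ag` for A candidates.
#' @export
classify_ipacs <- function(ipacs, contexts, cfg = classification_config(),
                           genome = NULL) {
  stopifnot(inherits(cfg, "classification_config"))
  if (nrow(ipacs) != nrow(contexts)) {
    stop("ipacs and contexts are not aligned 1:1")
  }
  n <- nrow(ipacs)
  cls <- character(n)
  rule <- character(n)
  so_as_cut <- if (is.null(cfg$so_antisense_cutoff_nt)) {
    cfg$antisense_proximal_cutoff_nt
  } else cfg$so_antisense_cutoff_nt
  d5s <- contexts$d5s; d3s <- contexts$d3s
  dmin_a <- suppressWarnings(pmin(contexts$d5a, contexts$d3a, na.rm = TRUE))
  dmin_a[is.infinite(dmin_a)] <- NA_real_
  has_as <- !is.na(ipacs$antisense_gene)

  se <- !is.na(d5s) & d5s < cfg$se_cutoff_nt
  cls[se] <- "SE"; rule[se] <- "d5s<se_cutoff"
  a_cand <- !se & has_as
  if (any(a_cand)) {
    if (is.null(genome)) stop("genome required for the priming filter")
    pf <- internal_priming_filter(ipacs[a_cand, , drop = FALSE],
                                  .as_genome(genome),
                                  window_nt = cfg$priming_window_nt,
                                  a_frac = cfg$priming_a_frac,
                                  ag_frac = cfg$priming_ag_frac)
    cls[a_cand] <- ifelse(pf$keep, "A", "FILTERED_IP")
    rule[a_cand] <- ifelse(pf$keep, "antisense_overlap",
                           "antisense_overlap+priming")
    ipacs$priming_frac_a <- NA_real_
    ipacs$priming_frac_ag <- NA_real_
    ipacs$priming_frac_a[a_cand] <- pf$frac_a
    ipacs$priming_frac_ag[a_cand] <- pf$frac_ag
  } else {
    ipacs$priming_frac_a <- NA_real_
    ipacs$priming_frac_ag <- NA_real_
  }
  rest <- !se & !a_cand
  prox <- rest & !is.na(dmin_a) & dmin_a < so_as_cut
  cls[prox] <- "ANTISENSE_PROXIMAL"; rule[prox] <- "antisense_proximity"
  rest <- rest & !prox
  prom <- rest & !is.na(d3s) & d3s < cfg$sense_promoter_cutoff_nt
  cls[prom] <- "SENSE_PROMOTER"; rule[prom] <- "d3s<promoter_cutoff"
  so <- rest & !prom
  cls[so] <- "SO"; rule[so] <- "remainder"

  ipacs$ipac_class <- cls
  ipacs$rule <- rule
  ipacs$d5s <- d5s; ipacs$d3s <- d3s
  ipacs$d5a <- contexts$d5a; ipacs$d3a <- contexts$d3a
  ipacs$gene5s <- contexts$gene5s; ipacs$gene3s <- contexts$gene3s
  ipacs
}

#' Class summary
#'
#' @param records Output of [classify_ipacs()].
#' @return A data.frame with one row per class (`n`, `fraction`), plus the
#'   attribute-style columns `a_candidates` (pre-filter A count, i.e.
#'   `A + FILTERED_IP`) exposed via the `A` row's `n_prefilter`.
#' @export
class_summary <- function(records) {
  n_total <- nrow(records)
  counts <- vapply(IPAC_CLASSES,
                   function(k) sum(records$ipac_class == k), 1L)
  out <- data.frame(class = IPAC_CLASSES, n = counts,
                    fraction = if (n_total) counts / n_total else 0,
                    row.names = NULL)
  out$n_prefilter <- NA_integer_
  out$n_prefilter[out$class == "A"] <- counts[["A"]] + counts[["FILTERED_IP"]]
  out
}

#' Antisense landing regions and host biotypes of A-IPACs
#'
#' Each A-IPAC's dominant site is located within its antisense host gene;
#' this reports which feature of the host it falls in (reverse-complement
#' position) and the biotype spectrum of the hosts.
#'
#' @param records Output of [classify_ipacs()] (rows labeled `A` are used).
#' @param ann An `ExtendedAnnotation`.
#' @return A list with `regions` (counts over UTR3/CDS/INTRON/UTR5/other)
#'   and `biotypes` (host-gene biotype counts over unique hosts).
#' @export
a_ipac_antisense_breakdown <- function(records, ann) {
  a <- records[records$ipac_class == "A", , drop = FALSE]
  if (nrow(a) == 0L) {
    return(list(regions = data.frame(region = character(), n = integer()),
                biotypes = data.frame(biotype = character(), n = integer())))
  }
  pts <- GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$dominant_site, a$dominant_site),
    strand = ifelse(a$strand == "+", "-", "+"))
  region <- rep("other", nrow(a))
  hits <- GenomicRanges::findOverlaps(pts, ann$features,
                                      ignore.strand = FALSE)
  if (length(hits)) {
    h <- data.table::data.table(
      q = S4Vectors::queryHits(hits),
      gene_id = ann$features$gene_id[S4Vectors::subjectHits(hits)],
      prec = match(ann$features$type[S4Vectors::subjectHits(hits)],
                   FEATURE_PRECEDENCE))
    # restrict to the recorded antisense host, resolve by precedence
    h <- h[gene_id == a$antisense_gene[q]]
    if (nrow(h)) {
      best <- h[, list(prec = min(prec)), by = "q"]
      region[best$q] <- FEATURE_PRECEDENCE[best$prec]
    }
  }
  region[region %in% c("EXON", "PSEUDOGENIC_EXON")] <- "other"
  reg <- as.data.frame(table(region), stringsAsFactors = FALSE)
  names(reg) <- c("region", "n")
  hosts <- unique(a$antisense_gene)
  bt <- ann$genes$biotype[match(hosts, ann$genes$gene_id)]
  bio <- as.data.frame(table(bt), stringsAsFactors = FALSE)
  names(bio) <- c("biotype", "n")
  list(regions = reg, biotypes = bio)
}
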