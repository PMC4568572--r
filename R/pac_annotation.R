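# Genomic categorisation of PACs against the extended annotation, and
# selection of the intergenic subset (IPACs).

REGION_CATEGORIES <- c("UTR3", "INTERGENIC", "CDS", "INTRON", "UTR5", "EXON",
                       "PSEUDOGENIC_EXON", "AMB")

#' Assign each PAC to exactly one genomic category
#'
#' The category is decided from the dominant site against same-strand
#' per-isoform features. Within one isoform, nested features resolve by the
#' precedence UTR3 (incl. the 3' extension) > CDS > INTRON > UTR5 > EXON >
#' PSEUDOGENIC_EXON; when overlapping isoforms disagree about the category
#' the PAC is AMB (ambiguous annotation, e.g. alternative transcription or
#' processing). No same-strand feature overlap means INTERGENIC. The
#' opposite-strand gene overlapping the dominant site (if any, extended
#' span) is recorded as `antisense_gene`.
#'
#' @param pacs PAC data.frame from [cluster_sites()].
#' @param ann An `ExtendedAnnotation`.
#' @return `pacs` with added columns `category`, `host_gene`,
#'   `antisense_gene`.
#' @export
annotate_pacs <- function(pacs, ann) {
  stopifnot(inherits(ann, "ExtendedAnnotation"))
  n <- nrow(pacs)
  category <- rep("INTERGENIC", n)
  host_gene <- rep(NA_character_, n)
  antisense_gene <- rep(NA_character_, n)
  if (n == 0L) {
    return(cbind(pacs, category = character(), host_gene = character(),
                 antisense_gene = character()))
  }
  bad <- !pacs$chrom %in% names(ann$chrom_lengths) |
    pacs$dominant_site < 1L |
    pacs$dominant_site > unlist(ann$chrom_lengths[pacs$chrom])
  if (any(bad)) {
    stop(sprintf("dominant site of %s lies outside its chromosome",
                 pacs$pac_id[which(bad)[1L]]))
  }
  pts <- GenomicRanges::GRanges(
    pacs$chrom, IRanges::IRanges(pacs$dominant_site, pacs$dominant_site),
    strand = pacs$strand)
  hits <- GenomicRanges::findOverlaps(pts, ann$features,
                                      ignore.strand = FALSE)
  if (length(hits)) {
    h <- data.table::data.table(
      pac = S4Vectors::queryHits(hits),
      tx_id = ann$features$tx_id[S4Vectors::subjectHits(hits)],
      gene_id = ann$features$gene_id[S4Vectors::subjectHits(hits)],
      prec = match(ann$features$type[S4Vectors::subjectHits(hits)],
                   FEATURE_PRECEDENCE))
    # per-isoform category by precedence, then consensus across isoforms
    per_tx <- h[, list(prec = min(prec), gene_id = gene_id[1L]),
                by = c("pac", "tx_id")]
    per_pac <- per_tx[, list(
      category = if (data.table::uniqueN(prec) > 1L) "AMB"
                 else FEATURE_PRECEDENCE[prec[1L]],
      host_gene = gene_id[which.min(prec)[1L]]), by = "pac"]
    category[per_pac$pac] <- per_pac$category
    host_gene[per_pac$pac] <- per_pac$host_gene
  }
  # antisense gene: opposite-strand extended span covering the site
  g <- ann$genes
  spans <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$ext_start, g$ext_end), strand = g$strand)
  opp <- GenomicRanges::GRanges(
    pacs$chrom, IRanges::IRanges(pacs$dominant_site, pacs$dominant_site),
    strand = ifelse(pacs$strand == "+", "-", "+"))
  ah <- GenomicRanges::findOverlaps(opp, spans, ignore.strand = FALSE)
  if (length(ah)) {
    first <- !duplicated(S4Vectors::queryHits(ah))
    antisense_gene[S4Vectors::queryHits(ah)[first]] <-
      g$gene_id[S4Vectors::subjectHits(ah)[first]]
  }
  pacs$category <- category
  pacs$host_gene <- ifelse(category == "INTERGENIC", NA_character_,
                           host_gene)
  pacs$antisense_gene <- antisense_gene
  pacs
}

#' Select the intergenic PACs (IPACs)
#'
#' @param annotated Output of [annotate_pacs()].
#' @return The `INTERGENIC` subset.
#' @export
select_ipacs <- function(annotated) {
  annotated[annotated$category == "INTERGENIC", , drop = FALSE]
}

#' Category summary over PACs and tags
#'
#' @param annotated Output of [annotate_pacs()].
#' @return A data.frame with one row per observed category: `n_pac`,
#'   `n_tags`, `pac_pct`, `tag_pct` (tag percentages weighted by
#'   `total_tags`).
#' @export
category_summary <- function(annotated) {
  if (nrow(annotated) == 0L) {
    return(data.frame(category = character(), n_pac = integer(),
                      n_tags = integer(), pac_pct = numeric(),
                      tag_pct = numeric()))
  }
  dt <- data.table::as.data.table(annotated)
  s <- dt[, list(n_pac = .N, n_tags = sum(total_tags)), by = "category"]
  s[, pac_pct := 100 * n_pac / sum(n_pac)]
  s[, tag_pct := 100 * n_tags / sum(n_tags)]
  s <- s[order(match(category, REGION_CATEGORIES))]
  as.data.frame(s)
}
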