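# Recruiting SE-IPACs as additional 3'-UTR poly(A) sites and measuring how
# 3'-UTR length distributions change.

# strand-aware stop-codon -> site distance
.utr_len <- function(ann, gene_id, site) {
  g <- ann$genes[match(gene_id, ann$genes$gene_id), ]
  ifelse(g$strand == "+", site - g$stop_codon_pos, g$stop_codon_pos - site)
}

#' Attach SE-IPACs to their upstream sense genes
#'
#' @param se_records [classify_ipacs()] rows labeled `SE` (must carry
#'   `gene5s`).
#' @param ann An `ExtendedAnnotation`.
#' @param utr3_pacs Optional annotated UTR3 PACs; when given, genes gaining
#'   their first poly(A) site are flagged.
#' @return A data.frame with one row per SE-IPAC: `gene_id`, `pac_id`,
#'   `dominant_site`, `utr_len` (stop codon to dominant site, nt),
#'   `newly_terminated` (gene had no UTR3 PAC).
#' @export
assign_se_to_genes <- function(se_records, ann, utr3_pacs = NULL) {
  se <- se_records[se_records$ipac_class == "SE", , drop = FALSE]
  if (nrow(se) == 0L) {
    return(data.frame(gene_id = character(), pac_id = character(),
                      dominant_site = integer(), utr_len = numeric(),
                      newly_terminated = logical()))
  }
  if (any(is.na(se$gene5s))) {
    stop("SE-IPAC without an upstream sense gene: classification is broken")
  }
  out <- data.frame(gene_id = se$gene5s, pac_id = se$pac_id,
                    dominant_site = se$dominant_site,
                    utr_len = .utr_len(ann, se$gene5s, se$dominant_site),
                    stringsAsFactors = FALSE)
  genes_with_pac <- if (is.null(utr3_pacs)) character(0) else {
    unique(utr3_pacs$host_gene[utr3_pacs$category == "UTR3"])
  }
  out$newly_terminated <- !(out$gene_id %in% genes_with_pac)
  out
}

#' 3'-UTR length distributions before and after recruiting SE-IPACs
#'
#' Lengths are measured from the stop codon to each PAC's dominant site.
#' "Before" uses the annotated-range (UTR3) PACs only; "after" pools them
#' with the recruited SE-IPACs. Reports medians and means of the pooled
#' per-PAC lengths, per-rank medians within genes carrying exactly k PACs
#' (k = 1, 2, 3; ranks ordered proximal to distal), and a Wilcoxon rank-sum
#' test between the two pooled length vectors. Genes without a stop codon
#' are excluded and counted.
#'
#' @param utr3_pacs Annotated PACs ([annotate_pacs()]); only `UTR3` rows
#'   with a coding host gene are used.
#' @param se_map Output of [assign_se_to_genes()].
#' @param ann An `ExtendedAnnotation`.
#' @return A list: `before`, `after` (length vectors), `records` (per-PAC
#'   UTRLengthRecord table), `summary` (medians/means), `rank_medians`,
#'   `wilcoxon` (statistic and p), `n_excluded_noncoding`.
#' @export
utr_length_stats <- function(utr3_pacs, se_map, ann) {
  u <- utr3_pacs[utr3_pacs$category == "UTR3", , drop = FALSE]
  coding <- ann$genes$gene_id[!is.na(ann$genes$stop_codon_pos)]
  n_excluded <- sum(!u$host_gene %in% coding)
  u <- u[u$host_gene %in% coding, , drop = FALSE]
  before_rec <- data.frame(
    gene_id = u$host_gene, pac_id = u$pac_id,
    utr_len = .utr_len(ann, u$host_gene, u$dominant_site),
    source = "UTR3_PAC", stringsAsFactors = FALSE)
  before_rec$utr_len <- pmax(0, before_rec$utr_len)
  se_rec <- if (nrow(se_map)) {
    data.frame(gene_id = se_map$gene_id, pac_id = se_map$pac_id,
               utr_len = pmax(0, se_map$utr_len), source = "SE_IPAC",
               stringsAsFactors = FALSE)
  } else before_rec[0, ]
  after_rec <- rbind(before_rec, se_rec)
  before <- before_rec$utr_len
  after <- after_rec$utr_len

  rank_medians <- .rank_medians(before_rec, after_rec)
  wt <- if (length(before) && length(after)) {
    suppressWarnings(stats::wilcox.test(after, before))
  } else NULL
  list(
    before = before, after = after,
    records = .ranked_records(before_rec, after_rec),
    summary = data.frame(
      phase = c("before", "after"),
      n = c(length(before), length(after)),
      median = c(stats::median(before), stats::median(after)),
      mean = c(mean(before), mean(after))),
    rank_medians = rank_medians,
    wilcoxon = if (is.null(wt)) NULL else {
      list(statistic = unname(wt$statistic), p_value = wt$p.value)
    },
    n_excluded_noncoding = n_excluded)
}

.ranked_records <- function(before_rec, after_rec) {
  add_rank <- function(rec, phase) {
    if (nrow(rec) == 0L) {
      return(cbind(rec, pac_rank = integer(0), phase = character(0)))
    }
    dt <- data.table::as.data.table(rec)
    data.table::setorder(dt, gene_id, utr_len)
    dt[, pac_rank := seq_len(.N), by = "gene_id"]
    dt[, phase := phase]
    as.data.frame(dt)
  }
  rbind(add_rank(before_rec, "before"), add_rank(after_rec, "after"))
}

.rank_medians <- function(before_rec, after_rec, ks = 1:3) {
  recs <- .ranked_records(before_rec, after_rec)
  out <- list()
  for (phase in c("before", "after")) {
    r <- recs[recs$phase == phase, ]
    if (nrow(r) == 0L) next
    npac <- table(r$gene_id)
    for (k in ks) {
      genes_k <- names(npac)[npac == k]
      rk <- r[r$gene_id %in% genes_k, ]
      if (nrow(rk) == 0L) next
      med <- tapply(rk$utr_len, rk$pac_rank, stats::median)
      out[[length(out) + 1L]] <- data.frame(
        phase = phase, n_pacs = k, pac_rank = as.integer(names(med)),
        median_len = as.numeric(med), n_genes = length(genes_k))
    }
  }
  if (!length(out)) {
    return(data.frame(phase = character(), n_pacs = integer(),
                      pac_rank = integer(), median_len = numeric(),
                      n_genes = integer()))
  }
  do.call(rbind, out)
}

#' Mean 3'-end extension beyond the previous distal end
#'
#' Per gene with SE-IPACs, the extension is the distal SE length minus the
#' previous distal 3' end: the gene's most distal UTR3 PAC when it had one,
#' otherwise the annotated 3' end (before the 50-nt working extension).
#' Negative contributions floor at 0. The mean is taken over extended
#' genes.
#'
#' @param se_map Output of [assign_se_to_genes()].
#' @param ann An `ExtendedAnnotation`.
#' @param utr3_pacs Optional annotated PACs supplying observed distal UTR3
#'   ends.
#' @return A list with `mean_extension_nt`, `n_genes` and the per-gene
#'   table `per_gene`.
#' @export
mean_extension <- function(se_map, ann, utr3_pacs = NULL) {
  if (nrow(se_map) == 0L) {
    stop("empty SE map: mean extension undefined")
  }
  distal_se <- tapply(se_map$utr_len, se_map$gene_id, max)
  genes <- names(distal_se)
  g <- ann$genes[match(genes, ann$genes$gene_id), ]
  annotated_len <- ifelse(g$strand == "+", g$tx_end - g$stop_codon_pos,
                          g$stop_codon_pos - g$tx_start)
  baseline <- annotated_len
  if (!is.null(utr3_pacs)) {
    u <- utr3_pacs[utr3_pacs$category == "UTR3" &
                     utr3_pacs$host_gene %in% genes, , drop = FALSE]
    if (nrow(u)) {
      obs <- tapply(pmax(0, .utr_len(ann, u$host_gene, u$dominant_site)),
                    u$host_gene, max)
      m <- match(names(obs), genes)
      baseline[m] <- pmax(baseline[m], as.numeric(obs))
    }
  }
  ext <- pmax(0, as.numeric(distal_se) - baseline)
  list(mean_extension_nt = mean(ext), n_genes = length(genes),
       per_gene = data.frame(gene_id = genes,
                             distal_se_len = as.numeric(distal_se),
                             baseline_len = baseline, extension = ext,
                             stringsAsFactors = FALSE))
}
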