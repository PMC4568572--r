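# Genome annotation model: parsing, validation, 3'-UTR extension and the
# interval queries every downstream stage relies on.

GENE_TYPES <- c("gene", "pseudogene", "transposable_element_gene", "ncRNA_gene")
TX_TYPES <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "tRNA", "rRNA",
              "snoRNA", "snRNA", "miRNA", "pre_miRNA",
              "pseudogenic_transcript", "antisense_RNA")

BIOTYPES <- c("protein_coding", "ncRNA", "pseudogene", "transposable_element",
              "miRNA", "rRNA", "tRNA", "snoRNA", "other")

# Category precedence used when a cleavage site overlaps nested features of a
# single isoform (e.g. an exon that is also annotated UTR).
FEATURE_PRECEDENCE <- c("UTR3", "CDS", "INTRON", "UTR5", "EXON",
                        "PSEUDOGENIC_EXON")

#' Load a genome annotation and apply the 3'-UTR extension
#'
#' Parses a GFF3 file into an `ExtendedAnnotation`: one representative model
#' per gene (union of exons, outermost transcript bounds, distal stop codon)
#' plus per-isoform feature intervals used for site categorisation. Each
#' gene's 3' end is extended by `extension_nt` in the transcription direction
#' (clipped to the chromosome), so that cleavage sites in the immediate
#' vicinity of annotated 3'-UTRs are not called intergenic.
#'
#' @param gff3_path Path to a GFF3 file with gene and mRNA/exon/CDS features.
#'   Chromosome lengths are taken from `##sequence-region` directives when
#'   present.
#' @param extension_nt Number of nucleotides by which every gene's 3' end is
#'   extended (default 50).
#' @param chrom_lengths Optional named integer vector or two-column TSV path
#'   (chrom, length) overriding/supplying chromosome lengths.
#' @return An object of class `ExtendedAnnotation` with components `genes`
#'   (one row per gene: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `ext_start`, `ext_end`, `stop_codon_pos`, `biotype`, `n_isoforms`),
#'   `features` (a [GenomicRanges::GRanges] of typed per-isoform intervals
#'   with the extension applied to 3'-UTRs), `tx`, `exons`, `cds` (raw
#'   components for round-tripping), `chrom_lengths` and `extension_nt`.
#' @export
load_annotation <- function(gff3_path, extension_nt = 50L,
                            chrom_lengths = NULL) {
  stopifnot(length(gff3_path) == 1L, file.exists(gff3_path))
  if (extension_nt < 0) stop("extension_nt must be >= 0")
  .check_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")

  if (is.character(chrom_lengths) && length(chrom_lengths) == 1L) {
    tb <- utils::read.table(chrom_lengths, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(as.integer(tb$length), tb$chrom)
  }
  sl <- GenomeInfoDb::seqlengths(gr)
  sr <- .sequence_region_lengths(gff3_path)
  if (length(sr)) sl[names(sr)] <- sr
  if (!is.null(chrom_lengths)) sl[names(chrom_lengths)] <- chrom_lengths
  missing_len <- is.na(sl)
  if (any(missing_len)) {
    # fall back to the rightmost feature end per chromosome
    ends <- tapply(GenomicRanges::end(gr), as.character(GenomicRanges::seqnames(gr)), max)
    sl[missing_len] <- as.integer(ends[names(sl)[missing_len]])
  }

  .build_annotation(gr, sl, as.integer(extension_nt))
}

# rtracklayer does not expose ##sequence-region on import; read it directly
.sequence_region_lengths <- function(path) {
  lines <- grep("^##sequence-region", readLines(path, warn = FALSE),
                value = TRUE)
  if (!length(lines)) return(integer(0))
  parts <- strsplit(trimws(lines), "\\s+")
  stats::setNames(vapply(parts, function(p) as.integer(p[4]), 1L),
                  vapply(parts, function(p) p[2], ""))
}

.check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nfield != 9L]
    if (length(bad)) {
      stop(sprintf("malformed GFF3 in '%s': line %d does not have 9 fields",
                   path, bad[1L]))
    }
  }
  invisible(TRUE)
}

.first_parent <- function(gr) {
  p <- gr$Parent
  vapply(as.list(p), function(x) if (length(x)) x[[1L]] else NA_character_,
         character(1))
}

.build_annotation <- function(gr, chrom_lengths, extension_nt) {
  type <- as.character(gr$type)
  gene_gr <- gr[type %in% GENE_TYPES]
  if (length(gene_gr) == 0L) stop("no gene features found in annotation")
  if (anyDuplicated(gene_gr$ID)) stop("duplicate gene IDs in annotation")
  bad <- GenomicRanges::end(gene_gr) <= GenomicRanges::start(gene_gr)
  if (any(bad)) {
    stop(sprintf("gene '%s' has end <= start", gene_gr$ID[which(bad)[1L]]))
  }

  tx_gr <- gr[type %in% TX_TYPES]
  tx_parent <- .first_parent(tx_gr)
  tx_gr <- tx_gr[tx_parent %in% gene_gr$ID]
  tx_parent <- tx_parent[tx_parent %in% gene_gr$ID]

  exon_gr <- gr[type == "exon"]
  cds_gr <- gr[type == "CDS"]
  exon_tx <- .first_parent(exon_gr)
  cds_tx <- .first_parent(cds_gr)
  keep_e <- exon_tx %in% tx_gr$ID
  keep_c <- cds_tx %in% tx_gr$ID
  exon_gr <- exon_gr[keep_e]; exon_tx <- exon_tx[keep_e]
  cds_gr <- cds_gr[keep_c]; cds_tx <- cds_tx[keep_c]

  tx <- data.frame(
    tx_id = tx_gr$ID,
    gene_id = tx_parent,
    chrom = as.character(GenomicRanges::seqnames(tx_gr)),
    strand = as.character(GenomicRanges::strand(tx_gr)),
    start = GenomicRanges::start(tx_gr),
    end = GenomicRanges::end(tx_gr),
    stringsAsFactors = FALSE)

  gid <- gene_gr$ID
  gchrom <- as.character(GenomicRanges::seqnames(gene_gr))
  gstrand <- as.character(GenomicRanges::strand(gene_gr))
  if (any(!gstrand %in% c("+", "-"))) {
    stop("all genes must be stranded (+ or -)")
  }

  # representative transcript bounds: outermost over isoforms, falling back
  # to the gene row itself when no transcript children exist
  tx_by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  tx_start <- GenomicRanges::start(gene_gr)
  tx_end <- GenomicRanges::end(gene_gr)
  n_isoforms <- integer(length(gid))
  for (i in seq_along(gid)) {
    idx <- tx_by_gene[[gid[i]]]
    n_isoforms[i] <- length(idx)
    if (length(idx)) {
      tx_start[i] <- min(tx$start[idx])
      tx_end[i] <- max(tx$end[idx])
    }
  }

  # distal stop codon: transcription-direction end of the union of CDS
  cds_gene <- tx$gene_id[match(cds_tx, tx$tx_id)]
  stop_codon_pos <- rep(NA_integer_, length(gid))
  if (length(cds_gr)) {
    for (i in seq_along(gid)) {
      sel <- which(cds_gene == gid[i])
      if (length(sel)) {
        stop_codon_pos[i] <- if (gstrand[i] == "+") {
          max(GenomicRanges::end(cds_gr)[sel])
        } else {
          min(GenomicRanges::start(cds_gr)[sel])
        }
      }
    }
  }

  biotype <- .gene_biotypes(gene_gr, gid, stop_codon_pos)

  clen <- as.integer(chrom_lengths[gchrom])
  ext_start <- ifelse(gstrand == "+", tx_start,
                      pmax(1L, tx_start - extension_nt))
  ext_end <- ifelse(gstrand == "+", pmin(clen, tx_end + extension_nt), tx_end)

  genes <- data.frame(
    gene_id = gid, chrom = gchrom, strand = gstrand,
    tx_start = tx_start, tx_end = tx_end,
    ext_start = as.integer(ext_start), ext_end = as.integer(ext_end),
    stop_codon_pos = stop_codon_pos, biotype = biotype,
    n_isoforms = n_isoforms, stringsAsFactors = FALSE)

  features <- .derive_features(tx, exon_gr, exon_tx, cds_gr, cds_tx,
                               genes, chrom_lengths, extension_nt)

  ann <- list(genes = genes, features = features, tx = tx,
              exons = exon_gr, exon_tx = exon_tx,
              cds = cds_gr, cds_tx = cds_tx,
              chrom_lengths = chrom_lengths, extension_nt = extension_nt)
  class(ann) <- "ExtendedAnnotation"
  ann
}

.gene_biotypes <- function(gene_gr, gid, stop_codon_pos) {
  bt <- if (!is.null(gene_gr$biotype)) as.character(gene_gr$biotype)
        else rep(NA_character_, length(gid))
  ft <- as.character(gene_gr$type)
  out <- character(length(gid))
  for (i in seq_along(gid)) {
    out[i] <- if (!is.na(bt[i]) && bt[i] %in% BIOTYPES) {
      bt[i]
    } else if (ft[i] == "pseudogene") {
      "pseudogene"
    } else if (ft[i] == "transposable_element_gene") {
      "transposable_element"
    } else if (!is.na(stop_codon_pos[i])) {
      "protein_coding"
    } else {
      "ncRNA"
    }
  }
  out
}

# Per-isoform typed intervals. UTR3 carries the 3' extension; non-coding
# isoforms contribute EXON (or PSEUDOGENIC_EXON) plus INTRON, with the
# extension typed like their exons.
.derive_features <- function(tx, exon_gr, exon_tx, cds_gr, cds_tx, genes,
                             chrom_lengths, extension_nt) {
  pieces <- list()
  add <- function(chrom, start, end, strand, type, gene_id, tx_id) {
    keep <- start <= end
    if (!any(keep)) return(invisible(NULL))
    pieces[[length(pieces) + 1L]] <<- data.frame(
      chrom = chrom[keep], start = start[keep], end = end[keep],
      strand = strand[keep], type = type[keep], gene_id = gene_id[keep],
      tx_id = tx_id[keep], stringsAsFactors = FALSE)
  }
  gmeta <- genes[match(tx$gene_id, genes$gene_id), ]
  for (i in seq_len(nrow(tx))) {
    tid <- tx$tx_id[i]; strand <- tx$strand[i]; chrom <- tx$chrom[i]
    coding_like <- gmeta$biotype[i] == "protein_coding"
    exon_type <- if (gmeta$biotype[i] == "pseudogene") "PSEUDOGENIC_EXON" else "EXON"
    es <- which(exon_tx == tid)
    ex_start <- GenomicRanges::start(exon_gr)[es]
    ex_end <- GenomicRanges::end(exon_gr)[es]
    if (length(es) == 0L) { # bare transcript: treat span as one exon
      ex_start <- tx$start[i]; ex_end <- tx$end[i]
    }
    o <- order(ex_start)
    ex_start <- ex_start[o]; ex_end <- ex_end[o]
    n <- length(ex_start)
    rep_all <- function(x) rep(x, n)
    cs <- which(cds_tx == tid)
    if (length(cs)) {
      cds_min <- min(GenomicRanges::start(cds_gr)[cs])
      cds_max <- max(GenomicRanges::end(cds_gr)[cs])
      # exonic parts upstream/downstream of the CDS span, in transcription
      # orientation
      left <- pmin(ex_end, cds_min - 1L)
      right <- pmax(ex_start, cds_max + 1L)
      left_type <- if (strand == "+") "UTR5" else "UTR3"
      right_type <- if (strand == "+") "UTR3" else "UTR5"
      add(rep_all(chrom), ex_start, left, rep_all(strand),
          rep_all(left_type), rep_all(tx$gene_id[i]), rep_all(tid))
      add(rep_all(chrom), right, ex_end, rep_all(strand),
          rep_all(right_type), rep_all(tx$gene_id[i]), rep_all(tid))
      add(rep_all(chrom), pmax(ex_start, cds_min), pmin(ex_end, cds_max),
          rep_all(strand), rep_all("CDS"), rep_all(tx$gene_id[i]),
          rep_all(tid))
    } else {
      add(rep_all(chrom), ex_start, ex_end, rep_all(strand),
          rep_all(exon_type), rep_all(tx$gene_id[i]), rep_all(tid))
    }
    if (n > 1L) { # introns: gaps between sorted exons
      add(rep(chrom, n - 1L), ex_end[-n] + 1L, ex_start[-1L] - 1L,
          rep(strand, n - 1L), rep("INTRON", n - 1L),
          rep(tx$gene_id[i], n - 1L), rep(tid, n - 1L))
    }
    if (extension_nt > 0L) { # 3' extension, clipped to the chromosome
      clen <- as.integer(chrom_lengths[[chrom]])
      ext_type <- if (coding_like) "UTR3" else exon_type
      if (strand == "+") {
        add(chrom, tx$end[i] + 1L, min(clen, tx$end[i] + extension_nt),
            strand, ext_type, tx$gene_id[i], tid)
      } else {
        add(chrom, max(1L, tx$start[i] - extension_nt), tx$start[i] - 1L,
            strand, ext_type, tx$gene_id[i], tid)
      }
    }
  }
  if (!length(pieces)) {
    return(GenomicRanges::GRanges(seqlengths = chrom_lengths))
  }
  df <- do.call(rbind, pieces)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type, gene_id = df$gene_id, tx_id = df$tx_id,
    seqlengths = chrom_lengths[unique(df$chrom)])
}

#' @export
print.ExtendedAnnotation <- function(x, ...) {
  cat(sprintf(
    "ExtendedAnnotation: %d genes on %d chromosome(s), 3' extension %d nt\n",
    nrow(x$genes), length(x$chrom_lengths), x$extension_nt))
  invisible(x)
}

#' Strand-specific intergenic intervals
#'
#' Returns the sorted, disjoint complement of the extended gene spans on one
#' strand. Intergenic space is strand-specific: only genes on `strand` are
#' subtracted, because an intergenic poly(A) site cluster is by definition a
#' cluster between two annotated genes on the same DNA strand.
#'
#' @param ann An `ExtendedAnnotation`.
#' @param strand `"+"` or `"-"`.
#' @param chroms Optional subset of chromosomes (default: all known).
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), sorted by chromosome then start.
#' @export
intergenic_intervals <- function(ann, strand, chroms = NULL) {
  stopifnot(inherits(ann, "ExtendedAnnotation"), strand %in% c("+", "-"))
  if (is.null(chroms)) chroms <- names(ann$chrom_lengths)
  unknown <- setdiff(chroms, names(ann$chrom_lengths))
  if (length(unknown)) {
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  g <- ann$genes[ann$genes$strand == strand & ann$genes$chrom %in% chroms, ]
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    len <- as.integer(ann$chrom_lengths[[chrom]])
    spans <- g[g$chrom == chrom, c("ext_start", "ext_end")]
    if (nrow(spans) == 0L) {
      gaps <- data.frame(start = 1L, end = len)
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(spans$ext_start, spans$ext_end))
      gp <- IRanges::gaps(ir, start = 1L, end = len)
      gaps <- data.frame(start = IRanges::start(gp), end = IRanges::end(gp))
    }
    if (nrow(gaps)) gaps$chrom <- chrom
    out[[k]] <- gaps
  }
  res <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  res[, c("chrom", "start", "end")]
}

#' Strand-aware gene boundary lookup
#'
#' @param ann An `ExtendedAnnotation`.
#' @param gene_id Gene identifier.
#' @param anchor One of `"stop_codon"` (transcription-direction end of the
#'   CDS; errors with a `missing_anchor` condition for non-coding genes),
#'   `"tx_end_extended"` (extended 3' boundary) or `"tx_start"`
#'   (transcription start).
#' @return A single genomic coordinate (1-based).
#' @export
gene_boundary <- function(ann, gene_id,
                          anchor = c("stop_codon", "tx_end_extended",
                                     "tx_start")) {
  anchor <- match.arg(anchor)
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop(sprintf("unknown gene '%s'", gene_id))
  g <- ann$genes[i, ]
  plus <- g$strand == "+"
  switch(anchor,
    stop_codon = {
      if (is.na(g$stop_codon_pos)) {
        stop(structure(
          class = c("missing_anchor", "error", "condition"),
          list(message = sprintf(
            "gene '%s' has no CDS: no stop-codon anchor", gene_id),
            call = sys.call(-1))))
      }
      g$stop_codon_pos
    },
    tx_end_extended = if (plus) g$ext_end else g$ext_start,
    tx_start = if (plus) g$tx_start else g$tx_end)
}

#' Write an annotation back to GFF3
#'
#' Emits gene/mRNA/exon/CDS rows from the raw (un-extended) components, so
#' that reloading reproduces the identical gene set and coordinates.
#'
#' @param ann An `ExtendedAnnotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in names(ann$chrom_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", chrom,
                       ann$chrom_lengths[[chrom]]), con)
  }
  row <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start, end, strand, attrs)
  }
  lines <- character(0)
  g <- ann$genes
  gene_type <- ifelse(g$biotype == "pseudogene", "pseudogene",
               ifelse(g$biotype == "transposable_element",
                      "transposable_element_gene", "gene"))
  lines <- c(lines, row(g$chrom, "ipactools", gene_type, g$tx_start, g$tx_end,
                        g$strand,
                        sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)))
  tx <- ann$tx
  if (nrow(tx)) {
    coding <- g$biotype[match(tx$gene_id, g$gene_id)] == "protein_coding"
    tx_type <- ifelse(coding, "mRNA", "ncRNA")
    lines <- c(lines, row(tx$chrom, "ipactools", tx_type, tx$start, tx$end,
                          tx$strand,
                          sprintf("ID=%s;Parent=%s", tx$tx_id, tx$gene_id)))
    if (length(ann$exons)) {
      e <- ann$exons
      lines <- c(lines, row(as.character(GenomicRanges::seqnames(e)),
                            "ipactools", "exon",
                            GenomicRanges::start(e), GenomicRanges::end(e),
                            as.character(GenomicRanges::strand(e)),
                            sprintf("Parent=%s", ann$exon_tx)))
    }
    if (length(ann$cds)) {
      cd <- ann$cds
      lines <- c(lines, row(as.character(GenomicRanges::seqnames(cd)),
                            "ipactools", "CDS",
                            GenomicRanges::start(cd), GenomicRanges::end(cd),
                            as.character(GenomicRanges::strand(cd)),
                            sprintf("Parent=%s", ann$cds_tx)))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Export intergenic intervals as BED6
#'
#' @param ann An `ExtendedAnnotation`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_intergenic_bed <- function(ann, path) {
  rows <- list()
  for (s in c("+", "-")) {
    iv <- intergenic_intervals(ann, s)
    if (nrow(iv)) {
      rows[[s]] <- data.frame(chrom = iv$chrom, start = iv$start - 1L,
                              end = iv$end, name = "intergenic", score = 0L,
                              strand = s, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
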