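# Fixtures and independent oracles shared across test files.

# Write a small GFF3 and load it. `genes` is a list of lists with fields
# chrom, strand, start, end, and optionally cds = c(start, end) (genomic),
# exons = matrix/list of c(start, end), biotype, extra transcript models
# (isoforms = list of list(exons=, cds=)).
make_annotation <- function(genes, chrom_len = c(chrS1 = 100000L),
                            extension_nt = 50L) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(chrom_len),
                     chrom_len))
  gi <- 0L
  for (g in genes) {
    gi <- gi + 1L
    gid <- if (!is.null(g$id)) g$id else sprintf("g%d", gi)
    biotype <- if (!is.null(g$biotype)) g$biotype else "protein_coding"
    chrom <- if (!is.null(g$chrom)) g$chrom else names(chrom_len)[1]
    lines <- c(lines, sprintf(
      "%s\tt\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s", chrom,
      if (biotype == "pseudogene") "pseudogene" else "gene",
      g$start, g$end, g$strand, gid, biotype))
    isoforms <- if (!is.null(g$isoforms)) g$isoforms else {
      list(list(exons = g$exons, cds = g$cds))
    }
    ti <- 0L
    for (iso in isoforms) {
      ti <- ti + 1L
      tid <- sprintf("%s.%d", gid, ti)
      lines <- c(lines, sprintf(
        "%s\tt\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", chrom,
        if (biotype == "protein_coding") "mRNA" else "ncRNA",
        g$start, g$end, g$strand, tid, gid))
      exons <- if (!is.null(iso$exons)) iso$exons else {
        list(c(g$start, g$end))
      }
      for (e in exons) {
        lines <- c(lines, sprintf(
          "%s\tt\texon\t%d\t%d\t.\t%s\t.\tParent=%s", chrom, e[1], e[2],
          g$strand, tid))
      }
      if (!is.null(iso$cds)) {
        for (cd in if (is.list(iso$cds)) iso$cds else list(iso$cds)) {
          lines <- c(lines, sprintf(
            "%s\tt\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s", chrom, cd[1], cd[2],
            g$strand, tid))
        }
      }
    }
  }
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  load_annotation(path, extension_nt = extension_nt)
}

# genome from plain strings
make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# minimal PAC row
make_pac <- function(chrom = "chrS1", strand = "+", dominant_site = 1000L,
                     total_tags = 5L, pac_id = "PACX", start = NULL,
                     end = NULL) {
  data.frame(pac_id = pac_id, chrom = chrom, strand = strand,
             start = if (is.null(start)) dominant_site else start,
             end = if (is.null(end)) dominant_site else end,
             n_sites = 1L, total_tags = total_tags,
             dominant_site = dominant_site, dominant_tags = total_tags,
             stringsAsFactors = FALSE)
}

# minimal neighbor context row
make_ctx <- function(d5s = NA, d3s = NA, d5a = NA, d3a = NA,
                     intergenic_len = NA, rel_pos = NA,
                     gene5s = NA_character_, gene3s = NA_character_) {
  data.frame(d5s = as.numeric(d5s), d3s = as.numeric(d3s),
             d5a = as.numeric(d5a), d3a = as.numeric(d3a),
             intergenic_len = as.numeric(intergenic_len),
             rel_pos = as.numeric(rel_pos), gene5s = gene5s,
             gene3s = gene3s, stringsAsFactors = FALSE)
}

# independent clustering oracle: connected components of the graph joining
# same-chrom same-strand sites at distance <= max_gap (O(n^2) brute force)
brute_cluster <- function(pos, chrom, strand, max_gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] && strand[i] == strand[j] &&
          abs(pos[i] - pos[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# canonical form of a partition: sorted member sets, sorted by first member
partition_sets <- function(labels, key) {
  s <- lapply(unname(split(key, labels)), sort)
  s[order(vapply(s, function(x) x[1], ""))]
}
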