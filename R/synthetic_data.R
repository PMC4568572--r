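# Synthetic annotated genomes with planted, labelled poly(A) site classes.
# The generator states a fixed world: gene and intergenic lengths follow the
# published genome-wide averages (2343 nt genes separated by 5086 nt), and
# planted sites obey the geometric definition of their class so that every
# downstream stage can be scored against a truth table.

#' Simulation configuration
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Total number of genes (split across chromosomes).
#' @param mean_gene_len Mean gene length in nt (default 2343).
#' @param mean_intergenic_len Mean gap between consecutive genes in nt
#'   (default 5086).
#' @param class_mix Named proportions over planted classes `UTR3`, `SE`, `A`,
#'   `SO`, `sense_promoter`, `antisense_proximal`; must sum to 1.
#' @param n_sites Number of planted sites (internal-priming artifacts are
#'   planted on top, see `ip_artifact_rate`).
#' @param tags_per_site Named numeric `c(min=, mean=)`: every planted site
#'   emits at least `min` tags (default 3, the downstream support threshold),
#'   with Poisson scatter up to `mean`.
#' @param ip_artifact_rate Fraction of `n_sites` planted additionally as
#'   internal-priming artifacts (antisense geometry, A-rich downstream
#'   tract).
#' @param microhet_jitter_nt Spread of cleavage positions around a planted
#'   site (must be <= 24 so one planted site yields one cluster).
#' @param hexamer_mix Named proportions over `AATAAA`, `VARIANT_1NT`,
#'   `NOPAS` poly(A)-signal classes planted upstream of sites.
#' @param min_gene_len,min_intergenic_len Lower bounds of the geometric-like
#'   length distributions.
#' @param utr5_len,utr3_len Annotated UTR lengths of simulated coding genes.
#' @param seed Integer seed fixing all randomness, or `NULL`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 2L,
                              n_genes = 200L,
                              mean_gene_len = 2343,
                              mean_intergenic_len = 5086,
                              class_mix = c(UTR3 = 0.20, SE = 0.45, A = 0.15,
                                            SO = 0.10, sense_promoter = 0.04,
                                            antisense_proximal = 0.06),
                              n_sites = 300L,
                              tags_per_site = c(min = 3, mean = 8),
                              ip_artifact_rate = 0.05,
                              microhet_jitter_nt = 10L,
                              hexamer_mix = c(AATAAA = 0.4, VARIANT_1NT = 0.3,
                                              NOPAS = 0.3),
                              min_gene_len = 800L,
                              min_intergenic_len = 300L,
                              utr5_len = 150L,
                              utr3_len = 200L,
                              seed = NULL) {
  cls <- c("UTR3", "SE", "A", "SO", "sense_promoter", "antisense_proximal")
  if (!setequal(names(class_mix), cls)) {
    stop("class_mix must be named over: ", paste(cls, collapse = ", "))
  }
  class_mix <- class_mix[cls]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be >= 0")
  if (abs(sum(hexamer_mix) - 1) > 1e-8) stop("hexamer_mix must sum to 1")
  if (mean_intergenic_len <= min_intergenic_len) {
    stop("mean_intergenic_len must exceed min_intergenic_len")
  }
  if (mean_gene_len <= min_gene_len) {
    stop("mean_gene_len must exceed min_gene_len")
  }
  if (microhet_jitter_nt > 24L) stop("microhet_jitter_nt must be <= 24")
  if (tags_per_site[["min"]] < 1) stop("tags_per_site['min'] must be >= 1")
  structure(list(
    n_chroms = as.integer(n_chroms), n_genes = as.integer(n_genes),
    mean_gene_len = mean_gene_len,
    mean_intergenic_len = mean_intergenic_len,
    class_mix = class_mix, n_sites = as.integer(n_sites),
    tags_per_site = tags_per_site, ip_artifact_rate = ip_artifact_rate,
    microhet_jitter_nt = as.integer(microhet_jitter_nt),
    hexamer_mix = hexamer_mix,
    min_gene_len = as.integer(min_gene_len),
    min_intergenic_len = as.integer(min_intergenic_len),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    seed = seed), class = "simulation_config")
}

# heavy-tailed positive lengths with the stated mean: min + geometric
.rlen <- function(n, mean_len, min_len) {
  min_len + stats::rgeom(n, 1 / (mean_len - min_len + 1))
}

#' Simulate an annotated genome
#'
#' Lays genes with stochastic strands along each chromosome, separated by
#' geometric-like gaps with the configured means, builds simple gene models
#' (UTRs, CDS, 0-2 introns for coding genes; single-exon models for the
#' occasional ncRNA/pseudogene), generates i.i.d. uniform background
#' sequence, and writes GFF3 + FASTA.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed); default a tempdir.
#' @return A list with `gff3`, `fasta` (paths), `ann` (the loaded
#'   [load_annotation()] result with 50-nt extension), `genome` (a
#'   [Biostrings::DNAStringSet]), and `cfg`.
#' @export
simulate_genome <- function(cfg, dir = tempfile("simgenome")) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  gff_lines <- c("##gff-version 3")
  seq_region <- character(cfg$n_chroms)
  seqs <- character(cfg$n_chroms)
  gene_counter <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- sprintf("chrS%d", ci)
    ng <- per_chrom[ci]
    gaps <- .rlen(ng + 1L, cfg$mean_intergenic_len, cfg$min_intergenic_len)
    lens <- .rlen(ng, cfg$mean_gene_len, cfg$min_gene_len)
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    biotypes <- sample(c("protein_coding", "ncRNA", "pseudogene"), ng,
                       replace = TRUE, prob = c(0.92, 0.05, 0.03))
    pos <- 0L
    for (gi in seq_len(ng)) {
      g_start <- pos + gaps[gi] + 1L
      g_end <- g_start + lens[gi] - 1L
      gene_counter <- gene_counter + 1L
      gff_lines <- c(gff_lines,
                     .gene_gff(chrom, g_start, g_end, strands[gi],
                               biotypes[gi], sprintf("sg%04d", gene_counter),
                               cfg))
      pos <- g_end
    }
    chrom_len <- pos + gaps[ng + 1L]
    seq_region[ci] <- sprintf("##sequence-region %s 1 %d", chrom, chrom_len)
    seqs[ci] <- paste(sample(c("A", "C", "G", "T"), chrom_len,
                             replace = TRUE), collapse = "")
    names(seqs)[ci] <- chrom
  }
  gff3 <- file.path(dir, "genome.gff3")
  writeLines(c(gff_lines[1], seq_region, gff_lines[-1]), gff3)
  genome <- Biostrings::DNAStringSet(seqs)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)
  ann <- load_annotation(gff3, extension_nt = 50L)
  list(gff3 = gff3, fasta = fasta, ann = ann, genome = genome, cfg = cfg)
}

# GFF3 rows for one gene; coding genes get UTR5/CDS/UTR3 and 0-2 introns,
# laid out in transcription-local coordinates then mapped to the genome
.gene_gff <- function(chrom, g_start, g_end, strand, biotype, gid, cfg) {
  L <- g_end - g_start + 1L
  tid <- paste0(gid, ".1")
  to_genomic <- function(lo_start, lo_end) {
    if (strand == "+") {
      cbind(g_start + lo_start - 1L, g_start + lo_end - 1L)
    } else {
      cbind(g_end - lo_end + 1L, g_end - lo_start + 1L)
    }
  }
  row <- function(type, start, end, attrs) {
    sprintf("%s\tipacsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  }
  gene_type <- switch(biotype, pseudogene = "pseudogene", "gene")
  lines <- c(
    row(gene_type, g_start, g_end,
        sprintf("ID=%s;biotype=%s", gid, biotype)),
    row(if (biotype == "protein_coding") "mRNA" else "ncRNA",
        g_start, g_end, sprintf("ID=%s;Parent=%s", tid, gid)))
  if (biotype != "protein_coding") {
    return(c(lines, row("exon", g_start, g_end, sprintf("Parent=%s", tid))))
  }
  u5 <- cfg$utr5_len; u3 <- cfg$utr3_len
  max_introns <- max(0L, min(2L, (L - u5 - u3 - 300L) %/% 300L))
  n_introns <- if (max_introns > 0L) sample(0:max_introns, 1L) else 0L
  introns <- NULL
  if (n_introns > 0L) { # 100-nt introns inside the CDS region
    lo <- u5 + 100L
    hi <- L - u3 - 200L
    starts <- sort(sample(seq(lo, hi, by = 150L), n_introns))
    introns <- cbind(starts, starts + 99L)
  }
  # local exon set = [1, L] minus introns
  ex <- if (is.null(introns)) {
    cbind(1L, L)
  } else {
    cbind(c(1L, introns[, 2] + 1L), c(introns[, 1] - 1L, L))
  }
  for (k in seq_len(nrow(ex))) {
    ge <- to_genomic(ex[k, 1], ex[k, 2])
    lines <- c(lines, row("exon", ge[1], ge[2], sprintf("Parent=%s", tid)))
  }
  # local CDS = [u5+1, L-u3] intersected with exons
  for (k in seq_len(nrow(ex))) {
    cs <- max(ex[k, 1], u5 + 1L)
    ce <- min(ex[k, 2], L - u3)
    if (cs <= ce) {
      gc <- to_genomic(cs, ce)
      lines <- c(lines, row("CDS", gc[1], gc[2], sprintf("Parent=%s", tid)))
    }
  }
  lines
}

# -- site geometry ------------------------------------------------------------

# Rule cascade evaluated directly from the gene table; used both to validate
# placements and to label planted sites. Independent of the vectorized
# neighborhood/classification modules.
.sim_cascade <- function(genes, chrom, pos, strand,
                         se_cutoff = 700L, as_prox = 200L, prom = 700L) {
  g <- genes[genes$chrom == chrom, ]
  same <- g[g$strand == strand, ]
  opp <- g[g$strand != strand, ]
  inside <- function(tab) {
    nrow(tab) > 0 && any(tab$ext_start <= pos & tab$ext_end >= pos)
  }
  if (inside(same)) return("genic")
  if (strand == "+") {
    up <- same[same$ext_end <= pos, ]
    d5s <- if (nrow(up)) {
      i <- which.max(up$ext_end)
      if (!is.na(up$stop_codon_pos[i])) pos - up$stop_codon_pos[i]
      else pos - up$ext_end[i]
    } else NA_integer_
    dn <- same[same$tx_start >= pos, ]
    d3s <- if (nrow(dn)) min(dn$tx_start) - pos else NA_integer_
  } else {
    up <- same[same$ext_start >= pos, ]
    d5s <- if (nrow(up)) {
      i <- which.min(up$ext_start)
      if (!is.na(up$stop_codon_pos[i])) up$stop_codon_pos[i] - pos
      else up$ext_start[i] - pos
    } else NA_integer_
    dn <- same[same$tx_end <= pos, ]
    d3s <- if (nrow(dn)) pos - max(dn$tx_end) else NA_integer_
  }
  if (!is.na(d5s) && d5s < se_cutoff) return("SE")
  if (inside(opp)) return("A")
  left <- opp[opp$ext_end <= pos, ]
  right <- opp[opp$ext_start >= pos, ]
  dl <- if (nrow(left)) pos - max(left$ext_end) else NA_integer_
  dr <- if (nrow(right)) min(right$ext_start) - pos else NA_integer_
  da <- suppressWarnings(min(c(dl, dr), na.rm = TRUE))
  if (is.finite(da) && da < as_prox) return("antisense_proximal")
  if (!is.na(d3s) && d3s < prom) return("sense_promoter")
  "SO"
}

# -- placement proposals ------------------------------------------------------

.propose_site <- function(class, genes, chrom_lengths, cfg, so_pool) {
  m <- cfg$microhet_jitter_nt + 1L
  coding <- genes[!is.na(genes$stop_codon_pos), ]
  switch(class,
    UTR3 = {
      g <- coding[sample(nrow(coding), 1L), ]
      d <- sample(seq(15L, cfg$utr3_len - 5L), 1L)
      pos <- if (g$strand == "+") g$stop_codon_pos + d else g$stop_codon_pos - d
      list(chrom = g$chrom, pos = pos, strand = g$strand, host = g$gene_id)
    },
    SE = {
      g <- coding[sample(nrow(coding), 1L), ]
      lo <- cfg$utr3_len + 50L + m + 5L
      d <- sample(seq(lo, 700L - m - 5L), 1L)
      pos <- if (g$strand == "+") g$stop_codon_pos + d else g$stop_codon_pos - d
      list(chrom = g$chrom, pos = pos, strand = g$strand, host = g$gene_id)
    },
    A = {
      g <- genes[sample(nrow(genes), 1L), ]
      if (g$tx_end - g$tx_start < 220L) return(NULL)
      pos <- sample(seq(g$tx_start + 100L, g$tx_end - 100L), 1L)
      list(chrom = g$chrom, pos = pos,
           strand = if (g$strand == "+") "-" else "+", host = g$gene_id)
    },
    SO = {
      if (nrow(so_pool) == 0L) return(NULL)
      k <- sample(nrow(so_pool), 1L, prob = so_pool$width)
      pos <- so_pool$lo[k] + sample.int(so_pool$width[k], 1L) - 1L
      list(chrom = so_pool$chrom[k], pos = pos,
           strand = sample(c("+", "-"), 1L), host = NA_character_)
    },
    sense_promoter = {
      g <- genes[sample(nrow(genes), 1L), ]
      u <- sample(seq(m + 5L, 700L - m - 5L), 1L)
      pos <- if (g$strand == "+") g$tx_start - u else g$tx_end + u
      list(chrom = g$chrom, pos = pos, strand = g$strand, host = g$gene_id)
    },
    antisense_proximal = {
      g <- genes[sample(nrow(genes), 1L), ]
      u <- sample(seq(m + 2L, 200L - m - 2L), 1L)
      pos <- if (sample(c(TRUE, FALSE), 1L)) g$ext_end + u else g$ext_start - u
      list(chrom = g$chrom, pos = pos,
           strand = if (g$strand == "+") "-" else "+", host = g$gene_id)
    })
}

# gaps (both strands pooled) wide enough to hold an SO site >= 2000 nt from
# every gene boundary
.so_pool <- function(genes, chrom_lengths, margin = 2005L) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    g <- genes[genes$chrom == chrom, ]
    len <- as.integer(chrom_lengths[[chrom]])
    if (nrow(g) == 0L) {
      out[[chrom]] <- data.frame(chrom = chrom, lo = 1L, hi = len)
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(g$ext_start, g$ext_end))
    gp <- IRanges::gaps(ir, start = 1L, end = len)
    lo <- IRanges::start(gp) + margin
    hi <- IRanges::end(gp) - margin
    keep <- lo <= hi
    if (any(keep)) {
      out[[chrom]] <- data.frame(chrom = chrom, lo = lo[keep],
                                 hi = hi[keep])
    }
  }
  pool <- do.call(rbind, out)
  if (is.null(pool)) {
    return(data.frame(chrom = character(), lo = integer(), hi = integer(),
                      width = integer()))
  }
  pool$width <- pool$hi - pool$lo + 1L
  rownames(pool) <- NULL
  pool
}

# -- sequence editing ---------------------------------------------------------

.edit_seq <- function(chars, start, end, replacement_chars) {
  n <- length(chars)
  s <- max(1L, start); e <- min(n, end)
  if (s > e) return(chars)
  off <- s - start
  chars[s:e] <- replacement_chars[(1L + off):(e - start + 1L)]
  chars
}

.rc_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

# cap every sliding 20-mer of an oriented downstream tract at <= 50% A and
# <= 60% A+G (the internal-priming thresholds are strict inequalities)
.deflate_arich <- function(tract) {
  n <- length(tract)
  if (n < 20L) return(tract)
  repeat {
    fixed <- TRUE
    for (s in seq_len(n - 19L)) {
      w <- s:(s + 19L)
      na <- sum(tract[w] == "A")
      ng <- sum(tract[w] == "G")
      if (na > 10L) {
        tract[w[which(tract[w] == "A")[1L]]] <- "T"
        fixed <- FALSE
      } else if (na + ng > 12L) {
        k <- which(tract[w] == if (ng > 0L) "G" else "A")[1L]
        tract[w[k]] <- "C"
        fixed <- FALSE
      }
    }
    if (fixed) return(tract)
  }
}

# remove accidental matches of `patterns` from an oriented window by
# overwriting them with CGCGCG, protecting [protect_lo, protect_hi] (window-
# local coordinates)
.scrub_window <- function(win, patterns, protect_lo = NA, protect_hi = NA) {
  repeat {
    hit <- 0L
    for (p in patterns) {
      pc <- strsplit(p, "")[[1]]
      for (s in seq_len(length(win) - 5L)) {
        if (!is.na(protect_lo) && s <= protect_hi && s + 5L >= protect_lo) next
        if (all(win[s:(s + 5L)] == pc)) { hit <- s; break }
      }
      if (hit > 0L) break
    }
    if (hit == 0L) return(win)
    win[hit:(hit + 5L)] <- c("C", "G", "C", "G", "C", "G")
  }
}

#' Plant labelled poly(A) sites and emit tags plus a truth table
#'
#' Places sites according to `cfg$class_mix` so that each one satisfies its
#' class geometry (validated against the ordered classification cascade),
#' embeds the assigned poly(A)-signal hexamer at positions -30..-25 upstream
#' of each site, plants internal-priming artifacts with an A/G-rich
#' downstream tract, scatters each site's tags within
#' `cfg$microhet_jitter_nt`, and writes the edited FASTA, a BED6 tag file
#' (score = tag count) and a TSV truth table.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (default: alongside the genome files).
#' @return A list with `sites` (cleavage-site data.frame: `chrom`, `pos`,
#'   `strand`, `n_tags`), `truth` (one row per planted site), `genome`
#'   (edited sequence), and paths `tags_bed`, `truth_tsv`, `fasta`.
#' @export
simulate_tags <- function(sim, dir = dirname(sim$fasta)) {
  cfg <- sim$cfg
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  genes <- sim$ann$genes
  chrom_lengths <- sim$ann$chrom_lengths

  n_per <- .largest_remainder(cfg$class_mix * cfg$n_sites)
  n_art <- round(cfg$ip_artifact_rate * cfg$n_sites)
  plan <- c(rep(names(n_per), n_per), rep("A", n_art))
  is_art <- c(rep(FALSE, sum(n_per)), rep(TRUE, n_art))

  so_pool <- .so_pool(genes, chrom_lengths)
  placed <- data.frame(chrom = character(), pos = integer(),
                       strand = character())
  m <- cfg$microhet_jitter_nt + 1L
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    class <- plan[i]
    ok <- FALSE
    for (try in seq_len(500L)) {
      cand <- .propose_site(class, genes, chrom_lengths, cfg, so_pool)
      if (is.null(cand)) next
      if (cand$pos < 60L ||
          cand$pos > chrom_lengths[[cand$chrom]] - 60L) next
      near <- placed$chrom == cand$chrom & placed$strand == cand$strand &
        abs(placed$pos - cand$pos) < 75L
      if (any(near)) next
      if (class == "UTR3") {
        ok <- TRUE
      } else {
        ok <- .sim_cascade(genes, cand$chrom, cand$pos, cand$strand) == class
      }
      if (ok) break
    }
    if (!ok) {
      stop(sprintf("could not place a site of class '%s': no eligible locus",
                   class))
    }
    amb <- if (class == "UTR3") FALSE else {
      !all(vapply(c(-m, m), function(dd) {
        .sim_cascade(genes, cand$chrom, cand$pos + dd, cand$strand) == class
      }, logical(1)))
    }
    placed <- rbind(placed, data.frame(chrom = cand$chrom, pos = cand$pos,
                                       strand = cand$strand))
    rows[[i]] <- data.frame(
      site_id = sprintf("ps%04d", i), chrom = cand$chrom, pos = cand$pos,
      strand = cand$strand, class = class,
      hexamer_class = NA_character_, is_ip_artifact = is_art[i],
      ambiguous = amb, host_gene = cand$host, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth$hexamer_class <- sample(names(cfg$hexamer_mix), nrow(truth),
                                replace = TRUE, prob = cfg$hexamer_mix)

  # ---- sequence edits
  seqs <- lapply(as.character(sim$genome), function(s) strsplit(s, "")[[1]])
  variants <- pas_variants()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    chars <- seqs[[tr$chrom]]
    plus <- tr$strand == "+"
    hex <- switch(tr$hexamer_class,
                  AATAAA = "AATAAA",
                  VARIANT_1NT = sample(variants, 1L),
                  NOPAS = NA_character_)
    # oriented upstream window [-50, -1]
    w_g <- if (plus) c(tr$pos - 50L, tr$pos - 1L) else c(tr$pos + 1L, tr$pos + 50L)
    win <- chars[w_g[1]:w_g[2]]
    if (!plus) win <- .rc_chars(win)
    if (!is.na(hex)) win <- .edit_seq(win, 21L, 26L, strsplit(hex, "")[[1]])
    scrub_pats <- if (tr$hexamer_class == "NOPAS") c("AATAAA", variants)
                  else "AATAAA"
    prot <- if (is.na(hex)) c(NA, NA) else c(21L, 26L)
    win <- .scrub_window(win, scrub_pats, prot[1], prot[2])
    back <- if (plus) win else .rc_chars(win)
    chars[w_g[1]:w_g[2]] <- back
    tract_len <- cfg$microhet_jitter_nt + 21L
    if (tr$is_ip_artifact) { # guaranteed A/G-rich 20-nt windows downstream
      tract <- rep(c("A", "A", "A", "A", "G"), length.out = tract_len)
      if (plus) {
        chars <- .edit_seq(chars, tr$pos + 1L, tr$pos + tract_len, tract)
      } else {
        chars <- .edit_seq(chars, tr$pos - tract_len, tr$pos - 1L,
                           .rc_chars(tract))
      }
    } else {
      # a genuine site must not carry the internal-priming signature, or its
      # truth label would contradict the filter's definition of an artifact
      dg <- if (plus) c(tr$pos + 1L, tr$pos + tract_len)
            else c(tr$pos - tract_len, tr$pos - 1L)
      if (dg[1] >= 1L && dg[2] <= length(chars)) {
        tract <- chars[dg[1]:dg[2]]
        if (!plus) tract <- .rc_chars(tract)
        tract <- .deflate_arich(tract)
        chars <- .edit_seq(chars, dg[1], dg[2],
                           if (plus) tract else .rc_chars(tract))
      }
    }
    seqs[[tr$chrom]] <- chars
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- names(seqs)

  # ---- tags: dominant position keeps a strict majority of the site's tags
  tag_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    n <- cfg$tags_per_site[["min"]] +
      stats::rpois(1L, max(0, cfg$tags_per_site[["mean"]] -
                                cfg$tags_per_site[["min"]]))
    nd <- ceiling(0.6 * n)
    k <- n - nd
    pos <- tr$pos; cnt <- nd
    if (k > 0L && cfg$microhet_jitter_nt > 0L) {
      offs <- sample(setdiff(seq(-cfg$microhet_jitter_nt,
                                 cfg$microhet_jitter_nt), 0L),
                     min(k, 3L))
      alloc <- table(sample(offs, k, replace = TRUE))
      pos <- c(pos, tr$pos + as.integer(names(alloc)))
      cnt <- c(cnt, as.integer(alloc))
    } else if (k > 0L) {
      cnt <- n
    }
    tag_rows[[i]] <- data.frame(chrom = tr$chrom, pos = pos,
                                strand = tr$strand, n_tags = cnt,
                                stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, tag_rows)
  sites <- stats::aggregate(n_tags ~ chrom + pos + strand, sites, sum)
  sites <- sites[order(sites$chrom, sites$strand, sites$pos), ]
  rownames(sites) <- NULL
  truth$n_tags <- NA_integer_ # filled below from emitted tags
  for (i in seq_len(nrow(truth))) {
    sel <- sites$chrom == truth$chrom[i] & sites$strand == truth$strand[i] &
      abs(sites$pos - truth$pos[i]) <= cfg$microhet_jitter_nt
    truth$n_tags[i] <- sum(sites$n_tags[sel])
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)
  tags_bed <- file.path(dir, "tags.bed")
  utils::write.table(
    data.frame(sites$chrom, sites$pos - 1L, sites$pos,
               sprintf("cs%05d", seq_len(nrow(sites))), sites$n_tags,
               sites$strand),
    tags_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sites = sites, truth = truth, genome = genome,
       tags_bed = tags_bed, truth_tsv = truth_tsv, fasta = fasta)
}

.largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

#' Simulate a complete labelled dataset
#'
#' Convenience wrapper running [simulate_genome()] then [simulate_tags()]
#' into one directory, so the on-disk FASTA contains the planted signals.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory.
#' @return The combined list from both stages.
#' @export
simulate_dataset <- function(cfg, dir = tempfile("simdata")) {
  sim <- simulate_genome(cfg, dir)
  tg <- simulate_tags(sim, dir)
  sim$genome <- tg$genome
  c(sim[c("gff3", "fasta", "ann", "genome", "cfg")],
    tg[c("sites", "truth", "tags_bed", "truth_tsv")])
}
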