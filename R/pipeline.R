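# End-to-end orchestration: one config, deterministic seeds, flat-file
# artifacts per stage plus a JSON manifest.

# stable per-stage seed: a global seed fans out through a string hash of the
# stage name, so adding stages never perturbs earlier stages' randomness
.stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 1048573
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with its published default. Either point
#' `gff3`/`fasta`/`tags` at input files, or set `simulate` to a
#' [simulation_config()] to run on a synthetic dataset.
#'
#' @param gff3,fasta,tags Input paths (annotation, genome, BED6 cleavage
#'   sites); ignored when `simulate` is given.
#' @param simulate `NULL` or a [simulation_config()].
#' @param out_dir Run directory for artifacts.
#' @param seed Global seed; fans out to per-stage seeds.
#' @param extension_nt 3'-UTR extension (50).
#' @param max_gap PAC clustering distance (24).
#' @param min_tags PAC support threshold (3).
#' @param fdr_step,fdr_max_d FDR grid (20, 2000).
#' @param alpha Target FDR for the SE cutoff (0.1).
#' @param se_cutoff_nt `NULL` to derive via [select_cutoff()], or a fixed
#'   distance (the published value is 700).
#' @param classification Extra arguments for [classification_config()].
#' @param profile_up,profile_down Composition window (300, 100).
#' @param pas_window Hexamer scan window (`c(-50, -1)`).
#' @param so_exclusion_nt SO near-gene exclusion (2000).
#' @param so_linkage_nt SO cluster linkage (`NULL`: derive via
#'   [inter_pac_distance()] from the extended 3'-UTRs, the published route
#'   to 431 nt; or a fixed distance).
#' @param evidence List of [evidence_set()]s to verify SO clusters against.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3 = NULL, fasta = NULL, tags = NULL,
                            simulate = NULL, out_dir = tempfile("ipacrun"),
                            seed = 1L, extension_nt = 50L, max_gap = 24L,
                            min_tags = 3L, fdr_step = 20L,
                            fdr_max_d = 2000L, alpha = 0.1,
                            se_cutoff_nt = NULL, classification = list(),
                            profile_up = 300L, profile_down = 100L,
                            pas_window = c(-50L, -1L),
                            so_exclusion_nt = 2000L, so_linkage_nt = NULL,
                            evidence = list()) {
  if (is.null(simulate) && (is.null(gff3) || is.null(fasta) ||
                            is.null(tags))) {
    stop("provide gff3+fasta+tags, or a simulation_config via 'simulate'")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full IPAC pipeline
#'
#' Stages: annotate -> cluster -> categorise -> neighbor distances ->
#' background/FDR -> classify -> signal profiles -> 3'-UTR statistics ->
#' SO clustering and evidence -> A-IPAC expression correlation. Every
#' intermediate is written as a flat TSV under `cfg$out_dir`, and
#' `manifest.json` records the configuration, seed, versions and artifact
#' checksums.
#'
#' @param cfg A [pipeline_config()].
#' @return An invisible list with the in-memory results of each stage plus
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(cfg$out_dir, name)

  if (!is.null(cfg$simulate)) {
    simcfg <- cfg$simulate
    if (is.null(simcfg$seed)) simcfg$seed <- .stage_seed(cfg$seed, "simulate")
    sim <- simulate_dataset(simcfg, dir = art("sim"))
    gff3 <- sim$gff3; fasta <- sim$fasta; tags <- sim$tags_bed
  } else {
    sim <- NULL
    gff3 <- cfg$gff3; fasta <- cfg$fasta; tags <- cfg$tags
  }
  if (!file.exists(fasta)) stop(sprintf("genome FASTA not found: %s", fasta))
  ann <- load_annotation(gff3, extension_nt = cfg$extension_nt)
  genome <- .as_genome(fasta)

  sites <- read_cleavage_sites(tags)
  pacs <- filter_min_support(cluster_sites(sites, max_gap = cfg$max_gap),
                             min_tags = cfg$min_tags)
  annotated <- annotate_pacs(pacs, ann)
  utils::write.table(annotated[, setdiff(names(annotated), "sites")],
                     art("annotated_pacs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  catsum <- category_summary(annotated)
  utils::write.table(catsum, art("category_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ipacs <- select_ipacs(annotated)
  cls_args <- cfg$classification
  anchor <- if (!is.null(cls_args$sense_anchor)) cls_args$sense_anchor
            else "stop_codon"
  contexts <- neighbor_contexts(ipacs, ann, sense_anchor = anchor)
  utils::write.table(cbind(pac_id = ipacs$pac_id, contexts),
                     art("neighbor_contexts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bg <- sample_background(ann, n = max(nrow(ipacs), 1L),
                          seed = .stage_seed(cfg$seed, "background"))
  bg_ctx <- neighbor_contexts(bg, ann, sense_anchor = anchor)
  curve <- fdr_curve(contexts$d5s, bg_ctx$d5s, step = cfg$fdr_step,
                     max_d = cfg$fdr_max_d)
  write_fdr_curve(curve, art("fdr_curve.tsv"))
  se_cutoff <- if (is.null(cfg$se_cutoff_nt)) {
    select_cutoff(curve, alpha = cfg$alpha)
  } else cfg$se_cutoff_nt

  cls_cfg <- do.call(classification_config,
                     c(list(se_cutoff_nt = se_cutoff), cls_args))
  records <- classify_ipacs(ipacs, contexts, cls_cfg, genome)
  utils::write.table(records[, setdiff(names(records), "sites")],
                     art("classified_ipacs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clsum <- class_summary(records)
  utils::write.table(clsum, art("class_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  profiles <- list()
  pas <- list()
  for (k in c("SE", "A", "SO")) {
    r <- records[records$ipac_class == k, , drop = FALSE]
    if (nrow(r) == 0L) next
    sdf <- data.frame(chrom = r$chrom, pos = r$dominant_site,
                      strand = r$strand)
    profiles[[k]] <- composition_profile(sdf, genome, up = cfg$profile_up,
                                         down = cfg$profile_down)
    write_profile(profiles[[k]], art(sprintf("profile_%s.tsv", k)))
    pas[[k]] <- cbind(pac_id = r$pac_id,
                      classify_pas(sdf, genome, window = cfg$pas_window))
    utils::write.table(pas[[k]], art(sprintf("pas_class_%s.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  se_map <- assign_se_to_genes(records, ann, utr3_pacs = annotated)
  utr_stats <- utr_length_stats(annotated, se_map, ann)
  utils::write.table(utr_stats$records, art("utr_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(utr_stats$summary, art("utr_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ext <- if (nrow(se_map)) mean_extension(se_map, ann, annotated) else NULL

  linkage <- if (is.null(cfg$so_linkage_nt)) {
    after <- utr_stats$records[utr_stats$records$phase == "after", ]
    if (nrow(after)) {
      inter_pac_distance(mean(after$utr_len),
                         nrow(after) / length(unique(after$gene_id)))
    } else 431L
  } else cfg$so_linkage_nt
  soc <- cluster_so(records, contexts,
                    near_gene_exclusion_nt = cfg$so_exclusion_nt,
                    linkage_nt = linkage)
  utils::write.table(soc$clusters, art("so_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  verification <- NULL
  if (length(cfg$evidence) && nrow(soc$clusters)) {
    items <- data.frame(chrom = soc$clusters$chrom,
                        pos = soc$clusters$dominant_site)
    verification <- data.frame(cluster_id = soc$clusters$cluster_id)
    for (ev in cfg$evidence) {
      verification[[ev$name]] <- verify_against_evidence(items, ev)
    }
    utils::write.table(verification, art("so_verification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  a_corr <- NULL
  a_rec <- records[records$ipac_class == "A", , drop = FALSE]
  if (nrow(a_rec) >= 3L) {
    # target expression: total tags of all PACs hosted by the antisense gene
    host_tags <- tapply(annotated$total_tags, annotated$host_gene, sum)
    y <- as.numeric(host_tags[a_rec$antisense_gene])
    y[is.na(y)] <- 0
    if (stats::sd(a_rec$total_tags) > 0 && stats::sd(y) > 0) {
      a_corr <- expression_correlation(a_rec$total_tags, y)
    }
  }

  manifest <- list(
    package = "ipactools",
    version = as.character(utils::packageVersion("ipactools")),
    seed = cfg$seed,
    se_cutoff_nt = se_cutoff, so_linkage_nt = linkage,
    config = .serializable(cfg),
    artifacts = as.list(tools::md5sum(list.files(cfg$out_dir,
                                                 pattern = "\\.tsv$",
                                                 full.names = TRUE))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(ann = ann, sim = sim, pacs = pacs, annotated = annotated,
                 category_summary = catsum, ipacs = ipacs,
                 contexts = contexts, background = bg, fdr_curve = curve,
                 se_cutoff = se_cutoff, records = records,
                 class_summary = clsum, profiles = profiles,
                 pas = pas, se_map = se_map, utr_stats = utr_stats,
                 mean_extension = ext, so_clusters = soc,
                 so_linkage_nt = linkage, verification = verification,
                 a_correlation = a_corr, out_dir = cfg$out_dir))
}

.serializable <- function(cfg) {
  out <- unclass(cfg)
  out$evidence <- lapply(out$evidence, function(e) {
    list(name = e$name, anchor_mode = e$anchor_mode,
         window_nt = e$window_nt, n_intervals = nrow(e$intervals))
  })
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}

#' Command-line entry point
#'
#' A thin dispatcher over the exported functions:
#' `ipac simulate|run --seed N --out DIR [--gff3 F --fasta F --tags F]`.
#' Installed as `inst/scripts/ipac`.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
ipac_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    message("usage: ipac <simulate|run> [--seed N] [--out DIR]",
            " [--gff3 F --fasta F --tags F] [--n-genes N] [--n-sites N]")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", tempfile("ipacrun"))
  if (cmd == "simulate") {
    cfg <- simulation_config(
      n_genes = as.integer(opt("--n-genes", "200")),
      n_sites = as.integer(opt("--n-sites", "300")), seed = seed)
    sim <- simulate_dataset(cfg, dir = out)
    message("simulated dataset in ", out)
  } else if (cmd == "run") {
    simulate <- NULL
    if (is.null(opt("--gff3"))) {
      simulate <- simulation_config(
        n_genes = as.integer(opt("--n-genes", "200")),
        n_sites = as.integer(opt("--n-sites", "300")))
    }
    cfg <- pipeline_config(gff3 = opt("--gff3"), fasta = opt("--fasta"),
                           tags = opt("--tags"), simulate = simulate,
                           out_dir = out, seed = seed)
    run_pipeline(cfg)
    message("pipeline artifacts in ", out)
  } else {
    stop(sprintf("unknown command '%s'", cmd))
  }
  invisible(0L)
}
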