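# ipactools

Tools for discovering and classifying **intergenic poly(A) site clusters
(IPACs)** from poly(A)-tag sequencing data.

## The problem

Poly(A)-tag sequencing anchors each read at an mRNA cleavage/poly(A)
junction, so mapped tags mark where transcripts end. A substantial fraction
of these cleavage sites falls *outside* annotated gene models. Such
intergenic sites can be (i) unannotated 3'-UTR extensions of the upstream
gene, (ii) the 3' ends of antisense transcripts overlapping a gene on the
opposite strand, or (iii) the 3' ends of entirely novel intergenic
transcripts. `ipactools` implements the genome-wide procedure for telling
these apart, for users working with plant (or other compact-genome) poly(A)
site data.

## The method

1. **PAC construction.** Cleavage sites within 24 nt of each other are
   single-linkage clustered into poly(A) site clusters (PACs), absorbing
   cleavage microheterogeneity; clusters with fewer than 3 tags are
   dropped. Each PAC is represented by its dominant (max-tag) site.
2. **Annotation.** Against a gene annotation whose 3'-UTRs are extended by
   50 nt, each PAC gets exactly one category (3'-UTR, CDS, intron, 5'-UTR,
   exon, pseudogenic exon, AMB for ambiguous isoform conflicts, or
   intergenic). The intergenic subset are the IPACs.
3. **Neighbor geometry.** For each IPAC the distances d5s, d3s, d5a, d3a to
   the nearest sense/antisense genes on both sides are computed, plus its
   position normalized by the intergenic gap length.
4. **Empirical FDR.** The same number of random intergenic positions gives
   a background distance distribution. For a distance *d*, FDR(*d*) =
   #{background ≤ *d*} / #background. The largest *d* with FDR < 0.1
   (700 nt in the original data, where 1528/16567 = 0.092) becomes the
   **SE** cutoff.
5. **Ordered classification.** d5s < 700 → **SE** (3'-UTR extension);
   else antisense-gene overlap → internal-priming filter (discard if the
   downstream 20-mer has > 50 % A or > 60 % A+G) → **A** or filtered;
   else within 200 nt of an antisense boundary or 700 nt of the downstream
   gene start → proximal leftovers; else **SO** (orphan).
6. **Downstream analyses.** Base-composition profiles and AATAAA-class
   hexamer (NUE) classification around sites; 3'-UTR length statistics
   after recruiting SE-IPACs (Wilcoxon test); SO clustering at the expected
   intra-gene inter-PAC distance (935 nt / 2.17 = 431 nt) into candidate
   novel transcripts, verified against evidence interval sets; antisense
   expression correlation; cross-sample IPAC matching at 50 nt.

A synthetic-data module (`simulation_config()`, `simulate_dataset()`)
generates annotated toy genomes with the published geometry (mean gene
length 2343 nt, mean intergenic gap 5086 nt) and plants labelled sites of
every class — including internal-priming artifacts and poly(A)-signal
hexamers — so the whole pipeline is testable with known truth.

## Worked example

```r
library(ipactools)

cfg <- simulation_config(n_genes = 120, n_sites = 180, seed = 4)
sim <- simulate_dataset(cfg)
run <- run_pipeline(pipeline_config(gff3 = sim$gff3, fasta = sim$fasta,
                                    tags = sim$tags_bed, seed = 4,
                                    se_cutoff_nt = 700))
run$category_summary
#>     category n_pac n_tags  pac_pct  tag_pct
#> 1       UTR3    36    289 19.04762 18.68132
#> 2 INTERGENIC   153   1258 80.95238 81.31868
run$class_summary
#>                class  n   fraction n_prefilter
#> 1                 SE 81 0.52941176          NA
#> 2                  A 27 0.17647059          36
#> 3                 SO 18 0.11764706          NA
#> 4     SENSE_PROMOTER  7 0.04575163          NA
#> 5 ANTISENSE_PROXIMAL 11 0.07189542          NA
#> 6        FILTERED_IP  9 0.05882353          NA
run$utr_stats$summary
#>    phase   n median     mean
#> 1 before  36    131 115.4167
#> 2  after 117    346 356.9829
```

Reading this output: 153 of 189 PACs are intergenic; 81 of them sit within
700 nt of an upstream stop codon and are recruited as 3'-UTR extensions
(SE), which moves the pooled median 3'-UTR length from 131 to 346 nt; 36
antisense candidates lose 9 sites to the internal-priming filter, leaving
27 A-IPACs; 18 orphan (SO) sites remain as candidate novel transcript
ends. All run artifacts (per-stage TSVs and a JSON manifest) land in
`run$out_dir`.

## CLI

```sh
inst/scripts/ipac simulate --seed 1 --out simdir
inst/scripts/ipac run --gff3 g.gff3 --fasta g.fa --tags tags.bed --out rundir
```

See `vignette("ipac-methods")` for the model, parameter defaults, what the
simulator does and does not emulate, and design decisions.
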