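---
title: "Methods: classifying intergenic poly(A) site clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying intergenic poly(A) site clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Poly(A)-tag reads define cleavage sites: (chromosome, position, strand,
tag count). `ipactools` treats a polyadenylation *event* as a cluster of
cleavage sites — microheterogeneity scatters cleavage over a couple of
dozen nucleotides — and asks, for every cluster that falls outside
annotated gene space, which transcriptional phenomenon most plausibly
produced it.

The classification is purely geometric, driven by distances to annotated
neighbors, and calibrated by an empirical null: random positions drawn
uniformly from the same intergenic space. If real IPACs crowd the first
700 nt downstream of stop codons far in excess of what random placement
yields, the excess is attributed to unannotated 3'-UTR extension. The
empirical FDR at distance $d$ is

$$\mathrm{FDR}(d) = \frac{\#\{\text{background} \le d\}}{N_\text{background}},$$

and the SE cutoff is the largest grid distance with FDR below the target
(default $\alpha = 0.1$).

**Assumptions.** One representative model per gene (union of exons,
outermost bounds, distal stop codon) is adequate for distance anchoring;
intergenic space is strand-specific (between consecutive same-strand
genes); the dominant (max-tag) site represents its cluster; cleavage sites
are already correctly mapped and deduplicated upstream.

# Parameters

| parameter | default | unit | why |
|---|---|---|---|
| cluster gap (`max_gap`) | 24 | nt | microheterogeneity scale of plant cleavage |
| min support (`min_tags`) | 3 | tags | removes singleton/doubleton noise |
| 3'-UTR extension | 50 | nt | absorbs sites just past annotated UTRs without swallowing true intergenic space |
| FDR grid | 20 / 2000 | nt | published binning of the distance curves |
| target FDR (`alpha`) | 0.1 | — | yields the 700-nt SE cutoff on the original data |
| antisense-proximal cutoff | 200 | nt | the stricter (FDR 0.01) proximity rule |
| sense-promoter cutoff | 700 | nt | symmetric with the SE distance |
| priming window / A / A+G | 20 / 0.50 / 0.60 | nt, fraction | internal-priming signature; strict inequalities |
| SO near-gene exclusion | 2000 | nt | a complete gene is unlikely to fit closer than this |
| SO linkage | derived (935/2.17 ≈ 431) | nt | expected intra-gene spacing of alternative poly(A) sites |
| profile window | −300..+100 | nt | covers NUE/FUE upstream signal and downstream cleavage element |
| hexamer scan window | −50..−1 | nt | NUE-proximal; the counting window is not fixed by the source analyses, so it is a config knob |
| cross-sample window | 50 | nt | twice the cluster gap |

# Design decisions

* **Coordinates.** Internally everything is 1-based inclusive, the native
  convention of `GRanges`/`IRanges` which do the interval arithmetic. I/O
  follows each format (GFF3 1-based, BED half-open). This deviates from a
  0-based-internal design sketch; fighting the container's convention is
  the classic source of off-by-one bugs in R.
* **Rule order.** SE → A → antisense-proximal → sense-promoter → SO. This
  is the only ordering under which the published class counts add up:
  antisense candidates are drawn from the *non-SE* IPACs, and the
  proximity screens apply to the remainder only. The alternative reading
  (a 700-nt 3'-antisense exclusion before SO) conflicts with the stated
  200-nt rule; 200 nt is the default and a separate `so_antisense_cutoff`
  exposes the 700-nt variant.
* **FDR denominator.** The published worked value (1528/16567 = 0.092)
  divides by *all* background positions, while the accompanying text
  describes dividing by background within 2000 nt. The arithmetic wins:
  `denominator = "total"` is the default, `"within_max"` is available.
* **Distance anchors.** The upstream sense distance anchors at the stop
  codon (distal across isoforms) when the gene codes, else at the extended
  3' end. Antisense distances anchor at the nearest extended boundary of
  the nearest opposite-strand gene — the source analyses never name an
  antisense anchor, so the symmetric, testable choice is used. A boundary
  coinciding with the site gives distance 0; a missing neighbor gives NA
  (absent), never 0.
* **Additivity convention.** `intergenic_len` is defined as the distance
  between the flanking extended boundaries, so `d5s + d3s =
  intergenic_len` holds exactly under the extended anchor and `rel_pos`
  lies in [0, 1].
* **AMB.** Within one isoform, nested features resolve by precedence
  UTR3 > CDS > intron > UTR5 > exon > pseudogenic exon; only
  *cross-isoform disagreement* about the category yields AMB. Strand
  ambiguity is not AMB: opposite-strand overlap is handled during
  classification.
* **Dominant-site tie-break.** Equal max-tag members resolve to the more
  distal site in transcription direction, consistent with the
  distal-extension theme of the analysis.
* **Priming filter placement.** The sequence filter is exposed generically
  but applied by default only to antisense candidates — its published
  placement. An earlier read-level priming removal belongs to upstream
  processing and is out of scope.
* **3'-UTR length statistics.** The before/after comparison uses *pooled
  per-PAC lengths* (every PAC contributes one length), not per-gene distal
  lengths; rank-wise medians within genes carrying exactly k PACs are
  reported separately. The pooled reading is the only one under which
  per-rank medians are a distinct, meaningful second statistic.
* **Mean extension baseline.** Per gene: the distal observed UTR3 PAC when
  one exists, otherwise the annotated (pre-extension) 3' end; negative
  extensions floor at 0.
* **Cross-sample matching.** One-to-one greedy by distance within 50 nt,
  ties toward the smaller coordinate; the shared fraction is relative to
  the first sample, i.e. deliberately asymmetric.
* **Stop-codon reconciliation.** With multiple isoforms the distal stop
  codon is used. The proximal alternative would shorten every d5s and can
  only enlarge the SE class; it is not currently exposed because the
  representative-model collapse already uses outermost bounds.

# The synthetic world

`simulate_genome()` lays genes on stochastic strands with geometric-like
lengths (mean 2343 nt, min 800) separated by geometric-like gaps (mean
5086 nt, min 300) — the published genome-wide averages for the organism
modeled. Coding genes get 150-nt 5'-UTRs, 200-nt 3'-UTRs and 0–2 introns;
5 % ncRNAs and 3 % pseudogenes exercise the biotype paths. Background
sequence is i.i.d. uniform over A/C/G/T.

`simulate_tags()` plants sites whose geometry is *validated against the
classification cascade at placement time*, in the proportions of
`class_mix` (default: 20 % genic 3'-UTR controls, then SE/A/SO/promoter/
antisense-proximal roughly in the published class proportions). Each site
emits ≥ 3 tags, the dominant position keeping a strict majority, the rest
jittered within ±10 nt. A poly(A)-signal hexamer (canonical, 1-nt variant,
or none, 40/30/30) is written at −30..−25; accidental canonical/variant
matches in the scan window are scrubbed so the planted signal class is the
true class. Internal-priming artifacts are planted with a deterministic
AAAAG-repeat downstream tract (80 % A), guaranteeing every 20-mer window
trips the strict thresholds; conversely the downstream tract of *genuine*
sites is deflated below the thresholds, because a "genuine" label on a
site carrying the artifact signature would contradict the filter's own
definition.

**What a green test establishes — and what it does not.** The simulator
validates mechanism: interval arithmetic, rule ordering, filter logic,
determinism. It does not emulate transcription or splicing, sequencing
error, chained genes sharing intergenic space with complex overlap,
realistic NUE/FUE composition gradients, or tag-count biology. Recovery
rates near 100 % on synthetic data say the code implements the stated
rules, not that the rules are biologically complete.

A planted site is flagged `ambiguous` when shifting it by ±(jitter+1) nt
changes the class the cascade assigns; recovery criteria score only
unambiguous sites, since a site genuinely straddling two class windows has
no single correct label.

# Numerical choices and degenerate inputs

* Strict inequalities throughout the priming filter (exactly 50 % A +
  10 % G survives); truncated windows evaluate over the available length
  and are flagged; an empty downstream window keeps the PAC.
* `select_cutoff` returns 0 when even the first grid point fails, and the
  grid maximum when the curve never reaches `alpha`.
* Empty inputs return empty, typed tables; an empty background errors
  (the curve is undefined); an empty SE map makes the mean extension an
  error, not NaN.
* All randomness flows through explicit seeds; the pipeline fans a global
  seed out per stage by hashing stage names, so adding a stage never
  perturbs earlier stages.
* The worked percentage checks in the acceptance suite compare at the
  printed integer precision; stochastic suite checks use tolerances
  derived from binomial error at the stated sample sizes, fixed before
  measurement.

# Limitations

* One representative model per gene: isoform-specific 3' ends are not
  distinguished beyond the AMB flag.
* The classifier consumes dominant sites only; a span-majority mode for
  categorisation is configurable at the annotation step but not propagated
  further.
* Evidence association reproduces the mechanism (windowed interval
  queries), not any particular published evidence files.
* The empirical FDR treats background positions as exchangeable with IPAC
  positions; length-biased sampling of very short gaps is inherited from
  the definition, not corrected.
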