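---
title: "cageAtlas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cageAtlas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cageAtlas builds a genome-wide annotation of transcription start sites
(TSS) and promoter-proximal enhancer candidates from multi-tissue CAGE
(Cap Analysis Gene Expression) data, and corroborates novel TSS with
whole-genome bisulfite sequencing (WGBS). This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic test panel does and does not establish about real data.

## Tag normalization and clustering

Each CAGE library is reduced to strand-specific 5'-end tag counts at
base-pair resolution (`TagProfile`). Counts are normalized to CAGE tags
per million mapped (CTPM): `count / totalMapped * 1e6`, so every
library's CTPM values sum to one million regardless of depth.

Uni-directional TSS calling operates on a pooled track. Pooling defaults
to the CTPM scale (`poolMode = "ctpm"`), which weights libraries equally;
raw-count pooling is available. Clustering merges consecutive signal
positions at most `mergeDist` bp apart (default 20 bp, the convention of
the CAGE clustering tools this pipeline follows; the merge distance
changes cluster widths but, at typical tag densities, few downstream
counts). The cluster peak is the position of maximum pooled signal, ties
broken 5'-most on the cluster strand so that peak choice is
deterministic.

Two filters follow, in a fixed order. First, clusters whose pooled raw
count is below `minClusterCount` (default 10 tags) are removed. Second,
the representation filter keeps clusters present in at least
`floor(nTissues * 2/3)` tissues — 37 of 56 for a full panel — where
presence defaults to a raw count of at least 10 in that tissue
(`count_ge_10`); an alternative rule, CTPM strictly greater than 10
(`ctpm_gt_10`), is provided because both conventions appear in practice
for this analysis and they differ for shallow libraries. Filtering at
cluster level (not per-bp before clustering) is the default; a per-bp
pre-filter would fragment jittered TSS and is deliberately not applied.

## Genomic-region annotation

Gene models come from GFF3. The TSS of a transcript is its 5'-most
transcribed base; the promoter window is that position ±100 bp, and the
proximal region extends to 1,000 bp upstream on the transcript strand.
Positions are classified with the fixed precedence
promoter > proximal > fiveUTR > threeUTR > exon > intron > intergenic,
evaluated over all transcripts covering the position. The precedence
order is a design choice (the category set is standard; no published
rule orders overlaps across genes); it is configurable in the sense
that each track is exposed on the `RegionIndex`. Promoter and proximal
matching is strand-aware by default — an antisense tag 50 bp from a TSS
is not "promoter" — with a flag to relax, since the analogous
annotation tools differ here. There is no separate "downstream"
category: sequence within 1 kb past a 3' end that is in no other class
is intergenic, which makes the seven classes an exact partition of the
genome (a property the tests assert).

Clusters are assigned the class of their peak position; ties were
already resolved at peak selection. Interval-level assignment (any
overlap) is used only for gene association, i.e. which promoter windows
a cluster touches.

## Bi-directional (TSS-Enhancer) clusters

Divergent transcription is scored with a Bhattacharyya balance
statistic. For a candidate midpoint, tags are tallied in four bins:
minus-strand upstream `[mid - w, mid)`, plus-strand downstream
`(mid, mid + w]`, and the two "wrong-way" combinations. With the tallies
normalized to proportions `p`, the score is
`B = sqrt(0.5 p_um) + sqrt(0.5 p_dp)` — the Bhattacharyya coefficient
against the ideal divergent profile (0.5, 0.5, 0, 0). `B = 1` is
perfectly balanced divergent transcription; a single-strand site scores
`sqrt(0.5) ≈ 0.707`. Defaults `w = 200` bp and threshold `B ≥ 0.95`
follow the published enhancer-detection algorithm this score comes
from; both are parameters.

Every position within `w` of signal is scanned. Contiguous
above-threshold candidates are grouped (groups separated by more than
`2w` bp), and each group's midpoint is refined to the midpoint of its
two arm centroids. The refinement matters numerically: the raw balance
maximum sits at the inner edge of an arm (removing an edge tag from the
larger arm rebalances the ratio), which would bias midpoints by the
arm offset; the centroid midpoint is unbiased for symmetric loci.

Retained clusters must lie 400-1,000 bp (inclusive) from the nearest
promoter centre. The bounds are the published detection window; the
filter requires an annotation and errors without one. Co-expression
links between bi- and uni-directional clusters use Kendall's tau-b on
per-tissue CTPM vectors for pairs within 10 kb, with Benjamini-Hochberg
control at q ≤ 0.05. The 10 kb reach and the BH rule are package
choices: the source analysis reports only "significant" pairs without
stating its criterion, so the conventional FDR 0.05 is used and
recorded here.

## Novel-TSS annotation

A cluster is "annotated" at range `w` when its interval comes within
`w` bp (inclusive) of a transcript TSS — evaluated at `w = 50`
(short range) and `w = 400` (long range); the complement of the 50 bp
rule is "novel". The ±50 bp window reproduces the effective reach of
the upstream-25/downstream-25/maxgap-25 overlap idiom used with
TxDb-style promoters, expressed as a single transparent parameter.
Matching is strand-agnostic by default (the overlap idiom it mirrors is
type "any"), and interval-based rather than peak-based; both have
flags. The per-tissue novelty table evaluates each tissue's present
clusters separately. In the end-to-end pipeline, uni-directional
clusters overlapping a retained bi-directional window are set aside as
enhancer-associated before the novelty table is built: divergent arms
are by construction 400-1,000 bp from promoters and would otherwise be
counted as "novel TSS", conflating two biologically distinct classes.

## Hypomethylated-region calling

WGBS enters as CGmap-style per-cytosine counts. Counts at the two
cytosines of a symmetric CpG pair are summed and reported at the
plus-strand C; orphaned records are kept with a notice. Only CpGs with
coverage ≥ 10 reads enter segmentation, matching standard practice for
confident methylation estimates.

Segmentation uses a two-state hidden Markov model with Beta-Binomial
emissions, which models both the methylation level and the per-site
read depth: `m_i ~ BetaBinomial(n_i, alpha_s, beta_s)` given state `s`.
Parameters are fitted by Baum-Welch EM; transitions and the initial
distribution have closed-form updates, and the emission shapes are
re-estimated each iteration by BFGS on log-shapes (warm-started, so the
expected log-likelihood cannot decrease and EM monotonicity is
preserved; the tests check this numerically). Initialization is
deterministic — state means 0.2 and 0.8, concentration 10,
self-transition 0.99 — so no random seed is involved. States are
relabelled so "hypo" is the low-mean state. Chains break at inter-CpG
gaps over 1 kb (CpG deserts carry no information about state
persistence at this grain), and hypomethylated regions are maximal runs
of Viterbi hypo-state CpGs with at least 3 members, extended one base
past the last CpG to cover the dinucleotide. These constants mirror
widely used methylome segmentation defaults and are all arguments.

Validation of TSS is pure interval overlap: a cluster overlapping any
hypomethylated region by ≥ 1 bp is `+HypoCpG`, crossed with the
annotated/novel label into four categories. No posterior score cutoff
is applied at this step; the per-CpG posterior track is exported
separately for browsers.

## Tissue expression profiles

Tissue similarity uses mutual information on binned expression.
Profiles are `log1p`-transformed and binned into 10 equal-width bins
per tissue; MI is the plug-in estimate in nats, and the distance is
`d = 1 - sqrt(1 - exp(-2 MI))`. The `log1p` step is a package choice:
CTPM distributions are heavy-tailed, and equal-width binning of raw
values collapses nearly all mass into the lowest bin, erasing the
signal MI is meant to capture (equal-frequency binning is available as
an alternative). MI is measured in nats so that
`sqrt(1 - exp(-2 MI)) = |rho|` exactly for bivariate normal data — a
property the tests exercise directly. The distance transform is written
here in terms of MI; the same expression is sometimes printed with the
distance symbol on both sides, which is circular as written, and the
MI-based reading is the standard one consistent with
`MIdistance = 1 - delta`. Tissues are clustered with average-linkage
hierarchical clustering (the source analysis does not name a linkage;
average linkage is the bioDist/hclust convention for correlation-like
distances) and exported as Newick.

CAGE-mRNA validation pairs each annotated cluster with the transcript
whose TSS it captures and computes Pearson correlation over flattened
(cluster CTPM, transcript TPM) pairs on the `log1p` scale.

## The synthetic tissue panel

`simulateCagePanel()` generates the full study layout: by default 56
tissues over 2 × 500 kb contigs with 200 genes on a 4 kb slot grid.
Planted features and their defaults:

- every gene has a TSS at its annotated position; 10% of genes carry a
  second transcript with an alternative TSS 600 bp downstream;
- novel TSS (40% of all widely-shared TSS) are placed ≥ 400 bp from
  every promoter;
- 5% of TSS are tissue-specific (expressed > 10 tags in exactly one
  tissue); four tissue families each share a block of 25
  family-specific TSS — these drive the MI dendrogram and, being
  present in under two-thirds of tissues, must be removed by the
  representation filter;
- 20% of genes have a divergent enhancer 450-950 bp upstream
  (arms ± 80 bp around the midpoint); 5% carry an out-of-range decoy
  (> 1 kb from every promoter), expressed in at most 20 tissues;
- expressed loci draw negative-binomial counts (mean 50, dispersion
  0.5) per tissue, spread multinomially over ± 2 bp of the peak;
  background noise is Poisson at 1e-5 tags/bp/tissue;
- WGBS tracks are emitted for 8 tissues: CpGs every 150-250 bp in the
  background (Beta(9,1) methylation) and every 25 bp inside planted
  501 bp hypomethylated islands (Beta(1,9)), coverage Poisson(20) split
  between strands. Islands cover 90% of annotated and 30% of novel TSS
  — the quantity the end-to-end test recovers — and no spurious locus.
- transcript TPM tables are the TSS counts under multiplicative
  lognormal noise (sd 1.5 on the log scale), giving the weak positive
  CAGE-mRNA correlation typical of cross-technology comparisons.

Slot geometry guarantees the planted constraints (novel ≥ 400 bp from
promoters, decoys > 1 kb, enhancers in range of exactly their own
promoter) by construction, so recovery scores measure the pipeline, not
the generator. All randomness flows from one seed; a fixed seed gives
byte-identical output files.

What the panel does not emulate: mapping artifacts and multi-mapper
filtering, promoter shape (sharp vs broad initiation), sequence-driven
CpG density, chained/nested gene structure, batch effects, and
biological replicate noise. Passing the recovery tests therefore shows
the algorithms are correct at realistic signal-to-noise, not that the
default thresholds are optimal for any particular real genome.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
panel defaults above (56 tissues, 1 Mb genome, ~570 planted loci, 8
WGBS tracks of ~10,000 CpGs) — large enough that the representation
filter, the enhancer distance gate and the HMM operate at their design
points, while one run stays within a few minutes on a single core.
Property checks (clustering and classification oracles) use thousands
of small randomized instances under fixed seeds. Every stochastic test
fixes its seed; the acceptance script takes the seed from the command
line and derives all panel randomness from it.

## Known limitations

- The enhancer caller assumes roughly symmetric divergent arms; highly
  asymmetric enhancers near the balance threshold can shift midpoints.
- The HMM shares one parameter set across contigs and breaks chains at
  1 kb gaps; genomes with strong regional methylation heterogeneity
  may prefer per-chromosome fits.
- Tissue-specific TSS detection reports clusters expressed in exactly
  one tissue; with single samples per tissue this cannot separate rare
  true TSS from noise, and the package deliberately leaves that
  interpretation to the analyst.
- The per-gene cluster summary counts promoter-window hits only; genes
  captured solely through novel TSS are reported as "not captured".
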