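---
title: "Methods: from strain transcriptomes to candidate transposable-element insertions"
author: "xenoTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from strain transcriptomes to candidate transposable-element insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoTE)
```

## The question the pipeline answers

When *Drosophila* strains are exposed to an insecticide such as malathion,
strains differ in tolerance and in the transcriptional response of the gut.
Transposable-element (TE) insertions segregate among strains and can rewire
*cis*-regulation — by carrying transcription-factor binding sites, by
altering chromatin accessibility, or simply by landing inside or next to a
gene. `xenoTE` chains the evidence types needed to nominate individual TE
insertions as plausible contributors to that response:

1. differentially expressed genes (DEGs) per strain, stress vs control;
2. TE–gene proximity (inside the gene or within 1 kb of it);
3. hub status of the nearby gene in a protein–protein interaction (PPI)
   network built from the strain's DEGs, ranked by Maximal Clique
   Centrality (MCC);
4. open chromatin over the TE (ATAC-seq reproducible peaks, open/closed
   calls against a background-noise model);
5. binding sites for cnc (the Nrf2-class master regulator of xenobiotic
   response) inside the TE sequence;
6. population-genetic evidence of selection at the insertion (supplied as
   input flags).

A TE becomes a candidate when it is the *single* TE near a hub DEG and
carries at least one additional line of evidence. Because no public data
accompany the workflow in a desk-runnable form, a synthetic-data module
generates every input with planted ground truth; all statistical claims in
the test suite are claims about recovery of that planted structure.

## Differential expression

Counts are normalized with median-of-ratios size factors: for each sample,
the factor is the median over features (expressed in every sample) of the
ratio of the sample's count to the feature's geometric mean. Raw medians
are returned; no rescaling to unit geometric mean is applied. When no
feature is expressed everywhere, an explicit error points to a
pseudo-reference fallback (`log(count + 0.5)` averages), which is flagged
in the result.

Each gene is modelled as negative binomial. Dispersion is estimated per
gene by pooled within-cell (strain × treatment) method of moments on
normalized counts, floored at `1e-8`. The stress-vs-control contrast for a
strain is the log ratio of that strain's two cell means (the cell-means
parametrization of `~ strain + treatment + strain:treatment`), tested with
a Wald statistic whose variance combines shot noise and the dispersion
term. The statistic is referred to a *t* distribution with the residual
degrees of freedom of the dispersion estimate — with the full four-strain
design that is 16 df, and simulation shows type-I error ≈ 0.05 at nominal
0.05 and > 90% power for planted four-fold changes at dispersion 0.05 with
three replicates per condition. A normal reference is anticonservative at
these sample sizes (empirically ≈ 0.12), which is why the heavier-tailed
reference was chosen. Genes are DEGs at BH-adjusted p ≤ 0.05 and |fold
change| ≥ 1.5 on the raw (unshrunken) estimate; both thresholds are
configurable. By default contrasts come from the full-design fit; a
`design = "per_strain"` flag restricts everything to the strain's six
samples.

Cross-strain sharing is summarized by an overlap table whose percentages
are relative to the *column* strain's DEG total, rounded half-up to one
decimal — the convention of the printed tables this layout mirrors — and
by direction-concordance counts over shared DEGs.

## TE annotation and enrichment

Coordinates live in `GRanges` (1-based, inclusive — the Bioconductor
convention); 0-based half-open formats (BED/tagAlign/bedGraph/narrowPeak)
are converted only at the IO boundary, so every overlap computed anywhere
in the package goes through one representation. "Near" means: any overlap
with the gene span (`inside_gene`, distance 0), or a nearest-edge gap
strictly below 1000 bp, with `five_prime`/`three_prime` assigned relative
to the gene's strand. DEG enrichment near TEs is a Pearson chi-square (1
df, no continuity correction by default) on the 2 × 2 table of DEG status
against TE-link status over all annotated genes; the universe is
configurable.

Genotype summaries partition genotyped insertions into present-in-all,
reference-only, and polymorphic; strains with failed genotyping are
ignored TE by TE, and TEs with no called non-reference genotype drop out
of the denominator. Family and order enrichment run per-class chi-squares
with BH adjustment across classes.

## PPI hubs by Maximal Clique Centrality

Edges with confidence score below 0.5 are discarded at load; the network
is then unweighted. MCC of a node is the sum of (|C| − 1)! over all
maximal cliques C containing it, with maximal cliques enumerated exactly
(Bron–Kerbosch with pivoting via `igraph`); a node in no clique of size
≥ 2 scores 0, and a configurable clique budget turns pathological graphs
into an explicit error rather than a silent approximation. Hubs are the
top `ceil(0.15 n)` nodes by score, including all nodes tied with the k-th
score (a conservative superset; no tie-breaking rule is imposed). Overlap
between the MCC and Degree hub sets is reported in both directions since
an overlap percentage does not fix its denominator.

## ATAC-seq processing

Fragments with insert size ≤ 100 bp (inclusive) are kept, pooled across
replicates, and split uniformly at random into two pseudo-replicates of
near-equal size. Peaks are called per half by a deliberately simple
threshold caller: positions with coverage ≥ 2 × the genome-wide mean,
runs bridged across gaps < 100 bp, minimum width 100 bp; the summit is
the leftmost coverage maximum and the peak score is the summit coverage.
The 2× default is intentionally permissive because the genome-wide mean
itself includes signal; reproducibility filtering, not the caller, is the
specificity mechanism. This caller is plumbing — it stands in for a
model-based caller whose internals are out of scope — and exposes only
these three parameters.

A peak is reproducible when a peak in the other half overlaps it by
strictly more than 50% of its own width, reciprocally (a single-direction
flag exists). Matched pairs then pass an irreproducible discovery rate
(IDR) filter: ranks of the pair scores are mapped through the inverse CDF
of the current mixture marginal to pseudo-values modelled as a
two-component Gaussian mixture — a reproducible component N(μ, σ², ρ) and
an independent standard-normal noise component — fitted by
pseudo-likelihood EM with the marginal re-derived between rounds. Three
design points matter here:

* **Pair score.** Pairs are scored by peak *area* (total coverage), not
  summit height. When open regions share a common density, summit heights
  differ only by counting noise and their ranks carry no reproducible
  signal, making the copula mixture unidentifiable; area inherits the
  region-width signal and keeps the fit identifiable in that regime.
  Summit coverage remains the per-peak score written to narrowPeak.
* **Convergence.** The marginal re-derivation jitters the
  pseudo-likelihood, so convergence is declared on the parameter vector
  (tolerance 1e-4, budget 20 000 iterations, three fixed starts, best
  converged likelihood wins). Non-convergence is an error with
  diagnostics, never a silent fallback.
* **Signal guard.** When the fitted copula's likelihood gain over the
  independence copula is below the 99.9% χ²(4 df) quantile, the mixture
  labels are arbitrary; the fit then declares *nothing* reproducible
  (IDR = 1 for all pairs). This makes independent scores pass ≈ 0 pairs
  while genuinely reproducible data keep everything.

Pairs with IDR < 0.05 survive; surviving peaks are rescaled to summit
± 100 bp (201 bp, clipped and flagged at chromosome edges), and all
strain × condition sets merge into a universal peak set with provenance.
Openness is called per coverage track: background noise is the median of
per-window median coverages over 10 000 random 1-kb windows, and a peak
is open iff its median coverage strictly exceeds that scalar. Peaks are
assigned to `gene_body` (any gene overlap, takes precedence), `promoter`
(within 1 kb upstream of a TSS, strand-aware), or `distal`. TE–peak
condition classes (`both`/`control_only`/`stress_only`/`none`) use ≥ 1 bp
intersection with the per-condition open sets. Accessibility profiles are
scaled by the 20-quantile rule: values are binned into 20 equal-count
bins and mapped linearly so the medians of the first and last bins hit 0
and 1.

## Motif scanning

The cnc model ships as an ARE-like consensus (TGACnnnGC) compiled to
log2-odds against a uniform background, with the hit threshold at 80% of
the maximum achievable score; any JASPAR-style PFM can be substituted and
all three pieces (matrix, background, threshold) are exposed. Both strands
are scanned, minus-strand hits are reported at their forward-strand start,
positions containing N can never reach the threshold, and overlapping hits
all count. Because the exact PWM and threshold behind published
binding-site counts are not recoverable from sequence alone, the
integration stage also accepts externally supplied per-TE counts as input
data.

## TE-family expression

Per-copy counts are summed exactly into family counts (unmapped copies go
to a flagged bin; aggregation conserves totals). Family-level DE reuses
the NB machinery but filters on the *raw* p ≤ 0.05 — deliberately not
BH-adjusted, matching the convention for repeat-family screens — and
|fold change| ≥ 3; a flag switches to adjusted p. Cross-dataset overlap of
DE family sets is a chi-square over a shared family universe with
direction concordance among the overlap, and the DE-family burden is
correlated (Pearson) with per-strain mortality.

## Evidence integration

One evidence row per (TE, hub gene) pair joins: proximity relation, hub
status and DEG direction, the single-TE flag, selection flags, cnc-site
counts, and open-peak overlap. A row is retained iff the gene is a hub,
the TE is the gene's single nearby TE (relaxable by flag), and
`evidence_count ≥ 1`, where evidence is selection ≠ none, cnc sites ≥ 1,
or an open peak. cnc sites count only for TEs near *non-downregulated*
hub genes — a binding site for a stress-response activator is
interpretable evidence only where expression went up or direction is
unknown. Removing any evidence source can only shrink the candidate set,
and every retained row is reachable by re-running the chain from the raw
inputs with the same `run_config()`.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the sequencing process. Defaults describe the study conditions: four
strains (mortality 0/0/15/25%), three replicates per condition, NB counts
with dispersion 0.05 and planted signed log2 fold changes in [1, 2] for
15% of genes per strain, TE placement with 40% of insertions inside or
< 1 kb from genes, genotype classes at 78.6% fixed / 11.9%
reference-only / rest polymorphic, ATAC open regions covering ~8% of the
genome at 20× open vs 1× closed filtered-fragment coverage, insert sizes
from a two-mode log-normal mixture (sub-nucleosomal ~60 bp, mono-
nucleosomal ~200 bp), planted PPI cliques over an Erdős–Rényi background,
and Poisson-planted motif copies in TE sequences (spurious consensus hits
are mutated away so manifest counts are exact). Genes near TEs are chosen
as DE with threefold weight, emulating TE-proximal regulatory effects, and
the number of DE TE families per strain scales with mortality so the
burden–sensitivity correlation is exercised. Open regions additionally
carry a lognormal intensity multiplier (sdlog 0.6, mean 1) because real
peak intensities span a wide dynamic range; setting
`open_intensity_sdlog = 0` reproduces the idealized uniform 20×/1×
contrast used in the recovery experiments.

Everything flows from one seed through fixed per-stage offsets, so stages
regenerate independently and a whole run is byte-identical across
invocations. Chosen problem sizes — two 400-kb chromosomes, 160 genes,
120 TEs — keep a full pipeline run around half a minute while leaving
every placement regime and every downstream test well-populated; the
heavier simulations behind the operating-characteristic tests use 2000
genes and 1000 IDR pairs.

What passing these tests does *not* show: the generator has constant
dispersion across genes (per-gene dispersion variation is an extension
point), no GC or mappability structure, no read-level errors or
multi-mapping (TE reads in real data are exactly the hard case), uniform
fragment placement within regions, and independent strains (no shared
population structure). Results on real data will degrade in proportion to
how much these matter.

## Numerical choices and degenerate inputs

Half-up rounding is used for printed percentages (base R rounds half to
even). All-zero genes get p = 1 and lfc = 0, flagged; a zero group mean
gets a half-count pseudo-offset, flagged. The BH step is the standard
step-up (note it is *not* idempotent on its own output). Chi-square tables
with a zero margin return NA with a warning rather than a fabricated p.
IDR needs ≥ 20 pairs and errors on fully tied scores. The quantile scaler
refuses constant input. Tie-breaks: summits take the leftmost maximum;
hub selection includes all boundary ties; reproducible-peak pairing keeps
the largest-overlap partner, then the leftmost.

## Reproducing

`run_pipeline(sim_config(rng_seed = <seed>))` executes the whole chain;
`scripts/acceptance.R` (repository root) recomputes the worked examples
and the operating characteristics from scratch and writes them as JSON.
The test suite (`tests/testthat/`) holds the per-module contracts, the
brute-force-oracle comparisons, and the end-to-end determinism check.
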