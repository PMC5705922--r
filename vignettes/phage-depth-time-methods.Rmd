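---
title: "Methods: depth and time structure of ocean phage assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth and time structure of ocean phage assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedepth)
```

## What this package computes

`phagedepth` analyzes assembled metagenomes from a stratified open-ocean
water column — seven depths from 25 to 1,000 m sampled repeatedly over more
than a year — to describe how dsDNA bacteriophage populations are organized
in space and time. It operates strictly downstream of assembly and
annotation: contig sequences, gene calls, alignment hit tables, domain score
tables and read-coverage profiles come in as plain tabular files, and the
package implements the analytical logic that turns them into curated viral
contigs, homology classes, abundance statistics, assemblage dendrograms,
lysogeny profiles and candidate novel genes.

Every cutoff lives in one place, `default_thresholds()`. All bit-score and
amino-acid-identity rules are strict (`>`); the contig length filter is
inclusive (`>=` 20 kbp). These conventions are enforced by boundary tests.

## Contig curation

Three predicates are applied in order by `run_cascade()`:

1. **Length.** Only contigs of at least 20 kbp are retained — the lower end
   of genome size in marine dsDNA phages — so the curated set represents
   near-complete genomes or large fragments.
2. **Structural gene.** A contig must carry at least one gene with even
   distant homology (domain bit score > 10) to one of eight phage structural
   families: terminase, portal, capsid, tail, base plate, spike, neck, head.
   Family labels are normalized case-insensitively through a small synonym
   table ("major head protein" counts as head), since annotation sources do
   not share an ontology.
3. **Contamination.** Genes are screened against single-copy prokaryotic
   marker families. A ribosomal marker hit above 50 bits removes the contig.
   Hits to recA and DNA helicase are tallied separately and tolerated:
   phages encode their own recombination and replication homologs, so these
   two families cannot distinguish a cell from a phage. The bit-50 cutoff
   for this screen is adopted from the catalog marker-profiling rule, as no
   separate value is fixed for this stage; it is configurable
   (`marker_bit`).

The report's completeness proxy is the observed fraction of distinct
non-ambiguous marker families. It is a deliberately simple stand-in for
lineage-aware genome completeness estimation, and is only ever compared
against planted truth in synthetic data, never interpreted on an absolute
scale.

## Homology classification

`classify_contigs()` implements a majority-gene average-amino-acid-identity
rule. For each reference genome *r*, let *f(r)* be the fraction of the
contig's genes whose **best** hit (maximal bit score; ties by higher AAI,
then lexicographic reference id) is to *r*, and *a(r)* the unweighted mean
AAI of those genes. The contig is assigned to *r* when *f(r)* > 0.5 and
*a(r)* > 60, with RefSeq genomes taking precedence over virome references,
then higher *f*, then higher *a*. No qualifying reference means novel.

Three open choices were resolved as follows, each behind a flag:

* The rule is evaluated per reference **genome**, never pooled per database:
  pooling would let chimeric similarity to many genomes masquerade as
  homology to one.
* All genes on the contig count in the denominator of *f(r)*, including
  genes with no hit (`denominator = "hit_genes"` switches this). A contig
  half of whose genes are unknown is at best half-explained by a reference.
* Mean AAI is unweighted by gene or alignment length — the plainest reading
  of "average amino acid identity".

Raising either cutoff can only move contigs toward novel, a monotonicity
property that the test suite checks, alongside exact agreement with an
exhaustive enumeration oracle on random small contigs.

## Coverage statistics

**Interquartile-mean coverage.** Conserved genes attract reads from related
phages and can inflate a contig's apparent depth locally. The statistic
sorts the per-base depths and averages only the positions whose 0-based rank
falls in `[ceiling(L/4), floor(3L/4))` — a deterministic rank slice with no
quantile interpolation, chosen because the quartile convention is otherwise
underdetermined. The implementation accepts run-length-encoded input and is
tested against a brute-force sort-and-slice oracle.

One numerical property deserves note. When a spike occupies the top
*fraction f* of positions, the middle half of the sorted vector covers
background quantiles `[(1/4)/(1-f), (3/4)/(1-f)]`, an asymmetric band whose
truncated mean is displaced by about `0.37 * sd` for *f* = 0.2. For
Poisson-distributed depth this is a relative displacement of `0.37/sqrt(λ)`:
about 8% at λ = 20 (the center of the simulated per-base coverage range),
about 11% at λ = 10. The statistic is thus robust to spikes in the sense
that matters — a 50-fold spike inflates the arithmetic mean ten-fold while
shifting the slice mean by under a tenth — but it is not unbiased, and the
unit tests assert its exact truncated-mean expectation rather than a vague
nearness to the base rate.

**Relative abundance** is the proportion of nucleotides mapped per contig,
normalized within each sample over the curated viral contigs only (not all
reads), so that proportions compare phage populations against each other.

**Mean-normalized variance.** Temporal variability within each depth bin is
the population-flavor variance (divisor *T*) of the relative-abundance
series divided by its mean — an index of dispersion. The 12 timepoints are
treated as the window of interest rather than a sample from a longer
process; `sample_variance = TRUE` switches the convention. Dividing by the
mean makes the statistic scale linearly rather than quadratically with
abundance, so abundant contigs do not dominate depth-bin comparisons.

**Depth groups.** The five-group binning (surface 25–75 m, DCM 125 m,
200 m, mesopelagic 500–1,000 m, sporadic) was a manual differential-coverage
judgment in the original setting; `assign_depth_groups()` provides an
automatic surrogate — peak depth of mean interquartile coverage, with
contigs whose home-bin dispersion exceeds a threshold labeled sporadic — and
honors a manual override table for exact control. The default sporadic
threshold is the 90th percentile of all contigs' dispersion values. It is
data-adaptive because no absolute dispersion scale is defined by the
problem; the percentile matches the planted sporadic fraction of the
simulated design (about one contig in ten), and recovery is validated
against planted truth, not against any real-data binning.

## Assemblage clustering

The gene catalog splits into a phage-specific set (viral best hit > 90%
AAI, minus photosystem genes at bit > 30, which cannot be attributed to
phage or host reliably) and a cell-associated complement. Each partition
yields a samples-by-samples Bray-Curtis matrix on relative abundances
(library size cancels), clustered by average linkage. Bray-Curtis and UPGMA
are standard steps and are delegated to `vegan::vegdist()` and
`stats::hclust()`; the test suite still verifies them against hand formulas
and an exhaustive UPGMA oracle, because the package's claims depend on them.
`compare_dendrograms()` summarizes the tanglegram comparison numerically:
Pearson correlation of cophenetic distances plus the fraction of sample
pairs co-clustered identically at a 7-group cut (one group per sampling
depth, configurable). These summaries are conventions of this package — the
original comparison was visual — so they are never checked against any
published number, only against planted structure.

## Life history

Two distinct marker rules coexist and are never conflated:

* **Catalog profile (strict):** curated-HMM domain bit > 50 assigns catalog
  genes to marker families (`detect_markers()`); a gene matching several
  families takes the highest-scoring one.
* **Per-contig flag (loose):** any gene at PFAM-style bit > 30 to integrase,
  CI repressor, Cro or excisionase flags the contig as prophage-carrying
  (`flag_prophage_contigs()`). Cro participates only here.

The lysogeny index is the summed coverage of prophage markers (integrase,
CI repressor, excisionase) over the summed coverage of capsids, per sample —
a sequencing-depth-invariant ratio. `fold_vs_surface()` divides each depth's
mean index by the mean over surface samples (25 and 75 m by default; the
"surface" set is configurable since it is not pinned down further). Because
integrase counts can be inflated by non-prophage integrases, per-family
indices are reported alongside the joint index, and a simulation scenario
with boosted integrase signal verifies that the excisionase- and
CI-specific indices are unaffected.

Copy numbers per cellular genome divide each marker family's summed
coverage by the arithmetic mean coverage of 10 universal single-copy
bacterial marker genes ("average coverage"; a geometric-mean option is
provided). Prophages being mostly nonreplicative, prophage-marker copy
numbers approximate prophages per genome.

## AMG detection

`find_candidates()` nominates a gene as a candidate novel phage gene when
(a) it carries a functional domain hit above 30 bits whose label is neither
in the shipped list of functions already reported from marine viromes
(`inst/extdata/known_amgs.txt`, editable data, matched case-insensitively)
nor itself a structural or marker family, and (b) its contig carries a
structural hit above 10 bits — the colocalization requirement that anchors
the call to a phage genome. An independent validator pass re-checks both
predicates gene by gene. Depth specificity labels the depth bins where the
host contig's relative abundance exceeds 0.001 in at least two samples;
exactly one bin, or two adjacent bins, counts as depth-specific. The
presence floor is a package convention (none is defined by the problem);
the in-silico nature of such calls means candidates are a screen, not a
functional assertion.

## The synthetic-data generator

`generate_fixture()` builds complete, seeded fixture sets so the entire
pipeline is testable offline. What it emulates:

* the 7-depth × 12-occasion design (83 casts: one depth/date combination is
  deliberately missing, as at sea);
* depth-stratified populations: each persistent contig has a home depth and
  a Gaussian-in-depth-index coverage profile (adjacent depths receive ~17%
  of peak); sporadic contigs bloom in 2–4 random timepoints at deep home
  depths and are otherwise absent;
* noise: per-base depth is Poisson around a per-contig, per-sample rate;
  the rate varies across samples as a mean-preserving lognormal with
  group-specific log-sd (0.3 at the surface rising to 0.7 in the
  mesopelagic — deep water is planted as more boom-and-bust). Rates below
  0.05 are treated as absence; this detection floor is a package convention
  for "virtually absent";
* a lysogeny gradient: the planted prophage:capsid coverage ratio is flat
  from 25 to 125 m, ramps at 200 m, and is `lysogeny_fold` (default 5)
  times the surface ratio from 500 m down;
* marker copy numbers that decline log-linearly with depth, a cellular
  single-copy coverage profile, contaminant contigs bearing ribosomal
  markers, conserved-gene coverage spikes (default 5% of length at 20×),
  and planted novel-function genes with decoys.

Per-base depth is simulated as piecewise-constant over 500-bp windows (one
Poisson draw per window, stored run-length encoded); gene lengths are fixed
at 900 bp and contig lengths are uniform on 20–108 kbp, matching the size
range the curated set is defined on. All draws flow from a single seed; the
same seed reproduces byte-identical files.

What it does **not** emulate: read-level data (no FASTQ, no mapping),
sequence-realistic protein content (hit tables and domain scores are
planted, not computed from sequence), assembly artifacts, chimerism, or
strain-level microdiversity. Passing recovery tests therefore demonstrates
that the analytical logic is correct and well-calibrated under the stated
noise model — not that the pipeline is robust to assembly or annotation
error in real data.

The worked-example fixtures (`fixture_curation_counts()`,
`fixture_catalog_counts()`, `fixture_amg_counts()`,
`fixture_classification_counts()`) rebuild, at full printed size, filter
inputs whose outcomes are fixed by arithmetic (e.g. 142 length-passing
contigs of which 13 lack structural hits leave 129); they exercise the
filters at scale without any stochastic recovery question.

## Problem sizes and determinism in the test suite

The recovery suites run 20 seeds per scenario at reduced problem sizes
chosen so each suite completes in seconds: default 60-contig fixtures for
depth-group recovery and the dispersion gradient; 6-contig fixtures (the
catalog, which drives these statistics, is unaffected by contig count) with
4,000-bp coverage windows for lysogeny-fold and copy-number recovery; and
5-contig fixtures for the clustering scenarios. Oracle-equivalence suites
use 500–1,000 random cases. Published-scale quantities (83 samples, the
7-depth design, all thresholds, noise levels, the planted fold of 5) are
never scaled down. Every stochastic test fixes its seeds, and
`run_all()` output files are hash-compared across reruns.

## Known limitations

* The sporadic/persistent boundary is a percentile rule on a noisy
  dispersion estimate from 12 timepoints; contigs near the boundary can
  swap labels between seeds (observed accuracy ~94% at default noise).
* The interquartile-mean estimator carries the truncated-mean displacement
  described above; comparisons across contigs with similar spike structure
  are unaffected, absolute coverage values are slightly high.
* `classify_contigs()` recomputes best hits per call; for very large hit
  tables, compute `best_hit_per_gene()` once and reuse.
* The completeness proxy is not a calibrated completeness estimate.
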