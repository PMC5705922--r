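# phagedepth

Post-assembly analysis of double-stranded DNA bacteriophage populations
across a stratified open-ocean water column, for microbial ecologists and
viral metagenomicists working with depth-resolved metagenome time series.
Starting from assembled contigs, gene calls, homology hit tables, domain
scores and read-coverage profiles, the package answers: which contigs are
high-confidence phage genomes, how do they relate to known viruses, how are
phage populations structured over depth and time, do phage and host
assemblages co-vary, how does the prevalence of lysogeny change down the
water column, and which phage genes carry previously unreported functions?

Everything runs on seeded synthetic fixtures that emulate a 7-depth
(25–1,000 m) × 12-occasion sampling design, so the full pipeline is testable
without downloading a single read.

## The statistics at the core

* **Curation cascade** — retain contigs ≥ 20 kbp, require a structural-gene
  hit (bit > 10 to terminase, portal, capsid, tail, base plate, spike, neck
  or head), remove contigs with ribosomal single-copy marker hits (bit > 50).
* **Homology classification** — contig → reference genome *r* when
  *f(r)* > 0.5 and *ā(r)* > 60, where *f(r)* is the fraction of genes
  best-hitting *r* and *ā(r)* their mean amino-acid identity; otherwise
  novel.
* **Interquartile-mean coverage** — mean per-base depth over the rank slice
  `[⌈L/4⌉, ⌊3L/4⌋)` of the sorted depth vector, robust to conserved-gene
  coverage spikes.
* **Mean-normalized variance** — Var(x)/mean(x) of a contig's
  relative-abundance time series within a depth bin (index of dispersion,
  population variance), the temporal-variability statistic.
* **Assemblage clustering** — Bray-Curtis distances
  d(i,j) = Σ|x<sub>gi</sub>−x<sub>gj</sub>| / Σ(x<sub>gi</sub>+x<sub>gj</sub>)
  between samples on phage-specific vs cell-associated gene partitions,
  UPGMA trees, cophenetic comparison.
* **Lysogeny index** — Σ coverage(integrase, CI repressor, excisionase) /
  Σ coverage(capsid) per sample, profiled as fold change against the
  surface (25–75 m) mean; marker copy numbers per cellular genome via
  normalization to 10 universal single-copy genes.
* **AMG detection** — genes with novel-function domain hits (bit > 30, label
  not in the known marine-phage list) colocated on contigs with structural
  genes (bit > 10), plus depth-specificity labels.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
fixture; each is a thin driver over exported functions.

```sh
Rscript analysis/01_simulate.R     # write the fixture under results/fixture
Rscript analysis/02_curate.R
Rscript analysis/04_abundance_groups.R
Rscript analysis/06_life_history.R
```

`02_curate.R` prints the cascade:

```
contig curation cascade:
  length           62 ->    62 retained (0 removed: length < 20000 bp)
  structural       62 ->    62 retained (0 removed: no structural-family hit > 10 bits)
  contamination    62 ->    60 retained (2 removed: ribosomal single-copy marker hit)
  marker-hit genes: 2 (0 phage-ambiguous) of 3908 genes; completeness proxy 0.100
```

Both planted cellular contaminants are caught by the ribosomal screen (the
default fixture's contigs are all ≥ 20 kbp and all carry structural genes,
so the first two stages pass everything). `04_abundance_groups.R` then
recovers the planted depth structure and the depth gradient in temporal
variability:

```
Depth-group sizes (automatic surrogate for manual binning):
        DCM mesopelagic    sporadic     surface two_hundred
         10          18           6          15          11
Agreement with planted groups: 93.3%
Mean dispersion at 25 m: 0.005; at 1,000 m: 0.056 (deep water is more temporally variable)
```

i.e. 93% of contigs land in their planted group, and mesopelagic phage
abundances are an order of magnitude more dispersed through time than
surface ones. `06_life_history.R` profiles the planted lysogeny gradient:

```
Lysogeny fold vs surface mean, by depth:
 depth_m fold
      25 0.99
      75 1.01
     125 1.07
     200 3.35
     500 4.98
     770 5.25
    1000 5.12
Mesopelagic fold estimate 5.30 vs planted fold 5.
```

The prophage:capsid index is flat through the DCM, ramps at 200 m, and sits
about five-fold above the surface mean in the mesopelagic — recovering the
planted fold of 5 to within a few percent.

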