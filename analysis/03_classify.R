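#!/usr/bin/env Rscript
# Stage 3: homology classification of curated contigs.
#
# A contig is assigned to a reference genome when strictly more than half of
# its genes best-hit that reference at a mean amino-acid identity strictly
# above 60%; RefSeq genomes take precedence over virome references, and
# contigs with no qualifying reference are novel. Per-sample category
# proportions are normalized by total nucleotides mapped to curated contigs.

library(phagedepth)

fixture <- "results/fixture"
genes <- read_genes_gff(file.path(fixture, "genes.gff"))
ref_hits <- read_ref_hits(file.path(fixture, "ref_hits.tsv"))
samples <- read_samples(file.path(fixture, "samples.tsv"))
coverage <- read_coverage(file.path(fixture, "coverage.tsv"))
retained <- readLines("results/curation/retained_contigs.txt")

cls <- classify_contigs(genes, ref_hits, retained)
cat("Homology categories among", nrow(cls), "curated contigs:\n")
print(table(cls$category))

summ <- coverage_summaries(coverage[coverage$contig_id %in% retained, ])
nuc <- summary_matrix(summ, "nucleotides_mapped", retained, samples$sample_id)
props <- category_proportions(cls, nuc, samples)

dir.create("results/classification", showWarnings = FALSE, recursive = TRUE)
write.table(cls, "results/classification/classifications.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(props$per_depth, "results/classification/proportions_by_depth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nMean novel proportion of mapped nucleotides by depth:\n")
nv <- props$per_depth[props$per_depth$category == "novel", ]
print(data.frame(depth_m = nv$depth_m, novel = round(nv$mean_proportion, 3),
                 se = signif(nv$se, 2)), row.names = FALSE)
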