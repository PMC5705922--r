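#!/usr/bin/env Rscript
# Stage 6: viral life history down the water column.
#
# Marker genes are detected in the catalog at curated-HMM bit > 50. The
# lysogeny index is the summed prophage-marker coverage (integrase, CI
# repressor, excisionase) over summed capsid coverage; its fold change
# against the surface (25-75 m) mean profiles the prevalence of lysogeny
# with depth. Marker copy numbers per cellular genome normalize by the mean
# coverage of 10 universal single-copy bacterial genes. Curated contigs are
# flagged as prophage-carrying by the looser PFAM-style bit > 30 rule
# (integrase, CI repressor, Cro, excisionase).

library(phagedepth)

fixture <- "results/fixture"
domain_hits <- read_domain_hits(file.path(fixture, "domain_hits.tsv"))
gcov <- read_gene_coverage(file.path(fixture, "gene_coverage.tsv"))
sc <- read_single_copy(file.path(fixture, "single_copy.tsv"))
samples <- read_samples(file.path(fixture, "samples.tsv"))
genes <- read_genes_gff(file.path(fixture, "genes.gff"))
retained <- readLines("results/curation/retained_contigs.txt")

asn <- detect_markers(domain_hits)
cat("Detected marker genes per family:\n")
print(table(asn$family))

idx <- lysogeny_index(asn, gcov)
prof <- fold_vs_surface(idx, samples)
cat("\nLysogeny fold vs surface mean, by depth:\n")
print(data.frame(depth_m = prof$depth_m,
                 fold = round(prof$fold_vs_surface, 2)), row.names = FALSE)

cn <- copy_number_per_genome(asn, gcov, sc)
d_of <- samples$depth_m[match(cn$sample_id, samples$sample_id)]
cn_depth <- tapply(cn$copy_number, list(cn$family, d_of), mean)
cat("\nMarker copies per cellular genome (depth means):\n")
print(round(cn_depth, 3))

flags <- flag_prophage_contigs(retained, genes, domain_hits)
cat(sprintf("\n%d of %d curated contigs carry a prophage marker flag.\n",
            sum(flags), length(flags)))

dir.create("results/life_history", showWarnings = FALSE, recursive = TRUE)
write.table(merge(idx, samples[, c("sample_id", "depth_m")]),
            "results/life_history/lysogeny_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof, "results/life_history/lysogeny_fold_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cn, "results/life_history/copy_numbers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(contig_id = names(flags), prophage_flagged = flags),
            "results/life_history/prophage_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(fixture, "truth.json"),
                             simplifyVector = TRUE)
est <- mean(prof$fold_vs_surface[prof$depth_m >= 500])
cat(sprintf("\nMesopelagic fold estimate %.2f vs planted fold %g.\n",
            est, truth$lysogeny_fold))
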