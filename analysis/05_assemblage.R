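#!/usr/bin/env Rscript
# Stage 5: assemblage clustering of the gene catalog.
#
# The catalog splits into phage-specific genes (viral best hit > 90% AAI,
# photosystem genes removed at bit > 30) and cell-associated genes. Samples
# are clustered independently on each partition (Bray-Curtis on relative
# abundance, average linkage) and the two dendrograms are compared.

library(phagedepth)

fixture <- "results/fixture"
catalog <- read_gene_catalog(file.path(fixture, "gene_catalog.tsv"))
gcov <- read_gene_coverage(file.path(fixture, "gene_coverage.tsv"))
samples <- read_samples(file.path(fixture, "samples.tsv"))

part <- partition_gene_catalog(catalog)
cat(sprintf("Catalog: %d genes -> %d phage-specific, %d cell-associated\n",
            nrow(catalog), length(part$phage_genes), length(part$cell_genes)))

ab <- gene_abundance_matrix(gcov)
t_ph <- average_linkage(
  bray_curtis_matrix(ab[rownames(ab) %in% part$phage_genes, , drop = FALSE]))
t_ce <- average_linkage(
  bray_curtis_matrix(ab[rownames(ab) %in% part$cell_genes, , drop = FALSE]))
cmp <- compare_dendrograms(t_ph, t_ce, k = 7)

dir.create("results/assemblage", showWarnings = FALSE, recursive = TRUE)
ape::write.tree(ape::as.phylo(t_ph), "results/assemblage/phage_tree.nwk")
ape::write.tree(ape::as.phylo(t_ce), "results/assemblage/cell_tree.nwk")
jsonlite::write_json(cmp, "results/assemblage/tree_comparison.json",
                     auto_unbox = TRUE, digits = NA)

cut7 <- stats::cutree(t_ph, 7)
depth <- samples$depth_m[match(names(cut7), samples$sample_id)]
cat(sprintf("Phage-gene tree vs cell-gene tree: cophenetic r = %.3f, ",
            cmp$cophenetic_correlation),
    sprintf("7-cut pair agreement = %.3f\n", cmp$pair_agreement))
cat("Phage-tree 7-group cut against sampling depth:\n")
print(table(cluster = cut7, depth_m = depth))

# labeled taxon-group panels (bubble-plot style summary)
tg <- taxon_group_abundance(catalog, ab)
by_depth <- sapply(sort(unique(depth)), function(d) {
  rowMeans(tg[, samples$sample_id[samples$depth_m == d], drop = FALSE])
})
colnames(by_depth) <- sort(unique(depth))
write.table(data.frame(taxon = rownames(by_depth), round(by_depth, 5),
                       check.names = FALSE),
            "results/assemblage/taxon_groups_by_depth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
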