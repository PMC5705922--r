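#!/usr/bin/env Rscript
# Stage 7: candidate novel phage genes / auxiliary metabolic genes.
#
# A gene qualifies when it carries a functional domain hit > 30 bits to a
# label absent from the known marine-phage function list, on a contig that
# also carries a structural-family hit > 10 bits. Each candidate's host
# contig is then profiled for depth specificity.

library(phagedepth)

fixture <- "results/fixture"
genes <- read_genes_gff(file.path(fixture, "genes.gff"))
domain_hits <- read_domain_hits(file.path(fixture, "domain_hits.tsv"))
samples <- read_samples(file.path(fixture, "samples.tsv"))
coverage <- read_coverage(file.path(fixture, "coverage.tsv"))
retained <- readLines("results/curation/retained_contigs.txt")

cand <- find_candidates(genes, domain_hits)
validate_candidates(cand, genes, domain_hits)
cat(sprintf("%d candidate novel genes pass both predicates.\n", nrow(cand)))

summ <- coverage_summaries(coverage[coverage$contig_id %in% retained, ])
nuc <- summary_matrix(summ, "nucleotides_mapped", retained, samples$sample_id)
ab <- relative_abundance_matrix(nuc)

spec <- lapply(cand$contig_id, function(cid) {
  if (!cid %in% rownames(ab)) return(list(depth_labels = NA, specific = NA))
  depth_specificity(cid, ab, samples)
})
cand$depth_labels <- vapply(spec, function(s)
  paste(s$depth_labels, collapse = ","), character(1))
cand$depth_specific <- vapply(spec, function(s)
  isTRUE(s$specific), logical(1))

dir.create("results/amg", showWarnings = FALSE, recursive = TRUE)
write.table(cand, "results/amg/amg_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(cand[, c("gene_id", "function_label", "pfam_bit", "structural_family",
               "depth_labels", "depth_specific")], row.names = FALSE)

truth <- jsonlite::read_json(file.path(fixture, "truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("\nRecovered %d of %d planted candidate genes.\n",
            length(intersect(cand$gene_id, truth$amg_gene_ids)),
            length(truth$amg_gene_ids)))
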