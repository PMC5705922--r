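#!/usr/bin/env Rscript
# Stage 2: contig quality-control cascade.
#
# Length filter (>= 20 kbp, inclusive), then the structural-gene requirement
# (any of terminase/portal/capsid/tail/base plate/spike/neck/head at bit > 10),
# then the cellular-contamination screen (ribosomal single-copy markers at
# bit > 50 remove a contig; recA / DNA helicase hits are tallied as
# phage-ambiguous but tolerated).

library(phagedepth)

fixture <- "results/fixture"
contigs <- read_contigs_fasta(file.path(fixture, "contigs.fasta"))
genes <- read_genes_gff(file.path(fixture, "genes.gff"))
domain_hits <- read_domain_hits(file.path(fixture, "domain_hits.tsv"))

out <- run_cascade(contigs, genes, domain_hits)
print(out$report)

dir.create("results/curation", showWarnings = FALSE, recursive = TRUE)
writeLines(out$retained$contig_id, "results/curation/retained_contigs.txt")
jsonlite::write_json(phagedepth:::curation_report_as_list(out$report),
                     "results/curation/curation_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

truth <- jsonlite::read_json(file.path(fixture, "truth.json"),
                             simplifyVector = TRUE)
removed_cell <- setdiff(truth$contaminant_ids, out$retained$contig_id)
cat(sprintf("\n%d of %d planted cellular contigs removed by the screen.\n",
            length(removed_cell), length(truth$contaminant_ids)))
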