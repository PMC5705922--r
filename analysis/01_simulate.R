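#!/usr/bin/env Rscript
# Stage 1: build the synthetic study fixture.
#
# Emulates the water-column sampling design — 7 depths (25 to 1,000 m) on 12
# occasions (83 casts) — with depth-stratified phage populations, a planted
# 5-fold lysogeny gradient below the DCM, cellular contaminant contigs and
# conserved-gene coverage spikes. Everything downstream reads these files;
# the planted truth stays in truth.json, which no pipeline stage opens.

library(phagedepth)

cfg <- sim_config(seed = 1)
dir <- "results/fixture"
make_fixture(cfg, dir)

fx <- generate_fixture(cfg, sequences = FALSE)
cat("Fixture written to", dir, "\n")
print(fx)
cat("\nPlanted depth-group composition:\n")
print(table(fx$truth$contigs$group))
cat("\nPlanted prophage:capsid ratio by depth (surface ratio",
    cfg$surface_ratio, "):\n")
print(round(unlist(fx$truth$ratio_by_depth), 3))
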