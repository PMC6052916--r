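#!/usr/bin/env Rscript

# Stage 1: build the synthetic study system.
#
# Simulates eight classes of ncRNA references (rRNA, tRNA, miRNA hairpins,
# snRNA, snoRNA, YRNA, mitochondrial tRNA/rRNA) and a candidate piRNA
# database of 1,000 genuine piRNAs (5'U bias 0.866, position-10 A bias 0.3,
# 26-31 nt) plus 40 planted reference-derived fragments (26-35 nt,
# unmutated), with log-normal RPM abundances and a full ground-truth table.
# Everything is written under results/simulated/.

suppressMessages(library(pirnascreen))

SEED <- 2026L
out_dir <- "results/simulated"

cfg <- synthetic_config(seed = SEED, n_genuine = 1000, n_contaminants = 40)
sim <- simulate_dataset(cfg, out_dir)

message(sprintf("references: %d classes, %d sequences",
                length(sim$refsets),
                sum(vapply(sim$refsets, function(r) length(r$seq), integer(1)))))
message(sprintf("database: %d sequences (%d planted contaminants)",
                nrow(sim$queries), sum(sim$truth$is_contaminant)))
message(sprintf("contaminant classes: %s",
                paste(sort(unique(stats::na.omit(sim$truth$source_class))),
                      collapse = ", ")))
message("wrote ", out_dir, "/ (FASTA references, database, abundances, truth, config)")
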