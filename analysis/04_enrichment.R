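#!/usr/bin/env Rscript

# Stage 4: enrichment scores of a fragment-heavy query set.
#
# Emulates comparing a reported somatic/extracellular piRNA list against the
# database it was called from: the query is a contaminant-enriched subset
# (40 fragments + 10 genuine), the reference is the full simulated database.
# ES = (query B/A) / (reference B/A) for both partition predicates, by
# sequence count and by summed RPM; the count ES is checked against the
# closed form from the truth table.

suppressMessages(library(pirnascreen))

sim_dir <- "results/simulated"
out_dir <- "results/enrichment"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

qs <- read_abundance_table(file.path(sim_dir, "abundances.tsv"))
truth <- utils::read.delim(file.path(sim_dir, "truth.tsv"))
classes <- sub("^refs_(.*)\\.fasta$", "\\1",
               list.files(sim_dir, pattern = "^refs_.*\\.fasta$"))
refs <- lapply(classes, function(cls)
  read_reference_fasta(file.path(sim_dir, sprintf("refs_%s.fasta", cls)), cls))

ann <- annotate_queries(qs, refs, match_params(max_mismatches = 0))
truthc <- truth$id[truth$is_contaminant]
pick <- c(truthc[1:40], truth$id[!truth$is_contaminant][1:10])
sub <- qs[qs$id %in% pick, ]

tab <- run_enrichment(qs, sub, ann, ann[ann$id %in% pick, ], use_weights = TRUE)
print(tab)

qB <- sum(pick %in% truthc); qA <- length(pick) - qB
rB <- length(truthc); rA <- nrow(qs) - rB
message(sprintf("truth-table closed form (ncRNA, count): %.1f",
                (qB / qA) / (rB / rA)))
pv <- overlap_pvalue(nrow(qs), rB, length(pick), qB)
message(sprintf("hypergeometric overlap: P(X >= %d) = %.3g", qB, pv))

utils::write.table(tab, file.path(out_dir, "enrichment_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out_dir, "/enrichment_scores.tsv")
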