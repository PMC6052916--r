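#!/usr/bin/env Rscript

# Stage 2: screen the simulated database against the reference classes.
#
# Runs the seed-indexed ungapped matcher at MM = 0 and MM = 1 (19-nt seed,
# >= 94% coverage) and checks recall/precision against the ground truth:
# with unmutated plants and rejection-sampled genuine sequences, MM = 0
# recovers every contaminant and nothing else.

suppressMessages(library(pirnascreen))

sim_dir <- "results/simulated"
out_dir <- "results/screen"
if (!file.exists(file.path(sim_dir, "abundances.tsv")))
  stop("run analysis/01_simulate.R first")

qs <- read_abundance_table(file.path(sim_dir, "abundances.tsv"))
classes <- sub("^refs_(.*)\\.fasta$", "\\1",
               list.files(sim_dir, pattern = "^refs_.*\\.fasta$"))
refs <- lapply(classes, function(cls)
  read_reference_fasta(file.path(sim_dir, sprintf("refs_%s.fasta", cls)), cls))
truth <- utils::read.delim(file.path(sim_dir, "truth.tsv"))

res <- run_screen(qs, refs, mm = c(0L, 1L), out_dir = out_dir)
print(res$table)

truthc <- truth$id[truth$is_contaminant]
found0 <- res$screens$MM0$best_hits$query_id
message(sprintf("MM=0 recall: %d/%d planted contaminants, %d false positives",
                sum(found0 %in% truthc), length(truthc),
                sum(!found0 %in% truthc)))
cls_ok <- res$screens$MM0$best_hits$ncrna_class ==
  truth$source_class[match(found0, truth$id)]
message(sprintf("source-class attribution correct for %d/%d hits",
                sum(cls_ok), length(cls_ok)))
message("wrote ", out_dir, "/ (overlap_table.tsv, best_hits_MM*.tsv)")
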