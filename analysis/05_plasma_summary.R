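#!/usr/bin/env Rscript

# Stage 5: contamination of the bundled plasma piRNA list.
#
# Uses the packaged table of the 25 piRNAs reported in human blood plasma at
# >= 10 RPM (mean across 40 individuals) with their published alternative
# annotations. Fragments of YRNAs, mitochondrial tRNA/rRNA and cytosolic
# tRNA/rRNA dominate; piRNA-cluster and CDS labels count as non-ncRNA.

suppressMessages(library(pirnascreen))

out_dir <- "results/plasma"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ann <- plasma_annotations()
rep <- run_contamination_report(ann, cutoffs = c(10, 50))
print(rep$summaries)
for (ct in c(10, 50)) print(contamination_summary(ann, ct))

p5 <- partition_sequences(load_plasma_pirnas(), "starts_with_U")
message(sprintf("5' base split: %d start with U, %d do not",
                p5$count_A, p5$count_B))
message(sprintf("top class among fragments: %s",
                names(sort(table(ann$best_class), decreasing = TRUE))[1]))

utils::write.table(rep$summaries, file.path(out_dir, "contamination_summaries.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_annotation_table(ann, file.path(out_dir, "plasma_annotations.tsv"))
write_composition_table(rep$composition_ncRNA,
                        file.path(out_dir, "composition_fragments.tsv"))
message("wrote ", out_dir, "/")
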