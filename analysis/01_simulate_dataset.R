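#!/usr/bin/env Rscript

# Step 1: generate the ground-truthed synthetic proximity-labeling data set
# used throughout the analysis, and write its on-disk representation
# (quant table, control lists, annotations, truth) under results/data/.
#
# The generator emulates a 2 bait x 2 control replicate-cross TMT design:
# 10% of proteins are truly labeled (log2 ratios centered at 2, SD 0.5,
# with a shared per-bait-replicate effect), the rest are zero-centered
# background (SD 0.5), with 5% missing cells.

suppressPackageStartupMessages(library(proxisec))

seed <- 20260926 %% 2147483647
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- sim_params(seed = seed)
sim <- simulate_dataset(params)

write_quant_table(sim$table, file.path(out, "quant.tsv"))
writeLines(sim$lists$pc, file.path(out, "pc_list.txt"))
writeLines(sim$lists$nc, file.path(out, "nc_list.txt"))
write_annotations(sim$annotations, file.path(out, "annotations.tsv"))
utils::write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cmp <- sim$table$design$comparisons
writeLines(c(paste0("dataset_name: ", sim$table$design$dataset_name),
             "species: SYNTH", "comparisons:",
             unlist(lapply(seq_len(nrow(cmp)), function(i) {
               c(paste0("- comparison_id: \"", cmp$comparison_id[i], "\""),
                 paste0("  numerator_label: ", cmp$numerator_label[i]),
                 paste0("  denominator_label: ", cmp$denominator_label[i]))
             }))),
           file.path(out, "design.yaml"))

n_lab <- sum(sim$truth$is_labeled)
message("simulated ", n_proteins(sim$table), " proteins (", n_lab,
        " truly labeled) over ", nrow(cmp), " comparisons")
message("control lists: ", length(sim$lists$pc), " PC / ",
        length(sim$lists$nc), " NC")
message("wrote inputs to ", out)
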