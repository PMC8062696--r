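#!/usr/bin/env Rscript

# Step 4: downstream statistics on the scored table -- signal-peptide
# enrichment across score strata (chi-square, score 0 vs score >= k),
# abundance shift between background and hits (Kruskal-Wallis with
# Benjamini-Krieger-Yekutieli two-stage FDR), and the overlap of two
# independent hit calls within the quantified universe.

suppressPackageStartupMessages(library(proxisec))

data_dir <- "results/data"
design <- read_design(file.path(data_dir, "design.yaml"))
tab <- read_quant_table(file.path(data_dir, "quant.tsv"), design)
tab <- median_normalize(filter_quant_table(tab))
cal <- utils::read.delim("results/calibration.tsv")
thr <- stats::setNames(cal$threshold, cal$comparison_id)
sc <- score_table(tab, thr)
ann <- load_annotations(file.path(data_dir, "annotations.tsv"))

sp <- stats::setNames(ann$signal_peptide, ann$protein_id)
sp_tab <- do.call(rbind, lapply(1:4, function(k) {
  res <- flag_enrichment_test(sc, sp, k = k, test = "chi_square")
  frac0 <- res$table["score0", "yes"] / sum(res$table["score0", ])
  frack <- res$table["scoreK", "yes"] / sum(res$table["scoreK", ])
  data.frame(k = k, frac_sp_score0 = frac0, frac_sp_scoreK = frack,
             statistic = res$statistic, p = res$p_value)
}))
utils::write.table(sp_tab, "results/stats_signal_peptide.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("signal-peptide fraction, background vs hits (chi-square):")
print(sp_tab, digits = 3)

ab <- stats::setNames(ann$abundance_ppm, ann$protein_id)
ab_tab <- abundance_shift_test(sc, ab, strata = 1:4)
utils::write.table(ab_tab, "results/stats_abundance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("abundance shift background vs hits (Kruskal-Wallis + BKY):")
print(ab_tab, digits = 3)

# overlap of hits called on the two bait replicates separately, within the
# universe of all quantified proteins
ids <- comparison_ids(design)
rep1 <- ids[startsWith(ids, "bait1")]
rep2 <- ids[startsWith(ids, "bait2")]
sub_design <- function(keep) {
  d <- tab$design
  d$comparisons <- d$comparisons[d$comparisons$comparison_id %in% keep, ]
  d
}
score_subset <- function(keep) {
  t2 <- tab
  t2$design <- sub_design(keep)
  t2$ratios <- t2$ratios[, keep, drop = FALSE]
  call_hits(score_table(t2, thr[keep]), 1)
}
h1 <- score_subset(rep1)
h2 <- score_subset(rep2)
ov <- overlap_test(h1, h2, tab$meta$protein_id)
message(sprintf(
  "replicate hit overlap: %d proteins, fold %.1f over expectation, p = %.3g",
  ov$overlap, ov$fold, ov$p))
utils::write.table(
  data.frame(set_a = length(h1), set_b = length(h2),
             universe = n_proteins(tab), overlap = ov$overlap,
             fold = ov$fold, p = ov$p),
  "results/stats_replicate_overlap.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("wrote results/stats_*.tsv")
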