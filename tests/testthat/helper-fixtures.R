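# In-code fixtures: small designs and quant tables built programmatically.

toy_design <- function(n_comp = 4L) {
  if (n_comp == 4L) {
    cross_design("toy", 2L, 2L)
  } else {
    comparison_design("toy", data.frame(
      comparison_id = paste0("c", seq_len(n_comp)),
      numerator_label = paste0("b", seq_len(n_comp)),
      denominator_label = paste0("w", seq_len(n_comp))))
  }
}

# build a quant_table from a ratio matrix (rows = proteins)
toy_quant_table <- function(ratios, design = NULL, protein_ids = NULL,
                            is_decoy = FALSE, is_contaminant = FALSE,
                            channels = NULL) {
  ratios <- as.matrix(ratios)
  if (is.null(design)) design <- toy_design(ncol(ratios))
  colnames(ratios) <- comparison_ids(design)
  n <- nrow(ratios)
  if (is.null(protein_ids)) protein_ids <- sprintf("P%03d", seq_len(n))
  meta <- data.frame(protein_id = protein_ids,
                     gene_symbol = paste0("g", seq_len(n)),
                     is_decoy = rep_len(is_decoy, n),
                     is_contaminant = rep_len(is_contaminant, n),
                     unique_peptides = NA_integer_,
                     total_intensity = NA_real_,
                     stringsAsFactors = FALSE)
  proxisec:::new_quant_table(design, meta, ratios, channels = channels)
}

# minimal score_table built directly from a score vector
make_scores <- function(score, protein_id = sprintf("P%03d", seq_along(score))) {
  structure(
    data.frame(protein_id = protein_id, gene_symbol = "",
               score = as.integer(score),
               n_observed = 4L, mean_log2 = 0, sem_log2 = 0,
               hit_class = ifelse(score >= 1, "hit", "background"),
               stringsAsFactors = FALSE),
    n_comparisons = 4L, min_score = 1L,
    class = c("score_table", "data.frame"))
}

# write a quant table TSV by hand (text fixture generated at test time)
write_toy_tsv <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}
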