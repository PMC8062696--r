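#' Per-protein enrichment score
#'
#' The enrichment score (E-S) of a protein is the number of replicate
#' comparisons in which its log2 bait/control TMT ratio meets or exceeds
#' that comparison's calibrated threshold. With a 2 x 2 replicate cross the
#' maximum is 4; with 3 x 3 it is 9. A score of 0 means background; higher
#' scores mean higher-confidence hits. Missing ratios never count towards
#' the score; the number of observed (non-missing) comparisons is returned
#' alongside so callers can filter on completeness.
#'
#' @param ratios Named numeric vector of log2 ratios keyed by comparison id
#'   (`NA` = missing).
#' @param thresholds Named numeric vector of thresholds covering every
#'   comparison in `ratios`.
#' @param strict If `TRUE`, count only strictly-above ratios instead of the
#'   default inclusive (at-or-above) convention.
#' @return A list with `score` and `n_observed` integers.
#' @export
enrichment_score <- function(ratios, thresholds, strict = FALSE) {
  absent <- setdiff(names(ratios), names(thresholds))
  if (length(absent) > 0L) {
    stop("no threshold for comparison(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  thr <- thresholds[names(ratios)]
  hit <- if (strict) ratios > thr else ratios >= thr
  list(score = sum(hit, na.rm = TRUE),
       n_observed = sum(!is.na(ratios)))
}

#' Mean and SEM of a protein's observed log2 ratios
#'
#' @param ratios Numeric vector of observed log2 ratios (no `NA`).
#' @return A list with `mean` and `sem` (sample SD / sqrt(n); `NA` when a
#'   single ratio is supplied).
#' @export
summarize_protein <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) {
    stop("cannot summarize a protein with no observed ratios", call. = FALSE)
  }
  n <- length(ratios)
  list(mean = mean(ratios),
       sem = if (n > 1L) stats::sd(ratios) / sqrt(n) else NA_real_)
}

#' Score every protein of a quant table
#'
#' Applies [enrichment_score()] and [summarize_protein()] across a filtered,
#' normalized table, producing the per-protein hit table.
#'
#' @param table A `quant_table`.
#' @param thresholds Named numeric vector keyed by comparison id (e.g. from
#'   [calibration_thresholds()]); must cover the whole design and contain no
#'   `NA`.
#' @param min_score Minimum E-S for `hit_class = "hit"` (default 1).
#' @param strict Passed to [enrichment_score()].
#' @return A `score_table` data frame with columns `protein_id`,
#'   `gene_symbol`, `score`, `n_observed`, `mean_log2`, `sem_log2`,
#'   `hit_class`, sorted by (score desc, mean_log2 desc, protein_id asc).
#' @export
score_table <- function(table, thresholds, min_score = 1L, strict = FALSE) {
  stopifnot(inherits(table, "quant_table"), min_score >= 1L)
  ids <- comparison_ids(table$design)
  absent <- setdiff(ids, names(thresholds))
  if (length(absent) > 0L) {
    stop("thresholds missing for comparison(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyNA(thresholds[ids])) {
    stop("thresholds contain NA; calibrate or supply manual values first",
         call. = FALSE)
  }
  thr <- thresholds[ids]
  r <- table$ratios[, ids, drop = FALSE]
  cmp <- sweep(r, 2L, thr, FUN = if (strict) ">" else ">=")
  score <- as.integer(rowSums(cmp, na.rm = TRUE))
  n_obs <- as.integer(rowSums(!is.na(r)))
  mean_log2 <- ifelse(n_obs > 0, rowMeans(r, na.rm = TRUE), NA_real_)
  sem_log2 <- apply(r, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(
    protein_id = table$meta$protein_id,
    gene_symbol = table$meta$gene_symbol,
    score = score, n_observed = n_obs,
    mean_log2 = mean_log2, sem_log2 = sem_log2,
    hit_class = ifelse(score >= min_score, "hit", "background"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, -xtfrm(out$mean_log2), out$protein_id), ]
  rownames(out) <- NULL
  attr(out, "min_score") <- as.integer(min_score)
  attr(out, "n_comparisons") <- length(ids)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Call hits from a score table
#'
#' @param scores A [score_table()] (or data frame with `protein_id` and
#'   `score`).
#' @param min_score Minimum E-S to call a hit (`>= 1`).
#' @return Character vector of hit protein ids.
#' @export
call_hits <- function(scores, min_score = 1L) {
  stopifnot(min_score >= 1L)
  scores$protein_id[scores$score >= min_score]
}

#' Collapse a score table to gene level
#'
#' Optional post-processing that keeps, for each non-empty gene symbol, the
#' protein record with the highest (score, mean_log2). Proteins without a
#' gene symbol are retained as-is.
#'
#' @param scores A [score_table()].
#' @return The collapsed score table.
#' @export
collapse_to_genes <- function(scores) {
  has_gene <- nzchar(scores$gene_symbol) & !is.na(scores$gene_symbol)
  with_gene <- scores[has_gene, , drop = FALSE]
  # table is already sorted best-first, so the first row per gene wins
  keep <- !duplicated(with_gene$gene_symbol)
  out <- rbind(with_gene[keep, , drop = FALSE],
               scores[!has_gene, , drop = FALSE])
  out <- out[order(-out$score, -xtfrm(out$mean_log2), out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Count presence of proteins across experiments
#'
#' Hemolymph-style analysis: given a logical proteins x experiments matrix
#' of detection calls, counts in how many experiments each protein was
#' observed, carrying its control category through (conflicting PC/NC
#' memberships should be resolved upstream with `conflict_policy = "other"`).
#'
#' @param observed Logical matrix, rownames = protein ids, colnames =
#'   experiment names.
#' @param categories Named character vector of categories (from
#'   [categorize()]) covering all proteins in `observed`.
#' @return Data frame with `protein_id`, `count`, `category`.
#' @export
presence_count <- function(observed, categories) {
  stopifnot(is.matrix(observed), is.logical(observed),
            !is.null(rownames(observed)))
  absent <- setdiff(rownames(observed), names(categories))
  if (length(absent) > 0L) {
    stop("no category for protein(s): ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(
    protein_id = rownames(observed),
    count = as.integer(rowSums(observed, na.rm = TRUE)),
    category = unname(categories[rownames(observed)]),
    stringsAsFactors = FALSE
  )
}

#' Write a score table as TSV
#' @param scores A [score_table()].
#' @param path Output path.
#' @param header_comment Optional '#' provenance line(s).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, header_comment = NULL) {
  out <- as.data.frame(scores)
  out$mean_log2 <- ifelse(is.na(out$mean_log2), "NA",
                          formatC(out$mean_log2, digits = 10, format = "g"))
  out$sem_log2 <- ifelse(is.na(out$sem_log2), "NA",
                         formatC(out$sem_log2, digits = 10, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
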