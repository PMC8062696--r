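#' Score-stratified categorical enrichment test
#'
#' Tests whether a per-protein categorical annotation (binary, e.g. "has a
#' predicted signal peptide", or three-outcome tissue expression
#' up/none/down) differs between background proteins (E-S = 0) and hits at
#' or above a score cutoff (E-S >= k). The contingency table is
#' 2 strata x L flag levels; the chi-square test (two-sided, no continuity
#' correction) handles any L, Fisher's exact test (two-sided) binary flags.
#'
#' @param scores A [score_table()].
#' @param flag Named character (or factor/logical) vector keyed by
#'   protein_id; proteins with `NA` flags are dropped.
#' @param k Score cutoff defining the hit stratum (`>= 1`).
#' @param test `"chi_square"` or `"fisher_exact"`.
#' @return A `contingency_result`: list with `table`, `test`, `statistic`,
#'   `p_value`.
#' @export
flag_enrichment_test <- function(scores, flag, k = 1L,
                                 test = c("chi_square", "fisher_exact")) {
  test <- match.arg(test)
  stopifnot(k >= 1L)
  if (is.logical(flag)) {
    flag <- stats::setNames(ifelse(flag, "yes", "no"), names(flag))
  }
  flag <- flag[!is.na(flag)]
  common <- intersect(scores$protein_id, names(flag))
  s <- scores$score[match(common, scores$protein_id)]
  f <- as.character(flag[common])
  in_bg <- s == 0L
  in_hit <- s >= k
  if (!any(in_bg) || !any(in_hit)) {
    stop("empty stratum: need proteins with score 0 and with score >= ", k,
         call. = FALSE)
  }
  stratum <- c(rep("score0", sum(in_bg)), rep("scoreK", sum(in_hit)))
  tab <- table(stratum, c(f[in_bg], f[in_hit]))
  if (test == "fisher_exact" && ncol(tab) > 2L) {
    stop("fisher_exact supports binary flags only (got ", ncol(tab),
         " levels); use chi_square", call. = FALSE)
  }
  if (test == "chi_square") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    statistic <- unname(ht$estimate)
  }
  structure(list(table = unclass(tab), test = test, statistic = statistic,
                 p_value = unname(ht$p.value)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("contingency_result (", x$test, "): p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Overlap test for two identifier sets within a universe
#'
#' Builds the 2 x 2 membership table of `set_a` x `set_b` over `universe`
#' and applies a two-sided Fisher's exact test. The fold enrichment is the
#' observed overlap over its expectation |A||B|/|U| under independence.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible identifiers.
#' @return List with `overlap`, `fold`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) > 0L ||
      length(setdiff(set_b, universe)) > 0L) {
    stop("sets must be contained in the universe", call. = FALSE)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, levels = c(TRUE, FALSE)),
               factor(in_b, levels = c(TRUE, FALSE)))
  overlap <- sum(in_a & in_b)
  expected <- length(set_a) * length(set_b) / length(universe)
  p <- if (length(set_a) == 0L || length(set_b) == 0L) 1 else
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(overlap = overlap,
       fold = if (expected > 0) overlap / expected else NA_real_,
       p = p)
}

#' Benjamini-Krieger-Yekutieli two-stage step-up FDR adjustment
#'
#' Two-stage linear step-up procedure: stage 1 runs Benjamini-Hochberg at
#' the deflated level q' = q/(1+q) and estimates the number of true nulls
#' as m0 = m - r1 (r1 = stage-1 rejections, floored at 1); stage 2 is BH
#' with m0 in place of m. The returned adjusted values are the stage-2
#' step-up adjusted p-values, clipped to [0, 1] and monotone in the sorted
#' order; when stage 1 rejects nothing (m0 = m) they coincide exactly with
#' ordinary BH.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q Nominal FDR level used for the stage-1 m0 estimate (default
#'   0.05).
#' @return Adjusted values in the input order.
#' @export
bky_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p_values, method = "BH") <= q1)
  m0 <- max(m - r1, 1L)
  ord <- order(p_values)
  ranks <- seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(p_values[ord] * m0 / ranks))))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Abundance-shift test between score strata
#'
#' For each score cutoff k, compares the whole-organism abundance
#' distribution of background proteins (E-S = 0) against hits (E-S >= k)
#' with the Kruskal-Wallis rank test, then applies the
#' Benjamini-Krieger-Yekutieli two-stage FDR across cutoffs. A systematic
#' shift towards lower abundance among high-scoring proteins indicates
#' enrichment of low-abundance secreted factors.
#'
#' @param scores A [score_table()].
#' @param abundances Named numeric vector (protein_id -> abundance, e.g.
#'   ppm); `NA` entries are dropped.
#' @param strata Integer vector of score cutoffs k to test.
#' @param q FDR level for [bky_adjust()].
#' @return Data frame with `k`, `n_background`, `n_hit`, `statistic`, `p`,
#'   `adj_p`.
#' @export
abundance_shift_test <- function(scores, abundances, strata = 1L, q = 0.05) {
  abundances <- abundances[!is.na(abundances)]
  common <- intersect(scores$protein_id, names(abundances))
  s <- scores$score[match(common, scores$protein_id)]
  a <- as.numeric(abundances[common])
  rows <- lapply(strata, function(k) {
    bg <- a[s == 0L]
    hit <- a[s >= k]
    if (length(bg) < 2L || length(hit) < 2L) {
      stop("insufficient data: need >= 2 proteins with abundance in both ",
           "strata (k = ", k, ")", call. = FALSE)
    }
    ht <- stats::kruskal.test(list(bg, hit))
    data.frame(k = k, n_background = length(bg), n_hit = length(hit),
               statistic = unname(ht$statistic), p = ht$p.value)
  })
  if (length(rows) < 1L) stop("no strata supplied", call. = FALSE)
  out <- do.call(rbind, rows)
  out$adj_p <- bky_adjust(out$p, q = q)
  rownames(out) <- NULL
  out
}

#' Cross-species secretome enrichment among hits
#'
#' A protein is "secretome-positive" when at least `min_datasets` of the
#' supplied published secretome data sets contain one of its mapped
#' orthologs (the >= 2-data-set rule guards against one-off observations).
#' Tests whether hits are enriched for secretome-positive proteins relative
#' to background.
#'
#' @param hits,background Disjoint character vectors of protein ids.
#' @param ortholog_map Data frame with columns `protein_id`, `ortholog_id`
#'   (many-to-many).
#' @param datasets List of character vectors of ortholog ids, one per
#'   published secretome data set.
#' @param min_datasets Minimum number of data sets containing an ortholog
#'   (default 2).
#' @param test `"fisher_exact"` or `"chi_square"`.
#' @return A `contingency_result` (table rows = hit/background, columns =
#'   positive/negative).
#' @export
secretome_ortholog_enrichment <- function(hits, background, ortholog_map,
                                          datasets, min_datasets = 2L,
                                          test = c("fisher_exact",
                                                   "chi_square")) {
  test <- match.arg(test)
  if (is.null(ortholog_map) || nrow(ortholog_map) == 0L) {
    stop("empty ortholog map", call. = FALSE)
  }
  if (length(datasets) < min_datasets) {
    stop("need at least min_datasets (", min_datasets, ") data sets",
         call. = FALSE)
  }
  stopifnot(all(c("protein_id", "ortholog_id") %in% names(ortholog_map)))
  is_positive <- function(ids) {
    vapply(ids, function(pid) {
      orth <- ortholog_map$ortholog_id[ortholog_map$protein_id == pid]
      if (length(orth) == 0L) return(FALSE)
      n_ds <- sum(vapply(datasets,
                         function(ds) any(orth %in% ds), logical(1)))
      n_ds >= min_datasets
    }, logical(1))
  }
  hit_pos <- is_positive(unique(hits))
  bg_pos <- is_positive(unique(background))
  tab <- rbind(hit = c(positive = sum(hit_pos), negative = sum(!hit_pos)),
               background = c(sum(bg_pos), sum(!bg_pos)))
  if (test == "fisher_exact") {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    statistic <- unname(ht$estimate)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ht$statistic)
  }
  structure(list(table = tab, test = test, statistic = statistic,
                 p_value = unname(ht$p.value)),
            class = "contingency_result")
}

#' Complementary t-test hit calling on per-channel values
#'
#' An alternative to threshold/E-S hit calling: per-channel log2 intensities
#' are multi-median normalized (each channel's median subtracted), then each
#' protein with complete-enough data is tested between the bait and control
#' channel groups with a two-sided two-sample t-test (Welch by default).
#' P-values are Benjamini-Hochberg adjusted across tested proteins.
#'
#' @param table A `quant_table` carrying a `channels` matrix of log2
#'   intensities.
#' @param group_a,group_b Channel label vectors (bait and control), each of
#'   length >= 2.
#' @param equal_var Use the pooled-variance t-test instead of Welch.
#' @param normalize Multi-median normalize channels before testing
#'   (default `TRUE`).
#' @return Data frame with `protein_id`, `log_fc` (mean A - mean B),
#'   `p_value`, `adj_p`. Proteins with fewer than 2 observations in either
#'   group are skipped with a message.
#' @export
ttest_hit_calling <- function(table, group_a, group_b, equal_var = FALSE,
                              normalize = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  if (is.null(table$channels)) {
    stop("quant table has no per-channel values", call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 channels", call. = FALSE)
  }
  absent <- setdiff(c(group_a, group_b), colnames(table$channels))
  if (length(absent) > 0L) {
    stop("unknown channel(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ch <- table$channels
  if (normalize) {
    ch <- sweep(ch, 2L, apply(ch, 2L, stats::median, na.rm = TRUE))
  }
  res <- lapply(seq_len(nrow(ch)), function(i) {
    a <- ch[i, group_a]; a <- a[!is.na(a)]
    b <- ch[i, group_b]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      # zero within-group variance: identical groups get p = 1, else p -> 0
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      p <- stats::t.test(a, b, var.equal = equal_var,
                         alternative = "two.sided")$p.value
    }
    data.frame(protein_id = table$meta$protein_id[i],
               log_fc = mean(a) - mean(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0L) {
    message("ttest_hit_calling: skipped ", skipped,
            " protein(s) with < 2 observations in a group")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(protein_id = character(0), log_fc = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0)))
  }
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Concordance between E-S and t-test hit calling
#'
#' Spearman rank correlation between the enrichment score and
#' -log10(adjusted p) over proteins present in both tables. A strong
#' positive correlation indicates the two hit-calling routes agree.
#'
#' @param scores A [score_table()].
#' @param ttest Result of [ttest_hit_calling()].
#' @return Spearman's rho in [-1, 1].
#' @export
concordance <- function(scores, ttest) {
  common <- intersect(scores$protein_id, ttest$protein_id)
  if (length(common) < 3L) {
    stop("need >= 3 proteins shared between the score and t-test tables",
         call. = FALSE)
  }
  s <- scores$score[match(common, scores$protein_id)]
  p <- ttest$adj_p[match(common, ttest$protein_id)]
  neglog <- -log10(pmax(p, .Machine$double.xmin))
  stats::cor(s, neglog, method = "spearman")
}
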