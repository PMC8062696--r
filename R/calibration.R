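#' Build the control-purity fraction curve for one comparison
#'
#' For every candidate log2-ratio value, counts the positive-control (PC)
#' and negative-control (NC) proteins whose ratio is at or above it
#' (inclusive), and computes
#' purity = #PC / (#PC + #NC), the PC recall (%PC of all observed PC at or
#' above), and the NC rate (%NC of all observed NC at or above). By default
#' candidates are the sorted unique observed ratios of PC and NC proteins;
#' a fixed-step grid can be requested instead. Non-control proteins are
#' ignored.
#'
#' @param ratios Named numeric vector of log2 ratios (names = protein ids);
#'   `NA` entries are dropped.
#' @param categories Named character vector of categories (`"PC"`, `"NC"`,
#'   anything else ignored) covering the ratio names.
#' @param grid `"observed"` (default) or a positive numeric step width for a
#'   regular grid spanning the observed control ratios.
#' @return A `fraction_curve`: data frame with columns `candidate`, `n_pc`,
#'   `n_nc`, `purity`, `pc_recall`, `nc_rate`, plus attributes
#'   `n_pc_total`, `n_nc_total`.
#' @export
fraction_curve <- function(ratios, categories, grid = "observed") {
  stopifnot(!is.null(names(ratios)))
  cat_of <- categories[names(ratios)]
  obs <- !is.na(ratios)
  pc_r <- ratios[obs & cat_of %in% "PC"]
  nc_r <- ratios[obs & cat_of %in% "NC"]
  if (length(pc_r) == 0L) {
    stop("no PC protein with an observed ratio", call. = FALSE)
  }
  if (length(nc_r) == 0L) {
    stop("no NC protein with an observed ratio", call. = FALSE)
  }
  if (identical(grid, "observed")) {
    candidates <- sort(unique(c(pc_r, nc_r)))
  } else {
    step <- as.numeric(grid)
    stopifnot(is.finite(step), step > 0)
    lo <- floor(min(c(pc_r, nc_r)) / step) * step
    hi <- ceiling(max(c(pc_r, nc_r)) / step) * step
    candidates <- seq(lo, hi, by = step)
  }
  n_pc <- vapply(candidates, function(t) sum(pc_r >= t), integer(1))
  n_nc <- vapply(candidates, function(t) sum(nc_r >= t), integer(1))
  total <- n_pc + n_nc
  curve <- data.frame(
    candidate = candidates,
    n_pc = n_pc,
    n_nc = n_nc,
    purity = ifelse(total > 0, n_pc / total, NA_real_),
    pc_recall = n_pc / length(pc_r),
    nc_rate = n_nc / length(nc_r)
  )
  attr(curve, "n_pc_total") <- length(pc_r)
  attr(curve, "n_nc_total") <- length(nc_r)
  class(curve) <- c("fraction_curve", "data.frame")
  curve
}

.calibration_result <- function(curve, rule, parameter, idx,
                                comparison_id = NA_character_) {
  if (is.na(idx)) {
    threshold <- NA_real_
    achieved_purity <- NA_real_
    achieved_fpr <- NA_real_
  } else {
    threshold <- curve$candidate[idx]
    achieved_purity <- curve$purity[idx]
    achieved_fpr <- if (curve$pc_recall[idx] > 0) {
      curve$nc_rate[idx] / curve$pc_recall[idx]
    } else NA_real_
  }
  structure(
    list(comparison_id = comparison_id, rule = rule, parameter = parameter,
         threshold = threshold, achieved_purity = achieved_purity,
         achieved_fpr = achieved_fpr, curve = curve),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration (", x$rule, " rule, parameter ", x$parameter, "): ",
      sep = "")
  if (is.na(x$threshold)) {
    cat("no attainable threshold\n")
  } else {
    cat("threshold ", format(x$threshold), " (purity ",
        format(x$achieved_purity, digits = 3), ", FPR ",
        format(x$achieved_fpr, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Select a threshold by the PC-purity rule
#'
#' Picks the smallest candidate log2 ratio whose purity
#' #PC/(#PC+#NC) meets the target (`mode = "ge"`: at least the target;
#' `"gt"`: strictly above). This is the fly-style calibration with a
#' default target of 0.9.
#'
#' @param curve A [fraction_curve()].
#' @param target Purity target in (0, 1].
#' @param mode `"ge"` (default) or `"gt"`.
#' @param comparison_id Optional label carried into the result.
#' @return A `calibration_result`; `threshold` is `NA` (with a warning) if
#'   no candidate qualifies.
#' @export
select_threshold_purity <- function(curve, target = 0.9,
                                    mode = c("ge", "gt"),
                                    comparison_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(target > 0, target <= 1)
  ok <- !is.na(curve$purity) &
    (if (mode == "ge") curve$purity >= target else curve$purity > target)
  idx <- if (any(ok)) which(ok)[1L] else NA_integer_
  if (is.na(idx)) {
    warning("no candidate reaches purity ", target, " (mode ", mode, ")")
  }
  .calibration_result(curve, "purity", target, idx, comparison_id)
}

#' Select a threshold by the false-positive-rate rule
#'
#' Picks the smallest candidate at which %NC/%PC (each as a fraction of its
#' own control list observed in the comparison) falls to `fpr` or below,
#' with %PC still positive. `fpr = 0` demands that no NC protein remains at
#' or above the threshold. This is the mouse-style calibration (0.1 for
#' teratoma, 0 for serum).
#'
#' @param curve A [fraction_curve()].
#' @param fpr Target false-positive rate, `>= 0`.
#' @param comparison_id Optional label carried into the result.
#' @return A `calibration_result`; `threshold` is `NA` (with a warning) if
#'   the rate is unattainable.
#' @export
select_threshold_fpr <- function(curve, fpr = 0.1,
                                 comparison_id = NA_character_) {
  stopifnot(fpr >= 0)
  ok <- curve$pc_recall > 0 &
    (if (fpr == 0) curve$n_nc == 0L
     else curve$nc_rate / curve$pc_recall <= fpr)
  idx <- if (any(ok)) which(ok)[1L] else NA_integer_
  if (is.na(idx)) {
    warning("no candidate attains FPR <= ", fpr)
  }
  .calibration_result(curve, "fpr", fpr, idx, comparison_id)
}

#' Inject a manually chosen threshold
#'
#' The published analyses involved curve-shape judgment when picking some
#' thresholds; `select_threshold_manual()` records a user-supplied value
#' verbatim while still reporting the purity and FPR achieved at that value
#' on the given curve.
#'
#' @param curve A [fraction_curve()].
#' @param threshold The log2-ratio threshold to adopt.
#' @param comparison_id Optional label carried into the result.
#' @return A `calibration_result` with `rule = "manual"`.
#' @export
select_threshold_manual <- function(curve, threshold,
                                    comparison_id = NA_character_) {
  stopifnot(is.finite(threshold))
  # achieved metrics at the manual value use the same inclusive convention:
  # counts at/above t equal the counts at the first candidate >= t
  at <- which(curve$candidate >= threshold)
  res <- .calibration_result(curve, "manual", threshold,
                             if (length(at) > 0) at[1L] else NA_integer_,
                             comparison_id)
  res$threshold <- threshold
  res
}

#' Calibrate every comparison of a quant table
#'
#' Builds the fraction curve and selects a threshold for each comparison in
#' the design, using the control lists to categorize proteins.
#'
#' @param table A filtered, median-normalized `quant_table`.
#' @param lists A `control_lists` object.
#' @param rule `"purity"`, `"fpr"` or `"manual"`.
#' @param parameter Purity target (default 0.9) or FPR (default 0.1),
#'   depending on `rule`.
#' @param manual_thresholds Named numeric vector (names = comparison ids)
#'   required when `rule = "manual"`.
#' @param grid Passed to [fraction_curve()].
#' @return A named list of `calibration_result`, one per comparison.
#' @export
calibrate_comparisons <- function(table, lists,
                                  rule = c("purity", "fpr", "manual"),
                                  parameter = NULL,
                                  manual_thresholds = NULL,
                                  grid = "observed") {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "quant_table"), inherits(lists, "control_lists"))
  ids <- comparison_ids(table$design)
  categories <- stats::setNames(categorize(table$meta$protein_id, lists),
                                table$meta$protein_id)
  if (rule == "manual") {
    missing_thr <- setdiff(ids, names(manual_thresholds))
    if (length(missing_thr) > 0L) {
      stop("manual rule needs a threshold for every comparison; missing: ",
           paste(missing_thr, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(parameter)) {
    parameter <- if (rule == "fpr") 0.1 else 0.9
  }
  out <- lapply(ids, function(cid) {
    r <- stats::setNames(table$ratios[, cid], table$meta$protein_id)
    curve <- fraction_curve(r, categories, grid = grid)
    switch(rule,
      purity = select_threshold_purity(curve, target = parameter,
                                       comparison_id = cid),
      fpr = select_threshold_fpr(curve, fpr = parameter,
                                 comparison_id = cid),
      manual = select_threshold_manual(curve, manual_thresholds[[cid]],
                                       comparison_id = cid))
  })
  stats::setNames(out, ids)
}

#' Tabulate a set of calibration results
#'
#' @param results A list of `calibration_result` (as returned by
#'   [calibrate_comparisons()]).
#' @return A data frame with one row per comparison: comparison_id, rule,
#'   parameter, threshold, achieved_purity, achieved_fpr, n_pc, n_nc.
#' @export
calibration_report <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(comparison_id = r$comparison_id, rule = r$rule,
               parameter = r$parameter, threshold = r$threshold,
               achieved_purity = r$achieved_purity,
               achieved_fpr = r$achieved_fpr,
               n_pc = attr(r$curve, "n_pc_total"),
               n_nc = attr(r$curve, "n_nc_total"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Extract the selected thresholds as a named vector
#' @param results A list of `calibration_result`.
#' @return Named numeric vector keyed by comparison id.
#' @export
calibration_thresholds <- function(results) {
  vapply(results, function(r) r$threshold, numeric(1))
}
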