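#' Define a TMT comparison design
#'
#' A comparison design names each bait/control TMT channel ratio used for
#' hit calling. In a replicate cross design every bait (BirA*) replicate is
#' compared against every control (wild-type) replicate, so 2 bait x 2
#' control replicates yield 4 comparisons and 3 x 3 yield 9.
#'
#' @param dataset_name Name of the data set (e.g. "fly_fb_legs").
#' @param comparisons A data frame with columns `comparison_id`,
#'   `numerator_label` (bait replicate) and `denominator_label` (control
#'   replicate), one row per comparison. Comparison ids are typically TMT
#'   channel ratios such as `"127N/126"`.
#' @param species Species tag used for contaminant filtering (e.g.
#'   "DROME", "MOUSE").
#'
#' @return An object of class `comparison_design`.
#' @export
comparison_design <- function(dataset_name, comparisons, species = "") {
  stopifnot(is.character(dataset_name), length(dataset_name) == 1L)
  comparisons <- as.data.frame(comparisons, stringsAsFactors = FALSE)
  required <- c("comparison_id", "numerator_label", "denominator_label")
  missing_cols <- setdiff(required, names(comparisons))
  if (length(missing_cols) > 0L) {
    stop("comparison table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(comparisons) < 1L) {
    stop("a design needs at least one comparison", call. = FALSE)
  }
  if (anyDuplicated(comparisons$comparison_id)) {
    stop("comparison_ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(comparisons$numerator_label)) ||
      any(!nzchar(comparisons$denominator_label))) {
    stop("numerator and denominator labels must be non-empty", call. = FALSE)
  }
  structure(
    list(dataset_name = dataset_name,
         comparisons = comparisons[, required],
         species = species),
    class = "comparison_design"
  )
}

#' Construct a full replicate-cross design
#'
#' Convenience constructor for the all-pairs bait x control design. Channel
#' labels default to `bait1..baitB` and `ctrl1..ctrlC`; comparison ids are
#' `"<bait>/<ctrl>"`.
#'
#' @param dataset_name,species Passed to [comparison_design()].
#' @param n_bait_reps,n_control_reps Number of bait and control replicates.
#' @param bait_labels,control_labels Optional channel label vectors.
#' @return A `comparison_design` with `n_bait_reps * n_control_reps`
#'   comparisons.
#' @export
cross_design <- function(dataset_name, n_bait_reps, n_control_reps,
                         bait_labels = paste0("bait", seq_len(n_bait_reps)),
                         control_labels = paste0("ctrl", seq_len(n_control_reps)),
                         species = "") {
  stopifnot(n_bait_reps >= 1L, n_control_reps >= 1L,
            length(bait_labels) == n_bait_reps,
            length(control_labels) == n_control_reps)
  grid <- expand.grid(denominator_label = control_labels,
                      numerator_label = bait_labels,
                      stringsAsFactors = FALSE)
  # order: bait-major, matching how channel ratio tables are usually laid out
  grid <- grid[, c("numerator_label", "denominator_label")]
  grid$comparison_id <- paste(grid$numerator_label, grid$denominator_label,
                              sep = "/")
  comparison_design(dataset_name, grid, species = species)
}

#' Read a comparison design from a YAML config
#'
#' Expected keys: `dataset_name`, `species` (optional) and `comparisons`, a
#' list of maps each with `comparison_id`, `numerator_label`,
#' `denominator_label`.
#'
#' @param path Path to a YAML file.
#' @return A `comparison_design`.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$dataset_name) || is.null(cfg$comparisons)) {
    stop("design config must define dataset_name and comparisons",
         call. = FALSE)
  }
  comps <- do.call(rbind, lapply(cfg$comparisons, function(x) {
    data.frame(comparison_id = x$comparison_id,
               numerator_label = x$numerator_label,
               denominator_label = x$denominator_label,
               stringsAsFactors = FALSE)
  }))
  comparison_design(cfg$dataset_name, comps,
                    species = if (is.null(cfg$species)) "" else cfg$species)
}

#' @export
print.comparison_design <- function(x, ...) {
  cat("Comparison design '", x$dataset_name, "' (",
      nrow(x$comparisons), " comparisons",
      if (nzchar(x$species)) paste0(", species ", x$species), ")\n", sep = "")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Comparison ids of a design
#' @param design A `comparison_design`.
#' @return Character vector of comparison ids.
#' @export
comparison_ids <- function(design) {
  stopifnot(inherits(design, "comparison_design"))
  design$comparisons$comparison_id
}
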