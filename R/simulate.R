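#' Parameters for the synthetic proximity-labeling generator
#'
#' Defines the generative model used to produce fully ground-truthed
#' synthetic TMT data sets. A minority of proteins (`frac_labeled`) are
#' truly labeled by the bait ligase: their log2 bait/control ratios are
#' centered at `mu_labeled`, with a per-bait-replicate latent effect shared
#' across that replicate's comparisons (inducing the replicate correlation
#' seen in real cross designs). Background proteins have zero-centered
#' ratios. Control-list membership, signal-peptide flags and whole-organism
#' abundance are drawn conditionally on the true labeling state.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param frac_labeled Fraction truly labeled (default 0.1).
#' @param mu_labeled Mean log2 ratio of labeled proteins (default 2).
#' @param sigma_labeled Marginal SD of labeled-protein ratios (default 0.5).
#' @param sigma_background SD of background ratios (default 0.5).
#' @param rep_correlation Fraction of labeled-ratio variance carried by the
#'   shared per-bait-replicate latent effect, in [0, 1) (default 0.5).
#' @param n_bait_reps,n_control_reps Replicate counts; comparisons = all
#'   bait x control pairs (defaults 2 x 2 = 4, fly-like; use 3 x 3 = 9 for
#'   a mouse-like design).
#' @param missing_rate Per-cell missingness probability (default 0.05,
#'   completely at random).
#' @param pc_coverage P(labeled protein is on the PC list) (default 0.3).
#' @param nc_coverage P(background protein is on the NC list) (default 0.3).
#' @param pc_contamination P(background protein is wrongly on the PC list)
#'   (default 0.01).
#' @param sp_sens,sp_spec Sensitivity/specificity of the signal-peptide
#'   flag with respect to the true labeling state (defaults 0.9, 0.95).
#' @param abundance_logmu,abundance_logsigma log10-normal abundance (ppm)
#'   parameters (defaults 1, 1: median 10 ppm).
#' @param abundance_shift_labeled Multiplicative abundance shift for
#'   labeled proteins (default 0.3: labeled proteins are ~3x less abundant,
#'   emulating low-abundance secreted factors).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_proteins = 2000L, frac_labeled = 0.1,
                       mu_labeled = 2, sigma_labeled = 0.5,
                       sigma_background = 0.5, rep_correlation = 0.5,
                       n_bait_reps = 2L, n_control_reps = 2L,
                       missing_rate = 0.05,
                       pc_coverage = 0.3, nc_coverage = 0.3,
                       pc_contamination = 0.01,
                       sp_sens = 0.9, sp_spec = 0.95,
                       abundance_logmu = 1, abundance_logsigma = 1,
                       abundance_shift_labeled = 0.3,
                       seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            frac_labeled = frac_labeled, mu_labeled = mu_labeled,
            sigma_labeled = sigma_labeled,
            sigma_background = sigma_background,
            rep_correlation = rep_correlation,
            n_bait_reps = as.integer(n_bait_reps),
            n_control_reps = as.integer(n_control_reps),
            missing_rate = missing_rate,
            pc_coverage = pc_coverage, nc_coverage = nc_coverage,
            pc_contamination = pc_contamination,
            sp_sens = sp_sens, sp_spec = sp_spec,
            abundance_logmu = abundance_logmu,
            abundance_logsigma = abundance_logsigma,
            abundance_shift_labeled = abundance_shift_labeled,
            seed = as.integer(seed))
  probs <- c("frac_labeled", "missing_rate", "pc_coverage", "nc_coverage",
             "pc_contamination", "sp_sens", "sp_spec", "rep_correlation")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$frac_labeled >= 1) stop("frac_labeled must be < 1", call. = FALSE)
  if (p$missing_rate >= 1) stop("missing_rate must be < 1", call. = FALSE)
  if (p$sigma_labeled <= 0 || p$sigma_background <= 0) {
    stop("sigmas must be positive", call. = FALSE)
  }
  if (p$n_proteins < 1L || p$n_bait_reps < 1L || p$n_control_reps < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (p$abundance_shift_labeled <= 0) {
    stop("abundance_shift_labeled must be positive", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

#' Simulate a ground-truthed proximity-labeling TMT data set
#'
#' Draws a full synthetic experiment under the model described in
#' [sim_params()]: a quant table of log2 ratios over the replicate-cross
#' design, positive/negative control lists, per-protein annotations
#' (signal peptide, abundance), and the ground-truth labeling table.
#' Bit-identical output for identical parameters (including seed).
#'
#' @param params A [sim_params()] object.
#' @return List with elements `table` (a `quant_table`), `lists`
#'   (`control_lists`), `annotations` (`annotation_table`), and `truth`
#'   (data frame `protein_id`, `is_labeled`).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  labeled <- stats::runif(n) < p$frac_labeled

  design <- cross_design("synthetic", p$n_bait_reps, p$n_control_reps,
                         species = "SYNTH")
  comps <- design$comparisons
  n_comp <- nrow(comps)

  # shared latent effect per (protein, bait replicate); labeled only
  rho <- p$rep_correlation
  sd_lat <- p$sigma_labeled * sqrt(rho)
  sd_res <- p$sigma_labeled * sqrt(1 - rho)
  latent <- matrix(stats::rnorm(n * p$n_bait_reps,
                                mean = p$mu_labeled, sd = sd_lat),
                   nrow = n)
  bait_idx <- match(comps$numerator_label,
                    unique(comps$numerator_label))
  ratios <- matrix(NA_real_, nrow = n, ncol = n_comp,
                   dimnames = list(NULL, comps$comparison_id))
  for (j in seq_len(n_comp)) {
    b <- bait_idx[j]
    ratios[, j] <- ifelse(
      labeled,
      latent[, b] + stats::rnorm(n, 0, sd_res),
      stats::rnorm(n, 0, p$sigma_background))
  }
  if (p$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_comp) < p$missing_rate,
                   nrow = n)
    ratios[miss] <- NA_real_
  }

  # control lists coupled to truth
  on_pc <- (labeled & stats::runif(n) < p$pc_coverage) |
    (!labeled & stats::runif(n) < p$pc_contamination)
  on_nc <- !labeled & stats::runif(n) < p$nc_coverage
  # a background protein drawn for both lists is a genuine conflict;
  # assemble_control_lists resolves it by policy
  pc_ids <- ids[on_pc]
  nc_ids <- ids[on_nc]
  lists <- assemble_control_lists(list(synthetic_pc = pc_ids),
                                  list(synthetic_nc = nc_ids),
                                  conflict_policy = "exclude")

  sp <- ifelse(labeled,
               stats::runif(n) < p$sp_sens,
               stats::runif(n) >= p$sp_spec)
  abundance <- 10^stats::rnorm(n, p$abundance_logmu, p$abundance_logsigma)
  abundance[labeled] <- abundance[labeled] * p$abundance_shift_labeled
  annotations <- data.frame(
    protein_id = ids,
    signal_peptide = sp,
    er_resident = stats::runif(n) < 0.03,
    tm_domain = stats::runif(n) < ifelse(labeled, 0.15, 0.25),
    unconventional = stats::runif(n) < 0.02,
    abundance_ppm = abundance,
    stringsAsFactors = FALSE
  )
  class(annotations) <- c("annotation_table", "data.frame")

  meta <- data.frame(
    protein_id = ids,
    gene_symbol = sub("^SYN", "Sg", ids),
    is_decoy = FALSE, is_contaminant = FALSE,
    unique_peptides = NA_integer_, total_intensity = NA_real_,
    stringsAsFactors = FALSE
  )
  table <- new_quant_table(design, meta, ratios, normalized = FALSE)
  truth <- data.frame(protein_id = ids, is_labeled = labeled,
                      stringsAsFactors = FALSE)
  list(table = table, lists = lists, annotations = annotations,
       truth = truth)
}

#' Evaluate hit calls against ground truth
#'
#' @param hits Character vector of called protein ids.
#' @param truth Truth data frame (`protein_id`, `is_labeled`) covering all
#'   hit ids.
#' @return List with `sensitivity` (TP / all labeled), `empirical_fdr`
#'   (FP / max(1, number of hits)) and `precision` (TP / number of hits;
#'   `NA` when no hits).
#' @export
evaluate_calls <- function(hits, truth) {
  hits <- unique(hits)
  unknown <- setdiff(hits, truth$protein_id)
  if (length(unknown) > 0L) {
    stop("hit id(s) absent from truth table: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  labeled <- truth$protein_id[truth$is_labeled]
  tp <- length(intersect(hits, labeled))
  fp <- length(hits) - tp
  list(sensitivity = if (length(labeled) > 0) tp / length(labeled) else NA_real_,
       empirical_fdr = fp / max(1L, length(hits)),
       precision = if (length(hits) > 0) tp / length(hits) else NA_real_)
}
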