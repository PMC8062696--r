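# End-to-end orchestration: load -> filter -> normalize -> calibrate ->
# score -> stats -> report. Configuration is one list (or YAML file); all
# outputs are TSVs under a single directory, each with a '#' provenance
# header carrying a config hash and the package version, so repeated runs
# are byte-identical.

# tiny polynomial hash over the serialized config; provenance only
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(dput(config)),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(config) {
  paste0("# proxisec ",
         as.character(utils::packageVersion("proxisec")),
         "; config ", .config_hash(config))
}

.write_report <- function(df, path, config) {
  out <- as.data.frame(df)
  out[] <- lapply(out, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", formatC(col, digits = 10, format = "g"))
    } else as.character(col)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(config), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full hit-calling pipeline
#'
#' Orchestrates the analysis from a single configuration: load (or accept)
#' a quant table, remove decoys/contaminants, median-normalize, calibrate a
#' threshold per comparison against the control lists, compute enrichment
#' scores and hit calls, optionally run annotation-enrichment and
#' abundance-shift statistics, and write the report bundle.
#'
#' @param config A list (or path to a YAML file) with keys:
#'   \describe{
#'     \item{dataset_name}{run label}
#'     \item{quant_path / design_path}{inputs when loading from disk;
#'       alternatively pass `table` and `lists` pre-built}
#'     \item{ratio_scale}{"log2" (default) or "linear"}
#'     \item{pc_list_path / nc_list_path}{gene-list files (one id/line)}
#'     \item{annotation_path}{optional annotation TSV}
#'     \item{rule}{"purity" (default), "fpr" or "manual"}
#'     \item{parameter}{purity target (default 0.9) or FPR (default 0.1)}
#'     \item{manual_thresholds}{named list, rule = "manual" only}
#'     \item{min_score}{hit cutoff (default 1)}
#'     \item{stats}{logical: run annotation statistics (default TRUE when
#'       annotations are available)}
#'     \item{out_dir}{output directory (created if needed)}
#'   }
#' @param table,lists,annotations Optional pre-built inputs overriding the
#'   corresponding paths (used by the synthetic route).
#' @return Invisibly, a list with `table`, `lists`, `calibration`,
#'   `thresholds`, `scores`, `hits`, `stats`, and `files` (paths written).
#' @export
run_pipeline <- function(config, table = NULL, lists = NULL,
                         annotations = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(table)) {
    table <- stage("load", {
      design <- read_design(config$design_path)
      read_quant_table(config$quant_path, design,
                       ratio_scale = if (is.null(config$ratio_scale))
                         "log2" else config$ratio_scale)
    })
  }
  if (is.null(lists)) {
    lists <- stage("controls", assemble_control_lists(
      list(pc = read_gene_list(config$pc_list_path)),
      list(nc = read_gene_list(config$nc_list_path)),
      conflict_policy = "exclude"))
  }
  if (is.null(annotations) && !is.null(config$annotation_path)) {
    annotations <- stage("annotations",
                         load_annotations(config$annotation_path))
  }

  table <- stage("filter", filter_quant_table(table))
  table <- stage("normalize", median_normalize(table))

  rule <- if (is.null(config$rule)) "purity" else config$rule
  manual_thr <- if (!is.null(config$manual_thresholds)) {
    unlist(config$manual_thresholds)
  } else NULL
  calib <- stage("calibrate", calibrate_comparisons(
    table, lists, rule = rule, parameter = config$parameter,
    manual_thresholds = manual_thr,
    grid = if (is.null(config$grid)) "observed" else config$grid))
  thresholds <- calibration_thresholds(calib)
  if (anyNA(thresholds)) {
    stop("pipeline stage 'calibrate' failed: no attainable threshold for ",
         paste(names(thresholds)[is.na(thresholds)], collapse = ", "),
         call. = FALSE)
  }

  min_score <- if (is.null(config$min_score)) 1L else
    as.integer(config$min_score)
  scores <- stage("score", score_table(table, thresholds,
                                       min_score = min_score))
  hits <- call_hits(scores, min_score = min_score)

  run_stats <- if (is.null(config$stats)) !is.null(annotations) else
    isTRUE(config$stats)
  stats_tabs <- NULL
  if (run_stats) {
    if (is.null(annotations)) {
      stop("pipeline stage 'stats' failed: stats requested but no ",
           "annotations supplied", call. = FALSE)
    }
    stats_tabs <- stage("stats", {
      tabs <- list()
      if ("signal_peptide" %in% names(annotations)) {
        flag <- stats::setNames(annotations$signal_peptide,
                                annotations$protein_id)
        ks <- seq_len(attr(scores, "n_comparisons"))
        tabs$signal_peptide <- do.call(rbind, lapply(ks, function(k) {
          res <- flag_enrichment_test(scores, flag, k = k,
                                      test = "chi_square")
          data.frame(k = k, test = res$test, statistic = res$statistic,
                     p = res$p_value)
        }))
      }
      if ("abundance_ppm" %in% names(annotations)) {
        ab <- stats::setNames(annotations$abundance_ppm,
                              annotations$protein_id)
        tabs$abundance <- abundance_shift_test(
          scores, ab, strata = seq_len(attr(scores, "n_comparisons")))
      }
      tabs
    })
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(out_dir, "calibration.tsv")
  .write_report(calibration_report(calib), f, config)
  files <- c(files, f)
  f <- file.path(out_dir, "scores.tsv")
  write_score_table(scores, f, header_comment = sub("^# ", "",
                                                    .provenance(config)))
  files <- c(files, f)
  f <- file.path(out_dir, "hits.tsv")
  .write_report(scores[scores$hit_class == "hit",
                       c("protein_id", "gene_symbol", "score",
                         "n_observed", "mean_log2", "sem_log2")],
                f, config)
  files <- c(files, f)
  if (!is.null(stats_tabs)) {
    for (nm in names(stats_tabs)) {
      f <- file.path(out_dir, paste0("stats_", nm, ".tsv"))
      .write_report(stats_tabs[[nm]], f, config)
      files <- c(files, f)
    }
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(.provenance(config),
               paste0("dataset: ", if (is.null(config$dataset_name))
                 table$design$dataset_name else config$dataset_name),
               paste0("proteins after filtering: ", n_proteins(table)),
               paste0("comparisons: ", length(thresholds)),
               paste0("rule: ", rule),
               paste0("hits (score >= ", min_score, "): ", length(hits))),
             log_path)
  files <- c(files, log_path)

  invisible(list(table = table, lists = lists, calibration = calib,
                 thresholds = thresholds, scores = scores, hits = hits,
                 stats = stats_tabs, files = files))
}
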