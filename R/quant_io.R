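#' @title Protein-level TMT quantification tables
#' @description
#' A `quant_table` holds one row of metadata per protein plus a proteins x
#' comparisons matrix of log2 bait/control TMT ratios. Missing ratios are
#' `NA` and are distinct from 0 throughout the pipeline. Optional per-channel
#' intensity values (for the complementary t-test route) live in a parallel
#' `channels` matrix.
#'
#' Internally:
#' \itemize{
#'   \item `design`: the [comparison_design()]
#'   \item `meta`: data frame with `protein_id`, `gene_symbol`, `is_decoy`,
#'     `is_contaminant`, `unique_peptides`, `total_intensity`
#'   \item `ratios`: numeric matrix, rownames = protein ids, colnames =
#'     comparison ids, always on the log2 scale
#'   \item `channels`: numeric matrix of per-channel values or `NULL`
#'   \item `normalized`: logical; `TRUE` after [median_normalize()]
#' }
#' @name quant_table
NULL

new_quant_table <- function(design, meta, ratios, channels = NULL,
                            normalized = FALSE) {
  stopifnot(inherits(design, "comparison_design"))
  stopifnot(is.data.frame(meta), is.matrix(ratios))
  if (anyDuplicated(meta$protein_id)) {
    stop("duplicate protein_id in quant table: ",
         paste(unique(meta$protein_id[duplicated(meta$protein_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(ratios), comparison_ids(design))) {
    stop("ratio columns do not match the design's comparison ids",
         call. = FALSE)
  }
  rownames(ratios) <- meta$protein_id
  if (!is.null(channels)) rownames(channels) <- meta$protein_id
  structure(
    list(design = design, meta = meta, ratios = ratios,
         channels = channels, normalized = normalized),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table: ", nrow(x$meta), " proteins x ",
      ncol(x$ratios), " comparisons (", x$design$dataset_name, ")",
      if (x$normalized) " [median-normalized]", "\n", sep = "")
  cat("  decoys: ", sum(x$meta$is_decoy),
      ", contaminants: ", sum(x$meta$is_contaminant),
      ", missing ratio cells: ", sum(is.na(x$ratios)), "\n", sep = "")
  invisible(x)
}

#' Number of proteins in a quant table
#' @param table A `quant_table`.
#' @return Integer count of records.
#' @export
n_proteins <- function(table) nrow(table$meta)

.as_logical_flag <- function(x, column) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "yes", "true", "TRUE", "True", "Y", "y")] <- TRUE
  out[x %in% c("0", "no", "false", "FALSE", "False", "N", "n", "", "NA")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("unparseable boolean in column '", column, "', row ", bad[1L],
         ": '", x[bad[1L]], "'", call. = FALSE)
  }
  out
}

.read_delim_auto <- function(path) {
  # tab-separated default, comma accepted; '#' comment lines allowed
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  sep <- if (length(first) > 0L &&
             !grepl("\t", first[1L]) && grepl(",", first[1L])) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Read a protein-protein comparison table
#'
#' Parses a delimited text export (tab default, comma accepted) with one row
#' per protein. Required columns: `protein_id` and one ratio column per
#' comparison id in `design`. Recognised optional columns: `gene_symbol`,
#' `is_decoy`, `is_contaminant`, `unique_peptides`, `total_intensity`, and
#' per-channel intensities prefixed `channel:`.
#'
#' @param path Path to the delimited file.
#' @param design A [comparison_design()].
#' @param ratio_scale `"log2"` (ratios stored as-is) or `"linear"` (ratios
#'   are converted with log2 on read). Ratios are always stored on the log2
#'   scale.
#' @return A `quant_table` with `normalized = FALSE`. Non-numeric or empty
#'   ratio cells become missing (`NA`).
#' @export
read_quant_table <- function(path, design, ratio_scale = c("log2", "linear")) {
  ratio_scale <- match.arg(ratio_scale)
  raw <- .read_delim_auto(path)
  ids <- comparison_ids(design)
  required <- c("protein_id", ids)
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0L) {
    stop("quant table is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  meta <- data.frame(
    protein_id = raw$protein_id,
    gene_symbol = if ("gene_symbol" %in% names(raw)) raw$gene_symbol else "",
    is_decoy = if ("is_decoy" %in% names(raw))
      .as_logical_flag(raw$is_decoy, "is_decoy") else FALSE,
    is_contaminant = if ("is_contaminant" %in% names(raw))
      .as_logical_flag(raw$is_contaminant, "is_contaminant") else FALSE,
    unique_peptides = if ("unique_peptides" %in% names(raw))
      suppressWarnings(as.integer(raw$unique_peptides)) else NA_integer_,
    total_intensity = if ("total_intensity" %in% names(raw))
      suppressWarnings(as.numeric(raw$total_intensity)) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(meta$protein_id))) {
    stop("empty protein_id encountered", call. = FALSE)
  }
  ratios <- sapply(ids, function(cid) {
    suppressWarnings(as.numeric(raw[[cid]]))
  })
  ratios <- matrix(ratios, nrow = nrow(raw), ncol = length(ids),
                   dimnames = list(NULL, ids))
  if (ratio_scale == "linear") {
    if (any(ratios <= 0, na.rm = TRUE)) {
      stop("linear ratios must be positive to take log2", call. = FALSE)
    }
    ratios <- log2(ratios)
  }
  chan_cols <- grep("^channel:", names(raw), value = TRUE)
  channels <- NULL
  if (length(chan_cols) > 0L) {
    channels <- sapply(chan_cols, function(cc) {
      suppressWarnings(as.numeric(raw[[cc]]))
    })
    channels <- matrix(channels, nrow = nrow(raw), ncol = length(chan_cols),
                       dimnames = list(NULL, sub("^channel:", "", chan_cols)))
  }
  new_quant_table(design, meta, ratios, channels = channels,
                  normalized = FALSE)
}

#' Flag records from species outside an allowed list as contaminants
#'
#' Accession suffixes of the form `NAME_SPECIES` (UniProt style) are matched
#' against `allowed_species`; anything else is marked `is_contaminant`.
#' Accessions carrying no species tag are left untouched.
#'
#' @param table A `quant_table`.
#' @param allowed_species Character vector of species mnemonics (e.g.
#'   `c("DROME")`).
#' @return The table with updated `is_contaminant` flags.
#' @export
flag_species_contaminants <- function(table, allowed_species) {
  stopifnot(inherits(table, "quant_table"))
  tag <- sub("^.*_", "", table$meta$protein_id)
  has_tag <- grepl("_", table$meta$protein_id)
  foreign <- has_tag & !(tag %in% allowed_species)
  table$meta$is_contaminant <- table$meta$is_contaminant | foreign
  table
}

#' Remove decoy and contaminant records
#'
#' Drops reverse (decoy) database hits and contaminant entries before any
#' normalization, so abundant contaminants cannot shift the ratio medians.
#'
#' @param table A `quant_table`.
#' @return The filtered `quant_table`. Removal counts are reported via
#'   `message()`; an all-flagged input yields an empty table with a warning.
#' @export
filter_quant_table <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  drop <- table$meta$is_decoy | table$meta$is_contaminant
  message("filter_quant_table: removed ", sum(table$meta$is_decoy),
          " decoy and ", sum(table$meta$is_contaminant),
          " contaminant records (", sum(!drop), " retained)")
  if (all(drop)) warning("all records were flagged; table is empty")
  keep <- !drop
  table$meta <- table$meta[keep, , drop = FALSE]
  rownames(table$meta) <- NULL
  table$ratios <- table$ratios[keep, , drop = FALSE]
  if (!is.null(table$channels)) {
    table$channels <- table$channels[keep, , drop = FALSE]
  }
  table
}

#' Median-normalize log2 ratios per comparison
#'
#' Subtracts, within each comparison, the median of the observed log2 ratios
#' from every observed value, centering each comparison's ratio distribution
#' at zero. Missing cells are preserved. Idempotent.
#'
#' @param table A `quant_table` (decoys/contaminants should be removed
#'   first).
#' @return The table with `normalized = TRUE`. A comparison with no observed
#'   values is left untouched with a warning.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  for (cid in colnames(table$ratios)) {
    v <- table$ratios[, cid]
    if (all(is.na(v))) {
      warning("comparison ", cid, " has no observed ratios; left untouched")
      next
    }
    table$ratios[, cid] <- v - stats::median(v, na.rm = TRUE)
  }
  table$normalized <- TRUE
  table
}

#' Write a quant table back to TSV
#'
#' Emits the same schema [read_quant_table()] consumes (log2-scale ratios),
#' preceded by '#' provenance comment lines recording the data set and
#' normalization state.
#'
#' @param table A `quant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  out <- cbind(table$meta,
               as.data.frame(table$ratios, check.names = FALSE))
  if (!is.null(table$channels)) {
    chan <- as.data.frame(table$channels, check.names = FALSE)
    names(chan) <- paste0("channel:", names(chan))
    out <- cbind(out, chan)
  }
  # full-precision numeric formatting so the table round-trips exactly
  out[] <- lapply(out, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", formatC(col, digits = 17, format = "g"))
    } else if (is.logical(col)) {
      ifelse(col, "1", "0")
    } else {
      as.character(col)
    }
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dataset: ", table$design$dataset_name,
                    "; ratio_scale: log2; normalized: ",
                    tolower(as.character(table$normalized))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
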