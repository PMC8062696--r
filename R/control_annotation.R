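#' Assemble positive/negative control lists
#'
#' Positive controls (PC) are known secreted/receptor proteins; negative
#' controls (NC) are confidently intracellular proteins (mitochondrial,
#' cytoskeletal, nuclear transcription factors). Sources within a role are
#' unioned. Identifiers claimed by both roles are either removed from both
#' (`conflict_policy = "exclude"`, the default used for threshold
#' calibration, which keeps the purity metric well defined) or moved to a
#' third `other` category (`conflict_policy = "other"`, used by the
#' hemolymph-style presence-count analysis).
#'
#' @param pc_sources Named (or unnamed) list of character vectors of
#'   positive-control identifiers.
#' @param nc_sources Same, for negative controls.
#' @param conflict_policy `"exclude"` or `"other"`.
#' @return A `control_lists` object with elements `pc`, `nc`, `other`
#'   (character vectors) and a `provenance` data frame (source, role,
#'   n_ids).
#' @export
assemble_control_lists <- function(pc_sources, nc_sources,
                                   conflict_policy = c("exclude", "other")) {
  conflict_policy <- match.arg(conflict_policy)
  if (length(pc_sources) < 1L || length(nc_sources) < 1L) {
    stop("need at least one PC and one NC source", call. = FALSE)
  }
  if (is.character(pc_sources)) pc_sources <- list(pc_sources)
  if (is.character(nc_sources)) nc_sources <- list(nc_sources)
  name_or <- function(sources, prefix) {
    nm <- names(sources)
    if (is.null(nm)) nm <- rep("", length(sources))
    ifelse(nzchar(nm), nm, paste0(prefix, seq_along(sources)))
  }
  pc_names <- name_or(pc_sources, "pc_source")
  nc_names <- name_or(nc_sources, "nc_source")
  pc <- sort(unique(unlist(pc_sources, use.names = FALSE)))
  nc <- sort(unique(unlist(nc_sources, use.names = FALSE)))
  if (length(pc) == 0L) stop("PC union is empty", call. = FALSE)
  if (length(nc) == 0L) stop("NC union is empty", call. = FALSE)
  conflict <- intersect(pc, nc)
  pc <- setdiff(pc, conflict)
  nc <- setdiff(nc, conflict)
  other <- if (conflict_policy == "other") conflict else character(0)
  provenance <- data.frame(
    source_name = c(pc_names, nc_names),
    role = c(rep("PC", length(pc_sources)), rep("NC", length(nc_sources))),
    n_ids = c(vapply(pc_sources, function(x) length(unique(x)), integer(1)),
              vapply(nc_sources, function(x) length(unique(x)), integer(1))),
    stringsAsFactors = FALSE
  )
  structure(list(pc = pc, nc = nc, other = other, provenance = provenance,
                 conflict_policy = conflict_policy),
            class = "control_lists")
}

#' @export
print.control_lists <- function(x, ...) {
  cat("control_lists: ", length(x$pc), " PC, ", length(x$nc), " NC, ",
      length(x$other), " other (policy=", x$conflict_policy, ")\n", sep = "")
  invisible(x)
}

#' Categorize a protein against control lists
#'
#' @param protein_id Character vector of identifiers.
#' @param lists A `control_lists` object.
#' @return Character vector with values `"PC"`, `"NC"`, `"other"` or
#'   `"unassigned"`, one per input id.
#' @export
categorize <- function(protein_id, lists) {
  stopifnot(inherits(lists, "control_lists"))
  out <- rep("unassigned", length(protein_id))
  out[protein_id %in% lists$pc] <- "PC"
  out[protein_id %in% lists$nc] <- "NC"
  out[protein_id %in% lists$other] <- "other"
  out
}

#' Read a gene-list file
#'
#' One identifier per line; blank lines and '#' comments are ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Load a per-protein annotation table
#'
#' A TSV keyed by `protein_id` with boolean columns `signal_peptide`,
#' `er_resident`, `tm_domain`, `unconventional` (parsed leniently from
#' 1/0/yes/no/true/false/Y/N), a numeric `abundance_ppm` column
#' (whole-organism abundance, parts per million; empty = missing), and any
#' number of three-outcome tissue-expression columns prefixed `expr:` with
#' values `up`, `none` or `down`. All annotation columns are optional;
#' absent proteins simply lack rows. These annotations are consumed as
#' inputs (SignalP/TMHMM/UniProt/PAXdb-style exports); the pipeline never
#' runs the predictors itself.
#'
#' @param path File path.
#' @return A data frame (class `annotation_table`) keyed by `protein_id`.
#' @export
load_annotations <- function(path) {
  raw <- .read_delim_auto(path)
  if (!"protein_id" %in% names(raw)) {
    stop("annotation table must have a protein_id column", call. = FALSE)
  }
  out <- data.frame(protein_id = raw$protein_id, stringsAsFactors = FALSE)
  for (col in c("signal_peptide", "er_resident", "tm_domain",
                "unconventional")) {
    if (col %in% names(raw)) out[[col]] <- .as_logical_flag(raw[[col]], col)
  }
  if ("abundance_ppm" %in% names(raw)) {
    ab <- suppressWarnings(as.numeric(raw$abundance_ppm))
    bad <- !is.na(ab) & ab < 0
    if (any(bad)) {
      stop("negative abundance_ppm at row ", which(bad)[1L], call. = FALSE)
    }
    out$abundance_ppm <- ab
  }
  for (col in grep("^expr:", names(raw), value = TRUE)) {
    v <- trimws(raw[[col]])
    bad <- !(v %in% c("up", "none", "down", "", "NA"))
    if (any(bad)) {
      stop("invalid expression category in column '", col, "', row ",
           which(bad)[1L], ": '", v[bad][1L], "'", call. = FALSE)
    }
    v[v %in% c("", "NA")] <- NA
    out[[col]] <- v
  }
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table (TSV)
#' @param annotations An `annotation_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- as.data.frame(annotations)
  out[] <- lapply(out, function(col) {
    if (is.logical(col)) ifelse(col, "1", "0")
    else if (is.double(col))
      ifelse(is.na(col), "", formatC(col, digits = 17, format = "g"))
    else as.character(col)
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
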