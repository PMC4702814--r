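#' Subsite names, N- to C-terminal
#'
#' The eight Schechter-Berger subsites flanking a scissile bond: P4, P3, P2,
#' P1 on the N-terminal side, then P1', P2', P3', P4'. Cleavage occurs after
#' the P1 residue.
#'
#' @return Character vector of length 8.
#' @export
subsite_names <- function() {
  c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")
}

#' Standard amino-acid alphabet
#'
#' @return The 20 standard one-letter amino-acid codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Marker used for subsites overhanging a sequence terminus
#' @return A single character, \code{"-"}.
#' @export
boundary_marker <- function() "-"

#' Build a cleavage request
#'
#' A request names the peptidase responsible, the substrate accession, and
#' the residue number (1-based, from the substrate entry) after which
#' cleavage occurs -- the P1 residue.
#'
#' @param peptidase Identifier string or \code{merops_id} for the peptidase.
#' @param substrate_accession Substrate accession (UniProt-style).
#' @param p1_residue Positive integer residue number of P1.
#' @param line Optional source line number, kept for error reporting.
#' @return A \code{cleavage_request} object.
#' @export
#' @examples
#' cleavage_request("C01.034", "O15144", 68)
cleavage_request <- function(peptidase, substrate_accession, p1_residue,
                             line = NA_integer_) {
  peptidase <- as_merops_id(peptidase)
  if (!is.character(substrate_accession) || !nzchar(substrate_accession))
    stop("substrate_accession must be a non-empty string")
  p1_residue <- as.integer(p1_residue)
  if (is.na(p1_residue) || p1_residue < 1L)
    stop("p1_residue must be a positive integer")
  structure(
    list(peptidase = peptidase, substrate_accession = substrate_accession,
         p1_residue = p1_residue, line = as.integer(line)),
    class = "cleavage_request"
  )
}

#' @export
print.cleavage_request <- function(x, ...) {
  cat(sprintf("<cleavage_request> %s cleaves %s after residue %d\n",
              x$peptidase$text, x$substrate_accession, x$p1_residue))
  invisible(x)
}

#' Extract the P4-P4' octamer around a cleavage site
#'
#' Returns the eight residues at positions \code{p1_residue - 3} through
#' \code{p1_residue + 4} of the substrate, ordered P4..P1, P1'..P4'.
#' Positions falling outside the sequence (cleavage close to a terminus) are
#' filled with the boundary marker \code{"-"}, which can only form a
#' contiguous prefix or suffix of the octamer.
#'
#' @param sequence Amino-acid string.
#' @param p1_residue 1-based P1 residue number; cleavage occurs after it.
#' @return Character string of length 8.
#' @export
#' @examples
#' extract_octamer("MKWVTFISLL", 5)   # "KWVTFISL"
#' extract_octamer("MKWVTFISLL", 2)   # "--MKWVTF"
extract_octamer <- function(sequence, p1_residue) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  p1_residue <- as.integer(p1_residue)
  if (is.na(p1_residue) || p1_residue < 1L || p1_residue > n)
    stop(sprintf("p1_residue %s is outside the sequence (length %d)",
                 p1_residue, n))
  pos <- (p1_residue - 3L):(p1_residue + 4L)
  chars <- ifelse(pos >= 1L & pos <= n,
                  substring(sequence, pos, pos),
                  boundary_marker())
  paste(chars, collapse = "")
}

#' Split an octamer into named subsites
#'
#' @param octamer An 8-character octamer string.
#' @return Character vector of 8 single letters named by [subsite_names()].
#' @export
octamer_subsites <- function(octamer) {
  stopifnot(is.character(octamer), length(octamer) == 1L,
            nchar(octamer) == 8L)
  stats::setNames(strsplit(octamer, "")[[1]], subsite_names())
}

#' Categorise a cleavage
#'
#' A cleavage is \code{synthetic} if the substrate is a synthetic peptide;
#' \code{physiological} when peptidase and substrate come from the same
#' organism; \code{pathological} when the organisms differ and stand in a
#' pathogen-host relationship; otherwise \code{non_physiological} (e.g. an
#' in vitro cleavage across unrelated species).
#'
#' @param peptidase_organism,substrate_organism Organism names.
#' @param is_synthetic Logical; synthetic substrate flag (dominates).
#' @param is_pathogen_host Logical; do the two organisms form a
#'   pathogen-host pair?
#' @return One of \code{"synthetic"}, \code{"physiological"},
#'   \code{"pathological"}, \code{"non_physiological"}.
#' @export
#' @examples
#' categorise_cleavage("Homo sapiens", "Homo sapiens")   # physiological
#' categorise_cleavage("Staphylococcus aureus", "Homo sapiens",
#'                     is_pathogen_host = TRUE)          # pathological
categorise_cleavage <- function(peptidase_organism, substrate_organism,
                                is_synthetic = FALSE,
                                is_pathogen_host = FALSE) {
  if (isTRUE(is_synthetic)) return("synthetic")
  if (!nzchar(peptidase_organism) || !nzchar(substrate_organism))
    stop("organism names must be non-empty for non-synthetic cleavages")
  if (identical(peptidase_organism, substrate_organism)) return("physiological")
  if (isTRUE(is_pathogen_host)) return("pathological")
  "non_physiological"
}

#' Read a cleavage-request table
#'
#' Parses the tab-delimited upload dialect: one cleavage per line with at
#' least three fields -- peptidase identifier, substrate accession, P1
#' residue number. A first line whose third field is non-numeric is treated
#' as a header; blank lines are skipped. Errors report the offending line
#' number.
#'
#' @param path File path, or a character vector of lines via \code{text}.
#' @param text Optional character vector of raw lines (overrides
#'   \code{path}).
#' @return List of [cleavage_request()] objects in input order.
#' @export
read_request_table <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  requests <- list()
  first_data <- TRUE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]], which = "right")
    if (!nzchar(trimws(line))) next
    fields <- trimws(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields, found %d",
                   i, length(fields)))
    if (first_data && !grepl("^[0-9]+$", fields[[3]])) {
      first_data <- FALSE  # header row, tolerated once
      next
    }
    first_data <- FALSE
    if (!grepl("^[0-9]+$", fields[[3]]))
      stop(sprintf("line %d: residue number '%s' is not an integer",
                   i, fields[[3]]))
    req <- tryCatch(
      cleavage_request(fields[[1]], fields[[2]],
                       as.integer(fields[[3]]), line = i),
      merops_error = function(e)
        stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    )
    requests[[length(requests) + 1L]] <- req
  }
  requests
}

#' Write a cleavage-request table
#'
#' Inverse of [read_request_table()]: one tab-separated line per request
#' (identifier, accession, P1 residue), no header.
#'
#' @param requests List of [cleavage_request()] objects.
#' @param path Output file path; if \code{NULL}, lines are returned.
#' @return Invisibly (or visibly when \code{path} is \code{NULL}) the lines.
#' @export
write_request_table <- function(requests, path = NULL) {
  lines <- vapply(requests, function(r) {
    paste(r$peptidase$text, r$substrate_accession, r$p1_residue, sep = "\t")
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' URL for viewing a cleavage-site alignment
#'
#' Builds the alignment-view URL from the triple: substrate accession
#' (\code{acc}), peptidase identifier (\code{mid}) and P1 residue number
#' (\code{residue}).
#'
#' @param acc Substrate accession.
#' @param mid Peptidase identifier (string or \code{merops_id}).
#' @param residue P1 residue number.
#' @return URL string.
#' @export
#' @examples
#' merops_url("P01966", "A01.009", 25)
merops_url <- function(acc, mid, residue) {
  mid <- as_merops_id(mid)
  sprintf(
    "http://merops.sanger.ac.uk/cgi-bin/align_substrate?acc=%s;mid=%s;residue=%d",
    acc, mid$text, as.integer(residue))
}

report_table_header <- function() {
  c("MEROPS ID", "total cleavages", "UniProt Acc", "homologues in UniRef50",
    "cleavage", subsite_names(), "URL")
}

#' Write a conservation-report table
#'
#' Emits the tab-delimited results dialect, one row per scored cleavage:
#' peptidase identifier, total cleavages known for that peptidase, substrate
#' accession, homologue count, P1 residue, the eight per-subsite
#' unacceptable-replacement counts (P4..P4'), and the alignment URL.
#'
#' @param reports List of \code{conservation_report} objects from
#'   [score_site()].
#' @param path Output file path; if \code{NULL}, lines are returned.
#' @return Invisibly (or visibly when \code{path} is \code{NULL}) the lines,
#'   header included.
#' @export
write_report_table <- function(reports, path = NULL) {
  header <- paste(report_table_header(), collapse = "\t")
  rows <- vapply(reports, function(rep) {
    req <- rep$request
    paste(c(req$peptidase$text, rep$total_cleavages, req$substrate_accession,
            rep$homologue_count, req$p1_residue,
            unname(rep$counts[subsite_names()]),
            merops_url(req$substrate_accession, req$peptidase,
                       req$p1_residue)),
          collapse = "\t")
  }, character(1))
  lines <- c(header, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a cleavage-collection table
#'
#' Reads the tab-delimited collection dialect with header columns
#' \code{peptidase}, \code{substrate_accession}, \code{peptidase_organism},
#' \code{substrate_organism}, \code{p1}, \code{category}.
#'
#' @param path File path.
#' @return Data frame with those columns (identifiers canonicalised).
#' @export
read_cleavage_collection <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("peptidase", "substrate_accession", "peptidase_organism",
              "substrate_organism", "p1", "category")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("collection table is missing columns: ",
         paste(missing, collapse = ", "))
  df$peptidase <- vapply(df$peptidase,
                         function(x) parse_identifier(x)$text, character(1))
  df$p1 <- as.integer(df$p1)
  df
}

#' Write a cleavage-collection table
#'
#' @param collection Data frame as returned by [read_cleavage_collection()]
#'   or [synth_cleavage_collection()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_cleavage_collection <- function(collection, path) {
  cols <- c("peptidase", "substrate_accession", "peptidase_organism",
            "substrate_organism", "p1", "category")
  cols <- intersect(c(cols, "octamer"), names(collection))
  utils::write.table(collection[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach octamers to a cleavage collection
#'
#' Looks up each substrate accession in a set of sequences and extracts the
#' P4-P4' octamer at the recorded P1 position.
#'
#' @param collection Cleavage-collection data frame (see
#'   [read_cleavage_collection()]).
#' @param sequences Named character vector of substrate sequences keyed by
#'   accession (e.g. from [read_fasta()]).
#' @return The collection with an \code{octamer} column added.
#' @export
collection_octamers <- function(collection, sequences) {
  missing <- setdiff(unique(collection$substrate_accession), names(sequences))
  if (length(missing))
    stop("no sequence supplied for accession(s): ",
         paste(missing, collapse = ", "))
  collection$octamer <- mapply(function(acc, p1) {
    extract_octamer(sequences[[acc]], p1)
  }, collection$substrate_accession, collection$p1, USE.NAMES = FALSE)
  collection
}
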