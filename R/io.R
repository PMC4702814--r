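#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector; names are truncated at the first
#'   whitespace (accession only).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a homologue alignment from aligned FASTA
#'
#' @param path Aligned FASTA path (gap character \code{"-"}).
#' @param reference_id Reference row id; defaults to the first record.
#' @return A [homologue_alignment()].
#' @export
read_alignment_fasta <- function(path, reference_id = NULL) {
  seqs <- read_fasta(path)
  if (is.null(reference_id)) reference_id <- names(seqs)[[1]]
  homologue_alignment(seqs, reference_id)
}

#' Write a homologue alignment to aligned FASTA
#'
#' @param alignment A [homologue_alignment()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  write_fasta(alignment$sequences, path)
}

#' Read family metadata and sequences
#'
#' Combines a family FASTA with a metadata TSV (columns \code{id},
#' \code{species}, \code{phylum}, optionally \code{gene_id},
#' \code{tandem_duplicate}, \code{is_holotype}, \code{merops_id},
#' \code{activity}) into a family table.
#'
#' @param fasta_path Family FASTA path.
#' @param metadata_path Metadata TSV path.
#' @return Family data frame (see [family_table()]).
#' @export
read_family <- function(fasta_path, metadata_path) {
  seqs <- read_fasta(fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("id", "species", "phylum") %in% names(meta)))
    stop("metadata must have at least id, species and phylum columns")
  missing <- setdiff(meta$id, names(seqs))
  if (length(missing))
    stop("metadata rows without sequences: ", paste(missing, collapse = ", "))
  get <- function(col, default) {
    if (col %in% names(meta)) meta[[col]] else default
  }
  family_table(
    id = meta$id, residues = unname(seqs[meta$id]),
    species = meta$species, phylum = meta$phylum,
    gene_id = get("gene_id", NA_character_),
    tandem_duplicate = as.logical(get("tandem_duplicate", FALSE)),
    is_holotype = as.logical(get("is_holotype", FALSE)),
    merops_id = get("merops_id", NA_character_),
    activity = get("activity", "unknown"))
}

#' Read an active-site annotation table
#'
#' TSV with columns \code{holotype_id}, \code{position}, \code{residue},
#' \code{role}, \code{essential}.
#'
#' @param path TSV path.
#' @return Named list of annotation tables, one per holotype id.
#' @export
read_active_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("holotype_id", "position", "residue", "role", "essential")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("annotation table is missing columns: ",
         paste(missing, collapse = ", "))
  lapply(split(df, df$holotype_id), function(d) {
    d <- d[order(d$position), ]
    active_site_annotation(d$position, d$residue, d$role,
                           as.logical(d$essential))
  })
}

#' Write an identifier-assignment table
#'
#' @param assignments Data frame from [assign_identifiers()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_assignment_table <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a merge log
#'
#' @param log Data frame from [merge_near_duplicates()]'s \code{log}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_merge_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a family's sequences as a FASTA library
#'
#' @param family Family data frame.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_family_fasta <- function(family, path) {
  write_fasta(stats::setNames(family$residues, family$id), path)
}
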