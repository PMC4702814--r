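#' Build a subsite acceptance profile for one peptidase
#'
#' For each of the eight subsites P4-P4', the profile records the set of
#' amino acids observed at that subsite across every known cleavage of the
#' peptidase. An amino acid never seen in a pocket is later treated as an
#' "unacceptable replacement" when it appears there in a substrate
#' homologue. Boundary markers and ambiguity codes (B, J, O, U, X, Z -- any
#' letter outside the 20 standard codes) contribute nothing to the sets.
#'
#' @param records Data frame of cleavage records with columns
#'   \code{peptidase} (identifier text) and \code{octamer} (8-character
#'   P4-P4' string); typically a collection subset for one peptidase.
#' @param peptidase Optional identifier; required when \code{records} is
#'   empty, checked against the records otherwise.
#' @return A \code{specificity_profile}: list with \code{peptidase}
#'   (canonical text), \code{pockets} (named list of 8 character vectors)
#'   and \code{total_cleavages}.
#' @export
#' @examples
#' recs <- data.frame(peptidase = "S01.001",
#'                    octamer = c("GGGKSGGG", "GGGRSGGG"))
#' p <- build_profile(recs)
#' p$pockets[["P1"]]   # "K" "R"
build_profile <- function(records, peptidase = NULL) {
  if (!is.null(peptidase)) peptidase <- as_merops_id(peptidase)$text
  if (is.null(records) || nrow(records) == 0L) {
    if (is.null(peptidase))
      stop("peptidase must be given when no records are supplied")
    pockets <- stats::setNames(
      rep(list(character(0)), 8L), subsite_names())
    return(structure(list(peptidase = peptidase, pockets = pockets,
                          total_cleavages = 0L),
                     class = "specificity_profile"))
  }
  ids <- unique(vapply(records$peptidase,
                       function(x) as_merops_id(x)$text, character(1)))
  if (length(ids) != 1L)
    stop("records mix peptidase identifiers: ", paste(ids, collapse = ", "))
  if (!is.null(peptidase) && !identical(peptidase, ids))
    stop(sprintf("records are for %s, not %s", ids, peptidase))
  bad <- nchar(records$octamer) != 8L
  if (any(bad))
    stop("octamers must be 8 characters long; offending row(s): ",
         paste(which(bad), collapse = ", "))
  mat <- do.call(rbind, strsplit(records$octamer, ""))
  pockets <- lapply(seq_len(8L), function(s) {
    sort(unique(mat[mat[, s] %in% amino_acids(), s]))
  })
  names(pockets) <- subsite_names()
  structure(
    list(peptidase = ids, pockets = pockets,
         total_cleavages = nrow(records)),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf("<specificity_profile> %s  (%d cleavages, evidence %s)\n",
              x$peptidase, x$total_cleavages, evidence_level(x)))
  for (s in subsite_names()) {
    cat(sprintf("  %-4s {%s}\n", s, paste(x$pockets[[s]], collapse = "")))
  }
  invisible(x)
}

#' Is an amino acid acceptable at a subsite?
#'
#' True iff the amino acid has been observed at that subsite in at least one
#' recorded cleavage of the profiled peptidase. Everything outside the
#' pocket set -- including ambiguity codes and non-standard letters -- is
#' unacceptable.
#'
#' @param profile A \code{specificity_profile}.
#' @param subsite One of [subsite_names()].
#' @param amino_acid A single residue letter.
#' @return Logical scalar.
#' @export
is_acceptable <- function(profile, subsite, amino_acid) {
  stopifnot(inherits(profile, "specificity_profile"))
  if (!subsite %in% subsite_names())
    stop(sprintf("'%s' is not a subsite (expected one of %s)",
                 subsite, paste(subsite_names(), collapse = ", ")))
  amino_acid %in% profile$pockets[[subsite]]
}

#' Evidence level of a profile
#'
#' Profiles built from few cleavages say little about what a pocket will
#' tolerate, so downstream calls are flagged. The default threshold of 10
#' separates sparsely characterised peptidases (e.g. 6 known cleavages) from
#' adequately characterised ones (e.g. 24).
#'
#' @param profile A \code{specificity_profile}.
#' @param threshold Minimum cleavage count for \code{"adequate"}.
#' @return \code{"low"} or \code{"adequate"}.
#' @export
evidence_level <- function(profile, threshold = 10L) {
  stopifnot(inherits(profile, "specificity_profile"))
  if (profile$total_cleavages < threshold) "low" else "adequate"
}

#' Export a profile as JSON
#'
#' @param profile A \code{specificity_profile}.
#' @param path Output path; if \code{NULL} the JSON string is returned.
#' @return JSON text (invisibly when written to \code{path}).
#' @export
export_profile <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "specificity_profile"))
  obj <- list(peptidase = profile$peptidase,
              total_cleavages = profile$total_cleavages,
              pockets = lapply(profile$pockets, as.list))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
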