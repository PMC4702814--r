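#' Construct a homologue alignment
#'
#' A gapped multiple alignment of substrate homologues with one row
#' designated as the reference (the substrate in which the cleavage was
#' observed). Rows must be equal length and ids unique.
#'
#' @param sequences Named character vector of aligned rows (gap \code{"-"}).
#' @param reference_id Name of the reference row.
#' @return A \code{homologue_alignment}.
#' @export
#' @examples
#' aln <- homologue_alignment(c(REF = "MKWVTFISLL", H1 = "MKWVSFISLL"), "REF")
homologue_alignment <- function(sequences, reference_id) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all alignment rows must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence ids in alignment: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L || widths[[1]] < 1L)
    stop("aligned rows must all have the same positive length")
  if (!reference_id %in% names(sequences))
    stop(sprintf("reference id '%s' is not a row of the alignment",
                 reference_id))
  structure(
    list(sequences = sequences, reference_id = reference_id,
         width = unname(widths[[1]])),
    class = "homologue_alignment"
  )
}

#' @export
print.homologue_alignment <- function(x, ...) {
  cat(sprintf("<homologue_alignment> %d rows x %d columns (reference %s)\n",
              length(x$sequences), x$width, x$reference_id))
  invisible(x)
}

#' Ungapped length of the reference row
#' @param alignment A \code{homologue_alignment}.
#' @return Integer count of non-gap symbols in the reference row.
#' @export
reference_length <- function(alignment) {
  stopifnot(inherits(alignment, "homologue_alignment"))
  ref <- alignment$sequences[[alignment$reference_id]]
  sum(strsplit(ref, "")[[1]] != "-")
}

#' Map a reference residue number to an alignment column
#'
#' Residue numbers come from the ungapped substrate entry; this returns the
#' 1-based alignment column holding the \code{residue_number}-th non-gap
#' symbol of the reference row.
#'
#' @param alignment A \code{homologue_alignment}.
#' @param residue_number 1-based residue number in the ungapped reference.
#' @return Integer column index.
#' @export
#' @examples
#' aln <- homologue_alignment(c(R = "AB-CD", H = "ABXCD"), "R")
#' map_residue_to_column(aln, 3)   # 4
map_residue_to_column <- function(alignment, residue_number) {
  stopifnot(inherits(alignment, "homologue_alignment"))
  residue_number <- as.integer(residue_number)
  ref <- strsplit(alignment$sequences[[alignment$reference_id]], "")[[1]]
  non_gap <- which(ref != "-")
  if (is.na(residue_number) || residue_number < 1L ||
      residue_number > length(non_gap))
    stop(sprintf(
      "residue %s is outside the reference '%s' (ungapped length %d)",
      residue_number, alignment$reference_id, length(non_gap)))
  non_gap[[residue_number]]
}

#' Default thresholds for the qualitative call
#'
#' @param unacceptable_fraction Per-subsite fraction of homologues with
#'   unacceptable replacements above which a subsite counts as degraded.
#' @param degraded_subsites Number of degraded subsites at or above which
#'   the site is called unlikely to be physiological.
#' @param conserved_tolerance Per-subsite fraction of homologues with
#'   unacceptable replacements up to which a site still counts as well
#'   conserved.
#' @param low_evidence Minimum cleavage count for an adequate-evidence
#'   profile (see [evidence_level()]).
#' @return Named list of the four thresholds.
#' @export
call_thresholds <- function(unacceptable_fraction = 0.25,
                            degraded_subsites = 3L,
                            conserved_tolerance = 0.05,
                            low_evidence = 10L) {
  list(unacceptable_fraction = unacceptable_fraction,
       degraded_subsites = as.integer(degraded_subsites),
       conserved_tolerance = conserved_tolerance,
       low_evidence = as.integer(low_evidence))
}

#' Score a cleavage site against a homologue alignment
#'
#' Locates the eight subsite columns (P4 = P1 residue minus 3 ... P4' = P1
#' residue plus 4) in the alignment via the reference row, then classifies
#' the symbol of every non-reference row at each column: equal to the
#' reference residue is \code{conserved}; a gap is \code{gap}; otherwise the
#' residue is an \code{acceptable_replacement} if the profile has seen it in
#' that pocket and an \code{unacceptable_replacement} if not. Per-subsite
#' mismatch counts tally unacceptable cells only (plus gaps when
#' \code{count_gaps} is set). Subsites overhanging the reference termini
#' score no cells and count zero.
#'
#' @param alignment A \code{homologue_alignment} whose reference id equals
#'   the request's substrate accession.
#' @param request A [cleavage_request()] for the same substrate.
#' @param profile The [build_profile()] result for the request's peptidase.
#' @param count_gaps Count gap cells as mismatches (default \code{FALSE}:
#'   only amino-acid replacements can be unacceptable).
#' @param thresholds See [call_thresholds()].
#' @param octamer Optional 8-character octamer for a consistency check: any
#'   non-boundary symbol that disagrees with the reference residue at the
#'   scored column is a hard error.
#' @return A \code{conservation_report}: request, homologue_count, per-
#'   subsite \code{counts}, \code{cells} classification matrix (homologues x
#'   subsites, \code{NA} where unscored), scored alignment \code{columns},
#'   reference residues, \code{total_cleavages}, \code{evidence},
#'   \code{raw_call} and final \code{call}.
#' @export
score_site <- function(alignment, request, profile, count_gaps = FALSE,
                       thresholds = call_thresholds(), octamer = NULL) {
  stopifnot(inherits(alignment, "homologue_alignment"),
            inherits(request, "cleavage_request"),
            inherits(profile, "specificity_profile"))
  if (!identical(alignment$reference_id, request$substrate_accession))
    stop(sprintf("alignment reference '%s' does not match request substrate '%s'",
                 alignment$reference_id, request$substrate_accession))
  if (!identical(profile$peptidase, request$peptidase$text))
    stop(sprintf("profile is for %s but the request names %s",
                 profile$peptidase, request$peptidase$text))
  ref_chars <- strsplit(alignment$sequences[[alignment$reference_id]], "")[[1]]
  non_gap <- which(ref_chars != "-")
  ref_len <- length(non_gap)
  p1 <- request$p1_residue
  if (p1 > ref_len)
    stop(sprintf("P1 residue %d is outside the reference (ungapped length %d)",
                 p1, ref_len))
  hom_ids <- setdiff(names(alignment$sequences), alignment$reference_id)
  hom_mat <- do.call(rbind, strsplit(alignment$sequences[hom_ids], ""))
  subsites <- subsite_names()
  columns <- stats::setNames(rep(NA_integer_, 8L), subsites)
  ref_res <- stats::setNames(rep(NA_character_, 8L), subsites)
  cells <- matrix(NA_character_, nrow = length(hom_ids), ncol = 8L,
                  dimnames = list(hom_ids, subsites))
  counts <- stats::setNames(integer(8L), subsites)
  for (i in seq_len(8L)) {
    resnum <- p1 - 4L + i
    if (resnum < 1L || resnum > ref_len) next  # overhangs a terminus
    col <- non_gap[[resnum]]
    columns[[i]] <- col
    ref_letter <- ref_chars[[col]]
    ref_res[[i]] <- ref_letter
    if (!is.null(octamer)) {
      oct <- substring(octamer, i, i)
      if (oct != boundary_marker() && oct != ref_letter)
        stop(sprintf(
          "stored octamer has '%s' at %s but the reference shows '%s' (column %d)",
          oct, subsites[[i]], ref_letter, col))
    }
    if (length(hom_ids)) {
      sym <- hom_mat[, col]
      cls <- ifelse(sym == "-", "gap",
             ifelse(sym == ref_letter, "conserved",
             ifelse(vapply(sym, function(a)
                      is_acceptable(profile, subsites[[i]], a), logical(1)),
                    "acceptable_replacement", "unacceptable_replacement")))
      cells[, i] <- cls
      counts[[i]] <- sum(cls == "unacceptable_replacement") +
        if (isTRUE(count_gaps)) sum(cls == "gap") else 0L
    }
  }
  report <- structure(
    list(request = request, peptidase = profile$peptidase,
         homologue_count = length(hom_ids), counts = counts, cells = cells,
         columns = columns, reference_residues = ref_res,
         total_cleavages = profile$total_cleavages,
         evidence = evidence_level(profile, thresholds$low_evidence),
         count_gaps = isTRUE(count_gaps), thresholds = thresholds,
         raw_call = NA_character_, call = NA_character_),
    class = "conservation_report"
  )
  report$raw_call <- call_site(report, thresholds, apply_evidence = FALSE)
  report$call <- call_site(report, thresholds)
  report
}

#' Qualitative call for a scored site
#'
#' A site is \code{unlikely_physiological} when the fraction of homologues
#' carrying an unacceptable replacement exceeds
#' \code{unacceptable_fraction} in at least \code{degraded_subsites}
#' subsites; \code{likely_physiological} when every subsite count is within
#' \code{conserved_tolerance} of the homologue count; otherwise
#' \code{indeterminate}. A low-evidence profile forces the final call to
#' \code{indeterminate} regardless (the raw call is kept on the report).
#'
#' @param report A \code{conservation_report}.
#' @param thresholds See [call_thresholds()].
#' @param apply_evidence Force \code{indeterminate} under low evidence.
#' @return One of \code{"likely_physiological"},
#'   \code{"unlikely_physiological"}, \code{"indeterminate"}.
#' @export
call_site <- function(report, thresholds = call_thresholds(),
                      apply_evidence = TRUE) {
  stopifnot(inherits(report, "conservation_report"))
  if (apply_evidence && identical(report$evidence, "low"))
    return("indeterminate")
  n <- report$homologue_count
  if (n == 0L) return("indeterminate")
  frac <- report$counts / n
  scored <- !is.na(report$columns)
  if (sum(frac[scored] > thresholds$unacceptable_fraction) >=
      thresholds$degraded_subsites)
    return("unlikely_physiological")
  if (all(report$counts[scored] <= thresholds$conserved_tolerance * n))
    return("likely_physiological")
  "indeterminate"
}

#' @export
print.conservation_report <- function(x, ...) {
  req <- x$request
  cat(sprintf("<conservation_report> %s on %s after residue %d\n",
              x$peptidase, req$substrate_accession, req$p1_residue))
  cat(sprintf("  homologues %d, total cleavages %d (evidence %s)\n",
              x$homologue_count, x$total_cleavages, x$evidence))
  cat("  unacceptable replacements: ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  call: %s (raw: %s)\n", x$call, x$raw_call))
  invisible(x)
}
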