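#' Alignment scoring configuration
#'
#' Parameters for the built-in pairwise local aligner: substitution matrix
#' name (any matrix shipped with Biostrings, default BLOSUM62) and affine
#' gap penalties.
#'
#' @param matrix Substitution matrix name.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return Named list of scoring parameters.
#' @export
align_config <- function(matrix = "BLOSUM62", gap_opening = 10,
                         gap_extension = 0.5) {
  list(matrix = matrix, gap_opening = gap_opening,
       gap_extension = gap_extension)
}

#' Construct a pairwise hit
#'
#' The exchange format between aligners and the classification procedures.
#' The built-in [pairwise_align()] produces these; an external search tool
#' can be plugged in through an adapter that populates the same fields.
#' Identity is defined as identical aligned pairs over aligned (non-gap)
#' pairs.
#'
#' @param query_id,target_id Sequence identifiers.
#' @param identity Fraction in [0, 1].
#' @param score Alignment score.
#' @param e_value E-value, or \code{NA} when the backend supplies none.
#' @param aligned_pairs Two-column integer matrix of (query_pos,
#'   target_pos) aligned residue pairs; may be 0-row.
#' @param n_identical,n_aligned Pair counts behind \code{identity}.
#' @return A \code{pairwise_hit}.
#' @export
pairwise_hit <- function(query_id, target_id, identity, score,
                         e_value = NA_real_,
                         aligned_pairs = matrix(integer(0), ncol = 2),
                         n_identical = NA_integer_,
                         n_aligned = NA_integer_) {
  stopifnot(identity >= 0, identity <= 1)
  structure(
    list(query_id = query_id, target_id = target_id,
         identity = identity, score = score, e_value = e_value,
         aligned_pairs = aligned_pairs,
         n_identical = as.integer(n_identical),
         n_aligned = as.integer(n_aligned)),
    class = "pairwise_hit"
  )
}

#' @export
print.pairwise_hit <- function(x, ...) {
  cat(sprintf("<pairwise_hit> %s vs %s: identity %.3f (%s/%s), score %.1f\n",
              x$query_id, x$target_id, x$identity,
              x$n_identical, x$n_aligned, x$score))
  invisible(x)
}

#' Pairwise local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps (via Biostrings) under a
#' standard substitution matrix. Identity is the fraction of aligned
#' (non-gap) residue pairs that are identical; a pair of sequences with no
#' positive-scoring local alignment yields identity 0 over 0 aligned pairs.
#'
#' @param query,target Amino-acid strings.
#' @param query_id,target_id Identifiers carried into the hit.
#' @param config See [align_config()].
#' @return A [pairwise_hit()].
#' @export
#' @examples
#' pairwise_align("ACDEFGHIK", "ACDEFGHIR")$identity   # 8/9
pairwise_align <- function(query, target, query_id = "query",
                           target_id = "target", config = align_config()) {
  if (!nzchar(query) || !nzchar(target))
    stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = config$matrix,
    gapOpening = config$gap_opening, gapExtension = config$gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  tpos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("query", "target")))
  n_id <- 0L
  if (length(p) && Biostrings::score(pa) > 0) {
    qs <- ts <- integer(length(p))
    keep <- logical(length(p))
    for (k in seq_along(p)) {
      if (p[[k]] != "-") qpos <- qpos + 1L
      if (s[[k]] != "-") tpos <- tpos + 1L
      if (p[[k]] != "-" && s[[k]] != "-") {
        keep[[k]] <- TRUE
        qs[[k]] <- qpos
        ts[[k]] <- tpos
        if (p[[k]] == s[[k]]) n_id <- n_id + 1L
      }
    }
    pairs <- cbind(query = qs[keep], target = ts[keep])
  }
  n_aln <- nrow(pairs)
  pairwise_hit(query_id, target_id,
               identity = if (n_aln > 0L) n_id / n_aln else 0,
               score = Biostrings::score(pa), e_value = NA_real_,
               aligned_pairs = pairs, n_identical = n_id,
               n_aligned = n_aln)
}
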