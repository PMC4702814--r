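#' Construct a family table of sequence records
#'
#' Families are handled as data frames with one row per sequence record:
#' \code{id}, \code{species}, \code{phylum}, \code{gene_id} (\code{NA} when
#' unknown), \code{tandem_duplicate} flag, \code{residues}, \code{is_holotype}
#' flag, \code{merops_id} (canonical text or \code{NA}) and \code{activity}
#' (\code{active}, \code{non_peptidase_homologue}, \code{fragment} or
#' \code{unknown}).
#'
#' @param id,residues Required character vectors.
#' @param species,phylum,gene_id,merops_id Optional character vectors.
#' @param tandem_duplicate,is_holotype Optional logical vectors.
#' @param activity Optional character vector.
#' @return Data frame with the columns above.
#' @export
family_table <- function(id, residues, species = "unknown",
                         phylum = "unknown", gene_id = NA_character_,
                         tandem_duplicate = FALSE, is_holotype = FALSE,
                         merops_id = NA_character_, activity = "unknown") {
  stopifnot(length(id) == length(residues), !anyDuplicated(id),
            all(nzchar(residues)))
  df <- data.frame(id = id, species = species, phylum = phylum,
                   gene_id = gene_id, tandem_duplicate = tandem_duplicate,
                   residues = residues, is_holotype = is_holotype,
                   merops_id = merops_id, activity = activity,
                   stringsAsFactors = FALSE)
  bad <- df$is_holotype & is.na(df$merops_id)
  if (any(bad))
    stop("holotypes must carry an identifier: ",
         paste(df$id[bad], collapse = ", "))
  ok_act <- c("active", "non_peptidase_homologue", "fragment", "unknown")
  if (!all(df$activity %in% ok_act))
    stop("activity must be one of: ", paste(ok_act, collapse = ", "))
  df
}

default_aligner <- function(config = align_config()) {
  function(query, target, query_id, target_id) {
    pairwise_align(query, target, query_id, target_id, config)
  }
}

# rank hits: lowest E-value when any backend supplies one, else highest
# score; ties broken by highest identity, then lexicographic target id
order_hits <- function(hits) {
  e <- vapply(hits, function(h) h$e_value, numeric(1))
  s <- vapply(hits, function(h) h$score, numeric(1))
  i <- vapply(hits, function(h) h$identity, numeric(1))
  t <- vapply(hits, function(h) h$target_id, character(1))
  if (any(!is.na(e))) {
    e[is.na(e)] <- Inf
    order(e, -i, t)
  } else {
    order(-s, -i, t)
  }
}

#' Assign identifiers by nearest holotype
#'
#' Every record in the family is matched against every holotype; the best
#' holotype is the one with the lowest E-value (when the aligner reports
#' E-values; otherwise the highest alignment score, ties broken by identity
#' then holotype id). The holotype's identifier is assigned when the
#' sequence identity to it is at least \code{min_identity} (default 40%);
#' below that the record stays unassigned.
#'
#' @param family Family data frame (see [family_table()]); must contain at
#'   least one holotype.
#' @param aligner Function \code{(query, target, query_id, target_id)}
#'   returning a [pairwise_hit()]; defaults to the built-in local aligner.
#'   Replace it to adapt an external search tool.
#' @param min_identity Assignment threshold on identity (inclusive).
#' @param hits Optional precomputed hits: list of [pairwise_hit()] objects
#'   covering every (record, holotype) pair, used instead of \code{aligner}.
#' @return Data frame with columns \code{id}, \code{assigned} (identifier
#'   text or \code{NA}), \code{best_holotype}, \code{identity}.
#' @export
assign_identifiers <- function(family, aligner = default_aligner(),
                               min_identity = 0.40, hits = NULL) {
  holos <- family[family$is_holotype, , drop = FALSE]
  if (nrow(holos) == 0L)
    stop("family contains no holotype; cannot assign identifiers")
  holos <- holos[order(holos$id), , drop = FALSE]
  if (!is.null(hits)) {
    key <- vapply(hits, function(h) paste(h$query_id, h$target_id),
                  character(1))
    hit_index <- stats::setNames(seq_along(hits), key)
  }
  res <- lapply(seq_len(nrow(family)), function(r) {
    rec <- family[r, ]
    rec_hits <- lapply(seq_len(nrow(holos)), function(j) {
      if (!is.null(hits)) {
        k <- paste(rec$id, holos$id[j])
        if (is.na(hit_index[k]))
          stop(sprintf("no precomputed hit for (%s, %s)", rec$id, holos$id[j]))
        hits[[hit_index[[k]]]]
      } else {
        aligner(rec$residues, holos$residues[j], rec$id, holos$id[j])
      }
    })
    best <- rec_hits[[order_hits(rec_hits)[1]]]
    j <- match(best$target_id, holos$id)
    data.frame(id = rec$id,
               assigned = if (best$identity >= min_identity)
                 holos$merops_id[j] else NA_character_,
               best_holotype = holos$id[j],
               identity = best$identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Merge near-duplicate records in a family
#'
#' Two records qualify for merging when their pairwise identity is strictly
#' greater than \code{identity_threshold} (default: greater than 94%), they
#' come from the same species, they are not known products of different
#' genes (two distinct non-missing \code{gene_id}s block the merge), they
#' are not both flagged as tandem duplicates in the same genome, and their
#' length ratio (shorter/longer) is at least \code{min_length_ratio} (so a
#' short identical fragment does not absorb a full-length record).
#' Qualifying pairs are clustered by single linkage to a fixed point; each
#' cluster keeps its longest member (ties broken by id).
#'
#' @param family Family data frame (see [family_table()]).
#' @param aligner As in [assign_identifiers()].
#' @param identity_threshold Strict lower bound on identity for merging.
#' @param min_length_ratio Shorter/longer length guard.
#' @param hits Optional precomputed list of [pairwise_hit()] covering the
#'   candidate pairs (same species); missing pairs are treated as
#'   non-qualifying.
#' @return List with \code{family} (merged table) and \code{log} (data
#'   frame of \code{kept}, \code{removed}, \code{identity}).
#' @export
merge_near_duplicates <- function(family, aligner = default_aligner(),
                                  identity_threshold = 0.94,
                                  min_length_ratio = 0.8, hits = NULL) {
  n <- nrow(family)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pair_identity <- matrix(NA_real_, n, n)
  if (!is.null(hits)) {
    key <- vapply(hits, function(h) paste(h$query_id, h$target_id),
                  character(1))
    hit_index <- stats::setNames(seq_along(hits), key)
  }
  log_rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- family[i, ]; b <- family[j, ]
      if (!identical(a$species, b$species)) next
      if (!is.na(a$gene_id) && !is.na(b$gene_id) &&
          !identical(a$gene_id, b$gene_id)) next
      if (isTRUE(a$tandem_duplicate) && isTRUE(b$tandem_duplicate)) next
      len <- nchar(c(a$residues, b$residues))
      if (min(len) / max(len) < min_length_ratio) next
      ident <- if (!is.null(hits)) {
        k1 <- paste(a$id, b$id); k2 <- paste(b$id, a$id)
        idx <- c(hit_index[k1], hit_index[k2])
        idx <- idx[!is.na(idx)]
        if (!length(idx)) next
        hits[[idx[[1]]]]$identity
      } else {
        aligner(a$residues, b$residues, a$id, b$id)$identity
      }
      pair_identity[i, j] <- ident
      if (ident > identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (root in unique(roots)) {
    members <- which(roots == root)
    lens <- nchar(family$residues[members])
    rep_i <- members[order(-lens, family$id[members])][1]
    keep[rep_i] <- TRUE
    for (m in setdiff(members, rep_i)) {
      ident <- max(pair_identity[rep_i, m], pair_identity[m, rep_i],
                   na.rm = TRUE)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        kept = family$id[rep_i], removed = family$id[m],
        identity = if (is.finite(ident)) ident else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(family = family[keep, , drop = FALSE],
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(kept = character(0), removed = character(0),
                             identity = numeric(0)))
}

#' Build an active-site annotation table
#'
#' @param position Integer positions in the holotype sequence, strictly
#'   increasing.
#' @param residue Residue letters at those positions.
#' @param role \code{"catalytic"} or \code{"metal_ligand"}.
#' @param essential Logical; residues whose loss abolishes activity.
#' @return Data frame with the four columns.
#' @export
active_site_annotation <- function(position, residue,
                                   role = "catalytic", essential = TRUE) {
  position <- as.integer(position)
  if (is.unsorted(position, strictly = TRUE))
    stop("annotation positions must be strictly increasing")
  if (!all(role %in% c("catalytic", "metal_ligand")))
    stop("role must be 'catalytic' or 'metal_ligand'")
  data.frame(position = position, residue = residue, role = role,
             essential = essential, stringsAsFactors = FALSE)
}

#' Transfer active-site residues from a holotype to a homologue
#'
#' Projects every annotated holotype position through the aligned pairs of a
#' pairwise hit. A projected residue is conserved when the target letter
#' equals the holotype letter, or belongs to the configured
#' conservative-substitution set for its role. The target is predicted
#' \code{active} if and only if every essential residue is both aligned and
#' conserved; otherwise it is a \code{non_peptidase_homologue}. Unaligned
#' essential positions count as not conserved. Applying this to records
#' previously classed as non-peptidase homologues reclassifies those whose
#' essential residues all turn out to be conserved.
#'
#' @param holotype Holotype record: list or one-row data frame with
#'   \code{id} and \code{residues}.
#' @param annotation Annotation table (see [active_site_annotation()]);
#'   residue letters must match the holotype sequence.
#' @param hit A [pairwise_hit()] aligning the holotype (query) to the
#'   target (subject).
#' @param target Target record with \code{id} and \code{residues}.
#' @param conservative Named list of allowed substitutions per role, e.g.
#'   \code{list(metal_ligand = c("D", "E"))}; empty by default (strict
#'   identity).
#' @return List with \code{annotation} (the table plus
#'   \code{target_position}, \code{target_residue}, \code{aligned},
#'   \code{conserved}) and \code{activity}.
#' @export
transfer_active_sites <- function(holotype, annotation, hit, target,
                                  conservative = list()) {
  holo_seq <- holotype$residues
  if (any(annotation$position > nchar(holo_seq)))
    stop("annotation positions fall outside the holotype sequence")
  holo_letters <- substring(holo_seq, annotation$position,
                            annotation$position)
  if (!all(holo_letters == annotation$residue))
    stop("annotation residues disagree with the holotype sequence at position(s): ",
         paste(annotation$position[holo_letters != annotation$residue],
               collapse = ", "))
  pairs <- hit$aligned_pairs
  tpos <- pairs[match(annotation$position, pairs[, 1]), 2]
  aligned <- !is.na(tpos)
  tres <- ifelse(aligned, substring(target$residues, tpos, tpos),
                 NA_character_)
  conserved <- vapply(seq_len(nrow(annotation)), function(k) {
    if (!aligned[[k]]) return(FALSE)
    allowed <- c(annotation$residue[[k]],
                 conservative[[annotation$role[[k]]]])
    tres[[k]] %in% allowed
  }, logical(1))
  out <- annotation
  out$target_position <- tpos
  out$target_residue <- tres
  out$aligned <- aligned
  out$conserved <- conserved
  essential <- out$essential
  activity <- if (all(conserved[essential])) "active"
              else "non_peptidase_homologue"
  list(annotation = out, activity = activity)
}

#' Select a representative set for a large family
#'
#' Families are shown in full up to \code{limit} sequences (default 200).
#' Above that, the representative set contains every holotype plus, for
#' each phylum with at least one member predicted to be an active
#' peptidase, one such member (the longest; ties broken by id). Fragments
#' and non-peptidase homologues never serve as phylum representatives, and
#' a phylum whose members are all inactive contributes none.
#'
#' @param family Family data frame (see [family_table()]).
#' @param limit Size above which the family is reduced.
#' @return Subset of \code{family} rows (all of them when at or below the
#'   limit), without duplicates.
#' @export
select_representatives <- function(family, limit = 200L) {
  if (nrow(family) <= limit) return(family)
  chosen <- family$id[family$is_holotype]
  active <- family[family$activity == "active", , drop = FALSE]
  for (ph in unique(active$phylum)) {
    cand <- active[active$phylum == ph, , drop = FALSE]
    pick <- cand$id[order(-nchar(cand$residues), cand$id)][1]
    chosen <- union(chosen, pick)
  }
  family[family$id %in% chosen, , drop = FALSE]
}
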