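# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

pick1 <- function(x) x[[sample.int(length(x), 1L)]]

mutate_chars <- function(chars, sub_prob, indel_prob = 0) {
  hit <- stats::runif(length(chars)) < sub_prob
  for (k in which(hit)) {
    chars[[k]] <- pick1(setdiff(amino_acids(), chars[[k]]))
  }
  if (indel_prob > 0) {
    del <- stats::runif(length(chars)) < indel_prob
    chars[del] <- "-"
  }
  chars
}

#' Default per-subsite pocket alphabets for synthetic collections
#'
#' A trypsin-like toy specificity: a narrow basic P1 pocket (K/R) with
#' small-residue preferences elsewhere.
#'
#' @return Named list of 8 character vectors.
#' @export
default_pocket_alphabets <- function() {
  list("P4" = c("S", "A", "T"), "P3" = c("G", "A", "S"),
       "P2" = c("P", "A", "G"), "P1" = c("K", "R"),
       "P1'" = c("S", "A", "G"), "P2'" = c("G", "S"),
       "P3'" = c("G", "A"), "P4'" = c("G", "S", "A"))
}

#' Specification for the synthetic-data generators
#'
#' One integer seed drives all randomness through a single generator, so an
#' identical spec reproduces byte-identical output. Sizes default to the
#' scale of a moderately characterised peptidase: 24 recorded cleavages, 32
#' substrate homologues, a family of 30 members. The mutation model is
#' i.i.d. per site, substituting uniformly over the 19 alternative amino
#' acids; indels are off by default.
#'
#' @param seed Integer seed.
#' @param n_records Cleavage records to synthesise.
#' @param n_homologues Non-reference rows in synthetic alignments.
#' @param family_size Non-holotype members in synthetic families.
#' @param sub_prob Per-site substitution probability (background).
#' @param indel_prob Per-site deletion probability (gap in a homologue row).
#' @param pocket_alphabets Named list of allowed letters per subsite.
#' @param mode \code{"conserved_site"} (scored columns stay within the
#'   reference letter or the pocket alphabet) or \code{"degraded_site"}
#'   (scored cells substituted outside the alphabet with
#'   \code{degrade_prob}).
#' @param degrade_prob Out-of-alphabet substitution probability at scored
#'   cells in degraded mode.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 1L, n_records = 24L, n_homologues = 32L,
                         family_size = 30L, sub_prob = 0.05,
                         indel_prob = 0,
                         pocket_alphabets = default_pocket_alphabets(),
                         mode = c("conserved_site", "degraded_site"),
                         degrade_prob = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(subsite_names() %in% names(pocket_alphabets)),
            all(lengths(pocket_alphabets[subsite_names()]) > 0L))
  structure(
    list(seed = as.integer(seed), n_records = as.integer(n_records),
         n_homologues = as.integer(n_homologues),
         family_size = as.integer(family_size), sub_prob = sub_prob,
         indel_prob = indel_prob,
         pocket_alphabets = pocket_alphabets[subsite_names()],
         mode = mode, degrade_prob = degrade_prob),
    class = "fixture_spec"
  )
}

#' Synthesise a cleavage collection for one peptidase
#'
#' Octamers are drawn per subsite from the spec's pocket alphabets, so the
#' profile built from a large enough collection has exactly those alphabets
#' as pocket sets.
#'
#' @param spec A [fixture_spec()].
#' @param peptidase Peptidase identifier for every record.
#' @param organism Organism name used for both peptidase and substrate
#'   (records are physiological).
#' @return Cleavage-collection data frame with an \code{octamer} column.
#' @export
synth_cleavage_collection <- function(spec, peptidase = "S01.001",
                                      organism = "Homo sapiens") {
  stopifnot(inherits(spec, "fixture_spec"))
  peptidase <- as_merops_id(peptidase)$text
  with_preserved_seed(spec$seed, {
    n <- spec$n_records
    octamers <- vapply(seq_len(n), function(i) {
      paste(vapply(spec$pocket_alphabets, pick1, character(1)),
            collapse = "")
    }, character(1))
    data.frame(
      peptidase = rep(peptidase, n),
      substrate_accession = sprintf("SYN%04d", seq_len(n)),
      peptidase_organism = rep(organism, n),
      substrate_organism = rep(organism, n),
      p1 = rep(50L, n),
      category = rep("physiological", n),
      octamer = octamers,
      stringsAsFactors = FALSE)
  })
}

#' Profile whose pockets are exactly the spec's alphabets
#'
#' Builds a [build_profile()] result from a deterministic covering
#' collection: enough octamers to show every alphabet letter at its subsite
#' exactly once. Useful when a test or analysis needs the pocket sets to
#' equal the generator's alphabets by construction rather than by sampling.
#'
#' @param spec A [fixture_spec()].
#' @param peptidase Peptidase identifier for the profile.
#' @param total_cleavages Optional cleavage count to report (padding the
#'   collection with repeats of its first octamer); defaults to the
#'   covering-collection size.
#' @return A \code{specificity_profile} with pockets equal to
#'   \code{spec$pocket_alphabets}.
#' @export
alphabet_profile <- function(spec, peptidase = "S01.001",
                             total_cleavages = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- max(lengths(spec$pocket_alphabets))
  octs <- vapply(seq_len(k), function(i) {
    paste(vapply(spec$pocket_alphabets, function(a)
      a[[(i - 1L) %% length(a) + 1L]], character(1)), collapse = "")
  }, character(1))
  if (!is.null(total_cleavages)) {
    if (total_cleavages < k)
      stop(sprintf("total_cleavages must be at least %d to cover the alphabets", k))
    octs <- c(octs, rep(octs[[1]], total_cleavages - k))
  }
  build_profile(data.frame(peptidase = as_merops_id(peptidase)$text,
                           octamer = octs))
}

#' Synthesise a homologue alignment around a cleavage site
#'
#' Homologue rows are mutated copies of the reference. Away from the
#' scored P4-P4' columns, sites substitute with the background
#' \code{sub_prob}. At scored columns the behaviour depends on the mode:
#' \code{conserved_site} draws each cell from the reference letter or the
#' subsite's pocket alphabet (so scoring against a profile containing those
#' alphabets yields zero unacceptable replacements by construction);
#' \code{degraded_site} substitutes outside the alphabet (and reference
#' letter) with \code{degrade_prob}. \code{forced} plants exact
#' out-of-alphabet replacements: the first \code{forced[[s]]} homologues get
#' one at subsite \code{s}, all other scored cells stay conserved-mode, so
#' the resulting unacceptable count at \code{s} is exactly
#' \code{forced[[s]]}.
#'
#' @param spec A [fixture_spec()].
#' @param reference Ungapped reference amino-acid sequence.
#' @param p1 P1 residue number in the reference.
#' @param reference_id Reference row id (also the substrate accession to
#'   use in requests).
#' @param forced Optional named integer vector/list, e.g. \code{c(P4 = 2)}.
#' @return A [homologue_alignment()].
#' @export
synth_homologue_alignment <- function(spec, reference, p1,
                                      reference_id = "REF", forced = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  L <- nchar(reference)
  p1 <- as.integer(p1)
  if (p1 < 1L || p1 > L)
    stop(sprintf("p1 %d is outside the reference (length %d)", p1, L))
  if (!is.null(forced)) {
    stopifnot(all(names(forced) %in% subsite_names()),
              all(unlist(forced) <= spec$n_homologues))
  }
  ref_chars <- strsplit(reference, "")[[1]]
  scored_pos <- (p1 - 3L):(p1 + 4L)
  in_seq <- scored_pos >= 1L & scored_pos <= L
  subsite_of <- stats::setNames(rep(NA_character_, L), NULL)
  subsite_of[scored_pos[in_seq]] <- subsite_names()[in_seq]
  with_preserved_seed(spec$seed, {
    rows <- vapply(seq_len(spec$n_homologues), function(h) {
      chars <- ref_chars
      bg <- which(is.na(subsite_of))
      chars[bg] <- mutate_chars(chars[bg], spec$sub_prob, spec$indel_prob)
      for (pos in which(!is.na(subsite_of))) {
        s <- subsite_of[[pos]]
        alphabet <- spec$pocket_alphabets[[s]]
        ref_letter <- ref_chars[[pos]]
        outside <- setdiff(amino_acids(), c(alphabet, ref_letter))
        f <- if (!is.null(forced) && s %in% names(forced))
          forced[[s]] else 0L
        chars[[pos]] <-
          if (h <= f) {
            pick1(outside)
          } else if (is.null(forced) && spec$mode == "degraded_site" &&
                     length(outside) && stats::runif(1) < spec$degrade_prob) {
            pick1(outside)
          } else {
            pick1(unique(c(ref_letter, alphabet)))
          }
      }
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- sprintf("H%03d", seq_len(spec$n_homologues))
    homologue_alignment(
      c(stats::setNames(reference, reference_id), rows), reference_id)
  })
}

#' Synthesise a peptidase family from holotype sequences
#'
#' Members are generated by mutating a randomly chosen holotype at the
#' spec's substitution rate; each record's \code{source_holotype} column
#' names its generating holotype so identifier-assignment recovery can be
#' checked.
#'
#' @param spec A [fixture_spec()]; \code{sub_prob} is the divergence.
#' @param holotypes Family data frame of holotype records (see
#'   [family_table()]) with \code{is_holotype = TRUE}.
#' @param species,phylum Metadata given to generated members.
#' @return Family data frame: the holotypes plus \code{family_size}
#'   members, with a \code{source_holotype} column.
#' @export
synth_family <- function(spec, holotypes, species = "Homo sapiens",
                         phylum = "Chordata") {
  stopifnot(inherits(spec, "fixture_spec"), nrow(holotypes) >= 1L,
            all(holotypes$is_holotype))
  with_preserved_seed(spec$seed, {
    members <- lapply(seq_len(spec$family_size), function(i) {
      src <- holotypes[sample.int(nrow(holotypes), 1L), ]
      chars <- strsplit(src$residues, "")[[1]]
      chars <- mutate_chars(chars, spec$sub_prob, indel_prob = 0)
      data.frame(id = sprintf("MEM%03d", i), species = species,
                 phylum = phylum, gene_id = NA_character_,
                 tandem_duplicate = FALSE,
                 residues = paste(chars, collapse = ""),
                 is_holotype = FALSE, merops_id = NA_character_,
                 activity = "unknown", source_holotype = src$id,
                 stringsAsFactors = FALSE)
    })
    holo <- holotypes
    holo$source_holotype <- holo$id
    rbind(holo[, names(members[[1]])], do.call(rbind, members))
  })
}
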