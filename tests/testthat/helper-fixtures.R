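# Shared helpers: tiny random generators and independent oracles.

AA <- amino_acids()

rand_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# random gapped alignment: reference plus homologues, random gap placement
rand_alignment <- function(n_hom = 5L, width = 25L, gap_prob = 0.08,
                           ref_id = "ACC") {
  repeat {
    ref <- vapply(seq_len(width), function(i) {
      if (runif(1) < gap_prob) "-" else sample(AA, 1)
    }, character(1))
    if (sum(ref != "-") >= 9L) break
  }
  rows <- c(setNames(paste(ref, collapse = ""), ref_id))
  for (h in seq_len(n_hom)) {
    row <- vapply(seq_len(width), function(i) {
      if (runif(1) < gap_prob) "-" else sample(AA, 1)
    }, character(1))
    # bias towards the reference so all four classes occur
    copy <- runif(width) < 0.5
    row[copy] <- ref[copy]
    rows[sprintf("H%02d", h)] <- paste(row, collapse = "")
  }
  homologue_alignment(rows, ref_id)
}

rand_profile <- function(peptidase = "S01.001", n_records = 12L) {
  pockets <- lapply(subsite_names(), function(s)
    sample(AA, sample(1:6, 1)))
  names(pockets) <- subsite_names()
  octs <- vapply(seq_len(n_records), function(i)
    paste(vapply(pockets, function(p) sample(p, 1), character(1)),
          collapse = ""),
    character(1))
  build_profile(data.frame(peptidase = peptidase, octamer = octs))
}

# Independent oracle: recount unacceptable cells per subsite by a naive
# double loop over rows and subsites, classifying from first principles.
naive_counts <- function(alignment, p1, profile, count_gaps = FALSE) {
  ref <- strsplit(alignment$sequences[[alignment$reference_id]], "")[[1]]
  non_gap <- which(ref != "-")
  hom <- setdiff(names(alignment$sequences), alignment$reference_id)
  counts <- setNames(integer(8), subsite_names())
  for (i in 1:8) {
    resnum <- p1 - 4L + i
    if (resnum < 1L || resnum > length(non_gap)) next
    col <- non_gap[resnum]
    for (h in hom) {
      sym <- substring(alignment$sequences[[h]], col, col)
      if (sym == "-") {
        if (count_gaps) counts[i] <- counts[i] + 1L
      } else if (sym != ref[col] &&
                 !(sym %in% profile$pockets[[subsite_names()[i]]])) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# analytic hit with a full-length ungapped pairing (adapter-style backend)
identity_hit <- function(query_id, target_id, identity, n = 1000L,
                         score = identity * n, e_value = NA_real_) {
  pairwise_hit(query_id, target_id, identity = identity, score = score,
               e_value = e_value,
               aligned_pairs = cbind(query = seq_len(n),
                                     target = seq_len(n)),
               n_identical = round(identity * n), n_aligned = n)
}

# aligner computing exact hamming identity over equal-length sequences
hamming_aligner <- function(query, target, query_id, target_id) {
  stopifnot(nchar(query) == nchar(target))
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q)
  pairwise_hit(query_id, target_id, identity = sum(q == t) / n,
               score = sum(q == t),
               aligned_pairs = cbind(query = seq_len(n),
                                     target = seq_len(n)),
               n_identical = sum(q == t), n_aligned = n)
}

# mutate a sequence at exactly k positions (to letters differing from the
# original), returning the mutated string
mutate_exact <- function(sequence, k, positions = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (is.null(positions))
    positions <- sample(length(chars), k)
  for (p in positions)
    chars[p] <- sample(setdiff(AA, chars[p]), 1)
  paste(chars, collapse = "")
}

make_holotypes <- function(n = 2L, len = 150L) {
  family_table(
    id = sprintf("HOLO%d", seq_len(n)),
    residues = vapply(rep(len, n), rand_seq, character(1)),
    species = "Homo sapiens", phylum = "Chordata",
    is_holotype = TRUE,
    merops_id = sprintf("S01.%03d", seq_len(n)),
    activity = "active")
}
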