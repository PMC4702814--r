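test_that("pairwise alignment reports identity over aligned pairs", {
  hit <- pairwise_align("ACDEFGHIK", "ACDEFGHIK", "a", "b")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$n_aligned, 9L)
  expect_equal(nrow(hit$aligned_pairs), 9L)

  hit2 <- pairwise_align("ACDEFGHIK", "ACDEFGHIR")
  expect_equal(hit2$identity, 8 / 9)
  expect_equal(hit2$n_identical, 8L)

  # no conserved local alignment: identity 0 over 0 pairs
  hit3 <- pairwise_align("AAAA", "WWWW")
  expect_true(hit3$identity == 0 || hit3$n_aligned == 0L)

  expect_error(pairwise_align("", "ACD"), "empty")
})

test_that("aligned pairs index the original sequences", {
  set.seed(37)
  for (rep_i in 1:10) {
    q <- rand_seq(60)
    t <- mutate_exact(q, 4)
    hit <- pairwise_align(q, t)
    pr <- hit$aligned_pairs
    qc <- strsplit(q, "")[[1]][pr[, "query"]]
    tc <- strsplit(t, "")[[1]][pr[, "target"]]
    expect_equal(sum(qc == tc), hit$n_identical)
    expect_equal(nrow(pr), hit$n_aligned)
    expect_equal(hit$identity, hit$n_identical / hit$n_aligned)
  }
})

test_that("identifier assignment follows the nearest holotype at >= 40% identity", {
  set.seed(41)
  holos <- make_holotypes(2, len = 120)
  # member mutated from holotype 1 at ~5%: clearly closest to it
  near <- mutate_exact(holos$residues[1], 6)
  # member unrelated to both
  far <- rand_seq(120)
  fam <- rbind(holos,
               family_table(id = c("NEAR", "FAR"),
                            residues = c(near, far),
                            species = "Homo sapiens", phylum = "Chordata"))
  res <- assign_identifiers(fam)
  expect_equal(res$assigned[res$id == "HOLO1"], "S01.001")
  expect_equal(res$identity[res$id == "HOLO1"], 1.0)
  expect_equal(res$assigned[res$id == "NEAR"], "S01.001")
  expect_equal(res$best_holotype[res$id == "NEAR"], "HOLO1")
  expect_true(is.na(res$assigned[res$id == "FAR"]) ||
                res$identity[res$id == "FAR"] >= 0.40)
  # every assignment respects the identity floor
  expect_true(all(is.na(res$assigned) | res$identity >= 0.40))
  expect_error(assign_identifiers(fam[!fam$is_holotype, ]), "no holotype")
})

test_that("assignment is invariant under family permutation", {
  set.seed(43)
  holos <- make_holotypes(3, len = 100)
  members <- family_table(
    id = sprintf("M%d", 1:6),
    residues = vapply(rep(1:3, 2), function(j)
      mutate_exact(holos$residues[j], 5), character(1)),
    species = "Homo sapiens", phylum = "Chordata")
  fam <- rbind(holos, members)
  res1 <- assign_identifiers(fam)
  perm <- fam[sample(nrow(fam)), ]
  res2 <- assign_identifiers(perm)
  res2 <- res2[match(res1$id, res2$id), ]
  expect_equal(res2$assigned, res1$assigned)
  expect_equal(res2$best_holotype, res1$best_holotype)
})

test_that("holotype ranking prefers the lowest E-value when present", {
  fam <- rbind(make_holotypes(2, len = 50),
               family_table("Q", rand_seq(50), species = "Homo sapiens"))
  hits <- list(
    identity_hit("Q", "HOLO1", identity = 0.50, score = 10,
                 e_value = 1e-5),
    identity_hit("Q", "HOLO2", identity = 0.90, score = 99,
                 e_value = 1e-3),
    identity_hit("HOLO1", "HOLO1", 1.0, e_value = 1e-80),
    identity_hit("HOLO1", "HOLO2", 0.2, e_value = 1),
    identity_hit("HOLO2", "HOLO1", 0.2, e_value = 1),
    identity_hit("HOLO2", "HOLO2", 1.0, e_value = 1e-80))
  res <- assign_identifiers(fam, hits = hits)
  # HOLO1 wins on E-value despite HOLO2's higher identity and score
  expect_equal(res$best_holotype[res$id == "Q"], "HOLO1")
  expect_equal(res$assigned[res$id == "Q"], "S01.001")
})

test_that("near-duplicate merging honours identity, species, gene and tandem guards", {
  set.seed(53)
  base <- rand_seq(100)
  pair <- function(..., ids = c("A", "B")) {
    merge_near_duplicates(family_table(id = ids, residues = c(base, base),
                                       ...))
  }
  # identical, same species: merged to one
  out <- pair(species = "Homo sapiens")
  expect_equal(nrow(out$family), 1L)
  expect_equal(out$log$removed, "B")
  # ~98% identity but different species: kept apart
  out <- merge_near_duplicates(family_table(
    id = c("A", "B"), residues = c(base, mutate_exact(base, 2)),
    species = c("Homo sapiens", "Mus musculus")))
  expect_equal(nrow(out$family), 2L)
  # same species, known products of different genes: kept apart
  out <- pair(species = "Homo sapiens", gene_id = c("g1", "g2"))
  expect_equal(nrow(out$family), 2L)
  # one known gene, the other unknown: no evidence of different genes
  out <- pair(species = "Homo sapiens", gene_id = c("g1", NA))
  expect_equal(nrow(out$family), 1L)
  # tandem duplicates in the same genome: kept apart
  out <- pair(species = "Homo sapiens", tandem_duplicate = c(TRUE, TRUE))
  expect_equal(nrow(out$family), 2L)
  # well below the identity threshold: kept apart
  out <- merge_near_duplicates(family_table(
    id = c("A", "B"), residues = c(base, mutate_exact(base, 30)),
    species = "Homo sapiens"))
  expect_equal(nrow(out$family), 2L)
})

test_that("merging is idempotent and never grows the family", {
  set.seed(59)
  base <- rand_seq(120)
  fam <- family_table(
    id = sprintf("S%d", 1:6),
    residues = c(base, base, mutate_exact(base, 1), mutate_exact(base, 40),
                 rand_seq(120), rand_seq(120)),
    species = "Homo sapiens")
  out <- merge_near_duplicates(fam)
  expect_lte(nrow(out$family), nrow(fam))
  again <- merge_near_duplicates(out$family)
  expect_equal(again$family$id, out$family$id)
  expect_equal(nrow(again$log), 0L)
})

test_that("merging is transitive and keeps the longest representative", {
  # analytic identities through the adapter: A~B and B~C qualify, A~C not
  fam <- family_table(
    id = c("A", "B", "C"),
    residues = c(strrep("K", 100), strrep("K", 110), strrep("K", 105)),
    species = "Homo sapiens")
  hits <- list(identity_hit("A", "B", 0.97), identity_hit("B", "C", 0.96),
               identity_hit("A", "C", 0.90))
  out <- merge_near_duplicates(fam, hits = hits)
  expect_equal(out$family$id, "B")  # longest of the single-linkage cluster
  expect_setequal(out$log$removed, c("A", "C"))
})

test_that("a short identical fragment is not merged into a full record", {
  long <- rand_seq(200)
  frag <- substring(long, 1, 60)
  fam <- family_table(id = c("FULL", "FRAG"), residues = c(long, frag),
                      species = "Homo sapiens")
  out <- merge_near_duplicates(fam)
  expect_setequal(out$family$id, c("FULL", "FRAG"))
})

test_that("active-site transfer predicts activity iff all essentials conserved", {
  holo <- list(id = "HOLO", residues = "MKHACDEFGHIKLMNPQRSDVWYAMKWVSFI")
  ann <- active_site_annotation(
    position = c(3, 20, 29),
    residue = c("H", "D", "S"),
    role = c("metal_ligand", "catalytic", "catalytic"),
    essential = c(TRUE, TRUE, TRUE))
  self_hit <- identity_hit("HOLO", "T", 1.0, n = nchar(holo$residues))

  same <- list(id = "T", residues = holo$residues)
  res <- transfer_active_sites(holo, ann, self_hit, same)
  expect_equal(res$activity, "active")
  expect_true(all(res$annotation$conserved))
  expect_equal(res$annotation$target_position, c(3L, 20L, 29L))

  # catalytic Ser -> Ala knocks the prediction out
  mutated <- holo$residues
  substr(mutated, 29, 29) <- "A"
  res2 <- transfer_active_sites(holo, ann, self_hit,
                                list(id = "T", residues = mutated))
  expect_equal(res2$activity, "non_peptidase_homologue")
  expect_equal(res2$annotation$conserved, c(TRUE, TRUE, FALSE))

  # an unaligned essential position counts as not conserved
  partial <- identity_hit("HOLO", "T", 1.0, n = 25L)  # pairs 1..25 only
  res3 <- transfer_active_sites(holo, ann, partial, same)
  expect_equal(res3$activity, "non_peptidase_homologue")
  expect_false(res3$annotation$aligned[3])

  # conservative substitutions can be allowed per role
  res4 <- transfer_active_sites(
    holo, ann, self_hit,
    list(id = "T", residues = sub("^MKH", "MKE", holo$residues)),
    conservative = list(metal_ligand = c("E")))
  expect_equal(res4$activity, "active")

  # a non-essential loss does not block activity
  ann_mixed <- ann
  ann_mixed$essential[1] <- FALSE
  res5 <- transfer_active_sites(holo, ann_mixed, self_hit,
                                list(id = "T",
                                     residues = sub("^MKH", "MKW",
                                                    holo$residues)))
  expect_equal(res5$activity, "active")

  expect_error(
    transfer_active_sites(holo, active_site_annotation(99, "S"), self_hit,
                          same),
    "outside the holotype")
  expect_error(
    transfer_active_sites(holo, active_site_annotation(3, "Q"), self_hit,
                          same),
    "disagree")
})

test_that("reclassification flips a conserved non-peptidase homologue to active", {
  holo <- list(id = "HOLO", residues = rand_seq(80))
  ann <- active_site_annotation(c(10, 40, 70),
                                substring(holo$residues,
                                          c(10, 40, 70), c(10, 40, 70)))
  target <- list(id = "NPH", residues = mutate_exact(
    holo$residues, 3, positions = c(20, 30, 55)))
  hit <- pairwise_align(holo$residues, target$residues, "HOLO", "NPH")
  res <- transfer_active_sites(holo, ann, hit, target)
  expect_equal(res$activity, "active")
})

test_that("representative sets keep holotypes plus one active member per phylum", {
  set.seed(47)
  n <- 250
  phyla <- rep(c("Chordata", "Arthropoda", "Nematoda", "Ascomycota",
                 "Proteobacteria"), each = 50)
  fam <- family_table(
    id = sprintf("R%03d", seq_len(n)),
    residues = vapply(sample(80:120, n, TRUE), rand_seq, character(1)),
    species = "various", phylum = phyla,
    is_holotype = c(TRUE, TRUE, TRUE, rep(FALSE, n - 3)),
    merops_id = c("S01.001", "S01.002", "S01.003", rep(NA, n - 3)),
    activity = sample(c("active", "non_peptidase_homologue", "fragment",
                        "unknown"), n, TRUE))
  fam$activity[1:3] <- "active"
  sel <- select_representatives(fam)
  expect_true(all(fam$id[fam$is_holotype] %in% sel$id))
  expect_lte(nrow(sel), 3 + length(unique(phyla)))
  expect_false(anyDuplicated(sel$id) > 0)
  # each represented phylum contributes its longest active member
  for (ph in unique(phyla)) {
    cand <- fam[fam$phylum == ph & fam$activity == "active", ]
    picks <- sel[sel$phylum == ph & !sel$is_holotype, ]
    if (nrow(cand) && nrow(picks))
      expect_true(max(nchar(cand$residues)) %in% nchar(picks$residues))
  }

  # below the limit: returned unchanged
  small <- fam[1:150, ]
  expect_equal(select_representatives(small), small)

  # a phylum with no active member contributes no representative
  fam2 <- fam
  fam2$activity[fam2$phylum == "Nematoda" & !fam2$is_holotype] <- "fragment"
  sel2 <- select_representatives(fam2)
  expect_equal(nrow(sel2[sel2$phylum == "Nematoda" & !sel2$is_holotype, ]),
               0L)
})
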