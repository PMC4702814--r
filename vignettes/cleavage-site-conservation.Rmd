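---
title: "Cleavage-site conservation analysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-site conservation analysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meropstools)
```

## The problem

High-throughput degradomics experiments report thousands of protease
cleavage events, but an observed cleavage is not necessarily a
physiological one: lysate preparation removes the compartment barriers
that normally keep peptidase and substrate apart, and many cleavages are
"bystander" events with no biological role. The working assumption of this
package is that a physiologically relevant cleavage site is under
selection and therefore conserved among orthologues of the substrate,
while an incidental site is free to drift.

## The scoring model

Substrate residues flanking the scissile bond are named in the
Schechter–Berger scheme: P4–P1 on the N-terminal side, P1′–P4′ on the
C-terminal side, with cleavage between P1 and P1′; the corresponding
enzyme pockets are S4–S4′. For a peptidase *e* the package builds an
**acceptance profile**: for each subsite *s*, the set

$$A_e(s) = \{ a : a \text{ observed at } s \text{ in some recorded cleavage of } e \}$$

taken over every cleavage in the collection (all categories pooled by
default — physiological, non-physiological, pathological and synthetic
evidence all inform what a pocket tolerates; callers can subset the
collection before profiling if they want a restricted evidence base).
This is deliberately a *set-membership* model, not a position weight
matrix: the question asked of each homologue residue is binary — has this
amino acid ever been seen in this pocket? — and no frequency weighting or
enrichment statistic is layered on top.

Given a cleavage request (peptidase, substrate accession, P1 residue
number) and a multiple alignment of substrate homologues containing the
substrate itself as reference row, `score_site()`:

1. maps each of the eight subsite residue numbers (P1−3 … P1+4) to its
   alignment column through the gapped reference row;
2. classifies every homologue symbol at each column as **conserved**
   (equal to the reference residue), **gap**, **acceptable replacement**
   (different but in $A_e(s)$) or **unacceptable replacement** (not in
   $A_e(s)$);
3. counts unacceptable replacements per subsite. Acceptable replacements
   are *not* mismatches; a subsite where two homologues carry an
   out-of-pocket residue has a count of exactly 2.

Subsites that overhang the reference termini (cleavage within three
residues of the N terminus or four of the C terminus) score no cells and
count zero; inside octamers the overhang is shown with a boundary marker.

### Gap cells

Gaps form their own class and by default do not contribute to mismatch
counts: the counts tally *replacement amino acids*, and a deletion is not
a replacement. Because an orthologue that has lost the site region
entirely is still informative, `score_site(count_gaps = TRUE)` folds gap
cells into the counts for callers who prefer that reading.

### The qualitative call

The qualitative interpretation uses three explicit, configurable
thresholds (`call_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `conserved_tolerance` | 0.05 | a site is *likely physiological* when every subsite's unacceptable count is ≤ 5% of homologues |
| `unacceptable_fraction` | 0.25 | a subsite is *degraded* when > 25% of homologues carry an unacceptable replacement |
| `degraded_subsites` | 3 | *unlikely physiological* requires at least this many degraded subsites |
| `low_evidence` | 10 | below this many recorded cleavages the profile is flagged low-evidence |

Everything between the two regimes is *indeterminate*. No published
numeric rule exists for the verbal categories "well conserved" and
"unlikely to be physiological", so these are this package's own stand-ins;
they are printed in every report and all four are arguments, not
constants. The 5% tolerance makes two deviant orthologues among 83
(a typical sequence-database sampling of one substrate) still read as
conserved, while the 0.25/3 rule requires degradation to be broad — across
several pockets — before a site is dismissed.

A peptidase with few recorded cleavages has pockets that look
artificially narrow, which inflates unacceptable counts. The evidence
flag therefore *forces* the final call to indeterminate when the profile
holds fewer than `low_evidence` cleavages, while the raw call is kept on
the report. The default of 10 sits between the sparsely characterised
(6 cleavages) and adequately characterised (24 cleavages) peptidases that
motivated the flag; it too is configurable.

Ambiguity codes (B, Z, X and other non-standard letters) never enter
pocket sets and always score as unacceptable when they appear in a
homologue — a conservative choice, since an ambiguous residue cannot be
shown to be tolerated.

## Identifier grammar

Identifiers follow the clan / family / protein-species hierarchy: clans
are two letters (first a catalytic-type letter: A, C, G, M, S, T, N for
aspartic, cysteine, glutamic, metallo, serine, threonine and
asparagine-lyase activities, plus P, U, I for mixed, unknown and protein
inhibitors); families are a letter plus a number; holotype-level
identifiers zero-pad the family to three characters and add a
three-character suffix. Suffixes beginning with 9 mark non-peptidase
homologues, with P pseudogenes, and with A/B/C model-organism sequences
not assignable to a characterised peptidase. The parser accepts
lower-case input and subfamily letters (S8A) and canonicalises both;
suffix letters outside {P, A, B, C} are a parse error rather than a
guess, since no other letters are documented.

## Family-maintenance procedures

**Identifier assignment.** Each family member is compared with every
holotype of the family; the best holotype is the one with the lowest
E-value when the search backend reports E-values, otherwise the highest
alignment score (ties: higher identity, then lexicographic holotype id,
which makes the result independent of input order). The holotype's
identifier is inherited iff identity ≥ 40%.

**Identity definition.** The built-in backend is Smith–Waterman local
alignment (Biostrings) under BLOSUM62 with affine gaps (open 10,
extend 0.5), and identity = identical aligned pairs / aligned non-gap
pairs of the local alignment. Whether the 40% rule should be computed
over the full peptidase unit or the local alignment is not settled
usage; the local-alignment denominator matches what sequence-search
tools report and is stated here so that tests can be exact. Any backend
that populates a `pairwise_hit` (including an external search tool, via
an adapter function or precomputed hit list) can be substituted.

**Near-duplicate merging.** Pairs merge when identity is *strictly*
greater than 94% and the records are from the same species, are not known
products of different genes (two distinct recorded gene ids block the
merge; an unknown gene id does not), and are not both flagged as tandem
duplicates in the same genome. Because a 60-residue fragment can be 100%
identical to its parent without being a duplicate *record*, a length-ratio
guard (shorter/longer ≥ 0.8, configurable) is added as this package's own
decision. Qualifying pairs are clustered by single linkage — transitivity
is not specified anywhere, and single linkage is the only choice that
makes the operation idempotent without recomputing identities on merged
output — and each cluster keeps its longest member.

**Active-site transfer.** Annotated catalytic residues and metal ligands
of a holotype are projected through the aligned pairs of a pairwise hit
onto a target sequence. The target is predicted an active peptidase iff
*every essential* residue is aligned and conserved (strict identity by
default; per-role conservative-substitution sets can be supplied, e.g.
Asp/Glu interchange at metal ligands). An essential residue that falls
outside the aligned region counts as not conserved — absence of evidence
of conservation is treated as loss. Records previously classed as
non-peptidase homologues whose essential residues all prove conserved are
thereby reclassified as peptidases.

**Representative sets.** Families of more than 200 sequences are reduced
to all holotypes plus, for each phylum containing at least one member
predicted active, one such member — the longest, ties broken by id, so
the selection is deterministic. Fragments and non-peptidase homologues
are never picked as phylum representatives (they remain eligible for
identifier assignment).

## The synthetic-data generators

Every component is testable offline through `fixture_spec()` and the
`synth_*` generators. One integer seed drives a single RNG stream whose
state is saved and restored around each call, so a given spec is
byte-reproducible and generation does not perturb the caller's RNG.

The generators emulate exactly what the scoring procedures consume:

* `synth_cleavage_collection()` draws octamers per subsite from
  configurable pocket alphabets (default: a trypsin-like toy with a
  narrow K/R P1 pocket), so the profile implied by a large collection is
  known by construction; `alphabet_profile()` builds that limiting
  profile deterministically when sampling coverage must not be left to
  chance.
* `synth_homologue_alignment()` mutates the reference under an i.i.d.
  per-site model (uniform over the 19 alternative residues; deletions
  optional and off by default). In conserved mode the scored P4–P4′
  columns stay within the reference residue or the pocket alphabet; in
  degraded mode they substitute outside it with a stated probability; a
  `forced` argument plants an exact number of out-of-alphabet
  replacements at chosen subsites, giving fixtures whose expected counts
  are known integers.
* `synth_family()` mutates randomly chosen holotypes at a stated
  divergence and labels each member with its generating holotype, so
  assignment recovery is directly checkable.

Default sizes — 24 cleavage records, 32 homologue rows, 30 family
members, 5% divergence — mirror a moderately characterised peptidase, a
typical orthologue cluster for one substrate, and the within-species
variation the 40%/94% thresholds are meant to separate.

What the model does **not** emulate: rate heterogeneity across sites,
phylogenetic correlation among homologues (rows are independent draws,
real orthologue alignments are tree-structured), insertions, compositional
bias, and alignment error. Passing tests therefore demonstrate that the
scoring, thresholding and classification machinery is correct on inputs
whose ground truth is known — not that the default thresholds are
well-calibrated for any particular real proteome; on real data the
alignment quality and the completeness of the cleavage collection
dominate.

## Numerical and degenerate-input choices

* Residue numbering is 1-based throughout; cleavage occurs *after* the P1
  residue.
* A request whose stored octamer disagrees with the reference row at a
  scored column is a hard error (data inconsistency), never silently
  rescored.
* Duplicate row ids in an alignment are an error; the homologue count is
  a plain count of non-reference rows.
* Scoring is invariant under homologue row order and under insertion of
  all-gap columns (checked property-style in the test suite).
* An empty local alignment (no positive-scoring segment) reports identity
  0 over 0 aligned pairs.
* Assignment uses ≥ (0.40 assigns); merging uses > (exactly 0.94 does
  not merge). Both boundaries are exercised with analytically constructed
  hits in the test suite.

## Validation scale

The test suite validates scoring against a naive independent recount on
1000 random gapped fixtures, exactness of forced-substitution counts and
conserved-site zeroes across seeds, both identity boundaries, exhaustive
single-substitution soundness of the activity prediction (every essential
position × every alternative residue), round-trips of tables and
identifiers, and ≥95% holotype recovery at 5% divergence over 20 seeded
families. `scripts/acceptance.R` recomputes the same quantities from
scratch (300 oracle fixtures, 20 seeds per stochastic check) and writes
them as JSON.

## Known limitations

* The acceptance-set model cannot distinguish a pocket that tolerates a
  residue rarely from one that tolerates it often; that is inherent to
  the set-membership rule.
* Profiles pool all cleavage categories by default; a synthetic-substrate
  bias in the collection widens pockets accordingly.
* The qualitative call thresholds are heuristics, and low-evidence
  profiles are flagged rather than rescued.
* Homologue retrieval and multiple alignment are out of scope: alignments
  are inputs, and their quality bounds the analysis.
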