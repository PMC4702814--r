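# meropstools

Tools for deciding whether an observed protease cleavage is likely to be
physiological, and for the classification housekeeping of peptidase
families: identifier grammar, nearest-holotype identifier assignment,
near-duplicate merging, active-site transfer and representative-set
selection.

## Who this is for

Degradomics and protease-biology groups who have lists of observed
cleavage events (peptidase, substrate accession, P1 residue number) —
typically from N-terminomics or other high-throughput experiments — and
need to separate physiologically relevant sites from bystander and
artefactual ones; and database maintainers who curate peptidase families
against holotype (type-example) sequences.

## The method

Substrate residues around the scissile bond are named P4–P1 and P1′–P4′
(Schechter–Berger); cleavage occurs between P1 and P1′, and the enzyme's
corresponding binding pockets are S4–S4′. For a peptidase *e*, the
package collects, for each subsite *s*, the **acceptance set**
*A<sub>e</sub>(s)* — every amino acid observed at *s* across all recorded
cleavages of *e*. A cleavage site is then scored against a multiple
alignment of homologues of its substrate: each homologue residue at each
subsite column is

* **conserved** if it equals the reference residue,
* an **acceptable replacement** if different but in *A<sub>e</sub>(s)*,
* an **unacceptable replacement** if the peptidase has never been seen to
  accept it in that pocket,
* or a **gap**.

Per-subsite counts of unacceptable replacements are reported, and a site
with many of them across several pockets is called unlikely to be
physiological — conservation of a functional site being the underlying
assumption. Profiles built from fewer than 10 known cleavages are flagged
low-evidence and their calls forced to indeterminate.

The family procedures implement the published rules: a member inherits
the identifier of its lowest-E-value (or highest-scoring) holotype at
≥ 40% identity; records merge as near-duplicates at > 94% identity with
same-species, different-gene and tandem-duplicate guards; a homologue is
predicted an active peptidase iff every essential catalytic residue or
metal ligand transfers conserved through a pairwise alignment; families
above 200 sequences reduce to holotypes plus one active member per
phylum.

## Worked example

```r
library(meropstools)

# acceptance profile from 12 recorded cleavages of furin-like S08.071
coll <- data.frame(
  peptidase = "S08.071",
  octamer   = c("SAKRSVAG", "RAKRSVAG", "TAKKSVAG"))
profile <- build_profile(coll[rep(1:3, length.out = 12), ])

# an alignment of 40 substrate orthologues; in two of them the P4 serine
# is replaced by asparagine, which S08.071 has never been seen to accept
ref  <- paste0("MGSA", "SAKRSVAG", "LLTE")          # P1 = residue 8
site <- sub("S", "N", "SAKRSVAG")
orth <- setNames(rep(ref, 40), sprintf("ORTH%02d", 1:40))
orth[c("ORTH01", "ORTH02")] <- paste0("MGSA", site, "LLTE")
aln <- homologue_alignment(c(P97857 = ref, orth), "P97857")

req <- cleavage_request("S08.071", "P97857", 8)
score_site(aln, req, profile)
```

```
<conservation_report> S08.071 on P97857 after residue 8
  homologues 40, total cleavages 12 (evidence adequate)
  unacceptable replacements: P4=2 P3=0 P2=0 P1=0 P1'=0 P2'=0 P3'=0 P4'=0
  call: likely_physiological (raw: likely_physiological)
```

Two orthologues carry an out-of-pocket residue at P4 and nowhere else —
5% of the homologues, within the conserved tolerance, so the cleavage is
still called likely physiological. `write_report_table()` emits the
tab-delimited results dialect (identifier, total cleavages, accession,
homologue count, P1, the eight counts, and the alignment-view URL built
from the acc/mid/residue triple), and `annotate_alignment()` renders the
alignment with every scored cell tagged.

Bulk analysis from the shell:

```sh
Rscript inst/scripts/analyse-substrates.R \
    --requests requests.tsv --alignments alignments/ \
    --collection cleavages.tsv --sequences substrates.fasta \
    --out report.tsv
Rscript inst/scripts/classify.R assign \
    --family family.fasta --metadata metadata.tsv --out assignments.tsv
```

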