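---
title: "Methods: AP2/ERF superfamily identification, classification and regulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP2/ERF superfamily identification, classification and regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ap2erf)
```

## The problem

AP2/ERF transcription factors are defined by the ~58-residue AP2
DNA-binding domain (three anti-parallel β-strands and one α-helix, binding
the GCC-box or the DRE element). In a transcriptome assembled from short
reads, an inventory of this superfamily must be built from contigs alone:
translate each contig, locate AP2 (and B3) domains, call each domain
complete or partial, classify genes into the AP2, ERF, RAV and Soloist
families from their domain architecture, place ERF members into the eleven
Nakano groups (I–X and VI-L), and relate those groups to the older Sakuma
DREB/ERF subfamily bands. Downstream, the inventory supports read-count
summaries per tissue library, qPCR relative quantification, and plant
miRNA target prediction on the family's transcripts.

`ap2erf` implements that workflow end to end, together with a synthetic
cohort generator that provides labelled ground truth for every stage, so
each step's recovery can be measured exactly.

## Domain model and scanning

Domains are located with a position-specific scoring model (PSSM) over the
58 structural positions, numbered 145–202 after the AtERF1 structure, plus
one insertion slot ("167i") between positions 167 and 168 that is occupied
in ERF group IX (hence its 59-residue domain). The model's scores are
log-odds of per-column residue frequencies against a uniform background
with additive pseudocounts; the insertion column carries zero deletion
penalty, so domains without the insertion skip it freely.

Contigs are translated in all six frames; every stop-free stretch of at
least 50 amino acids (contigs from expressed transcripts need no
ATG anchoring, and partial contigs may begin mid-protein) is scanned by
affine-gap local alignment against the model (gap open 4, extension 0.5 in
score units; implemented in C++). A hit is accepted when its score reaches
60% of the maximum attainable score *over the matched model span* and the
span covers at least 10 columns. Normalising by the matched span rather
than the full model is deliberate: partial domains, which the inventory
must count, only ever cover part of the model and would otherwise always
be rejected.

Local alignment maximises score and therefore trims terminal model columns
whose residues are substituted away from the consensus. A hit whose span
ends within 6 columns of a model boundary is extended gaplessly, column by
column, into adjacent peptide residues, and the extension is kept only if
the extended hit still clears the score threshold. Completeness is then
read off the matched span: `full` covers positions 1–58 with fewer than 4
internal deletions, `short` covers both ends with ≥4 internal deletions
(the Soloist architecture: six missing residues including R152),
`partial_N`/`partial_C`/`partial_both` otherwise. The 6-column extension
bound means a domain genuinely missing up to 6 terminal residues — but
flanked by coding sequence — is called full; true partial contigs are
truncated at a sequence end and lack the flanking residues, so they are
unaffected.

Greedy best-score-first masking finds up to two AP2 domains per peptide
(the AP2 family's double domain); overlapping hits across frames resolve
best-score-first on forward-strand coordinates. The B3 model (RAV family)
works identically, with a minimum span of 30 columns.

## Family classification

Architecture rules: two AP2 domains → AP2; one AP2 plus one B3 → RAV; one
short AP2 → Soloist; one full or partial AP2 → ERF. Single-domain genes
that actually belong to the AP2 family (truncated double-domain contigs)
are recovered by a homology override: the domain is anchored to the model
and compared at seven family-informative positions (position 150, where
the AP2 family carries T/A against the ERF family's invariant R, plus six
positions where the AP2-family consensus diverges); a strict majority of
at least two concordant residues among the positions the (possibly
partial) domain covers flips the call to AP2, and the override is recorded.

## Anchoring, block curation, tree and groups

Each gene's first complete AP2 domain (the second repeat when the first is
absent) is anchored to the numbering by glocal alignment — the peptide
fully aligned, model end columns free — yielding a residue vector over
positions 145–202 and 167i. Alignment columns are curated into conserved
blocks: a column is kept when at least half the rows are non-gap and the
modal residue frequency reaches 0.5 (default), and maximal runs of at
least 10 consecutive conserved columns are retained. The 167i column is
gap-major and drops out, reproducing the behaviour of block-curation tools
on this alignment.

Pairwise p-distances over the curated block (fraction of differing
residues among mutually non-gap columns) feed a neighbour-joining
agglomeration (Saitou–Nei), with a deterministic tie-break (smallest row,
then column index) and negative branch-length estimates clamped to zero
and flagged. For display the tree is rooted on the branch separating the
AP2 and RAV families from the rest when that split is clean.

ERF groups are assigned by placement: queries and a labelled reference
panel are joined in one NJ tree, and each query takes the majority group
label of its smallest enclosing clade that contains a reference. The
group-diagnostic residues serve as secondary evidence: each group has a
signature (its diagnostic residues, the 158/163 subfamily pair, and for
group IX the 167i occupancy), and when a query carries exactly one group's
most specific signature but the tree disagrees, the signature decides and
the `method` field records it. Subgroup letters are carried from the
assigned group's references, never inferred. Sakuma banding then maps
groups I–IV to the DREB subfamily (A-1 to A-6), V–X to ERF (B-1 to B-6),
and VI-L to B-6; AP2, RAV and Soloist map to themselves.

## Diagnostic residues

Per-group, per-position residue frequencies (gap fraction reported
separately) drive two discoveries:

* **Universal residues** — positions where one residue reaches the
  threshold (default 100%) in *every* ERF group; on the reference panel
  these are exactly G148, R150, R152, G155, E160, I161, W172, L173, G174
  and A182.
* **Group markers** — a residue is reported for a group when its
  within-group conservation reaches `within_min` (90%) while at most
  `max_shared_groups` (1) other groups carry it above `outside_max`
  (10%). Strict exclusivity (`max_shared_groups = 0`) cannot represent
  the markers that two groups legitimately share — group VIII's pair is
  borrowed from groups V (K168) and VI (P153), and G168 is diagnostic in
  both IV and VII — so one shared group is admitted by default and the
  table annotates nothing away. At a position carrying a reported marker,
  additional residues above `secondary_min` (5%) that pass the same
  exclusivity test are reported too, which represents two-residue entries
  of the T150/A150 kind. Group IX is reported through the 167i occupancy
  rule ("+X167") rather than a residue identity.

The subfamily call is a two-position rule: V158 with E163 → DREB, A158
with D163 → ERF, anything else unresolved (the caller falls back to tree
placement). Motif scans are literal (YRG, WLG, RAYD, KREYD) except the EAR
repression motif, scanned as (L/F)DLN(L/F)xP — the consensus adopted from
the repression-domain literature and kept in one overridable constant.

## Read distribution and qPCR

Read membership is a contig × library count matrix; aggregation by any
grouping adds margin row and column, and margins are conserved under
partition refinement. Tissue shares are percentages of the total, rounded
half-up to one decimal (matching the printed precision of the source
tables). The qPCR normalized ratio is efficiency-corrected,
`E_t^(−Cp_t) / E_r^(−Cp_r)` with amplification factors defaulting to 2.0
per cycle, which reduces to the classical `2^−ΔCp` form; differential
expression testing is intentionally not reimplemented — the count matrix
is exported in the layout such packages consume.

## miRNA target prediction

A miRNA is aligned against every transcript window under additive
penalties per miRNA position from its 5' end: gap 2, non-pair 1, G:U
wobble 0.5. Hits are kept when total penalty ≤ 3, alignment length ≥ 15
columns, positions 10–11 are paired (Watson–Crick or wobble), and the
duplex free energy is at most −20 kcal/mol. Overlapping hits resolve to
the lowest penalty. The scan is a fit-alignment dynamic programme over the
reversed miRNA (antiparallel duplex), vectorised with a running-minimum
scan; candidate ends are traced back in a small window.

Duplex energy is a per-pair additive model — G:C −3.0, A:U −2.0, G:U −1.0,
non-pairs and gaps 0 kcal/mol — published here as the model definition.
It is *not* a nearest-neighbour stacking model and printed energies from
thermodynamic folding tools are not reproduced exactly; only the −20
kcal/mol acceptance bound is contractual, and the pair table is one
overridable constant. Inhibition mode follows the convention of
plant-target servers: cleavage when miRNA positions 9–11 are all
Watson–Crick paired, translation inhibition otherwise (a wobble at a
central position is not Watson–Crick). Site region labels (5'UTR,
CDS-before/inside/after-AP2, 3'UTR) follow the midpoint of the site.

## The synthetic cohort generator

The generator's defaults are the study conditions: 25 AP2-family genes
(9 with two full domains, 4 full+partial, 2 two-partial, 7 one-full,
3 one-partial), 141 ERF genes (115 full-domain over the eleven groups —
12, 7, 11, 3, 5, 5, 6, 23, 15, 19 and 9 for I–X and VI-L — plus 26
partials), 4 RAV and 3 Soloist genes; tissue weights 0.298/0.222/0.212/
0.164/0.104 for root/bark/latex/embryogenic/leaf. Domains are built on a
58-position scaffold carrying the YRG, WLG and RAYD elements; each gene
plants its family/group diagnostics noise-free (universal residues,
158/163 subfamily pair, group markers, the VI-L KREYD block, the group-IX
insertion, the Soloist deletion of positions 149–154 — a contiguous block
chosen to contain the one named missing residue, R152) and draws every
other position from the consensus with 5% substitution noise, a
conservation level in line with shaded alignment figures of conserved
domains.

Two design choices make recovery exact at *any* seed rather than merely
likely:

* **Group drift.** Real ERF groups diverge across the domain, not only at
  diagnostic sites; with markers alone, between-group p-distances barely
  exceed within-group noise and tree placement degrades. Each group (and
  RAV) therefore carries its own consensus at eight additional
  non-diagnostic positions. A deterministic share of each group's members
  (⌊0.15·n⌋+1, round-robin) reverts each drift position to the scaffold,
  capping within-group conservation below the 90% marker threshold, so
  drift separates the tree without ever entering the marker table.
* **Deterministic family allocation.** Each AP2-family variant position
  reverts in exactly three full-domain members (85% panel conservation),
  every gene deviates at most once (keeping the homology hint decisive),
  and exactly two full-domain members carry A150 against T150 for the
  rest. A post-pass guarantees no non-universal column is 100% conserved
  in every ERF group, so the universal-residue set is exactly the planted
  ten.

Partial domains are truncated at a transcript end, keeping 20–40 model
columns — at least 18 columns short of full, so a truncated domain can
never be promoted to full by the 6-column extension. UTRs are uniform
50–300 nt; coding flanks 30–80 amino acids; codons are drawn uniformly
among synonymous codons.

Planted miRNA sites take the reverse complement of an existing transcript
window as the miRNA and perturb the *miRNA* side only (one wobble outside
positions 9–11 for cleavage-type sites; a non-pairing base opposite
position 9 for translation-type), so planting never disturbs the
transcript or its domains; sites are placed in UTRs and CDS regions
outside the AP2 domain for the same reason.

The generator does **not** emulate 454 homopolymer errors, chimeric or
mis-assembled contigs, allelic variants collapsing into one contig,
frameshifts, or genuinely novel groups. Passing recovery tests on this
cohort therefore demonstrates that the pipeline's logic is correct on
clean data with the published structure — not that real contigs with
sequencing artifacts would classify as cleanly; on real data the partial,
frameshifted and divergent cases would land on the tree-placement and
homology-override paths, whose behaviour is exercised here only in their
clean form.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally; structural positions
145–202 appear only in displays and reports. Rounding of percentages is
half-up to one decimal. NJ requires ≥3 taxa, rejects asymmetric input, and
clamps negative branch estimates to zero with a flag. Block curation
errors when no run reaches the minimum length, suggesting a lower
threshold; p-distance errors on a pair with no comparable columns. The
scanner's tie-breaks are deterministic (leftmost start; smallest index
pair in NJ; lowest penalty, then leftmost, for overlapping miRNA hits).
Config validation names the offending field. All randomness flows from
explicit integer seeds, and the caller's RNG state is restored.

Problem sizes used throughout the analyses and tests: the 173-gene default
cohort, a 33-domain ERF reference panel (3 per group), 200 random 4- and
5-taxon trials for the NJ oracle, and 100+100 cases for the
planted-vs-random score separation check — sizes at which every stage runs
in seconds and the brute-force oracles remain exhaustive.

## Known limitations

* Family assignment of single-domain AP2 members depends on the
  informative-position profile; real lineages with divergent profiles
  would need the tree-placement fallback.
* The duplex energy model is per-pair additive; use a thermodynamic
  folding engine where absolute energies matter.
* Branch supports (bootstrap, aLRT) are out of scope; the NJ tree is a
  classification device, not a publication phylogeny.
* Subgroup letters exist only insofar as references carry them.
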