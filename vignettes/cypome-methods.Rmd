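---
title: "Mining bacterial CYPomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial CYPomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypome)
```

## The problem

Cytochrome P450 monooxygenases (CYPs/P450s) are heme-thiolate enzymes
whose substrate promiscuity and regio-/stereo-selectivity make them
central players in bacterial secondary metabolism. Marine actinomycetes
of the genus *Salinispora* are prolific producers of natural products,
and a large fraction of their P450 complement (the *CYPome*) sits inside
secondary metabolite biosynthetic gene clusters (smBGCs). `cypome`
implements the full analytical chain for this kind of study: mining P450
candidates from predicted proteomes, separating complete P450s from
fragments, assigning standard CYP nomenclature, profiling family
presence/absence across genomes, linking P450 genes to smBGC intervals,
and summarising the CYPome with a small set of closed-form statistics.

Because the original data live behind genome portals, the package also
ships two self-contained data sources:

* packaged TSV transcriptions of the published *Salinispora* summary
  tables (126 strains, family/subfamily counts, smBGC compositions),
  guarded by a manifest of row counts and column sums; and
* a synthetic-genome simulator that plants P450s, fragments, decoys and
  clusters with known ground truth, so every stage is testable offline.

## Identifying P450s: the motif-and-length rule

Complete P450s carry two diagnostic sequence motifs: the K-helix
**EXXR** tetrapeptide and the **CXG** core of the heme-binding loop
(the cysteine is the axial heme thiolate ligand). The classifier calls a
protein a complete P450 when both motifs occur, in order (EXXR before
CXG), and the sequence reaches a minimum length; a sequence with exactly
one motif, or with both motifs but short length, is a *P450 fragment*;
a sequence with neither motif is not a P450. Fragments are excluded from
all family and subfamily counts, mirroring standard practice.

Two parameters matter:

* **`minLength` (default 300 aa).** "Short" is not defined numerically
  in the field's rule of thumb; complete bacterial P450s run ~350–450
  aa, so 300 excludes clear truncations without rejecting compact P450s.
* **Motif windows (default on).** EXXR and CXG are C-terminal features
  (K helix and heme loop). A 4-letter pattern matches random sequence
  often, so by default EXXR must start in the C-terminal 60% of the
  sequence and CXG must lie within the final 120 residues, with EXXR
  strictly before CXG. `motifConfig(useWindows = FALSE)` widens the
  search to the whole sequence. When several candidate matches exist,
  the last window-compliant CXG is chosen together with the latest EXXR
  preceding it, mirroring the motifs' known placement.

The ambiguity code X is accepted in wildcard positions but never matches
the fixed letters E, R, C, G — a conservative reading of ambiguous
residues. One case the rule leaves open is both motifs present but out
of order at full length; we call it a fragment so that the three statuses
always partition the input.

When a precomputed P450 domain-hit table is available (e.g. InterPro
IPR001128 presence), `applyDomainPrefilter()` restricts candidates
before the motif rule; without it the motif rule alone governs.

## Nomenclature by percent identity

Family and subfamily assignment follows the International P450
Nomenclature Committee thresholds: a query joins the family of its best
named homolog at **>40%** identity and its subfamily at **>55%**;
below 40% it founds a new family. The committee rule does not fix the
identity definition; we compute **global (Needleman–Wunsch) alignment
identity** over full-length proteins — BLOSUM62 scores, gap open 10,
gap extend 0.5 — counting identical pairs over aligned residue pairs
with gap columns excluded. Global identity is the natural reading of
"percent identity" between complete P450s; all parameters are
configurable through `alignmentParams()`.

Boundary semantics are strict: exactly 40.0 falls to new-family and
exactly 55.0 to family-match (both ">" thresholds read literally). Ties
at the best identity resolve to the lexicographically smallest reference
name, for determinism.

Queries below the family threshold against every panel entry are grouped
among themselves by single-linkage at the same >40% threshold, so
mutually similar novel queries share one placeholder family
(`CYPNEW-1`, `CYPNEW-2`, ... in order of first occurrence) — the way a
cohesive novel family would be named once. Family-level matches without
a subfamily-level hit receive placeholder subfamilies (`!1`, `!2`, ...)
grouped by the same construction at >55% within the matched family; the
grouping rule at subfamily level was an open choice and we mirrored the
family-level one for coherence.

The package ships no curated panel: real named-P450 panels are
user-supplied FASTA (headers like `>CYP105AB1`), and the simulator
provides synthetic demonstration panels.

## Profiling, blooming, conservation, heat maps

`buildProfile()` tabulates complete P450s per genome and family
(genomes with no P450s keep all-zero rows). Three closed-form statistics
summarise a CYPome:

* average P450s per genome = P450s / species;
* P450 diversity percentage = 100 × families / (P450s × species with
  P450s);
* percentage of P450s in smBGCs = 100 × P450s in clusters / P450s.

Raw reals are always retained; report rounding (integer average, 2-dp
diversity, integer percentage) is applied only by `formatStats()`,
matching the precision such tables are printed at.

Two informal field notions are operationalised with explicit, exposed
thresholds: a family is **bloomed** when it has ≥3 copies in ≥50% of
genomes (duplication-driven expansion), and **conserved** when present
in 100% of genomes (both fractions adjustable).

The profile heat map follows the published convention: presence encoded
as 3 and absence as −3, rows (genomes) and columns (families) clustered
hierarchically on Euclidean distance. The linkage method is not stated
in the sources this convention comes from; we use **average linkage**
and cluster the binary encoding (it is the encoding the convention
describes). All-equal matrices return identity orderings with a warning.

## smBGC linkage

A P450 gene belongs to a cluster when it lies on the same genome and
contig and its interval is **fully contained** in the cluster interval.
Containment, not any-overlap, is the default because antiSMASH-style
cluster boundaries are generous — genes genuinely in a cluster lie
inside them; `overlap = TRUE` switches to any-overlap. Membership is
strand-agnostic and symmetric under coordinate mirroring. A gene inside
two overlapping clusters is recorded in both, with a warning.

Each cluster's **signature** is the comma-joined list of member
family+subfamily labels in gene order along the contig — order is kept
because orthologous clusters share gene order, and the published
composition "varieties" are order-sensitive strings. Aggregation by
cluster type counts clusters, distinct varieties and member P450s per
type. The packaged cluster table can be expanded into signatures
(`fixtureSignatures()`) and fed through the same aggregation; literal
`-fragment`-suffixed labels in the published table are preserved by
default (the pipeline itself never places fragment calls in signatures).

## Phylogeny

The original analysis aligned all P450s with MAFFT and inferred a "best
tree" on a web service; re-running web services is out of scope and
their settings are unrecorded. The package instead builds a
**neighbor-joining tree over all-pairs global-identity distances**
(`d = 1 − identity/100`). This is a declared method substitution: the
tree is accepted on properties — NJ is exact on additive matrices, and
planted families on simulated data come out monophyletic — never as a
reproduction of the original figure's topology. Negative NJ branch
lengths (a standard artifact on non-additive input) are clamped to zero
and counted in an attribute. `familyColoring()` exports the top-*k*
(default 8) most abundant families as color indices for external tree
viewers.

All-pairs alignment is quadratic, so the pipeline's tree stage works on
stratified per-family representatives (default 8 per family,
`treeMaxPerFamily`); family-level structure, which is what the coloring
shows, is preserved while keeping the stage at a few hundred alignments.

## The simulator and what it does (not) show

`simulateCypome()` generates: a panel of archetype P450s (length 420 aa,
motifs planted at window-compliant positions, mutual identity
rejection-sampled below 40%); genomes with per-family Poisson copy
numbers whose copies are mutated away from their archetype into a chosen
identity band; fragments made by heme-motif ablation or truncation below
the length threshold; motif-free decoys; and cluster intervals drawn
around contiguous blocks of planted member genes with margins smaller
than the intergenic gap, so containment recovers exactly the planted
membership.

Identity bands are enforced by **measure-and-resample**: a target
identity is drawn inside the band, the corresponding number of
BLOSUM62-weighted substitutions applied (motif columns frozen), and the
mutant re-aligned to its archetype; mutants landing outside the band are
resampled. Alignment identity is not a simple function of substitution
rate once gaps enter, and recovery guarantees need strict band
membership, hence measurement rather than a rate formula. Default bands
are 60–92% (subfamily), 43–53% (family) and 15–38% (novel), keeping
≥2-point margins around both thresholds so planted band membership is
never ambiguous at the boundary.

Default scale — 10 genomes × 6 families × ~3.3 copies ≈ 200 complete
P450s (~20 per genome, matching the per-genome averages reported for
actinomycete CYPomes), 5% fragment rate, up to 3 clusters per genome
with 1–6 members — keeps a full simulate–classify–assign–link round
trip within a couple of minutes on one CPU; the test suite uses this
scale for its end-to-end checks and smaller configurations elsewhere.

What passing on synthetic data does **not** show: real proteomes contain
atypical P450s lacking EXXR, gene-calling artifacts, identity values
sitting on the 40/55 boundaries, and families whose within-family
identity spread straddles thresholds. The simulator deliberately avoids
these (margins around thresholds, frozen motifs, substitutions-only by
default), so the recovery rates measure the pipeline's correctness, not
the biological difficulty of real classification.

## Numerical and degenerate-input choices

* Identity is reported in percent over aligned pairs; symmetric to
  1e-9 (alignment of (a,b) and (b,a) is the same optimum).
* Strict inequalities at both nomenclature thresholds; equality falls
  to the lower tier (documented above, covered by tests).
* Heat-map clustering ties are resolved by `hclust`'s deterministic
  index-based merging; degenerate all-equal matrices return identity
  permutations with a warning rather than an error.
* Empty inputs: an empty FASTA yields an empty record table (not an
  error); zero species or zero P450s make the affected ratio an error;
  an empty reference panel is an error.
* NJ requires a symmetric labelled matrix with n ≥ 3; negative branch
  lengths are clamped to 0 and counted.
* Every simulation output is a deterministic, byte-identical function
  of its configuration (including the seed).

## Known limitations

* The nomenclature engine assigns against a user-supplied panel; it does
  not consult the live nomenclature database, and allele-level numbering
  is out of scope.
* Global identity is one defensible reading of the committee rule;
  BLAST-style local identity can differ near the thresholds.
* The NJ tree is a distance method over pairwise identities, not a
  model-based phylogeny; use it for family-level structure, not for
  branch-length interpretation.
* Cluster membership by containment is a reproducible surrogate for
  portal-side gene-list membership; the two can disagree for genes
  straddling cluster boundaries.
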