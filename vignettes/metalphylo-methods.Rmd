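---
title: "Models and methods behind metalphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metalphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable
parameters, and the design decisions behind each stage of the
pipeline, in the order data flows through it. Nothing here states an
empirical result: the numbers the package produces are computed by
its test suite and by `scripts/acceptance.R`.

## Profile HMM search

### Model

A profile is built from a seed multiple alignment. Columns whose
residue occupancy is at least `occupancy_threshold` (default 0.5)
become match states; all other columns are insert-emitting. This
reproduces the familiar property that the number of match states is
smaller than the alignment length whenever some columns are
gap-majority. Match emissions are weighted residue counts plus a
background-proportional pseudocount of total weight
`pseudocount_weight` (default 1); the background is the smoothed
observed residue frequency of the alignment unless supplied.
Transition probabilities between the M/I/D states are estimated from
the per-row paths through the alignment under a weak prior favouring
match continuation (continuation prior 1.0, gap moves 0.125); the
rarely-observed I↔D moves are folded into the nearest supported move
so the scoring recursion stays on the standard M→M/I/D, I→I/M,
D→D/M topology.

Scoring is local, with deliberately simple semantics that the package
defines (rather than imitating any particular search program's
entry/exit weighting, which is out of scope): uniform `1/M` entry
into any match state, free exit from any match state, flanking
residues scored as background (0 bits), and insert emissions equal to
background. Both the Viterbi (best path) and Forward (sum over
paths) scores are reported in bits. Because the semantics are fully
specified, the scores are testable against exhaustive enumeration of
all paths on small profiles — the test suite and the acceptance
script both do this on profiles of up to 4 match states, where
enumeration is exact.

Ambiguity codes (B, Z, J, X, U, O) score as background-weighted
averages over their residue sets, so real proteomes never cause hard
failures. The empty sequence scores as the all-delete path, a
defined finite value, not an exception.

### E-value calibration

A Gumbel (extreme-value) law for maxima is fitted to decoy Viterbi
bit scores by maximum likelihood (profile likelihood in the scale
parameter, solved by safeguarded root finding on the standard score
equation; the weights are computed in a shifted exponential form so
large scores cannot overflow). E-values are
`E(s) = n · (1 − exp(−exp(−λ(s − μ))))`, on the database size `n`.
Calibration requires at least 500 decoys and refuses degenerate
(zero-variance) score sets. E-values are reported from Viterbi
scores; the Forward score is available from the same call.

### Threshold detection

Screening reports one row per sequence with `E ≤ cutoff`. The
empirical "breakdown" that separates a sharply-scoring family from
the background is formalized as the largest gap between consecutive
sorted log10 E-values: if the gap spans at least `min_gap_orders`
(default 3) orders of magnitude, the threshold is the geometric
midpoint of the two flanking E-values; ties resolve toward the
smaller (more stringent) threshold, and E-values of exactly 0 are
clamped to the smallest positive double. No threshold is reported
when no qualifying gap exists — the caller must then choose one.

## Alignment masking

Three filters, each of which records per-column provenance
(`kept` / `dropped-insertion` / `dropped-block`) and a strictly
increasing kept-to-original column map:

* **Insertion columns**: a column held by fewer than
  `occupancy_threshold` (default 0.5) of the rows is discarded.
  Whether a column at exactly 50% occupancy survives is genuinely
  ambiguous in the usual phrasing of this rule; the strict reading —
  *less than* 50% is dropped, exactly 50% is kept — is the default,
  with `keep_at_threshold = FALSE` as the documented switch for the
  other convention.
* **Conserved blocks**: each column is classified from the frequency
  of its most common residue (gaps excluded from the numerator,
  included in the denominator — the simplest reading of "identity").
  A column is *conserved* when that count strictly exceeds
  `min_conserved_fraction · n` (reproducing the "`n/2 + 1`"
  convention at the 0.5 default) and *highly conserved* (flank
  eligible) at `ceiling(min_flank_fraction · n)`. Runs of more than
  `max_contiguous_nonconserved` nonconserved columns are rejected,
  surviving blocks are trimmed to highly-conserved boundaries, blocks
  shorter than `min_block_length` are rejected, and the preset's gap
  rule (`none` / `half` / `all`) removes gap-bearing columns last.
  The named presets are: **loose** (0.50 / 0.50 / 10 / 5 / gaps in up
  to half), **medium** (0.50 / 0.85 / 8 / 10 / no gaps), **strict**
  (0.60 / 0.90 / 6 / 10 / no gaps). "Loose" and "medium" follow the
  parameter families of the classic block-selection program, and
  "strict" was chosen so that the three presets are parameter-wise
  monotone; the kept-column sets then nest (strict ⊆ medium ⊆ loose)
  by construction, a property the tests verify on random alignments.
  One simplification relative to the classic program: nonconserved
  columns *adjacent* to gap columns are not additionally removed.
* **Partial sequences**: rows with strictly more than
  `missing_threshold` (default 0.5) missing characters relative to
  the row with the most residues are removed; the boundary case (a
  row at exactly 50% missing) is kept, matching the strict reading of
  "more than".

The built-in progressive aligner (average-linkage guide tree on 3-mer
distances, profile–profile global alignment under BLOSUM62
column-average scoring with affine gaps costing
`gap_open + g · gap_extend`) is a deterministic fallback for
desk-scale inputs; externally computed alignments can be imported
instead, and for production-size datasets they should be.

## Tree inference

Distances are maximum-likelihood estimates per sequence pair:
the independent-sites likelihood under a reversible empirical
exchangeability model (LG by default; WAG, JTT and others are
available from the same model store, plus a Poisson equal-rates
model) with stationary frequencies and discrete-gamma rate
heterogeneity (k = 4 equal-probability categories, each category rate
the mean of its quantile interval). Gap columns are
pairwise-deleted. The optimization is a bracketed one-dimensional
search on t ∈ [0, `t_max`] (default 10 substitutions/site); saturated
pairs are capped at `t_max` with a warning, identical pairs return
exactly 0. In the equal-rates uniform-frequency limit the optimum
has the 20-state closed form `−(19/20)·ln(1 − 20p/19)`, which the
tests check to 1e-6; phangorn's independent ML-distance
implementation serves as a cross-check oracle, never as the
implementation.

Trees come from canonical neighbor joining with two determinism
guarantees: tied minimal Q-criterion entries resolve to the lowest
(row, column) index pair, and negative branch lengths are clamped to
zero. On additive matrices NJ is consistent, so the tests demand
exact topology recovery (Robinson–Foulds 0) on random 6–12-leaf
trees. Full ML or Bayesian topology search is intentionally not
re-implemented — externally computed trees (e.g. from PhyML or
PhyloBayes runs) are imported via Newick/NEXUS with support-kind
auto-detection (values ≤ 1 are tagged posterior probabilities,
otherwise bootstrap percentages).

Bootstrap support resamples alignment columns with replacement (100
pseudo-replicates by default; replicate r seeds the generator with
`seed + r`, so runs are reproducible and replicates independent),
rebuilds each replicate tree with the same distance + NJ engine, and
reports for every internal bipartition of the point tree the
percentage of replicates containing it. Supports are additionally
stored keyed by canonical tip set, so they survive rerooting, and
`split_support()` queries the support of any named split.

Outgroup rooting places the root on the branch subtending the
smallest clade containing all outgroup taxa; a non-monophyletic
outgroup triggers a warning and rooting on the branch maximizing
outgroup/ingroup separation. Ladderization sorts children by
descendant-leaf count with lexicographic tie-breaking, touching only
the edge order — node numbers, metadata and the bipartition set are
invariant, and the operation is a fixed point under reapplication.

## Annotation and subgroup assignment

Specificity labels transfer from the best local-alignment hit against
a user-supplied reference panel (exact Smith–Waterman via Biostrings,
BLOSUM62 with gap open 11 / extend 1; raw scores convert to bits with
the published gapped-BLOSUM62 constants λ = 0.267, K = 0.041). Ties
break by longer aligned span, then lexicographic id; hits below
`min_score` (default 50 bits) yield `"unassigned"`.

The TM6 motif is read at homologous alignment columns anchored on a
named reference row whose motif position is given in its own ungapped
coordinates — not located by transmembrane-topology prediction, which
is out of scope. Because block filtering changes the reference's
ungapped coordinate frame, motif calls are made on the unmasked
alignment. Trigram classes: `CP*` → CPx, `SPC`, `APC`, anything else
`other`; a gap in any of the three columns gives `unresolved`.

Taxonomy comes from a 4-column table (or NCBI-style dumps); internal
nodes are annotated with the lowest common ancestor taxon of their
descendant leaves, and unmapped leaves are kept with an `"unknown"`
label and a warning, never dropped. Collapsing at a rank replaces
every maximal clade (two or more leaves) whose leaves share one taxon
with a pendant node named for the taxon, carrying the leaf count and
the incoming branch plus the clade's maximum depth as branch length;
singleton leaves are left as they are, so collapsing at a rank where
every leaf is distinct leaves the tree unchanged.

Subgroup assignment takes a named anchor set per subgroup (reference
proteins). Each subgroup's clade is the smallest rooted clade
containing all of its anchors; every leaf goes to the smallest anchor
clade containing it, leaves in none are `"unassigned"`, and a
monophyly verdict reports whether a clade contains only its own
subgroup's leaves. Anchors should span their subgroup — in practice
two or three references from distant lineages; the test fixtures pick
up to three subfamily members from species chosen greedily for
maximal spread on the species tree, which is how a curator would pick
references.

## EST integration

Six-frame translation uses the standard code (stops `*`, fuzzy codons
`X`). For each fragment the best-scoring frame is recruited against
the calibrated family profile; the Viterbi traceback gives the
matched profile columns, which map back to alignment columns because
the profile records its match-column positions. Three rejection
gates formalize what would otherwise be manual curation: `min_bits`
(default 20), `min_match_states` (default 50 — the "too partial to be
placed" judgment call), and a maximum fraction of `*`/`X` in the
matched region (default 2%). Contig assembly then operates in
alignment-column space: fragments of one organism merge when their
matched columns overlap by at least `min_overlap_columns` (default
10) with at most `max_overlap_mismatch` (default 5%) disagreement,
the higher-scoring fragment winning on the overlap; disagreeing
overlaps stay separate as putative paralogs. Orthology is a margin
test — best bits against an ortholog panel must exceed best bits
against a paralog panel by `margin` (default 5 bits) for insertion;
the converse gives `"paralog"`, the band between `"ambiguous"`.
Insertion writes matched residues at their columns and gap-fills the
rest; pre-existing rows and the kept-column set are untouched
(checked bytewise in the tests).

## Census and logos

The presence/absence matrix counts proteins per genome × category;
binary presence is derived, and co-occurrence regions for 2 or 3
categories always sum to the genome count (integer conservation is an
invariant, not a hope). Taxonomic breakdowns report per-category
genome totals, distinct-taxon counts at a rank, and per-taxon
fractions; genomes without the rank count under `"unranked"` with a
warning. Logo matrices track residue frequencies per column plus an
explicit gap mass, so columns sum to 1 within 1e-12 (testable) while
the gap row is simply not drawn; information mode computes
`R = log2(20) − H` with gaps excluded from the entropy and no
small-sample correction. Region extraction maps an interval in a
reference row's ungapped coordinates to alignment columns and labels
the slice with the reference numbering.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline
assumes: one ancestral gene radiating into named subfamilies at depth
`ancestral_divergence` (caterpillar order over the subfamily labels),
each subfamily then evolving down a species tree under a
continuous-time birth–death walk (duplication/loss events Poisson in
branch length), sequences evolving site-wise under LG + Γ₄ (matrix
exponentials of the scaled rate matrix via a symmetric
eigendecomposition; per-site gamma categories fixed across the tree),
and the subfamily motif written over the anchored columns after
simulation so that truth labels are exact by construction.
CDSs for EST simulation are back-translated with uniform synonymous
codon choice; fragments are drawn from the sense strand at random
offsets with i.i.d. point errors.

Default study conditions used by the tests and the acceptance script:
6 species on a coalescent tree of depth 0.25 substitutions/site, five
subfamilies (an outgroup plus IB-1, chloroplast IB-1, IB-2, IB-4 —
the chloroplast pair mirroring a nested ancestral duplication, IB-4
carrying SPC), 180-residue proteins, duplication rate 0.05 and loss
rate 0.02 per unit branch length, ancestral divergence 0.5. These
sizes keep a full recipe run (alignment, 100 bootstrap replicates,
rooting, assignment, motifs, logos) to a couple of minutes on one
core while leaving enough divergence that the stages are genuinely
exercised; no published values exist for them, so they are fixtures,
chosen once.

What the generator deliberately does **not** emulate — and hence what
green tests do *not* establish about real data: insertions and
deletions inside the family core (alignment columns are known by
construction, so the aligner and the masking rules face easier inputs
than real proteomes), codon usage bias and selection, rate shifts
across lineages, compositional heterogeneity, and contamination or
horizontal transfer other than what duplication/loss produces.
Results on real proteomes depend on alignment quality and model
adequacy in ways the synthetic truth cannot certify.

## Numerical choices

* All dynamic programming is in log2 space; Forward uses
  max-offset log-sum-exp (exact to within double rounding for the
  magnitudes involved).
* The Gumbel score equation is solved on a bracket scaled by the
  score standard deviation; weights use a shifted exponential to
  avoid overflow at large λ.
* `optimize()` never evaluates interval endpoints, so near-zero
  distance optima are snapped to exactly 0 when the boundary
  likelihood is at least as good.
* Branch lengths are serialized with `%.10g`; round-trip tests demand
  1e-9 agreement.
* Deterministic tie-breaks everywhere a tie can occur: NJ pair
  selection, traceback preference order (match, insert, delete),
  ladderization, best-hit label transfer.

## Limitations

* The in-house tree engine is distance-based; it stands in for — and
  does not claim parity with — full ML or Bayesian topology search.
  Import externally computed trees where that matters.
* Profile scoring has no composition-bias or multi-hit corrections;
  E-values are honest only relative to the decoy model used for
  calibration.
* The progressive aligner is quadratic per merge and intended for
  family-scale, not proteome-scale, alignment.
* The orthology margin test is a formalization of an unpublished
  manual procedure; its thresholds (`margin`, panels) are judgment
  calls exposed as parameters, not validated constants.
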