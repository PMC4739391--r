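---
title: "Evaluating candidate DNA barcode loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating candidate DNA barcode loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeGauge)
```

## The problem

A DNA barcode is useful when the genetic distance between species
comfortably exceeds the variation within them — the "barcoding gap" —
and when an unknown specimen, matched against a reference panel,
lands on the right species. For congeneric medicinal plants the
stakes are practical: permitted botanical origins and their
adulterants are congeners, so the discriminating signal must come
from a short, amplifiable locus. This package implements the
evaluation battery used to compare candidate loci (ITS2, *rbcL*,
*psbA–trnH*, ITS, *matK*) on a common accession panel, together with
a simulator that generates congeneric datasets with known truth so
every stage can be validated without downloads.

## Distance model

All distances are Kimura 2-parameter (K2P):

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q) $$

with `P` the proportion of transition differences (A↔G, C↔T) and `Q`
the proportion of transversions, computed per pair over the alignment
columns where both rows carry an unambiguous base (**pairwise
deletion**). Pairwise deletion is the default because it is the usual
choice for barcoding panels with ragged ends and scattered
ambiguities; complete deletion is available via
`distance_matrix(..., deletion = "complete")`. When `1 - 2P - Q` or
`1 - 2Q` is non-positive the pair is saturated: the entry is flagged
`NA` and excluded from all downstream means rather than silently set
to zero, because a zero would masquerade as identity precisely where
the signal is least trustworthy.

## Divergence parameters

Six summaries, each mean ± SD:

- **all_intra / all_inter** pool every conspecific / heterospecific
  pair;
- **θ** and **coalescent depth** are the per-species mean and maximum
  conspecific distance, averaged across species with ≥ 2 accessions;
- **θ′** and **minimum interspecific distance** are the per-species
  mean and minimum distance to congeners, averaged across all species.

θ′ and the minimum interspecific distance are defined per species and
then averaged; the barcoding literature uses these per-species
summaries, and the per-species-then-average convention keeps a
heavily sampled species from dominating the genus-level figure.
Species with a single accession cannot contribute intraspecific
values and are excluded from those denominators only.

## Barcoding gap and locus comparison

`barcoding_gap()` bins conspecific and heterospecific distances into
histograms (default bin width 0.005 substitutions/site, a round value
that resolves the intraspecific mode of a typical spacer) and reports
an overlap statistic: the fraction of intraspecific distances at or
above the 5th percentile of the interspecific distribution. A clean
gap gives ≈ 0; identical distributions give ≈ 0.95 by construction
(the definition trims the lower 5 % of the interspecific mass).

`compare_loci()` compares two loci by pairing the distances that
belong to the same unordered accession pair in both loci and applying
the Wilcoxon signed-rank test. Zero differences are dropped and ties
mid-ranked. Up to n = 25 non-zero differences the two-sided p-value
is exact, computed from the full null distribution of the positive
rank sum over all $2^n$ sign assignments (doubling the mid-ranks
makes them integers, so the distribution is built by exact integer
convolution); beyond that a normal approximation with continuity and
tie corrections takes over. The reported direction follows the sign
of the median difference. Joining on shared accession pairs is a
design choice: the original analyses of this kind do not state their
pairing scheme, and published rank sums are not reproducible from the
marginal data, so the package treats direction and significance — not
the W values — as the comparable output.

## Identification efficiency

Both leave-one-out criteria remove the query from the panel and
assign it the species of its best reference:

- **nearest distance**: smallest K2P distance;
- **top hit**: highest local-alignment score, an in-package stand-in
  for a BLAST top-hit criterion. The affine-gap Smith–Waterman engine
  is used instead of an external BLAST executable so results are
  deterministic and the package self-contained; no E-values or
  heuristic seeding are involved.

Tie policy: if several references tie for best and span more than one
species, the query counts as a success only when all tied references
are conspecific with it. This "all-tied-conspecific" rule was chosen
over "first hit wins" because it makes the outcome independent of
record order. Queries whose species has no second representative are
excluded from the species-level denominator — they cannot possibly be
matched correctly — and count at genus level only. This choice shifts
percentages relative to analyses that keep singletons in the
denominator and is therefore stated prominently here.

## Trees and monophyly

`nj_tree()` wraps the Saitou–Nei neighbor-joining implementation in
\pkg{ape}. Undefined (saturated) entries are imputed as 1.1 × the
largest defined distance — keeping saturated pairs peripheral without
failing the run — unless more than 5 % of entries are undefined, which
aborts. Negative branch lengths are clamped to zero with the deficit
moved to the sibling branch (standard practice; raw lengths are kept
in an attribute). A species' accessions are "misplaced" when they
fall outside the largest bipartition side containing only that
species; the total misplaced count operationalizes "accessions in an
incorrect taxonomic category", for which no formal criterion exists
in the source analyses.

## Alignment

The pairwise engine scores +1/−1 with affine gaps (−5 to open, −1 to
extend; a gap of length k costs `gap_open + (k-1)·gap_extend`). These
defaults approximate classic DNA alignment settings of
ClustalW-generation tools; all are exposed as arguments. Traceback
ties are broken deterministically (diagonal, then up, then left) so
identical inputs always give identical alignments. The progressive
multiple aligner builds an NJ guide tree from pairwise identity
distances and merges profiles in postorder; it deliberately omits
ClustalW's sequence weighting and iterative refinement — at
within-genus divergences (< 0.12 substitutions/site) profile merging
recovers essentially the same columns, which we verified by comparing
K2P distance summaries against mafft alignments of simulated data.

Variable sites are columns with ≥ 2 distinct unambiguous bases; gap
and ambiguity symbols never make a column variable. Indels are
counted as *events* — distinct (start, end) intervals of maximal gap
runs — because a single shared deletion is one mutation regardless of
how many accessions carry it; a column-count mode is provided for
comparison with tools that report gapped columns.

## Diagnostic features

Species-diagnostic insertions are detected as maximal homopolymer
runs (≥ 6 bp by default) and perfect tandem arrays (unit 3–10 bp,
≥ 2 full copies, ≥ 12 bp total; the smallest rotational unit is
reported, and period-1 arrays are left to the homopolymer detector).
Only perfect repeats are sought — the diagnostic insertions this
workflow targets are perfect, and approximate-repeat finding would
add parameters without adding discrimination.

Inversions are found by locally aligning the reverse complement of
the query against a reference and keeping blocks of at least 50 bp at
≥ 98 % identity that score strictly better than the forward-strand
alignment of the same segment; hits are masked and the scan repeated,
so multiple inversions can be reported. The full-matrix local
alignment is used rather than a windowed scan: barcode loci are a few
hundred bp, so the exhaustive search is both simpler and faster than
windowing at these sizes. All feature coordinates are 1-based
inclusive on the ungapped sequence (BED export converts to 0-based
half-open at the writer).

## The simulator

`simulate_dataset()` generates a congeneric panel with known truth:

- a star-like species tree whose stems average
  `(target_inter − target_intra)/2` with 8 % lognormal jitter, and
  star-like within-species depths averaging `target_intra/2` with
  15 % jitter — so conspecific and heterospecific path lengths hit
  the two targets in expectation. The star shape matches the
  situation barcoding cares about (well-separated species, shallow
  intraspecific structure); it does not emulate deep cladogenesis
  within the genus, incomplete lineage sorting, or introgression, so
  passing tests say nothing about loci whose failure mode is shared
  ancestral polymorphism;
- sequences evolved from a root of configurable GC content under a
  two-rate substitution process with transition/transversion ratio
  κ = 2 by default (a typical plant spacer value). Substitutions are
  applied as Poisson events (rate = branch length × sites) placed
  uniformly; multiple hits arise naturally and the K2P estimator
  corrects them, which the tests verify against the configured
  branch lengths;
- indels as Poisson events (default 0.02 events/site per unit branch)
  with geometric lengths of mean 3 — unstated by typical source
  studies and chosen as a realistic spacer regime;
- planted diagnostic features (poly-A run, tandem `ATTAAA`, a 74-bp
  inversion) injected after evolution at one shared coordinate per
  feature across the carrier species, since a diagnostic feature
  models a single evolutionary event. Positions are drawn at random
  and rejection-checked so every planted feature is maximal and
  detectable at exact coordinates in every carrier (e.g. a poly-A
  run is never planted next to an existing A); each carrier's
  pre-inversion sequence is retained as the detection reference.

Two presets encode contrasting regimes: `"ITS2"` (intra 0.006, inter
0.035, GC 0.66, 220 bp — short, GC-rich, gap-poor) and `"psbA-trnH"`
(intra 0.048, inter 0.107, GC 0.25, 287 bp — AT-rich, highly
divergent). Every random draw derives from the single `seed`, and the
same seed reproduces the dataset byte for byte.

## Numerical choices and degenerate inputs

- Exact signed-rank enumeration switches to the normal approximation
  above n = 25 (the integer-convolution table stays exact and cheap
  to n = 25; beyond that the approximation error is far below the
  decision threshold of any locus comparison).
- All-zero difference vectors give p = 1 and direction "equal".
- Locus pairs sharing fewer than 4 accession pairs are flagged
  "underpowered" and not tested.
- Saturated distance pairs: flagged `NA`, excluded from means,
  imputed peripherally only for tree building (above).
- NJ on < 3 taxa, alignment of empty sequences, and empty datasets
  are hard errors with informative messages rather than silent
  degeneracies.
- QC is idempotent: filtering an already filtered dataset changes
  nothing (verified as a property test).

## Problem sizes used in validation

The shipped tests and the acceptance script validate parameter
recovery on 10 species × 5 accessions × 500 bp over 5 seeds, gap
behavior on 10 × 5 × 300 bp panels at inter/intra ratios 10 and ~1,
feature recovery on 100 seeded 300-bp simulations (plus 100
feature-free ones for false positives), NJ exactness on 50 random
additive matrices up to 12 taxa, and signed-rank exactness against
full sign enumeration for 200 samples with n ≤ 10. These sizes give
tight Monte Carlo error (e.g. ±6 % realized relative error on the
intraspecific target) while keeping a full run in tens of seconds.

## Known limitations

- The aligner is a plain progressive profile aligner; on loci with
  extensive length variation beyond the within-genus regime it will
  diverge from ClustalW/mafft output, and distance summaries at small
  panel sizes (few species, ~200 bp) carry substantial Poisson noise
  regardless of aligner.
- The top-hit method emulates a BLAST1-style criterion with exact
  local alignment; scores are not BLAST bit-scores, so per-query
  agreement with a real BLAST run is expected but not guaranteed at
  near-ties.
- Overall mean divergence uses K2P; analyses computed with the
  maximum-composite-likelihood model will differ in absolute value
  (locus *ordering* is the robust comparison).
- Published accession panels can only be reproduced to the extent the
  sequences are fetched; the package ships the accession table (so
  panel counts are reproducible offline) but no sequence data, and
  quantities that depend on the actual sequences — per-locus GC,
  length means, the published efficiency percentages, the 4-of-77
  misplaced accessions — additionally depend on the exclusion rules
  and tie policies documented above.
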