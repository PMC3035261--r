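---
title: "Genome-to-genome distances and digital DDH: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-to-genome distances and digital DDH: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdp)
```

## The problem

Wet-lab DNA-DNA hybridization (DDH) is the conventional yardstick for
deciding whether two prokaryotic strains belong to the same species: below
roughly 70% DDH similarity, a novel species can be established.  DDH is
slow, laboratory-bound and not incrementally reusable, so distances
computed directly from genome sequences are an attractive replacement.
This package implements one family of such distances — Genome BLAST
Distance Phylogeny (GBDP) — in which intergenomic distances are derived
from sets of local matches (high-scoring segment pairs, HSPs, or maximal
unique matches, MUMs) and then mapped onto the familiar DDH percent scale
through calibrated linear models.

## The procedure

The method has three steps.

**1. Match detection.**  Local similarities between the two genomes are
collected.  Because heuristic similarity search is asymmetric, the search
runs twice, with the roles of query and subject exchanged.  The package
ships its own deterministic finders — an exact-word seed-and-extend HSP
finder with ungapped x-drop extension (`findHSPs()`) and a MUM finder
(`findMUMs()`) — and ingests the output of external tools (NCBI-BLAST
tabular via `parseBlastTabular()`, MUMmer match files via
`parseMummer()`).  Match sets can be stored compactly in a CGVIZ-style
text format (`writeCgviz()`/`readCgviz()`) that records coordinates,
alignment length, identities, score, and the e-value on the log10 scale.

The built-in finders are stand-ins for the external tools, not
re-implementations of them: similarity search is a pluggable step and the
method's substance lies downstream.  Consequently no claim is made that
the built-in finder reproduces the sensitivity or runtime behaviour of
BLAST and friends; its e-values use fixed, approximate Karlin–Altschul
constants ($\lambda = 1.28$, $K = 0.46$ for the default +1/−2 scoring).
The documented command-line presets for the external tools are available
from `alignerPresets()`.

**2. Distance calculation.**  Matches with an e-value above $10^{-2}$ are
first removed (`filterByEvalue()`; equality at the cutoff is kept, reading
"above" literally).  Overlaps are then resolved in one of two ways:

* *greedy-with-trimming* (`greedyTrim()`): matches are accepted in
  descending score order and every later match is trimmed to its longest
  contiguous part that overlaps no previously accepted interval on
  *either* genome.  The output is guaranteed pairwise non-overlapping on
  both genomes — this postcondition, not the specific trimming mechanics,
  is what the distances depend on.
* *coverage* (`coverageBases()`): the union of matched positions is
  measured without trimming.  This pathway pairs with the MUM engine.

From the resolved match set, with $G$ the minimum or average of the two
total genome lengths, three ratios are formed:

1. total matched length / $G$,
2. identities / total HSP length,
3. identities / $G$,

and the distance is $d = 1 - \mathrm{ratio}$ (optionally
$-\ln(\mathrm{ratio})$).  Formula 2 does not involve $G$ at all, which is
why it is robust to incomplete genomes: removing a third of one genome
removes matches and their aligned columns in equal measure.  Formulas 1
and 3 deliberately do involve $G$ and therefore respond to missing
genome fraction.  The two per-direction distances are combined by their
arithmetic mean (`symmetrizeDistance()`); the combination rule is
intentionally isolated in one function so it can be swapped.

**3. Conversion to DDH-analogous similarities.**  A registry of 13
calibrated linear models $s(d) = c + m\,d$ (one per combination of search
method, overlap algorithm and formula) converts distances to percent
similarities (`toSimilarity()`), and a per-model distance threshold makes
the species call (`classifySpecies()`): a distance *strictly above* the
threshold indicates two distinct species.  The registry is shipped as a
plain-text table so that refitted constants can replace it;
`fitConversion()` refits a line from user-supplied (distance, DDH) pairs.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `evalueCutoff` | `1e-2` | e-value filter before overlap resolution |
| `algorithm` | `trimming` | overlap handling (`coverage` for MUMs) |
| `formula` | `2` | headline distance ratio; all three are reported by `runPair()` |
| `lengthMode` | `average` | how $G$ enters formulas 1 and 3 |
| `useLog` | off | $-\ln$ transform of the ratio |
| `wordSize` | 11 | HSP seed length; larger is faster, less sensitive |
| `xdrop` | 20 | extension termination (score drop from the running best) |
| `minScore` | 30 | HSP report threshold |
| `minLength` (MUM) | 44 | minimum exact-match length |

`lengthMode = "average"` is the default because it is symmetric under
exchange of the genomes by construction; the choice between minimum and
average has little practical effect, as does `useLog`.  Formula 2 is the
recommended headline — and the one that must be used when genomes are
incomplete — while formula 3 tracks overall relatedness more closely when
completeness can be assumed.

## Design choices

Several points are underdetermined by the method's published description;
the package fixes them as follows.

* **Internal coordinates are 1-based inclusive** (the IRanges/Biostrings
  convention of the host ecosystem); every file dialect is converted at
  the boundary.  The CGVIZ dialect on disk is 1-based inclusive, writes
  e-values as log10, uses `.` for absent fields, and adds optional
  per-record header lines so multi-replicon genomes re-validate on read.
* **Trimming details.**  Score ties are broken by longer alignment, then
  query start, then subject start, making the procedure fully
  deterministic.  A trimmed match keeps the single longest surviving
  fragment; its alignment length and identities are rescaled by the
  retained fraction of the query span (rounded half-up, identities capped
  at the alignment length) and its score proportionally (unrounded, since
  scores are real-valued).  Whether the original implementations rescaled
  or recomputed trimmed statistics is not documented; proportional
  rescaling is this package's choice.
* **E-value sentinel.** A reported e-value of 0 becomes $-400$ on the
  log10 scale: finite, orderable, far below any plausible cutoff.
* **Ambiguity codes** collapse to `N` at input, and `N` never matches
  anything (not even `N`), so identities are counted conservatively.
* **MUM uniqueness** is defined as: the matched substring occurs exactly
  once in each genome, counting both strands.  Exact matches are maximal
  (extension by one base breaks them).
* **Robust refitting** uses the Theil–Sen estimator (median of pairwise
  slopes; intercept as the median residual), which is deterministic,
  needs no tuning, and tolerates gross outliers that break least squares.
* **Similarities are clamped to [0, 100]** for reporting, since a DDH
  analogue should be a percentage and two calibrated intercepts exceed
  100; the unclamped value is always reported alongside.
* **Species threshold is strict**: equality at the threshold is not
  called distinct.

## The synthetic-data generator

`randomGenome()` and `evolvePair()` provide seeded, reproducible inputs:
an i.i.d. ancestor with configurable GC content, per-site substitutions,
block inversions and translocations, and — applied last, so the fraction
is directly interpretable as missing genome — contiguous deletions
emulating incomplete sequencing.  A single seed derives all per-stage
seeds, and the applied events are returned as a truth log.

What the generator does *not* emulate: realistic indel length spectra,
repeat families and low-complexity regions, horizontal transfer,
compositional heterogeneity along the genome.  Tests passing on this
generator therefore demonstrate the correctness of the distance machinery
and the qualitative behaviour of the formulas (e.g. formula 2's
robustness to deletion), not calibration accuracy on real genomes — the
shipped conversion constants come from external calibrations on real
data and are used as published.

## Worked example

```{r example}
pair <- evolvePair(20000, substitutionRate = 0.05, seed = 4)
report <- runPair(pair$ancestor, pair$derived, quiet = TRUE)
report[, c("formula", "distance", "ddh", "distinct")]
```

At 5% divergence the formula-2 distance sits close to the substitution
rate (identities per aligned column), while formula 1 stays near zero
because almost the whole genome is covered by matches.  The formula-2
distance is far above its species threshold (0.0412), so the pair is
called distinct — consistent with 5% nucleotide divergence being well
beyond the species boundary.

## Numerical and scale choices

Test and example problem sizes (2–20 kb genomes, up to a few thousand
matches) were chosen so the full suite exercises every code path,
including the 20 kb deletion-robustness simulations, at desk scale; the
finders are implemented in C++ and handle these sizes in fractions of a
second.  Distances are exact rational arithmetic in double precision;
round-trips through the text formats are tested to $10^{-9}$ on
real-valued fields; direction symmetry of the bidirectional pipeline is
exact to $10^{-12}$.  Degenerate inputs are defined, not errors: an empty
match set saturates the distance at 1 (or the cap 99 under the log
transform), and a single genome yields a valid 1×1 zero matrix.

## Known limitations

* The built-in HSP finder performs ungapped extension only; gapped
  alignment, DUST/seg masking and translated searches are out of scope.
  For publication-grade similarity search, run the external tools with
  the documented presets and ingest their output.
* The shipped conversion constants apply to the match engines they were
  calibrated on; applying the `ncbi-blast` row to built-in-finder output
  (the default, with a logged caveat) is an approximation.
* The greedy overlap resolution is not globally optimal; it implements
  the standard greedy-with-trimming scheme whose two-sided non-overlap
  postcondition the distances require.
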