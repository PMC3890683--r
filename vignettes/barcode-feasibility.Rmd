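---
title: "Assessing the feasibility of DNA-barcode identification with barcodeID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the feasibility of DNA-barcode identification with barcodeID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeID)
```

## The problem

A DNA barcode reference library promises to identify a specimen from a short
standardized mitochondrial fragment (~658 bp of COI) by comparing its
sequence against morphologically identified vouchers. Whether that promise
holds for a particular taxonomic group is an empirical question: it fails
when intraspecific variation overlaps interspecific divergence (no "barcode
gap"), when species share identical haplotypes, when the library contains
species represented by a single sequence (singletons), or when population
structure (geography, host races) inflates within-species distances.

`barcodeID` evaluates a library's fitness for identification the way
feasibility studies in this field do: every sequence is used as a query
against all remaining sequences (leave-one-out), each query receives a
verdict under several published criteria, and threshold-based accounting of
true and false positives and negatives turns the verdicts into quantitative
reliability statements — including a regression-based *ad hoc* threshold
whose sign says whether the library should be trusted at all.

## Distances

All comparisons use the Kimura 2-parameter distance,

$$d = -\tfrac{1}{2}\,\ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\,\right],$$

with $P$ and $Q$ the proportions of transitional and transversional
differences over the compared sites. Sites are compared under **pairwise
deletion**: a column counts for a pair only when both sequences carry an
unambiguous A/C/G/T there; partial matches against IUPAC ambiguity codes are
never credited. Distances are held as proportions internally — percent
appears only in reports, which avoids an entire class of unit bugs in a
literature that mixes "0.3%" and "0.003" freely. Saturated pairs (where the
logarithm's argument is non-positive) and pairs with no comparable sites are
recorded as *undefined* and excluded from pools with a warning; they never
abort a run. This situation does not arise at barcode-level divergences but
the policy must exist and be conservative.

```{r distances}
truth <- simulate_dataset(preset("clean", seed = 1))
ds <- truth$dataset
dm <- distance_matrix(ds)
summarize_distances(dm, ds)
```

The summary pools pairs as: intraspecific (same species), interspecific
(different species), intrageneric (different species, same genus),
intergeneric (different genera), with outgroup comparisons kept apart.
Empty pools are reported as absent, never as zero. The barcode-gap overlap
is the fraction of all ingroup comparisons falling between the minimum
interspecific and the maximum intraspecific distance — zero means a clean
gap.

## Trees

Tree-based criteria run on a neighbour-joining tree built from the distance
matrix. The agglomeration is the standard Saitou–Nei procedure with two
deliberate determinism choices, since published software does not document
its own: ties in the Q criterion break toward the lowest index pair (merged
nodes appended last), and negative branch lengths are clamped to zero with
the deficit moved to the sibling branch, preserving the pair's path length.
On additive matrices the implementation reconstructs the generating tree
exactly (this is property-tested against random trees and against an
independent NJ implementation).

Internal branches of length at most `epsilon` (default `1e-9`, i.e.
effectively zero) can be collapsed into polytomies — the structure the
node-level criterion reasons about. Rooting places the root on the
outgroup's pendant branch. Order matters: collapse first, then root, because
rooting introduces a zero-length root edge that a later collapse would undo.
Bootstrap supports resample alignment columns with replacement and count
bipartition recurrence across replicate trees.

## Identification criteria

Five criteria, two families. Throughout, outgroup sequences are never
queries and never candidate matches, and a singleton species can never be
"correct" — there is no conspecific in the library to match.

**Tree-based.** *NJT*: a species is correctly identified when its sequences
form an exclusive cluster (the minimal spanning clade of its leaves contains
no foreign leaf); a species scattered across the tree is misidentified;
singletons are ambiguous. All sequences of a species share its NJT outcome.
*NJT_M* judges each sequence individually, one node into the tree: with
$S(v)$ the other leaves under the sequence's parent $v$, an all-conspecific
$S(v)$ of size ≥ 2 is correct, an all-foreign $S(v)$ of size ≥ 2 is
incorrect, and singletons, single-sibling (sister-group) configurations and
mixed polytomies are ambiguous. The published wording of the sister-group
case is ambiguous between a narrow cherry reading and a broader one; the
narrow reading is used and isolated behind a single internal predicate so
the alternative is a one-line change.

**Similarity-based.** *BM* (Best Match): the nearest neighbour decides;
equally-near matches (within a `1e-12` absolute tie tolerance — distances
are ratios of small integers, so representation noise must not create or
destroy ties) from more than one species make the query ambiguous; a tie
entirely within one foreign species is a misidentification. *BCM* (Best
Close Match) adds a distance threshold: a best match beyond it is
`no_match`. *ASB* (All Species Barcodes) is the strict variant: within the
threshold, identification succeeds only if every conspecific outranks every
allospecific; a foreign sequence interleaving before the least-similar
conspecific gives ambiguity; a foreign species entirely closer than all
conspecifics gives misidentification. A singleton query with an in-threshold
match is ambiguous under ASB: its "all conspecifics on top" condition is
vacuously true, and counting vacuous truth as success would contradict the
fact that singletons cannot be identified.

```{r criteria}
thr <- intraspecific_percentile_threshold(dm, ds)   # 95th percentile
evaluate_dataset(ds, "BCM", dm = dm, threshold = thr)
```

Percentages are rounded half-up to two decimals; the underlying counts are
always carried alongside, since published tables in this field demonstrably
mix rounding conventions.

## Thresholds, errors, and the ad hoc threshold

The conventional BCM/ASB threshold is the 95th percentile of all pooled
intraspecific distances, computed by linear interpolation between order
statistics ($h = (n-1)p + 1$; the choice is isolated and configurable since
the historical tools never published theirs).

For threshold diagnostics each query is classified against a threshold
$t$: **TP** correctly identified with best distance ≤ $t$; **FP** not
correctly identified (ambiguity included) below $t$; above $t$, **FN** if
the best match was conspecific (a correct identification was discarded) and
**TN** otherwise (a misidentification was correctly rejected). From these:
accuracy $TP+TN$, precision $TP/(TP+FP)$, overall identification error
$FP+FN$, and relative identification error $FP/(TP+FP) = 1 -$ precision,
reported as absent when nothing falls below the threshold.

`threshold_sweep()` evaluates this over a grid — by default 30 evenly
spaced thresholds from 0.15 down to 0 — and `ad_hoc_threshold()` fits
ordinary least squares of relative identification error on threshold over
all sweep rows, solving for the threshold at which the fitted error equals
5%. A non-positive estimate is the diagnostic of an unreliable library:
even at a zero threshold the expected relative error exceeds tolerance.

```{r adhoc}
sw <- threshold_sweep(ds, dm)
ad_hoc_threshold(sw)
```

Degenerate fits (zero variance in the error column, typical of perfectly
clean libraries where the error is identically zero) report the estimate as
absent rather than inventing a number.

## Stripping experiments and problem taxa

`strip_dataset()` supports the "perfect world" counterfactuals: drop named
species or whole genera, then drop singletons from what remains (that order,
so a genus removal can create no phantom singletons), with exact bookkeeping
of what went. `flag_problem_taxa()` aggregates leave-one-out reports per
species and genus and flags taxa that are mostly not identifiable or that
contain sequences with *identical allospecific matches* — a zero-distance
barcode in another species, the signature of shared or recently sorted
haplotypes, and a symmetric relation by construction. Flagged taxa are the
ones a curated reference database should mark for alternative markers.

## The synthetic library generator

Real deposited barcode data cannot ship with a package, so every pipeline
stage is exercised against simulated libraries with controlled structure:
a genus → species → population → specimen hierarchy whose sequences evolve
from a random root under a two-parameter (Kimura) substitution process with
transition/transversion ratio `kappa` (default 4, a typical COI value).
Branch lengths are assigned so that each configured divergence level is the
*expected pairwise divergence* between sequences of that relationship —
e.g. `between_species = 0.05` means two congeneric species are expected to
differ by 0.05 substitutions per site. Because the K2P estimator is
consistent for exactly this quantity, parameter recovery is a meaningful
end-to-end test, not a tautology.

Defaults place intraspecific variation around 0.1–0.4% and congeneric
divergence at 5%, matching what European fruit-fly COI surveys report;
within-population divergence (0–0.2%) and between-population divergence
(0.2–0.5%) are loosely calibrated to published intraspecific means and
maxima, and are configuration-exposed rather than asserted. Scenarios
implement the pathologies that drive real-world failures:

* `singleton_rich` — a configurable fraction of species collapse to one
  specimen;
* `shared_haplotype` (`urophora_like` preset) — one designated genus whose
  populations carry identical haplotypes reused *across species*, at low
  inter-haplotype divergence, with population members identical (exactly
  the empirical description of barcode-sharing gall flies);
* `host_race` — a designated species whose populations separate at
  species-level divergence, mimicking host-plant races.

The `paper_shaped` preset reproduces the shape of a real family-wide
survey: 135 species in 42 genera, a specimen histogram of 41×1, 78×2–8,
15×9–15 and one 23-specimen species, 658 bp, one outgroup.

What the simulator deliberately does **not** model: indels (barcode COI is
indel-free in practice and the analysis assumes aligned, equal-length
input), rate heterogeneity across sites, codon structure (unless
`coding = TRUE`, which only rejects internal stop codons), selection, and
coalescent genealogies — within-group sequences are star-shaped around
their ancestor. Passing tests on simulated libraries therefore demonstrate
the correctness of the *accounting* — distances, criteria, thresholds,
error classes — not that any real library is reliable; that is precisely
the question the package is meant to answer per dataset.

## Numerical and design choices

* Tie tolerance for "equally good" matches: `1e-12` absolute.
* Percentile: interpolation type 7; configurable percentile.
* Collapse epsilon: `1e-9` (zero-length branches only) by default.
* NJ ties: lowest current-matrix index pair; merged nodes appended last.
* Negative NJ branches: clamped to zero, deficit moved to the sibling.
* Undefined distances: recorded, warned about, excluded from pools; an
  error only where an operation cannot proceed without them (tree building).
* Confusion accounting consumes threshold-free Best-Match verdicts and
  applies the threshold itself, so one leave-one-out pass serves a whole
  sweep.
* Regression for the ad hoc threshold uses all sweep rows with a defined
  relative error; $R^2$ is reported so a poor linear fit is visible.
* Percentages: rounded half away from zero, two decimals, counts always
  retained.

Problem sizes in the test-suite simulations (30 species × 4 specimens for
calibration checks; ~150–630 sequences for scenario and survey-shaped runs)
were chosen so the full suite exercises every stage, including
leave-one-out over a 600+ sequence library, while staying comfortably
within a desktop R session.

## Known limitations

* NJ is implemented in plain R; it is exact and deterministic but not tuned
  for libraries beyond a few thousand sequences.
* Tree-criterion tallies depend on NJ tie-breaking in degenerate regions of
  the tree; since historical software does not document its tie rules,
  cross-tool agreement on polytomy-rich data is expected only up to those
  ties.
* Only the K2P model is offered — deliberately, as the field's standard for
  barcode work — and no model selection is attempted.
* The ad hoc threshold is a linear extrapolation; on sweeps where the
  error–threshold relation is strongly non-linear the $R^2$ diagnostic
  should temper any conclusion drawn from the point estimate.
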