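---
title: "Methods: detecting and dating horizontal transposon transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and dating horizontal transposon transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httdetect)
```

## The inference problem

Transposable elements (TEs) are usually inherited vertically, but
occasionally cross between host lineages that do not interbreed —
horizontal transposon transfer (HTT). The central observable is a
comparison of divergences. After insertion, a TE copy is essentially
unconstrained and accumulates substitutions at the host's neutral rate;
protein-coding host genes evolve more slowly because purifying selection
removes a fraction of mutations. Between two host species, then,

* **vertical inheritance** predicts TE divergence ≥ orthologous gene
  divergence (both lineages carried the element since their split, and the
  element evolved at least as fast as any gene), while
* a **recent horizontal transfer** leaves TE divergence far *below* gene
  divergence, because the element's true coalescence is the transfer event,
  not the host split.

`httdetect` operationalizes this argument, together with three supporting
lines of evidence: patchy taxonomic distribution (many losses required
under vertical descent), host/element tree incongruence, and failure of
per-species copy monophyly.

## Distances

All divergences are Jukes–Cantor (JC69) corrected distances,
`d = -(3/4) ln(1 - (4/3) p)`, where `p` is the observed mismatch
proportion. JC69 assumes equal base frequencies and exchange rates; it is
the simplest correction and the one the downstream test needs, since the
comparison is between two distance sets computed identically — model
misspecification largely cancels. Sites where either sequence carries a
gap or `N` are excluded per pair (*pairwise deletion*, the default), which
preserves signal in ragged TE copy alignments; a `complete` deletion mode
is available through `htt_config(gap_deletion=)` for users who prefer a
common site set. Ambiguity codes other than `N` carry no information under
JC69 and are read as `N`. `p ≥ 0.75` has no finite JC69 distance; such
pairs are flagged undefined rather than silently dropped, and downstream
operations refuse or exclude them explicitly.

Alignments may be trimmed before distance computation: a column is removed
when its fraction of gaps plus `N` strictly exceeds `max_missing_fraction`
(default 0.25). The strict inequality means a column missing in exactly a
quarter of the sequences is kept. Trimming is idempotent.

## The vertical-null test

For one TE family and one species pair, let `T` be the set of between-
species TE distances (consensus–consensus or copy–copy) and `G` the set of
distances for an orthologous gene panel. The verdict is

* `HT` iff `min(G) − max(T) > min_margin` (default 0 — strict range
  separation),
* `vertical-compatible` iff `min(T) ≥ min(G)`,
* `indeterminate` otherwise (overlapping ranges).

Range separation is the most conservative formalization of "TE distances
much lower than gene distances": it demands that *every* TE distance falls
below *every* gene distance. The `min_margin` knob (substitutions/site)
lets a user require a wider gap. A Mann–Whitney U p-value between the two
sets is reported as supporting context only: gene distances are a fixed
panel, not exchangeable draws, so no distributional test decides the
verdict. The verdict depends only on range endpoints, and is therefore
invariant to duplicating values within either list.

## Burst-age dating

A transposition burst leaves many copies that subsequently diverge
independently from their common source sequence, which the family
consensus approximates. With neutral rate `r` (substitutions/site/myr),

`age (myr) = mean copy-to-consensus JC distance / r`.

The default rate is 0.0346 substitutions/site/myr, the experimentally
derived *Drosophila melanogaster* neutral rate; `burst_age()` deliberately
has **no default** in its signature at the API boundary of the estimate —
callers must pass a rate, because neutral rates are lineage-specific and
none exists for several host groups (isopods among them). Saturated copies
are excluded from the mean with a warning and a count. Ages are reported
at full precision in JSON and at two significant figures in human-readable
output.

## Consensus reconstruction and element anatomy

The consensus is per-column plurality over aligned copies. Column depth
counts informative residues only (gap and `N` both excluded); columns with
depth below `min_consensus_depth` (default 5 copies) are dropped, so the
entire reported consensus is covered by at least that many copies.
Plurality ties break in the fixed order A < C < G < T, making the result
deterministic and permutation-invariant. At depth 9 with a per-site copy
error rate of 0.05, the expected number of consensus errors in a 200-bp
element is about `200 · P(Bin(9, 0.05) ≥ 5) ≈ 0.006`, which the test suite
checks against a seeded fixture.

Anatomy checks mirror what diagnoses a Tc1/Mariner element: terminal
inverted repeats (TIR detection is ungapped and end-anchored — the longest
prefix whose reverse complement matches the suffix with at most
`max_mismatch` mismatches — appropriate for short terminal TIRs, with no
indel model), TA target-site duplications on both flanks, and the longest
ORF over all six frames. An ORF runs from ATG to the next in-frame stop;
codons containing `N` translate to `X`, never to a stop, so missing data
cannot fabricate a nonsense mutation. Copy intactness is judged in the
consensus-defined ORF frame rather than by re-detecting ORFs per copy:
the question is whether the copy's transposase reading frame is free of
premature stops.

Hit filtering is strict on both thresholds (`identity > 90`,
`length > 500`), matching the convention that a hit *exceeding* the cutoff
counts. Hit-table subject coordinates are 1-based inclusive; minus-strand
hits are reverse-complemented on extraction so all copies are stored in
element orientation.

## Tree evidence

* **Neighbor joining** (Saitou–Nei Q-criterion) builds copy trees from JC
  distance matrices. Ties in Q break at the lowest index pair and negative
  branch lengths are clamped to zero with the total deficit logged — both
  choices are for determinism and reproducibility, not accuracy. On
  exactly additive matrices NJ provably recovers the generating topology,
  which the suite verifies on 100 random 5–8 leaf trees. Species-tree
  estimation is *not* reimplemented: host trees are accepted as newick
  input, since the HTT evidence uses the tree, not its estimation method.
* **Dollo parsimony**: a TE family is assumed gained once, at the most
  recent common ancestor of the species carrying it; the reported number
  is the minimum count of loss events explaining the absences. A large
  loss count quantifies "patchiness" — the implausibility the HT
  alternative is weighed against. Dollo rather than Fitch parsimony is the
  right null here because single origin is precisely the hypothesis being
  stressed.
* **Copy monophyly**: a species' copies are monophyletic iff some edge of
  the unrooted copy tree splits exactly them from everything else;
  single-copy species are reported separately as trivial. Transfer among
  hosts tends to break monophyly.
* **Robinson–Foulds** distance between the host tree (pruned to carriers)
  and an NJ tree of between-species mean TE distances quantifies
  incongruence; `max_rf = 2(n−3)`. The pipeline reports it only when at
  least four carrier species exist, as RF is vacuous below that.

The pipeline reports Dollo losses, monophyly counts and RF side by side
rather than collapsing them into a single "number of HT events": the
mapping from patchiness and incongruence to an event count is an
interpretive step we deliberately leave to the user.

## The simulator and what it does (not) show

`transfer_scenario()` fixes the generative model: an ultrametric pure-birth
host tree (branch lengths in myr); genes evolving under JC69 at
`gene_rate × s_g`, with per-gene scalings `s_g` drawn uniformly around
`gene_scaling` (default 0.5 ± 40%) as a deterministic proxy for purifying
selection; the element evolving neutrally (`te_rate`, default 0.0346)
along an explicit element genealogy: a single insertion point, vertical
descent, optional horizontal grafts at stated times, and a star-like
terminal burst of `copies_per_species` copies (default 5, enough to
support a per-species consensus at the default depth floor) each
`copy_age_myr` old.

Default calibration: the host tree is 10 myr deep. At these rates the
deepest species pair shows ortholog distances spanning roughly 0.21–0.49
substitutions/site (mean ≈ 0.35) and vertical TE distances around 0.69 —
the distance *structure* of a deep arthropod-style split, scaled so that
nothing saturates under JC69 (a literal several-hundred-myr depth at a
neutral rate of 0.0346 would drive every distance past `p = 0.75`; real
deep-split data avoid saturation because effective gene rates are far
below neutral, which the scaled-down depth emulates with a mean scaling of
0.5). The default HT scenario inserts the element on one side of the root
only and transfers it 1 myr ago across the deepest split, giving expected
TE distances of ≈ 0.10 against a gene floor of ≈ 0.21 for that pair.

All randomness flows from the single scenario seed; identical scenarios
produce byte-identical datasets, and the pipeline report is a pure
function of (inputs, config, seed). Simulated JC distances are unbiased
for `2 · rate · t`, which the suite verifies analytically at
t = 1, 10, 100 myr.

What the simulator does **not** model: indels by default (alignments are
trivially correct; an optional gap process would exercise trimming more),
base-composition or transition/transversion bias, rate variation across
sites, copy-number dynamics within a burst, solo-LTR-style partial copies,
and transfer vectors. Passing the truth-scored tests therefore shows the
*inference logic* is correct under its own model assumptions — not that
real alignments, with their alignment error and rate heterogeneity, will
be as clean. The sensitivity/false-positive figures (≥ 0.90 / ≤ 0.05 over
200 replicates) are properties of the default scenario's geometry, not
universal operating characteristics.

## Numerical and design choices

* Distances are stored as proportions (substitutions/site) everywhere;
  percentages appear only in reporting, avoiding unit mistakes.
* JC69 saturation raises an explicit error (`p ≥ 0.75`) at the scalar
  level and an `NA`-with-warning at the matrix level, so nothing is
  silently lost.
* Problem sizes in tests and the acceptance script — 46 genes × 600 bp,
  1-kb elements, 5 copies/species, 6-species trees, 200 replicates per
  condition, 10-kb elements for single-burst dating — were chosen as the
  smallest sizes at which the analytic expectations are comfortably inside
  two standard errors; they mirror the structure of a real ortholog-panel
  study at desk scale.
* The per-gene scaling spread (±40%) makes the simulated panel span a
  realistic min–max range rather than collapsing to a point mass at the
  mean, which matters because the test's decision boundary is the *gene
  minimum*.
* MEGA-style complete deletion versus pairwise deletion is genuinely
  underdetermined for this analysis; both are implemented and pairwise is
  the default (see above).

## Known limitations

* JC69 only; no K2P/GTR or gamma rates. For the null test this is by
  design (identical treatment of both distance sets); for absolute burst
  ages it means mild underestimation at high divergence.
* TIR detection has no indel model; elements with drifted, gapped TIRs
  will report shorter repeats.
* The element genealogy builder supports one insertion per family and
  requires HT recipients not already carrying the family (it validates and
  refuses otherwise); recurrent invasion of the same lineage needs one
  scenario per wave.
* Consensus building requires pre-aligned copies; merging overlapping
  genomic fragments into a copy alignment is upstream of this package.
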