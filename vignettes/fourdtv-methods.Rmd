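---
title: "Dating whole-genome duplications from fourfold-degenerate transversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating whole-genome duplications from fourfold-degenerate transversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourdtv)
```

## The statistic

Cyprinid fishes such as the golden-line barbels (*Sinocyclocheilus*) and
common carp carry a recent lineage-specific whole-genome duplication (WGD)
on top of the teleost-wide third-round (3R) duplication. Because every gene
is duplicated at once, a WGD leaves a burst of paralog pairs of equal age,
visible as a peak in a paralog divergence distribution.

The divergence measure used here is **4dTv**: the proportion of transversion
differences at fourfold-degenerate third codon positions. A codon column of
a paralog pair alignment contributes a site when neither codon contains a
gap or ambiguity, the first two codon positions are identical in both
sequences, and that shared dinucleotide heads one of the eight
fourfold-degenerate codon families (TC, CT, CC, CG, AC, GT, GC, GG). Under
the standard code every substitution at such a site is synonymous, so the
statistic approximates a neutral clock. Requiring identity at the first two
positions in *both* sequences is the stricter of the two common site rules;
it guarantees both codons belong to the same synonymous family. The cost is
a few discarded sites; the benefit is that no nonsynonymous third-position
change can leak in.

The raw proportion `Q = n_tv / n4` saturates with time, so it is corrected
for multiple hits under an HKY-type model with purine frequency
$\pi_R$ and pyrimidine frequency $\pi_Y$:

$$d = -2\pi_R\pi_Y \ln\!\left(1 - \frac{Q}{2\pi_R\pi_Y}\right).$$

This is the standard transversion-distance correction for unequal base
frequencies; at $\pi_R=\pi_Y=\tfrac12$ it reduces exactly to the Kimura
two-parameter form $-\tfrac12\ln(1-2Q)$, which the tests use as an analytic
anchor. Base frequencies are pooled per pair over both sequences at the 4d
third positions only, so each pair's statistic is self-contained and no
genome-wide pass is needed (whether the original analyses pooled per pair
or genome-wide is not documented anywhere we know of; per-pair is this
package's choice). A pair whose `Q` reaches $2\pi_R\pi_Y$ has no finite
corrected distance and is excluded with status `saturated`; a pair without
fourfold columns is excluded with `no_sites`. Both counts are reported, and
excluded pairs never error a batch.

## From distribution to date

Corrected values of the `ok` pairs are binned into half-open bins
$[iw, (i+1)w)$ with width $w = 0.01$, and the peak is reported as the
**lower edge of the modal bin** — two decimals at the default width, the
granularity at which such peaks are conventionally quoted (0.04–0.06 for
the five barbel genomes and common carp). Ties go to the smaller bin index;
an optional Gaussian smoothing of the counts exists but is off by default,
so the mode comes from raw counts.

The peak converts to an absolute age linearly against the 3R calibration:

$$T = \frac{T_{3R}}{v_{3R}} \times v_{\mathrm{WGD}},$$

with defaults $T_{3R} = 320$ Mya and $v_{3R}$ the interval 0.65–0.75. An
interval calibration yields an age range from the two endpoints and a point
estimate from the midpoint (0.70): a 0.04 peak gives 18.3 Mya, range
17.1–19.7 Mya, consistent with the published ~18.1 and ~18.4 Mya statements
for the carp/barbel duplication. The midpoint convention is this package's
choice; the published analyses do not print the operand values they used.

## The simulator and what it does (not) emulate

`simulate_pair_set()` builds ancestral sequences entirely from
fourfold-degenerate codons (prefix uniform over the eight families, third
base from the model's stationary frequencies) and evolves only the third
positions along the two descendant branches with the HKY transition matrix.
The matrix is computed by eigendecomposition of the reversibility-
symmetrised rate matrix, which is exact to machine precision (the tests
check it against an independent numerical matrix exponential). The branch
length is solved by bisection so that the *expected* corrected 4dTv equals
the requested value, to an absolute tolerance of 1e-9.

Freezing the first two codon positions is a deliberate simplification: it
conserves 4d-family membership, so every codon yields a site and the
third-position process — the thing the statistic measures — is isolated.
Real coding evolution also changes prefixes (losing and gaining 4d sites),
has rate heterogeneity among sites and lineages, and produces alignment
errors and indels; none of that is emulated. Passing recovery tests
therefore demonstrate correctness of the estimator and of the pipeline
plumbing under the model's own assumptions, not robustness to real-data
artefacts.

`simulate_paralogome()` adds background duplicate pairs at uniform
divergences over 0.1–0.6 to the WGD burst, emulating small-scale
duplications of assorted ages. `simulate_kmer_histogram()` draws genomic
k-mer depths Poisson and error k-mer depths geometric (success 0.7,
support starting at 1). `simulate_pseudogenes()` plants exactly one lesion
per non-intact copy — internal TGA, 1–2 bp deletion, or a whole-codon
deletion of ≥ 30 codons — so classifier sensitivity and specificity have
exact expected values. `simulate_anchors()` plants monotonic gap-bounded
anchor runs plus uniform noise.

## Discretisation at bin edges

One property of the floor-binning/lower-edge convention deserves note.
When the generating divergence sits exactly on a bin edge (0.04, 0.06 —
printed peak values are two-decimal, so this is the typical case), the
per-pair estimator's sampling distribution straddles that edge. With a
fixed 500 sites per pair the estimator also lives on a lattice
(`Q = k/500`), and slightly more lattice points fall in the bin *below* the
edge than above it, so the recovered modal edge can land one bin (0.01)
below the generating value even at large pair counts. The recovery
contract is therefore *within one bin width*, and the dating consistency
check is range containment rather than equality. Real paralog sets, with
varying site counts per pair, blur the lattice but keep the edge-straddling
ambiguity.

## Other numerical and design choices

* **Hit filtering.** Thresholds exclude strictly smaller values
  (aligned ratio < 0.5, identity < 50%), so boundary hits pass. "Similarity"
  is read as percent identity. The redundancy rule — connected components of
  reciprocal overlap ≥ 0.5 on the same scaffold, keep the best score, ties
  to smaller start then query id — is this package's definition; the
  original pipelines do not state one.
* **Collinear blocks.** A deliberately simple stand-in for i-ADHoRe-style
  synteny detection: repeated longest-chain dynamic programming over
  anchors monotonic in both gene orders (either orientation), per-step
  index gaps ≤ 15, blocks of ≥ 3 anchors, each anchor in at most one
  block. It captures the role the step plays — restricting 4dTv pairs to
  duplicated segments (the default; a flag admits all pairs) — without the
  probabilistic cloud model. Defaults suit the small simulated genomes.
* **K-mer peak.** The error component is excluded by scanning for the first
  local minimum from depth 1 and taking the argmax above it; without a
  local minimum the global argmax is used, ties to the smaller depth.
  `K_num` is computed from the histogram as $\sum d\cdot n_d$ — read-level
  counting is out of scope.
* **Pseudogene calling.** Premature stops are read in alignment-frame codon
  columns (gap-free triplets) strictly before the reference's final codon
  column; frameshifts are gap runs of length ≢ 0 (mod 3) in either row;
  "missing exon regions" is interpreted on the aligned CDS — a gap run of
  ≥ 30 codons or < 80% reference-codon coverage — since genomic exon
  structure is not examined. Both thresholds are configurable. A candidate
  may carry several flags; pseudogene status is their disjunction.
* **Percent reporting** uses half-up rounding at one decimal, matching the
  precision of the published assembly/BUSCO figures.
* **Binning** adds a 1e-9 epsilon before the floor so that values printed
  on a bin edge (0.05) land in the upper half-open bin despite binary
  floating point.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen so the whole suite
stays fast while estimates remain tight: 1,000 burst pairs × 500 fourfold
sites for peak recovery (per-pair SE ≈ 0.009 at d = 0.04), 300 background
pairs, a 1 Mb simulated genome at 30× for the k-mer survey, 400 candidates
for the pseudogene confusion matrix, and ≤ 10-anchor instances for the
exhaustive-enumeration cross-checks of the chaining DP.

## Limitations

Beyond the simulator simplifications above: no mixture-model deconvolution
of overlapping WGD peaks and no bootstrap interval on the peak location
(mode at bin resolution only); no Ks/Ka or codon-model estimation; the
collinearity finder is not a replacement for i-ADHoRe/MCScanX on real
genomes; and the dating inherits the full uncertainty of the 3R calibration
interval, which dominates the quoted age range.
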