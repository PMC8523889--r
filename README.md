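# fourdtv

Dating lineage-specific whole-genome duplications (WGD) from transversion
distances at fourfold-degenerate third codon positions — the **4dTv**
statistic used in cyprinid comparative genomics (golden-line barbels,
*Sinocyclocheilus*, and common carp) — together with the surrounding survey
arithmetic: 17-mer genome-size estimation, assembly summary statistics,
homology-hit filtering with collinear-block chaining, and pseudogene /
copy-number classification. Seeded simulators generate every input the
pipeline needs, so the whole analysis runs and is tested at desk scale
without any downloads.

Intended users: comparative genomicists who want a small, fully tested
implementation of the 4dTv→WGD-dating chain, and anyone who needs its
pieces (HKY transition matrices, k-mer survey arithmetic, lesion calling on
codon alignments) as plain R functions.

## The method

For each paralog pair, a codon column yields a **4d site** when both codons
are clean, share their first two nucleotides, and that dinucleotide heads
one of the eight fourfold-degenerate codon families. With `n4` sites and
`n_tv` transversion differences, the raw statistic `Q = n_tv / n4` is
corrected for multiple hits with purine/pyrimidine frequencies πR, πY
pooled over the pair:

    d = −2 πR πY ln(1 − Q / (2 πR πY))        (K2P form −½ ln(1−2Q) at equal frequencies)

Corrected values are binned (width 0.01, half-open bins), the WGD peak is
the lower edge of the modal bin, and the peak dates the duplication
linearly against the teleost 3R calibration:

    T = T_3R / v_3R × v_WGD,   T_3R = 320 Mya, v_3R = 0.65–0.75

Genome size is estimated from a 17-mer depth spectrum as
`K_num / K_depth` (total k-mer instances over the modal depth, after
excluding the low-depth error peak). Pseudogenes are called on
reference/candidate codon alignments by premature stop codons, frameshift
gap runs (length ≢ 0 mod 3), or missing regions (≥ 30 codons or < 80%
coverage).

## Worked example

```r
library(fourdtv)

report <- run_wgd_pipeline(
  wgd_d = 0.04,            # corrected 4dTv of the simulated WGD burst
  n_pairs = 1000, n_background = 300, n_codons = 500,
  model = hky_model(kappa = 2), seed = 42
)
report$peak
#> [1] 0.03
report$T_point
#> [1] 13.71429
date_wgd(0.04)$range
#> [1] 17.06667 19.69231
genome_size_estimate(40525178512, 23) / 1e9   # published 17-mer statistics
#> [1] 1.761964
percent_of(1.7, 1.8)
#> [1] 94.4
```

`report$peak` is the modal bin's lower edge of the corrected-4dTv
distribution over 1,300 simulated pairs (1,000 duplication-burst pairs at
d = 0.04 plus 300 background duplicates). Note the peak reads 0.03, one bin
below the generating value: a burst placed exactly on a bin edge straddles
it, and with fixed-length pairs slightly more probability falls in the
lower bin (the vignette's discretisation section walks through this; the
recovery contract is one bin width). `date_wgd(0.04)` shows the calibration
arithmetic on the published peak value itself: point 18.3 Mya, range
17.1–19.7 Mya under the 320 Mya / 0.65–0.75 3R calibration. The genome-size
line reproduces the published worked example: 40,525,178,512 17-mers at
modal depth 23 give 1.76 Gb ≈ 1.8 Gb, of which a 1.7 Gb assembly covers
94.4%.

The numbered scripts under `analysis/` run the same computations as a
narrative workflow (simulation → 4dTv and dating → genome survey → hit
filtering and collinearity → copy number / pseudogenes) and write their
tables under `results/`.

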