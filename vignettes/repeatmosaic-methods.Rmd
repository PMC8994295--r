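---
title: "Measuring somatic repeat instability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring somatic repeat instability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatmosaic)
```

# Scope

`repeatmosaic` measures somatic mosaicism of expanded tandem repeats —
the cell-to-cell variation in repeat length that arises post-zygotically
— from two complementary data types: bulk fragment-analysis traces
(sensitive to the majority of alleles, cheap, but blind to rare events
and biased by PCR) and single-molecule small-pool PCR (SP-PCR; sensitive
to rare alleles, quantitative at the molecule level, expensive). The
motivating system is the hexameric CCCTCT repeat of X-linked dystonia
parkinsonism, whose inherited length (30–55 units) inversely predicts
age at onset, but nothing in the package is specific to that locus
beyond the defaults (6 bp repeat unit, 37/44/50-repeat sizing
standards).

This vignette explains the models, the tunable constants and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the methods literature is silent.

# Sizing and modal-allele calling

Capillary electrophoresis reports fragment sizes in bp. `fit_calibration()`
fits `size_bp ~ repeat_units` by least squares to co-amplified standards
of known repeat length and refuses slopes outside 5.5–6.5 bp/repeat: a
hexamer must migrate at close to 6 bp per unit, and any other slope
means the standards are mislabeled or the run failed. The intercept
estimates the constant flanking length of the amplicon; the default
calibration (138 bp intercept) is a reconstruction consistent with the
330 bp ↔ 32 repeats and ~560 bp ↔ 70 repeats anchors of the accurate
sizing window, not a measured flank.

`bp_to_repeats()` inverts the line and rounds to the nearest integer
repeat. Binning by nearest repeat after calibration (rather than by a
fixed 6 bp comb anchored at the modal peak) is robust to sub-bp drift in
the electrophoresis. Fragments outside the accurate window are converted
by extrapolating the same line and *flagged*, never dropped: rare large
SP-PCR alleles live out there, and summaries must include them even
though their sizing is approximate. The modal allele is the tallest
binned peak; ties break to the smaller repeat, the conservative choice
against calling spurious expansion. Peaks that bin to the same unit have
their heights summed, treating height as a proxy for molecule count.

# The expansion index

For a binned distribution with modal repeat *m* and weights
*h<sub>r</sub>*, peaks with *h<sub>r</sub>* < *t*·*h<sub>m</sub>* are
discarded (threshold fraction *t* = 0.05 by default), retained weights
are normalized to sum to one, and

$$E = \sum_{r > m} w_r (r - m), \qquad C = \sum_{r < m} w_r (m - r).$$

Choices that matter:

- **Denominator.** The normalization is over *all* retained peaks —
  modal and contraction side included. The index literature is not
  explicit on this point; this is the single most consequential
  reconstruction in the package, it is recorded here prominently, and
  the test suite pins it with an independent brute-force enumeration
  oracle so it cannot drift silently.
- **Why only the expansion side is interpreted.** Peaks left of the
  mode in bulk PCR are dominated by slippage stutter, so somatic
  contraction cannot be read from a bulk trace; the contraction index
  is computed (same formula, |Δ|) but biological claims rest on *E* and
  on SP-PCR. The 5% threshold removes baseline noise and most of the
  stutter shoulder (with the default stutter decay of 0.2 per unit, the
  −1 peak at 20% of modal survives, −2 at 4% does not).
- **Δ is measured from the modal allele of the same trace**, not from a
  genotyped reference, so the index is self-calibrating per sample.
- **Two-allele (autosomal) loci.** `split_biallelic()` cuts the
  distribution at the midpoint between two declared modal repeats and
  indexes each half separately; alleles closer than 4 units are refused
  (`alleles too close`) because their stutter/expansion envelopes
  overlap irrecoverably.

Scale invariance (indices unchanged under uniform height scaling),
threshold monotonicity, and strict growth when an expansion peak is
added are all asserted as property tests.

# Single-molecule SP-PCR

At high dilution, the number of amplifiable template molecules per well
is Poisson. The fraction of product-negative wells estimates
*P*(0) = e^(−λ), so `estimate_lambda()` returns λ̂ = −ln(*n*₀/*n*) with a
95% interval obtained by transforming a Clopper–Pearson binomial
interval on the negative fraction through −ln (the literature states no
interval procedure; exact binomial is the conservative standard). With
no negative wells the estimate is unbounded and the result is flagged
`too_concentrated` rather than returned as a number.

`select_single_molecule_dilution()` picks the dilution whose negative
fraction is nearest the 1/3 target (λ ≈ ln 3 ≈ 1.1); ties go to the more
dilute member, trading wells for purity. Plate QC
(`qc_plate()`) applies three rules: every no-DNA control negative, at
least 1/3 of DNA wells negative, and every sized peak at least 150 RFU.
QC reports reasons and never throws.

`tabulate_alleles()` classifies each sized molecule by the sign of its
distance from the modal reference (default: the SP-PCR modal itself,
most frequent sized length, tie to the smaller) and fills nested
magnitude bins (1–4, ≥5, ≥20 on each side). Cross-tissue class
frequencies are compared with a Pearson χ² without continuity
correction on the tissues × (contracted, modal, expanded) table — df =
2(R−1) — with the standard warning when an expected cell drops below 5.

# The synthetic-data generator

Somatic mosaicism is emulated at the cell level. Each cell's length
change Δ is drawn from a four-component mixture: stay (point mass at
0), expand (+1 + Geometric), contract (−1 − Geometric), or a rare large
jump. The geometric tails are the simplest shapes concentrating mass at
±1–4 units, where real single-molecule distributions put the majority
of their changes. Rare jumps carry a 0.75 expansion sign bias and
asymmetric magnitudes — 20 + Geom(0.08) when expanding (reaching past
100 units), 20 + Geom(0.3) when contracting — because observed rare
expansions extend tens-to->100 units while rare contractions stay
within ~20–30.

The per-cell expansion probability is linear in repeat length:
`expansion_rate_per_unit × (inherited − 30)`, clamped to zero below the
reference and capped so total change probability never exceeds one.
Linearity in (inherited − 30) mirrors how expansion indices regress
linearly on repeat length within tissues. The default tissue panel
orders rates blood (0.004/unit) < cerebellum (0.013) < caudate <
putamen < hippocampus < cingulate gyrus < occipital cortex (0.024),
reproducing the canonical rank order (blood lowest; cerebellum the most
stable brain region; occipital cortex the least). Contraction (0.18 per
cell in brain) and rare-jump (0.01) rates are length-independent. These
defaults put single-molecule expansion fractions in the ~25–58% range
across inherited lengths 41–55 while remaining valid probabilities
across the whole 30–55 range; bulk index medians that result are lower
in absolute terms than patient brain values, so the package's tests
treat tissue *ordering*, not absolute index levels, as the reproducible
quantity.

Traces are built by giving every true allele a geometric stutter ladder
(default decay 0.2/unit below, 0.04 above — minus-stutter dominates, as
in real slippage), multiplying by an amplification-efficiency bias of
1.02 per unit shorter (the source of bulk contraction bias), summing
across alleles, and jittering heights with multiplicative log-normal
noise (CV 0.1; trace noise magnitude is not documented anywhere, so the
CV is exposed). Peak positions are laid on the calibration grid, which
is why adjacent single-unit peaks are exactly 6 bp apart.

Dilution plates draw molecules per well from Poisson(λ) and report, for
multi-molecule wells, the shortest allele drawn: the shorter template
amplifies preferentially and produces the taller peak, and the other
molecule is lost. This is a documented simplification — real SP-PCR
cannot resolve collisions either — and a sensitivity test compares
classification frequencies at λ = 0.1 vs 1.1.

At the cohort level, onset age is `100 − 1.4 × repeat + N(0, 6)` years,
floored at 12 (the youngest onset observed in this disease); with the
repeat-length distribution (normal, mean 42, SD 3.9, clamped to 30–55)
this makes repeat length explain ≈45% of onset variance. Death age is
onset plus a duration drawn *independently* of repeat length
(N(9, 4) years, floored at 0.5), encoding the observed absence of a
length–duration correlation; a death age is recorded for 25% of
individuals. One further generator term deserves emphasis: each
individual carries a log-normal (SD 0.3) instability factor shared by
all tissues of an anatomical block (cortical, subcortical, blood).
Without it, tissues would differ only in their mean level, column
z-scoring would erase exactly that difference, and no clustering method
could recover tissue blocks; the factor encodes the within-individual
covariation of related brain regions that real heatmaps visibly
display, and it is what makes planted cortical/subcortical blocks
recoverable.

What the generator does **not** emulate: germline transmission,
sequence-level repeat structure, age dependence of mosaicism (no age
term exists in the generator, since tissue donors' ages are not
modeled), Southern-blot densitometry, or cell-type heterogeneity within
a tissue. Passing tests therefore demonstrate that the pipeline
recovers what the generative model encodes — ordering, length
dependence, Poisson behaviour, index arithmetic — not that real tissue
values will match numerically.

# Cohort statistics

- **Regressions** are ordinary least squares; the p-value reported is
  the slope t-test, equivalent to the model F-test with one predictor
  (the choice between the two conventions is otherwise unstated in the
  source methods; both coincide here).
- **Correlation method switch**: Shapiro–Wilk at α = 0.05 on both
  variables; Pearson iff both pass, Spearman otherwise. The normality
  test is not named in the methods this follows; Shapiro–Wilk is the
  default any R practitioner would reach for at these sample sizes.
- **Pairwise tissue tests**: two-sided Wilcoxon rank-sum for every
  tissue pair, Bonferroni-multiplied by the number of pairs in the run
  (the family is all pairs of one analysis), capped at 1.
- **Heatmap clustering**: the individuals × tissues matrix is filtered
  (tissues with <12 measures, then individuals with <6 tissues — the
  order matters and tissues go first since columns are the display
  unit), columns are z-scored over non-missing entries, and rows and
  columns are clustered by average-linkage agglomeration on Manhattan
  distance. Missing cells stay missing; distances use
  pairwise-complete coordinates rescaled by the fraction shared, which
  is the documented behaviour of `stats::dist()`. Column scaling (not
  row) is the chosen orientation, and the linkage is exposed as an
  argument, since only the distance metric is fixed by convention.
  Constant columns are dropped with a warning — a zero-SD column cannot
  be z-scored.
- **Cross-locus comparison** reduces each locus to per-tissue mean
  indices and correlates the two vectors (Pearson) over shared tissues,
  requiring at least 4.

# Numerical and testing choices

Determinism: every generator takes an explicit seed; there is no hidden
global state beyond R's RNG, which seeded entry points set. Fixture
files regenerate byte-identically for the same seed.

Problem sizes in the test suite are chosen to exercise each claim at
desk scale: 10⁴ random distributions against the brute-force index
oracle; 50 random tables against the textbook χ²; 200 regenerated
cohorts for slope CI coverage (0.95 ± 0.03); 1000 dilution series for λ
coverage (≥93% within own CI at λ ∈ {0.3, 1.1, 3}); 30 cohorts for
tissue-ordering stability; 20 cohorts of 25 individuals for planted
block recovery (≥90%); 100 runs of ~144 sized molecules for the
expansion-bias direction (≥95%); 100 cohorts for duration
non-significance (≥90% with p > 0.05). The full suite runs in a few
minutes on one CPU.

Known limitations: the expansion index depends on the reconstructed
normalization denominator discussed above; absolute simulated index
levels sit below patient-tissue values; collision handling in simulated
plates loses the longer molecule; and extrapolated sizing beyond the
accurate window inherits whatever error the linear calibration has out
there, which cannot be quantified without ladder-level data.
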