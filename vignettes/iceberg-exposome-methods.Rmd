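---
title: "Methods: chemometer exposome analysis and iceberg mixture modeling"
author: "icebergExposome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometer exposome analysis and iceberg mixture modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebergExposome)
```

## The problem

Marine mammals accumulate complex mixtures of hydrophobic organic
contaminants (HOCs) — PCBs, organochlorine pesticides, brominated flame
retardants, PAHs, musks, pyrethroids — in their tissues. Passive
equilibrium sampling with a silicone "chemometer" (a PDMS sheet
equilibrated with homogenized tissue) transfers that mixture into a
well-defined polymer reference phase without changing its composition.
The same extract can then be profiled two ways: by targeted chemical
analysis (GC-HRMS quantification of a fixed analyte list, expressed as
c~PDMS~ in pg analyte per mg PDMS) and by cell-based *in vitro*
bioassays that respond to the whole mixture. **Iceberg modeling**
compares the two: the mixture effect *predicted* from the quantified
chemicals is the visible tip; the ratio of predicted to measured effect
is the *explained fraction*, and everything above 100% of it remains
attributable to unknown, untargeted, or undetected chemicals.

This package implements the full data path from raw quantification
tables to explained fractions:

1. **quantification post-processing** — method detection limits,
   procedural-blank subtraction, lipid-uptake correction, censoring;
2. **partition conversions** — silicone / lipid / wet-weight bases;
3. **organ statistics** — detection frequencies, geometric summaries,
   ratio paired t-tests of organ pairs, group profiles, effect-threshold
   exceedance;
4. **iceberg mixture modeling** — BEQ and TU bookkeeping under
   concentration addition;
5. a **synthetic-study generator** with known ground truth.

## Data model

The central object is the `ConcentrationTable`, a
`SummarizedExperiment` whose rows are compounds (the `CompoundRegistry`:
identity, group, molar mass, MDL, partition coefficients, effect data)
and whose columns are tissue extracts (the `SampleTable`: animal,
species, organ, lipid fraction, PDMS mass, lipid uptake). Two assays are
carried in parallel: the numeric `conc` (c~PDMS~, `NA` for nondetects)
and a `status` label per cell — `detected`, `nondetect`, or
`above_calibration` for values extrapolated beyond the calibration
range, which stay in the analysis but flag every downstream result that
touches them as semi-quantitative. Censoring state is explicit: the
pipeline stages already applied are recorded in the object's metadata,
and `validateStudy()` enforces that a censored table carries no detected
value below its compound's MDL.

## Quantification post-processing

The pipeline order is fixed: **blank subtraction → lipid-uptake
correction → MDL censoring** (`quantifyPipeline()`). The end state is
idempotent — re-censoring a censored table changes nothing.

**MDL.** `computeMDL()` implements the EPA-style replicate-spike
procedure: the Student-t quantile times the replicate standard
deviation. The default reading is a *two-tailed* 99% interval, i.e.
`qt(0.995, n - 1) * sd`; because the classic 40 CFR 136 Appendix B
procedure uses a one-tailed 99% quantile, `method = "epa_one_tailed"`
selects that variant. Values strictly below the MDL become nondetects; a
value exactly at the MDL counts as detected, since it is *below* the
limit that defines non-detection.

**Blanks.** Procedural blanks are averaged arithmetically per compound
and subtracted from every quantified value; results at or below zero are
censored. Whether a study should subtract the mean or the maximum blank
is a policy question; the mean is the default here and the blank vectors
are kept per compound so alternatives can be layered on.

**Lipid uptake.** In-tissue sampling lets the polymer take up a small
amount of lipid (of order 1% of the PDMS mass), and part of the
extracted analyte resided in that co-extracted lipid. The correction is
a two-phase mass balance: the analyte mass distributes over the PDMS
and the co-extracted lipid according to K~lipid/PDMS~, so

c~PDMS~ = m~analyte~ / (m~PDMS~ + K~lipid/PDMS~ · m~lipid~),

which reduces to the naive m/m~PDMS~ at zero uptake. On a whole table
this is a per-cell factor 1/(1 + K~i~ · u~j~) with u~j~ the sample's
lipid uptake per unit PDMS mass. The correction can be disabled
(`correctLipid = FALSE`) for sensitivity analysis.

## Partition conversions

Silicone-based concentrations are converted to equivalent lipid-based
concentrations by **c~lipid,eq~ = K~lipid/PDMS~ × c~PDMS~**. K is the
equilibrium concentration ratio lipid/PDMS, so the conversion is a
multiplication; lipid-normalized burdens are reported in mg/kg lipid
(1 pg/mg × K of 23 → 23 pg/mg lipid = 0.023 mg/kg). Experimental K
values exist for a minority of compounds; all others use a fallback
mean, default 23, the arithmetic mean of the experimental values of the
detected compounds with the HCH isomers excluded (their experimental
values are outliers relative to the HOCs the mean is meant to
represent). `meanKExperimental()` recomputes the fallback from data and
offers a geometric-mean option, since partition coefficients are
log-distributed; the arithmetic mean is the default because that is the
convention in chemometer field studies. Wet-weight concentrations are
c~lipid~ × lipid fraction. `partitionConsistencyCheck()` compares
converted values with paired exhaustive-extraction measurements and
flags pairs outside a configurable factor (default 3).

## Organ statistics

All sum burdens use the **lower-bound convention**: nondetects
contribute zero. Geometric summaries (`geoSummary()`) are computed over
detected values only and refuse non-positive input.

The **ratio paired t-test** (`ratioPairedTTest()`, `organRatioTest()`)
asks whether paired organ concentrations differ by a constant factor: a
one-sample t-test on ln(numerator) − ln(denominator), with the
geometric-mean ratio `exp(mean Δln)` and a 95% CI
`exp(mean ± t(0.975, n−1)·SE)`. Pairs with a nondetect member are
dropped, not imputed — imputation at MDL/√2 would manufacture
information exactly where the data are weakest, and per-compound pair
counts are reported so the reader sees the basis shrink. Degenerate
inputs are handled explicitly: a single pair yields a point estimate
without inference; zero log-ratio variance yields the exact GM with a
degeneracy flag instead of a meaningless p-value. The test is exactly
reciprocal: swapping numerator and denominator inverts the GM and
mirrors the CI, with identical p.

**Threshold assessment** converts each rule's analyte sum to the rule's
basis and tests *strict* exceedance (a burden exactly at the threshold
does not transgress it). The built-in rules are the three commonly used
sum-PCB thresholds in marine mammal tissue — 9.0, 11.0 and
41.0 mg/kg~lipid~ for the onset of physiological effects, expected
reproductive failure, and profound reproductive impairment — plus the
1 mg/kg~wet weight~ toxicity threshold for the DDX sum (4,4′-DDE +
4,4′-DDD + 4,4′-DDT). Group profiles are mass-based by default, with a
molar option, because "share of total concentration" is ambiguous in
the field literature.

## Iceberg modeling

The model is **concentration addition** with a reference chemical per
assay (benzo[a]pyrene for AhR-CALUX and AREc32, rosiglitazone for
PPARγ-bla):

* measured: BEQ~bio~ = EC~ref~ / EC~extract~ (mol~ref~ kg~PDMS~^−1^),
  TU~bio~ = 1 / IC~extract~ (L kg~PDMS~^−1^);
* predicted: BEQ~chem~ = Σ~i~ REP~i~ · c~i~ with
  REP~i~ = EC~ref~ / EC~i~, and TU~chem~ = Σ~i~ c~i~ / IC~i~, with c~i~
  the detected compound's molar concentration per kg PDMS
  (c~PDMS~ · 10^−6^ / M);
* explained fraction = 100 × predicted / measured, reported as-is even
  above 100%.

Compounds *tested but inactive* contribute zero potency yet still count
as "captured" in the burden accounting — their effect is known (none),
unlike compounds without effect data. Compounds with K~medium/air~
below 10^4^ evaporate from the bioassay wells and are excluded from the
capture domain altogether (`VolatilityRule`; a missing K is treated as
non-volatile with a warning, the conservative choice for heavy HOCs).
`fractionAccounting()` splits each extract's detected burden into
captured / no-effect-data / volatile shares that sum to 100%, mass-based
by default. Concentration addition makes BEQ~chem~ and TU~chem~ additive
over disjoint compound sets and homogeneous of degree 1; the test suite
verifies both, plus equivalence with a brute-force mole-sum oracle to 10
significant digits. Synergism and antagonism are out of scope, as is
fitting dose-response curves — EC/IC values are inputs.

## The synthetic-study generator

No public dataset accompanies this kind of study, so the generator
(`generateStudy()`, configured by `SynthConfig`) is a first-class,
tested module that produces complete studies with known ground truth.
The default preset (`fieldStudyPreset()`) encodes the targeted design: 12
animals (harbor porpoises, harbor seals, a ringed seal, an orca), 8 with
four organs and 4 with liver + blubber (40 extracts), 117 analytes in 8
groups, and bioassay panels for 7 animals.

Generative structure, per compound × sample:

* a per-compound *presence* indicator (all PCBs, the DDX compounds and
  fluorene always present; others with probability 0.55) reproduces the
  observation that a large minority of target analytes is never found;
* a per-compound persistent log-offset (SD 1.2) around the group's
  log-median reproduces steep congener patterns — a few dominant
  congeners, many rare ones — and heterogeneous detection frequencies;
* a log-normal per-animal draw (SD 1.2) times organ enrichment factors
  (pyrethroids 12× in blubber, musks 3× in liver) times within-animal
  organ noise (SD 0.3) times an 8-fold multiplier on the orca;
* lipid uptake ~ N(0.88%, 0.62%) truncated at 0.05%, per-compound MDLs
  log-normal around 3 pg/mg, procedural blanks for 20% of compounds,
  and an above-calibration flag beyond 1000 pg/mg.

The raw table handed to the pipeline is built by *inverting* the
quantification chain — latent value diluted by lipid uptake, plus the
mean blank — so `quantifyPipeline()` must actively undo both to recover
the latent truth. Bioassay extract ECs are back-computed so that
BEQ~bio~ = BEQ~chem,true~ / f for the configured explained fraction f
(per assay endpoint), before optional log-normal measurement noise.
With zero noise the pipeline recovers 100·f % exactly (to floating
point); with noise the recovery is unbiased in the log domain, verified
over 200 seeds. Determinism uses one hashed pseudorandom substream per
entity, so adding animals never perturbs existing draws, and the ground
truth is a separate output the pipeline never reads.

**What the preset does and does not emulate.** It reproduces the
study-scale features the analysis depends on: ~65% of compounds
detected somewhere, a handful of near-ubiquitous PCBs, a dominant
high-burden individual, realistic lipid uptake, capture fractions
around 75%, and a large unexplained effect fraction. It does not
reproduce inter-compound correlation (congeners co-vary strongly in
real tissue), toxicokinetics, or the exact field burden scale — the
synthetic sum-PCB burdens run higher than typical field data because
synthetic congener patterns are less steep than real ones, so
threshold-exceedance counts on the preset are upper-end. Passing tests
therefore demonstrate correctness of the computations and their
invariances, not field-scale realism of any particular aggregate.

## Numerical and design choices

* Problem sizes in the test suite are kept small deliberately: toy
  mixtures of ≤5 compounds against brute-force oracles, studies of 2-4
  animals × 40 compounds for closure properties, 200 seeds for the
  noise-recovery check, and the full 117 × 40 preset once per run.
* Detection boundary: `value == MDL` is detected; threshold boundary:
  `burden == threshold` is not an exceedance.
* The ratio test treats numerically-zero log-ratio variance (differences
  equal to machine precision) as degenerate rather than reporting a
  spurious p-value.
* Replicate PDMS sheets are averaged to one value per extract at read
  time (arithmetic mean over detected replicates; nondetect only when
  all replicates are); the analysis operates on one value per
  (compound, extract).
* Above-calibration values participate at their extrapolated magnitude
  (dropping them would bias sums low exactly for the most contaminated
  extracts) but are propagated as a `semi_quantitative` flag on every
  iceberg row they touch.
* `explainedFraction()` refuses a non-positive measured effect rather
  than returning infinity; extracts without measurable effect are
  simply absent from the bioassay panel.

## Known limitations

* Left-censored statistics beyond the lower-bound convention (e.g.
  Kaplan-Meier or ROS estimators for censored means) are not
  implemented; geometric summaries are detected-only and say so.
* The volatility cut-off is a hard threshold; partial losses near
  K~medium/air~ = 10^4^ are not modeled.
* Multiple-testing correction across per-compound ratio tests is
  intentionally not applied, matching common practice in this
  literature; readers should treat per-compound significance stars
  accordingly.
* The iceberg model assumes strict concentration addition across modes
  of action within an assay; for cytotoxicity this is a deliberate
  simplification.
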