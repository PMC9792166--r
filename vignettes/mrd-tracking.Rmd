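---
title: "Methods: tumor-informed ctDNA tracking and its simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed ctDNA tracking and its simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdtrack)
```

## The problem

After curative-intent surgery for colorectal cancer, some patients carry
residual disease that imaging and the serum biomarker CEA detect late or
not at all. Tumor-informed MRD assays address this by sequencing the
resected tumor, selecting a handful of patient-specific somatic
mutations, and re-assaying exactly those loci in serial plasma samples
at very high depth. Because the tracked mutations are known a priori,
positivity reduces to a threshold question: is the variant allele
fraction (VAF) at any tracked locus above what background sequencing
error can produce?

`mrdtrack` implements that workflow downstream of alignment and variant
calling: the inputs are variant tables and per-amplicon read counts, not
reads. Panel-of-normals filtering, CHIP removal via matched white blood
cells, and functional annotation are assumed to have happened upstream
and arrive as input columns.

## Panel selection

All non-synonymous tumor variants are ranked by a criterion-count score.
Four boolean criteria contribute one point each:

1. `pathogenic_deleterious` — ClinVar-pathogenic **or** predicted
   deleterious. The two evidence sources are combined with OR because
   either alone is sufficient reason to believe the call is real and
   functional; requiring both would discard well-annotated truncating
   variants that prediction tools do not score.
2. `stopgain_in_tsg` — nonsense mutation in a tumor suppressor.
3. `recurrent_oncogene` — oncogene mutation with COSMIC recurrence
   strictly greater than 3.
4. `in_house_validated` — previously confirmed tumor-derived.

The FFPE VAF (a fraction in [0, 1]) is then added to the integer
criterion count. This makes the design intent explicit: the criterion
count dominates, and VAF orders variants *within* a tier, never across
tiers. The field practice this encodes — "highest score, then highest
VAF" — admits other readings (e.g. VAF-first); count-dominant is the
simplest total order consistent with it, and the weighting is trivially
changeable because the flags are returned alongside the score.
Remaining ties break by VAF, then by (chrom, pos) ascending, so
selection is a total order: permuting the input cannot change the panel,
and dropping a non-selected variant cannot either. Variants in
low-complexity regions are excluded (the flag is an input; a mask BED
can be applied upstream). The requested panel size is clamped to
[2, 10] with default 5; fewer than two eligible variants yields a panel
flagged `below_minimum` rather than an error, because a one-marker
panel is still clinically usable, just fragile.

FFPE VAF ≥ 10% is attached as an advisory `detectable_in_plasma` flag —
low-VAF tumor mutations are markedly harder to find in plasma — but it
never excludes a variant, since for patients with few mutations a
low-VAF marker beats no marker.

The 5% FFPE VAF spectrum floor (`filter_spectrum`) is applied only for
cohort landscape summaries, not before ranking: ranking already uses
VAF as a criterion, and discarding sub-5% variants before selection
would silently shrink the candidate pool for low-purity samples.

## Positivity calling and its boundaries

Per-amplicon QC: depth below 10,000X fails; exactly 10,000X passes
(the failure rule is "less than 10,000X"). Failed amplicons leave both
the positivity decision and the mean-VAF denominator. A sample whose
amplicons *all* fail is `indeterminate`, a distinct state — treating it
as negative would let QC dropout masquerade as molecular clearance.

A sample is positive when at least one QC-passing tracked mutation has
VAF ≥ LOD (inclusive). The sample-level mean VAF follows a two-branch
rule: mean over positive mutations when any exist, else mean over all
retained tracked mutations. Consequently the mean VAF of a positive
sample is always ≥ LOD, a property the test suite checks.

cfDNA input QC passes at concentration ≥ 0.1 ng/µL **or** total ≥ 3 ng
(OR semantics: either criterion alone demonstrates sufficient input).

## LOD calibration

`calibrate_lod` takes titration observations (reference mixtures at
known average VAFs — by default 3%, 0.5%, 0.1%, 0.05% and 0%) and a
healthy-donor panel (default 150 donors, 5 tracked sites each). For
each candidate threshold `t` it computes the false-positive rate as the
fraction of healthy *measurements* with VAF ≥ t, and selects the
smallest candidate with FP rate strictly below `fp_max` (default 1%).
The per-measurement definition is the stricter and better-defined
quantity; the per-sample rate (any tracked site ≥ t) is reported
alongside in the FP table since both are cheap and reviewers ask. If no
candidate passes, calibration errors with the full FP table rather than
silently picking the largest threshold. The threshold is global; the
per-level detection fractions reported for the chosen threshold make
per-amplicon weaknesses visible without per-site thresholds.

## Longitudinal monitoring

Molecular relapse is the earliest *post-operative* sample with a
positive call; indeterminate samples are skipped, not counted as
negative, and a positive–negative–positive sequence is reported as its
first positive plus the full unsmoothed call sequence. Samples dated on
the surgery day count as pre-operative (pre-operative draws precede
surgery by design; the tie goes to the pre-operative side). Lead time
is `(clinical − molecular) / 30.4375` days-per-month — a
calendar-neutral month, chosen because lead times are reported as
fractional months; negative lead times (molecular call after clinical
diagnosis) are permitted and flagged. CEA is classified against the
standard 5 ng/mL cut-off (≥ 5 elevated).

## The simulator

The generator exists so that every stage is testable end to end without
patient-level data. It emulates, with documented parameters:

* **Cohort structure** — stages drawn from (I .134, II .423, III .412,
  IV .031), the stage mix of the emulated cohort renormalized over
  known stages; headline genes present per patient by independent
  Bernoulli draws at configured frequencies (APC .699, TP53 .631,
  KRAS .398, FAT4 .272, ...); total mutation count = headline presences
  plus a heavy-tailed negative-binomial filler count, calibrated so the
  mean is 7 with ~1% of patients mutation-free.
* **Mutation classes** — missense .723, frameshift .135, nonsense .123,
  remainder split across splice/in-frame/other. KRAS/NRAS/BRAF-mutated
  patients receive a hotspot "primary" mutation (KRAS resistance codons
  with G12 at .568 of KRAS patients, NRAS Q61, BRAF V600E in .38 of
  BRAF patients); since these primaries are missense by construction,
  the remaining class draws are adjusted so the *pooled* class
  distribution stays at the configured probabilities.
* **FFPE VAFs** — Beta(2, 4) (mean 1/3, long left tail), a reasonable
  shape for clonal-to-subclonal mixtures at ≥ 60% tumor cellularity.
* **Read counts** — depth ~ negative binomial (mean 100,000X, size 50),
  with 3.8% of amplicons forced below 10,000X; per-site background
  error drawn from Beta(4, ·) with mean 1.5 × 10⁻⁴, then
  `alt ~ Binomial(depth, tf × heterozygosity + error)` — an
  overdispersed beta-binomial. The error parameters were fixed at
  design time so the simulated assay reproduces the calibration
  behaviour the workflow is specified to have: FP ≈ 0.2% of healthy
  measurements at 0.05% VAF (so 0.05% is selectable under the 1% FP
  budget) but ≈ 24% at 0.02% (so tighter candidates are rejected).
  They describe a plausible assay of this class, not any particular
  instrument's chemistry.
* **Heterozygosity factor** — 0.5: one mutant allele per shed diploid
  genome equivalent; configurable for CNV-heavy use cases.
* **Shedding** — pre-operative tumor fraction is a two-component
  mixture: non-shedders at 0, shedders log-normal(log 0.01, 1). The
  per-stage shedder probability is *solved*, not tuned: given the
  marginal detection target (0.905) and a stage-I relative detection of
  0.75 (stage I tumors shed less), the calibrator computes the null
  per-sample positive rate and the shedder detection probability by
  deterministic quadrature over the error model — using the expected
  effective panel size, panel_size × (1 − fail rate), so depth dropouts
  do not bias the target — and inverts the mixture. At n = 1,000
  simulated patients the realized marginal is within a point of the
  target.
* **Relapse** — probability 2/19 per patient; clinical relapse uniform
  at 9–15 months post-op; tumor fraction ramps exponentially
  (doubling monthly) up to 0.1 over the preceding 8 months, so with the
  default visit schedule (pre-op draw, 1 month, then every 6 months) at
  least one visit falls in the shedding window and molecular detection
  precedes clinical diagnosis by construction. Monitoring stops at
  clinical relapse.
* **CEA** — elevated pre-operatively with probability 0.413
  (marginally, regardless of ctDNA status), and with probability 0.3
  at draws inside the relapse ramp — CEA is deliberately a weak
  relapse signal here, as it is in practice.

Everything is deterministic under the master seed, and seeded
generation restores the caller's RNG stream.

**What the simulator does not emulate** — and therefore what passing
tests do *not* establish about real data: sequencing error is i.i.d.
beta-binomial with no site-, context- or batch-specific structure; no
CHIP leakage or germline contamination; gene presences are independent
across genes (no real co-occurrence/exclusivity structure — interaction
tests are validated against exact enumeration oracles instead);
mutation classes are independent of gene (real APC skews nonsense);
tumor fraction is constant across loci within a sample except through
sampling noise; and clinical timelines are schematic. Recovery tests
demonstrate the pipeline is correct and the calibration self-consistent,
not that the assay would achieve these operating characteristics on
patients.

## Numerical choices and degenerate inputs

* Boundaries: spectrum floor inclusive at 5%; amplicon QC inclusive at
  10,000X; positivity inclusive at LOD; detectability flag inclusive at
  10%; CEA elevated at exactly 5; tumor QC strict at both bounds
  (>98%, <1%); COSMIC recurrence strict (>3).
* Exact tests use the hypergeometric two-sided convention (sum of table
  probabilities ≤ observed, with the standard 1 + 10⁻⁷ relative
  tolerance); odds ratios are conditional-MLE with 0 and ∞ permitted.
  No multiple-testing correction by default — pairwise labels are
  exploratory; Benjamini–Hochberg is available behind `p_adjust = TRUE`
  and the choice is recorded in the output's attributes.
* Missing annotation columns default to the least-favorable value
  (false / 0 / "other"): absent evidence must never raise a score.
* VAF at zero depth is an error in `compute_vaf`; zero-depth amplicons
  are QC failures upstream of any VAF use.
* Quadrature grids: 400 quantile points over the error Beta for null
  rates, 100 over the shedding log-normal; both deterministic.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
as the smallest sizes at which the stochastic recovery bands (three
binomial standard errors) are meaningfully tight: 200-patient cohorts
(~1,400 mutations) for parameter recovery, 50 replicates per titration
level with 150 healthy donors for calibration, 10,000 null measurements
for the false-positive bound, and exhaustive oracle sweeps over all
2×2 tables with n ≤ 30 and panel instances with ≤ 12 variants.

## Known limitations

* The LOD is a single global threshold; per-amplicon thresholds exist
  in some assays and would slot in at `calibrate_lod`'s per-level
  machinery but are not implemented.
* The bundled actionability table is a small, editable starting point
  with laboratory-evidence rows marked as placeholders; it is not a
  clinical knowledge base and carries no versioned provenance.
* No survival analysis and no tumor-mutational-burden normalization;
  monitoring summaries stop at relapse dates and lead times.
* VCF ingestion expects single-sample somatic records with AF or AD/DP
  FORMAT fields and flat INFO annotation keys; richly annotated VEP/ANN
  strings must be flattened upstream.
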