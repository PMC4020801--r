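---
title: "CE-MS peptidomics with cemspep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CE-MS peptidomics with cemspep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemspep)
```

## The analysis in one paragraph

`cemspep` implements a label-free bottom-up peptidomics analysis for
capillary-electrophoresis mass spectrometry (CE-MS). Each sample arrives as a
centroided peak list (m/z, intensity, migration time). The pipeline estimates
a robust noise floor, keeps signals with signal-to-noise ratio above 4 and
charge above 1, groups peaks into isotope envelopes, and deconvolutes charge
states into neutral monoisotopic masses. Samples are then brought into a
common frame: high-frequency features (detected in at least 35% of samples)
serve as references for per-sample linear regressions of migration time and
mass, and a set of internal-standard peptides — consistently detected and not
associated with the case/control contrast — scales intensities by a
median-ratio factor. Aligned, normalized features are clustered across
samples into consensus peptides under mass- and time-dependent identity
tolerances; consensus peptides seen only once are discarded. An in-silico
tryptic digest of a protein FASTA annotates consensus peptides by
monoisotopic mass, using the predicted CE charge to break near-isobaric ties,
and proteins carried by fewer than two distinct peptides are dropped. Protein
abundance is the mean of its detected peptide intensities per sample, and a
variance-gated two-group test with Benjamini–Hochberg correction produces the
final differential report.

## Identity tolerances

Two detections are "the same peptide" when both coordinates agree within

* mass: ±50 ppm at 800 Da rising linearly to ±75 ppm at 15 kDa, clamped
  outside those anchors;
* migration time: ±2% of the time at 19 min rising linearly to ±5% at 50 min,
  clamped outside.

Both windows are symmetric half-widths, evaluated at the consensus centroid
rather than at the candidate feature, so the test a feature faces does not
depend on the feature's own noise. The 2–5% figure is read as a relative
half-width; this interpretation is isolated in `ce_window()` so a full-width
reading would be a one-line change.

## Deconvolution

The noise floor is 1.4826 × MAD of the intensities below the intensity
median. This estimator looks only at the lower half of the intensity
distribution, so arbitrarily strong signals cannot inflate it; an all-equal
degenerate input clamps to machine epsilon and is flagged. The SNR filter
keeps peaks strictly above 4 × noise.

Envelope extraction is greedy by intensity. The strongest unassigned peak
seeds an isotope grid `mz0 + k·1.00235/z`; co-eluting peaks matching the grid
within 10 ppm vote for each charge 1–10, and the smallest charge explaining
the most peaks wins. Two safeguards matter in crowded regions: only the
contiguous isotopologue run containing the seed is kept (a stray from a
coincident grid of another molecule is almost never adjacent to the true
run), and a peak below the seed's m/z may join only at ≥40% of the seed
intensity (a true monoisotopic neighbour of a heavier-than-1.8-kDa peptide is
at least about half the seed's height under the isotope model). Neutral mass
is taken from the lowest retained isotope: `M = z·mz − z·1.00728`.
Monoisotopic (not average) mass is used throughout.

Envelopes with charge ≤ 1 are discarded. Remaining envelopes are merged
across charge states when masses and times agree within the identity
tolerances, with one restriction: a feature never holds two envelopes of the
same charge, because those are two molecules, not two charge states of one.
The merged feature sums member intensities (the spread across charge states
is instrument partitioning of one analyte, so summing — not maxing — restores
the analyte total) and records the union of charges.

## Calibration and normalization

Reference features are clusters detected in ≥35% of samples; their canonical
coordinates are across-sample medians. Because a reference set built from
still-drifted features is itself fragmented, `calibrate_cohort()` iterates:
a first pass matches with a 3× inflated time window (gross drift can exceed
the nominal CE window at early migration times), aligns, re-selects
references from the aligned features and refits; per-sample transformations
are composed so the final model maps raw coordinates directly into the
cohort frame. The mass window is never inflated: simulated and realistic
mass drift stays well inside ±50 ppm.

The per-axis fit is ordinary least squares of canonical on observed
coordinates with two robustness devices, both of which earned their place
during development on simulated cohorts:

* matches must be reciprocal — the reference's nearest feature must have that
  reference as its own nearest. One-sided nearest matching preferentially
  pairs drifted features with time-closer wrong references and visibly
  attenuates the fitted drift toward the identity;
* an iterated MAD-based trim (3.5 × MAD, two rounds) removes the remaining
  gross mismatches. A single 3-SD trim was tried first and left the fit
  biased, because mismatches inflate the SD that defines the trim.

Fits with fewer than 5 matched references, or slopes outside (0.5, 2), raise
an alignment failure; the pipeline drops such samples with a warning rather
than letting a silent bad calibration contaminate the cohort frame.

Internal standards are consensus peptides detected in ≥80% of samples whose
case/control rank-sum p-value exceeds 0.5 — consistently detected and showing
no hint of disease association — taking the top 22 by frequency. Each
sample's intensities are multiplied by `reference median / sample median`,
where the sample median is over its detected standards and the reference
median is the median across samples of those per-sample medians. This makes
the operation exactly idempotent and makes a sample whose intensities are
uniformly doubled come back with factor 0.5. Samples detecting fewer than
3 standards are flagged and left unscaled. The count 22 honours the original
workflow's choice and is configurable; on synthetic cohorts the number of
qualifying candidates, like the number of references, is an emergent
property, not a target.

## Consensus matching

Clustering is greedy and centroid-based: features from all samples are
visited in decreasing intensity order; each joins the nearest consensus
(Euclidean distance in tolerance-normalized units, ties to the lower mass)
whose centroid lies within both windows and which has no feature from the
same sample yet, else seeds a new consensus. Centroids are intensity-weighted
means. Because centroid updates can leave two clusters inside each other's
tolerance, a final maximality pass merges any such pair whose sample sets
are disjoint. The fixed visiting order makes the whole procedure
deterministic, which the test suite checks by permuting input rows.
Consensus peptides contributed by a single sample are removed.

## Annotation

The digest cleaves C-terminal to K or R except before P, up to a configurable
number of missed cleavages (default 1). Carbamidomethyl-C (+57.02146 Da) is
fixed; oxidised M and hydroxylated P (+15.99491 Da each) are enumerated as
count-based variants with at most 2 variable sites per peptide — placements
of the same modification are isobaric, so positions are not tracked. The
predicted CE charge is `1 + #K + #R + #H`: at the acidic pH of the CE
separation the N-terminus and all three basic side chains are protonated.
Whether neutral polar residues should enter this charge rule quantitatively
is left out: they enter the migration model (below) instead.

A consensus peptide takes the candidate within the mass tolerance; among
several, candidates whose predicted charge is in the observed charge set are
preferred, then the smallest |mass error|, then fewer modifications, then
lexicographic order — a fully deterministic cascade. If no candidate is
charge-consistent the charge filter is waived rather than discarding the
match, and the assignment is flagged `charge_consistent = FALSE`.
Unannotated consensus peptides stay in the outputs but never enter protein
statistics. Proteins with fewer than 2 distinct assigned sequences are
dropped.

## Differential statistics

Protein abundance in a sample is the arithmetic mean of that protein's
detected peptide intensities, 0 when none is detected (a `detected_only`
flag exposes the sensitivity of this convention). Per protein, a two-sided
variance-ratio F-test at α = 0.05 gates the choice between an equal-variance
t-test and a Mann–Whitney test. The named F-test is implemented literally as
a variance-ratio test; it is a variance gate, not a normality test, and the
gate is swappable. The Mann–Whitney branch uses the normal approximation
without continuity correction, so a perfectly symmetric split returns
p = 1 exactly; with both branches, identical groups give p = 1.

Benjamini–Hochberg adjustment is the step-up rule
`adj(i) = min over j ≥ i of p(j)·m/j`, capped at 1, with `m_total` allowed to
exceed the number of supplied p-values: when only a subset of tested
p-values is listed, the unlisted ones are at least as large as the listed
maximum and cannot lower any running minimum, so the formula over the listed
set is exact. Within the pipeline `m_total` is the number of proteins
tested. The reported `fold_sd` is the standard deviation of the case values
divided by the control mean — the case-group dispersion on the fold scale;
this definition is isolated in `fold_change()`.

## The synthetic cohort generator

The generator exists so that every stage can be tested against ground truth
without any instrument data. Its defaults describe the study conditions the
pipeline is built for:

| parameter | default | meaning |
|---|---|---|
| `n_case`, `n_control` | 20, 15 | group sizes of the default end-to-end cohort |
| `n_proteins`, `mean_length` | 97, 120 | protein database size |
| fold changes | 19 spikes | the 19 reported fold magnitudes (6.56 … 1.73) on seeded-random proteins, others 1 |
| `n_standards` | 22 | spiked invariant peptides |
| `noise_cv` | 0.2 | multiplicative lognormal intensity noise |
| `detection_prob` | 0.7 (0.9 for standards) | per-peptide per-sample Bernoulli detection |
| `mass_jitter_ppm` | 5 | per-(peptide, sample) Gaussian mass error |
| `time_jitter_pct` | 0.3 | migration-time jitter, % of time |
| drift | on | per-sample linear drift: time slope 0.95–1.05, intercept ±1 min; mass slope 1±2·10⁻⁵, intercept ±5 mDa |
| `noise_floor`, `n_decoys` | 50, 3000 | uniform decoy peaks at 0.5–4 × the floor, below the SNR threshold |

Abundances are lognormal (protein level spread ≈ one decade, fixed
per-peptide ionization efficiencies), a choice made once because no abundance
distribution for vitreous peptides is established; it is a tunable, not a
claim. A detected peptide emits an isotope-resolved envelope at its
predicted charge (70% of the signal) and the next charge up (30%), isotope
intensities from a binomial model with roughly one heavy-atom unit per
1000 Da (`size ≈ 0.044·M`, `p = 0.0107`), isotope spacing exactly
`1.00235/z`, monoisotopic m/z `(M + z·1.00728)/z`, and peaks outside m/z
350–3000 dropped. All truth peptide masses lie in 804–3953 Da.

Migration time follows classical electrophoretic mobility scaling
`t ∝ M^(2/3)/z_eff`, affinely mapped into the 19–50 min window, with
`z_eff = z + 0.15 · #[STNQYCW]`. The polar-residue term is there for a
structural reason: a migration time that is a pure function of mass and
charge makes every pair of near-isobaric peptides co-elute exactly, which no
real separation does and which would make the deconvolution and matching
problems artificially unsolvable. Composition-dependent migration is also
what links sequence to the CE coordinate in this field's matching of
sequenced peptides to CE-MS features.

What the generator deliberately does not emulate: correlated (structured)
missingness, retention-order swaps or nonlinear time warp, chemical noise
with isotope structure, charge-state intensity ratios that depend on
composition, and real isotopologue fine structure. Passing tests therefore
show that the algorithms are correct under the stated noise model, not that
the pipeline's numerical performance transfers unchanged to instrument data.

Determinism: every random draw derives from the cohort seed (per-sample
streams are derived with a fixed integer recurrence), so regeneration with
the same seed is byte-identical, and the test suite asserts it.

## Problem sizes used by the test suite

The suite runs entirely on generated data, sized for a desk machine: the
default cohort (97 proteins, 35 samples, ≈ 600 truth peptides, ≈ 5000 peaks
per sample) is run end-to-end once; deconvolution recovery uses one default
sample; drift recovery uses a 12-sample low-noise cohort (all noise channels
at the 0.05 level — the recovery tolerances of ±0.005 on the slope and
±0.05 min on the intercept sit at the estimator's noise floor under the
default 0.3% time jitter, so the low-noise setting is the condition under
which the parameter-recovery claim is meaningful); matching fidelity uses a
20-sample, ≈125-peptide cohort at 5 ppm mass jitter; the BH oracle check
uses 1000 random vectors of length ≤ 40 against an O(n²) brute-force step-up
implementation plus one length-10⁴ vector against `stats::p.adjust`; the
null type-I experiment uses 1000 simulated protein tests; and the spiked
fold-4 recovery runs the differential stage over 20 seeds at the default
cohort conditions (97 proteins, 20+15 samples, noise CV 0.2), with the
heavy upstream stages exercised by the single full run.

## Known limitations

* Quantification is intensity-based without charge-state-specific response
  modelling; summing across charge states is asserted, tested, and isolated.
* Near-isobaric peptides within a few ppm of each other that also share
  predicted charge cannot be distinguished; annotation picks the smaller
  mass error and flags nothing, exactly as a mass-and-charge rule must.
* A 2-peptide protein whose peptides fall outside the acquisition window at
  their natural charge, or lose an isobar tie, silently leaves the report —
  the minimum-two-peptides rule makes this loss explicit in the drop log.
* The calibration model is strictly linear; nonlinear (spline) time warping
  is out of scope by design.
* m/z 350–3000 and the tolerance anchors are constants of the workflow this
  package reproduces, not instrument-agnostic defaults.
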