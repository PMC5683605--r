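---
title: "Methods: quantitative peptidomics profiling of carboxypeptidase specificity"
author: "cpdquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative peptidomics profiling of carboxypeptidase specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdquant)
```

## The scientific problem

Metallocarboxypeptidases (MCPs) remove single amino acids from peptide
C-termini. Human carboxypeptidase D (CPD) is unusual in carrying two active
carboxypeptidase domains with overlapping but distinct specificities: domain
I strongly prefers C-terminal Arg, while domain II cleaves C-terminal Lys
and Arg comparably; the two domains also differ in pH optimum. `cpdquant`
implements the quantitative-peptidomics workflow used to establish such
specificity profiles: a defined tryptic peptide library (or a cellular
peptidome) is incubated with increasing enzyme amounts or with
single-domain-active mutants, each reaction is labeled with one of five
isotopologues of an amine-reactive TMAB (4-trimethylammoniumbutyrate) tag,
the reactions are pooled and analyzed in one LC-MS run, and per-peptide
intensity ratios against the no-enzyme control reveal which peptides were
cleaved, how strongly, and by which domain.

## Peptide mass and charge bookkeeping

All masses derive from a frozen 5-decimal monoisotopic residue table
(`amino_acid_masses()`), water 18.010565 Da, proton 1.00728 Da, N-terminal
acetylation +42.01057 Da and Met oxidation +15.99491 Da. The neutral
monoisotopic mass convention matches the "Theor M" columns of published
substrate tables; `parse_peptide()` accepts the table notation (`Ac-`
prefix, `Mox` marker).

Charge and tag-count rules mirror the identification criteria of the
workflow:

* expected charge = basic residues (Lys + Arg; His optionally) + 1 for a
  free N-terminus. Observed charge states at or below the expectation are
  admissible, since the rule is an upper bound in practice (published
  tables report e.g. a 4-amine peptide observed at z = 2).
* tag count = free amines = Lys count + 1 for a free N-terminus.
* identifications are gated at 50 ppm parent-mass error, correct tag
  count, admissible charge, and — when MS2 is available — at least 80% of
  the major fragments matching predicted b/y ions with a minimum of five
  matches (`validate_identification()`). Without MS2 the fragment gate is
  reported as not evaluated and the remaining gates decide.
* peptides containing Cys, Tyr or His are flagged and excluded before
  classification: these residues undergo side reactions with label
  impurities and show intensities uncorrelated with enzyme amount.

## Tryptic library construction

`trypsin_digest()` cleaves after every Lys/Arg, by default suppressing
cleavage before Pro (the Keil rule; the workflow's own protease behavior is
not documented at this level, so the rule is exposed as a flag). The
default of up to 2 missed cleavages reproduces the documented 1- and
2-missed reference peptides (e.g. `LRVDPVNFK`, `KFEKLPESK`). The packaged
FASTA (`library_proteins_fasta()`) holds *synthetic stand-in* sequences for
the five library proteins, assembled so that their digests contain the
documented reference peptides of each precursor; they are not curated
database sequences, and peptide coordinates are therefore fixture-relative.

## TMAB peak-set geometry

The five channels D0/D3/D6/D9/D12 add, per tag, 0 / 3.01883 / 6.03766 /
9.05649 / 12.06656 Da relative to D0. The steps are frozen constants from
standard atomic masses (3 H→D substitutions = 3 × 1.006277 Da; 3 ¹²C→¹³C =
3 × 1.003355 Da). The absolute D0 tag addition (128.10753 Da per labeled
amine) is a neutral-equivalent convention: the tag's permanent quaternary
cation contributes one charge that is bookkept like a proton at the m/z
stage, so `m/z = (labeled mass + z × 1.00728)/z`. Only the relative channel
spacings — `tags × step / z` — are observable peak-set geometry, and those
are exact under any such convention.

Peak-set detection (`detect_peaksets()`) predicts the 5-channel pattern for
each library peptide at each admissible charge and takes the nearest
centroid per channel within a 50 ppm tolerance (exact distance ties break
toward lower m/z, for determinism). A set is reported when at least two
channels match; unmatched channels get zero intensity.

## Ratios, censoring, classification

Ratios are per-condition channel intensity over the control channel
(apex-centroid intensity; summed-envelope quantification is out of scope).
A numerator at or below the background estimate, or a ratio below 0.10, is
censored at the floor 0.10 ("<0.10" in printed tables); ratios above 5.00
are censored at the cap (">5.00"). The background is configurable and
defaults to zero for synthetic data; for real peak lists a low quantile of
run intensities is a reasonable estimate.

Classification thresholds follow the published definitions, applied to the
ratio at the highest enzyme amount:

| category | rule |
|---|---|
| good substrate | decrease ≥ 60%, i.e. ratio ≤ 0.40 |
| weak substrate | decrease ≥ 20% and < 60%, i.e. ratio in (0.40, 0.80] |
| non-substrate | decrease < 20% |
| product | ratio ≥ 1.5 and non-decreasing with enzyme amount |

The product threshold is not quantified in the published workflow ("an
increase correlated with enzyme amount"); 1.5× was chosen conservatively
and is configurable. Monotonicity is tested with a 25% relative step
slack: with ~5% channel-level multiplicative noise a dose-to-dose ratio
step has a log-scale SD near 0.07, so a slack of several SD is required to
keep the consistency check from rejecting genuine products, while truly
decreasing profiles are already excluded by the 1.5× gate. The secondary
good-substrate observation (partial decrease at the intermediate amount) is
recorded as `dose_consistent` but never overrides the 60% rule — published
good-substrate rows exist with essentially no intermediate decrease.

Domain preference compares residual intensities after incubation with the
single-domain-active mutants (control = double mutant). The dI/dII ratio is
censored to [0.10, 5.00]; a below-background domain-I numerator forces the
floor and a below-background domain-II denominator forces the cap. Cutoffs
≤ 0.50 (domain I preferential) and ≥ 2.00 (domain II preferential) are not
printed anywhere in the source tables; they were chosen to reproduce every
qualitative call derivable from the published dI/dII column and are
configurable. When reproducing printed tables the ratio is computed from
the two printed per-condition columns, which can differ numerically from a
ratio of raw intensities (one published row prints 3.53 where the column
quotient is 2.86) without changing any call.

P1′/P1 profiles tally the C-terminal and penultimate residues per category;
the P1 profile counts only peptides with permissive (Lys/Arg) C-termini,
matching the published convention. Product peptides are traced back to
their precursors with `deduce_cleavage()`; the residue immediately
downstream of the product's C-terminus is the residue the enzyme removed,
and multiple occurrences are reported with an ambiguity flag.

## Michaelis–Menten kinetics

`fit_mm()` fits `v = Vmax·S/(Km+S)` by Levenberg–Marquardt least squares
with positivity enforced through a log-parameterization; the default start
(`Vmax0 = max rate`, `Km0 = median S`) is robust, and a badly scaled user
start falls back to it. Units are centralized: Km in µM, enzyme in nM,
kcat in s⁻¹, with `kcat = rate_to_conc × Vmax / ([E] × 10⁻³)`. The
`rate_to_conc` calibration factor (default 1, i.e. rates already in µM/s)
exists because fluorescence-based assays report arbitrary rate units; it
must be supplied explicitly for such data. Degenerate data (all-equal or
all-zero rates, as for an inactive double mutant) returns `converged =
FALSE`, mirroring "not detectable" entries. The ≤20% substrate-consumption
condition of the assay is an initial-rate validity note, not part of the
model.

`ph_summary()` normalizes an activity series to percent of maximum and
reports the optimum (argmax) and the half-maximal range as the outermost
*measured* grid pH values, contiguous with the optimum, at ≥50% activity.
Interpolated crossings were considered and rejected: the published summary
statements quote measured grid endpoints, and a 0.5-unit grid makes
interpolation precision illusory.

## Docking pose filter

A docking pose is counted correct when the centers of mass of its P1′
(C-terminal) and P1 (penultimate) residues lie within 10 Å of the centers
of mass of the receptor's S1′ and S1 pocket residues respectively (for CPD:
Asp268/Glu315 in domain I, Asp682/Glu727 in domain II, numbered per the
input receptor file). Centers of mass use heavy atoms only — pose files
frequently omit hydrogens — over all atoms of the residue (backbone + side
chain). The statistic is the percentage of correct poses over the supplied
ensemble (101 minimized poses in the published protocol), and
`rank_correlation()` relates it to experimental cleavage as Spearman's ρ
between percent-correct and 1 − ratio, so ρ > 0 means more correct poses go
with stronger cleavage. Docking itself (pose generation, scoring,
electrostatics) is out of scope; the filter consumes poses as given.

## The synthetic-data generator

Because no raw LC-MS data accompany the source tables, the generator
provides every input with known truth:

* **Enzyme model** (`enzyme_model()`): only Lys/Arg P1′ is cleavable;
  Pro/Asp/Ile in P1 blocks cleavage; per-peptide cleavage efficiency is
  drawn uniformly from residue-specific ranges — domain I `K: [0, 0.25],
  R: [0.4, 0.95]` (Arg-biased), domain II `K and R: [0.35, 0.95]`
  (comparable), full enzyme similar to domain II. These ranges encode the
  qualitative published contrasts, not measured values.
* **Dose response**: `ratio(E) = (1 − eff) + eff·exp(−E/E50)` with
  per-peptide E50 ~ log-normal(log 10 nM, 0.5). This invented but
  documented form has the two endpoint behaviors that are knowable: ratio
  1 at zero enzyme and residual fraction `1 − eff` at saturating enzyme.
  Products rise complementarily, `1 + 2·eff·(1 − exp(−E/E50))`.
* **Conditions**: enzyme amounts 0/0.1/1/10/100 nM with channels
  D0 = 100 nM … D12 = no enzyme, the published dose-response design;
  replicates may permute the channel assignment via the channel→condition
  map.
* **Spectra** (`render_spectra()`): peaks at the predicted channel m/z at
  the peptide's expected charge, log-normal multiplicative intensity noise
  (unbiased, CV configurable), optional uniform background peaks, peaks at
  or below background omitted.
* **Truth categories** are the classification thresholds applied to the
  noise-free ratios, so the zero-noise round trip is exact by definition
  of the generator, and noisy accuracy measures only the noise
  sensitivity of detection + censoring + classification.

What the generator does **not** emulate — and what passing round-trip tests
therefore do not demonstrate about real data: chromatographic co-elution
and retention drift, isotope envelopes and charge-state distributions,
incomplete labeling, label side reactions (beyond the C/Y/H exclusion
flag), shared peaks between near-isobaric peptides, and Mascot-style
open-database identification (the pipeline matches against a closed
library).

## Problem sizes and numerical choices

The validation suite uses a 200-peptide synthetic library (≈340 observable
peptides including products) for the pipeline round trip, 100 replicate
fits for kinetics bias checks, and 101-pose ensembles for the docking
statistic — sizes at which every check runs in seconds while keeping
binomial noise on accuracy estimates near one percentage point.
Deterministic tie-breaks (nearest-ppm, then lower m/z), closed/open
threshold boundaries exactly as published (0.40 good, 0.80 weak), and
seeded generators make all results reproducible.

## Known limitations

* Synthetic stand-in precursor sequences: positions are not database
  coordinates.
* The absolute TMAB tag mass is a documented convention; only channel
  spacings are validated against observable geometry.
* Apex-centroid (not envelope-summed) quantification.
* No P2/P3 positional analysis and no enrichment statistics on profiles
  (the source workflow reports raw counts).
* The `rate_to_conc` calibration for fluorescence assays must come from
  the user; kcat values are only as good as that calibration.
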