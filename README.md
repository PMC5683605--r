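# cpdquant

Quantitative peptidomics profiling of carboxypeptidase substrate
specificity in R.

## What this package is for

Metallocarboxypeptidases remove single amino acids from peptide C-termini,
and which peptides they cleave is governed by the C-terminal (P1′) and
penultimate (P1) residues. Human carboxypeptidase D (CPD) carries two
active carboxypeptidase domains whose specificities differ — domain I
prefers C-terminal Arg, domain II cleaves Lys and Arg comparably — and the
workhorse assay for mapping such preferences is isotopic-label quantitative
peptidomics: a tryptic peptide library (or a cellular peptidome) is
incubated with increasing enzyme amounts or with single-domain-active
mutants, each reaction is labeled with one of five TMAB
(4-trimethylammoniumbutyrate) isotopologue channels (D0/D3/D6/D9/D12),
everything is pooled into one LC-MS run, and per-peptide channel-intensity
ratios against the no-enzyme control reveal substrates, products and domain
preferences.

`cpdquant` implements that pipeline end to end for analysts working with
such data (or validating methods against synthetic data):

* **Peptide chemistry** — monoisotopic masses from a frozen residue table,
  free-amine (tag) counting, expected charge, b/y fragment series, ppm
  comparison; parser for table notation (`Ac-`, `Mox`).
* **Digestion** — in-silico trypsin with missed cleavages and the Keil
  (no-cleavage-before-Pro) rule; pooled, de-duplicated libraries.
* **TMAB labeling** — 5-channel labeled masses and peak-set m/z geometry
  (spacing = tags × step / charge).
* **Quantification** — peak-set detection in centroided MS1 peak lists at
  50 ppm, identification gates (mass / tags / charge / 80% b-y fragments,
  minimum five), censored enzyme/control ratios (floor 0.10, cap 5.00).
* **Classification** — good (≥60% decrease at the top dose), weak
  (20–60%), non-substrates, products (correlated increase); domain
  preference from dI/dII ratios; P1′/P1 preference profiles; product
  cleavage-site deduction.
* **Kinetics** — Michaelis–Menten fitting (`v = Vmax·S/(Km+S)`) by
  Levenberg–Marquardt with log-parameterized positivity, kcat and kcat/Km,
  pH-activity summaries.
* **Docking pose filter** — percent of poses whose P1′/P1 residue centers
  of mass fall within 10 Å of the S1′/S1 pocket residue centers of mass.
* **Synthetic data** — generators for libraries, dose-response cleavage
  with ground truth, labeled spectra with log-normal noise, peptidomes,
  kinetic datasets and toy pose ensembles, enabling exact round-trip
  validation.

## Worked example

Classify a reference substrate from its printed dose-response ratios and
verify its mass/charge bookkeeping:

```r
library(cpdquant)

monoisotopic_mass("LVTDLTK")   # 788.4644 (table prints Theor M 788.46)
count_free_amines("LVTDLTK")   # 2  (free N-terminus + 1 Lys -> 2 tags)
expected_charge("LVTDLTK")     # 2

t2 <- cpd_reference("tryptic_good")
row <- t2[t2$sequence == "LVTDLTK", ]
r <- parse_ratio(unlist(row[c("ratio_0.1nM", "ratio_1nM",
                              "ratio_10nM", "ratio_100nM")]))
classify_substrate(setNames(r$value, c("0.1nM", "1nM", "10nM", "100nM")))
#> $category
#> [1] "good"
#> $dose_consistent
#> [1] TRUE
#> $evidence
#> 0.1nM   1nM  10nM 100nM
#>  1.08  1.05  0.84  0.40
```

The ratios fall monotonically with enzyme amount to 0.40 at 100 nM — a 60%
decrease, the boundary of the good-substrate class.

Fit kinetics from data generated at the standard 8-concentration series:

```r
d <- generate_rates(Km = 153, kcat = 12.5, enzyme_conc = 2.5)  # nM enzyme
fit_mm(d$S, d$rate, enzyme_conc = 2.5)
#> <mm_fit> Vmax = 0.03125  Km = 153  kcat = 12.5 1/s  kcat/Km = 0.0817
```

Run a complete synthetic experiment (200-peptide library, 5-plex labeling,
detection, censored ratios, classification, cleavage deduction) and compare
against the generator's truth:

```r
ex <- run_synthetic_experiment(n = 200, noise_cv = 0.05, seed = 1)
ex$category_accuracy   # 97.3 (% of true categories recovered)
ex$cleavage_accuracy   # 100  (% of true cleaved residues deduced)
```

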