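---
title: "Methods: automated DS-FIA-MRM method assembly and QC chemometrics"
author: "fiamrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated DS-FIA-MRM method assembly and QC chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiamrm)
```

## The problem

Targeted triple-quadrupole (QqQ) metabolomics in multiple-reaction
monitoring (MRM) mode offers precision and sensitivity, but every monitored
metabolite needs instrument parameters — a precursor/product m/z pair (Q1,
Q3), a collision energy, and quadrupole potentials — that are classically
obtained by optimizing against reference standards. Most of a microbial
metabolome has no affordable standard. `fiamrm` assembles organism-specific
MRM screening methods from three complementary information sources:
manually optimized in-house transitions, literature transitions, and
in-silico predictions (fragment spectra from competitive fragmentation
modelling plus per-group pKa values), then distributes the selected
transitions into short flow-injection methods (no chromatography; one
injection per method package, one minute per injection). The downstream
statistics pipeline turns the resulting peak-area tables into
discriminating-metabolite calls.

## Ionization-mode selection from per-group pKa values

Electrospray polarity is decided from the acid dissociation constants of
the *individual functional groups* (one pKa per acidic or basic group), not
from a whole-molecule constant. The strongest group governs: with
$a = \min(\text{acidic pKa})$ and $b = \max(\text{basic pKa})$,

| condition | class | allocated mode |
|---|---|---|
| no pKa values | unclassified | excluded from the method |
| $a < 6.5$, no strong base | acid | negative |
| $b > 8.5$, no strong acid | base | positive |
| $a < 6.5$ and $b > 8.5$ | amphoteric | both, deferred |
| only weak groups | neutral | by the weak group(s) |

Two decisions here were genuinely open:

* **Aggregation.** The taxonomy is defined on per-group values; whether a
  molecule with several groups is judged by its strongest group or by any
  group is not fixed by the class definitions alone. We aggregate by the
  strongest group (min over acidic, max over basic), which reproduces the
  canonical examples: a nucleotide triphosphate with acidic pKa values of
  1-4 and a weak basic site classifies as an acid; an amino acid with a
  carboxyl pKa near 2 and an amine pKa near 9.5 as amphoteric.
* **Boundary equality.** $a = 6.5$ (or $b = 8.5$) counts as *weak*: the
  classification predicates are strict inequalities. The thresholds are
  configurable through `classifierThresholds()`; 6.5/8.5 are the defaults.

Neutral molecules carrying one weak group keep the polarity that group
supports; neutrals with both weak groups, like amphoterics, are allocated
to both modes with the final choice *deferred* to transition selection,
where avoiding isobaric convolutions may favour one polarity.

## Spectral prediction validation

Predicted fragment spectra (three collision-energy blocks, low/medium/high
mapped to ±10/±20/±40 V) are compared against measured product-ion spectra
with five fractions: recall $R$ and precision $P$ (matched peak counts over
measured resp. predicted counts), weighted recall/precision $WR$, $WP$
(matched intensity over total intensity on each side) and the Jaccard score
$J = |m| / (|M| + |P| - |m|)$. By construction $J \le \min(R, P)$, and
intensity weighting makes $WR > R$ exactly when the matched peaks are the
intense ones.

Numerical choices:

* **Matching tolerance**: absolute, default 0.01 Th, appropriate for
  high-resolution product-ion spectra; configurable. A ppm-relative
  tolerance would behave nearly identically over the 50-1000 Th range at
  these densities.
* **Pairing**: greedy nearest-m/z within tolerance, each peak used once,
  ties broken toward the smaller mass error and then the more intense
  predicted peak. Greedy pairing is deterministic and, at peak spacings
  far coarser than the tolerance, coincides with optimal bipartite
  matching; the unit tests verify agreement with an exact set-intersection
  oracle on such spectra.
* **Intensities**: $WR$/$WP$ use raw intensities; because each fraction is
  normalized within one spectrum, raw and relative intensities give
  identical values.

## Method assembly

For an organism's metabolite records the builder applies, in order:

1. **Filtering**: keep $30 < MW < 1500$ g/mol (strict) and a classifiable
   pKa set.
2. **Enantiomer deduplication**: records sharing formula and molecular
   weight whose structure strings are identical after removing
   stereo-descriptors collapse to one record; the smallest KEGG identifier
   survives (deterministic; the choice among true enantiomers is
   arbitrary for MS, which cannot distinguish them).
3. **Candidate gathering** with origin priority in-house > literature >
   predicted. Predicted candidates pool the fragments of all three
   collision-energy blocks (each fragment keeps its own CE), deduplicate
   by product m/z keeping the most intense occurrence, drop fragments
   above the precursor m/z, and are ranked by intensity. The precursor is
   $MW \pm 1.00728$ (proton mass) for positive/negative mode. Missing
   entrance and cell-exit potentials default to 10 V and 4 V; missing
   declustering potentials are interpolated by a per-mode least-squares
   line of DP over precursor mass fitted on the in-house/literature
   entries (pooled fit when a mode has fewer than two points); dwell time
   is 50 ms.
4. **Convolution detection**: two candidates convolve when they share the
   ionization mode and agree on Q1 and Q3 within `iso_tol` (default
   0.5 Th — unit resolution of a QqQ; the tolerance is a design choice,
   as mode + m/z agreement defines the phenomenon but not the window).
   Cross-polarity coincidences are not convolutions because the modes are
   acquired separately.
5. **Selection**: per metabolite, the most intense convolution-free
   candidate; deferred (dual-mode) metabolites pick the mode offering a
   convolution-free candidate. When both modes qualify the mode whose best
   candidate has the higher relative intensity wins, with a residual tie
   going to negative mode (the larger half of a typical microbial
   metabolite set ionizes negatively). Only if every candidate in every
   allowed mode is convolved is the top-ranked candidate taken and
   flagged, so an avoidable convolution is never selected — the test suite
   checks this against exhaustive enumeration on small instances.
6. **Packaging**: per mode, $\lceil n / 40 \rceil$ packages, sizes
   balanced to differ by at most one (sort by Q1, deal round-robin). The
   alternative reading — fill packages to 40 and leave a remainder — obeys
   the same package-count rule; balancing was chosen because it equalizes
   cycle time across packages. Each package is one 1-minute flow
   injection, so a method set's analysis time in min/sample equals its
   package count: 96 positive + 156 negative selections give 3 + 4 = 7
   packages and 7 min/sample at an average of 36 transitions per package.
7. **Batch creation**: per polarity plate, a blank, a QC, then the
   seed-shuffled sample injections with a QC inserted after every sixth
   sample (plus a closing QC when the final block is incomplete). Both
   plates use the same randomization, mirroring identical plate
   allocation for the two polarities.

## The statistics pipeline

Stages run in a fixed, enforced order (each stage refuses to run after a
later one): signal-to-noise filter (S/N > 5, strict) → QC-anchored LOESS
drift correction → QC acceptance (QC RSD < 20 % with the $n-1$ standard
deviation, QC missingness < 30 %) → imputation → models.

**LOESS correction.** Per metabolite, a degree-1 (locally linear,
tricube-weighted) LOESS of QC area over injection order; the span is
selected from the grid $\{0.3, 0.4, \dots, 1.0\}$ by leave-one-out
cross-validation on the QC injections ("low-order" fixes the degree but
not the span; the grid covers the usable range at typical QC counts).
Corrected areas are raw × (QC median / interpolated trend). Degenerate
cases: fewer than 4 usable QCs — skipped with a warning; non-positive
interpolated trend — left uncorrected and flagged; a correction that fails
to reduce the QC RSD is rolled back, so correction never makes a
metabolite worse.

**Imputation.** The two imputation rules need a missingness diagnosis the
data cannot give per cell, so it is operationalized class-wise: a class
with *some* replicates present is treated as missing at random and gets
the class mean; a class missing *entirely* is treated as
missing-not-at-random (below detection) and gets half of the metabolite's
global minimum. Each decision is logged per metabolite × class.

**Modelling.** Range scaling ($x - \min$)/($\max - \min$)) is fitted on
training data only, inside every cross-validation split, so no test
information leaks; test values are not clipped. PCA uses the standard
singular-value decomposition with a cross-validated $Q^2X$
(reconstruction of left-out rows from training loadings). PLS-DA is NIPALS
PLS2 on the one-hot class matrix — implemented in-package and
cross-checked in the tests against an independent PLS-DA implementation —
with class calls by argmax of the predicted columns. Model validation is a
stratified double five-fold cross-validation: the outer folds estimate
$Q^2Y$ (pooled PRESS over total sum of squares about the training means),
the inner folds select the latent-variable count by the gain rule — stop
adding components when $Q^2Y$ improves by less than 5 % (absolute, 0.05 on
the $Q^2$ scale). Class-specific VIP scores use the per-response-column
explained sum of squares, normalized so the mean squared VIP over
variables is 1 for every class (asserted on every fit).

**Inference.** Percentile confidence intervals for the class-specific
regression coefficients and VIP scores come from class-stratified
bootstrap resampling (default $n = 1000$; the test and acceptance runs use
100 to keep runtimes short — the interval width, not the selection logic,
depends on $n$). The univariate screen is the tie-corrected
Kruskal-Wallis test at $\alpha = 0.05$ without multiplicity correction
(matching the stated error level; Benjamini-Hochberg adjustment is
available via `qcConfig(p_adjust = "BH")` but off by default). A
metabolite is *selected* when the Kruskal-Wallis p-value is below
$\alpha$ and, for at least one class, the bootstrap CI of its coefficient
excludes zero while its VIP point estimate exceeds 1 (strict). Whether the
coefficient criterion is CI-exclusion or a nonzero point estimate is
ambiguous in principle; CI-exclusion is the default because the bootstrap
exists exactly to provide it, and `beta_criterion = "point"` switches to
the literal reading.

## What the synthetic generators emulate

`genLibrary()` produces a compound library spanning all five species
classes, straddling both MW bounds, with one enantiomer pair and one
isobaric pair per polarity; `genPredictedSpectra()` emits parseable
three-block spectrum documents with known base peaks and planted
sub-threshold peaks; `genBatch()` simulates a measurement batch: class
means with planted fold-change discriminators, multiplicative lognormal
noise (peak areas are positive with roughly constant CV, making the
lognormal the natural noise model), a smooth injection-order drift, QC
injections as pooled class means (QC samples are pools), sparse
missing-at-random cells and whole-class knockouts, and S/N modelled as a
compound property — a few metabolites sit at the detection limit
everywhere (the population QC acceptance exists to remove), with only
sporadic per-cell dropouts elsewhere.

Default design: 3 classes × 6 technical replicates, 100 metabolites, 10
two-fold discriminators, 10 % noise CV, 20 % sinusoidal drift, a lead
blank with three lead-in QCs (batch equilibration) and a QC every six
samples. A two-fold change at 10 % CV is ≈ 7 standard deviations — a
strong, clearly plantable effect; the recovery results on this design
(≥ 9/10 planted recovered, ≤ 5/90 false positives) therefore demonstrate
that the pipeline's plumbing is correct, *not* that real yeast extracts
would yield comparable power. Real data differ in ways the generator does
not model: correlated metabolites (pathway structure), heteroscedastic and
occasionally non-lognormal noise, matrix effects and ion suppression that
vary by injection, and drift that is not smooth in injection order.
Whole-class knockouts carry genuine class information by construction, so
recovery tallies count them with the planted effects rather than as false
positives.

## Problem sizes and runtime

The test suite and the acceptance script run the full pipeline at the
default design (25 injections × 100 metabolites), 100 bootstrap draws,
200 null simulations for the Kruskal-Wallis error rate and 10-20 label
permutations; this keeps a complete run in the tens of seconds on one CPU
while leaving every code path exercised. All randomness is seeded;
generators restore the caller's RNG state.

## Known limitations

* Live database access (KEGG/PubChem/ChEMBL) is specified as a fetcher
  contract; the shipped REST sketch covers only the identifier/structure
  links and is not used by any test. Resolved libraries are consumed as
  local TSV dumps.
* The fragmentation model itself is out of scope: predicted spectra are
  parsed, never re-derived, and prediction quality is only *measured* (R,
  P, WR, WP, J), not improved.
* Precursor m/z uses the average molecular weight from the library record
  rather than the monoisotopic mass; at unit resolution with a 0.5 Th
  convolution tolerance this is adequate for screening but not for exact
  mass work.
* Single-batch correction only: the LOESS model handles intra-batch drift;
  inter-batch normalization and absolute quantification (isotope dilution)
  are out of scope.
* $Q^2Y \le R^2Y$ holds on common folds but the reported $R^2Y$ (final
  refit) and $Q^2Y$ (outer CV) are computed on different data partitions;
  pathological cases could order them otherwise.
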