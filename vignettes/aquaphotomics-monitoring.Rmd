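---
title: "Methods: NIR aquaphotomics and leakage statistics for shelf-life monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR aquaphotomics and leakage statistics for shelf-life monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the procedure left room for judgement.

## The monitoring problem

Ready-to-eat rocket salad is sealed under one of three atmospheres
(A: air, 21 % O2 / 78 % N2; B: 30 % O2 / 70 % N2; C: 10 % CO2 / 5 % O2 /
85 % N2), stored at 4 °C and sampled at days 0, 1, 4, 7, 11 and 13. Three
measurements track deterioration:

* **NIR reflectance spectra** through the sealed bag (900–1600 nm, 125
  points, 3 bags × 2 sides × 10 replicates = 60 spectra per treatment per
  checkpoint). The packaging contribution is removed by subtracting the
  mean of a set of empty-packaging spectra; spectra are converted to
  absorbance as `A = log10(1/R)`.
* **Electrolyte leakage**: the index of leaf damage
  `I_LD = 100 · IC / FC` compares the conductivity of a leaf-piece bath
  before (`IC`) and after (`FC`) a freeze–thaw cycle that releases all
  electrolytes. Intact membranes leak little, so `I_LD` rises as cells are
  damaged.
* **E-nose**: ten MOS sensors reporting the conductivity ratio G/G0 of
  sample gas over carrier gas.

## Water as the reporter: aquagrams

Within the first overtone of water (1300–1600 nm), twelve narrow
coordinate ranges (C1–C12, 6–20 nm wide) are consistently activated by
perturbations of the aqueous matrix. Each hosts a water absorbance band
(WAB) tied to a water species: free water (S0) at 1416 nm, water with 1–4
hydrogen bonds (S1–S4) at 1441/1466/1478/1490 nm, solvation shells at
1366/1385/1453 nm, strongly bound water at 1509 nm, and combination bands
at 1342/1373/1428 nm. The reference set is available as `default_wabs()`.

The aquagram chain (`aqua_prep` preset) is:

1. Savitzky–Golay second derivative, window 21 points, second-order
   polynomial — resolves the broad overlapped water bands;
2. multiplicative scatter correction against the mean spectrum — removes
   per-spectrum affine scatter;
3. truncation to 1300–1600 nm;
4. per-wavelength standardisation over all spectra,
   `z_λ = (A_λ − μ_λ) / σ_λ` (`aqua_normalize()`), which places every
   wavelength on a comparable scale. The returned statistics allow new
   spectra to be projected into the same space.

`compute_aquagram()` then averages `z` per group (treatment × day by
default) and reads it at the twelve WABs; `render_aquagram()` draws the
radar chart, C1 at the top proceeding clockwise, with one radial scale
shared across panels so patterns stay comparable.

### Sign convention

The package plots aquagram axes as the **negated** standardised
second-derivative value (`flip_sign = TRUE` by default). At the centre of
an absorbance band the second derivative is negative, and it grows *more*
negative as the band gains amplitude; without negation, "more free water"
would read as a *shrinking* free-water axis. With the flip, a prevalence
of free or weakly bonded water late in storage appears — as it should —
as a rise at 1416/1428 nm mirrored by a fall at 1490/1509 nm.
`flip_sign = FALSE` gives the raw standardised scale.

### Truncation position

The column statistics μ and σ are computed *after* truncation to
1300–1600 nm, so the standardisation is driven solely by the water first
overtone and is unaffected by edits elsewhere on the grid.

### WAB selection

`select_wabs()` re-derives the twelve bands from data: within each
coordinate range (default ±6 nm around the reference wavelength,
consistent with the 6–20 nm coordinate widths), candidates are ranked by
the magnitude of the group-mean standardised extremum and, when supplied,
by |PCA loading| and |PLS loading|; ranks are summed and the lowest total
wins, ties breaking to the lower wavelength. Rank summation is a
deliberate neutral choice: the selection criteria (spectral extremum,
loading impact) have no canonical relative weighting, and rank sums are
invariant to the criteria's scales. The selection is deterministic and
stable under duplication of the sample set.

### Interpolation

The 125-point instrument grid (≈5.6 nm spacing) does not contain the
reference wavelengths exactly, so WAB values are linearly interpolated
between flanking grid points; at a grid point interpolation is exact.
Linear interpolation was preferred to nearest-neighbour because the
standardised second-derivative spectrum varies smoothly on the grid scale
and nearest-neighbour would quantise trajectories.

## Pretreatment operators

All windowed operators trim edges rather than pad — padding would invent
data next to the 1300/1600 nm boundaries where the WABs live — and all
operators preserve sample metadata and row order.

| operator | parameters (defaults) | notes |
|---|---|---|
| `moving_average` | window 15 pts | boxcar; exact on constants and linear trends |
| `sg_derivative` | window 21 (aquagram) or 11 (PLS) pts, order 2, deriv 2 | least-squares polynomial filter; derivative scaled by the nm spacing (AU·nm⁻ᵈ) so outputs are comparable across grids; exact on polynomials up to the fit order |
| `norris_gap` | span 21 pts, deriv 1 | symmetric difference over the gap; exact on linear spectra |
| `snv` | — | row standardisation; affine-invariant |
| `msc` | reference = mean spectrum | OLS fit `x ≈ a·ref + b`, corrected `(x−b)/a`; slopes `a ≤ 0` are flagged |
| `aqua_normalize` | — | column standardisation; invertible via the returned statistics |

Two conventions required a decision because "gap size N points" is used
loosely across chemometrics software:

* For **Savitzky–Golay**, "gap size N" is read as the full window length
  N (odd), matching the phrasing "second-order polynomial fit and 21
  points".
* For the **Norris gap derivative**, "gap size N" is read as the total
  span N, i.e. g = (N−1)/2 points on each side; `gap_is_half = TRUE`
  supplies g directly for software that uses the one-sided convention.

The Savitzky–Golay convolution assumes a uniform wavelength grid and
refuses grids whose spacing varies by more than one part in 10⁶.

## Chemometrics

**PCA** (`fit_pca`) is the SVD of the column-centred matrix, with a
deterministic sign convention (the largest-magnitude loading element of
each component is positive). By default the exploratory PCA consumes
checkpoint-mean spectra: replicate spectra are averaged sides-within-bag,
bags-within-checkpoint (`checkpoint_means()`), so the staged means weight
bags equally under unbalanced replication.

**PLS** (`fit_pls`) is PLS1 by NIPALS, kept in-package so the
cross-validation scheme and error definitions are explicit: `r_cal` and
`r_cv` are Pearson correlations of fitted respectively held-out
predictions with the observations, and
`SECV = sqrt(Σ(ŷ_cv − y)² / (n − 1))` in the response units (percent
`I_LD`). Cross-validation defaults to leave-one-out for n ≤ 40 and ten
seeded random segments otherwise. The regression pairs bag-mean spectra
with bag-mean leakage (n = 54 in the default design) — the leakage assay
is destructive and bag-level is the finest unit on which the two
measurements coexist. `cross_validate()` tabulates `r_cv`/SECV per
component count and recommends the smallest count within one standard
error of the SECV minimum (one-SE parsimony rule).

At full rank PLS reproduces ordinary least squares; with a single latent
direction one component is exact. Both identities, and the equality of
PCA explained variances with covariance eigenvalues, are enforced in the
test suite against independent oracles (`eigen`, `lm`, and an external
NIPALS implementation).

## Group statistics

`anova_oneway()` is the classical one-way decomposition (via
`stats::aov`). Post-hoc tests:

* **Fisher LSD** (`lsd_test`): pair (i, j) significant iff
  `|m_i − m_j| > t(1−α/2, df_w) · sqrt(MSE (1/n_i + 1/n_j))`. For two
  groups this is exactly the pooled t-test.
* **Tukey HSD** (`tukey_hsd`): studentized-range critical differences
  (Tukey–Kramer under imbalance), with adjusted p-values from `ptukey`.

LSD is anti-conservative relative to Tukey — every Tukey-significant pair
is LSD-significant — which the suite checks as a property. E-nose sensors
are tested independently per treatment across days on bag means, with no
multiplicity correction across sensors (each sensor is reported on its
own, as sensor panels conventionally are). If every observation is
identical the ANOVA is reported as F = 0, p = 1 rather than as an error.

## The synthetic scenario

`spectral_scenario()` encodes the study conditions; its defaults are the
study design itself (3 × 6 × 3 × 2 × 10 spectra, 125-point grid, three
bags in triplicate for leakage and E-nose). The spectral model is a sum
of Gaussian bands in absorbance — the simplest shape that reproduces
broad overlapped NIR bands while keeping second derivatives analytic for
oracles — with three broad water bands (≈975, ≈1160, ≈1435 nm) and twelve
narrow bands at the reference WABs over a 0.15 AU baseline.

Deterioration is a latent damage score: logistic in storage day
(midpoint day 8, scale 2 days, asymptote 18), multiplied by a
per-treatment rate (A 1.0, B 0.7, C 1.4 — the CO2-enriched atmosphere
deteriorates fastest, the oxygen-enriched slowest). Band amplitudes drift
linearly in the damage score with a **conserved redistribution**: the
amplitude gained at 1416/1428 nm (free/weakly bonded water) equals the
amplitude lost at 1490/1509 nm (strongly bound water), echoing a species
shift rather than net water loss. The remaining eight bands carry smaller
drifts, positive on the weakly bonded low-wavelength side and negative on
the strongly bonded side. The magnitudes (0.0008–0.0025 AU per damage
unit) are synthetic conventions — no quantitative effect sizes exist for
this system — chosen once so that the drift is comparable to, not
drowned by, the scatter and noise levels below.

Measurement structure: per-spectrum affine scatter `a·x + b` with half
the variance shared at bag level (slope sd 0.015, offset sd 0.004 AU),
additive Gaussian noise (0.0015 AU), and emission in reflectance mode as
`R = 10^(−A)`. Leakage links linearly to the damage score
(`I_LD = 4 + 1 · damage + N(0, 0.6)` percent), giving trajectories flat
until about day 7 and rising thereafter; conductivity pairs are
back-solved from a fixed 1500 µS/cm final-conductivity scale so
`compute_ild(ic, fc)` reproduces the emitted index exactly. The E-nose
model drifts the three broad-range channels (W5S strongest, W1S, W2S)
multiplicatively with damage under lognormal noise and keeps the other
seven stationary. The `trial2` preset doubles the scatter variance (a
more heterogeneous raw material) and reverses the drift signs, producing
aquagrams of opposite orientation.

Every generator returns its ground truth (per-bag damage scores, realized
band amplitudes, scatter coefficients), so recovery claims in the tests
are checked against stored truth, never against the pipeline itself.

### What the generator does not emulate

Real leaf optics are not additive Gaussian bands: radiative transfer in
a stack of leaf layers produces specular and internal-scattering effects
that MSC only approximates, chlorophyll and dry-matter absorptions
overlap the water bands, and real water-species shifts need not conserve
total band area. Band positions do not shift in wavelength (real
perturbations can move a band, not only rescale it), replicates are
exchangeable rather than spatially structured, and E-nose cross-sensor
correlations are ignored. Passing the recovery tests therefore
demonstrates that the pipeline detects the structure it is designed for
at realistic noise levels — not that it would perform identically on any
real harvest.

Two systematic artefacts of the model are worth knowing. First, the
21-point second-derivative window spans ≈113 nm, so neighbouring band
drifts bleed into each other's coordinates; on the default scenario the
small drifts at C2/C3 are overridden by their larger neighbours and the
recovered trajectory signs agree with the generator truth at 10 of the
12 WABs — the four large-drift axes are always recovered. Second,
exploratory PCA on the checkpoint means concentrates ≈95 % of variance
on PC1 (the damage direction), with the remainder mostly scatter.

## Numerical and reproducibility choices

* All randomness flows from the scenario seed through `withr::with_seed`;
  generators derive fixed offsets (+1 leakage, +2 E-nose) so the three
  families are independent yet jointly reproducible.
* `run_all()` re-runs byte-identically for a given config; the manifest
  records a hash of the semantic config fields (output location
  excluded) and per-stage timings, which are the only varying entries.
* CSV emission prints 17 significant digits, enough to round-trip
  doubles exactly; `read_spectra`/`write_spectra` round trips are tested
  bit-wise.
* Degenerate inputs fail loudly and early: constant spectra in SNV, zero
  column spread in the standardisation (named wavelength), non-positive
  reflectance (named sample and wavelength), empty truncation ranges,
  coordinate ranges containing no grid point.

The test suite runs the full default scenario (1080 spectra × 125
wavelengths), 500 Monte-Carlo replicates for the type-I calibration of
the leakage ANOVA and 200 for LSD power, 20 random instances for the
PCA/eigen oracle and 10 for the ANOVA/permutation oracle — sizes at which
every check completes in seconds while leaving the Monte-Carlo error well
below the tolerances tested.

## Known limitations

* PLS1 only (a single response); multi-response PLS2 is out of scope.
* No variable selection (VIP, iPLS) or classification (PLS-DA).
* The Norris derivative supports first order only.
* Aquagram significance bands and temperature-perturbation aquaphotomics
  are not implemented.
* The E-nose module consumes ready sensor vectors; raw signal-over-time
  processing belongs to the instrument software.
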