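---
title: "Models and methods behind quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

## The measurement and its models

A steady-state fluorescence titration monitors the intrinsic Trp/Tyr
emission of a protein (here modelled on serum albumin at 1.5 μM, excitation
280 nm) while a ligand — the *quencher* — is added in steps, typically
0–27.5 μM. Three linearized models extract physical constants from the
resulting intensity series, and all three are ordinary least-squares line
fits after a transform:

**Inner filter correction.** At the absorbances typical of these
experiments, part of the exciting and emitted light is reabsorbed by the
sample. When per-point absorbances at the excitation and emission
wavelengths are available, `correct_inner_filter()` applies
$F_{cor} = F_{obs}\,e^{(A_{ex}+A_{em})/2}$ before any fitting. The
correction is the identity at zero absorbance, strictly increasing in each
absorbance, and opt-in per file (absorbance columns present), because
per-point absorbances are frequently not recorded. The geometry-dependent
refinements of this formula (cuvette path lengths, beam offsets) are out of
scope.

**Stern–Volmer.** $F_0/F = 1 + K_{sv}[Q]$. The slope of $F_0/F$ against
molar quencher concentration is $K_{sv}$ (M⁻¹), and
$k_q = K_{sv}/\tau_0$ is the bimolecular quenching constant, with
$\tau_0 = 10^{-8}$ s the customary unquenched-lifetime value for
biopolymers (overridable). We fit the intercept rather than forcing it to
1: a fitted intercept is what the reported Pearson correlations of such
tables reflect, and its deviation from 1 is itself diagnostic, so a
deviation beyond three standard errors raises a warning. Points with
$F \ge F_0$ (net enhancement) are retained in this fit and flagged, never
silently dropped.

**Mechanism classification.** Static (ground-state complex) and dynamic
(collisional) quenching are distinguished by two independent criteria:
$K_{sv}$ strictly decreasing with temperature votes static (the complex
dissociates on heating) and strictly increasing votes dynamic; and $k_q$
above the diffusion-limited ceiling of $2\times10^{10}$ M⁻¹s⁻¹ at every
temperature votes static, at or below it votes dynamic. Agreement (or a
single applicable criterion) gives the label; conflict gives `ambiguous`
with both outcomes recorded. The temperature trend uses strict monotonicity
of the point estimates with no significance test — the convention of the
field's tables, which report no uncertainty on the trend.

**Double-log binding fit.**
$\log_{10}\!\frac{F_0-F}{F} = \log_{10}K_b + n\,\log_{10}[Q]$, with $[Q]$
in mol/L so $K_b$ carries M⁻ⁿ. Base-10 logarithms are used here (matching
how binding constants are tabulated); the natural logarithm is reserved for
van't Hoff. Points with $F \ge F_0$ make the transform undefined; they are
excluded and counted, and fewer than three usable points is an error rather
than a degenerate fit. The standard error of $K_b$ is propagated from the
intercept by the delta method, $\sigma_{K_b} = K_b \ln(10)\,
\sigma_{intercept}$.

**van't Hoff.** $\ln K_b = -\Delta H^\circ/(RT) + \Delta S^\circ/R$ with
$R = 8.314$ J mol⁻¹ K⁻¹, assuming $\Delta H^\circ$ constant over the
narrow temperature range (the linear van't Hoff approximation; heat
capacity corrections are out of scope). $\Delta G^\circ = \Delta H^\circ -
T\Delta S^\circ$ is evaluated at caller-chosen temperatures — deliberately
caller-chosen, because published tables for this class of experiment are
not always internally consistent about whether the top temperature was 307
or 310 K, and the package records what was used instead of resolving such
conflicts. Units follow the tables: $\Delta H^\circ$ and $\Delta G^\circ$
in kJ/mol, $\Delta S^\circ$ in J/(mol K); the kJ/J mix is handled in
exactly one place (`gibbs()`).

**Force classification** follows Ross's sign rules: both $\Delta H^\circ$
and $\Delta S^\circ$ negative → van der Waals + hydrogen bonding; both
positive → hydrophobic; $\Delta H^\circ<0,\ \Delta S^\circ>0$ →
electrostatic. Driving force and spontaneity are evaluated at 298 K.

**Competition and site inference.** A fixed-concentration second ligand
turns the binary system ternary; `compare_systems()` reports the $K_b$
fold change, the $K_{sv}$ change, and the change in total quenching
percentage $100\,(F_0-F_{last})/F_0$. The characteristic displacement
signature — $K_{sv}$ rising while $K_b$ falls — is flagged explicitly, as
it indicates increased surface accessibility with displaced specific
binding. Site-marker inference computes the relative change
$|K_b^{marker}-K_b|/K_b$ per marker and assigns a Sudlow site only when
exactly one marker exceeds the threshold (default 0.30 relative change;
published judgments of "similar" vs "strongly influenced" are qualitative,
so the threshold is configurable). The marker→site map defaults to
phenylbutazone → Site I, ibuprofen → Site II and is user-extensible (no
standard marker exists for Site III).

## Spectral features

`find_peak()` refines the grid argmax with a three-point parabola, because
the shifts of interest (1 nm in synchronous Trp spectra) sit at the grid
resolution; ties go to the lowest wavelength, monotone spectra are flagged
`boundary`, flat ones `flat`. `peak_shift()` reports bound-minus-free shift
and direction (redshift = increased polarity of the fluorophore
microenvironment, blueshift = increased hydrophobicity) plus the peak
intensity change. `synchronous_spectrum()` samples an
excitation–emission matrix along $\lambda_{em}=\lambda_{ex}+\Delta\lambda$
with linear interpolation between emission grid points (Δλ = 15 nm probes
Tyr, 60 nm Trp; Δλ = 0 is the Rayleigh ridge). `eem_peaks()` labels every
grid cell within a tolerance (default two emission grid steps) of the
Rayleigh ($\lambda_{em}=\lambda_{ex}$) or second-order
($\lambda_{em}=2\lambda_{ex}$) ridge, then takes strict 8-neighbour local
maxima of the off-ridge surface; Peak I (Trp/Tyr) is the strongest maximum
with excitation in 260–300 nm and Peak II (polypeptide backbone) in
210–250 nm — windows we chose, since the peaks are conventionally named
but not delimited.

## The synthetic-data generator

`generate_titration()` produces series *consistent with the linearized
models above*, not with a mass-balance binding simulation: static data obey
$(F_0-F)/F = K_b^{app}[Q]^n$ exactly, dynamic data
$F_0/F = 1+K_{sv}(T)[Q]$ with $K_{sv}$ rising 1%/K above 298 K. This is a
deliberate choice: it makes zero-noise recovery tests exact inverses, so
any discrepancy is an implementation defect rather than model mismatch. The
cost is equally explicit — passing recovery tests demonstrates correctness
of the estimators, not their robustness to ligand depletion, saturation
curvature, photobleaching, or instrument drift, none of which the generator
emulates. Competition is modelled as classical competitive attenuation
$K_b^{app} = K_b/(1+K_c[C])$; noise is multiplicative Gaussian with a
given CV applied to every intensity including $F_0$ (a shot/gain-noise
approximation, default CV 0.01 ≈ a benchtop spectrofluorometer); the inner
filter effect is applied in reverse so correction recovers truth; and every
series is deterministic under its integer seed without disturbing the
caller's RNG stream. Defaults mirror a standard albumin experiment: 1.5 μM
protein, 11 concentrations linearly spanning 0–27.5 μM, $F_0 = 1000$.

## What the estimators can and cannot deliver

The suite measures parameter recovery at noise CV 1% on the 11-point grid
over 200 replicates (sizes chosen to estimate medians stably at desk
scale). Two structural facts about the double-log estimator are worth
stating because they bound what any user should expect from it:

- The intercept $\log_{10}K_b$ is an extrapolation. With $[Q]$ spanning
  2.75–27.5 μM, $\log_{10}[Q] \in [-5.56, -4.56]$, so the intercept at 0
  sits ~5 decades outside the data and its standard error is ≈4.8× the
  residual standard deviation. At 1% intensity noise the median relative
  error of $K_b$ is ~50% even though $K_{sv}$ (no extrapolation) recovers
  to ~2%. This matches the ±5% standard deviations typically printed for
  $K_b$ from far smoother real curves, and it is why the package reports
  `kb_sd` prominently.
- Weakly bound high-temperature series can be signal-starved: a
  $K_b$ of ~344 M⁻¹ gives a maximum quench of 0.94% over this
  concentration range, below a 1% noise floor, so van't Hoff parameters
  fitted through such a point carry very large variance and some replicates
  cannot be fitted at all (fewer than three points below $F_0$). The
  estimator is implemented exactly as specified; the remedy in practice is
  more concentrated titrations or replicate averaging, not a different
  line fit.

## Numerical and interface choices

- μM → mol/L conversion happens exactly once at fit time (factor 1e-6); the
  converted vector carries a unit attribute and converting twice is an
  error, so unit bugs fail loudly.
- The $[Q]=0$ row is mandatory and defines $F_0$; there is no other
  convention for the reference intensity.
- JSON reports are written at full precision with alphabetically stable key
  order: re-reading reproduces every value to better than 1e-9 relative and
  re-running identical inputs yields byte-identical files. The
  human-readable `summary_table()` uses 6 significant digits. (Full
  precision wins over pretty formatting in the machine-readable artifact;
  the two requirements conflict in a single file.)
- Pearson *r* is reported for every line fit (the tabulated convention),
  not $r^2$; it is `NA` for zero-variance input rather than a warning.
- Pipeline stages in `run_full_analysis()` are error-isolated: a failing
  stage is recorded by name and the partial report survives, since a single
  corrupt file should not void an afternoon of titrations.
- This package is used from R: the exported functions compose the full
  workflow, `scripts/acceptance.R` shows the scripted form, and no separate
  command-line binary is shipped.

## Known limitations

No Lehrer (modified Stern–Volmer) accessible-fraction analysis, no
Scatchard/Hill linearizations, no global nonlinear isotherm fit, no
ligand-depletion mass balance, no heat-capacity (curved) van't Hoff, no
time-resolved lifetime fitting, and no interpretation of shift directions
beyond polarity/hydrophobicity labels. Binding constants from the
double-log transform are *effective* constants whose units (M⁻ⁿ) depend on
the fitted stoichiometry; comparisons across systems assume $n \approx 1$.
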