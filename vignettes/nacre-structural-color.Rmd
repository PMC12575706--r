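---
title: "Modelling the structural color of nacreous layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the structural color of nacreous layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacreoptics)
```

## The physical problem

Nacre — the iridescent inner layer of many mollusk shells — is a
one-dimensional photonic stack: aragonite platelets of thickness
$d_1 \approx 140\text{–}300$ nm separated by thin interlamellar layers of
thickness $d_2$.  In living shells such as abalone the interlamellar layer
is an organic sheet ($d_2 \approx 11$ nm, $n_2 \approx 1.43$); in
gem-grade fossilized ammonite nacre (Ammolite) the organics are gone and
the plates are separated by **air nanogaps** of only $d_2 \approx 4$ nm.
Ammolite shows far more saturated reds, greens and blues than modern
shells, and this package implements the optical chain of reasoning that
explains why:

1. small gaps reflect weakly, so light penetrates deeply and many
   lamination planes contribute to the interference;
2. many contributing planes make the reflection band narrow;
3. a narrow band without a broadband ("white noise") background maps to a
   chromaticity far from the white point, i.e. a saturated color —
   provided the lamination period is homogeneous with depth so that every
   plane reinforces the same wavelength.

The package models this end to end: **structure → spectrum → color**.

## Models and solvers

### Stack generator

A `stack_spec()` is a stochastic recipe: plate and gap thicknesses are
drawn independently from truncated Gaussians (plates floored at 1 nm,
gaps at 0.5 nm), with the mean plate thickness either constant with depth
(Ammolite-like), drifting linearly (abalone / Madagascar-ammonite-like) or
following a custom per-period profile.  Defaults are chosen to represent
the measured microstructures: $d_1$ means of 190/160/140 nm for red/green/
blue Ammolite with SDs near 8–18 nm, $d_2 = 4 \pm 2$ nm air gaps
($11 \pm 3$ nm organic-filled for abalone), and 300 periods, which at a
$\approx 164$ nm period is the ~50 µm of homogeneous stacking associated
with brilliant color.  Mean-±-SD is all that is reported for the real
tissues; the Gaussian shape is an assumption (histograms of measured plate
thickness are unimodal), and any plate–gap covariance is unmeasured and
taken to be zero.  Note one consequence of the truncation floor: for gaps
at $4 \pm 2$ nm the 0.5 nm floor sits only 1.75σ below the mean, so the
realized mean gap is ~0.18 nm (4.5 %) above the nominal value — the exact
truncated-normal moments are what the generator tests check against.

Everything is seeded: the same `stack_spec` always produces the identical
stack, and sampling never disturbs the caller's RNG stream.

### Exact solver

`tmm_reflectance()` solves the stack exactly with the transfer-matrix
(characteristic-matrix) method: one 2×2 matrix per layer, admittances
$\eta = n\cos\theta$ (s) and $n/\cos\theta$ (p), unpolarized light as the
mean of the two intensities.  All media are lossless and dispersion-free;
aragonite is given the single effective index 1.63 (its birefringent
principal indices are 1.530/1.681/1.686, but the isotropic effective value
is the standard treatment for nacre and is what the analytic layer uses
too).  Energy conservation $R + T = 1$ holds to $10^{-8}$ and is tested.

For laterally uniform planar stacks this 1D coherent solver is physically
equivalent to grid-based electromagnetic simulation (the tool used for the
original figures this package's experiments mirror) while being exact and
fast — no spatial discretization, no numerical dispersion.  What it cannot
represent is anything laterally structured: tablet boundaries, roughness
scattering, 2D/3D disorder.  Disorder enters only through layer
thicknesses, and broadening is produced by that disorder, not by partial
coherence.

`ensemble_reflectance()` averages intensities over independent stack
realizations (realization *i* uses seed `seed + i - 1`), modelling
distinct lateral patches of nacre adding incoherently at the detector.
The default 100 realizations gives Monte-Carlo standard errors on the mean
spectrum that are small against every effect asserted in the tests; the
per-wavelength SE is attached to the returned spectrum.

### Analytic layer

The closed-form companions are the Bragg-Snell condition
$2d\sqrt{n^2-\sin^2\theta} = m\lambda$ with the effective-medium index
$n = \sqrt{n_1^2 \varphi_1 + n_2^2 \varphi_2}$ (volume-fraction-weighted
RMS over one period), and the Airy multiple-reflection reflectance of a
single gap of index $n_2$ between aragonite half-spaces,
$R = |r_{12}(1-e^{2i\beta})/(1-r_{12}^2 e^{2i\beta})|^2$.  For the 4 nm
air nanogap at 500 nm this gives $6.5\times10^{-4}$ — a fraction of a
percent per gap, the quantitative seed of the penetration-depth argument.
`effective_plane_count()` carries that argument as the heuristic
$N_\mathrm{eff} \propto 1/\sqrt{R_\mathrm{gap}}$ (the amplitude reflected
per plane is $\sqrt{R_\mathrm{gap}}$ and the band saturates once the
accumulated amplitude is of order one); it is used for qualitative
ordering only.  The corresponding bandwidth theory is realized
numerically: `fwhm_vs_planes()` measures the FWHM of exactly solved
stacks of increasing period count and shows the narrowing and its
saturation at the intrinsic stop-band width set by the index contrast.

```{r analytic}
# per-gap reflectance of the Ammolite nanogap, and the three band centers
single_gap_reflectance(4, n1 = 1.63, n2 = 1.00, lambda = 500)
sapply(c(red = 190, green = 160, blue = 140), function(d1)
  bragg_wavelength(d1 + 4, effective_index(d1, 4)))
```

The order selector `choose_order()` returns the smallest order landing in
380–780 nm: $m = 1$ for Ammolite-scale periods, $m = 2$ for the thicker
abalone periods.  Measured peak positions at oblique viewing are known to
sit somewhat red of the Bragg-Snell curve for real fossil nacre
(disorder-related); the package documents this and does not attempt to
reproduce it.

## Spectral summaries and colorimetry

`peak_stats()` reports the peak wavelength, the FWHM, the peak
reflectance and the off-band baseline (median reflectance outside
$\lambda_\mathrm{max} \pm 1.5\,\mathrm{FWHM}$, iterated once — the
baseline is this package's operational meaning of "white noise").
Numerical conventions that matter:

* FWHM spans the **outermost** half-maximum crossings (linear
  interpolation).  The envelope width stays meaningful for chirped-period
  stacks, whose bands are rippled plateaus with fringes dipping below half
  maximum inside the band; the peak-nearest crossing would collapse to a
  single fringe there.
* A band still above half maximum at a grid edge is clamped to the edge,
  so the reported FWHM is then a lower bound (this happens for the very
  broad 20 nm-gap ensembles).
* A peak rising less than `min_contrast = 0.03` above the baseline is not
  a resolvable band (`fwhm = NA`): a single-period stack, for instance,
  only modulates the surface reflection by ~2 %.
* A flat spectrum has no peak at all (`lambda_max = NA`).

`spectrum_to_chromaticity()` integrates reflectance × illuminant × the
CIE 1931 2° color-matching functions (embedded as the standard 5 nm
table, linearly interpolated).  The default illuminant is E (equal
energy) because the physical reference emulated is diffuse white light on
a white plate rather than daylight; D65 is available.  Saturation is the
Euclidean distance of $(x, y)$ from the white point of the same
illuminant **computed on the same grid**, so a flat spectrum has
saturation exactly zero by construction and no external white-point
constants are needed.  CIE excitation purity would be a defensible
alternative; plain white-point distance is kept as the simplest measure
matching how the chromaticity diagram is read.  Chromaticity is invariant
under positive scaling of a spectrum, and adding a flat background
strictly decreases saturation — the literal, testable form of the
white-noise desaturation argument.

## The experiments

```{r experiments, eval = FALSE}
run_d1_scan()          # hue vs plate thickness; disorder broadens bands
run_d2_scan()          # the nanogap sweet spot at d2 = 4 nm
run_homogeneity_scan() # period drift broadens bands
run_order_scan()       # m = 1 vs m = 2 regimes
run_angle_scan()       # iridescent blue shift
```

Study conditions follow the measured parameters: the plate-thickness scan
uses $d_1 \in \{137, 157, 194\}$ nm with SDs $\{18, 8, 15\}$ nm and a
fixed 4 nm air gap; the gap scan holds $d_1 = 150 \pm 15$ nm and scans
$d_2 \in \{1, 4, 11, 20\}$ nm for $n_2 = 1.00$ and $1.43$.  Both use
300-period stacks and 100-realization ensembles; unit tests exercise the
same code at smaller sizes, and the full-scale runs live in the
acceptance suite (the two scans take seconds to tens of seconds on one
core).  The gap scan reproduces the conclusion chain quantitatively:
shrinking the air gap from 4 nm to 1 nm starves the band (peak 0.77 →
0.17), widening it to 20 nm floods the spectrum with broadband baseline
(0.08 → 0.18), and saturation over $\{1, 4, 11, 20\}$ nm is maximized at
4 nm, while the organic-filled 11 nm gap reflects markedly less than the
air-filled one.

One directional claim did **not** survive contact with the exact solver
and is deliberately not asserted: that a drifting lamination period also
lowers saturation relative to the constant-period stack at matched mean.
The constant zero-disorder stack's band is so narrow (~8 nm FWHM) that,
sitting on the unavoidable ~5.7 % air/aragonite front-surface reflection,
it carries little in-band energy and lands *closer* to the white point
than the broadened drifting band.  Narrow-band-implies-saturated holds
when broadening comes with added white noise (as in the gap scan, and as
in the real samples, where inhomogeneous nacres are also noisy); it is
not a theorem for noise-free broadening against a fixed specular
baseline.  The FWHM broadening under drift, which is the structural
claim, holds monotonically in the drift rate and is asserted.

## What the synthetic data do and do not show

The generator emulates per-layer thickness statistics and depth profiles
of the lamination period — the features the microscopy of real nacres
quantifies.  It does not emulate lateral tablet structure, interface
roughness, absorption by residual organics, index dispersion, or the
instrument function of a real spectrometer.  Tests passing on these
synthetic stacks therefore validate the optical reasoning (structure →
band shape → chromaticity), not any claim about a particular specimen;
measured spectra of real material enter only as the printed band centers
(640/540/460 nm) that the Bragg-Snell layer matches within 3 %.

## Known limitations

* Lossless, dispersion-free media; no birefringence in the solver.
* 1D only: no lateral structure or roughness scattering.
* The FWHM of strongly truncated bands is a lower bound (edge clamping).
* The penetration-depth plane count is a heuristic ordering, not a
  quantitative bandwidth theory.
* Photograph-based colorimetry of real specimens involves an RGB→xy
  transform this package does not model; spectra-based chromaticities are
  comparable to it only qualitatively.
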