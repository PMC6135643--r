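---
title: "Methods: dynamic-ensemble XANES fitting and force-field refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic-ensemble XANES fitting and force-field refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmxan)
```

## The procedure

The dynamic analysis implemented here inverts the usual XANES fitting
logic.  A static fit varies structural parameters of a single geometry
until a computed spectrum matches experiment.  Here the structure is not a
fit parameter at all: a conformational ensemble — in a full study, MD
snapshots; here, Metropolis samples of a harmonic site model — determines
the theoretical spectrum as the plain arithmetic mean of per-snapshot
spectra,

$$\sigma^N(E) = \frac{1}{N}\sum_{k=1}^{N} y_k(E),$$

and the only quantities fitted against experiment are the four
inelastic-loss parameters.  Agreement is scored by the square residual

$$R_{sq} = \frac{n\sum_i w_i\left[(y_i^{th}-y_i^{exp})/\varepsilon_i\right]^2}{\sum_i w_i},$$

with $n$ the number of free parameters, $\varepsilon$ a constant
per-point experimental error and $w_i$ statistical weights (default 1).
During the dynamic fit $n = 4$, counting the four adjustable loss
parameters.  Structural information then enters through an outer loop:
bonded force-field parameters are perturbed, a fresh ensemble is sampled,
and perturbations that raise $R_{sq}$ are discarded (`refineLoop()`).
Two diagnostics support the comparison: the pointwise squared misfit
$f(E) = (y^{th}(E)-y^{exp}(E))^2$ with its cumulative trapezoidal
integral, and the ensemble-convergence residual
$R_f(N) = \lVert\sigma^N-\sigma^{N-1}\rVert_2$, which for i.i.d. frames
decays as $1/N$ (an identity, $R_f(N) = \lVert y_N -
\sigma^{N-1}\rVert_2/N$, that the test suite uses as a cross-check).

## Assumptions

* The experimental error is one positive constant over the whole curve,
  the usual convention for normalized edge spectra; `readSpectrum()`
  therefore collapses a per-point error column to its mean unless asked
  not to.
* All energy grids are relative to the absorption edge ($E_0 = 0$); the
  default analysis grid is 0–200 eV in 1 eV steps, matching the energy
  range over which such fits are typically performed.
* Per-snapshot spectra depend only on the geometry of the
  absorber-centered cluster (the nearest 100 atoms by convention; the
  reduced site model here has only 7 neighbors, so the cap never binds in
  the shipped examples).

## The forward model is a stand-in

Full multiple-scattering XANES engines (muffin-tin potentials, complex
optical potentials, extended-continuum bound states) are external programs
outside this package's scope.  `computeRawSpectrum()` implements a
deliberately simple surrogate: an arctan edge
$\mu_0(E) = \tfrac12 + \tfrac1\pi\arctan(E/\Gamma_0)$ modulated by
EXAFS-like single-scattering oscillations
$$\chi_j(E) = A\,\frac{Z_j}{Z_{Fe}}\,F_j\,
\frac{\sin(2kr_j + a + bk)}{k\,r_j^2}\,e^{-2r_j/\lambda},
\qquad k = 0.5123\sqrt{E}\ \mathrm{\AA}^{-1},$$
plus a forward-focusing factor
$F_j = 1 + g\,e^{-(\pi-\beta_j)^2/2w^2}$ for atoms shadowed by a
first-shell scatterer ($\beta_j$ the absorber–bridge–atom angle, e.g.
Fe–C–O, taken over the most collinear first-shell bridge; atoms within
2.5 Å count as first shell).  The design goal is structural, not
spectroscopic: all four refinable quantities — Fe–C, Fe–N(His), C–O and
the Fe–C–O angle — imprint measurably and monotonically on the output, so
the refinement problem retains its character.  The model is registered
under the key `"toy"`; a real engine can be slotted in through
`registerCalculator()` without touching any other stage.  Defaults
($\Gamma_0 = 2$ eV, $\lambda = 8$ Å, $A = 0.4$, $a = 0$, $b = -0.35$
rad Å, $g = 2$, $w = 0.3$ rad) are fixed and recorded in the output
metadata.

## Broadening and its fit

Inelastic losses are applied as a Lorentzian convolution whose FWHM
depends on the energy of the *source* point:
$$\Gamma(E) = \gamma_{core} + \gamma_{exp} +
A_s\left[\tfrac12 + \tfrac1\pi\arctan\!\frac{E-E_s}{\delta}\right].$$
The literature leaves the exact functional form of the plasmon switch-on
to the implementation; the smooth arctan step with fixed width
$\delta = 5$ eV is this package's documented choice — constant
core-hole-plus-experimental width below the onset, rising by $A_s$ above
it — and the form is pluggable.

Two numerical points deserve note.  First, the convolution treats the
input as zero outside its grid; spectra should therefore extend well past
the energy range of interest (the default 0–200 eV grid leaves ample
margin for widths of a few eV).  A source column whose width falls below
$10^{-9}$ eV degenerates to an identity (delta) kernel, so the all-zero
parameter limit returns the input exactly.  Second, $\gamma_{exp}$ and
$\gamma_{core}$ enter $\Gamma(E)$ only through their sum and are thus
exactly non-identifiable from data.  `fitNonstructural()` acknowledges
this: the Nelder–Mead simplex (maximum 500 iterations per start, relative
tolerance $10^{-6}$ on $R_{sq}$, one polishing restart, non-negativity by
reflection) searches over the three identified quantities (base width,
onset, amplitude) and apportions the fitted base width between the two
components in the ratio of the initial guess.  Reported per-component
widths therefore inherit the init's split; only their sum is a
measurement.

## What the synthetic generator emulates — and what it does not

`buildSiteModel()` places Fe at the origin, four pyrrole nitrogens fixed
in-plane at 2.00 Å (typical heme value; scenery, not a refined
parameter), the proximal-histidine nitrogen and the carbonyl C and O on
the axis at their equilibrium bond lengths.  `sampleEnsemble()` runs
Metropolis Monte Carlo in the Cartesian coordinates of the three movable
atoms (N_His, C, O) under
$U = \sum \tfrac12 k_b(r-r_0)^2 + \sum \tfrac12 k_\theta(\theta-\theta_0)^2$
at 300 K ($k_BT = 0.5962$ kcal/mol).  Cartesian sampling matters: it
carries the $r^2$ and $\sin\theta$ Jacobians automatically, which is why a
bending potential with its minimum at 180° yields a sampled mean near
173° with a spread near 3.5° for $k_\theta = 67.4$ kcal mol$^{-1}$
rad$^{-2}$ — the bending-angle deviation is Rayleigh-distributed, with
mean $s\sqrt{\pi/2}$ and standard deviation $s\sqrt{2-\pi/2}$ for
$s = \sqrt{k_BT/k_\theta}$.  The test suite checks the sampler against
these closed forms and against a Kolmogorov–Smirnov comparison with the
$r^2$-weighted Boltzmann bond marginal.

The published bending constants for this site are quoted without an
explicit statement of whether the $\tfrac12 k(\theta-\theta_0)^2$ or the
CHARMM-style $K(\theta-\theta_0)^2$ convention applies.  The half-$k$
convention is adopted here because it reproduces the ~3.5° spread above;
`halfK = FALSE` switches to the other convention (the sampler then uses
$2K$, and the topology exporter doubles constants on output, since
GROMACS uses the half-$k$ form).

Known omissions, hence what passing tests do *not* show about real data:
no solvent, no protein beyond the first shell, no electrostatics or
hydrogen bonding (distal-histidine tautomers enter only as geometric
ensemble differences), no constraint dynamics or thermostat physics, and
no physical clock — frames are stamped at a nominal 5 ps interval
(`frameDt`), the usual snapshot-collection spacing, so that time-windowed
analyses have a scale.  Bond force constants and partial charges are not
published for this reduced site; CHARMM-typical values (Fe–C 300,
Fe–N_His 270, C–O 1115 kcal mol$^{-1}$ Å$^{-2}$; N_His–Fe–C 50
kcal mol$^{-1}$ rad$^{-2}$) and a plausible charge set summing to the
declared −2 are used and clearly labeled as scenery.

`makeSyntheticExperiment()` chains sampler → toy spectra → average →
broadening → additive i.i.d. Gaussian noise of standard deviation
$\varepsilon$, and returns the generating truth alongside, enabling
closed-loop recovery tests.  The noise stream is seeded independently of
the sampler (offset by a fixed large prime) so the two sources of
randomness never alias.

## Numerical choices

* **Resampling** is linear interpolation, exact on piecewise-linear
  curves; extrapolation is refused with the offending energy named.
* **Cluster selection** sorts by Euclidean distance with ties broken by
  input atom order (a stable radix sort), so results are deterministic
  and permutation-invariant up to the documented tie rule.  Requesting
  more atoms than exist returns all atoms with a warning.
* **RdF** is reported as the raw per-frame distance histogram (default
  bins 0.02 Å up to 10 Å) plus the running coordination number, so peak
  positions read directly as bond lengths; no $4\pi r^2\rho$ volume
  normalization is applied, since shell positions — not densities — are
  the quantities of interest at these ranges.
* **Ensemble averaging** records $R_f(N)$ in stream order but computes
  the final mean with an order-invariant per-energy sorted summation, so
  shuffling frame order cannot change the average even at the level of
  floating-point non-associativity.
* **Windows** in `windowedRsq()` are contiguous, non-overlapping and
  left-aligned; a frame landing exactly on the final boundary joins the
  last window, so a window equal to the full duration yields exactly one
  window.  Discarding the first window (equilibration) is a flag.
* **Sampler tuning**: the maximum displacement auto-tunes toward ~40%
  acceptance during burn-in (checked every 200 steps, ×1.1 / ×0.9
  adjustments) and is then frozen; a post-tuning acceptance outside
  [0.2, 0.7] raises a warning.  All randomness flows through R's RNG, so
  a single seed makes runs bit-reproducible.
* **Refinement** is greedy coordinate descent: ±step candidates per
  refinable parameter (non-physical values skipped), the best strictly
  improving candidate accepted, all steps halved when none improves,
  stopping when every step falls below its floor (defaults: 0.05 Å
  initial, 0.005 Å floor for bond lengths; 50-round budget).  The
  published refinements were manual and iterative with unstated step
  sizes; these defaults are this package's automation choices, not
  claims about any particular study.  Common random numbers (one seed
  per round shared by baseline and candidates) remove most sampling
  noise from the accept/reject comparison and make the loop
  deterministic given the master seed.
* **Pipeline seeds** derive from the master seed and the stage name by a
  small modular hash, are recorded in the manifest, and stay below
  $2^{31}$.

## Problem sizes

The shipped tests exercise the pipeline at desk scale: ensembles of
60–400 frames (10$^6$ thinned samples for the angle-statistics checks,
where the sampler's C++ core makes 2×10$^6$ Metropolis steps a
sub-second operation), 201-point energy grids, 20-replicate
discrimination experiments and two-scenario refinement runs.  These sizes
were chosen so that every statistic tested sits comfortably above its
Monte-Carlo noise floor — e.g. 150-frame evaluation ensembles under
common random numbers resolve 0.005 Å bond-length steps — while the whole
suite remains quick to run.

## Known limitations

* The toy forward model is not a spectroscopic theory; absolute $R_{sq}$
  values against *real* experimental curves are meaningless until a real
  multiple-scattering calculator is registered.
* Only bond $r_0$, angle $k_\theta$ and angle $\theta_0$ are refinable;
  charges are deliberately excluded (they are derived quantum-chemically
  in practice, not by residual descent), and parameters are updated one
  at a time — no simultaneous multi-parameter line search.
* Error bars on refined parameters are not produced; the refinement
  trace records every evaluation, but uncertainty quantification is out
  of scope.
* Binary trajectory formats (XTC/TRR/DCD) are not read; multi-model PDB
  and multi-frame XYZ are the supported carriers, and periodic-boundary
  imaging is assumed done upstream.
* The $R_f$ convergence threshold depends on the cross-section
  normalization and is therefore a run-time input, not a constant.
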