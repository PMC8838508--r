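---
title: "Methods: correlated protein dynamics and label IR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated protein dynamics and label IR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protdyn)
```

# What the package computes

`protdyn` analyses how attaching a small vibrational probe — an azide
group on an alanine side chain is the motivating case — perturbs a
protein's internal dynamics, and how the probe reports on its
environment through its infrared band. Four statistics carry that
analysis, each implemented here from first principles:

1. **RMSD**: the per-frame least-squares deviation from a reference
   structure after optimal rigid-body (Kabsch) superposition.
2. **RMSF**: the per-residue fluctuation about the trajectory-mean
   position, after superposition onto the reference.
3. **DCCM**: the matrix of normalized displacement-vector covariances
   $C_{ij} = \langle \Delta\mathbf{r}_i \cdot \Delta\mathbf{r}_j\rangle
   / (\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle)^{1/2}$
   over Cα sites, its difference between modified and wild-type
   systems, and thresholded feature extraction from the difference map.
4. **IR spectrum**: the Fourier transform of the dipole autocorrelation
   function $C(t) = \langle \boldsymbol{\mu}(0)\cdot\boldsymbol{\mu}(t)
   \rangle$, Blackman-windowed and scaled by the harmonic quantum
   correction factor $\beta\hbar\omega/(1 - e^{-\beta\hbar\omega})$.

Because converged solvated-protein MD cannot run inside a test suite,
the package also ships *generators* whose outputs have closed-form
ground truth: a correlated Gaussian ensemble whose DCCM expectation is
an input matrix, a rigid-motion-plus-noise fixture for superposition,
and Langevin dynamics of the harmonic triatomic label whose spectrum is
predicted by its own normal-mode analysis. Every downstream stage is
validated against these.

# Conventions and parameters

## Units

Internally: Å, fs, amu, kcal/mol; $k_B = 0.0019872041$ kcal/mol/K. One
conversion constant ($4.184\times10^{-4}$ amu Å²/fs² per kcal/mol)
turns energies into integrator units, and one
($\tilde\nu = \omega / 2\pi c$) turns angular frequencies into
wavenumbers; both live in `pd_constants` and nowhere else. The quantum
correction uses $hc/k_B = 1.43878$ cm·K.

## The label force field

The azide label is three collinear point masses with CHARMM-convention
harmonic terms — $E = k(x - x_0)^2$ *without* the $\tfrac12$ factor, so
the published constants are used verbatim and the Newtonian spring
constant is $2k$:

| parameter | value | units |
|---|---|---|
| bond $r_e$ | 1.14 | Å |
| bond $k_b$ | 877.413 | kcal/mol/Å² |
| angle $\theta_e$ | 180 | degrees |
| angle $k_\theta$ | 46.706 | kcal/mol/rad² |

With three ¹⁴N masses this puts the asymmetric stretch at
2105.5 cm⁻¹ — squarely in the experimental azide window near
2100 cm⁻¹ — the symmetric stretch at 1215.6 cm⁻¹ ($\sqrt3$ lower,
exactly, for equal masses) and the doubly degenerate bend at
602.6 cm⁻¹. The linear equilibrium makes the usual
$1/\sin\theta$ angle-gradient singularity removable: the gradient code
substitutes the series limit of $(\theta - \pi)/\sin\theta$ when
$\sin\theta$ underflows, and the Hessian used for normal modes treats
the bend analytically as $2k_\theta\, \mathbf{g}\mathbf{g}^{\mathsf T}
\otimes P_\perp$ with $\mathbf{g} = (1/r_{12},\, -(1/r_{12}+1/r_{23}),\,
1/r_{23})$ and $P_\perp$ the projector perpendicular to the molecular
axis. A linear triatomic has exactly five zero modes (three
translations, two rotations), which the eigenvalue classifier reports
using a relative tolerance of $10^{-10}$.

Partial charges for the label have no published values at this level of
theory; the defaults $(0.2, -0.4, 0.2)\,e$ are arbitrary, neutral test
values chosen so the asymmetric stretch is IR-active (a symmetric
charge pattern makes the symmetric stretch dark, as for real azide).
They are not physical claims.

## Langevin dynamics

`simulate_triatomic()` uses the BAOAB splitting of velocity Verlet
(half kick, half drift, Ornstein–Uhlenbeck velocity refresh, half
drift, half kick), chosen for its excellent configurational sampling of
harmonic systems; at zero friction it reduces to plain symplectic
velocity Verlet, which is how the energy-conservation tests run. The
default friction, 10 ps⁻¹, is a common solvent-like thermostat rate;
the default timestep 0.25 fs resolves the fastest period (≈15.9 fs) by
a factor ~64, and a timestep above one tenth of that period is refused
up front rather than allowed to blow up silently. All randomness flows
through R's RNG from the `seed` argument, so the C++ engine and the
pure-R reference engine (`engine = "R"`) produce bit-identical
trajectories — one of the tests asserts exactly that.

## DCCM estimation

Displacements are taken about each site's mean over the *entire*
trajectory (single pass, no windowing). The correlated-ensemble
generator draws per-axis site displacements as $\mathbf{z} S$ with $S$
the symmetric square root of the target matrix $R$, independently for
x, y and z; that construction makes the DCCM expectation equal $R$
exactly, so recovery error is pure sampling noise and shrinks as
$n_{\text{frames}}^{-1/2}$ (a regression test asserts the −0.5 ± 0.1
log–log slope). Planted couplings are equicorrelated clusters over the
union of the two residue ranges: a cross-range coupling *without*
within-range coherence is not a valid correlation matrix once
$\rho\sqrt{n_1 n_2} > 1$, so the cluster form is both the physically
sensible and the mathematically consistent ground truth.

The difference map uses the convention **modified − WT** (stored in the
object), making coupling gained upon labelling positive. Thresholding
is *strict*: an entry exactly at the 0.25 cutoff is masked. The
documented analysis band for differences is $0.25 < |\Delta C_{ij}|
\le 0.75$; larger changes are not expected for this class of
modification. Feature blocks are 8-connected components of surviving
cells in the strict upper triangle (diagonally adjacent cells belong to
one visual feature), reported as bounding residue ranges with the sign
and magnitude of the extremal entry, sorted by magnitude.

## Superposition choices

RMSF fluctuations are measured about the trajectory mean *after*
superposing every frame onto the X-ray-style reference — the standard
two-step pipeline. RMSD and RMSF are Cα-only and mass-unweighted by
default (weights are available in `kabsch_fit()`). There is no
iterative core-finding: one fit per frame. The Kabsch implementation
enforces a proper rotation by sign-correcting the smallest singular
vector and refuses degenerate (collinear) configurations rather than
silently returning a non-unique rotation. `compute_rmsf()` and
`compute_dccm()` warn when a trajectory is not flagged as superposed:
rigid-body motion inflates fluctuations and masquerades as long-range
correlation.

## Spectroscopy choices

Several details of the dipole-ACF recipe are conventions the package
fixes explicitly:

- **Mean removal.** The static mean dipole is subtracted before the
  ACF; otherwise its square dominates every lag and buries the
  far-infrared region under a zero-frequency artifact.
- **Biased normalization.** Lag sums divide by $N$, not $N-\tau$: the
  estimator stays positive semi-definite and $|C(\tau)| \le C(0)$
  holds, at the price of a benign taper at long lags.
- **Window placement.** The "Blackman filter" is the classic 3-term
  window (0.42, 0.5, 0.08) applied to the one-sided ACF as a lag taper
  (1 at lag zero, 0 at the maximum lag), the conventional choice in
  MD-IR workflows. Default maximum lag is one quarter of the series,
  zero-padding ×4; both are exposed.
- **Intensity.** The real part of the transform times the quantum
  correction, nothing else — no extra $\omega^2$ prefactor, no
  per-spectrum normalization (a `normalize = "max"` option exists for
  display).
- **Peaks.** Band maxima are refined by 3-point parabolic
  interpolation; FWHM comes from linear interpolation of the
  half-maximum crossings, which makes a single-bin δ-like peak report
  exactly one grid spacing.

# What the generators do and do not establish

The synthetic ensembles reproduce the *statistical structure* the
estimators consume — prescribed correlations, isotropic noise,
thermalized harmonic motion — not protein physics. A green DCCM
recovery test establishes that the estimator converges to the planted
truth at the theoretical rate; it says nothing about conformational
sampling, solvent damping, or anharmonicity in a real trajectory.
Real data enter through the PDB/XYZ readers and are analysed by exactly
the same code paths.

One instructive case of real physics *inside* the toy model: at 300 K
the simulated label's stretch band peaks ~6 cm⁻¹ below the normal-mode
frequency with a ~38 cm⁻¹ width. That is not an estimator artifact but
the classical rotational band envelope plus centrifugal distortion of a
freely tumbling triatomic (rotational spread $\sim\sqrt{k_BT/I}$, in
wavenumber terms ≈14 cm⁻¹ at 300 K; in a protein the tethered label
cannot tumble freely). The cross-module consistency test therefore runs
where the harmonic 1-D oracle actually applies — 20 K, weak friction —
and recovers the normal-mode frequency within the grid resolution. The
velocity-Verlet discretization itself blue-shifts the peak by
$(\omega\Delta t)^2/24 \approx$ 0.9 cm⁻¹ at 0.25 fs, visible in the
zero-friction test and well inside its tolerance.

Numerical tolerances throughout follow the quantity's own statistics:
machine-precision checks for algebraic identities (thresholding, ΔDCCM
antisymmetry, FFT-vs-double-loop equivalence at $10^{-10}$–$10^{-12}$),
sampling-error bounds for Monte-Carlo quantities (e.g. max-norm DCCM
error ≤ 0.02 at $10^5$ frames), and resolution-limited bounds for
spectral positions (one grid bin, or 2 cm⁻¹ for the Langevin peak).

# Open choices made here

- **Config format** is JSON (via `jsonlite`) rather than TOML/YAML; no
  parser for the latter is a hard dependency of the stack, and JSON
  serializes every stage parameter losslessly.
- **Whole-trajectory RMSF** (no block averaging): the simplest
  statement of "fluctuation about the mean", and the one the other
  statistics (DCCM) already assume.
- **Cα-only RMSD/RMSF**: side-chain atoms add mass-weighting decisions
  without changing the comparisons the statistic serves.
- **DCD input is not implemented**: XYZ is the required text dialect
  (download-free, bit-exact in tests); the reader contract would admit
  a DCD backend unchanged.

# Known limitations

- The harmonic label has no electrostatic or van der Waals coupling to
  an environment; solvatochromic shifts of the azide band are out of
  scope.
- Feature extraction reports bounding boxes of connected components;
  two overlapping physical features merge into one block.
- The spectral estimator assumes a uniformly sampled, stationary
  series; trajectories with drifting means need detrending beyond the
  static mean removal.
- `read_pdb()` reads the first model only and drops altLoc ≠ ' '/'A'
  atoms by design (deterministic atom counts), so multi-model NMR
  ensembles must be split upstream.
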