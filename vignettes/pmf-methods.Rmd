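---
title: "Potentials of mean force from targeted MD and umbrella sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potentials of mean force from targeted MD and umbrella sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pmfpath)
```

## The problem

A potential of mean force (PMF) is the free energy of a system as a function
of a chosen reaction coordinate,

$$ W(\xi) \;=\; -k_BT \,\ln P(\xi) + \text{const}, $$

where $P(\xi)$ is the equilibrium probability density of the coordinate.
Direct simulation cannot estimate $P$ where barriers make visits rare, so the
standard remedy is *umbrella sampling*: a set of biased simulations
("windows"), each restrained near a center $r_{i0}$ by a harmonic potential

$$ V_i(r) \;=\; \tfrac12\,k_2\,(r - r_{i0})^2 , $$

whose overlapping biased histograms are recombined into one unbiased profile
by the weighted histogram analysis method (WHAM).

The practical difficulty that this package addresses is *where the window
starting structures come from*. Its answer is targeted molecular dynamics
(TMD): an ordinary simulation with an extra restraint

$$ E_{\mathrm{TMD}}(t) \;=\; \tfrac12\,k_1\,N\,
   \bigl[\mathrm{RMSD}(t) - \mathrm{RMSD}_0(t)\bigr]^2 , $$

where $\mathrm{RMSD}(t)$ is the mass-weighted RMSD of the $N$ restrained
atoms to a target structure (after optimal rigid-body superposition) and the
setpoint $\mathrm{RMSD}_0(t)$ ramps linearly from its initial value to zero.
One TMD trajectory traces a continuous path from a start conformation to a
target conformation; snapshots whose coordinate value lies nearest each
window center become the umbrella starting structures. `k1` is a per-atom
force constant: the total restraint stiffness scales with the restrained
atom count, matching the convention of the MD engines that popularised the
method.

The package implements this TMD → window selection → umbrella sampling →
WHAM chain end to end for three kinds of coordinates — torsion (dihedral)
angles, mass-weighted RMSD, and radius of gyration — together with the
trajectory-analysis operators used to characterise conformational
transitions (dynamical cross-correlation maps, hydrogen-bond occupancies,
interhelical angles, mass-center distances).

## The simulation engine

Sampling is generated by a compiled BAOAB-splitting Langevin integrator over
a minimal class-I force field (harmonic bonds `E = kb (r - r0)^2`, harmonic
angles, torsion Fourier series `(V_n/2)[1 + cos(n phi - gamma)]`,
Lennard-Jones and Coulomb terms with 1-2/1-3 exclusions and scaled 1-4
pairs, plus analytic one-body "external" terms for the toy systems). Units
are Angstrom, kcal/mol, amu, ps and kelvin throughout; angles cross the user
interface in degrees.

Key numerical choices:

* **Integrator.** BAOAB splitting with a default timestep of 1 fs and
  friction 1 ps⁻¹. With friction 0 and no thermostat noise it reduces to
  velocity Verlet, which the tests exploit to verify energy conservation
  (drift < 10⁻³ kcal/mol over 10 ps for butane at 0.5 fs).
* **Randomness.** A Mersenne-Twister (64-bit) stream with hand-rolled
  Box–Muller normals, seeded per run. The C++ standard's
  `normal_distribution` is implementation-defined, so normals are generated
  explicitly to make trajectories bitwise reproducible across platforms.
  Every pipeline stage derives its seed from the configuration's base seed
  (TMD runs by section index, umbrella runs by window index), and every
  artifact file records the seed and a configuration hash in its header.
* **Superposition.** Optimal weighted rigid-body superposition uses the
  Kabsch construction (SVD of the weighted covariance with a determinant
  guard against reflections); weights default to atomic masses, giving the
  mass-weighted RMSD. The RMSD gradient is evaluated at the optimal
  superposition, where the rotation's own derivative terms vanish; exactly
  at RMSD = 0 the gradient is undefined and is returned as a flagged zero
  matrix (the harmonic bias force vanishes there anyway).
* **Dihedral convention.** Values are reported in degrees on
  $[-180°, 180°)$ with $-180° \equiv 180°$; umbrella deviations use the
  minimum image, and angular force constants are interpreted per rad², so
  `k2 = 33 kcal/(mol rad^2)` pairs naturally with centers given in degrees.

## The butane fixture

The worked example is the rotational free-energy profile of butane about its
central C–C bond. The fixture is a united-atom model: four carbon sites
(CH3/CH2 masses), bonds `kb = 310 kcal/(mol A^2)`, `r0 = 1.526 A`, angles
`ka = 63 kcal/(mol rad^2)`, `theta0 = 112.4°`, no charges and no
Lennard-Jones interactions, and a three-term torsion Fourier series with
$V_n/2 = (0.889150,\, 0.259672,\, 1.860850)$ kcal/mol for $n = 1, 2, 3$.
The coefficients were fitted once so the vacuum torsional profile has its
gauche minima at 0.90, its intermediate tops at 3.78 and its syn barrier at
5.50 kcal/mol relative to anti (minima near ±64°, tops near ±119°); with no
nonbonded terms the exact free-energy profile along the torsion *is* this
curve, up to a constant, which makes the fixture its own analytic reference.

Because an RMSD restraint cannot tell apart conformations related by a full
360° turn, the rotation is driven in three overlapping arcs
(−180°→0°, −60°→90°, 60°→180°), with per-atom TMD force constants 90, 110
and 65 kcal/(mol Å²) and a 1 ns ramp each.

Two umbrella routes are implemented:

* **Dihedral route.** 19 windows at 20° spacing (10 + 4 + 5 across the three
  arcs; the −180° and +180° centers are physically equivalent restraints
  contributing two independent windows at anti), `k2 = 33 kcal/(mol rad^2)`,
  500 ps of Langevin sampling per window at 300 K, periodic WHAM on 2° bins.
* **RMSD route.** Windows along the RMSD-to-target coordinate of each arc
  (8, 5 and 7 windows at 0.1 Å spacing starting from each arc's initial
  RMSD, force constants ramped linearly across 50–90, 80–160 and
  50–90 kcal/(mol Å²), stiffer toward small RMSD where the coordinate
  bunches up), non-periodic WHAM per segment, an RMSD→dihedral calibration
  from each TMD trajectory, and a stitch of the three mapped segments.

## WHAM

The solver iterates the standard two self-consistent equations,

$$ P(x_b) = \frac{\sum_i n_i(x_b)}
  {\sum_i N_i \exp[(F_i - V_i(x_b))/k_BT]},
  \qquad
  F_i = -k_BT \ln \sum_b P(x_b)\, \exp[-V_i(x_b)/k_BT], $$

until the window free-energy constants move by less than 10⁻⁶ kcal/mol
(at most 10⁵ iterations), then reports $-k_BT \ln P$ referenced to its
minimum (`min_zero`; an `endpoint_zero` convention is available, and for the
butane profile the two coincide because anti is the global minimum). Windows
are sorted by center before solving; unvisited bins are reported as `NA`;
windows whose histograms share no visited bin raise a disconnected-support
error rather than returning a profile glued across a gap.

The solver is validated against an analytic oracle: a single particle on the
1-D potential $U(x) = 2.0\,[1+\cos 3x]$ kcal/mol, sampled with the same
19-window/20°-spacing/33 kcal mol⁻¹ rad⁻²/500 ps design as butane, must
recover $U$ with an RMS error of at most 0.15 kcal/mol. The toy particle's
mass (0.05 amu) is a numerical choice, not a physical one: it puts the
coordinate's autocorrelation time near 0.2 ps so that a 500 ps window holds
thousands of effectively independent samples and the oracle bound is
statistically meaningful. Two further identities pin the solver down: with
zero bias it reduces exactly to $-k_BT\ln(\text{histogram})$ on the same
counts, and a single harmonic window on a flat landscape unbiases to a flat
profile within binomial noise.

## RMSD→dihedral calibration and stitching

Along one TMD arc the RMSD to the target and the driven dihedral move
together monotonically, so each RMSD value corresponds to one dihedral
value. The calibration is built from per-time-bin medians of the TMD
trajectory (50 bins by default) rather than raw frames: time averaging
suppresses the thermal vibration noise of the instantaneous RMSD, and
medians resist contamination by brief excursions onto the mirror dihedral
branch, which an RMSD restraint cannot distinguish and which are therefore
filtered out by an arc window (±15° beyond the driven range) before
binning. A monotonicity check (30° excursion tolerance) rejects folded
relations, e.g. a trajectory driven through its target.

Segment PMFs are mapped onto the dihedral axis by pure relabeling through
the calibration (no Jacobian correction — the mapped profile remains the
free energy *along the RMSD coordinate*, displayed against the dihedral,
which is also why the two routes legitimately disagree at the
kcal/mol level). Bins outside the calibrated range or holding fewer than a
minimum number of samples (25 in the pipeline) are dropped first; sparsely
visited tail bins otherwise contribute large histogram noise. Stitching
aligns each segment to the running merge by a least-squares constant offset
over the overlap, averages overlapping bins, and smooths the seam bins with
a centered 3-point moving average; the result is referenced to `min_zero`.

## Window diagnostics

`diagnose_histograms()` operationalises the visual sufficiency checks
applied to per-window histograms — smooth, no major shift, no bare patch —
with three configurable flags: *rough* when the residual between a histogram
and its 3-point moving average exceeds 25 % of the peak over the core
(bins above 20 % of the peak), *shifted* when a window's sampled mean sits
more than three quarters of a window spacing from its center (windows on
steep free-energy slopes shift by an appreciable fraction of the spacing
even when healthy), and *gap* when any bin strictly between the extreme
window means collects no counts at all. `choose_k2()` applies the same
machinery to candidate restraint strengths and returns the smallest
candidate whose test-window distributions are unimodal and centered.

## What the fixture shows — and what it cannot

The dihedral-route pipeline at its default budget (3 × 1 ns TMD,
19 × 500 ps windows; about half a minute of computation) reproduces the
fixture's stationary values to well within statistical noise, and the
three-maxima/two-minima structure of the rotational profile. The RMSD-route
segments reproduce their own tops at −120° and +120° in agreement with the
dihedral route.

The stitched RMSD-route profile, however, systematically underestimates the
syn barrier. This is a real property of the united-atom fixture, not of the
solver: near syn the rigid-geometry RMSD-to-target changes by only
~0.1 Å across 60° of rotation, so at the "syn radius" the equilibrium
ensemble is dominated by gauche conformers stretched vibrationally by
~0.1 Å — a path that costs 2–3 kcal/mol instead of the 5.5 kcal/mol
torsional barrier. An all-atom geometry separates the gauche and syn radii
about twice as far and suppresses this bypass, which is why the RMSD
coordinate works better there. The package reports what its model actually
computes; the discrepancy is documented rather than patched, and it is a
useful caution about RMSD as a reaction coordinate for soft systems.

The synthetic trajectories used by the analysis operators (correlated and
anti-correlated sinusoids, geometric hydrogen-bond constructions, ideal
helical point sets) verify counting identities and closed forms. Passing
them shows the operators are implemented correctly; it says nothing about
sampling adequacy on a real protein, where correlation maps and occupancies
converge slowly and depend on equilibration that desk-scale runs cannot
provide. The interhelical angle is computed from dominant mass-weighted
principal axes (oriented first-to-last atom); it agrees with dedicated
helix-geometry programs on ideal helices but can differ on kinked ones.

## Known limitations

* Vacuum Langevin dynamics on a united-atom model stands in for solvated
  all-atom simulation; absolute barrier heights inherit that approximation.
* 1-D WHAM only; no MBAR, no 2-D coordinates, no bootstrap error bars.
* The RMSD coordinate degenerates where its mapping to the driven angle
  flattens (see above); the calibration errors out on genuinely folded
  relations instead of guessing a branch.
* No constraints (SHAKE), barostats, or particle-mesh electrostatics; the
  nonbonded loop is a plain pair sum suitable for small systems.
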