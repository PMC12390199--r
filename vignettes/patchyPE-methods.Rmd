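---
title: "Critical adsorption of a polyelectrolyte onto a patchy dielectric sphere: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical adsorption of a polyelectrolyte onto a patchy dielectric sphere: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

A flexible polyelectrolyte (PE) near an oppositely charged surface
undergoes a sharp adsorption–desorption transition: screened electrostatic
attraction competes with the translational and conformational entropy the
chain loses on binding.  For PE–protein complexation two further features
matter: proteins are *patchy* (their surface carries regions of both
signs, so a PE can complex with a protein of like net charge — binding on
the "wrong side" of the isoelectric point), and the protein interior is a
*low-dielectric* medium, so every external charge induces polarization
(image) charges at the dielectric boundary.

`patchyPE` simulates the minimal model that contains all three
ingredients: a bead–spring PE in screened (Debye–Hückel) electrolyte
around a rigid sphere with an axisymmetric two-cap surface-charge pattern
and an arbitrary interior permittivity, and locates the critical
adsorption–desorption boundaries — the critical charge density of the
attractive cap, $\sigma_{n,c}$, and the critical screening, $\kappa_c a$ —
from the sampled adsorbed fraction.

## Model

**Units.**  All internal quantities use Ångström / $k_BT$ / $e_0$; SI
inputs (C/m², N/m, mol/L) are converted once at the boundary.  In these
units the Bjerrum length $l_B = e_0^2/(4\pi\epsilon_0\epsilon_w k_BT)
\approx 7.12$ Å (water, 298.15 K) makes every energy expression
dimensionless, and $\kappa = \sqrt{8\pi l_B n_0}$ for a 1:1 salt of
ion-pair density $n_0$.  The anchor that pins the whole constant set:
5 mM salt with a 70 Å sphere gives $\kappa a = 1.625$.

**Particle.**  The surface charge density is the smoothed two-cap profile
$$\sigma(\theta) = \tfrac{\sigma_p}{2}\bigl[1-\tanh n(\theta-\theta_p)\bigr]
 - \tfrac{\sigma_n}{2}\bigl[1+\tanh n(\theta-\theta_n)\bigr],$$
i.e. a positive cap ($\theta<\theta_p$, density $\sigma_p$), a negative
cap ($\theta>\theta_n$, density $-\sigma_n$) and an optionally neutral
belt.  The abruptness $n = 20$ per radian gives a transition width of
about 0.1 rad — sharp on the particle scale but smooth enough for the
eigenfunction expansion to converge; the cap integrals are insensitive to
further increases of $n$.

**Electrostatics.**  Outside the sphere the dimensionless potential is the
multipole series
$$\Psi_\sigma(r,\theta) = \sum_{l=0}^{l_{max}} C_l\,k_l(\kappa r)
  P_l(\cos\theta), \qquad
C_l = \frac{2\pi l_B \epsilon_w (2l+1)\,a\,I_l}
           {\epsilon_{part}\,l\,k_l(\kappa a)-\epsilon_w\,\kappa a\,
            k_l'(\kappa a)},$$
with $I_l = \int_0^\pi \tilde\sigma(\theta)P_l(\cos\theta)\sin\theta\,
d\theta$ and $k_l$, $i_l$ the modified spherical Bessel functions.  Two
conventions had to be fixed once: $k_0(x) = e^{-x}/x$ (no $\pi/2$ factor),
and the overall prefactor expressed through $l_B$.  Both are pinned by the
requirement that a uniformly charged sphere reproduce the closed-form
screened-sphere potential $l_B Z e^{-\kappa(r-a)}/[r(1+\kappa a)]$ — the
package asserts this to $10^{-8}$ relative for any interior permittivity
(the monopole term is $\epsilon_{part}$-independent).

The polarization (image-charge) response of the interior is the
reaction-field series
$$\Psi_{j,polar}(\mathbf r) = \sum_l R_l\,k_l(\kappa r_j)\,k_l(\kappa r)\,
P_l(\cos\gamma_{rj}), \qquad
R_l = l_B\kappa\,(2l+1)\,
\frac{\epsilon_w \kappa a\,i_l'(\kappa a)-\epsilon_{part}\,l\,i_l(\kappa a)}
     {\epsilon_{part}\,l\,k_l(\kappa a)-\epsilon_w\,\kappa a\,k_l'(\kappa a)}.$$
We re-derived these coefficients independently by solving the
boundary-value problem (interior Laplace solution, exterior screened
multipoles, continuity of $\phi$ and $\epsilon\,\partial_r\phi$) with the
screened-Coulomb addition theorem; the result is identical.  Note that
$R_l \neq 0$ even at $\epsilon_{part}=\epsilon_w$: the ion-free interior
excludes the screening cloud.  The solvent-matched baseline is therefore
run with the polarization terms switched off entirely
(`image_charges = FALSE`), which is the package's default.

**Energies.**  Beads are monovalent hard spheres of radius $b = 2$ Å
joined by bonds $u(r) = k(r-r_0)^2$ ($k = 0.5$ N/m $\approx 1.215\,
k_BT/$Å$^2$, $r_0 = 7$ Å; note there is no factor $\tfrac12$).  All bead
pairs — bonded neighbours included — interact through the screened Coulomb
potential $l_B e^{-\kappa r}/r$ with a hard core at $r \le 2b = 4$ Å, which
automatically generates the electrostatic persistence length.  The
bead–particle energy per bead is
$\Psi_\sigma + \tfrac12\Psi_{self} + \sum_{i\neq k}\Psi_{i,polar}$; the
configuration total counts each cross-polarization pair **once**
(consistent with $U = \tfrac12\sum_j q_j\Psi_{polar}$ for linear
response), while the per-bead form — which counts a moved bead's pair
terms fully — is the correct single-bead move increment.  A literal
per-bead summation (each pair twice) is available as
`cross_counting = "literal"` for comparison.  Hard constraints (bead–bead,
bead–particle at $r < a+b$, spherical box wall at $r > R_{box}-b$) are
enforced by move rejection, which is Metropolis-exact.

## Monte Carlo engine

Moves are chosen uniformly among pivot and crankshaft rotations
(bond-preserving), single-bead displacements, and whole-chain translations
and rotations; a run equilibrates (default $10^6$ moves) with per-kind
amplitudes tuned multiplicatively toward ~50% acceptance, then freezes the
amplitudes and records samples every $10^3$ moves (configurable).  The
whole-chain translation keeps a large amplitude floor (box/8) so it can
carry the chain between the adsorbed and desorbed basins; it is the only
move that crosses that barrier efficiently.  Incremental energies exploit
move structure (rigid rotations preserve intra-segment pair distances;
whole-chain translations leave all pair terms unchanged), and a full
recomputation every $2^{20}$ moves cancels round-off drift — the
incremental total is verified to track the from-scratch total to better
than $10^{-6}\,k_BT$ over full runs.  The engine uses its own PCG32
generator, so runs are bit-reproducible from the protocol seed and
independent of R's RNG state.

## Observables and the critical-boundary estimator

Each sample records the binding energy $E_B$ (the PE–particle part of the
energy), the squared radius of gyration, and the minimum bead–surface
distance.  A sample is *adsorbed* when $E_B < -1\,k_BT$: the two basins
are separated by a wide gap ($E_B \approx 0$ desorbed vs. $\lesssim -10\,
k_BT$ adsorbed), so the threshold choice is uncritical; a distance-based
classifier (minimum gap < 10 Å) is provided for sensitivity checks.
Statistical errors use 10-block averaging.

A critical scan runs one simulation per grid value of the control
variable ($\sigma_n$, or $\kappa a$ adjusted through the salt
concentration), expands the grid geometrically until adsorbed fractions
below 0.25 and above 0.75 are bracketed, and fits
$$f_{ads}(x) = \frac{1}{1+e^{\alpha(x-x_{1/2})}},$$
whose midpoint $x_{1/2}$ — where adsorbed and desorbed states are equally
populated — is the critical value.  The Pearson correlation between
observed and fitted fractions is reported and flagged below 0.9;
uncertainties come from a parametric bootstrap over per-point binomial
errors.  Per-point seeds derive from the master seed by counter and are
logged with the results.

## Validation oracles

Independent code paths gate the implementation: the closed-form screened
sphere potential (uniform limit); adaptive-quadrature recomputation of the
cap integrals; $l_{max}\,10\to20$ truncation sensitivity (< 1% near the
surface); incremental-vs-scratch energy consistency; and deterministic
Boltzmann quadrature for one- and two-bead chains (2-D and 5-D
tensor-product Gauss–Legendre with node-doubling convergence checks),
which must agree with MC runs within three block errors.  The oracle path
evaluates its Bessel functions through half-integer-order `besselK`/
`besselI` and a different derivative recurrence than the engine's upward
recursions.  `refinement_suite()` runs the whole gate.

## Numerical choices

* Cap integrals: Gauss–Legendre in $\cos\theta$, 1024 nodes, with an
  error raised if doubling changes any integral by more than $10^{-8}$
  relative (profiles with the transition at a pole need the finer grid;
  the default covers them).
* Bessel evaluation in the engine: stable upward recursion for $k_l$ from
  $k_0 = e^{-x}/x$; the setup-time $i_l$ values come from scaled
  `besselI` to avoid the unstable upward recursion.
* Zero salt is rejected for potential evaluation (the screened series is
  ill-defined at $\kappa = 0$); the practical floor is $10^{-4}$ mM.
* Degenerate proposals (zero amplitude, $2\pi$ rotations) reduce to
  identities and are covered by tests.
* Sigmoid fitting of near-step data: a strongly first-order transition can
  yield adsorbed fractions of exactly 0 and 1 on the whole grid, which
  makes the least-squares problem singular.  The fitter retries with
  progressively steeper starting slopes and, as a last resort, returns the
  linearly interpolated crossing of $\tfrac12$ with steepness set by the
  grid spacing — the midpoint, which is the quantity of interest, is then
  determined to grid resolution.
* The $l_{max} = 10$ model is truncation-defined at bead–surface
  contact: from $l_{max}$ 10 to 20, $\Psi_\sigma$ at the cap poles
  changes by a few percent (more in the ring near the patch boundary,
  which $l \le 10$ cannot resolve), and the polarization self term — the
  image of a charge 4 Å under a 70 Å sphere — by ~30%.  Both series are
  converged below 1% about one patch-resolution length (~25 Å) off the
  surface.  The truncation is part of the reference model, and the
  refinement suite reports the measured sensitivity rather than hiding
  it.

## Design decisions on genuinely open points

* **Box radius.**  Only "large enough" is prescribed by the problem; the
  desorbed-state entropy, and hence the critical values, depend weakly
  (logarithmically) on it.  Default: $a + N r_0 + 100$ Å = 520 Å for the
  standard system, logged with every run.
* **Equilibration.**  A fixed move budget (default $10^6$) rather than an
  adaptive criterion, for reproducibility; an energy-drift check is
  available but off by default.
* **Cross-polarization counting.**  Once per pair in totals (see above);
  the literal double-counted mode is provided because the per-bead
  definition sums to it.
* **Translations in production.**  Enabled, amplitude-tuned but floored,
  since basin exchange otherwise stalls.
* **Preset naming.**  Reference parameter bundles are named by their
  physical content (e.g. `coexistence_high_salt`, `density_eps4_theta90`,
  `uniform_sphere`).

## What the desk-scale defaults do and do not show

The package defaults ($10^4$ samples at $10^3$-move spacing; the test
suite uses still shorter runs) resolve the location of the
adsorption–desorption boundary to a few percent and the adsorbed-basin
energy band well, because the transition is strongly first-order-like:
individual runs sit almost entirely in one basin and the boundary is
where the preferred basin flips.  They do **not** resolve coexistence
dynamics: near-critical runs rarely hop between basins, so adsorbed
fractions near $\tfrac12$ are trapping-dominated and the fitted midpoint
carries a grid-resolution uncertainty.  Full-fidelity statistics
($10^7$ samples, `fidelity = "full"` in `make_preset()`) are needed for
quantitative coexistence traces.  Two consequences observed with the desk
protocol, both documented in the tests: the apparent $\kappa_c$ of a
strongly adsorbed state drifts above the equilibrium boundary (desorption
events are rare), and free-energy-level comparisons between two variants
of the Hamiltonian (e.g. with and without the dielectric interface) are
only trustworthy where their adsorbed-basin energies differ clearly.

On the last point: with the full Hamiltonian the dielectric interface
*strengthens* adsorption onto large patches at moderate screening (the
low-$\epsilon_{part}$ denominator amplifies the $l\ge1$ multipoles of the
attractive cap) but *weakens* it at strong screening and fixed cap charge,
where the $O(N^2)$ mutual image repulsion of the compact adsorbed chain
outweighs the $O(N)$ direct enhancement.  The single-bead form of the
crossover — repulsive image effect on a homogeneous sphere, attractive
net effect on a 120° patchy particle — is exact and is asserted by
quadrature in the test suite.

## Simulation sizes used by the automated checks

The test suite and the acceptance script use, per state point,
$4\times10^5$–$10^6$ equilibration moves and $3\times10^3$–$10^5$ samples
at 100-move spacing, with 4–6-point scan grids; these sizes resolve the
boundary positions to well within the tolerances asserted while keeping
the whole suite in the tens of minutes on one core.

## Known limitations

Linear (Debye–Hückel) electrostatics overestimates binding at high
surface potentials; no explicit ions, charge regulation, or non-
electrostatic chain stiffness; axisymmetric charge patterns only; no
interior-potential evaluation.  These mirror the model's scope, not
implementation shortcuts.
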