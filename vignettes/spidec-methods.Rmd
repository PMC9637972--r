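---
title: "Computing binodals and interfacial tension from spinodal decomposition"
author: "spidec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing binodals and interfacial tension from spinodal decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidec)
```

## The method

A phase-separating fluid quenched to a homogeneous density *inside its
spinodal* is thermodynamically unstable: large-scale density fluctuations
grow without a nucleation barrier, and the system demixes spontaneously
(spinodal decomposition). In a periodic rectangular box of side $L_x$ (in x
and y) and $L_z \ge L_x$, the dense phase that emerges takes one of a small
set of shapes fixed by the competition between bulk free energy and surface
energy at the given overall density $\rho_0$: with increasing $\rho_0$ a
sphere, a cylinder, a slab, a hollow cylinder, and a hollow sphere, bounded
below and above by the two homogeneous single-phase regions.

The slab is the useful morphology: it presents two flat interfaces normal to
$z$, so the equilibrium dilute- and dense-phase densities
($\rho_b$, $\rho_d$) can be read off a one-dimensional density profile, and
the interfacial tension follows from the anisotropy of the pressure tensor.
Instead of preparing a dense slab by hand (the classical slab method), one
simply starts from random insertion at a $\rho_0$ in the slab range and lets
spinodal decomposition produce the slab — which it does quickly, on the
order of $2\times10^4$ MD steps for Lennard-Jones particles at the
conditions used throughout this package.

The workflow is: **simulate** (Langevin MD or Metropolis MC from a
homogeneous start) → **watch the separation** ($\tau_{PS}$ from the
max-slice-density plateau, $\tau_{SS}$ from slab counting) → **average the
recentered density profile** over the equilibrated window → **fit the
interface** → **aggregate over temperatures** into a binodal and a critical
point, and over aspect ratios into morphology-boundary scaling.

## Model systems

Four coarse-grained systems, all in reduced units (lengths in the bead
diameter $\sigma$, energies in $\epsilon$, temperature in $\epsilon/k_B$,
time in $\tau = \sqrt{m\sigma^2/\epsilon}$, $m = 1$):

* **LJ particles** — 12-6 Lennard-Jones, truncated at $r_c = 3\sigma$ and
  shifted so $U(r_c) = 0$. The force is the bare LJ force inside $r_c$ (the
  constant energy shift has zero derivative); the force discontinuity at the
  cutoff is part of the model definition.
* **LJ chains** — 10 beads per chain; non-adjacent beads interact through a
  *force-shifted* LJ potential ($U$ and $U'$ both zero at $r_c = 6\sigma$);
  adjacent beads are excluded from the nonbonded potential and connected by
  harmonic bonds $U = \tfrac12 k (r - \sigma)^2$ with $k = 75{,}000\,
  \epsilon/\sigma^2$ by default (750 and 75 are supported; the bond
  convention carries the explicit $\tfrac12$, so these constants mean what
  they say under `bond_params()`).
* **HP chains** — the same topology with two bead types: H–H pairs keep the
  force-shifted attraction, H–P and P–P pairs are purely repulsive (WCA).
  The default sequence puts P beads at positions 1 and 5; positions 5 and 6
  are the documented alternative.
* **Patchy particles** — hard spheres decorated with four attractive
  Kern-Frenkel patches at tetrahedron vertices, range
  $\lambda = 0.5\sigma$. Two particles at separation
  $\sigma \le r < \sigma + \lambda$ gain $-\epsilon$ for every pair of
  patches whose cones both contain the center-to-center direction.

### The patch half-angle

The tetrahedral patchy model is specified by its surface coverage: the four
patches cover a fraction 0.7 of the particle surface. Four tetrahedral caps
of half-angle $\theta_s$ cover $2(1 - \cos\theta_s)$ when they do not
overlap, so coverage 0.7 fixes $\cos\theta_s = 0.65$ — caps of half-angle
$49.5°$, comfortably disjoint at the $109.47°$ tetrahedral separation. This
is the package default, and `patch_coverage()` verifies it by Fibonacci
spherical quadrature with a point-in-any-union test. The complementary value
$1 - \cos\theta_s = 0.35$ sometimes quoted for this model cannot be the
cosine itself: caps of half-angle $\arccos(0.35) = 69.5°$ would overlap into
99.95% coverage, making the attraction effectively isotropic (bond energies
up to $16\epsilon$) and destroying the patchy phase behavior the model
exists to produce.

## Engines

**MD** is constant-NVT Langevin dynamics integrated with the BAOAB splitting
of velocity Verlet: friction $\gamma = 0.1\,m/\tau$, $dt = 0.005\tau$ for
particle systems and $0.001\tau$ for chains. With $\gamma = 0$ the noise
vanishes and the integrator is plain velocity Verlet; energy conservation at
zero friction, equipartition, the free-particle (Ornstein–Uhlenbeck)
mean-square displacement, and momentum conservation are all tested. One
seeded counter of a 64-bit Mersenne generator drives each run, so
trajectories are bitwise reproducible per seed on a given platform.

Random insertion leaves overlapping cores. Two safeguards relax them without
rejection sampling: a short displacement-limited steepest-descent phase
before dynamics, and a per-step displacement cap during the first $10^3$
steps. The steepest-descent step is limited to $0.5/k$ for bonded systems —
a larger step is unstable on the stiff bond modes (curvature $k$) and
injects spurious bond energy. Both safeguards are off by default when a run
continues from an existing state.

**MC** is Metropolis sampling with one sweep = one attempted move per
particle. Patchy particles alternate displacements (uniform in a cube of
side $0.09\sigma$) and rotations with equal probability; hard-core overlaps
are always rejected. LJ-particle MC uses displacements only. The prose
description of the rotation move in the literature is compressed, so the
package defines it explicitly as a symmetric proposal: tilt the body z axis
uniformly within a spherical cap of half-angle $0.05$ rad about its current
direction (rotating about the line of nodes), then spin about the new z axis
by an angle uniform in $\pm 0.05$ rad. The reverse move is equally likely,
so detailed balance holds; the sampler is checked against an exact
quadrature oracle (below). Incremental energy bookkeeping is verified
against full recomputation at the end of every run.

The pressure tensor
$p_{aa} = (\sum_i m v_a^2 + \sum_{\mathrm{pairs}} r_a f_a)/V$ is sampled
every 10 MD steps; in MC the kinetic part is replaced by the ideal term
$\rho T$. It is refused for patchy particles, whose discontinuous potential
has no well-defined virial.

## Analyses

**Density profile.** Slices of $0.1\sigma$ (profiles) or $1\sigma$ (slab
counting) along the slab normal. Each frame is first translated so its
center of mass sits at the box center; under periodic wrap the center of
mass is computed as a circular mean (the naive mean is ill-defined when the
slab straddles the boundary). The profile is then averaged over the analysis
window: the second half of the run, or from $\tau_{SS}$ to the end when slab
fusion completes late.

**Interface fit.** The half-profile on the positive side of the center is
fit to $\rho(z) = \frac{\rho_d + \rho_b}{2} - \frac{\rho_d -
\rho_b}{2}\tanh[(z - z_0)/w]$ by Levenberg–Marquardt least squares
(`minpack.lm`), with plateau-based starting values. A fitted $w$ larger than
the box, inverted plateaus, or a profile without detectable contrast raise a
convergence error rather than returning nonsense. A negative fitted $w$ is
resolved by the tanh sign identity (swap phases, flip $w$).

**Time scales.** $\tau_{PS}$ is the first time the maximum slice density
reaches its plateau; the plateau is estimated as the median of the final
quarter of the series, and a final quarter still rising more than 5% above
the third quarter reports "not converged" instead of a number (the original
procedure tuned slice thickness against visual inspection; an algorithm
needs an explicit rule). $\tau_{SS}$ is the first time the slab count
reaches 1 *and persists* for at least 5 saved frames (or a shorter trailing
run that reaches the end of the series) — the raw "first time" is sensitive
to single-frame flicker. Slab counts come from the circular H/L sequence:
slices above $\rho_H$ are H, below $\rho_L$ are L, in-between slices are
filtered out, and slabs = transitions/2. Defaults $\rho_H = 0.55$ and
$\rho_L = 0.25$ are the centers of the working ranges 0.5–0.6 and 0.1–0.4,
overridable per system.

**Morphology classification.** The published labels are visual; the package
formalizes them. The density is sampled on a grid of points (spacing
$\approx 1.5\sigma$) by counting particles within a ball of radius
$2.8\sigma$ — a volume-weighted smooth field, deliberately *not* a
per-particle statistic, which would be biased toward whichever phase holds
most particles. A frame is homogeneous when the field extremes are
consistent with uniform-density counting noise (dilute side: maximum below
the mean $+\,6$ Poisson standard deviations; dense side: minimum above half
the mean — dense-liquid fluctuations are strongly sub-Poissonian, while a
bubble drives the local density essentially to zero). Otherwise the field is
thresholded at the midpoint of its extremes (an estimate of
$(\rho_b + \rho_d)/2$) and the periodic connected components of the dense
and dilute voxel sets are found by breadth-first search that tracks
unwrapped coordinates, so wrap-around — spanning — is detected exactly.
Dense component spanning 0/1/2 box directions → sphere / cylinder / slab;
dense spanning all 3 → the dilute complement decides (spanning 1 → hollow
cylinder, 0 → hollow sphere, absent → homogeneous dense). The window label
is the majority over the last five frames. This classifier reproduces the
full sphere → cylinder → slab → hollow cylinder → hollow sphere sequence of
the LJ system at $T = 0.65$ from actual simulations, which is also how the
boundary-scan acceptance checks exercise it.

**Interfacial tension.** Kirkwood–Buff:
$\gamma = \frac{L_z}{2}\langle p_{zz} - \tfrac12(p_{xx}+p_{yy})\rangle$
over the analysis window (the $L_z/2$ counts the two interfaces), with a
standard error from 5-block averaging.

**Chain size.** Per-chain radius of gyration with the backbone unwrapped
bead-to-bead through the minimum image; the dense-phase selector keeps
chains whose centers lie within the fitted slab half-width $z_0$ of the slab
center. The ideal freely jointed 10-bead reference is
$\langle R_g^2\rangle = b^2(n^2-1)/6n = 1.65\sigma^2$, RMS
$R_g = 1.2845\sigma$; the dense phase at $T = 1.7$ expands this to
$\approx 1.49\sigma$ through inter-chain attraction.

**Concentration conversion.** For solvated systems analyzed in ångströms,
number densities of molecule centers convert to weight-per-weight as
$\rho_{\text{Å}^{-3}} \times M_W \times 1.66054 / d_w$ (with $d_w$ in kg/L);
the slice volume cancels.

## Cross-temperature and cross-geometry aggregation

**Critical point.** The binodal is fit jointly to the rectilinear-diameter
law $\tfrac12(\rho_b + \rho_d) = \rho_c + A(T - T_c)$ and the
order-parameter law $\rho_d - \rho_b = B(T_c - T)^{0.32}$ (3-D Ising
$\beta$, fixed). Both share $T_c$; for fixed $T_c$ each equation is linear,
so the implementation profiles a one-dimensional objective over $T_c$ and
solves the rest in closed form — exact on synthetic data to the optimizer
tolerance. Temperatures within 2% of the running $T_c$ estimate are excluded
and the fit repeated once, because near-critical profiles in elongated boxes
are systematically biased (interfaces widen into the bulk region). Standard
errors come from the Jacobian at the optimum.

**Morphology-boundary scan.** One short run per (aspect ratio, $\rho_0$,
seed), classified post-separation; the per-density label is the majority
over seeds, a tie marking the run ambiguous, in which case its own $\rho_0$
is the boundary (the tie rule). Boundaries between adjacent differing labels
are midpoints; the lowest and highest boundaries are the effective spinodal
densities, since on the spinodal-decomposition timescale metastable states
do not nucleate. Scan runs are $10^5$ MD steps — about five times the
phase-separation time at the reference conditions — and are extended once
when the max-density series has not plateaued.

**Boundary scaling.** Across aspect ratios the boundaries follow
$\rho_0(\xi) = (\rho_1 + \rho_\infty\xi)/(1 + \xi)$ with
$\xi = L_z/L_x - 1$: linear least squares in the basis $1/(1+\xi)$,
$\xi/(1+\xi)$. With `shared_rho_inf` several transitions are fit jointly
with one common $\rho_\infty$ (stacked design matrix); whether the original
analysis constrained the transitions jointly or averaged separate fits is
not documented, so both routes are exposed and the joint fit is the default
interpretation of "common value".

**Theory curves.** The van der Waals fluid in critical units has spinodal
$t = \tfrac94 x(1 - x/3)^2$ and a binodal obtained by a Maxwell
construction: for each $T < T_c$ the coexistence pressure is bracketed
between the spinodal extrema and solved by bisection for equal chemical
potential on the outer branches (equal pressure holds by construction; the
self-check verifies it to $10^{-10}$). The symmetric Flory–Huggins blend
(both species length $L$) has $\phi_c = 1/2$, $\chi_c = 2/L$, spinodal
$\chi_s(\phi) = [1/\phi + 1/(1-\phi)]/2L$, and a symmetric binodal from
$\frac1L\ln\frac{\phi}{1-\phi} + \chi(1 - 2\phi) = 0$.

## Oracles and synthetic data

Every analysis operation is testable without long simulations:

* `make_tanh_profile()` runs the interface model forward (a symmetric
  double-interface slab, optionally with Gaussian noise) so the fit is
  checked against known parameters. Note the generator is a *finite slab*:
  the opposite interface contributes $O(10^{-4})$ at the box center, which
  sets the attainable round-trip accuracy.
* `sample_fjc()` draws ideal freely jointed chains with exact closed-form
  size statistics.
* `make_voxel_morphology()` builds periodic ground-truth masks for the
  classifier.
* `boltzmann_patchy_pair()` is an exact equilibrium oracle for two patchy
  particles in a periodic box. It exploits the model's structure: the pair
  energy depends only on the radial shell and on $k_1 k_2$, where $k_i$ is
  the number of patch centers within the cone of a uniformly random
  direction, so the 6-dimensional configurational integral factorizes into
  shell volumes times a patch-count distribution computed by spherical
  quadrature. Convergence is enforced by refinement (the estimate must move
  less than $10^{-3}$ on doubling the resolution). The Metropolis sampler is
  required to reproduce its bonded fraction — this is the detailed-balance
  test.

The synthetic generators emulate the *outputs* of equilibrated simulations
(profiles, masks, chain ensembles) with known parameters; they do not
emulate critical fluctuations, capillary waves, finite-size interface
broadening, or the kinetics of coarsening. Passing the synthetic tests
therefore validates the estimators, while the simulation-based tests (the
morphology sequence, the boundary scans, $\tau_{PS}$ at $N = 4000$, the
dense-phase chain size, MD/MC agreement, tension monotonicity) validate the
physics end to end at reduced scale.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest systems where the tested property is stable:

* Boundary scans: $L_x = 10$, $T = 0.65$, $10^5$-step runs, majority over 3
  seeds ($N \le 300$); aspect-ratio scaling uses $L_z/L_x \in \{1, 3, 5\}$
  on a 0.005 density grid with one seed.
* Phase-separation time: the full $N = 4000$, $L_z/L_x = 3.26$ system
  (the plateau is established well within $5\times10^4$ steps).
* Dense-phase chain size: 101 chains at $L_x = 13$ (the chain cutoff
  $6\sigma$ requires $L_x > 12$), started from a preformed slab — random
  insertion restricted to the central $10\sigma$ — because the property is
  an equilibrium average of the dense phase, not a statement about the
  separation pathway.
* Scaled-down binodals for the monotonicity and MD/MC-agreement properties:
  $L_x = 7$, $L_z/L_x = 3$, three temperatures. The MC leg starts from the
  MD-equilibrated slab: both samplers must hold the same stationary
  coexistence, and this isolates the comparison from MC's slower transport.

Degenerate inputs fail loudly: zero/negative pair distances, non-rotation
orientation matrices, cutoffs exceeding half the box, flat profiles in the
interface fit, patchy input to the pressure tensor, blown-up integrations
(reported with the failing step), and hard-core insertion at infeasible
density (bounded retries, then a packing error).

## Known limitations

* Tension is computed for planar interfaces only; no curvature corrections
  for spheres or cylinders, and no capillary-wave analysis.
* The classifier labels one morphology per window; genuinely bicontinuous
  transients are reported as slabs with an ambiguity flag.
* Near $T_c$, narrow boxes bias $\rho_d$ down and $\rho_b$ up; the
  critical-point fit mitigates this by excluding near-critical temperatures
  but does not correct the bias.
* Gelation (arrested decomposition at deep quenches) is reachable with the
  engines but has no dedicated analysis.
* MC for chains is not implemented (displacement-only moves equilibrate
  polymers poorly); chains use MD, matching the original protocols.
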