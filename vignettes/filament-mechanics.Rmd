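---
title: "Coarse-grained mechanics of twisted membrane-bound MreB filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained mechanics of twisted membrane-bound MreB filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MreBTwist)
```

## The model

MreB, the bacterial actin homolog, polymerizes into short antiparallel
double protofilaments that bind the inner face of the plasma membrane and
direct cell-wall synthesis. Molecular-dynamics analyses indicate that the
double protofilament has an intrinsic *left-handed twist* whose magnitude
depends on the bound nucleotide, on regulatory proteins such as RodZ, and
on point mutations. A twisted filament can only present its single
membrane-binding face continuously if it untwists, so twist frustrates
membrane binding; this package quantifies the consequences of that
frustration for filament length and orientation.

The filament is a one-dimensional elastic object confined to the inner
surface of a rigid cylinder of radius $r$ (the turgor-inflated cell wall
fixes the membrane geometry; $r = \infty$ is a flat supported membrane).
Its state is the local tilt angle $\theta(s)$ between the filament tangent
and the cylinder axis, and the local twist angle $\psi(s)$ of the binding
face away from the membrane ($\psi = 0$ means fully bound). The energy per
unit length combines four terms:

$$
\mathcal{H} = \frac{1}{2}\int_{-L/2}^{L/2}\!\! ds\left[
C\!\left(\frac{\sin^2\theta}{r} - k_0\right)^{\!2} + C\,\theta'^2
+ K\!\left(\psi' - \frac{\sin 2\theta}{2r} - \omega_0\right)^{\!2}
+ 2V\sin^2\!\frac{\psi}{2}\right]
$$

* the normal curvature imposed by the cylinder, $\sin^2\theta / r$,
  penalized against the intrinsic curvature $k_0$ with bending modulus $C$;
* tilt gradients, same modulus;
* the deviation of the twist rate from the intrinsic rate $\omega_0$,
  where a helical path on the cylinder contributes the geometric torsion
  $\sin 2\theta / (2r)$, penalized with torsional modulus $K$; and
* the membrane binding potential $V$ per unit length, fully recovered only
  at $\psi = 0$. The single-sided binding interface is why the potential is
  $2V\sin^2(\psi/2)$, with period $2\pi$, rather than a potential that
  would also reward $\psi = 180^\circ$.

Energies are in units of $k_BT$, lengths in nm, and angles in radians
internally (degrees at all user-facing interfaces).

### Default constants

The defaults in `filamentParams()` are fluctuation- and binding-derived
estimates for wild-type MreB double protofilaments, obtained with the
estimators of this package (`torsionalModulus()`,
`bindingPotentialPerLength()`, `polymerizationDensity()`,
`intrinsicRates()`):

| constant | default | origin |
|---|---|---|
| $K$ | $4.6\times10^3\ k_BT$ nm | twist-angle SD of 1.88° per 5-nm monomer step, $K = k_BT\,\Delta l/\sigma^2$ |
| $C$ | $4.6\times10^3\ k_BT$ nm | same magnitude as $K$; only enters the flat limit length through $e_0 = Ck_0^2/2 \approx 0.012\ k_BT$/nm, so the limit length is insensitive to it |
| $V$ | $4\ k_BT$/nm | 10 $k_BT$ membrane binding per monomer, two protofilaments, 5-nm rise |
| $\mu_0$ | $2\ k_BT$/nm | 5 $k_BT$ polymerization free energy per monomer (actin-like kinetics) |
| $k_0$ | $2.3\times10^{-3}$ rad/nm | bending-angle means per monomer step |
| $\omega_0$ | $0.03595$ rad/nm | 10.3° of left-handed twist per 5-nm rise (ATP state); `twistRate()` converts |

## Flat-membrane solution and limit length

On a flat membrane the tilt terms decouple and minimizing over $\psi(s)$
gives a pendulum-type first integral. The optimal profile is antisymmetric,
$\psi(\pm L/2) = \pm\psi_m$ with natural boundary conditions
$\psi'(\pm L/2) = \omega_0$: the filament unbinds its twist into boundary
layers of width $\ell_m/\omega_0$, $\ell_m = \sqrt{K/2V}\,\omega_0$, and
keeps its interior bound and untwisted. Both the length and the energy of
the optimal filament are quadratures over $\psi$ parameterized by
$\psi_m$; `flatTwistLength()` and `flatTwistEnergy()` evaluate them by
adaptive quadrature, which is the normative path. The equivalent closed
form in incomplete elliptic integrals is implemented internally and
checked against the quadrature to $10^{-6}$; it is not the primary path
because the convention of the elliptic second argument (modulus vs
parameter) is a classic source of silent errors.

As $\sin(\psi_m/2) \to \min(\ell_m, 1)$ the interior twist rate vanishes
and $L \to \infty$; `psiMBound()` exposes this singular bound and the
quadratures refuse it loudly rather than returning NaN.

`energyLengthCurve()` sweeps $\psi_m$ (log-spaced toward the bound),
resamples onto a monotone length grid with a monotone spline, and
differentiates by centered differences. The *limit length* is the first
crossing `dE/dL = mu0` (`limitLength()`): beyond it, extending the filament
costs more elastic and binding energy than polymerization releases. If the
slope never reaches $\mu_0$ the growth is unbounded up to the grid maximum
and `Inf` is returned. Two analytic facts anchor the tests: the asymptotic
slope is $e_0 + K\omega_0^2/2$ (equivalently $e_0 + V\sin^2(\psi_b/2)$),
and at any crossing $dE/dL = e_0 + V\sin^2(\psi_m/2)$.

```{r limit-length}
wt <- filamentParams()
prof <- energyLengthCurve(wt, LMax = 800)
limitLength(prof, wt@mu0)
```

With the default constants the crossing sits near 120 nm. It is worth
stating plainly how sensitive this number is: growth is unbounded whenever
$K\omega_0^2/2 < \mu_0$, i.e. below a twist of about 8.45° per 5-nm step,
and between 8.5° and 10.3° the limit length falls from ~270 nm to ~120 nm.
Within the uncertainty of the twist estimate, the flat-membrane limit
length is therefore an order-of-magnitude prediction, not a precision one;
the *trends* in twist, $K$, $V$, $C$, $k_0$ are the robust output.

A note on the branch choice: the quadratures are restricted to profiles
without full $2\pi$ twist walls (`n = 0`). Energetically, periodic twist
walls would become favorable for long filaments (a wall costs
$4\sqrt{2KV}$ but relieves $2\pi K\omega_0$), but a real MreB filament is
expected to break rather than sustain a full 360° twist, so the walled
branch is excluded on physical grounds. The `n` argument exists for
completeness and is untested against any reference.

## Metropolis minimization on the cylinder

On a finite-radius cylinder no closed-form solution exists, so
`metropolisMinimize()` minimizes the discretized Hamiltonian. The filament
is split into $N = L/\Delta l$ segments ($\Delta l$ = 5 nm, the monomer
rise, configurable); angles live on the $N+1$ segment-boundary nodes, and
each segment contributes a midpoint-rule term with averaged angles and
finite-difference derivatives. This discretization is exact for uniform
states and second-order accurate for smooth ones (checked against fine
trapezoid quadrature of the continuum integrand to $10^{-4}$).

Each Metropolis step perturbs one uniformly chosen node angle ($\theta$ or
$\psi$ with probability 1/2) by a uniform draw in $[-\delta, \delta]$,
accepting uphill moves with probability $e^{-\Delta E/k_BT}$; $\theta$
proposals leaving $[0, \pi]$ are rejected outright. $\delta$ is tuned to
30–50% acceptance during a burn-in (first 10% of the budget, at most
$10^5$ steps) and then frozen. Convergence is declared when the *minimized*
(best-visited) energy improves by less than 1% over the preceding $10^4$
steps; the instantaneous energy at $k_BT = 1$ fluctuates by
$O(\sqrt{N}\,k_BT)$ at equilibrium and would never satisfy such a
criterion. Because thermal sampling sits $O(N k_BT)$ above the minimum,
the minimizer tracks the best-visited configuration and, by default
(`polish = TRUE`), finishes it with a deterministic quench — bounded BFGS
on the discretized energy with analytic gradients — so that reported
energies are local minima, comparable with the analytical branch. Runs are
bit-reproducible from their seed; replicates use consecutive derived
seeds, and `energyLengthCurveMC()` excludes (with a message) any
non-converged replicate rather than silently averaging it.

```{r mc, eval = FALSE}
cfg <- mcConfig(maxSteps = 1e6, replicates = 3, seed = 1)
limitLengthMC(filamentParams(r = 80), cfg, LMax = 1000, LStep = 50)
```

Two cross-checks tie the engines together: at $r = 10^4$ nm the Monte
Carlo energies match the flat analytical curve within 5% over
$L \in [40, 400]$ nm, and the analytical curve itself matches an
independent brute-force minimization of the discretized flat energy within
1%. `pitchAngleSummary()` reports the length-weighted mean tilt (degrees)
and its deviation from circumferential (90°); `interiorPitch()` gives the
deterministic boundary-layer-free counterpart by minimizing the bound
interior energy density over the tilt.

## From trajectories to parameters

`trajectory geometry.` Subdomain centroids (`subdomainCenters()`) are
unweighted over the labelled atoms by default — mass weighting is provided
and changes test-frame angles by well under 0.1° — with the N-terminal
amphipathic helix (residues 1–8, label `none`) always excluded. The
opening angle is the mean of the two cleft angles at IIA and IA; the
dihedral angle is the absolute angle between the IA–IB–IIA and
IIB–IIA–IA plane normals, reported in $[0°, 180°]$ with coplanar = 0°
(trends over time carry the sign information). Subunit body frames
(`subunitTriad()`) are carried from a reference structure by the rotation
part of a Kabsch superposition; the reference triad has $d_3$ along the
filament axis, $d_2$ the membrane normal component perpendicular to it,
and $d_1 = d_3 \times d_2$. Relative rotations are decomposed
(`eulerBendTwist()`) as twist about $d_3$ first, then bend about $d_2$,
then bend about $d_1$ — the order is a convention; at the observed angles
(< 20°) reordering changes the result by under 0.5°, which is asserted by
test. `|theta2|` near 90° is flagged as gimbal-adjacent. SASA uses a
rolling probe of 0.14 nm with 960 deterministic golden-spiral points per
atom; buried SASA is $(A_1 + A_2 - A_{1+2})/2$, clipped at zero with a
warning if sampling noise drives it slightly negative. Membrane curvature
fits $z = ax^2 + bxy + cy^2 + dx + ey + f$ in the cloud's principal-axes
frame and returns the largest-magnitude principal curvature at the center,
signed positive toward the protein side (a reference point orients the
normal; without one the sign is arbitrary).

`parameter estimation.` Gaussian fits of the trailing 40-ns window
(half-open, so 200 frames at 0.2 ns) use 0.5°-bin histograms and nonlinear
least squares, falling back to sample moments (flagged `degenerate`) when
the histogram cannot support a fit. The estimators
$K = k_BT\Delta l/\sigma^2$, $C = \mathrm{mean}(C_1, C_2)$ (warning above
5% anisotropy), $\omega_0 = \theta_3/\Delta l$,
$k_0 = \sqrt{\theta_1^2 + \theta_2^2}/\Delta l$ convert degrees to radians
exactly once, at entry. A single 200-frame window with a 2-ns
autocorrelation time carries only ~10 effective samples, so an individual
$K$ estimate scatters by tens of percent; the estimator is unbiased in
$1/K$ and recovery tests therefore average over independent windows.
`pearsonWithP()` implements the small-panel correlation test
($t = r\sqrt{(n-2)/(1-r^2)}$, two-tailed).

## Patch quantification

`segmentPatches()` normalizes the image to $[0, 1]$, thresholds at a fixed
0.5 (the classical default of global bi-level conversion; Otsu is offered
as an alternative), labels components with 8-connectivity, and discards
components below 0.02 µm² — the structured-illumination resolution limit.
Each surviving component is summarized by its binary second-moment
ellipse: major-axis length (with the standard $+1/12$ single-pixel
variance correction) as the filament-length proxy, and major-axis
orientation folded into $[0°, 90°]$ against the long cell axis as the
pitch angle. `lengthDistribution()` pools patches and reports the
empirical CDF and the 99th percentile — the observational proxy for the
limit length — refusing the percentile below 100 patches.
`pitchDistribution()` reports mean ± SEM.

## Synthetic data: what it does and does not emulate

Every pipeline input has a seeded generator with ground truth attached, so
all recovery claims are tested without external data.

* `genAngleSeries()` — discrete Ornstein–Uhlenbeck series with a mean
  relaxing from zero over a 60-ns burn-in and a 2-ns autocorrelation time,
  emulating the approach to equilibrium and the correlated frame-to-frame
  statistics of equilibrium trajectories. It does not emulate multi-state
  hopping or drift.
* `genRigidPair()` — a deterministic 100-atom template subunit duplicated,
  rotated by planted bend/twist angles composed in the documented
  convention, lifted by the 5-nm rise, and jittered. Real subunits deform
  internally; this fixture is rigid by design so Euler recovery has an
  exact truth.
* `genMembraneCloud()` — jittered lattice on a cylinder (plane at zero
  curvature); no thermal undulations.
* `genSurfaceImage()` — elliptical band footprints (the shape whose
  binary second-moment major axis equals the planted length), with the
  rendered extent padded by $0.8\sigma_{PSF}$ to compensate the axial
  half-max erosion of the blur, Gaussian PSF ($\sigma$ = 0.05 µm), Poisson
  shot noise on a 2×10⁴-photon scale and 0.5% Gaussian read noise —
  i.e. a smooth reconstructed super-resolution image, not a raw frame.
  The planted length is thus defined as *the length the measurement
  convention reports*, which is what makes planted-recovery tolerances of
  one pixel meaningful.
* `genMutantPanel()` — the end-to-end fixture: per strain, the analytical
  limit length (capped at 1 µm to stand in for the finite cell) and the
  interior pitch at $r$ = 400 nm (a 0.8-µm-wide cell) set the center of
  log-normal length and Gaussian pitch distributions from which surface
  images are rendered. The default strains span twists of 2–8.7° per
  step: under the default constants, strains twisted much beyond ~9.3°
  predict limit lengths below the ~200-nm detectability scale implied by
  the 0.02-µm² area filter, and would contribute no measurable patches.
  Consequently, passing panel tests demonstrate that the pipeline
  preserves the planted orderings (length down, pitch deviation up, with
  twist) — they do not reproduce any specific in vivo correlation
  coefficient.

## Numerical choices and degenerate inputs

* Quadratures: `integrate()` at `rel.tol = 1e-10`; the $\psi_m$ sweep is
  log-spaced toward the singular bound; profiles are resampled with
  `monoH.FC` monotone splines before differencing.
* $\omega_0 = 0$ or $V = 0$: the energy-length curve is exactly linear
  with slope $e_0$ and is returned in closed form.
* Multiple `dE/dL = mu0` crossings: the first is returned and all are
  reported via a message and the `"crossings"` attribute.
* Exactly duplicated atoms are collapsed before SASA point-testing, so a
  doubled atom does not occlude itself.
* Constant nonzero images cannot be normalized and error; blank images
  return an empty patch table.
* Convergence of a Metropolis run near zero energy uses an absolute floor
  of $10^{-3}\,k_BT$ in the relative criterion.

Test problem sizes were chosen to exercise each claim at the smallest
scale where the statistics are meaningful: Monte Carlo runs of $2$–$5
\times 10^5$ steps with 2–3 replicates at lengths up to 600 nm, a radius
sweep to $10^4$ nm, recovery panels of 10–20 seeded replicates, and images
of 128–256 pixels with 100+ measurable patches per strain.

## Known limitations

* The membrane is rigid: no membrane deformation energy, although MreB
  double protofilaments demonstrably curve membranes; and no
  polymerization kinetics — the limit length is an equilibrium statement.
* The flat-membrane analytical branch excludes $2\pi$ twist walls by
  construction (see above).
* Pitch on a cylinder is driven by terms of order $1/r$; at cell-scale
  radii these are shallow minima, so Monte Carlo pitch estimates need the
  quench to be reproducible.
* The image pipeline assumes flattened single-surface images with
  additive band intensities; it does not model cell curvature projection,
  channel registration, or reconstruction artifacts.
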