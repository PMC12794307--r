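---
title: "Effective MR axon radius mapping: models, estimators and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective MR axon radius mapping: models, estimators and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonradius)
```

## The biophysical model

At strong diffusion weightings (b ≥ 6 ms/µm²) the extra-cellular
white-matter signal has decayed to a negligible level and the remaining
signal is attributed to water restricted inside impermeable,
micrometre-thin cellular processes. We model one such process as an
infinite cylinder of radius $r$ with intrinsic axoplasmic diffusivity
$D_0$ and apparent parallel diffusivity $D_{c\parallel}$. For a PGSE
experiment (amplitude $g$, duration $\delta$, separation $\Delta$) the
perpendicular attenuation in the long-pulse (Neumann) limit
$\delta \gg r^2/D_0$ is

$$S_\perp(r \mid g,\delta) = \exp(-\kappa r^4),\qquad
  \kappa = \frac{7\,\gamma^2 g^2 \delta}{48\, D_0},$$

with $\gamma = 2.6752\times10^8\,\mathrm{rad\,s^{-1}T^{-1}}$ the proton
gyromagnetic ratio. Internally the package works in µm, ms and mT/m, so
that b-values are in ms/µm², diffusivities in µm²/ms and $\kappa$ in
µm⁻⁴; all published parameter values can be used unchanged. With these
constants, the maximum-gradient condition of the reference protocol
(273 mT/m, $\Delta/\delta = 30/15$ ms) lands on b = 30 ms/µm², which
the test suite checks.

The more general Gaussian-phase (Van Gelderen) series over roots of
$J_1'$ is provided as `vangelderen_perp()`; analytically its
long-pulse limit equals the Neumann exponent (the Bessel-root sum
$\sum_m [\beta_m^4(\beta_m^2-1)]^{-1} = 7/192$), and the convergence of
one to the other is a tested invariant.

### Spherical mean and spherical variance

Averaging the single-cylinder kernel
$K(\xi) = f e^{-bD_{c\parallel}\xi^2} S_\perp^{\,1-\xi^2}$ (with $\xi$
the cosine between gradient and fiber axis; the $S_\perp^{1-\xi^2}$
form is exact because every Gaussian-phase log-attenuation scales with
$g^2$) over the sphere and over the fiber ODF yields the rotationally
invariant features. With $\mathrm{erf}(\sqrt{bD_{c\parallel}})\approx 1$:

* order 0 (spherical mean, SM):
  $\bar S(b) = \beta\, S_\perp / \sqrt b$ with
  $\beta = f\sqrt{\pi/4D_{c\parallel}}$;
* order 2 (spherical variance, SV):
  $\bar S_\sigma(b) = p_2\, \gamma'\,(2bD_{c\parallel}-3)\,
  S_\perp / b^{3/2}$ with
  $\gamma' = f\sqrt{\pi}/(8D_{c\parallel}^{3/2})$,

where $p_2 \in [0,1]$ is the $\ell=2$ Legendre moment of the ODF. The
SV expression is the exact $\ell=2$ Legendre projection of the kernel:
$\tfrac12\int_{-1}^{1} P_2(\xi)\,e^{-x\xi^2}d\xi =
\sqrt{\pi}\,(3-2x)/(8x^{3/2})$ up to $O(e^{-x})$ terms, with
$x = bD_{c\parallel}$. The projection is negative for $x > 3/2$; since
RISH features are norms, the package works with its magnitude and
treats $x \le 3/2$ as an out-of-regime error. We verified the
projection against numerical quadrature before freezing it, and the
test suite keeps the forward model and the two-shell inversion in
exact algebraic correspondence (round-trip error ≤ 10⁻⁹ µm⁴ across
$r \in [0.5, 5]$ µm, $D_{c\parallel} \in \{1.5, 2, 2.5\}$,
$p_2 \in \{0.3, 0.7\}$).

Two approximation flags are exposed rather than silently ignored: the
erf approximation is flagged when $bD_{c\parallel} < 6$, and the
Neumann regime when $\delta < 10\,r^2/D_0$. The reference protocol
at $r = 3$ µm sits outside the strict Neumann regime flag; the
resulting model error is quantified (not assumed away) by inverting
Van Gelderen-generated data with the Neumann-based estimator, which
the acceptance script reports as a percentage discrepancy at
$r \le 3$ µm.

## Estimators

`loglinear_radius_sm()` inverts the SM model from exactly two shells:

$$r^4 = \frac{\log\!\big(\sqrt{b_1}\bar S(b_1)\big) -
              \log\!\big(\sqrt{b_2}\bar S(b_2)\big)}{\kappa_2-\kappa_1}.$$

The prefactor $\beta$ — and hence $f$ and $D_{c\parallel}$ — cancels,
which is the practical appeal of the closed form. The SV inversion is
identical after moving the $(2b_jD_{c\parallel}-3)$ factors across
shells (they cross-pair: shell 1's term carries shell 2's factor), so
$p_2$ and $f$ cancel but $D_{c\parallel}$ must be supplied, e.g. from a
standard-model fit of the lower shells. Design choices:

* **Negative $r^4$** (possible under noise, or when slow-decaying
  isotropic signal makes the apparent decay shallower than a stick):
  reported as $r = 0$ with a `negative_r4` flag, while the raw $r^4$ is
  preserved for unbiased aggregation across voxels or segments.
* **More than two shells**: weighted linear regression of the
  log-transformed feature on $\kappa$, the natural extension of the
  log-linear form; each shell's $\kappa$ uses its own $(g,\delta)$.
* **Nonlinear reference estimator**: least-squares fit of
  (prefactor, $r$) with the prefactor profiled out analytically and
  $r$ located by bracketed 1-D optimization over [0, 10] µm from three
  starting intervals; available with either perpendicular model. On
  noiseless same-model data it agrees with the closed form to < 10⁻⁶,
  a tested invariant.

`fit_radius()` wraps both paths into a classed model object with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods;
`diffusivity_sweep()` re-estimates supplied feature pairs over
$(D_0, D_{c\parallel})$ grids and returns the mean $r_{SM}-r_{SV}$
surface, whose strong $D_{c\parallel}$ and weak $D_0$ dependence is a
tested property.

## RISH extraction

Per shell, even-order real spherical harmonics (default
$L_{max} = 6$) are fitted to the directional signals; with a known
noise level the coefficients maximize the Rician likelihood
(BFGS with analytic gradients, ordinary least squares as initializer
and fallback). The RISH scale convention is
$S_\ell = \lVert c_\ell\rVert / \sqrt{4\pi(2\ell+1)}$, chosen so that
$S_0$ equals the plain spherical mean — the same convention used by
the forward models, which is all the two-shell ratios require (any
fixed scale cancels). Negative predicted signals are clipped at
10⁻¹² inside the likelihood, which is undefined for negative
locations.

Two noise facts matter for interpretation and are covered by tests:
at low SNR the least-squares mean coefficient inherits the positive
Rician floor bias, which the ML fit largely removes (at moderate
parameterization; with $L_{max}=6$ and few directions the ML fit's own
small-sample bias becomes visible); and the SV, being the norm of five
noisy coefficients, follows a noncentral-chi law whose expectation
exceeds the true value — `sv_bias_probe()` quantifies that inflation.

## The Monte Carlo simulator

The walker engine (compiled, but driven by R's RNG so that every run
is reproducible under a seed) advances $10^4$-scale ensembles by
fixed-length off-lattice steps of 0.40 µm, the time step tied to the
step length by $dt = \mathrm{step}^2/6D_0$. Geometries are impermeable:
spheres, infinite cylinders, finite cylinders with reflecting caps,
independent dispersed cylinder sets, and a parametric glia cell (soma
sphere of 5 µm plus 20 isotropically oriented processes of radius
1–2 µm and length 30 µm) standing in for microscopy reconstructions;
an SWC reader can build the union geometry from real morphologies.
Collisions are handled by specular reflection of the residual step; at
junctions of a union where one reflection cannot resolve the step, the
move is rejected so that containment is never violated (the boundary
rule is not prescribed by the physics literature we follow; the
engine's correctness is instead pinned by oracles: the Einstein
relation, the free-diffusion signal $e^{-bD_0}$, transverse variance
saturation at $r^2/2$, and the perpendicular-cylinder signal against
the Van Gelderen series, all within three standard errors).

Because the PGSE lobes are ideal rectangles, a walk only needs the two
time-integrated positions over the lobes; signals for any gradient
amplitude and direction set then follow as $\langle\cos\phi\rangle$
without storing trajectories.

## The glia-fraction experiment

The axon compartment is analytic: a Watson ODF with $\langle P_2\rangle
= 0.7$ (concentration matched numerically) convolving the restricted
cylinder kernel — using simulated straight cylinders instead would
only add Monte Carlo noise, and real axonal meshes (beading,
undulation) are deliberately out of scope. Glia compartments are
simulated, and compartments mix by signal fraction, not geometry.

Study conditions, fixed once: ground-truth axon radius 1 µm — thin
relative to the 1–2 µm glial processes, which is the regime where glia
can confound the radius (thick processes relative to axons); parallel
and intrinsic diffusivities 2.5 µm²/ms; estimation at the generative
diffusivities so that the zero-glia rows are exact. Three substrate
classes are examined:

* **soma only** (5 µm sphere): its slowly decaying isotropic signal
  inflates $r_{SM}$ strongly while the SV, blind to isotropic content,
  is nearly untouched — the sign property that makes the SM/SV
  comparison diagnostic;
* **isotropic thick cylinders** (unbounded, dispersed): their steeper
  perpendicular attenuation inflates $r_{SM}$; their $\ell=2$ content
  is a small residual of the finite orientation sample, so curves are
  averaged over ten substrate realizations (mirroring analyses that
  average over a sample of reconstructed cells);
* **full parametric glia** (soma + finite processes): the 30 µm
  process length adds axial restriction, i.e. a slow-decaying
  quasi-isotropic floor — this geometry class behaves like the soma
  ("dot") mechanism rather than the dispersed-cylinder mechanism.

One finding from these defaults deserves emphasis: with *genuinely
isotropic* process orientations the realization-averaged $r_{SV}$
stays essentially at the ground truth (flat to slightly below) while
$r_{SM}$ rises — the SV's robustness to isotropically dispersed
contributions. An upward drift of $r_{SV}$ with glia fraction requires
partially coherent process anisotropy, which real reconstructed cells
possess but a fully isotropic parametric stand-in excludes by
construction; we did not inject artificial anisotropy to manufacture
that trend; the corresponding assertion in the package's simulation
test suite documents the discrepancy by failing.

## Synthetic data

`connectom_protocol()` reproduces the five-shell acquisition (b = 0.5, 1,
2.5, 6, 30 ms/µm² with 30/30/30/120/240 spherical-Fibonacci
directions, 23 b0 volumes) with per-shell amplitudes back-computed
from the b-values at fixed timings. Voxels mix the dispersed-cylinder
axon signal with an isotropic glia-like compartment — by default an
ideal dot (unit signal at all b), or per-direction signals from the
simulator — then apply two-channel Rician noise with
$\sigma = S_{b0}/\mathrm{SNR}$, matching magnitude reconstruction with
Rician statistics. The phantom writer emits standard NIfTI +
bval/bvec + a JSON ground-truth sidecar consumed unchanged by the
estimation pipeline. What the generator does *not* emulate: imaging
artifacts (motion, eddy currents, Gibbs ringing), spatially varying
noise, multi-coil noncentral-chi statistics, exchange, relaxation
weighting, and realistic axonal morphology — so passing tests certify
the estimator chain and its stated confounds, not robustness to
acquisition artifacts.

## Numerical choices

Van Gelderen series: first 10 roots of $J_1'$, truncation flagged when
the last term exceeds 10⁻⁹ on the exponent. Watson concentration
solved by bisection on $\langle P_2\rangle$ over [0, 700] (i.e.
$p_2 \lesssim 0.995$; larger values are rejected as unattainable,
$p_2 = 1$ uses the delta-ODF kernel directly). ODF quadrature uses a
2000-point Fibonacci grid. Shell grouping clusters b-values whose gaps
are ≤ 0.25 ms/µm². The per-segment statistics use the sample (N−1)
standard deviation in the CoV, the √(π/2)-scaled mean absolute
relative difference for TRV, and no multiple-comparison correction by
default (a per-segment testing convention), with Benjamini–Hochberg
available through `p.adjust` downstream. Simulation sizes in the test
suite (10⁴ walkers for physics oracles, 10 × 4000 walkers for the
glia curves, 10⁴ repeats for the type-I-error calibration) were chosen
so that three-standard-error assertions are meaningful at the effect
sizes involved.

## Known limitations

The estimators inherit the single-compartment model's assumptions:
negligible extra-cellular signal at the chosen shells, negligible
exchange at diffusion times ≤ 45 ms, and a fixed $D_0$ (2.5 µm²/ms by
default) that is not identifiable from two shells. The effective MR
radius is a tail-weighted summary of the underlying radius
distribution, not a mean radius. Voxel-wise estimates at realistic
SNR are noisy — segment-level averaging (as in `segment_aggregate()`)
is the intended operating point — and the log-transform adds a small
1/SNR² bias at low feature SNR. The SV path additionally requires
$D_{c\parallel}$ and loses precision as dispersion increases (its SNR
is proportional to $p_2$).
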