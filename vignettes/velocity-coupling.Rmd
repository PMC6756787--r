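---
title: "Velocity coupling of grid-cell modules: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity coupling of grid-cell modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Grid cells encode an animal's position through several modules. Each module
is a continuous attractor whose state is a periodic phase (one per spatial
dimension): position modulo the module's grid spacing $\lambda_\mu$,

$$\theta_\mu = \frac{x \bmod \lambda_\mu}{\lambda_\mu} \in [0, 1).$$

The joint code over $m$ modules with incommensurate spacings has enormous
dynamic range, but it is fragile: noise drives the phases of different
modules apart, and because each module's code is periodic, a *small*
incompatible drift can move the jointly decoded position by a *large*
amount — a catastrophic readout error. The package implements a coupling
architecture that suppresses incompatible drift without restricting which
phase combinations are reachable, so the capacity of the code is untouched.

## Single-module model

A 1D module is a double ring: two sub-populations of $N$ neurons (right and
left), preferred phases uniform on $[0,1)$. Synaptic activations follow

$$\dot s_i + s_i/\tau = r_i = \phi\Big(\sum_j W_{ij} s_j + I_0 \pm dI\Big),
\qquad \phi(x) = \tau^{-1}\max(x, 0),$$

with $+dI$ to the right and $-dI$ to the left sub-population. Outgoing
weights are distance-dependent and shifted by $\mp\varphi$ for the two
sub-populations,

$$W^\pm_{ij} = w(|\theta_i - \theta_j \mp \varphi|_P), \qquad
w(\theta) = \frac{A}{2N}\big[e^{-\theta^2/2\sigma^2} - 1\big],$$

where $|\cdot|_P$ is the minimal ring distance. All weights are
non-positive: the network is inhibition-dominated, a bump forms where
inhibition is weakest, and differential drive $dI$ moves it at a phase
velocity proportional to $dI$ — velocity integration.

In 2D each module has four sub-populations (R/L/U/D) on a rhombic sheet
with generators $u_1 = (1,0)$, $u_2 = (\tfrac12, \tfrac{\sqrt3}{2})$ and
periodic boundaries (a twisted torus); R/L weights are shifted by
$\mp(\varphi, 0)$ and U/D by $\mp(0, \varphi)$. The horizontal and vertical
velocity channels are independent, so every analysis of the 1D model
applies per axis. Gluing the rhombus is what makes single-neuron firing
fields hexagonal in position space.

Reference parameters (`module_spec()` defaults): $\tau = 10$ ms, $I_0 = 3$,
$A = 200$, $\sigma^2 = 0.1$, $\varphi = 0.2$, $N = 1000$ per sub-population
in 1D and $64^2$ at full scale in 2D. Explicit Euler integration with
$dt = 0.1$ ms by default; the integrator refuses $dt > \tau/10$.

## Velocity readout and coupling

The key observation is that the bump's phase velocity is well approximated
by a *linear* functional of the synaptic activations,

$$\omega = \frac{\beta}{\tau}\Big(\sum_{i \in R} s_i - \sum_{i \in L}
s_i\Big) \approx \dot\theta,$$

whose coefficients do not depend on where the bump sits. Feeding module
$\rho$'s readout into module $\mu$'s velocity input (and each module's own
readout back negatively) couples the modules' *velocities* while leaving
their *phases* unconstrained:

$$r_{\mu,i} = \phi\Big(\textstyle\sum_j W_{ij} s_{\mu,j} + I_0 \pm b_\mu
\pm a \sum_\rho C_{\mu\rho}\, \omega_\rho\Big),$$

with $a = [\beta \sum_i \phi'(\cdot)]^{-1} = \tau/(\beta\, n_{\rm act})$
evaluated once at the steady bump (`compute_input_scaling()`), so that
$a\,\omega$ — and hence the dynamics — is independent of $\beta$. The
coupling is equivalent to all-to-all synapses of uniform magnitude whose
sign depends only on the pre- and post-synaptic sub-populations
(`coupling_weight_matrix()`); every combination of module phases remains a
steady state, which the test suite verifies directly.

Reduced description: the phases obey the filtered velocity-coupling
dynamics
$\dot{\vec\theta} = \alpha \vec b(t) + C (f * \dot{\vec\theta})$ with $f$
the unit-area exponential filter of time scale $\tau$
(`phase_reduction()`), and for slow inputs
$\dot{\vec\theta} = X \vec b$ with the linear response tensor
$X = \alpha (I - C)^{-1}$. The single-module gain $\alpha$ has no printed
closed form and is calibrated by regression of measured phase velocity on
input level (`calibrate_gain()`; $R^2 > 0.999$ over the default range; we
measure $\alpha \approx 107$ in the 1D reference network and
$\approx 26$ per axis in 2D). Two practicalities of the reduction are worth
noting. First, the readout $\omega$ equals $\dot\theta$ only for one
particular $\beta$; for any $\beta$ the properly normalised statement is
that $a\,\omega$ recovers the velocity input (we measure
$a\,\omega / dI = 0.99$), and the simulator keeps the dynamics exactly
$\beta$-free by folding $a\beta/\tau = 1/n_{\rm act}$ into one constant.
Second, the explicit Euler scheme applied to the filtered-velocity
subsystem is stiff: its modes decay at $|{\rm eig}(C) - 1|/\tau$ (about
$4100\,\mathrm{s^{-1}}$ for the reference couplings), so
`phase_reduction()` enforces $dt < 1.8\,\tau/|{\rm eig}-1|$ — 0.2 ms is
used in the drift experiments — and refuses larger steps with an
informative error.

The shipped couplings (`standard_coupling()`) use self coupling
$C_s = -20$ and, for $m = 2$, $C_1 = -C_s/\lambda$, $C_2 = -C_s\lambda$
with spacing ratio $\lambda = \sqrt 2$. With these values
$C_s + \sqrt{C_1 C_2} = 0$, so the joint-motion gain is $X_+ = \alpha$
(full responsiveness to real motion) while the relative-motion gain is
$X_- = \alpha/41$: incompatible inputs are suppressed 41-fold. Stability
requires every eigenvalue of $C$ below unity (`check_stability()`; for
complex spectra we require the real part below unity, the point where the
filtered feedback loop reaches unit gain). The $m = 3$ matrix is
tridiagonal — coupling only between modules of adjacent spacing — with the
printed values $C_{12} = 14.14$, $C_{21} = C_{23} = 9.4$,
$C_{32} = 28.3$.

A note on $\lambda$: the source text of the model states the spacing ratio
once as "2", but every printed coupling value and caption is consistent
only with $\lambda = \sqrt 2$ ($14.14 = 20/\sqrt2$, $28.3 = 20\sqrt2$); the
package adopts $\sqrt 2$ throughout.

## Intrinsic noise and the diffusion tensor

With Poisson spiking ($\dot s_i + s_i/\tau = \sum_\chi \delta(t -
t_i^\chi)$, each spike incrementing $s_i$ by one, counts drawn per step
with mean $r_i\,dt$), the phases diffuse. Linearizing the coupled drift
around the joint steady state and extracting the $m$ left null eigenvectors
$\nu_\mu$ (bi-orthonormalized against the attractor tangents,
$\nu_\mu \cdot T_\rho = \delta_{\mu\rho}$) gives the diffusion tensor

$$D_{\mu\rho} = \tfrac12 \sum_i \nu_{\mu,i}\, \nu_{\rho,i}\, \bar r_i$$

in phase$^2$/s (`phase_diffusion()`). Uncoupled modules give an isotropic
tensor; the reference coupling makes it strongly anisotropic, with the
major axis within a fraction of a degree of the joint-motion direction
$u \propto (1, \lambda)$.

Numerical choices and findings worth knowing:

* **Lattice pinning.** With a rectified-linear transfer function the
  translation symmetry of the continuum is broken by the neuron lattice:
  the "zero" mode of the Jacobian sits at $|{\rm eig}| \sim 1\text{–}4\,
  \mathrm{s}^{-1}$ for $N \lesssim 500$ and drops to
  $\sim 10^{-2}\text{–}10^{0}\,\mathrm{s}^{-1}$ at $N \ge 1000$,
  fluctuating with the commensuration of the bump, the weight shift and the
  lattice. The default near-zero tolerance is $10^{-3}/\tau$; desk-scale
  analyses pass an explicit looser tolerance ($5\times10^{-2}/\tau$ at
  $N = 200$), and the full-scale pipeline uses $10^{-2}/\tau$ — in all
  cases the gap to the first relaxation mode ($\approx 96\ \mathrm{s}^{-1}$)
  exceeds a factor 10. Only lattice-commensurate translations of the
  relaxed state are exact steady states; the tensor is exactly invariant
  under them (tested to $10^{-8}$).
* **Null-mode extraction.** Below ~1500 neurons a full eigendecomposition
  is used (with the spectral-gap check); above, shifted inverse subspace
  iteration started from the tangents (one LAPACK QR factorization, three
  solves), with the Rayleigh quotients checked against the same tolerance.
  The two routes agree on $D$ to $10^{-6}$ relative (tested).
* **Computed anisotropy.** At $N = 1000$ with the reference couplings the
  pipeline yields $D_+/D_- = 38.5$, stable under deeper relaxation,
  different relative phases, and $N \in [700, 1200]$. The analytic
  response-tensor ratio is exactly 41; the diffusion anisotropy of the
  full network is genuinely a few percent below it.
* **Weak-noise approximation.** Spikes kick $s_i$ by 1, which is not small
  against $\bar s_i \lesssim 0.5$; Monte-Carlo simulation
  (`empirical_diffusion()`) reproduces the predicted structure and
  principal axis but runs $\sim 25\%$ below the linearized magnitudes.
  The Monte-Carlo check in the test suite therefore asserts agreement
  within its bootstrap confidence intervals and a factor-2 band on the
  anisotropy ratio, not exact equality.

## Synthetic inputs

No behavioural data ships with the package; `generate_trajectory()` stands
in for a measured foraging path. Velocity components follow a
mean-reverting (Ornstein–Uhlenbeck) process with correlation time
$\tau_v = 0.7$ s and mean speed 0.2 m/s (Rayleigh-distributed speeds in
2D), with reflecting walls in a $1.5 \times 1.5$ m arena — a typical
foraging enclosure. Velocity drives are
$b_{\mu,q} = \gamma_\mu (V_q + \eta_{\mu,q})$ with white noise of intensity
$\eta$ realized as per-sample Gaussian deviates of standard deviation
$\eta/\sqrt{dt}$ (Euler–Maruyama convention); $\eta = 0.02\ \mathrm{m\,
s^{-1/2}}$ in the noisy-input experiments, 0 otherwise. The default gains
$\gamma = 0.06\,(1, \lambda, \lambda^2)$ give spacings of roughly 0.64,
0.46 and 0.32 m in 2D — rat-like scales.

What the generator does *not* emulate: thigmotaxis and wall-following,
speed–turning correlations, head direction distinct from heading, and
landmark-driven corrections. Passing tests therefore demonstrate the
network and decoder mechanics under realistic speeds and coverage, not
behavioural realism.

## Decoding and catastrophic errors

Receptive-field templates $\bar r_i(x)$ are measured by translating the
relaxed bump to the phase representing each grid position and reading the
steady rates (`measure_receptive_fields()`), with a floor of $10^{-4}$ of
each neuron's peak rate inside the logarithm. Position is decoded by
maximizing $\sum_i n_i(t) \ln \bar r_i(x)$ where $n_i$ are effective spike
counts under a decaying exponential kernel with $\tau_d = 10$ ms
(`decode_position()`; the running update and the explicit kernel sum agree
to machine precision). Ties break toward the lowest grid index; samples
before the first spike are invalid, not zero.

Because the phases are updated purely by path integration, the
*represented* position is not confined by the arena walls: accumulated
drift can carry it slightly past a boundary. The decoding grid therefore
extends a configurable margin (default 0.15 m, a few standard deviations
of the accumulated common-mode drift) beyond the arena — without it, a
represented position just outside a wall has no matching hypothesis and a
remote alias inside the arena can capture the maximum likelihood.

A readout discontinuity is a jump between consecutive decoded samples
larger than $\lambda_{\min}/2$ (the source work states no number; this is
far above decoder jitter and far below any legitimate move at rat speeds
for strides up to 100 ms). Decoding stride defaults to 10 ms (one
$\tau_d$); grid step $\lambda_{\min}/50$ capped at $200^2$ points, with the
desk experiments using an explicit $64^2$ grid over the arena. A success at
time $t$ is a trial with no discontinuity up to $t$; the random-guess MSE
baseline is the expected squared distance to a uniform arena point.

One desk-scale subtlety: on a $24\times24$ lattice the velocity gain is
measurably anisotropic (x vs y differ by $\sim 3\%$) and the coupled gain
differs from the slow-input prediction $X\gamma$ by $\sim 2\%$. The
decoder's position-to-phase map therefore uses per-axis gains measured
from the network itself (`calibrate_spacings()` probes both axes);
building the map from a single nominal spacing leaves a systematic phase
error that grows with distance travelled and erodes the likelihood margin
of the true position.

## Scaled-down experiment sizes

The scripted experiments (`experiment_tracking()`, `experiment_drift()`,
`experiment_decoding()`, `experiment_diffusion()`) default to desk scales
chosen once: 1D analyses at $N = 200$ (full scale $N = 1000$ where the
quantity demands it, as in the diffusion anisotropy), 2D decoding at
$N = 24^2$ per sub-population with $dt = 0.5$ ms, 10 trials and a 10 s
horizon, drift statistics through the phase reduction with 400
realisations over 20 s. The drift comparison is paired: the coupled and
uncoupled variants consume identical noise realisations (common random
numbers), which removes most of the sampling variance from the reported
MSE-slope ratio without touching its expectation; with the published
three-module couplings that ratio is 2.6 — the idealized rank-one coupling
would give exactly the module count, 3. The test suite integrates the decoding check at
$dt = \tau/10 = 1$ ms, the integrator's guard limit; a convergence
spot-check against halved $dt$ is part of the suite. Trials are batched as
columns of one seeded run (one BLAS call advances all trials), so trials
within a run share one random stream; runs are reproducible bit-for-bit
given the seed, but individual trials are not separately seeded.

## Known limitations

* The diffusion analysis is implemented for 1D modules; the 2D channels
  decouple into two copies of the 1D problem, so nothing conceptual is
  lost, but no 2D tensor is assembled.
* The constrained optimization that produced the multi-module couplings is
  not re-implemented (its target function is not public); the printed
  matrices are shipped and arbitrary user matrices are screened for
  stability only.
* The linearized diffusion tensor overestimates absolute diffusion by
  ~25% at reference scale (finite spike-kick size); ratios and axes are
  robust.
* Serialization is plain CSV/JSON; there is no binary container support.
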