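# gridlock

Velocity-coupled grid-cell attractor modules: a simulator and analysis
toolkit for studying how recurrent connectivity can keep a modular,
periodic population code for position coherent under noise.

## The scientific problem

Grid cells represent an animal's position through several modules, each a
continuous attractor network with its own spatial period
λ<sub>μ</sub>: the module encodes the phase
θ<sub>μ</sub> = (x mod λ<sub>μ</sub>)/λ<sub>μ</sub>. Jointly the phases
form a code of enormous dynamic range — but also a fragile one. Noise
drifts the phases of different modules independently, and because every
module is periodic, a small *incompatible* drift can teleport the
maximum-likelihood position estimate to a distant location: a catastrophic
readout error.

The model implemented here couples modules through a **linear velocity
readout**: each double-ring (1D) or four-population torus (2D) attractor
broadcasts ω = (β/τ)(Σ<sub>R</sub> s − Σ<sub>L</sub> s), a weighted sum of
synaptic activations approximating its own phase velocity θ̇, into the
velocity inputs of the other modules, with negative self-feedback
(C<sub>s</sub> = −20) for stability. Because the coupling involves only
velocities, every combination of phases remains a steady state — capacity
is preserved — while *relative* drift is suppressed. For slow inputs the
phase velocities obey

    θ̇ = X b,   X = α (I − C)⁻¹,

and with the reference couplings (C₁ = −C<sub>s</sub>/λ,
C₂ = −C<sub>s</sub>·λ, λ = √2) the joint-motion gain X₊ = α is 41 times
the relative-motion gain X₋. The package provides, on top of the
simulator: the response-tensor analysis and stability screen, the
phase-reduction ODE, the phase diffusion tensor of the Poisson-spiking
network D<sub>μρ</sub> = ½ Σ<sub>i</sub> ν<sub>μ,i</sub> ν<sub>ρ,i</sub>
r̄<sub>i</sub> from the linearized dynamics, a maximum-likelihood spike
decoder with an exponential temporal kernel, catastrophic-error metrics,
and a synthetic foraging-trajectory generator.

## Worked example

Two coupled 1D modules, velocity input to module 1 only; the coupling
makes module 2 track at the spacing-ratio velocity:

```r
library(gridlock)

C <- standard_coupling(2)
check_stability(C)$values
#> [1] -40   0

rt <- response_tensor(C, alpha = 1)
rt$X_plus / rt$X_minus
#> [1] 41

res <- experiment_tracking("desk", T = 4, seed = 3)
res$ratio        # fitted theta2-dot / theta1-dot, coupled
#> [1] 1.325106
res$ratio_pred   # linear-response prediction X21/X11 = 28.28/21
#> [1] 1.34687
res$uncoupled_leak  # module 2 displacement / module 1, uncoupled
#> [1] 5.337558e-16
```

The fitted velocity ratio of the coupled pair sits within ~2% of the
linear-response prediction 1.347 (itself ~5% below λ = √2: with input to
one module only, the small relative-motion response mixes in); uncoupled,
module 2 does not move at all. The diffusion tensor of the spiking pair tells the
same story for intrinsic noise:

```r
res <- experiment_diffusion(N = 200)   # desk scale; N = 1000 reproduces the reference configuration
res$ratio              # D+/D- anisotropy, coupled
#> [1] 38.26818
res$uncoupled_offdiag  # uncoupled tensor is isotropic
#> [1] 3.024816e-16
```

Coupled, the phases diffuse almost exclusively along the coordinated
direction (u ∝ (1, λ)); relative diffusion is suppressed ~40-fold.

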