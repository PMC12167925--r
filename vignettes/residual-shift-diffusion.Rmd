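---
title: "Residual-shifting diffusion for paired MRI super-resolution: model, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-shifting diffusion for paired MRI super-resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdiff)
```

## The problem and the model

Super-resolution of MRI is a paired-image problem: after nearest-neighbour
pre-upsampling, the low-resolution (LR) slice lives on the same pixel grid
as its high-resolution (HR) counterpart, and the two differ by a
structured residual $e_0 = x^{LR} - x^{HR}$. A conventional denoising
diffusion model ignores this structure — it diffuses the HR image all the
way to white noise and pays for it with hundreds of reverse steps.
The residual-shifting construction diffuses toward the LR image instead:

$$x_t = x_{t-1} + \alpha_t e_0 + \gamma\sqrt{\alpha_t}\,\epsilon,
\qquad \epsilon \sim \mathcal N(0, I),$$

with $\alpha_t = \beta_t - \beta_{t-1}$. Because the increments add, the
marginal at any step is available in closed form,

$$q(x_t \mid x^{HR}, x^{LR}) =
\mathcal N\!\big(x^{HR} + \beta_t e_0,\; \gamma^2\beta_t I\big),$$

so training never has to simulate the chain, and at $t = T$ (where
$\beta_T = 0.9999$) the state is statistically indistinguishable from the
LR image plus $\gamma^2$-scaled noise. The reverse transition follows
from multiplying the forward kernel with the marginal; for steps
$t_{hi} > t_{lo}$,

$$\mu = \frac{\beta_{t_{lo}}}{\beta_{t_{hi}}} x_{t_{hi}} +
\frac{\beta_{t_{hi}} - \beta_{t_{lo}}}{\beta_{t_{hi}}}\hat x_0,
\qquad
\Sigma = \gamma^2 \frac{(\beta_{t_{hi}} - \beta_{t_{lo}})\,
\beta_{t_{lo}}}{\beta_{t_{hi}}} I,$$

where $\hat x_0 = g_\varphi(x_{t_{hi}}, x^{LR}, t_{hi})$ is the
denoiser's estimate of the clean slice. Two properties make few-step
sampling work: the residual $e_0$ cancels out of the posterior (only
$x_t$ and $\hat x_0$ are needed at test time, when $x^{HR}$ is unknown),
and the expression is valid for *any* pair $t_{hi} > t_{lo}$, not just
adjacent steps. The adjacent-step case recovers the textbook posterior
exactly.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `T` | 15 | number of diffusion steps the model is trained on |
| `p` | 0.3 | growth exponent of the geometric schedule; smaller values front-load noise (unitless) |
| `gamma` | 2 | noise scale of the forward kernel, in units of image intensity (images are normalized to [0, 1]) |
| `kappa` | 0.04 | bound on the initial noise: $\gamma\sqrt{\beta_1} = \kappa$, keeping step 1 close to the clean image |
| `beta_T` | 0.9999 | terminal shift fraction; how completely the chain reaches the LR distribution |
| `lam` | 10 | weight of the $\ell_2$ fidelity term relative to the perceptual term |

The schedule builder pins $\beta_1 = (\kappa/\gamma)^2$ and $\beta_T$
exactly and fills the interior with the geometric formula
$\sqrt{\beta_t} = \sqrt{\beta_1}\exp[((t-1)/(T-1))^p
\ln\sqrt{\beta_T/\beta_1}]$; the sentinel $\beta_0 = 0$ makes the final
reverse step deterministic, which is the same convention as setting the
last noise draw to zero in the sampling loop.

```{r schedule}
sch <- srdiff_schedule()
round(sch$beta, 5)
```

## Few-step sampling: a design that had to be decided

The training schedule has 15 steps but sampling is advertised at 4. Two
non-distillation readings are possible: (a) subsample the trained grid
and use the generalized skip-step posterior above, or (b) rebuild the
schedule with $T = 4$. This package defaults to (a) — grid
`15 11 7 3 0` from `srdiff_step_grid()` — because it keeps the marginal
family the network was trained on and reduces exactly to the per-step
recursion when the grid is dense; (b) is available by passing a rebuilt
schedule. Under a perfect denoiser ($\hat x_0 \equiv x^{HR}$) and
suppressed noise, *any* valid grid returns $x^{HR}$ identically — an
induction over the posterior mean that the test suite checks to 1e-5 on
64×64 phantoms, and a useful canary for indexing errors.

One wording conflict in the model class is resolved on the side of the
algorithm: the terminal distribution is initialized with variance
$\gamma^2\beta_T$ (the sampling algorithm's line), not $\gamma^2$ (the
prose approximation); with $\beta_T = 0.9999$ the two differ negligibly.
Similarly, the summed per-step noise coefficients do not square to
$\gamma^2\beta_t$ term-by-term, but independent increment variances add,
so the closed-form marginal variance $\gamma^2\beta_t$ is the consistent
choice; the moment-matching test (iterated kernel vs marginal, $10^5$
scalar draws) confirms it.

## The denoiser

$g_\varphi$ is a U-shaped encoder–decoder in channels-last matrix layout:
$x_t$ and $x^{LR}$ enter concatenated along channels; each residual block
is layer-norm → SiLU → 3×3 convolution (reflection padding, so masked
backgrounds do not ring) with a per-block scale-and-shift injected from a
sinusoidal timestep embedding passed through a two-layer MLP; window
attention blocks (layer norm, windowed multi-head self-attention, layer
norm, MLP, each residually added) sit at the two coarsest resolutions,
and `use_swin = FALSE` removes them — the ablation arm. Windows are plain
(unshifted): with attention only at 16×16 and 8×8 feature maps the
receptive-field argument for shifted windows is weak, and the contract
(LN → window-MSA → LN → MLP) does not require them. The network predicts
a correction to $x^{LR}$ through a global residual connection, which is
the natural parameterization when the target is close to one of the
inputs.

Because no deep-learning framework is available to R here, the package
carries its own reverse-mode automatic differentiation engine: a linear
tape over dense-matrix ops (matmul, fused im2col convolution with a
sparse adjoint, fused layer norm, fused window attention, gathers for
up/down-sampling and broadcasts). Its gradients are verified in the test
suite against central differences at 25 randomly sampled parameters of a
small network to a relative error of 1e-4, and a gradient-flow test
asserts every parameter of both ablation arms receives a nonzero
gradient.

Presets: `"tiny"` (16 base channels, depth 2, window 4, ~165k parameters)
is the CPU desk-scale configuration used by all tests; `"paper"` (64 base
channels, depth 4, window 8) mirrors the conventional full-scale shape.
The published architecture's exact layer counts are not public, so the
presets are conventions, and in-package comparisons (with/without
attention) hold everything else fixed.

## Training

Training follows the standard recipe: per sample, draw
$t \sim U\{1..T\}$, corrupt through the closed-form marginal with fresh
noise, predict $\hat x_0$, and minimize
$\lambda\,\mathrm{MSE} + \ell_p$ with $\lambda$ on the fidelity term. The
MSE uses a pixel-mean reduction so $\lambda$ is comparable across image
sizes. The perceptual term $\ell_p$ is a pluggable contract: the default
for tests is the null function; the built-in no-download option is a
multi-scale Prewitt gradient-magnitude distance; an adapter for a
pretrained feature-space metric can be plugged in where downloads are
possible. The optimizer is rectified Adam, with plain Adam behind a
config switch; the learning rate ramps linearly over the warm-up and
then decays along a half cosine to zero. Gradient clipping and weight
averaging are available but off by default.

Determinism is a first-class contract: every per-step draw (batch
indices, timesteps, noise) derives from a counter-based substream of one
master seed, so loss traces and sampled outputs are bit-reproducible and
a checkpoint resumes identically to the uninterrupted run — both are
asserted in the tests.

Full-scale reference settings are batch 16, learning rate in
2e-5–5e-5, 5000 warm-up steps, and order-1e5 total steps. The tiny
preset deliberately departs (batch 8, lr 1e-3, warm-up 80, 800 steps) —
at 165k parameters and 32×32 slices, desk-scale optimization is a
different regime, and these values were fixed from a step-time budget
before the acceptance checks were run, not tuned against them.

## Synthetic phantoms: what they do and do not show

`make_phantom()` emulates the *geometry* of skull-stripped, masked MRI
slices: an outer ellipse with exact-zero background, nested elliptical
compartments (piecewise-smooth anatomy), 1–2 px curvilinear features
(vessel-like), small bright or dark lesions, a smooth multiplicative
bias field, and additive Gaussian noise, all clipped to [0, 1] and
re-masked. The LR counterpart applies the same degradation protocol as
the full-scale pipeline: per-axis downsampling in image space (linear,
no anti-alias prefilter, matching the default of the standard resampling
tool; a Gaussian presmooth is available as a switch) followed by
nearest-neighbour pre-upsampling back onto the exact original grid.
Presets: isotropic 4×4×4 (0.8 mm → 3.2 mm) and spacing-driven ≈3×3×2
(0.66 mm → 2 mm in-plane, 1.5 mm → 3 mm through-plane).

What passing tests on phantoms demonstrate: the forward/reverse algebra,
the trainability of the denoiser, the few-step-equals-many-step property
at desk scale, and the end-to-end plumbing. What they do not demonstrate:
performance on real anatomy and scanner physics — phantoms have no
k-space sampling, no Rician noise, no coil shading beyond the polynomial
bias, no inter-slice anatomy, and far less texture than tissue. Absolute
metric values on phantoms are not comparable to clinical numbers.

A measurement note: the spectral signature of this degradation depends on
what dominates the high band. On full-field textures the LR volume keeps
less than half the HR energy above the decimated Nyquist; on masked
phantoms the mask-edge discontinuity survives nearest-neighbour
re-gridding, so the reduction is real but milder. The tests assert the
sharp bound on textures and monotone reduction on masked anatomy.

## Metrics

PSNR, SSIM and GMSD are implemented from their defining formulas: SSIM
with the original constants ($K_1 = 0.01$, $K_2 = 0.03$, 11×11 Gaussian
window, $\sigma = 1.5$, population covariance, mean over valid windows) —
cross-checked against an independent reference implementation to 1e-9 on
frozen seeded images; GMSD with 1/3-normalized Prewitt gradients, the
published 2× average-pool preprocessing and $c = 170/255^2$ on the [0, 1]
range, cross-checked against a from-scratch loop implementation to 1e-6.
Identical inputs give SSIM 1 and GMSD 0 exactly; PSNR's infinity at zero
MSE is reported as the machine-epsilon-capped sentinel
$10\log_{10}(R^2/\epsilon) \approx 156.5$ dB so aggregates stay finite.
The perceptual column is pluggable and defaults to absent; the built-in
gradient-magnitude distance requires no pretrained weights.

## Numerical choices and degenerate inputs

* Schedules are computed in double precision; the endpoints are assigned
  exactly rather than through the exponential formula.
* `posterior_params()` at $t_{lo} = 0$ returns variance 0 identically —
  the deterministic final step — rather than relying on floating-point
  cancellation.
* Degradation factors that exceed a dimension raise an error; constant
  volumes are exact fixed points of degrade-then-upsample (interpolation
  weights sum to 1 by construction).
* `normalize_volume()` clips to the [0.5, 99.5] percentile range before
  min–max scaling and warns (returning zeros) on constant masked
  regions; the inverse transform restores unclipped voxels exactly.
* Non-finite training losses abort with the drawn timesteps in the
  message rather than silently propagating NaNs.

## Problem sizes used by the checks

The acceptance-style checks run, on one CPU: schedule verification
against a 40-digit reference (instant); $10^5$-draw moment matching at
$t \in \{1, 7, 15\}$; a discretized-Bayes posterior oracle over all
adjacent pairs plus the 4-step grid's skip pairs; perfect-denoiser
inversion on a 64×64 phantom; and the end-to-end experiment — 200
training phantoms at 32×32 with factor-4 degradation, 800 optimizer
steps at batch 8, then 4-step and 15-step restoration of 20 held-out
slices. These sizes are the package's desk-scale study conditions; the
end-to-end run takes a few minutes.

## Known limitations

* Strictly 2D per-slice processing; volumetric consistency across slices
  is out of scope, as in the model class this package implements.
* The R-native training loop is appropriate for desk-scale studies, not
  for full-resolution clinical training runs.
* Pretrained feature-space perceptual metrics are adapter-only (they
  require downloads); the built-in perceptual distance is
  gradient-based.
* Phantoms do not model scanner physics (see above), so conclusions
  about real data require real data.
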