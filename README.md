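# srdiff — residual-shifting diffusion for MRI super-resolution

`srdiff` fits and applies residual-error-shifting diffusion models for
paired-image super-resolution of MRI slices. Conventional diffusion models
corrupt an image all the way to white noise and then walk back over
hundreds of steps; for super-resolution that is wasteful, because the
low-resolution (LR) image already sits close to the high-resolution (HR)
target. `srdiff` instead builds a short Markov chain that shifts the HR
slice *toward its own LR counterpart*, so the reverse process only has to
undo the degradation — and can do so in as few as **four** sampling steps.

The package is aimed at methods researchers in medical image analysis who
want a fully inspectable, CPU-runnable implementation of this model class:
every component — the noise schedule, forward and reverse kernels, the
U-net denoiser with window attention, its training loop, the degradation
protocol, and the image-quality metrics — is implemented natively in R and
tested against independent oracles. A seeded synthetic phantom generator
stands in for clinical data, so the whole pipeline runs without any
external dataset.

## The model

With residual $e_0 = x^{LR} - x^{HR}$, the forward process over
$t = 1,\dots,T$ is

$$q(x_t \mid x_{t-1}, x^{LR}) = \mathcal N\!\big(x_{t-1} + \alpha_t e_0,\;
\gamma^2 \alpha_t I\big),$$

where $\alpha_t = \beta_t - \beta_{t-1}$ and $\{\beta_t\}$ is a monotone
schedule with $\beta_1 = (\kappa/\gamma)^2 \to 0$ and
$\beta_T = 0.9999 \to 1$. The increments telescope, giving the closed-form
marginal

$$q(x_t \mid x^{HR}, x^{LR}) = \mathcal N\!\big(x^{HR} + \beta_t e_0,\;
\gamma^2 \beta_t I\big),$$

so at $t = T$ the chain has essentially *become* the LR image plus noise.
$\sqrt{\beta_t}$ follows a geometric (log-linear in $((t-1)/(T-1))^p$)
schedule; defaults are $T = 15$, $p = 0.3$, $\gamma = 2$,
$\kappa = 0.04$.

A network $g_\varphi(x_t, x^{LR}, t) \to \hat x_0$ (U-net with
window-attention blocks; channel concatenation of $x_t$ and $x^{LR}$;
sinusoidal timestep embedding) is trained with

$$\mathcal L_\varphi = \lambda\,\lVert g_\varphi - x^{HR}\rVert_2^2 +
\ell_p(g_\varphi, x^{HR}), \qquad \lambda = 10,$$

and sampling runs the Gaussian posterior

$$\mu = \tfrac{\beta_{t_{lo}}}{\beta_{t_{hi}}}\,x_t +
\tfrac{\beta_{t_{hi}}-\beta_{t_{lo}}}{\beta_{t_{hi}}}\,\hat x_0,\qquad
\Sigma = \gamma^2\,\tfrac{(\beta_{t_{hi}}-\beta_{t_{lo}})\,\beta_{t_{lo}}}
{\beta_{t_{hi}}}\,I$$

along a strictly decreasing step grid from $T$ to $0$ — the generalized
(skip-step) form lets a model trained with $T = 15$ sample in 4 steps
(grid `15 11 7 3 0`). Because $\beta_0 = 0$, the final step is
deterministic.

The denoiser and its training loop run on a small reverse-mode automatic
differentiation engine written in R (BLAS matmuls, fused im2col
convolutions, fused layer norm and window attention), with gradients
verified against central differences in the test suite. The optimizer is
rectified Adam (plain Adam behind a switch).

## Worked example

Generate seeded phantoms (masked slices with nested ellipses, thin
curvilinear features and small lesions), degrade them with the factor-4
protocol, fit the model, and score 4-step restorations:

```r
library(srdiff)

sch <- srdiff_schedule()
sch
#> Residual-shift schedule: T = 15, p = 0.3, gamma = 2, kappa = 0.04
#>   beta_1 = 0.0004, beta_T = 0.9999, sum(alpha) = 0.9999

ds <- make_dataset(60, phantom_spec(size = 32, factors = c(4, 4)),
                   fractions = c(50/60, 0, 10/60), master_seed = 7)
fit <- res_srdiff(ds$train,
                  control = train_config(total_steps = 200, batch_size = 8,
                                         lr_init = 1e-3, warmup_steps = 20,
                                         seed = 1))
fit
#> Residual-shifting diffusion super-resolution model
#>   schedule: T = 15, p = 0.3, gamma = 2
#> srdiff denoiser (tiny preset): depth 2, base width 16, window attention, 164673 parameters
#>   trained 200 steps on 50 slices; final loss 0.22438

sr <- predict(fit, ds$test, steps = 4, seed = 1)
evaluate_pairs(Map(function(r, p) list(restored = r, hr = p$x_hr),
                   sr, ds$test),
               metric_config(perceptual = "gm"))
#> Metric report over 10 pairs (mean +/- sd):
#>   psnr_db     17.1372 +/- 1.3499
#>   ssim         0.4796 +/- 0.0748
#>   gmsd         0.1702 +/- 0.0206
#>   perceptual   0.0293 +/- 0.0090
```

For reference, the LR inputs themselves score 16.56 dB PSNR and 0.235
GMSD against the same targets, so even this 200-step demonstration fit
gains +0.58 dB and cuts the gradient-similarity deviation by a quarter;
the full desk-scale run (800 steps, below) gains about +1.5 dB. Higher
PSNR/SSIM and lower GMSD/perceptual are better. `summary()`, `coef()`,
`plot()` (loss and learning-rate traces), `residuals()` and `simulate()`
(forward-process draws) complete the fitted-model interface.

A command-line front end over the same pipeline lives in
`inst/cli/res-srdiff.R`:

```sh
Rscript inst/cli/res-srdiff.R phantom --config cfg.yaml
Rscript inst/cli/res-srdiff.R train   --config cfg.yaml
Rscript inst/cli/res-srdiff.R sample  --config cfg.yaml --set sample.steps=4
Rscript inst/cli/res-srdiff.R eval    --config cfg.yaml
```

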