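#' Geometric residual-shift noise schedule
#'
#' Builds the monotone shift sequence \eqn{\beta_1 \dots \beta_T} that drives
#' the residual-shifting forward diffusion, together with its first
#' differences \eqn{\alpha_t = \beta_t - \beta_{t-1}}. The square root of
#' \eqn{\beta_t} grows geometrically (log-linear in \eqn{((t-1)/(T-1))^p})
#' from \eqn{\sqrt{\beta_1} = \kappa/\gamma} to \eqn{\sqrt{\beta_T}}. A
#' sentinel \eqn{\beta_0 = 0} is prepended so that the final reverse step is
#' deterministic.
#'
#' The defaults are the values used throughout: 15 training steps, growth
#' exponent \eqn{p = 0.3}, noise scale \eqn{\gamma = 2}, initial-noise bound
#' \eqn{\kappa = 0.04} (so \eqn{\beta_1 = (\kappa/\gamma)^2 = 4\times10^{-4}}),
#' and terminal value \eqn{\beta_T = 0.9999}. Endpoints are assigned exactly;
#' interior values follow the geometric formula. Schedules are computed in
#' double precision.
#'
#' @param T integer number of diffusion steps (at least 2).
#' @param p growth-rate exponent (> 0); smaller values front-load the noise.
#' @param gamma noise scale \eqn{\gamma} of the forward kernel (> 0).
#' @param kappa initial-noise bound \eqn{\kappa}; \eqn{\gamma\sqrt{\beta_1}}
#'   equals \eqn{\kappa} and must be small.
#' @param beta_T terminal cumulative shift fraction, in
#'   \eqn{((\kappa/\gamma)^2, 1]}.
#' @return An object of class `srdiff_schedule`: a list with elements `T`,
#'   `p`, `gamma`, `kappa`, `beta_T`, `beta` (length `T + 1`, starting at the
#'   \eqn{\beta_0 = 0} sentinel) and `alpha` (length `T`).
#' @examples
#' sch <- srdiff_schedule()
#' sch$beta[2]          # beta_1 = (0.04 / 2)^2 = 4e-4
#' sum(sch$alpha)       # conserves beta_T
#' @export
srdiff_schedule <- function(T = 15L, p = 0.3, gamma = 2, kappa = 0.04,
                            beta_T = 0.9999) {
  T <- as.integer(T)
  if (is.na(T) || T < 2L)
    stop("invalid schedule configuration: 'T' must be an integer >= 2")
  if (!is.finite(p) || p <= 0)
    stop("invalid schedule configuration: 'p' must be > 0")
  if (!is.finite(gamma) || gamma <= 0)
    stop("invalid schedule configuration: 'gamma' must be > 0")
  beta1 <- (kappa / gamma)^2
  if (!is.finite(beta1) || beta1 <= 0)
    stop("invalid schedule configuration: 'kappa' must give (kappa/gamma)^2 > 0")
  if (!is.finite(beta_T) || beta_T <= beta1 || beta_T > 1)
    stop("invalid schedule configuration: 'beta_T' must lie in ((kappa/gamma)^2, 1]")

  t <- seq_len(T)
  sqrt_beta <- sqrt(beta1) *
    exp(((t - 1) / (T - 1))^p * log(sqrt(beta_T / beta1)))
  beta <- sqrt_beta^2
  beta[1L] <- beta1        # endpoints exact
  beta[T]  <- beta_T
  alpha <- diff(c(0, beta))
  structure(
    list(T = T, p = p, gamma = gamma, kappa = kappa, beta_T = beta_T,
         beta = c(0, beta), alpha = alpha),
    class = "srdiff_schedule"
  )
}

#' @exportS3Method print srdiff_schedule
print.srdiff_schedule <- function(x, ...) {
  cat(sprintf(
    "Residual-shift schedule: T = %d, p = %g, gamma = %g, kappa = %g\n",
    x$T, x$p, x$gamma, x$kappa))
  cat(sprintf("  beta_1 = %.6g, beta_T = %.6g, sum(alpha) = %.6g\n",
              x$beta[2L], x$beta_T, sum(x$alpha)))
  invisible(x)
}

## beta_t with the beta_0 = 0 sentinel; t may be a vector in [0, T]
sched_beta <- function(sched, t) sched$beta[t + 1L]

check_step <- function(sched, t) {
  if (length(t) != 1L || is.na(t) || t != round(t) || t < 1L || t > sched$T)
    stop(sprintf("timestep t = %s out of range [1, %d]", format(t), sched$T))
  as.integer(t)
}

#' Paired high-/low-resolution sample
#'
#' Bundles a high-resolution slice with its low-resolution counterpart
#' (already pre-upsampled to the identical pixel grid) and an optional
#' binary foreground mask. The residual \eqn{e_0 = x^{LR} - x^{HR}} drives
#' the forward diffusion.
#'
#' @param x_hr numeric matrix, high-resolution image with intensities in
#'   \[0, 1\].
#' @param x_lr numeric matrix of the same dimension, pre-upsampled
#'   low-resolution image.
#' @param mask optional logical/0-1 matrix of the same dimension marking
#'   foreground pixels.
#' @return An object of class `srdiff_pair` with elements `x_hr`, `x_lr`,
#'   `mask` and the residual `e0`.
#' @export
srdiff_pair <- function(x_hr, x_lr, mask = NULL) {
  x_hr <- as.matrix(x_hr); x_lr <- as.matrix(x_lr)
  if (!identical(dim(x_hr), dim(x_lr)))
    stop("x_hr and x_lr must share an identical pixel grid")
  e0 <- x_lr - x_hr
  if (!all(is.finite(e0)))
    stop("residual e0 = x_lr - x_hr contains non-finite values")
  if (!is.null(mask)) {
    mask <- as.matrix(mask) != 0
    if (!identical(dim(mask), dim(x_hr)))
      stop("mask must share the pair's pixel grid")
  }
  structure(list(x_hr = x_hr, x_lr = x_lr, e0 = e0, mask = mask),
            class = "srdiff_pair")
}

#' @exportS3Method print srdiff_pair
print.srdiff_pair <- function(x, ...) {
  cat(sprintf("HR/LR pair: %d x %d, residual range [%.4g, %.4g]\n",
              nrow(x$x_hr), ncol(x$x_hr), min(x$e0), max(x$e0)))
  invisible(x)
}

srdiff_state <- function(x, t) {
  structure(list(x = x, t = as.integer(t)), class = "srdiff_state")
}

#' One forward diffusion step
#'
#' Applies the Markov transition kernel of the residual-shifting forward
#' process: \eqn{x_t = x_{t-1} + \alpha_t e_0 + \gamma\sqrt{\alpha_t}\,
#' \epsilon}.
#'
#' @param x_prev image at step `t - 1`.
#' @param e0 residual image \eqn{x^{LR} - x^{HR}}.
#' @param sched an [srdiff_schedule()].
#' @param t target step, in `[1, T]`.
#' @param noise unit-normal noise image (same shape); pass 0 for the
#'   deterministic drift.
#' @return The image at step `t`.
#' @export
forward_step <- function(x_prev, e0, sched, t, noise) {
  t <- check_step(sched, t)
  a <- sched$alpha[t]
  x_prev + a * e0 + sched$gamma * sqrt(a) * noise
}

#' Closed-form forward marginal
#'
#' Draws \eqn{x_t} directly from the marginal
#' \eqn{q(x_t \mid x^{HR}, x^{LR}) = N(x^{HR} + \beta_t e_0,
#' \gamma^2 \beta_t I)} rather than iterating [forward_step()].
#'
#' @param pair an [srdiff_pair()].
#' @inheritParams forward_step
#' @return An `srdiff_state` carrying the diffused image and `t`.
#' @export
forward_marginal <- function(pair, sched, t, noise) {
  t <- check_step(sched, t)
  b <- sched_beta(sched, t)
  srdiff_state(pair$x_hr + b * pair$e0 + sched$gamma * sqrt(b) * noise, t)
}

#' Reverse-process posterior parameters
#'
#' Mean and variance of the Gaussian posterior
#' \eqn{q(x_{t_{lo}} \mid x_{t_{hi}}, x_0)} of the residual-shifting chain.
#' For adjacent steps (`t_lo = t_hi - 1`) this is the textbook product of
#' the transition kernel and the marginal:
#' \eqn{\mu_q = (\beta_{t-1}/\beta_t) x_t + (\alpha_t/\beta_t) x_0},
#' \eqn{\Sigma_q = \gamma^2 \alpha_t \beta_{t-1}/\beta_t}. The generalized
#' (skip-step) form replaces \eqn{\alpha_t} with
#' \eqn{\beta_{t_{hi}} - \beta_{t_{lo}}} and \eqn{\beta_{t-1}} with
#' \eqn{\beta_{t_{lo}}}; the residual \eqn{e_0} cancels algebraically, so
#' only \eqn{x_t} and the denoiser estimate \eqn{\hat{x}_0} are needed.
#' With \eqn{\beta_0 = 0} the final step collapses to \eqn{\hat{x}_0}
#' exactly (variance 0).
#'
#' @param x_t image at step `t_hi`.
#' @param x0_hat estimate of the clean high-resolution image.
#' @param sched an [srdiff_schedule()].
#' @param t_hi,t_lo source and target steps, `0 <= t_lo < t_hi <= T`.
#' @return A list with `mean` (image) and `var` (scalar).
#' @export
posterior_params <- function(x_t, x0_hat, sched, t_hi, t_lo) {
  if (t_lo >= t_hi) stop("posterior requires t_lo < t_hi")
  t_hi <- check_step(sched, t_hi)
  if (t_lo < 0L || t_lo != round(t_lo)) stop("t_lo must be an integer >= 0")
  b_hi <- sched_beta(sched, t_hi)
  b_lo <- sched_beta(sched, as.integer(t_lo))
  w <- b_lo / b_hi
  list(mean = w * x_t + (1 - w) * x0_hat,
       var  = sched$gamma^2 * (b_hi - b_lo) * b_lo / b_hi)
}

#' Initialize reverse sampling
#'
#' First line of the sampling algorithm:
#' \eqn{x_T = x^{LR} + \gamma\sqrt{\beta_T}\,\epsilon}.
#'
#' @param x_lr pre-upsampled low-resolution image.
#' @param sched an [srdiff_schedule()].
#' @param noise unit-normal noise image (or 0).
#' @return An `srdiff_state` at `t = T`.
#' @export
init_sample <- function(x_lr, sched, noise) {
  srdiff_state(x_lr + sched$gamma * sqrt(sched$beta_T) * noise, sched$T)
}

#' One reverse sampling step
#'
#' Draws \eqn{x_{t_{lo}} = \mu + \sqrt{\Sigma}\,\epsilon} with
#' \eqn{(\mu, \Sigma)} from [posterior_params()]. At `t_lo = 0` the variance
#' is zero, so the noise contributes nothing and the step returns the
#' denoiser estimate.
#'
#' @param state an `srdiff_state` at some step `t_hi > t_lo`.
#' @param x0_hat denoiser estimate of the clean image.
#' @param sched an [srdiff_schedule()].
#' @param t_lo target step (`0 <= t_lo < state$t`).
#' @param noise unit-normal noise image (or 0).
#' @return An `srdiff_state` at `t_lo`.
#' @export
reverse_step <- function(state, x0_hat, sched, t_lo, noise) {
  if (t_lo >= state$t) stop("reverse step requires t_lo < current state t")
  pp <- posterior_params(state$x, x0_hat, sched, state$t, t_lo)
  srdiff_state(pp$mean + sqrt(pp$var) * noise, t_lo)
}

#' Default sampling step grid
#'
#' Evenly spaced subsequence of the training grid, anchored at `T` and
#' terminating at 0, used for few-step sampling.
#'
#' @param sched an [srdiff_schedule()].
#' @param n_steps number of reverse transitions (grid has `n_steps + 1`
#'   entries counting the terminal 0).
#' @return Integer vector, strictly decreasing from `T` to 0.
#' @examples
#' srdiff_step_grid(srdiff_schedule(), 4)   # 15 11 7 3 0
#' @export
srdiff_step_grid <- function(sched, n_steps = 4L) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L || n_steps > sched$T)
    stop("n_steps must be in [1, T]")
  g <- unique(c(floor(seq(sched$T, sched$T / n_steps, length.out = n_steps)), 0L))
  as.integer(g)
}

check_grid <- function(sched, step_grid) {
  g <- as.integer(step_grid)
  if (g[1L] != sched$T || g[length(g)] != 0L)
    stop("step grid must start at T and end at 0")
  if (any(diff(g) >= 0)) stop("step grid must be strictly decreasing")
  g
}

#' Reverse-process sampler
#'
#' Runs the full reverse recursion: initializes at
#' \eqn{x_T = x^{LR} + \gamma\sqrt{\beta_T}\epsilon}, then for each
#' consecutive pair of `step_grid` calls the denoiser for \eqn{\hat{x}_0}
#' and applies [reverse_step()]. With the default 15-step schedule and a
#' 4-transition grid this restores a slice in four denoiser calls.
#'
#' @param x_lr pre-upsampled low-resolution image (matrix).
#' @param denoiser an `srdiff_denoiser` contract (see [build_denoiser()]),
#'   or any function `(x_t, x_lr, t) -> x0_hat` (e.g. an oracle in tests).
#' @param sched an [srdiff_schedule()].
#' @param step_grid strictly decreasing integer grid from `T` to 0; default
#'   [srdiff_step_grid()] with 4 transitions.
#' @param seed integer seed; the trajectory draws fresh unit-normal noise at
#'   every step through a counter-based substream, so identical seeds give
#'   bit-identical outputs.
#' @param noise_free logical; if `TRUE` all noise draws are suppressed
#'   (deterministic mean trajectory).
#' @return The restored image (matrix).
#' @export
srdiff_sample <- function(x_lr, denoiser, sched,
                          step_grid = srdiff_step_grid(sched),
                          seed = 1L, noise_free = FALSE) {
  g <- check_grid(sched, step_grid)
  predict_fn <- denoiser_fn(denoiser)
  dm <- dim(x_lr)
  draw <- function(k) {
    if (noise_free) return(0)
    set.seed(srdiff_substream(seed, k))
    matrix(stats::rnorm(prod(dm)), dm[1L], dm[2L])
  }
  state <- init_sample(x_lr, sched, draw(0L))
  for (k in seq_len(length(g) - 1L)) {
    x0_hat <- predict_fn(state$x, x_lr, state$t)
    state <- reverse_step(state, x0_hat, sched, g[k + 1L], draw(k))
  }
  state$x
}

## Extracts the predict function from a denoiser contract or bare function.
denoiser_fn <- function(denoiser) {
  if (is.function(denoiser)) return(denoiser)
  if (!is.null(denoiser$predict)) return(denoiser$predict)
  stop("'denoiser' must be a function or an srdiff_denoiser contract")
}

#' Counter-based seed substream
#'
#' Derives a deterministic per-step seed below 2^31 from a master seed and a
#' counter, so a single seed controls a whole trajectory while each step
#' still gets an independent stream.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer counter.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
srdiff_substream <- function(seed, counter) {
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + as.double(counter) * 16807 + 1) %% 2147483647
  as.integer(s %% 2147483645) + 1L
}

#' Write / read a schedule manifest
#'
#' Plain-text key-value dump of the hyper-parameters and the full beta
#' sequence, for reproducibility manifests. `read_schedule()` rebuilds the
#' schedule from the stored hyper-parameters and verifies the stored betas.
#'
#' @param sched an [srdiff_schedule()].
#' @param path file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the schedule.
#' @export
write_schedule <- function(sched, path) {
  lines <- c(
    sprintf("T: %d", sched$T),
    sprintf("p: %.17g", sched$p),
    sprintf("gamma: %.17g", sched$gamma),
    sprintf("kappa: %.17g", sched$kappa),
    sprintf("beta_T: %.17g", sched$beta_T),
    sprintf("beta: %s", paste(sprintf("%.17g", sched$beta), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  sched <- srdiff_schedule(T = as.integer(vals[["T"]]),
                           p = as.numeric(vals[["p"]]),
                           gamma = as.numeric(vals[["gamma"]]),
                           kappa = as.numeric(vals[["kappa"]]),
                           beta_T = as.numeric(vals[["beta_T"]]))
  stored <- as.numeric(strsplit(vals[["beta"]], " ", fixed = TRUE)[[1L]])
  if (max(abs(stored - sched$beta)) > 1e-12)
    stop("stored beta sequence disagrees with rebuilt schedule")
  sched
}
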