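#' Fit a residual-shifting diffusion super-resolution model
#'
#' The main entry point. Trains the conditional denoiser
#' \eqn{g_\varphi(x_t, x^{LR}, t) \to \hat{x}_0} on a collection of paired
#' high-/low-resolution slices under the residual-shifting forward process:
#' each training slice is corrupted to a uniformly drawn step of the
#' geometric schedule via the closed-form marginal
#' \eqn{x_t = x^{HR} + \beta_t e_0 + \gamma\sqrt{\beta_t}\epsilon}, and the
#' network is optimized to recover the clean slice under the
#' \eqn{\lambda}-weighted fidelity + perceptual objective. Restoration then
#' runs the learned reverse process in as few as four steps (see
#' [predict.res_srdiff()]).
#'
#' @param data list of [srdiff_pair()] training slices, e.g. the `train`
#'   split of [make_dataset()].
#' @param schedule an [srdiff_schedule()]; the default is the 15-step
#'   geometric schedule with \eqn{p = 0.3}, \eqn{\gamma = 2},
#'   \eqn{\kappa = 0.04}, \eqn{\beta_T = 0.9999}.
#' @param denoiser a [denoiser_config()] or a pre-built
#'   [build_denoiser()] contract (e.g. to resume or to fix an ablation
#'   arm's initialization).
#' @param loss a [loss_config()].
#' @param control a [train_config()].
#' @param keep_data keep the training data in the fitted object (needed by
#'   [residuals.res_srdiff()] and [simulate.res_srdiff()] without
#'   `newdata`).
#' @param verbose print training progress.
#' @return An object of class `res_srdiff` with components `denoiser`,
#'   `schedule`, `loss_cfg`, `control`, `trace` (per-step loss), `lr`, and
#'   (optionally) `data`.
#' @examples
#' \donttest{
#' ds <- make_dataset(12, phantom_spec(size = 32), master_seed = 7)
#' fit <- res_srdiff(ds$train,
#'                   control = train_config(total_steps = 5, warmup_steps = 2,
#'                                          batch_size = 2))
#' sr <- predict(fit, ds$test[[1]]$x_lr, steps = 4, seed = 1)
#' }
#' @export
res_srdiff <- function(data,
                       schedule = srdiff_schedule(),
                       denoiser = denoiser_config("tiny"),
                       loss = loss_config(),
                       control = train_config(),
                       keep_data = TRUE,
                       verbose = FALSE) {
  cl <- match.call()
  den <- if (inherits(denoiser, "srdiff_denoiser")) denoiser
         else build_denoiser(denoiser, seed = control$seed)
  run <- srdiff_fit(data, den, schedule, loss, control, verbose = verbose)
  structure(list(denoiser = run$denoiser, schedule = schedule,
                 loss_cfg = loss, control = control,
                 trace = run$trace, lr = run$lr,
                 opt_state = run$opt_state,
                 data = if (keep_data) data else NULL,
                 n_train = length(data), call = cl),
            class = "res_srdiff")
}

#' @exportS3Method print res_srdiff
print.res_srdiff <- function(x, ...) {
  cat("Residual-shifting diffusion super-resolution model\n")
  cat(sprintf("  schedule: T = %d, p = %g, gamma = %g\n",
              x$schedule$T, x$schedule$p, x$schedule$gamma))
  print(x$denoiser)
  n <- length(x$trace)
  if (n > 0L)
    cat(sprintf("  trained %d steps on %d slices; final loss %.5f\n",
                n, x$n_train, x$trace[n]))
  invisible(x)
}

#' @exportS3Method summary res_srdiff
summary.res_srdiff <- function(object, ...) {
  n <- length(object$trace)
  k <- min(100L, max(1L, n %/% 2L))
  s <- list(
    schedule = object$schedule,
    param_count = object$denoiser$param_count,
    use_swin = object$denoiser$cfg$use_swin,
    n_train = object$n_train,
    total_steps = n,
    loss_head = if (n) mean(object$trace[seq_len(k)]) else NA_real_,
    loss_tail = if (n) mean(object$trace[seq.int(n - k + 1L, n)]) else NA_real_,
    lam = object$loss_cfg$lam)
  class(s) <- "summary.res_srdiff"
  s
}

#' @exportS3Method print summary.res_srdiff
print.summary.res_srdiff <- function(x, ...) {
  cat("Residual-shifting diffusion SR model\n")
  cat(sprintf("  denoiser: %d parameters (%s)\n", x$param_count,
              if (x$use_swin) "with window attention" else "ablation, no attention"))
  cat(sprintf("  schedule: T = %d, p = %g, gamma = %g, beta_T = %g\n",
              x$schedule$T, x$schedule$p, x$schedule$gamma, x$schedule$beta_T))
  cat(sprintf("  training: %d steps on %d slices, lambda = %g\n",
              x$total_steps, x$n_train, x$lam))
  if (x$total_steps > 0)
    cat(sprintf("  loss: leading mean %.5f -> trailing mean %.5f\n",
                x$loss_head, x$loss_tail))
  invisible(x)
}

#' @export
coef.res_srdiff <- function(object, ...) {
  P <- object$denoiser$params
  stats::setNames(flatten_params(P),
                  rep(names(P), vapply(P, length, 0L)))
}

#' Restore high resolution from low-resolution slices
#'
#' Runs the learned reverse process: initializes at
#' \eqn{x_T = x^{LR} + \gamma\sqrt{\beta_T}\epsilon} and walks a strictly
#' decreasing step grid down to 0, calling the fitted denoiser at each
#' visited step. The default grid has four transitions — the few-step
#' sampling regime; `steps = object$schedule$T` gives the full per-step
#' recursion.
#'
#' @param object a fitted [res_srdiff()] model.
#' @param newdata an [srdiff_pair()], a list of pairs, a matrix (the
#'   pre-upsampled LR slice), or a list of matrices. Defaults to the
#'   training data.
#' @param steps number of reverse transitions (default 4).
#' @param step_grid explicit strictly decreasing grid from `T` to 0
#'   (overrides `steps`).
#' @param seed integer seed for the sampling noise.
#' @param noise_free suppress all sampling noise (deterministic mean
#'   trajectory).
#' @param ... unused.
#' @return A restored image matrix, or a list of them when `newdata` holds
#'   several slices.
#' @export
predict.res_srdiff <- function(object, newdata = NULL, steps = 4L,
                               step_grid = NULL, seed = 1L,
                               noise_free = FALSE, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata)) stop("no newdata and the model kept no training data")
  single <- FALSE
  if (inherits(newdata, "srdiff_pair") || is.matrix(newdata)) {
    newdata <- list(newdata)
    single <- TRUE
  }
  grid <- if (!is.null(step_grid)) step_grid
          else srdiff_step_grid(object$schedule, steps)
  out <- lapply(seq_along(newdata), function(i) {
    item <- newdata[[i]]
    x_lr <- if (inherits(item, "srdiff_pair")) item$x_lr else as.matrix(item)
    srdiff_sample(x_lr, object$denoiser, object$schedule, grid,
                  seed = srdiff_substream(seed, i), noise_free = noise_free)
  })
  if (single) out[[1L]] else out
}

#' Restoration residuals
#'
#' Difference between the restored slice and the high-resolution reference
#' for each pair.
#'
#' @param object a fitted [res_srdiff()] model.
#' @param newdata list of [srdiff_pair()] (default: training data).
#' @param ... passed to [predict.res_srdiff()].
#' @return List of residual matrices.
#' @export
residuals.res_srdiff <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata)) stop("no newdata and the model kept no training data")
  if (inherits(newdata, "srdiff_pair")) newdata <- list(newdata)
  restored <- predict(object, newdata, ...)
  lapply(seq_along(newdata), function(i) restored[[i]] - newdata[[i]]$x_hr)
}

#' Simulate the forward diffusion
#'
#' Draws from the closed-form forward marginal
#' \eqn{N(x^{HR} + \beta_t e_0, \gamma^2\beta_t I)} of the fitted
#' schedule — the corruption the model was trained to invert.
#'
#' @param object a fitted [res_srdiff()] model.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param pair an [srdiff_pair()] (default: first kept training pair).
#' @param t timestep (default `T`).
#' @param ... unused.
#' @return List of `nsim` diffused image matrices.
#' @export
simulate.res_srdiff <- function(object, nsim = 1, seed = 1L, pair = NULL,
                                t = NULL, ...) {
  if (is.null(pair)) pair <- object$data[[1L]]
  if (is.null(pair)) stop("no pair supplied and the model kept no training data")
  if (is.null(t)) t <- object$schedule$T
  dm <- dim(pair$x_hr)
  lapply(seq_len(nsim), function(k) {
    set.seed(srdiff_substream(seed, k))
    noise <- matrix(stats::rnorm(prod(dm)), dm[1L], dm[2L])
    forward_marginal(pair, object$schedule, t, noise)$x
  })
}

#' Plot training diagnostics
#'
#' Loss trace (log scale) and the warm-up + cosine learning-rate schedule.
#'
#' @param x a fitted [res_srdiff()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.res_srdiff <- function(x, ...) {
  if (length(x$trace) == 0L) {
    warning("no training steps to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trace, type = "l", log = "y", xlab = "step",
                 ylab = "training loss", main = "loss trace", ...)
  graphics::plot(x$lr, type = "l", xlab = "step", ylab = "learning rate",
                 main = "lr schedule")
  invisible(x)
}
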