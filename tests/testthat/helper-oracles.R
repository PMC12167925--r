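## Shared independent oracles and small fixtures, built in code.

## Reference beta sequence for the default schedule (T = 15, p = 0.3,
## gamma = 2, kappa = 0.04, beta_T = 0.9999), evaluated from the geometric
## formula with a 40-digit arbitrary-precision calculator and frozen here.
BETA_REF_DEFAULT <- c(
  0.0004,
  0.0138526166947238088,
  0.0314320082244388175,
  0.0552745157178203469,
  0.0861912028729629977,
  0.125030267860916928,
  0.172695675524535794,
  0.230149284253230831,
  0.298411803757668004,
  0.378563975805432679,
  0.47174804684387146,
  0.579169462657137767,
  0.70209872363983037,
  0.841873359823476333,
  0.9999)

## Discretized-Bayes numerical posterior oracle for scalar instances:
## multiplies the transition likelihood N(x_t; x_lo + (b_hi - b_lo) e0,
## g^2 (b_hi - b_lo)) with the marginal N(x_lo; x0 + b_lo e0, g^2 b_lo) on
## a fine grid and returns the normalized mean and variance.
posterior_grid_oracle <- function(x_t, x0, e0, sched, t_hi, t_lo,
                                  grid_halfwidth = 8, grid_step_frac = 5e-4) {
  b_hi <- sched$beta[t_hi + 1L]
  b_lo <- sched$beta[t_lo + 1L]
  g <- sched$gamma
  s_lik <- g * sqrt(b_hi - b_lo)
  s_pri <- g * sqrt(b_lo)
  centre <- (x0 + b_lo * e0 + x_t - (b_hi - b_lo) * e0) / 2
  spread <- max(s_lik, s_pri)
  h <- grid_step_frac * min(s_lik, s_pri)
  x <- seq(centre - grid_halfwidth * spread, centre + grid_halfwidth * spread,
           by = h)
  logw <- stats::dnorm(x_t, mean = x + (b_hi - b_lo) * e0, sd = s_lik,
                       log = TRUE) +
    stats::dnorm(x, mean = x0 + b_lo * e0, sd = s_pri, log = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  m <- sum(w * x)
  list(mean = m, var = sum(w * (x - m)^2))
}

## From-scratch GMSD recomputation, written independently of the package
## implementation (explicit loops, explicit zero padding).
gmsd_direct <- function(ref, test, c_const = 170 / 255^2, downsample = TRUE) {
  pool_loop <- function(m) {
    H2 <- nrow(m) %/% 2L; W2 <- ncol(m) %/% 2L
    out <- matrix(0, H2, W2)
    for (i in seq_len(H2)) for (j in seq_len(W2))
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  if (downsample) { ref <- pool_loop(ref); test <- pool_loop(test) }
  hx <- matrix(c(1, 0, -1, 1, 0, -1, 1, 0, -1) / 3, 3, 3, byrow = TRUE)
  hy <- t(hx)
  grad_mag <- function(m) {
    H <- nrow(m); W <- ncol(m)
    gx <- matrix(0, H, W); gy <- gx
    at <- function(i, j) if (i >= 1 && i <= H && j >= 1 && j <= W) m[i, j] else 0
    for (i in seq_len(H)) for (j in seq_len(W)) {
      sx <- 0; sy <- 0
      for (di in -1:1) for (dj in -1:1) {
        sx <- sx + hx[di + 2, dj + 2] * at(i + di, j + dj)
        sy <- sy + hy[di + 2, dj + 2] * at(i + di, j + dj)
      }
      gx[i, j] <- sx; gy[i, j] <- sy
    }
    sqrt(gx^2 + gy^2)
  }
  m1 <- grad_mag(ref); m2 <- grad_mag(test)
  gms <- (2 * m1 * m2 + c_const) / (m1^2 + m2^2 + c_const)
  sd(as.vector(gms))
}

## Tiny denoiser configuration for fast CPU tests (8x8 or 16x16 inputs).
micro_denoiser_config <- function(use_swin = TRUE)
  denoiser_config("tiny", base_width = 4, depth = 1, window_size = 2,
                  time_embed_dim = 8, n_heads = 2, channel_mult = c(1, 2),
                  use_swin = use_swin)

## Small seeded paired dataset of smooth slices for trainer tests.
micro_pairs <- function(n, size = 16, seed = 5) {
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(size = size, factors = c(2, 2), noise_sigma = 0.005,
                      seed = srdiff_substream(seed, i))
    make_phantom(sp)
  })
}
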