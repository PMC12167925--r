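## Image-quality metrics implemented from their defining formulas: PSNR,
## SSIM (Gaussian-weighted local statistics, the original publication's
## constants) and GMSD (Prewitt gradient-magnitude similarity deviation).
## The perceptual slot is pluggable; the built-in choice is the multi-scale
## gradient-magnitude distance, which needs no pretrained weights.

#' Metric configuration
#'
#' @param data_range intensity range of the images (default 1.0).
#' @param ssim_window Gaussian window width (odd; default 11).
#' @param ssim_sigma Gaussian window s.d. (default 1.5).
#' @param ssim_k1,ssim_k2 SSIM stabilization constants (0.01, 0.03).
#' @param gmsd_c GMSD contrast constant; the published value 170 on the
#'   0-255 scale, i.e. `170/255^2` for images in \[0, 1\].
#' @param gmsd_downsample apply the published 2x average-pool
#'   preprocessing.
#' @param perceptual `NULL` (absent), `"gm"` for the gradient-magnitude
#'   distance, or a function `(restored, reference) -> scalar`.
#' @return An object of class `srdiff_metric_config`.
#' @export
metric_config <- function(data_range = 1.0, ssim_window = 11L,
                          ssim_sigma = 1.5, ssim_k1 = 0.01, ssim_k2 = 0.03,
                          gmsd_c = 170 / 255^2, gmsd_downsample = TRUE,
                          perceptual = NULL) {
  stopifnot(data_range > 0, ssim_window > 0, ssim_sigma > 0,
            ssim_k1 > 0, ssim_k2 > 0, gmsd_c > 0)
  structure(list(data_range = data_range, ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma, ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 gmsd_c = gmsd_c, gmsd_downsample = isTRUE(gmsd_downsample),
                 perceptual = perceptual),
            class = "srdiff_metric_config")
}

check_same_shape <- function(ref, test) {
  if (!identical(dim(as.matrix(ref)), dim(as.matrix(test))))
    stop("reference and test images must have identical shape")
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10\log_{10}(R^2/\mathrm{MSE})} in dB. Identical inputs (MSE = 0)
#' return the capped sentinel \eqn{10\log_{10}(R^2/\epsilon)} with
#' \eqn{\epsilon} the double-precision machine epsilon, so aggregates stay
#' finite.
#'
#' @param ref,test images of identical shape.
#' @param cfg a [metric_config()].
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, cfg = metric_config()) {
  check_same_shape(ref, test)
  mse <- mean((ref - test)^2)
  cap <- 10 * log10(cfg$data_range^2 / .Machine$double.eps)
  if (mse == 0) return(cap)
  min(10 * log10(cfg$data_range^2 / mse), cap)
}

## Valid-mode separable filtering with a 1D kernel g along both axes.
filter2_valid <- function(x, g) {
  k <- length(g)
  band <- function(n) {
    M <- matrix(0, n - k + 1L, n)
    for (i in seq_len(n - k + 1L)) M[i, i:(i + k - 1L)] <- g
    M
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Structural similarity index
#'
#' Mean of the local SSIM map computed with Gaussian-weighted local
#' moments (11x11 window, sigma 1.5, K1 = 0.01, K2 = 0.03 by default) over
#' the valid interior (windows fully inside the image).
#'
#' @inheritParams psnr
#' @return SSIM in \[-1, 1\]; exactly 1 for identical inputs.
#' @export
ssim <- function(ref, test, cfg = metric_config()) {
  check_same_shape(ref, test)
  x <- as.matrix(ref); y <- as.matrix(test)
  w <- cfg$ssim_window
  if (nrow(x) < w || ncol(x) < w)
    stop(sprintf("image (%dx%d) smaller than the %dx%d SSIM window",
                 nrow(x), ncol(x), w, w))
  r <- (w - 1L) / 2L
  g <- exp(-0.5 * ((-r:r) / cfg$ssim_sigma)^2)
  g <- g / sum(g)
  C1 <- (cfg$ssim_k1 * cfg$data_range)^2
  C2 <- (cfg$ssim_k2 * cfg$data_range)^2
  mu_x <- filter2_valid(x, g); mu_y <- filter2_valid(y, g)
  sxx <- filter2_valid(x * x, g) - mu_x^2
  syy <- filter2_valid(y * y, g) - mu_y^2
  sxy <- filter2_valid(x * y, g) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s)
}

## 'same'-mode zero-padded 3x3 correlation.
conv3_same <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2L, W + 2L)
  xp[2:(H + 1L), 2:(W + 1L)] <- x
  out <- matrix(0, H, W)
  for (dr in 0:2) for (dc in 0:2)
    if (k[dr + 1L, dc + 1L] != 0)
      out <- out + k[dr + 1L, dc + 1L] * xp[(1L + dr):(H + dr), (1L + dc):(W + dc)]
  out
}

#' Gradient magnitude similarity deviation
#'
#' Gradient magnitudes of reference and test via 3x3 Prewitt operators
#' (after the published optional 2x average-pool), pixel-wise similarity
#' \eqn{(2 m_1 m_2 + c)/(m_1^2 + m_2^2 + c)}, and the standard deviation of
#' the similarity map as the score. Identical inputs give exactly 0; lower
#' is better.
#'
#' @inheritParams psnr
#' @return GMSD score (>= 0).
#' @export
gmsd <- function(ref, test, cfg = metric_config()) {
  check_same_shape(ref, test)
  x <- as.matrix(ref); y <- as.matrix(test)
  if (cfg$gmsd_downsample) {
    pool <- function(m) {
      H2 <- nrow(m) %/% 2L; W2 <- ncol(m) %/% 2L
      m <- m[seq_len(2L * H2), seq_len(2L * W2), drop = FALSE]
      0.25 * (m[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                m[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                m[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
                m[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)])
    }
    x <- pool(x); y <- pool(y)
  }
  px <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3L, 3L)  # d/dcol
  py <- t(px)                                                # d/drow
  m1 <- sqrt(conv3_same(x, px)^2 + conv3_same(x, py)^2)
  m2 <- sqrt(conv3_same(y, px)^2 + conv3_same(y, py)^2)
  gms <- (2 * m1 * m2 + cfg$gmsd_c) / (m1^2 + m2^2 + cfg$gmsd_c)
  stats::sd(as.vector(gms))
}

#' Perceptual distance (gradient-magnitude fallback)
#'
#' Multi-scale Prewitt gradient-magnitude distance: mean squared
#' difference of gradient-magnitude maps at full and half resolution. Zero
#' for identical inputs. A no-download stand-in for feature-space
#' perceptual metrics; a pretrained adapter can be plugged into
#' [metric_config()] or [loss_config()] instead.
#'
#' @param restored,reference images of identical shape.
#' @return Non-negative scalar.
#' @export
perceptual_gm <- function(restored, reference) {
  check_same_shape(restored, reference)
  gm_distance(as.matrix(restored), as.matrix(reference))
}

#' Evaluate restored/reference pairs
#'
#' Per-pair PSNR, SSIM, GMSD (and the configured perceptual distance),
#' plus the mean and standard deviation across pairs — the reporting
#' convention of quantitative super-resolution comparisons.
#'
#' @param pairs list; each element a list/pair with the restored image
#'   first and the reference second (names `restored`/`hr` also accepted).
#' @param cfg a [metric_config()].
#' @return List of class `srdiff_metric_report`: `per_pair` (data.frame)
#'   and `summary` (data.frame of mean and sd per metric).
#' @export
evaluate_pairs <- function(pairs, cfg = metric_config()) {
  if (length(pairs) == 0L) stop("no pairs to evaluate")
  pfun <- if (is.function(cfg$perceptual)) cfg$perceptual
          else if (identical(cfg$perceptual, "gm")) perceptual_gm
          else NULL
  rows <- lapply(pairs, function(p) {
    restored <- p$restored %||% p[[1L]]
    hr <- p$hr %||% p[[2L]]
    out <- data.frame(psnr_db = psnr(hr, restored, cfg),
                      ssim = ssim(hr, restored, cfg),
                      gmsd = gmsd(hr, restored, cfg))
    if (!is.null(pfun)) out$perceptual <- pfun(restored, hr)
    out
  })
  per_pair <- do.call(rbind, rows)
  summary <- data.frame(
    metric = names(per_pair),
    mean = vapply(per_pair, mean, 0),
    sd = vapply(per_pair, stats::sd, 0),
    row.names = NULL)
  structure(list(per_pair = per_pair, summary = summary),
            class = "srdiff_metric_report")
}

#' @exportS3Method print srdiff_metric_report
print.srdiff_metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d pairs (mean +/- sd):\n",
              nrow(x$per_pair)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %8.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
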