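## Seeded synthetic MRI phantom generator. Emulates skull-stripped,
## background-masked single-channel slices: piecewise-smooth nested
## elliptical anatomy, thin curvilinear structures (1-2 px), small
## high-contrast lesions, a smooth multiplicative bias field and additive
## noise — the features the degradation protocol and the restoration model
## interact with. It does not emulate scanner physics (k-space sampling,
## coil profiles, Rician noise).

#' Phantom specification
#'
#' @param size slice edge length in pixels.
#' @param n_structures number of nested ellipses.
#' @param lesion_count number of small high-contrast lesions.
#' @param lesion_radius_px lesion radius in pixels.
#' @param curvilinear_count number of thin curvilinear features.
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param bias_amplitude relative amplitude of the smooth bias field.
#' @param factors per-axis in-plane degradation factors for the LR
#'   counterpart.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `srdiff_phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, n_structures = 4L, lesion_count = 3L,
                         lesion_radius_px = 2, curvilinear_count = 2L,
                         noise_sigma = 0.01, bias_amplitude = 0.1,
                         factors = c(4, 4), seed = 1L) {
  structure(list(size = as.integer(size), n_structures = as.integer(n_structures),
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_px = lesion_radius_px,
                 curvilinear_count = as.integer(curvilinear_count),
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 factors = as.numeric(factors), seed = as.integer(seed)),
            class = "srdiff_phantom_spec")
}

inside_ellipse <- function(X, Y, cx, cy, a, b, theta = 0) {
  xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a synthetic HR/LR phantom pair
#'
#' Draws the high-resolution slice (nested ellipses, curvilinear features,
#' lesions, smooth bias field, additive noise, exactly-zero background),
#' derives the low-resolution counterpart by [degrade()] followed by
#' re-masking (emulating masking applied after acquisition), and returns
#' the aligned pair. All intensities lie in \[0, 1\].
#'
#' @param spec a [phantom_spec()].
#' @return An [srdiff_pair()] with the foreground `mask`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  n <- spec$size
  cs <- seq(-1, 1, length.out = n)
  X <- matrix(cs, n, n)              # column coordinate varies over cols
  Y <- matrix(cs, n, n, byrow = TRUE)

  img <- matrix(0, n, n)
  a0 <- stats::runif(1, 0.72, 0.88); b0 <- stats::runif(1, 0.72, 0.88)
  th0 <- stats::runif(1, -0.3, 0.3)
  mask <- inside_ellipse(X, Y, 0, 0, a0, b0, th0)
  img[mask] <- 0.3

  for (j in seq_len(spec$n_structures)) {
    shrink <- stats::runif(1, 0.25, 0.85)
    cx <- stats::runif(1, -0.3, 0.3) * a0
    cy <- stats::runif(1, -0.3, 0.3) * b0
    val <- stats::runif(1, 0.2, 0.9)
    reg <- inside_ellipse(X, Y, cx, cy, shrink * a0 * 0.8, shrink * b0 * 0.8,
                          stats::runif(1, -0.5, 0.5)) & mask
    img[reg] <- val
  }

  ## thin curvilinear features: perturbed arcs, 1-2 px wide
  px <- function(u) pmin(pmax(as.integer(round((u + 1) / 2 * (n - 1) + 1)), 1L), n)
  for (j in seq_len(spec$curvilinear_count)) {
    t <- seq(0, 2 * pi, length.out = 8L * n)
    r <- stats::runif(1, 0.15, 0.5) *
      (1 + 0.25 * sin(stats::runif(1, 1, 4) * t + stats::runif(1, 0, 2 * pi)))
    cx <- stats::runif(1, -0.25, 0.25); cy <- stats::runif(1, -0.25, 0.25)
    xs <- cx + r * cos(t); ys <- cy + r * sin(t)
    keep <- seq_along(t) <= stats::runif(1, 0.3, 0.9) * length(t)
    ii <- px(ys[keep]); jj <- px(xs[keep])
    val <- stats::runif(1, 0.55, 0.95)
    wide <- stats::runif(1) < 0.5
    for (k in seq_along(ii)) {
      if (mask[ii[k], jj[k]]) img[ii[k], jj[k]] <- val
      if (wide && ii[k] < n && mask[ii[k] + 1L, jj[k]])
        img[ii[k] + 1L, jj[k]] <- val
    }
  }

  ## small high-contrast lesions
  for (j in seq_len(spec$lesion_count)) {
    cx <- stats::runif(1, -0.5, 0.5) * a0
    cy <- stats::runif(1, -0.5, 0.5) * b0
    rr <- spec$lesion_radius_px / (n / 2)
    reg <- inside_ellipse(X, Y, cx, cy, rr, rr) & mask
    img[reg] <- if (stats::runif(1) < 0.7) stats::runif(1, 0.85, 1) else
      stats::runif(1, 0, 0.1)
  }

  ## smooth multiplicative bias field
  if (spec$bias_amplitude > 0) {
    cf <- stats::runif(4, -1, 1)
    bias <- 1 + spec$bias_amplitude *
      (cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * (X^2 - Y^2)) / 2
    img <- img * bias
  }

  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)

  img <- pmin(pmax(img, 0), 1)
  img[!mask] <- 0

  lr <- degrade(img, degrade_spec(factors = c(spec$factors, 1)))
  lr <- pmin(pmax(lr, 0), 1)
  lr[!mask] <- 0
  srdiff_pair(img, lr, mask)
}

#' Generate a seeded train/validation/test phantom dataset
#'
#' Per-item seeds derive deterministically from the master seed through a
#' counter-based substream, so the dataset is fully reproducible and the
#' splits are disjoint by construction.
#'
#' @param n total number of phantom pairs.
#' @param spec a [phantom_spec()] template (its `seed` field is ignored).
#' @param fractions train/val/test fractions summing to 1.
#' @param master_seed integer master seed.
#' @return List with elements `train`, `val`, `test` (lists of
#'   [srdiff_pair()]), plus per-split item seeds in attribute `"seeds"`.
#' @export
make_dataset <- function(n, spec = phantom_spec(),
                         fractions = c(0.8, 0.1, 0.1), master_seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  seeds <- vapply(seq_len(n), function(i) srdiff_substream(master_seed, i), 0L)
  items <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    make_phantom(sp)
  })
  bounds <- round(cumsum(c(0, fractions)) * n)
  take <- function(k) {
    ix <- seq.int(bounds[k] + 1L, length.out = bounds[k + 1L] - bounds[k])
    structure(items[ix], seeds = seeds[ix])
  }
  list(train = take(1L), val = take(2L), test = take(3L))
}
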