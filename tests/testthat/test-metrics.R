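test_that("PSNR: closed form, sentinel cap and direct recomputation", {
  x <- matrix(0.4, 16, 16)
  expect_equal(psnr(x, x + 0.1), 20)             # 10*log10(1/0.01)
  cap <- 10 * log10(1 / .Machine$double.eps)
  expect_equal(psnr(x, x), cap)
  set.seed(2)
  a <- matrix(runif(400), 20, 20)
  b <- matrix(runif(400), 20, 20)
  expect_lt(abs(psnr(a, b) - 10 * log10(1 / mean((a - b)^2))), 1e-10)
  expect_error(psnr(a, matrix(0, 3, 3)), "shape")
  ## data_range scaling
  expect_equal(psnr(255 * x, 255 * (x + 0.1), metric_config(data_range = 255)),
               20)
})

test_that("SSIM: identity, luminance penalty, window guard", {
  set.seed(3)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(x, x), 1.0)
  expect_lt(ssim(x, x + 0.5), 1)       # beyond the luminance stabilizer
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("SSIM matches an independent reference implementation", {
  ## expected values computed once with scikit-image's
  ## structural_similarity (gaussian_weights, sigma 1.5, population
  ## covariance, data_range 1) on these seeded images, and frozen
  expected_ssim <- c(0.983568192641, 0.986469386220, 0.984736023105)
  expected_psnr <- c(26.065186941575, 26.551415755356, 26.037614853403)
  set.seed(101)
  for (i in 1:3) {
    ref <- matrix(runif(32 * 32), 32, 32)
    tst <- pmin(pmax(ref + matrix(rnorm(32 * 32, sd = 0.05), 32, 32), 0), 1)
    expect_equal(ssim(ref, tst), expected_ssim[i], tolerance = 1e-9)
    expect_equal(psnr(ref, tst), expected_psnr[i], tolerance = 1e-9)
  }
})

test_that("GMSD: identity, sensitivity, and from-scratch recomputation", {
  set.seed(4)
  x <- matrix(runif(24 * 24), 24, 24)
  expect_equal(gmsd(x, x), 0)
  shuffled <- matrix(sample(x), 24, 24)
  expect_gt(gmsd(x, shuffled), 0)
  for (i in 1:3) {
    a <- matrix(runif(24 * 24), 24, 24)
    b <- pmin(pmax(a + matrix(rnorm(24 * 24, sd = 0.1), 24, 24), 0), 1)
    expect_lt(abs(gmsd(a, b) - gmsd_direct(a, b)), 1e-6)
    ## and without the 2x pooling stage
    cfg <- metric_config(gmsd_downsample = FALSE)
    expect_lt(abs(gmsd(a, b, cfg) - gmsd_direct(a, b, downsample = FALSE)),
              1e-6)
  }
})

test_that("noise of growing strength degrades every metric monotonically", {
  ref <- make_phantom(phantom_spec(size = 48, seed = 77))$x_hr
  sigmas <- c(0.02, 0.05, 0.1)
  m <- sapply(sigmas, function(s) {
    rowMeans(sapply(1:10, function(k) {
      set.seed(1000 + k)
      noisy <- pmin(pmax(ref + matrix(rnorm(length(ref), sd = s),
                                      nrow(ref)), 0), 1)
      c(psnr = psnr(ref, noisy), ssim = ssim(ref, noisy),
        gmsd = gmsd(ref, noisy))
    }))
  })
  expect_true(all(diff(m["psnr", ]) < 0))
  expect_true(all(diff(m["ssim", ]) < 0))
  expect_true(all(diff(m["gmsd", ]) > 0))
})

test_that("metrics are invariant to a joint transpose", {
  set.seed(6)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- pmin(pmax(a + matrix(rnorm(32 * 32, sd = 0.08), 32, 32), 0), 1)
  expect_identical(psnr(a, b), psnr(t(a), t(b)))
  expect_equal(ssim(a, b), ssim(t(a), t(b)), tolerance = 1e-12)
  expect_equal(gmsd(a, b), gmsd(t(a), t(b)), tolerance = 1e-12)
})

test_that("pair evaluation aggregates per-slice reports correctly", {
  x <- matrix(runif(24 * 24), 24, 24)
  rep1 <- evaluate_pairs(list(list(restored = x, hr = x)),
                         metric_config(perceptual = "gm"))
  expect_equal(rep1$per_pair$ssim, 1)
  expect_equal(rep1$per_pair$gmsd, 0)
  expect_equal(rep1$per_pair$perceptual, 0)
  expect_equal(rep1$summary$mean, unlist(rep1$per_pair[1, ]),
               ignore_attr = TRUE)

  set.seed(9)
  pairs <- lapply(1:5, function(i) {
    hr <- matrix(runif(24 * 24), 24, 24)
    list(restored = pmin(pmax(hr + rnorm(576, sd = 0.05), 0), 1), hr = hr)
  })
  rp <- evaluate_pairs(pairs)
  ## spreadsheet-style recomputation of the aggregate
  expect_equal(rp$summary$mean[rp$summary$metric == "psnr_db"],
               mean(vapply(pairs, function(p) psnr(p$hr, p$restored), 0)))
  expect_equal(rp$summary$sd[rp$summary$metric == "ssim"],
               sd(vapply(pairs, function(p) ssim(p$hr, p$restored), 0)))
  ## two pairs: mean is the arithmetic average
  rp2 <- evaluate_pairs(pairs[1:2])
  expect_equal(rp2$summary$mean[1], mean(rp2$per_pair$psnr_db))
  expect_error(evaluate_pairs(list()), "no pairs")
})
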