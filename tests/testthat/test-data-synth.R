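test_that("NIfTI volumes round-trip with their voxel spacing", {
  set.seed(13)
  vol <- array(runif(16 * 16 * 4), c(16, 16, 4))
  path <- tempfile(fileext = ".nii")
  save_volume(vol, path, spacing = c(0.8, 0.8, 0.8))
  back <- load_volume(path)
  expect_identical(dim(back$data), c(16L, 16L, 4L))
  expect_equal(back$data, vol, tolerance = 1e-12)
  expect_equal(back$spacing, c(0.8, 0.8, 0.8), tolerance = 1e-6)
  expect_error(load_volume(tempfile(fileext = ".nii")), "NIfTI|exist")
})

test_that("intensity normalization scales, clips and inverts", {
  set.seed(5)
  vol <- array(runif(8^3), c(8, 8, 8))
  out <- normalize_volume(vol)
  expect_true(all(out >= 0 & out <= 1))
  ## already-[0,1] input changes only by clipping at the percentile tails
  expect_lt(mean(abs(out - vol)), 0.02)
  ## constant region degrades gracefully
  expect_warning(z <- normalize_volume(array(3, c(4, 4, 4))), "constant")
  expect_true(all(z == 0))
  ## inverse recovers masked intensities up to clipping loss
  mask <- array(TRUE, dim(vol))
  nrm <- normalize_volume(vol, mask)
  rec <- denormalize_volume(nrm, attr(nrm, "norm"))
  q <- quantile(vol, c(0.005, 0.995))
  interior <- vol > q[1] & vol < q[2]
  expect_equal(rec[interior], vol[interior], tolerance = 1e-12)
})

test_that("degradation presets preserve the grid and fix constants", {
  const <- array(0.42, c(32, 32, 8))
  for (preset in c("brain", "prostate")) {
    spec <- degrade_spec(preset)
    lr <- degrade(const, spec)
    expect_identical(dim(lr), dim(const))
    expect_equal(lr, const, tolerance = 1e-12)
  }
  ## 2D slices behave as single-slice volumes
  img <- matrix(0.7, 24, 24)
  expect_identical(dim(degrade(img, degrade_spec(factors = c(4, 4, 1)))),
                   dim(img))
  expect_error(degrade(matrix(0, 3, 3), degrade_spec(factors = c(5, 5, 1))),
               "exceeds")
  expect_error(degrade_spec(factors = c(0.5, 1, 1)), ">= 1")
})

test_that("the brain preset keeps a 288x288 slice stack on its grid", {
  vol <- array(runif(288 * 288 * 4), c(288, 288, 4))
  lr <- degrade(vol, degrade_spec("brain"))
  expect_identical(dim(lr), c(288L, 288L, 4L))
})

test_that("degradation removes high-frequency spectral energy", {
  ## full-field texture: the masked phantoms put most of their high band
  ## into the mask-edge discontinuity, which survives nearest-neighbour
  ## re-gridding, so the spectral oracle uses a windowless texture
  n <- 64
  cut <- 0.5 / 4   # beyond the decimated grid's Nyquist
  hf_ratio <- function(img) {
    lr <- degrade(img, degrade_spec(factors = c(4, 4, 1)))
    f <- c(0:(n / 2), (n / 2 - 1):1) / n   # folded frequency axis
    hf <- outer(f, f, pmax) > cut
    sum((Mod(stats::fft(lr))^2)[hf]) / sum((Mod(stats::fft(img))^2)[hf])
  }
  ratios <- vapply(1:5, function(s) {
    set.seed(s)
    hf_ratio(matrix(runif(n * n), n, n))
  }, 0)
  expect_lt(mean(ratios), 0.5)
  ## masked anatomy is degraded too, just less sharply (mask edges persist)
  hr <- make_phantom(phantom_spec(size = n, noise_sigma = 0.05,
                                  curvilinear_count = 4, seed = 7))$x_hr
  expect_lt(hf_ratio(hr), 1)
})

test_that("phantoms are seeded, bounded, masked and structured", {
  sp <- phantom_spec(size = 32, seed = 7)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a, b)
  expect_true(all(a$x_hr >= 0 & a$x_hr <= 1))
  expect_true(all(a$x_lr >= 0 & a$x_lr <= 1))
  expect_true(all(a$x_hr[!a$mask] == 0))
  expect_true(all(a$x_lr[!a$mask] == 0))
  expect_true(all(a$e0[!a$mask] == 0))
  expect_gt(mean(a$mask), 0.2)
  ## stripped-down spec leaves only the piecewise-constant nested ellipses
  plain <- make_phantom(phantom_spec(size = 32, n_structures = 4,
                                     lesion_count = 0, curvilinear_count = 0,
                                     noise_sigma = 0, bias_amplitude = 0,
                                     seed = 9))
  ## piecewise constant: background, base tissue, and one level per ellipse
  expect_lte(length(unique(as.vector(plain$x_hr))), 6L)
})

test_that("stronger downsampling monotonically degrades LR fidelity", {
  mean_psnr <- function(f) {
    mean(vapply(1:10, function(s) {
      p <- make_phantom(phantom_spec(size = 48, factors = c(f, f), seed = s))
      psnr(p$x_hr, p$x_lr)
    }, 0))
  }
  p2 <- mean_psnr(2); p3 <- mean_psnr(3); p4 <- mean_psnr(4)
  expect_gt(p2, p3)
  expect_gt(p3, p4)
})

test_that("dataset generation splits deterministically and disjointly", {
  ds <- make_dataset(10, phantom_spec(size = 16, factors = c(2, 2)),
                     c(0.8, 0.1, 0.1), master_seed = 3)
  expect_identical(lengths(ds[c("train", "val", "test")]),
                   c(train = 8L, val = 1L, test = 1L))
  ds2 <- make_dataset(10, phantom_spec(size = 16, factors = c(2, 2)),
                      c(0.8, 0.1, 0.1), master_seed = 3)
  expect_identical(ds, ds2)
  seeds <- c(attr(ds$train, "seeds"), attr(ds$val, "seeds"),
             attr(ds$test, "seeds"))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_error(make_dataset(4, phantom_spec(), c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("bicubic comparator restores the grid and beats nothing up", {
  p <- make_phantom(phantom_spec(size = 32, seed = 15))
  bc <- bicubic_upsample(p$x_lr, c(4, 4))
  expect_identical(dim(bc), dim(p$x_hr))
  expect_true(all(is.finite(bc)))
})
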