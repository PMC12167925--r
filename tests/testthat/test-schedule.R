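test_that("default schedule hits its endpoints and conserves mass", {
  sch <- srdiff_schedule()
  expect_identical(sch$T, 15L)
  expect_identical(sch$beta[1], 0)                       # beta_0 sentinel
  expect_identical(sch$beta[2], (0.04 / 2)^2)            # beta_1 exact
  expect_identical(sch$beta[16], 0.9999)                 # beta_T exact
  expect_true(all(diff(sch$beta) > 0))
  expect_true(all(sch$alpha > 0))
  expect_equal(sum(sch$alpha), sch$beta_T, tolerance = 1e-14)
  expect_true(all(sch$beta[-1] > 0 & sch$beta[-1] <= 1))
})

test_that("interior betas match the high-precision reference to 1e-12", {
  sch <- srdiff_schedule()
  expect_lt(max(abs(sch$beta[-1] - BETA_REF_DEFAULT)), 1e-12)
})

test_that("invalid hyper-parameters raise errors naming the field", {
  expect_error(srdiff_schedule(T = 1), "T")
  expect_error(srdiff_schedule(p = 0), "p")
  expect_error(srdiff_schedule(gamma = -1), "gamma")
  expect_error(srdiff_schedule(kappa = 0), "kappa")
  expect_error(srdiff_schedule(beta_T = 1.2), "beta_T")
  expect_error(srdiff_schedule(beta_T = 1e-5), "beta_T")  # below beta_1
})

test_that("schedule conservation holds across a (T, p) grid", {
  for (T in c(4L, 15L, 100L)) for (p in c(0.3, 1, 3)) {
    sch <- srdiff_schedule(T = T, p = p)
    expect_true(all(diff(sch$beta) > 0), label = sprintf("T=%d p=%g", T, p))
    expect_equal(sum(sch$alpha), sch$beta_T, tolerance = 1e-12)
    expect_true(all(sch$beta[-1] > 0 & sch$beta[-1] <= 1))
  }
})

test_that("smaller growth exponent p front-loads the noise", {
  s_lo <- srdiff_schedule(p = 0.3)
  s_hi <- srdiff_schedule(p = 1)
  interior <- 3:14   # strictly interior steps (beta_0/1/T pinned)
  expect_true(all(s_lo$beta[interior] > s_hi$beta[interior]))
})

test_that("forward step applies the drift + noise kernel exactly", {
  sch <- srdiff_schedule()
  x <- matrix(runif(16), 4, 4)
  e0 <- matrix(rnorm(16, sd = 0.1), 4, 4)
  expect_identical(forward_step(x, e0 * 0, sch, 3, 0), x)
  expect_equal(forward_step(x, e0, sch, 5, 0), x + sch$alpha[5] * e0)
  n <- matrix(rnorm(16), 4, 4)
  expect_equal(forward_step(x, e0, sch, 5, n),
               x + sch$alpha[5] * e0 + 2 * sqrt(sch$alpha[5]) * n)
  expect_error(forward_step(x, e0, sch, 0, 0), "out of range")
  expect_error(forward_step(x, e0, sch, 16, 0), "out of range")
})

test_that("iterated forward steps match the closed-form marginal moments", {
  ## scalar chain vs marginal, modest draw count (full-scale check in the
  ## acceptance suite)
  sch <- srdiff_schedule()
  set.seed(31)
  N <- 20000L
  x0 <- 0.4; e0 <- -0.25
  x <- rep(x0, N)
  for (t in 1:7)
    x <- forward_step(x, e0, sch, t, rnorm(N))
  b <- sch$beta[8]
  se_mean <- sch$gamma * sqrt(b) / sqrt(N)
  expect_lt(abs(mean(x) - (x0 + b * e0)), 4 * se_mean)
  expect_gt(var(x) / (sch$gamma^2 * b), 0.95)
  expect_lt(var(x) / (sch$gamma^2 * b), 1.05)
})

test_that("forward marginal reproduces its stated mean and degenerate cases", {
  sch <- srdiff_schedule()
  p <- make_phantom(phantom_spec(size = 16, factors = c(2, 2), seed = 2))
  st <- forward_marginal(p, sch, 15, 0)
  expect_identical(st$t, 15L)
  expect_lte(max(abs(st$x - p$x_lr)), (1 - sch$beta_T) * max(abs(p$e0)) + 1e-12)
  same <- srdiff_pair(p$x_hr, p$x_hr)
  for (t in c(1, 8, 15))
    expect_equal(forward_marginal(same, sch, t, 0)$x, p$x_hr)
  n <- matrix(rnorm(256), 16, 16)
  expect_equal(forward_marginal(p, sch, 4, n)$x,
               p$x_hr + sch$beta[5] * p$e0 + 2 * sqrt(sch$beta[5]) * n)
})

test_that("posterior parameters: degenerate, algebraic and ordering cases", {
  sch <- srdiff_schedule()
  x_t <- matrix(runif(16), 4, 4)
  x0 <- matrix(runif(16), 4, 4)
  ## final reverse step collapses to the denoiser estimate
  pp <- posterior_params(x_t, x0, sch, 1, 0)
  expect_equal(pp$mean, x0)
  expect_identical(pp$var, 0)
  ## noise-free trajectory: mean interpolates along the beta path
  e0 <- matrix(rnorm(16, sd = 0.2), 4, 4)
  for (tt in list(c(9L, 8L), c(15L, 11L), c(7L, 3L))) {
    xt_nf <- x0 + sch$beta[tt[1] + 1L] * e0
    pp <- posterior_params(xt_nf, x0, sch, tt[1], tt[2])
    expect_equal(pp$mean, x0 + sch$beta[tt[2] + 1L] * e0)
    expect_gte(pp$var, 0)
  }
  expect_error(posterior_params(x_t, x0, sch, 3, 3), "t_lo < t_hi")
  expect_error(posterior_params(x_t, x0, sch, 3, 5), "t_lo < t_hi")
})

test_that("posterior matches a discretized-Bayes oracle on scalar cases", {
  sch <- srdiff_schedule()
  set.seed(7)
  for (pair in list(c(5L, 4L), c(12L, 11L), c(15L, 11L), c(7L, 3L))) {
    x0 <- runif(1); e0 <- runif(1, -0.3, 0.3)
    x_t <- x0 + sch$beta[pair[1] + 1L] * e0 + rnorm(1, sd = 0.3)
    pp <- posterior_params(x_t, x0, sch, pair[1], pair[2])
    or <- posterior_grid_oracle(x_t, x0, e0, sch, pair[1], pair[2])
    expect_lt(abs(pp$mean - or$mean), 1e-3)
    expect_lt(abs(pp$var - or$var), 1e-3)
  }
})

test_that("sampler initialization follows the terminal kernel", {
  sch <- srdiff_schedule()
  x_lr <- matrix(runif(16), 4, 4)
  expect_identical(init_sample(x_lr, sch, 0)$x, x_lr)
  expect_identical(init_sample(x_lr, sch, 0)$t, 15L)
  one <- matrix(1, 4, 4)
  expect_equal(init_sample(x_lr, sch, one)$x, x_lr + 2 * sqrt(0.9999) * one)
  set.seed(12)
  draws <- replicate(20000, init_sample(0.5, sch, rnorm(1))$x)
  expect_gt(var(draws) / (sch$gamma^2 * sch$beta_T), 0.95)
  expect_lt(var(draws) / (sch$gamma^2 * sch$beta_T), 1.05)
})

test_that("oracle denoiser recursion returns the HR slice exactly", {
  sch <- srdiff_schedule()
  p <- make_phantom(phantom_spec(size = 16, factors = c(2, 2), seed = 4))
  oracle <- function(x_t, x_lr, t) p$x_hr
  for (grid in list(seq(15L, 0L), c(15L, 11L, 7L, 3L, 0L))) {
    out <- srdiff_sample(p$x_lr, oracle, sch, grid, noise_free = TRUE)
    expect_lt(max(abs(out - p$x_hr)), 1e-5)
  }
  ## single reverse step to t_lo = 0 ignores noise entirely
  st <- srdiff_state_for_test <- forward_marginal(p, sch, 3, 0)
  out <- reverse_step(st, p$x_hr, sch, 0, matrix(1e6, 16, 16))
  expect_equal(out$x, p$x_hr)
  expect_error(reverse_step(st, p$x_hr, sch, 3, 0), "t_lo")
})

test_that("explicit per-step grid reproduces the manual recursion", {
  sch <- srdiff_schedule()
  p <- make_phantom(phantom_spec(size = 16, factors = c(2, 2), seed = 6))
  den <- function(x_t, x_lr, t) 0.5 * x_t + 0.5 * x_lr   # arbitrary denoiser
  out <- srdiff_sample(p$x_lr, den, sch, seq(15L, 0L), seed = 3)
  ## manual recursion with the same substreams
  dm <- dim(p$x_lr)
  draw <- function(k) {
    set.seed(srdiff_substream(3, k))
    matrix(rnorm(prod(dm)), dm[1], dm[2])
  }
  st <- init_sample(p$x_lr, sch, draw(0))
  for (k in 1:15) {
    x0h <- den(st$x, p$x_lr, st$t)
    st <- reverse_step(st, x0h, sch, 15L - k, draw(k))
  }
  expect_identical(out, st$x)
})

test_that("sampling is bit-reproducible and validates its grid", {
  sch <- srdiff_schedule()
  p <- make_phantom(phantom_spec(size = 16, factors = c(2, 2), seed = 8))
  den <- function(x_t, x_lr, t) 0.7 * x_t + 0.3 * x_lr
  a <- srdiff_sample(p$x_lr, den, sch, seed = 42)
  b <- srdiff_sample(p$x_lr, den, sch, seed = 42)
  expect_identical(a, b)
  c <- srdiff_sample(p$x_lr, den, sch, seed = 43)
  expect_false(identical(a, c))
  expect_error(srdiff_sample(p$x_lr, den, sch, c(14, 7, 0)), "start at T")
  expect_error(srdiff_sample(p$x_lr, den, sch, c(15, 7, 1)), "start at T|end")
  expect_error(srdiff_sample(p$x_lr, den, sch, c(15, 7, 7, 0)), "decreasing")
})

test_that("default step grids are anchored, decreasing and well spaced", {
  sch <- srdiff_schedule()
  expect_identical(srdiff_step_grid(sch, 4), c(15L, 11L, 7L, 3L, 0L))
  expect_identical(srdiff_step_grid(sch, 15), c(15:0))
  expect_identical(srdiff_step_grid(sch, 1), c(15L, 0L))
  for (n in 2:10) {
    g <- srdiff_step_grid(sch, n)
    expect_identical(g[1], 15L)
    expect_identical(g[length(g)], 0L)
    expect_true(all(diff(g) < 0))
  }
})

test_that("schedule manifests round-trip through plain text", {
  sch <- srdiff_schedule(T = 9, p = 0.7, gamma = 1.5, kappa = 0.03,
                         beta_T = 0.999)
  path <- tempfile(fileext = ".txt")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(back$beta, sch$beta)
  expect_identical(back$T, sch$T)
  expect_identical(readLines(path)[1], "T: 9")
})

test_that("substream seeds are deterministic, distinct and in range", {
  s <- vapply(0:200, function(k) srdiff_substream(99, k), 0L)
  expect_identical(s, vapply(0:200, function(k) srdiff_substream(99, k), 0L))
  expect_true(all(s >= 1 & s < 2^31))
  expect_gt(length(unique(s)), 195)   # collisions essentially absent
  expect_false(identical(srdiff_substream(1, 5), srdiff_substream(2, 5)))
})
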