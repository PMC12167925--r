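test_that("composite loss: zero at the fixed point, closed form, linearity", {
  x <- matrix(runif(64), 8, 8)
  expect_identical(training_loss(x, x, loss_config()), 0)
  expect_identical(training_loss(x, x, loss_config(perceptual = "gm")), 0)
  ## uniform error 0.1 at lambda 10 with null perceptual
  expect_equal(training_loss(x + 0.1, x, loss_config(lam = 10)), 0.1)
  l1 <- training_loss(x + 0.03, x, loss_config(lam = 10))
  l2 <- training_loss(x + 0.03, x, loss_config(lam = 20))
  expect_equal(l2, 2 * l1)
  expect_error(training_loss(x, matrix(0, 4, 4), loss_config()), "shape")
  expect_error(loss_config(lam = 0), "lam")
})

test_that("custom perceptual functions are honoured", {
  x <- matrix(runif(64), 8, 8)
  cfg <- loss_config(lam = 10, perceptual = function(a, b) 7)
  expect_equal(training_loss(x, x, cfg), 7)
})

test_that("learning rate: linear warm-up then half-cosine decay to zero", {
  cfg <- train_config(total_steps = 1000, warmup_steps = 100, lr_init = 2e-4)
  expect_equal(lr_at_step(100, cfg), 2e-4)
  expect_equal(lr_at_step(50, cfg), 1e-4)
  expect_equal(lr_at_step(1000, cfg), 0)
  expect_equal(lr_at_step(100 + 450, cfg), 1e-4)   # cosine midpoint
  expect_error(train_config(total_steps = 10, warmup_steps = 10), "warmup")
})

test_that("degenerate corruption reduces the step loss to the plain objective", {
  sch <- srdiff_schedule()
  den <- build_denoiser(micro_denoiser_config(), seed = 1)
  p0 <- micro_pairs(1, size = 8)[[1]]
  same <- srdiff_pair(p0$x_hr, p0$x_hr)    # e0 = 0
  lcfg <- loss_config()
  set.seed(77)
  st <- srdiff_train_step(list(same), den, sch, lcfg, lr = 0,
                          noise_free = TRUE)
  set.seed(77)
  t_drawn <- sample.int(sch$T, 1)
  expect_equal(st$t, t_drawn)
  expect_equal(st$loss,
               training_loss(den$predict(same$x_hr, same$x_hr, t_drawn),
                             same$x_hr, lcfg))
})

test_that("training steps are bit-reproducible under a fixed seed", {
  sch <- srdiff_schedule()
  batch <- micro_pairs(4, size = 8)
  run_once <- function() {
    den <- build_denoiser(micro_denoiser_config(), seed = 1)
    opt <- NULL
    losses <- numeric(10)
    for (k in 1:10) {
      set.seed(srdiff_substream(5, k))
      r <- srdiff_train_step(batch, den, sch, loss_config(), 1e-3, opt)
      den <- r$denoiser; opt <- r$opt_state; losses[k] <- r$loss
    }
    list(losses = losses, params = den$params)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$losses, b$losses)
  expect_identical(a$params, b$params)
})

test_that("fit honours total_steps = 0 and resumes identically", {
  sch <- srdiff_schedule()
  data <- micro_pairs(6, size = 8)
  den <- build_denoiser(micro_denoiser_config(), seed = 2)
  r0 <- srdiff_fit(data, den, sch, train_cfg = train_config(total_steps = 0))
  expect_identical(r0$denoiser$params, den$params)
  expect_identical(length(r0$trace), 0L)

  cfg <- train_config(total_steps = 8, warmup_steps = 2, batch_size = 3,
                      seed = 9, checkpoint_every = 4)
  dir <- tempfile(); dir.create(dir)
  full <- srdiff_fit(data, den, sch, train_cfg = cfg, checkpoint_dir = dir)
  resumed <- srdiff_fit(data, den, sch, train_cfg = cfg,
                        resume_from = file.path(dir, "ckpt_000004.rds"))
  expect_identical(resumed$trace, full$trace)
  expect_identical(resumed$denoiser$params, full$denoiser$params)
})

test_that("a short run on smooth pairs drives the loss down", {
  sch <- srdiff_schedule()
  data <- micro_pairs(12, size = 8, seed = 21)
  den <- build_denoiser(micro_denoiser_config(), seed = 3)
  run <- srdiff_fit(data, den, sch, loss_config(),
                    train_config(total_steps = 60, warmup_steps = 6,
                                 batch_size = 4, lr_init = 2e-3, seed = 2))
  expect_lt(mean(run$trace[51:60]), mean(run$trace[1:10]))
  expect_true(all(is.finite(run$trace)))
})

test_that("constant pairs drive the fidelity term toward its floor", {
  ## with x_lr = x_hr the identity is learnable, so the null-perceptual
  ## loss should approach zero
  sch <- srdiff_schedule()
  base <- micro_pairs(8, size = 8, seed = 33)
  data <- lapply(base, function(p) srdiff_pair(p$x_hr, p$x_hr))
  den <- build_denoiser(micro_denoiser_config(), seed = 6)
  run <- srdiff_fit(data, den, sch, loss_config(),
                    train_config(total_steps = 100, warmup_steps = 10,
                                 batch_size = 4, lr_init = 2e-3, seed = 8))
  expect_lt(mean(run$trace[91:100]), mean(run$trace[1:10]))
  expect_lt(mean(run$trace[91:100]), 0.05)
})

test_that("RAdam and Adam updates move parameters and stay finite", {
  set.seed(3)
  theta <- rnorm(20)
  grad <- rnorm(20)
  for (kind in c("radam", "adam")) {
    st <- srdiff:::opt_init(20)
    th <- theta
    for (k in 1:10) {
      up <- srdiff:::opt_update(th, grad, st, 1e-2, kind)
      th <- up$theta; st <- up$state
    }
    expect_true(all(is.finite(th)))
    expect_false(identical(th, theta))
    ## descent direction on a fixed gradient
    expect_lt(sum((th - theta) * grad), 0)
  }
})
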