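## Convolutional U-net denoiser with window-attention (Swin-style) blocks.
##
## Images are kept in channels-last matrix layout: a batch of B HxW slices
## with C channels is a (B*H*W) x C matrix, pixels in R's column-major
## order within each image. 3x3 convolutions are expressed as an im2col
## row-gather (9 neighbour index vectors, reflection padding) followed by a
## single BLAS matmul with a (9*C_in) x C_out weight, which is also how the
## backward pass falls out of the autodiff tape.

## --- index plumbing -------------------------------------------------------

reflect_idx <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

## Neighbour index vectors for a 3x3 kernel over a batch of B HxW images,
## optionally with output stride. Cached per geometry.
.idx_cache <- new.env(parent = emptyenv())

conv3_indices <- function(H, W, B, stride = 1L) {
  key <- paste(H, W, B, stride, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ro <- seq.int(1L, H, stride)
  co <- seq.int(1L, W, stride)
  oh <- length(ro); ow <- length(co)
  rr <- rep(ro, times = ow)
  cc <- rep(co, each = oh)
  base <- rep((seq_len(B) - 1L) * (H * W), each = oh * ow)
  idx <- vector("list", 9L)
  k <- 0L
  for (dc in -1L:1L) for (dr in -1L:1L) {
    k <- k + 1L
    r2 <- reflect_idx(rr + dr, H)
    c2 <- reflect_idx(cc + dc, W)
    idx[[k]] <- rep.int((c2 - 1L) * H + r2, B) + base
  }
  big_idx <- unlist(idx, use.names = FALSE)
  out <- list(idx = idx, oh = oh, ow = ow, big_idx = big_idx,
              R = oh * ow * B, n_in = H * W * B,
              st = Matrix::sparseMatrix(i = big_idx,
                                        j = seq_along(big_idx), x = 1,
                                        dims = c(H * W * B, length(big_idx))))
  .idx_cache[[key]] <- out
  out
}

## Broadcast index: repeats row b of a B-row matrix over the H*W pixels of
## sample b; cached with its sparse adjoint.
broadcast_indices <- function(H, W, B) {
  key <- paste("bc", H, W, B, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- rep(seq_len(B), each = H * W)
  out <- list(idx = idx,
              st = Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                                        dims = c(B, length(idx))))
  .idx_cache[[key]] <- out
  out
}

## Nearest-neighbour 2x upsampling index: maps (B*2H*2W) output rows to
## (B*H*W) input rows.
upsample2_indices <- function(H, W, B) {
  key <- paste("up", H, W, B, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  r2 <- rep(seq_len(2L * H), times = 2L * W)
  c2 <- rep(seq_len(2L * W), each = 2L * H)
  src <- ((c2 + 1L) %/% 2L - 1L) * H + (r2 + 1L) %/% 2L
  idx <- rep.int(src, B) + rep((seq_len(B) - 1L) * (H * W), each = 4L * H * W)
  out <- list(idx = idx,
              st = Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                                        dims = c(H * W * B, length(idx))))
  .idx_cache[[key]] <- out
  out
}

## Window partition permutation: rows of a (B*H*W) x C matrix reordered so
## each ws x ws window is contiguous. Returns the permutation (gather with
## it) and its inverse (gather back).
window_indices <- function(H, W, B, ws) {
  key <- paste("win", H, W, B, ws, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  nwr <- H %/% ws; nwc <- W %/% ws
  perm1 <- integer(H * W)
  k <- 0L
  for (wc in seq_len(nwc)) for (wr in seq_len(nwr))
    for (cc in seq_len(ws)) for (rr in seq_len(ws)) {
      k <- k + 1L
      perm1[k] <- ((wc - 1L) * ws + cc - 1L) * H + (wr - 1L) * ws + rr
    }
  perm <- rep.int(perm1, B) + rep((seq_len(B) - 1L) * (H * W), each = H * W)
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  out <- list(perm = perm, inv = inv, tokens = ws * ws)
  .idx_cache[[key]] <- out
  out
}

## --- sinusoidal timestep embedding ---------------------------------------

#' Sinusoidal timestep embedding
#'
#' Standard transformer-style encoding of the diffusion step indicator:
#' half sines, half cosines over geometrically spaced frequencies. Distinct
#' steps map to distinct vectors.
#'
#' @param t non-negative integer timestep (vectorized).
#' @param dim even embedding length.
#' @param max_period frequency base.
#' @return A `length(t) x dim` matrix (sin columns interleaved with cos).
#' @export
timestep_embedding <- function(t, dim, max_period = 10000) {
  if (dim %% 2L != 0L) stop("embedding dim must be even")
  if (any(t < 0)) stop("timestep must be >= 0")
  half <- dim %/% 2L
  freqs <- exp(-log(max_period) * (seq_len(half) - 1L) / half)
  ang <- outer(as.numeric(t), freqs)
  out <- matrix(0, length(t), dim)
  out[, seq(1L, dim, 2L)] <- sin(ang)
  out[, seq(2L, dim, 2L)] <- cos(ang)
  out
}

## --- configuration --------------------------------------------------------

#' Denoiser configuration
#'
#' Describes the U-shaped encoder-decoder that estimates the clean
#' high-resolution slice from `(x_t, x_lr, t)`. Window-attention blocks
#' (layer norm, windowed multi-head self-attention, layer norm, MLP, each
#' with a residual addition) sit at the two coarsest resolutions when
#' `use_swin` is on; the `use_swin = FALSE` arm is the attention-free
#' ablation variant.
#'
#' @param preset `"tiny"` (CPU desk scale) or `"paper"` (64 base channels,
#'   4 levels).
#' @param base_width channel count at the input resolution.
#' @param depth number of 2x down/up levels.
#' @param window_size attention window edge length.
#' @param use_swin logical ablation toggle for the window-attention blocks.
#' @param time_embed_dim width of the sinusoidal timestep embedding.
#' @param n_heads attention head count.
#' @param channel_mult per-level channel multipliers (length `depth + 1`).
#' @return An object of class `srdiff_denoiser_config`.
#' @export
denoiser_config <- function(preset = c("tiny", "paper"),
                            base_width = NULL, depth = NULL,
                            window_size = NULL, use_swin = TRUE,
                            time_embed_dim = NULL, n_heads = NULL,
                            channel_mult = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    tiny  = list(base_width = 16L, depth = 2L, window_size = 4L,
                 time_embed_dim = 32L, n_heads = 2L,
                 channel_mult = c(1L, 2L, 2L)),
    paper = list(base_width = 64L, depth = 4L, window_size = 8L,
                 time_embed_dim = 256L, n_heads = 4L,
                 channel_mult = c(1L, 2L, 2L, 4L, 4L)))
  cfg <- list(
    preset = preset,
    base_width = as.integer(base_width %||% def$base_width),
    depth = as.integer(depth %||% def$depth),
    window_size = as.integer(window_size %||% def$window_size),
    use_swin = isTRUE(use_swin),
    time_embed_dim = as.integer(time_embed_dim %||% def$time_embed_dim),
    n_heads = as.integer(n_heads %||% def$n_heads),
    channel_mult = as.integer(channel_mult %||% def$channel_mult))
  if (length(cfg$channel_mult) != cfg$depth + 1L)
    stop("channel_mult must have depth + 1 entries")
  if (cfg$time_embed_dim %% 2L != 0L) stop("time_embed_dim must be even")
  class(cfg) <- "srdiff_denoiser_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_divisibility <- function(cfg, H, W) {
  f <- 2L^cfg$depth
  if (H %% f != 0L || W %% f != 0L)
    stop(sprintf("input size %dx%d must be divisible by 2^depth = %d",
                 H, W, f))
  if (cfg$use_swin) {
    for (lev in attn_resolutions(cfg)) {
      h <- H %/% 2L^lev; w <- W %/% 2L^lev
      if (h %% cfg$window_size != 0L || w %% cfg$window_size != 0L)
        stop(sprintf(
          "attended level at %dx%d must be divisible by window_size = %d",
          h, w, cfg$window_size))
    }
  }
  invisible(TRUE)
}

## Downscale exponents (relative to the input) that carry attention:
## the two coarsest feature resolutions.
attn_resolutions <- function(cfg) c(cfg$depth - 1L, cfg$depth)

## --- parameters -----------------------------------------------------------

level_widths <- function(cfg) cfg$base_width * cfg$channel_mult

init_denoiser_params <- function(cfg, seed = 1L) {
  set.seed(as.integer(seed))
  P <- list()
  conv_w <- function(cin, cout, gain = 1)
    matrix(stats::rnorm(9L * cin * cout, sd = gain * sqrt(2 / (9 * cin))),
           9L * cin, cout)
  lin_w <- function(cin, cout, gain = 1)
    matrix(stats::rnorm(cin * cout, sd = gain * sqrt(1 / cin)), cin, cout)
  add_ln <- function(name, C) {
    P[[paste0(name, "_g")]] <<- matrix(1, 1L, C)
    P[[paste0(name, "_b")]] <<- matrix(0, 1L, C)
  }
  add_conv <- function(name, cin, cout, gain = 1) {
    P[[paste0(name, "_W")]] <<- conv_w(cin, cout, gain)
    P[[paste0(name, "_b")]] <<- matrix(0, 1L, cout)
  }
  add_lin <- function(name, cin, cout, gain = 1) {
    P[[paste0(name, "_W")]] <<- lin_w(cin, cout, gain)
    P[[paste0(name, "_b")]] <<- matrix(0, 1L, cout)
  }
  add_resblock <- function(name, cin, cout, td) {
    add_ln(paste0(name, "_ln1"), cin)
    add_conv(paste0(name, "_c1"), cin, cout)
    add_lin(paste0(name, "_emb"), td, 2L * cout)
    add_ln(paste0(name, "_ln2"), cout)
    add_conv(paste0(name, "_c2"), cout, cout, gain = 0.5)
    if (cin != cout) add_lin(paste0(name, "_skip"), cin, cout)
  }
  add_swin <- function(name, C, mlp_mult = 2L) {
    add_ln(paste0(name, "_ln1"), C)
    add_lin(paste0(name, "_qkv"), C, 3L * C)
    add_lin(paste0(name, "_proj"), C, C, gain = 0.5)
    add_ln(paste0(name, "_ln2"), C)
    add_lin(paste0(name, "_fc1"), C, mlp_mult * C)
    add_lin(paste0(name, "_fc2"), mlp_mult * C, C, gain = 0.5)
  }

  td <- cfg$time_embed_dim
  w <- level_widths(cfg)
  add_lin("tmlp1", td, td)
  add_lin("tmlp2", td, td)
  add_conv("stem", 2L, w[1L])
  for (l in seq_len(cfg$depth)) {
    add_resblock(sprintf("down%d", l), w[l], w[l], td)
    if (cfg$use_swin && (l - 1L) %in% attn_resolutions(cfg))
      add_swin(sprintf("down%d_attn", l), w[l])
    add_conv(sprintf("ds%d", l), w[l], w[l + 1L])
  }
  wd <- w[cfg$depth + 1L]
  add_resblock("mid1", wd, wd, td)
  if (cfg$use_swin) add_swin("mid_attn", wd)
  add_resblock("mid2", wd, wd, td)
  for (l in rev(seq_len(cfg$depth))) {
    add_conv(sprintf("us%d", l), w[l + 1L], w[l])
    add_resblock(sprintf("up%d", l), 2L * w[l], w[l], td)
    if (cfg$use_swin && (l - 1L) %in% attn_resolutions(cfg))
      add_swin(sprintf("up%d_attn", l), w[l])
  }
  add_ln("head_ln", w[1L])
  add_conv("head", w[1L], 1L, gain = 0.1)
  P
}

## --- forward graph --------------------------------------------------------

## Builds the forward computation on a tape. `pn` is the named list of
## parameter nodes; xt/xlr are (B*H*W) x 1 value matrices, tvec length B.
denoiser_graph <- function(tape, pn, cfg, xt, xlr, tvec, H, W) {
  B <- length(tvec)

  conv3 <- function(x, name, H, W, stride = 1L) {
    ci <- conv3_indices(H, W, B, stride)
    ad_add_bias(ad_matmul(ad_im2col(x, ci), pn[[paste0(name, "_W")]]),
                pn[[paste0(name, "_b")]])
  }
  linear <- function(x, name)
    ad_add_bias(ad_matmul(x, pn[[paste0(name, "_W")]]),
                pn[[paste0(name, "_b")]])
  ln <- function(x, name)
    ad_layernorm(x, pn[[paste0(name, "_g")]], pn[[paste0(name, "_b")]])

  resblock <- function(x, name, temb, cin, cout, H, W) {
    h <- conv3(ad_silu(ln(x, paste0(name, "_ln1"))), paste0(name, "_c1"), H, W)
    ss <- linear(ad_silu(temb), paste0(name, "_emb"))         # B x 2*cout
    bc <- broadcast_indices(H, W, B)
    sc <- ad_gather_rows(ad_slice_cols(ss, 1L, cout), bc$idx, st = bc$st)
    sh <- ad_gather_rows(ad_slice_cols(ss, cout + 1L, 2L * cout), bc$idx,
                         st = bc$st)
    h <- ad_add(ad_mul(h, ad_add_scalar(sc, 1)), sh)
    h <- conv3(ad_silu(ln(h, paste0(name, "_ln2"))), paste0(name, "_c2"), H, W)
    skip <- if (cin != cout) linear(x, paste0(name, "_skip")) else x
    ad_add(skip, h)
  }

  swin <- function(x, name, C, H, W) {
    wi <- window_indices(H, W, B, cfg$window_size)
    y <- ln(x, paste0(name, "_ln1"))
    y <- ad_gather_rows(y, wi$perm, inv = wi$inv)
    qkv <- linear(y, paste0(name, "_qkv"))
    q <- ad_slice_cols(qkv, 1L, C)
    k <- ad_slice_cols(qkv, C + 1L, 2L * C)
    v <- ad_slice_cols(qkv, 2L * C + 1L, 3L * C)
    a <- ad_window_attention(q, k, v, cfg$n_heads, wi$tokens)
    a <- linear(a, paste0(name, "_proj"))
    x <- ad_add(x, ad_gather_rows(a, wi$inv, inv = wi$perm))
    z <- ad_silu(linear(ln(x, paste0(name, "_ln2")), paste0(name, "_fc1")))
    ad_add(x, linear(z, paste0(name, "_fc2")))
  }

  w <- level_widths(cfg)
  temb0 <- ad_const(tape, timestep_embedding(tvec, cfg$time_embed_dim))
  temb <- linear(ad_silu(linear(temb0, "tmlp1")), "tmlp2")

  x <- ad_cbind(list(xt, xlr))
  h <- conv3(x, "stem", H, W)
  skips <- vector("list", cfg$depth)
  hh <- H; ww <- W
  for (l in seq_len(cfg$depth)) {
    h <- resblock(h, sprintf("down%d", l), temb, w[l], w[l], hh, ww)
    if (cfg$use_swin && (l - 1L) %in% attn_resolutions(cfg))
      h <- swin(h, sprintf("down%d_attn", l), w[l], hh, ww)
    skips[[l]] <- h
    h <- conv3(h, sprintf("ds%d", l), hh, ww, stride = 2L)
    hh <- hh %/% 2L; ww <- ww %/% 2L
  }
  wd <- w[cfg$depth + 1L]
  h <- resblock(h, "mid1", temb, wd, wd, hh, ww)
  if (cfg$use_swin) h <- swin(h, "mid_attn", wd, hh, ww)
  h <- resblock(h, "mid2", temb, wd, wd, hh, ww)
  for (l in rev(seq_len(cfg$depth))) {
    ui <- upsample2_indices(hh, ww, B)
    hh <- hh * 2L; ww <- ww * 2L
    h <- conv3(ad_gather_rows(h, ui$idx, st = ui$st), sprintf("us%d", l),
               hh, ww)
    h <- ad_cbind(list(h, skips[[l]]))
    h <- resblock(h, sprintf("up%d", l), temb, 2L * w[l], w[l], hh, ww)
    if (cfg$use_swin && (l - 1L) %in% attn_resolutions(cfg))
      h <- swin(h, sprintf("up%d_attn", l), w[l], hh, ww)
  }
  out <- conv3(ad_silu(ln(h, "head_ln")), "head", H, W)
  ad_add(out, xlr)   # global residual skip: the network refines x_lr
}

## --- public contract ------------------------------------------------------

#' Build a denoiser contract
#'
#' Instantiates the learnable estimator \eqn{g_\varphi(x_t, x^{LR}, t)
#' \to \hat{x}_0}: a U-shaped encoder-decoder that concatenates the
#' diffused slice and the low-resolution reference along channels, injects
#' a sinusoidal timestep embedding into each residual block through
#' scale-and-shift, and (when `use_swin`) applies window-attention blocks
#' at the two coarsest resolutions. Convolutions use reflection padding.
#' The network predicts a correction to `x_lr` through a global residual
#' connection.
#'
#' @param cfg a [denoiser_config()].
#' @param seed integer; two builds from the same seed have identical
#'   initial parameters.
#' @return An object of class `srdiff_denoiser`: list with `cfg`, `params`
#'   (named list of matrices), `param_count` and `predict(x_t, x_lr, t)`.
#' @export
build_denoiser <- function(cfg = denoiser_config("tiny"), seed = 1L) {
  params <- init_denoiser_params(cfg, seed)
  new_denoiser(cfg, params)
}

new_denoiser <- function(cfg, params) {
  den <- list(cfg = cfg, params = params,
              param_count = sum(vapply(params, length, 0L)))
  den$predict <- function(x_t, x_lr, t) {
    x_t <- as.matrix(x_t); x_lr <- as.matrix(x_lr)
    H <- nrow(x_t); W <- ncol(x_t)
    check_divisibility(cfg, H, W)
    tape <- ad_tape()
    pn <- lapply(den$params, function(v) ad_const(tape, v))
    out <- denoiser_graph(tape, pn, cfg, ad_const(tape, cbind(as.vector(x_t))),
                          ad_const(tape, cbind(as.vector(x_lr))),
                          as.numeric(t), H, W)
    matrix(ad_value(out), H, W)
  }
  class(den) <- "srdiff_denoiser"
  den
}

#' @exportS3Method print srdiff_denoiser
print.srdiff_denoiser <- function(x, ...) {
  cat(sprintf(
    "srdiff denoiser (%s preset): depth %d, base width %d, %s, %d parameters\n",
    x$cfg$preset, x$cfg$depth, x$cfg$base_width,
    if (x$cfg$use_swin) "window attention" else "no attention (ablation)",
    x$param_count))
  invisible(x)
}

## Batched forward + gradient for training. pairs_xt, pairs_xlr: lists of
## H x W matrices (same size); tvec integer per-sample timesteps; targets:
## list of H x W matrices. Returns loss value and named gradient list.
denoiser_loss_grad <- function(den, xt_list, xlr_list, tvec, target_list,
                               loss_cfg) {
  H <- nrow(xt_list[[1L]]); W <- ncol(xt_list[[1L]])
  check_divisibility(den$cfg, H, W)
  tape <- ad_tape()
  pn <- lapply(den$params, function(v) ad_param(tape, v))
  xt <- ad_const(tape, cbind(unlist(lapply(xt_list, as.vector))))
  xlr <- ad_const(tape, cbind(unlist(lapply(xlr_list, as.vector))))
  target <- cbind(unlist(lapply(target_list, as.vector)))
  out <- denoiser_graph(tape, pn, den$cfg, xt, xlr, as.numeric(tvec), H, W)
  loss <- ad_scale(ad_mse(out, target), loss_cfg$lam)
  if (!identical(loss_cfg$perceptual, "null"))
    loss <- ad_add(loss, perceptual_graph(tape, out, target, loss_cfg,
                                          H, W, length(tvec)))
  grads <- ad_backward(loss)
  g <- lapply(pn, function(node) grads[[node$id]])
  nullg <- vapply(g, is.null, TRUE)
  if (any(nullg)) g[nullg] <- lapply(den$params[nullg], function(v) v * 0)
  list(loss = ad_value(loss)[1L], grads = g,
       x0_hat = matrix(ad_value(out), H * W, length(tvec)))
}

## Differentiable multi-scale gradient-magnitude distance (the no-download
## perceptual fallback): mean squared difference of Prewitt gradient
## magnitudes at full and half resolution.
perceptual_graph <- function(tape, out, target, loss_cfg, H, W, B) {
  px <- prewitt_pair_const(tape)
  gm <- function(x, H, W) {
    ci <- conv3_indices(H, W, B, 1L)
    xx <- ad_im2col(x, ci)
    gx <- ad_matmul(xx, px$gx)
    gy <- ad_matmul(xx, px$gy)
    ad_sqrt(ad_add_scalar(ad_add(ad_mul(gx, gx), ad_mul(gy, gy)), 1e-12))
  }
  tnode <- ad_const(tape, target)
  term <- ad_mse(ad_sub(gm(out, H, W), gm(tnode, H, W)), 0)
  pool <- function(x, H, W) {   # 2x2 mean pooling via strided 3x3 gather
    ci <- conv3_indices(H, W, B, 2L)
    xx <- ad_cbind(lapply(ci$idx[c(5L, 6L, 8L, 9L)],
                          function(ix) ad_gather_rows(x, ix)))
    ad_matmul(xx, ad_const(tape, matrix(0.25, 4L, 1L)))
  }
  H2 <- H %/% 2L; W2 <- W %/% 2L
  term2 <- ad_mse(ad_sub(gm(pool(out, H, W), H2, W2),
                         gm(pool(tnode, H, W), H2, W2)), 0)
  ad_scale(ad_add(term, term2), loss_cfg$perceptual_weight)
}

prewitt_pair_const <- function(tape) {
  ## 9 rows ordered (dc, dr) as in conv3_indices
  kx <- rep(c(-1, 0, 1), each = 3) / 3
  ky <- rep(c(-1, 0, 1), times = 3) / 3
  list(gx = ad_const(tape, cbind(kx)), gy = ad_const(tape, cbind(ky)))
}

## Flatten / unflatten parameter lists for the optimizer.
flatten_params <- function(P) unlist(P, use.names = FALSE)

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    out[[nm]] <- matrix(vec[(pos + 1L):(pos + n)], nrow(template[[nm]]),
                        ncol(template[[nm]]))
    pos <- pos + n
  }
  out
}
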