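## Minimal reverse-mode automatic differentiation on a linear tape.
##
## Every tensor is a dense double matrix. A node records its value, its
## parent node ids and a backward closure mapping the incoming gradient to
## per-parent gradients. The tape is an environment holding a growing node
## list; ad_backward() walks it once in reverse. This is all the machinery
## the denoiser needs: matmul, elementwise ops, row gather/scatter (which
## expresses im2col convolution, up/downsampling, window partition and
## per-sample broadcast), fused layer-norm and fused window attention.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ad_node <- function(tape, value, parents = integer(0), backfn = NULL,
                    requires_grad = FALSE) {
  ## force all promises before reading the tape counter: argument
  ## expressions may themselves append nodes (nested op calls)
  force(value); force(parents); force(backfn)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", n))
  tape$nodes[[n]] <- list(value = value, parents = parents, backfn = backfn,
                          requires_grad = requires_grad)
  tape$n <- n
  list(id = n, tape = tape)
}

ad_value <- function(x) x$tape$nodes[[x$id]]$value

## Constant (no gradient tracked) and parameter (gradient tracked) leaves.
ad_const <- function(tape, value) ad_node(tape, value)
ad_param <- function(tape, value) ad_node(tape, value, requires_grad = TRUE)

## Reverse pass from scalar (1x1) node `out`; returns list of gradients
## indexed by node id (NULL where no gradient flows).
ad_backward <- function(out) {
  tape <- out$tape
  nodes <- tape$nodes
  grads <- vector("list", tape$n)
  v <- nodes[[out$id]]$value
  grads[[out$id]] <- matrix(1, nrow(v), ncol(v))
  for (i in seq.int(out$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    if (is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      j <- ps[k]
      grads[[j]] <- if (is.null(grads[[j]])) pg[[k]] else grads[[j]] + pg[[k]]
    }
  }
  grads
}

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(a$tape, A %*% B, c(a$id, b$id),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

ad_add <- function(a, b) {
  ad_node(a$tape, ad_value(a) + ad_value(b), c(a$id, b$id),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$tape, ad_value(a) - ad_value(b), c(a$id, b$id),
          function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

## x + bias, bias a 1 x C row broadcast over rows.
ad_add_bias <- function(x, bias) {
  X <- ad_value(x); bv <- as.vector(ad_value(bias))
  ad_node(x$tape, X + matrix(bv, nrow(X), length(bv), byrow = TRUE),
          c(x$id, bias$id),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_scale <- function(x, s) {   # s: plain scalar constant
  ad_node(x$tape, ad_value(x) * s, x$id, function(g) list(g * s))
}

ad_add_scalar <- function(x, s) {
  ad_node(x$tape, ad_value(x) + s, x$id, function(g) list(g))
}

ad_silu <- function(x) {
  X <- ad_value(x)
  sig <- 1 / (1 + exp(-X))
  ad_node(x$tape, X * sig, x$id,
          function(g) list(g * (sig * (1 + X * (1 - sig)))))
}

ad_sqrt <- function(x) {
  V <- sqrt(ad_value(x))
  ad_node(x$tape, V, x$id, function(g) list(g * (0.5 / V)))
}

scatter_rows <- function(g, idx, nrow_out) {
  out <- matrix(0, nrow_out, ncol(g))
  tmp <- rowsum(g, group = idx, reorder = FALSE)
  out[as.integer(rownames(tmp)), ] <- tmp
  out
}

## Row gather: out = x[idx, ]. Backward scatter-adds into the source rows.
## Fast paths: `inv` (idx is a permutation with the given inverse) turns the
## scatter into a gather; `st` (precomputed sparse adjoint, n_in x n_out)
## turns it into one sparse matmul.
ad_gather_rows <- function(x, idx, st = NULL, inv = NULL) {
  force(idx); force(st); force(inv)   # closure must not see later rebinds
  X <- ad_value(x)
  nr <- nrow(X)
  ad_node(x$tape, X[idx, , drop = FALSE], x$id,
          function(g) {
            if (!is.null(inv)) return(list(g[inv, , drop = FALSE]))
            if (!is.null(st)) return(list(as.matrix(st %*% g)))
            list(scatter_rows(g, idx, nr))
          })
}

## Fused im2col for a 3x3 kernel: one indexed read of the 9 shifted copies,
## reinterpreted as (rows x 9*C) by a plain dim change (the column order is
## kernel-position-fastest, which the conv weight layout matches). The
## backward pass is the reverse reshape plus one sparse-adjoint multiply.
ad_im2col <- function(x, ci) {
  force(ci)
  X <- ad_value(x)
  C <- ncol(X)
  R <- ci$R
  m <- X[ci$big_idx, , drop = FALSE]
  dim(m) <- c(R, 9L * C)
  ad_node(x$tape, m, x$id,
          function(g) {
            dim(g) <- c(9L * R, C)
            list(as.matrix(ci$st %*% g))
          })
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  ncols <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_node(xs[[1L]]$tape, do.call(cbind, vals),
          vapply(xs, function(x) x$id, 0L),
          function(g) lapply(seq_along(ncols), function(k)
            g[, starts[k]:ends[k], drop = FALSE]))
}

ad_slice_cols <- function(x, from, to) {
  X <- ad_value(x)
  nc <- ncol(X)
  ad_node(x$tape, X[, from:to, drop = FALSE], x$id,
          function(g) {
            out <- matrix(0, nrow(g), nc)
            out[, from:to] <- g
            list(out)
          })
}

## Fused layer normalization over rows (channels-last layout), with affine
## gain/bias per channel.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- ad_value(x)
  gv <- as.vector(ad_value(gamma))
  bv <- as.vector(ad_value(beta))
  n <- nrow(X); C <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  y <- xc * inv
  gm <- matrix(gv, n, C, byrow = TRUE)
  out <- y * gm + matrix(bv, n, C, byrow = TRUE)
  ad_node(x$tape, out, c(x$id, gamma$id, beta$id),
          function(g) {
            dy <- g * gm
            dx <- inv * (dy - rowMeans(dy) - y * rowMeans(dy * y))
            list(dx, matrix(colSums(g * y), 1L), matrix(colSums(g), 1L))
          })
}

## Fused multi-head self-attention within fixed-size token windows.
## q, k, v: (n_windows * tokens) x C, window-contiguous rows.
ad_window_attention <- function(q, k, v, n_heads, tokens) {
  Q <- ad_value(q); K <- ad_value(k); V <- ad_value(v)
  n <- nrow(Q); C <- ncol(Q)
  stopifnot(n %% tokens == 0L, C %% n_heads == 0L)
  d <- C %/% n_heads
  sc <- 1 / sqrt(d)
  nw <- n %/% tokens
  out <- matrix(0, n, C)
  Ps <- vector("list", nw * n_heads)
  for (w in seq_len(nw)) {
    rows <- ((w - 1L) * tokens + 1L):(w * tokens)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * sc
      S <- S - apply(S, 1L, max)
      P <- exp(S); P <- P / rowSums(P)
      Ps[[(w - 1L) * n_heads + h]] <- P
      out[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  ad_node(q$tape, out, c(q$id, k$id, v$id),
          function(g) {
            dQ <- matrix(0, n, C); dK <- matrix(0, n, C); dV <- matrix(0, n, C)
            for (w in seq_len(nw)) {
              rows <- ((w - 1L) * tokens + 1L):(w * tokens)
              for (h in seq_len(n_heads)) {
                cols <- ((h - 1L) * d + 1L):(h * d)
                P <- Ps[[(w - 1L) * n_heads + h]]
                gO <- g[rows, cols, drop = FALSE]
                Vw <- V[rows, cols, drop = FALSE]
                dV[rows, cols] <- crossprod(P, gO)
                dP <- tcrossprod(gO, Vw)
                dS <- P * (dP - rowSums(dP * P))
                dQ[rows, cols] <- (dS %*% K[rows, cols, drop = FALSE]) * sc
                dK[rows, cols] <- crossprod(dS, Q[rows, cols, drop = FALSE]) * sc
              }
            }
            list(dQ, dK, dV)
          })
}

## Mean squared error against a constant target; returns a 1x1 node.
ad_mse <- function(x, target) {
  X <- ad_value(x)
  D <- X - target
  n <- length(D)
  ad_node(x$tape, matrix(mean(D * D), 1L, 1L), x$id,
          function(g) list((2 * g[1L]) / n * D))
}

ad_mean_all <- function(x) {
  X <- ad_value(x)
  n <- length(X)
  ad_node(x$tape, matrix(mean(X), 1L, 1L), x$id,
          function(g) list(matrix(g[1L] / n, nrow(X), ncol(X))))
}
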