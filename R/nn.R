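# A compact convolutional-network engine. Batches are H x W x C x N arrays;
# convolutions are lowered to matrix multiplication (im2col + BLAS), which
# keeps CPU training of the small backbone fast enough for desk-scale
# experiments. Layers are plain lists; composite layers (residual blocks,
# dense concatenation blocks) recurse through the same forward/backward
# machinery.

# ---- im2col ----------------------------------------------------------------

# Lower (H, W, C, N) patches of size k (stride, zero-pad) to a
# (k*k*C) x (Ho*Wo*N) matrix. Column order: output row fastest, then output
# column, then batch; row order: patch row fastest, then patch column, then
# channel. The index matrix is kept for the backward scatter.
nn_im2col <- function(x, k, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (pad > 0) {
    xp <- array(0, c(H + 2 * pad, W + 2 * pad, C, N))
    xp[(pad + 1):(pad + H), (pad + 1):(pad + W), , ] <- x
  } else xp <- x
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  off <- as.vector(outer(0:(k - 1), (0:(k - 1)) * Hp, "+"))
  off <- as.vector(outer(off, (0:(C - 1)) * (Hp * Wp), "+"))
  base <- as.vector(outer(1 + (0:(Ho - 1)) * stride, ((0:(Wo - 1)) * stride) * Hp, "+"))
  base <- as.vector(outer(base, (0:(N - 1)) * (Hp * Wp * C), "+"))
  idx <- outer(off, base, "+")
  list(col = matrix(xp[as.vector(idx)], nrow = k * k * C),
       idx = idx, dim_pad = dim(xp), pad = pad, Ho = Ho, Wo = Wo)
}

# Scatter-add column gradients back through nn_im2col.
nn_col2im <- function(dcol, ic, in_dim) {
  dxp <- numeric(prod(ic$dim_pad))
  for (r in seq_len(nrow(ic$idx))) {
    ii <- ic$idx[r, ]
    dxp[ii] <- dxp[ii] + dcol[r, ]
  }
  dxp <- array(dxp, ic$dim_pad)
  p <- ic$pad
  if (p > 0) {
    dxp <- dxp[(p + 1):(p + in_dim[1]), (p + 1):(p + in_dim[2]), , , drop = FALSE]
  }
  dxp
}

# ---- layer constructors ----------------------------------------------------

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
       W = matrix(stats::rnorm(cout * k * k * cin, sd = sd), cout, k * k * cin),
       b = if (bias) numeric(cout) else NULL)
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", c = c, eps = eps, momentum = momentum,
       gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

nn_relu <- function() list(type = "relu")
nn_maxpool <- function(k, stride = k, pad = 0L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
nn_avgpool <- function(k, stride = k, pad = 0L)
  list(type = "avgpool", k = k, stride = stride, pad = pad)
nn_gap <- function() list(type = "gap")
nn_linear <- function(din, dout) {
  sd <- sqrt(2 / din)
  list(type = "linear", din = din, dout = dout,
       W = matrix(stats::rnorm(dout * din, sd = sd), dout, din),
       b = numeric(dout))
}
nn_residual <- function(branch, shortcut = NULL)
  list(type = "residual", branch = branch, shortcut = shortcut)
nn_dense_concat <- function(branch) list(type = "dense_concat", branch = branch)

# ---- forward / backward ----------------------------------------------------

nn_forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      ic <- nn_im2col(x, layer$k, layer$stride, layer$pad)
      out <- layer$W %*% ic$col
      if (!is.null(layer$b)) out <- out + layer$b
      N <- dim(x)[4]
      out <- aperm(array(out, c(layer$cout, ic$Ho, ic$Wo, N)), c(2, 3, 1, 4))
      list(out = out, cache = list(ic = ic, in_dim = dim(x)))
    },
    bn = {
      d <- dim(x); C <- d[3]
      out <- x
      cache <- list(in_dim = d)
      if (training) {
        mu <- apply(x, 3, mean)
        v <- apply(x, 3, function(m) mean((m - mean(m))^2))
        xhat <- array(0, d)
        for (c in seq_len(C))
          xhat[, , c, ] <- (x[, , c, ] - mu[c]) / sqrt(v[c] + layer$eps)
        for (c in seq_len(C))
          out[, , c, ] <- layer$gamma[c] * xhat[, , c, ] + layer$beta[c]
        cache$xhat <- xhat; cache$var <- v; cache$mu <- mu
        cache$new_run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        cache$new_run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        for (c in seq_len(C))
          out[, , c, ] <- layer$gamma[c] *
            (x[, , c, ] - layer$run_mean[c]) / sqrt(layer$run_var[c] + layer$eps) +
            layer$beta[c]
      }
      list(out = out, cache = cache)
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    maxpool = {
      d <- dim(x)
      xr <- array(x, c(d[1], d[2], 1L, d[3] * d[4]))
      ic <- nn_im2col(xr, layer$k, layer$stride, layer$pad)
      am <- max.col(t(ic$col), ties.method = "first")
      M <- ncol(ic$col)
      vals <- ic$col[cbind(am, seq_len(M))]
      out <- array(vals, c(ic$Ho, ic$Wo, d[3], d[4]))
      list(out = out, cache = list(ic = ic, am = am, in_dim = d,
                                   r_dim = dim(xr)))
    },
    avgpool = {
      d <- dim(x)
      xr <- array(x, c(d[1], d[2], 1L, d[3] * d[4]))
      ic <- nn_im2col(xr, layer$k, layer$stride, layer$pad)
      out <- array(colMeans(ic$col), c(ic$Ho, ic$Wo, d[3], d[4]))
      list(out = out, cache = list(ic = ic, in_dim = d, r_dim = dim(xr)))
    },
    gap = {
      d <- dim(x)
      list(out = apply(x, c(3, 4), mean), cache = list(in_dim = d))
    },
    linear = {
      out <- layer$W %*% x
      out <- out + layer$b
      list(out = out, cache = list(x = x))
    },
    residual = {
      fb <- nn_forward(layer$branch, x, training)
      if (!is.null(layer$shortcut)) {
        fs <- nn_forward(layer$shortcut, x, training)
        pre <- fb$out + fs$out
        list(out = pmax(pre, 0),
             cache = list(branch = fb$caches, shortcut = fs$caches,
                          mask = pre > 0))
      } else {
        pre <- fb$out + x
        list(out = pmax(pre, 0),
             cache = list(branch = fb$caches, shortcut = NULL, mask = pre > 0))
      }
    },
    dense_concat = {
      fb <- nn_forward(layer$branch, x, training)
      dx <- dim(x); dy <- dim(fb$out)
      out <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
      out[, , seq_len(dx[3]), ] <- x
      out[, , dx[3] + seq_len(dy[3]), ] <- fb$out
      list(out = out, cache = list(branch = fb$caches, c_in = dx[3]))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- nn_forward_layer(layers[[i]], x, training)
    x <- f$out
    caches[[i]] <- f$cache
  }
  list(out = x, caches = caches)
}

nn_backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d_in <- cache$in_dim
      N <- d_in[4]
      dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$cout)
      grads <- list(W = dmat %*% t(cache$ic$col))
      if (!is.null(layer$b)) grads$b <- rowSums(dmat)
      dcol <- crossprod(layer$W, dmat)
      list(dx = nn_col2im(dcol, cache$ic, d_in), grads = grads)
    },
    bn = {
      d <- cache$in_dim; C <- d[3]
      m <- d[1] * d[2] * d[4]
      dgamma <- numeric(C); dbeta <- numeric(C)
      dx <- array(0, d)
      for (c in seq_len(C)) {
        dz <- dout[, , c, ]
        xh <- cache$xhat[, , c, ]
        dgamma[c] <- sum(dz * xh)
        dbeta[c] <- sum(dz)
        inv <- layer$gamma[c] / sqrt(cache$var[c] + layer$eps)
        dx[, , c, ] <- inv * (dz - sum(dz) / m - xh * sum(dz * xh) / m)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = {
      M <- length(cache$am)
      tgt <- cache$ic$idx[cbind(cache$am, seq_len(M))]
      dv <- as.vector(dout)
      agg <- rowsum(dv, tgt)
      dxp <- numeric(prod(cache$ic$dim_pad))
      dxp[as.integer(rownames(agg))] <- agg
      dxp <- array(dxp, cache$ic$dim_pad)
      p <- cache$ic$pad
      if (p > 0)
        dxp <- dxp[(p + 1):(p + cache$r_dim[1]),
                   (p + 1):(p + cache$r_dim[2]), , , drop = FALSE]
      list(dx = array(dxp, cache$in_dim), grads = NULL)
    },
    avgpool = {
      k2 <- nrow(cache$ic$col)
      dcol <- matrix(rep(as.vector(dout) / k2, each = k2), nrow = k2)
      dxr <- nn_col2im(dcol, cache$ic, cache$r_dim)
      list(dx = array(dxr, cache$in_dim), grads = NULL)
    },
    gap = {
      d <- cache$in_dim
      npix <- d[1] * d[2]
      dx <- array(rep(as.vector(dout), each = npix) / npix, d)
      list(dx = dx, grads = NULL)
    },
    linear = {
      list(dx = crossprod(layer$W, dout),
           grads = list(W = dout %*% t(cache$x), b = rowSums(dout)))
    },
    residual = {
      dpre <- dout * cache$mask
      bb <- nn_backward(layer$branch, cache$branch, dpre)
      if (!is.null(layer$shortcut)) {
        bs <- nn_backward(layer$shortcut, cache$shortcut, dpre)
        list(dx = bb$dx + bs$dx,
             grads = list(branch = bb$grads, shortcut = bs$grads))
      } else {
        list(dx = bb$dx + dpre, grads = list(branch = bb$grads, shortcut = NULL))
      }
    },
    dense_concat = {
      ci <- cache$c_in
      dx_part <- dout[, , seq_len(ci), , drop = FALSE]
      dy <- dout[, , -seq_len(ci), , drop = FALSE]
      bb <- nn_backward(layer$branch, cache$branch, dy)
      list(dx = dx_part + bb$dx, grads = list(branch = bb$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- nn_backward_layer(layers[[i]], caches[[i]], dout)
    dout <- b$dx
    grads[i] <- list(b$grads)   # keep NULL placeholders for param-free layers
  }
  list(dx = dout, grads = grads)
}

# Fold batch-norm running-stat updates (computed during a training forward
# pass) back into the layer list.
nn_commit_bn <- function(layers, caches) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    ca <- caches[[i]]
    if (l$type == "bn" && !is.null(ca$new_run_mean)) {
      layers[[i]]$run_mean <- ca$new_run_mean
      layers[[i]]$run_var <- ca$new_run_var
    } else if (l$type %in% c("residual", "dense_concat")) {
      layers[[i]]$branch <- nn_commit_bn(l$branch, ca$branch)
      if (l$type == "residual" && !is.null(l$shortcut))
        layers[[i]]$shortcut <- nn_commit_bn(l$shortcut, ca$shortcut)
    }
  }
  layers
}

# ---- SGD with momentum ------------------------------------------------------

# PyTorch-style velocity update: v <- mu*v + g; p <- p - lr*v. `state`
# mirrors the layer tree; NULL states are initialized lazily.
nn_sgd_step <- function(layers, grads, state, lr, momentum) {
  if (is.null(state)) state <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv", "linear", "bn")) {
      nms <- intersect(names(g), c("W", "b", "gamma", "beta"))
      if (is.null(state[[i]])) state[[i]] <- list()
      for (nm in nms) {
        if (is.null(g[[nm]])) next
        v <- state[[i]][[nm]]
        if (is.null(v)) v <- g[[nm]] * 0
        v <- momentum * v + g[[nm]]
        layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * v
        state[[i]][[nm]] <- v
      }
    } else if (l$type %in% c("residual", "dense_concat")) {
      if (is.null(state[[i]])) state[[i]] <- list(branch = NULL, shortcut = NULL)
      sb <- nn_sgd_step(l$branch, g$branch, state[[i]]$branch, lr, momentum)
      layers[[i]]$branch <- sb$layers
      state[[i]]$branch <- sb$state
      if (l$type == "residual" && !is.null(l$shortcut) && !is.null(g$shortcut)) {
        ss <- nn_sgd_step(l$shortcut, g$shortcut, state[[i]]$shortcut, lr, momentum)
        layers[[i]]$shortcut <- ss$layers
        state[[i]]$shortcut <- ss$state
      }
    }
  }
  list(layers = layers, state = state)
}

# ---- loss -------------------------------------------------------------------

# Softmax cross-entropy on (n_class x N) logits; y is an integer class index
# vector (1-based). Returns mean loss, gradient wrt logits, and class
# probabilities.
nn_softmax_ce <- function(logits, y) {
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  N <- ncol(logits)
  picked <- p[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(y, seq_len(N))] <- dl[cbind(y, seq_len(N))] - 1
  list(loss = loss, dlogits = dl / N, prob = p)
}

# ---- architectures ----------------------------------------------------------

nn_basic_block <- function(cin, cout, stride) {
  branch <- list(nn_conv(cin, cout, 3, stride, 1, bias = FALSE), nn_bn(cout),
                 nn_relu(),
                 nn_conv(cout, cout, 3, 1, 1, bias = FALSE), nn_bn(cout))
  shortcut <- if (stride != 1 || cin != cout)
    list(nn_conv(cin, cout, 1, stride, 0, bias = FALSE), nn_bn(cout)) else NULL
  nn_residual(branch, shortcut)
}

nn_bottleneck <- function(cin, mid, cout, stride) {
  branch <- list(nn_conv(cin, mid, 1, 1, 0, bias = FALSE), nn_bn(mid), nn_relu(),
                 nn_conv(mid, mid, 3, stride, 1, bias = FALSE), nn_bn(mid), nn_relu(),
                 nn_conv(mid, cout, 1, 1, 0, bias = FALSE), nn_bn(cout))
  shortcut <- if (stride != 1 || cin != cout)
    list(nn_conv(cin, cout, 1, stride, 0, bias = FALSE), nn_bn(cout)) else NULL
  nn_residual(branch, shortcut)
}

nn_resnet <- function(block_counts, bottleneck = FALSE, n_class = 2L) {
  layers <- list(nn_conv(3, 64, 7, 2, 3, bias = FALSE), nn_bn(64), nn_relu(),
                 nn_maxpool(3, 2, 1))
  widths <- c(64, 128, 256, 512)
  exp <- if (bottleneck) 4L else 1L
  cin <- 64L
  for (s in seq_along(block_counts)) {
    w <- widths[s]
    for (b in seq_len(block_counts[s])) {
      stride <- if (b == 1 && s > 1) 2L else 1L
      if (bottleneck) {
        layers[[length(layers) + 1L]] <- nn_bottleneck(cin, w, w * exp, stride)
      } else {
        layers[[length(layers) + 1L]] <- nn_basic_block(cin, w, stride)
      }
      cin <- w * exp
    }
  }
  layers[[length(layers) + 1L]] <- nn_gap()
  layers[[length(layers) + 1L]] <- nn_linear(cin, n_class)
  layers
}

nn_densenet <- function(block_counts = c(6, 12, 24, 16), growth = 32L,
                        n_class = 2L) {
  layers <- list(nn_conv(3, 64, 7, 2, 3, bias = FALSE), nn_bn(64), nn_relu(),
                 nn_maxpool(3, 2, 1))
  c <- 64L
  for (s in seq_along(block_counts)) {
    for (b in seq_len(block_counts[s])) {
      branch <- list(nn_bn(c), nn_relu(),
                     nn_conv(c, 4L * growth, 1, 1, 0, bias = FALSE),
                     nn_bn(4L * growth), nn_relu(),
                     nn_conv(4L * growth, growth, 3, 1, 1, bias = FALSE))
      layers[[length(layers) + 1L]] <- nn_dense_concat(branch)
      c <- c + growth
    }
    if (s < length(block_counts)) {
      half <- c %/% 2L
      layers[[length(layers) + 1L]] <- nn_bn(c)
      layers[[length(layers) + 1L]] <- nn_relu()
      layers[[length(layers) + 1L]] <- nn_conv(c, half, 1, 1, 0, bias = FALSE)
      layers[[length(layers) + 1L]] <- nn_avgpool(2, 2, 0)
      c <- half
    }
  }
  layers[[length(layers) + 1L]] <- nn_bn(c)
  layers[[length(layers) + 1L]] <- nn_relu()
  layers[[length(layers) + 1L]] <- nn_gap()
  layers[[length(layers) + 1L]] <- nn_linear(c, n_class)
  layers
}

nn_smallnet <- function(n_class = 2L) {
  list(nn_conv(3, 16, 3, 1, 1), nn_relu(), nn_maxpool(2, 2, 0),
       nn_conv(16, 32, 3, 1, 1), nn_relu(), nn_maxpool(2, 2, 0),
       nn_conv(32, 64, 3, 1, 1), nn_relu(),
       nn_gap(), nn_linear(64, n_class))
}

# Output dimension of the network head (number of classes).
nn_head_dim <- function(layers) {
  last <- layers[[length(layers)]]
  stopifnot(last$type == "linear")
  last$dout
}
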