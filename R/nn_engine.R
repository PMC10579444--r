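# Minimal neural-network engine: dense / conv / batch-norm / ReLU /
# average-pool layers with hand-derived backward passes and an Adam
# optimizer. Written against base R matrix algebra (BLAS does the heavy
# lifting via im2col for convolutions). Internal to the package; the
# user-facing surface is the model constructors and trainers in
# multistage_model.R.

layer_dense <- function(n_in, n_out) {
  sd <- sqrt(2 / n_in)                    # He initialization
  list(type = "dense",
       params = list(W = matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out),
                     b = numeric(n_out)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_bn <- function(n) {
  list(type = "bn",
       params = list(gamma = rep(1, n), beta = numeric(n)),
       state = list(mean = numeric(n), var = rep(1, n), momentum = 0.9))
}

layer_conv <- function(c_in, c_out, k = 3L) {
  sd <- sqrt(2 / (k * k * c_in))
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       params = list(W = matrix(stats::rnorm(k * k * c_in * c_out, 0, sd),
                                k * k * c_in, c_out),
                     b = numeric(c_out)))
}

layer_pool <- function() list(type = "pool", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

# neighbor index table for 3x3 "same" convolution on an H x W plane
conv_index <- function(H, W, k = 3L) {
  Hp <- H + k - 1L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k)
  o <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    idx[, o] <- (j + dj - 1L) * Hp + (i + di)
    o <- o + 1L
  }
  idx
}

layer_forward <- function(layer, x, training = TRUE) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$params$W
      out <- sweep(out, 2, layer$params$b, "+")
      list(out = out, cache = list(x = x))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    bn = {
      eps <- 1e-5
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(sweep(x, 2, mu)^2)
        layer$state$mean <- layer$state$momentum * layer$state$mean +
          (1 - layer$state$momentum) * mu
        layer$state$var <- layer$state$momentum * layer$state$var +
          (1 - layer$state$momentum) * v
      } else {
        mu <- layer$state$mean; v <- layer$state$var
      }
      invstd <- 1 / sqrt(v + eps)
      xhat <- sweep(sweep(x, 2, mu), 2, invstd, "*")
      out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                   layer$params$beta, "+")
      list(out = out, cache = list(xhat = xhat, invstd = invstd),
           state = layer$state)
    },
    conv = {
      d <- dim(x)                          # H, W, C, B
      H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
      k <- layer$k
      pad <- array(0, c(H + k - 1L, W + k - 1L, C, B))
      pad[(1:H) + (k - 1L) %/% 2, (1:W) + (k - 1L) %/% 2, , ] <- x
      dim(pad) <- c((H + k - 1L) * (W + k - 1L), C, B)
      idx <- conv_index(H, W, k)
      P <- pad[as.vector(idx), , , drop = FALSE]
      dim(P) <- c(H * W, k * k, C, B)
      P <- aperm(P, c(1, 4, 2, 3))         # HW, B, kk, C
      dim(P) <- c(H * W * B, k * k * C)
      out <- P %*% layer$params$W
      out <- sweep(out, 2, layer$params$b, "+")
      dim(out) <- c(H * W, B, layer$c_out)
      out <- aperm(out, c(1, 3, 2))
      dim(out) <- c(H, W, layer$c_out, B)
      list(out = out, cache = list(P = P, dims = d, idx = idx))
    },
    pool = {
      d <- dim(x)
      o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
      out <- (x[o1, o1, , , drop = FALSE] + x[o1, o2, , , drop = FALSE] +
                x[o2, o1, , , drop = FALSE] + x[o2, o2, , , drop = FALSE]) / 4
      list(out = out, cache = list(dims = d))
    },
    flatten = {
      d <- dim(x)
      out <- t(matrix(x, prod(d[1:3]), d[4]))
      list(out = out, cache = list(dims = d))
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    bn = {
      B <- nrow(dout)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, layer$params$gamma, "*")
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- cache$xhat * matrix(colMeans(dxhat * cache$xhat),
                                B, ncol(dout), byrow = TRUE)
      list(dx = sweep(t1 - t2, 2, cache$invstd, "*"),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    conv = {
      d <- cache$dims
      H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
      k <- layer$k
      dm <- aperm(dout, c(1, 2, 4, 3))     # H, W, B, Cout
      dim(dm) <- c(H * W * B, layer$c_out)
      dW <- crossprod(cache$P, dm)
      db <- colSums(dm)
      dP <- dm %*% t(layer$params$W)       # HW*B x kk*C
      dim(dP) <- c(H * W, B, k * k, C)
      dP <- aperm(dP, c(1, 3, 4, 2))       # HW, kk, C, B
      dpad <- array(0, c((H + k - 1L) * (W + k - 1L), C, B))
      for (o in seq_len(k * k)) {
        ii <- cache$idx[, o]
        dpad[ii, , ] <- dpad[ii, , , drop = FALSE] +
          array(dP[, o, , ], c(H * W, C, B))
      }
      dim(dpad) <- c(H + k - 1L, W + k - 1L, C, B)
      off <- (k - 1L) %/% 2
      dx <- dpad[(1:H) + off, (1:W) + off, , , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    pool = {
      d <- cache$dims
      dx <- array(0, d)
      o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
      q <- dout / 4
      dx[o1, o1, , ] <- q; dx[o1, o2, , ] <- q
      dx[o2, o1, , ] <- q; dx[o2, o2, , ] <- q
      list(dx = dx, grads = list())
    },
    flatten = {
      list(dx = array(t(dout), cache$dims), grads = list())
    })
}

# run a stack of layers; returns output, per-layer caches, and the
# (possibly updated, for BN running stats) layers
net_forward <- function(layers, x, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
    if (!is.null(res$state)) layers[[i]]$state <- res$state
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- res$dx
    grads[[i]] <- res$grads
  }
  list(dx = dout, grads = grads)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      p <- layers[[i]]$params[[nm]]
      if (wd > 0 && nm %in% c("W"))        # L2 on weights, not biases/BN
        g <- g + wd * p
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      # bias correction folded into a scalar step size
      lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
      layers[[i]]$params[[nm]] <- p - lr_t * st$m / (sqrt(st$v) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

n_params <- function(layers)
  sum(vapply(layers, function(l) sum(lengths(l$params)), 0))
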