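# Compact CNN engine: layers are plain lists with a $type, trainable arrays in
# $par and non-trainable state in $buf. Batches are column-major arrays
# [H, W, C, N] for spatial layers and matrices [d, N] once pooled. Forward
# passes return caches that the matching backward pass consumes; gradients
# mirror the $par structure so the optimizer can walk layers and grads in
# parallel. Convolutions and max-pooling run in compiled code (see
# src/conv_ops.cpp); everything else is vectorized R.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# bias = FALSE for convolutions immediately followed by batch norm (the BN
# shift makes the bias redundant, and reference parameter counts omit it).
layer_conv <- function(k, cin, cout, stride = 1, pad = (k - 1) %/% 2,
                       bias = TRUE) {
  par <- list(W = he_init(c(k, k, cin, cout), k * k * cin))
  if (bias) par$b <- numeric(cout)
  list(type = "conv", k = k, cin = cin, cout = cout, stride = stride, pad = pad,
       bias = bias, par = par)
}

layer_relu <- function() list(type = "relu", par = list())

layer_maxpool <- function(k = 3, stride = 2, pad = 1)
  list(type = "maxpool", k = k, stride = stride, pad = pad, par = list())

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       par = list(gamma = rep(1, c), beta = numeric(c)),
       buf = list(mean = numeric(c), var = rep(1, c)))
}

layer_gap <- function() list(type = "gap", par = list())

# linear layers use the standard uniform +/- 1/sqrt(din) initialization, so
# an untrained classifier emits near-uniform class probabilities
layer_linear <- function(din, dout) {
  bound <- 1 / sqrt(din)
  list(type = "linear", din = din, dout = dout,
       par = list(W = matrix(runif(dout * din, -bound, bound), dout, din),
                  b = numeric(dout)))
}

layer_layernorm <- function(d, eps = 1e-5) {
  list(type = "layernorm", d = d, eps = eps,
       par = list(gamma = rep(1, d), beta = numeric(d)))
}

# Residual basic block: main = conv-bn-relu-conv-bn, shortcut empty list
# (identity) or conv-bn; output ReLU applied after the sum.
layer_resblock <- function(cin, cout, stride = 1) {
  main <- list(layer_conv(3, cin, cout, stride = stride, bias = FALSE),
               layer_bn(cout), layer_relu(),
               layer_conv(3, cout, cout, bias = FALSE), layer_bn(cout))
  short <- if (stride != 1 || cin != cout)
    list(layer_conv(1, cin, cout, stride = stride, pad = 0, bias = FALSE),
         layer_bn(cout))
  else list()
  list(type = "resblock", main = main, short = short, par = list())
}

# --- forward -----------------------------------------------------------------

bn_stats_apply <- function(x, l, train) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  if (train) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
  } else {
    mu <- l$buf$mean
    v <- l$buf$var
  }
  invstd <- 1 / sqrt(v + l$eps)
  xhat <- (xp - rep(mu, each = nrow(xp))) * rep(invstd, each = nrow(xp))
  y <- xhat * rep(l$par$gamma, each = nrow(xp)) +
    rep(l$par$beta, each = nrow(xp))
  y <- aperm(array(y, c(H, W, N, C)), c(1, 2, 4, 3))
  list(y = y, xhat = xhat, invstd = invstd, mu = mu, v = v, dims = d)
}

nn_layer_fwd <- function(l, x, train) {
  switch(l$type,
    conv = {
      y <- cpp_conv2d_fwd(x, dim(x), l$par$W, l$k, l$cin, l$cout,
                          l$par$b %||% numeric(l$cout), l$stride, l$pad)
      list(y = y, cache = list(x = x), layer = l)
    },
    relu = {
      y <- cpp_relu_fwd(x)
      list(y = y, cache = list(y = y), layer = l)
    },
    maxpool = {
      r <- cpp_maxpool_fwd(x, dim(x), l$k, l$stride, l$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)), layer = l)
    },
    bn = {
      s <- bn_stats_apply(x, l, train)
      if (train) {
        m <- l$momentum
        l$buf$mean <- (1 - m) * l$buf$mean + m * s$mu
        l$buf$var <- (1 - m) * l$buf$var + m * s$v
      }
      list(y = s$y, cache = s[c("xhat", "invstd", "dims")], layer = l)
    },
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
      list(y = y, cache = list(xdim = d), layer = l)
    },
    linear = {
      list(y = l$par$W %*% x + l$par$b, cache = list(x = x), layer = l)
    },
    layernorm = {
      mu <- colMeans(x)
      xc <- sweep(x, 2, mu)
      v <- colMeans(xc^2)
      invstd <- rep(1 / sqrt(v + l$eps), each = nrow(x))
      xhat <- xc * invstd
      list(y = xhat * l$par$gamma + l$par$beta,
           cache = list(xhat = xhat, invstd = invstd), layer = l)
    },
    resblock = {
      fm <- nn_forward(l$main, x, train)
      fs <- if (length(l$short)) nn_forward(l$short, x, train)
            else list(out = x, caches = NULL, layers = list())
      y <- cpp_relu_fwd(fm$out + fs$out)
      l$main <- fm$layers
      if (length(l$short)) l$short <- fs$layers
      list(y = y,
           cache = list(main = fm$caches, short = fs$caches, y = y,
                        identity_short = !length(l$short)),
           layer = l)
    },
    stop("unknown layer type: ", l$type))
}

# Returns list(out, caches, layers); `layers` carries updated buffers (BN
# running stats) and must be kept by the caller when train = TRUE.
nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_layer_fwd(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

# --- backward ----------------------------------------------------------------

nn_layer_bwd <- function(l, cache, gy, need_gx = TRUE) {
  switch(l$type,
    conv = {
      r <- cpp_conv2d_bwd(cache$x, dim(cache$x), l$par$W, l$k, l$cin, l$cout,
                          gy, l$stride, l$pad, need_gx)
      g <- list(W = r$gw)
      if (l$bias %||% TRUE) g$b <- r$gb
      list(gx = if (need_gx) r$gx else NULL, grads = g)
    },
    relu = list(gx = cpp_relu_bwd(gy, cache$y), grads = list()),
    maxpool = list(gx = cpp_maxpool_bwd(gy, cache$argmax, cache$xdim),
                   grads = list()),
    bn = {
      d <- cache$dims
      n <- d[1] * d[2] * d[4]
      gp <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
      ggamma <- colSums(gp * cache$xhat)
      gbeta <- colSums(gp)
      gxhat <- gp * rep(l$par$gamma, each = n)
      gxp <- (gxhat - rep(gbeta * l$par$gamma / n, each = n) -
                cache$xhat * rep(ggamma * l$par$gamma / n, each = n)) *
        rep(cache$invstd, each = n)
      gx <- aperm(array(gxp, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    gap = {
      d <- cache$xdim
      hw <- d[1] * d[2]
      gx <- array(rep(as.numeric(gy), each = hw) / hw, d)
      list(gx = gx, grads = list())
    },
    linear = {
      list(gx = if (need_gx) crossprod(l$par$W, gy) else NULL,
           grads = list(W = tcrossprod(gy, cache$x), b = rowSums(gy)))
    },
    layernorm = {
      d <- nrow(cache$xhat)
      gxhat <- gy * l$par$gamma
      m1 <- colMeans(gxhat)
      m2 <- colMeans(gxhat * cache$xhat)
      gx <- (gxhat - rep(m1, each = d) - cache$xhat * rep(m2, each = d)) *
        cache$invstd
      list(gx = gx,
           grads = list(gamma = rowSums(gy * cache$xhat), beta = rowSums(gy)))
    },
    resblock = {
      gs <- cpp_relu_bwd(gy, cache$y)
      bm <- nn_backward(l$main, cache$main, gs, need_gx = TRUE)
      gx <- bm$gx
      gshort <- list()
      if (cache$identity_short) {
        gx <- gx + gs
      } else {
        bs <- nn_backward(l$short, cache$short, gs, need_gx = TRUE)
        gx <- gx + bs$gx
        gshort <- bs$grads
      }
      list(gx = gx, grads = list(main = bm$grads, short = gshort))
    },
    stop("unknown layer type: ", l$type))
}

nn_backward <- function(layers, caches, gy, need_gx = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_layer_bwd(layers[[i]], caches[[i]], gy,
                      need_gx = need_gx || i > 1)
    grads[[i]] <- r$grads
    gy <- r$gx
  }
  list(gx = gy, grads = grads)
}

# --- parameters and optimizer ------------------------------------------------

nn_count_params <- function(layers) {
  n <- 0L
  for (l in layers) {
    n <- n + sum(vapply(l$par, length, 0L))
    if (l$type == "resblock")
      n <- n + nn_count_params(l$main) + nn_count_params(l$short)
  }
  n
}

sgd_state_init <- function(layers) {
  lapply(layers, function(l) {
    # velocity buffers mirror each parameter's shape; plain vectors must stay
    # dim-less so updated biases still broadcast over matrix columns
    s <- lapply(l$par, function(p)
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
    if (l$type == "resblock")
      s <- list(main = sgd_state_init(l$main), short = sgd_state_init(l$short))
    s
  })
}

# SGD with momentum and decoupled-from-nothing classic L2 weight decay
# (decay added to the gradient, as in standard SGD implementations).
sgd_step <- function(layers, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "resblock") {
      rm <- sgd_step(l$main, grads[[i]]$main, state[[i]]$main, lr, momentum,
                     weight_decay)
      l$main <- rm$layers; state[[i]]$main <- rm$state
      if (length(l$short)) {
        rs <- sgd_step(l$short, grads[[i]]$short, state[[i]]$short, lr,
                       momentum, weight_decay)
        l$short <- rs$layers; state[[i]]$short <- rs$state
      }
      layers[[i]] <- l
      next
    }
    for (nm in names(l$par)) {
      g <- grads[[i]][[nm]] + weight_decay * l$par[[nm]]
      v <- momentum * state[[i]][[nm]] + g
      state[[i]][[nm]] <- v
      l$par[[nm]] <- l$par[[nm]] - lr * v
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cross-entropy over softmax. logits: K x N, labels: integer 1..K.
softmax_ce <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- exp(sweep(logits, 2, m))
  p <- sweep(z, 2, colSums(z), "/")
  idx <- cbind(labels, seq_len(N))
  pi <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(pi, 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / N, prob = p)
}
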