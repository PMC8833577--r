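# Minimal feed-forward CNN engine: layers carry parameters and expose
# forward/backward passes; the network topology is a fixed list of layers
# (plus residual blocks), so no general autodiff is needed.  Convolution and
# max-pooling run in compiled code (src/conv.cpp).

new_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  list(type = "conv", params = list(w = w, b = numeric(cout)),
       stride = as.integer(stride), pad = as.integer(pad))
}

new_bn2d <- function(c) {
  list(type = "bn2d", params = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(mean = numeric(c), var = rep(1, c)),
       eps = 1e-5, momentum = 0.1)
}

new_bn1d <- function(d) {
  list(type = "bn1d", params = list(gamma = rep(1, d), beta = numeric(d)),
       state = list(mean = numeric(d), var = rep(1, d)),
       eps = 1e-5, momentum = 0.1)
}

new_act <- function(slope = 0) list(type = "act", params = list(), slope = slope)
new_maxpool <- function(k, stride, pad = 0L)
  list(type = "maxpool", params = list(), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
new_gap <- function() list(type = "gap", params = list())
new_dropout <- function(p) list(type = "dropout", params = list(), p = p)

new_fc <- function(din, dout) {
  list(type = "fc",
       params = list(w = matrix(stats::rnorm(dout * din, sd = sqrt(2 / din)), dout, din),
                     b = numeric(dout)))
}

new_resblock <- function(cin, cout, stride = 1L) {
  block <- list(type = "resblock",
                conv1 = new_conv(3, 3, cin, cout, stride, 1L),
                bn1 = new_bn2d(cout),
                conv2 = new_conv(3, 3, cout, cout, 1L, 1L),
                bn2 = new_bn2d(cout),
                downsample = NULL)
  if (stride != 1L || cin != cout) {
    block$downsample <- list(conv = new_conv(1, 1, cin, cout, stride, 0L),
                             bn = new_bn2d(cout))
  }
  block
}

bn_moments_2d <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  list(mean = colMeans(xm), var = colMeans(xm^2) - colMeans(xm)^2)
}

sweep_channels <- function(x, v, op = "*") {
  # apply per-channel scalar v over dim 3 of a 4-d array
  d <- dim(x)
  vv <- rep(rep(v, each = d[1] * d[2]), times = d[4])
  if (op == "*") x * vv else x + vv
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      y <- nn_conv_fwd(x, layer$params$w, layer$params$b, layer$stride, layer$pad)
      list(y = y, cache = list(x = x))
    },
    bn2d = {
      if (training) {
        mo <- bn_moments_2d(x)
        m <- prod(dim(x)[c(1, 2, 4)])
        invstd <- 1 / sqrt(mo$var + layer$eps)
        xhat <- sweep_channels(sweep_channels(x, -mo$mean, "+"), invstd, "*")
        y <- sweep_channels(sweep_channels(xhat, layer$params$gamma, "*"),
                            layer$params$beta, "+")
        list(y = y, cache = list(xhat = xhat, invstd = invstd, m = m),
             state = list(mean = (1 - layer$momentum) * layer$state$mean + layer$momentum * mo$mean,
                          var = (1 - layer$momentum) * layer$state$var + layer$momentum * mo$var))
      } else {
        invstd <- 1 / sqrt(layer$state$var + layer$eps)
        xhat <- sweep_channels(sweep_channels(x, -layer$state$mean, "+"), invstd, "*")
        y <- sweep_channels(sweep_channels(xhat, layer$params$gamma, "*"),
                            layer$params$beta, "+")
        list(y = y, cache = NULL)
      }
    },
    bn1d = {
      if (training) {
        mu <- rowMeans(x); v <- rowMeans(x^2) - mu^2
        invstd <- 1 / sqrt(v + layer$eps)
        xhat <- (x - mu) * invstd
        list(y = xhat * layer$params$gamma + layer$params$beta,
             cache = list(xhat = xhat, invstd = invstd, m = ncol(x)),
             state = list(mean = (1 - layer$momentum) * layer$state$mean + layer$momentum * mu,
                          var = (1 - layer$momentum) * layer$state$var + layer$momentum * v))
      } else {
        invstd <- 1 / sqrt(layer$state$var + layer$eps)
        xhat <- (x - layer$state$mean) * invstd
        list(y = xhat * layer$params$gamma + layer$params$beta, cache = NULL)
      }
    },
    act = {
      y <- pmax(x, 0) + layer$slope * pmin(x, 0)
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(y = y, cache = list(pos = x > 0))
    },
    maxpool = {
      r <- nn_maxpool_fwd(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
      list(y = y, cache = list(xdim = d))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        y <- x * mask
        if (!is.null(dim(x))) dim(y) <- dim(x)
        list(y = y, cache = list(mask = mask))
      } else list(y = x, cache = NULL)
    },
    fc = {
      list(y = layer$params$w %*% x + layer$params$b, cache = list(x = x))
    },
    resblock = resblock_forward(layer, x, training),
    stop("unknown layer type")
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- nn_conv_bwd(cache$x, layer$params$w, dy, layer$stride, layer$pad, TRUE)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn2d = {
      d <- dim(dy)
      dsum <- function(a) colSums(matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3]))
      dgamma <- dsum(dy * cache$xhat)
      dbeta <- dsum(dy)
      dxhat <- sweep_channels(dy, layer$params$gamma, "*")
      m <- cache$m
      t1 <- sweep_channels(dxhat, -dsum(dxhat) / m, "+")
      t2 <- sweep_channels(cache$xhat, dsum(dxhat * cache$xhat) / m, "*")
      dx <- sweep_channels(t1 - t2, cache$invstd, "*")
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    bn1d = {
      dgamma <- rowSums(dy * cache$xhat)
      dbeta <- rowSums(dy)
      dxhat <- dy * layer$params$gamma
      m <- cache$m
      dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$invstd
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      scale <- layer$slope + (1 - layer$slope) * cache$pos
      dx <- dy * scale
      if (!is.null(dim(dy))) dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      list(dx = nn_maxpool_bwd(dy, cache$argmax, as.integer(cache$xdim)), grads = NULL)
    },
    gap = {
      d <- cache$xdim
      per <- d[1] * d[2]
      dx <- array(rep(as.numeric(dy), each = per) / per, dim = d)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else {
        dx <- dy * cache$mask
        if (!is.null(dim(dy))) dim(dx) <- dim(dy)
        list(dx = dx, grads = NULL)
      }
    },
    fc = {
      list(dx = t(layer$params$w) %*% dy,
           grads = list(w = dy %*% t(cache$x), b = rowSums(dy)))
    },
    resblock = resblock_backward(layer, cache, dy),
    stop("unknown layer type")
  )
}

resblock_forward <- function(block, x, training) {
  caches <- list()
  f1 <- layer_forward(block$conv1, x, training); caches$conv1 <- f1$cache
  f2 <- layer_forward(block$bn1, f1$y, training); caches$bn1 <- f2$cache
  st <- list(); if (!is.null(f2$state)) st$bn1 <- f2$state
  a1 <- layer_forward(new_act(0), f2$y, training); caches$act1 <- a1$cache
  f3 <- layer_forward(block$conv2, a1$y, training); caches$conv2 <- f3$cache
  f4 <- layer_forward(block$bn2, f3$y, training); caches$bn2 <- f4$cache
  if (!is.null(f4$state)) st$bn2 <- f4$state
  if (!is.null(block$downsample)) {
    s1 <- layer_forward(block$downsample$conv, x, training); caches$ds_conv <- s1$cache
    s2 <- layer_forward(block$downsample$bn, s1$y, training); caches$ds_bn <- s2$cache
    if (!is.null(s2$state)) st$ds_bn <- s2$state
    short <- s2$y
  } else short <- x
  pre <- f4$y + short
  a2 <- layer_forward(new_act(0), pre, training); caches$act2 <- a2$cache
  list(y = a2$y, cache = caches, state = if (length(st)) st else NULL)
}

resblock_backward <- function(block, cache, dy) {
  grads <- list()
  b2 <- layer_backward(new_act(0), cache$act2, dy)
  dpre <- b2$dx
  g4 <- layer_backward(block$bn2, cache$bn2, dpre); grads$bn2 <- g4$grads
  g3 <- layer_backward(block$conv2, cache$conv2, g4$dx); grads$conv2 <- g3$grads
  ga <- layer_backward(new_act(0), cache$act1, g3$dx)
  g2 <- layer_backward(block$bn1, cache$bn1, ga$dx); grads$bn1 <- g2$grads
  g1 <- layer_backward(block$conv1, cache$conv1, g2$dx); grads$conv1 <- g1$grads
  dx <- g1$dx
  if (!is.null(block$downsample)) {
    s2 <- layer_backward(block$downsample$bn, cache$ds_bn, dpre); grads$ds_bn <- s2$grads
    s1 <- layer_backward(block$downsample$conv, cache$ds_conv, s2$dx); grads$ds_conv <- s1$grads
    dx <- dx + s1$dx
  } else dx <- dx + dpre
  list(dx = dx, grads = grads)
}

# update running BN statistics inside a layer list after a training forward
apply_bn_state <- function(layers, states) {
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (is.null(st)) next
    if (layers[[i]]$type == "resblock") {
      for (nm in names(st)) {
        if (nm == "ds_bn") layers[[i]]$downsample$bn$state <- st[[nm]]
        else layers[[i]][[nm]]$state <- st[[nm]]
      }
    } else layers[[i]]$state <- st
  }
  layers
}
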