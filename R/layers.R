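# Minimal neural-network layer kernel used by the whole package.
#
# Feature maps are arrays with dim (H, W, C, N); dense activations are
# matrices with dim (N, features). All layers implement forward(); the subset
# needed for on-CPU training and Grad-CAM also implements backward().
# Parameter arrays live in layer$params, non-trainable state in layer$buffers.

new_layer <- function(type, ..., params = list(), buffers = list()) {
  structure(list(type = type, ..., params = params, buffers = buffers),
            class = c(paste0("layer_", type), "bcs_layer"))
}

is_container <- function(layer) {
  layer$type %in% c("sequential", "residual", "concat", "shuffle_stride", "shuffle_basic")
}

layer_children <- function(layer) {
  switch(layer$type,
    sequential = layer$layers,
    residual   = layer$layers,
    concat     = layer$branches,
    shuffle_stride = c(layer$branch1, layer$branch2),
    shuffle_basic  = layer$branch2,
    list())
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- constructors -----------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, kernel, stride = 1L, padding = 0L,
                         depthwise = FALSE, bias = TRUE) {
  kh <- kernel[1]; kw <- if (length(kernel) > 1) kernel[2] else kernel[1]
  cin_g <- if (depthwise) 1L else in_ch
  if (depthwise && out_ch != in_ch)
    stop("depthwise conv requires out_ch == in_ch")
  fan_in <- kh * kw * cin_g
  params <- list(w = he_init(c(kh, kw, cin_g, out_ch), fan_in))
  if (bias) params$b <- numeric(out_ch)
  new_layer("conv2d", in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw,
            stride = as.integer(stride), padding = as.integer(padding),
            depthwise = depthwise, has_bias = bias, params = params)
}

layer_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("batchnorm2d", ch = ch, eps = eps, momentum = momentum,
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)))
}

layer_linear <- function(in_features, out_features, bias = TRUE) {
  lim <- sqrt(6 / (in_features + out_features))
  params <- list(w = array(stats::runif(in_features * out_features, -lim, lim),
                           dim = c(in_features, out_features)))
  if (bias) params$b <- numeric(out_features)
  new_layer("linear", in_features = in_features, out_features = out_features,
            has_bias = bias, params = params)
}

layer_act <- function(fun) new_layer("act", fun = fun)

layer_maxpool2d <- function(kernel, stride = kernel, padding = 0L) {
  new_layer("maxpool2d", k = as.integer(kernel), stride = as.integer(stride),
            padding = as.integer(padding))
}

layer_global_avgpool <- function() new_layer("global_avgpool")

layer_flatten <- function() new_layer("flatten")

# Architectural placeholder: active dropout is not used at this package's
# training scale, so forward is the identity in both modes.
layer_dropout <- function(p) new_layer("dropout", p = p)

layer_sequential <- function(layers) new_layer("sequential", layers = layers)

layer_residual <- function(layers) new_layer("residual", layers = layers)

layer_concat <- function(branches) new_layer("concat", branches = branches)

# ShuffleNetV2 units: the stride unit runs both branches on the full input and
# concatenates; the basic unit splits channels in half and transforms the
# second half. Both end with a channel shuffle of group 2.
layer_shuffle_stride <- function(branch1, branch2) {
  new_layer("shuffle_stride", branch1 = list(layer_sequential(branch1)),
            branch2 = list(layer_sequential(branch2)))
}

layer_shuffle_basic <- function(branch2) {
  new_layer("shuffle_basic", branch2 = list(layer_sequential(branch2)))
}

layer_se_block <- function(ch, squeeze_ch, act = "relu", gate = "sigmoid") {
  new_layer("se_block", ch = ch, squeeze_ch = squeeze_ch, act = act, gate = gate,
            params = list(
              w1 = he_init(c(squeeze_ch, ch), ch), b1 = numeric(squeeze_ch),
              w2 = he_init(c(ch, squeeze_ch), squeeze_ch), b2 = numeric(ch)))
}

layer_spatial_block <- function(kernel = 7L) {
  new_layer("spatial_block", k = as.integer(kernel),
            params = list(w = he_init(c(kernel, kernel, 2, 1), kernel * kernel * 2),
                          b = numeric(1)))
}

# ---- activation functions ---------------------------------------------------

act_fun <- function(fun, x) {
  switch(fun,
    relu     = pmax(x, 0),
    relu6    = pmin(pmax(x, 0), 6),
    sigmoid  = 1 / (1 + exp(-x)),
    silu     = x / (1 + exp(-x)),
    hardswish = x * pmin(pmax(x + 3, 0), 6) / 6,
    hardsigmoid = pmin(pmax(x / 6 + 0.5, 0), 1),
    identity = x,
    stop("unknown activation: ", fun))
}

act_grad <- function(fun, x) {
  switch(fun,
    relu    = (x > 0) * 1,
    relu6   = (x > 0 & x < 6) * 1,
    sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
    silu    = { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) },
    hardswish = ifelse(x <= -3, 0, ifelse(x >= 3, 1, x / 3 + 0.5)),
    hardsigmoid = (x > -3 & x < 3) / 6,
    identity = array(1, dim(x) %||% length(x)),
    stop("no gradient for activation: ", fun))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- low-level conv helpers -------------------------------------------------

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

conv_out_len <- function(n, k, stride, padding) (n + 2L * padding - k) %/% stride + 1L

# im2col on an (Hp, Wp, N, C)-permuted padded input.
im2col <- function(xp, kh, kw, stride, hout, wout) {
  n <- dim(xp)[3]; ch <- dim(xp)[4]
  cols <- array(0, c(hout, wout, n, kh, kw, ch))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    cols[, , , i, j, ] <- xp[seq(i, by = stride, length.out = hout),
                             seq(j, by = stride, length.out = wout), , ]
  }
  dim(cols) <- c(hout * wout * n, kh * kw * ch)
  cols
}

conv2d_fwd <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[4]
  s <- layer$stride; p <- layer$padding
  hout <- conv_out_len(h, layer$kh, s, p); wout <- conv_out_len(w, layer$kw, s, p)
  xp <- pad_hw(x, p)
  if (layer$depthwise) {
    ch <- layer$in_ch
    out <- array(0, c(hout, wout, ch, n))
    xs_list <- vector("list", layer$kh * layer$kw)
    idx <- 0
    for (i in seq_len(layer$kh)) for (j in seq_len(layer$kw)) {
      idx <- idx + 1
      xs <- xp[seq(i, by = s, length.out = hout),
               seq(j, by = s, length.out = wout), , , drop = FALSE]
      dim(xs) <- c(hout, wout, ch, n)
      xs_list[[idx]] <- xs
      wk <- layer$params$w[i, j, 1, ]
      out <- out + xs * rep(wk, each = hout * wout)
    }
    if (layer$has_bias) out <- out + rep(layer$params$b, each = hout * wout)
    list(out = out, cache = list(xs_list = xs_list, in_dim = d, hout = hout, wout = wout))
  } else {
    xpp <- aperm(xp, c(1, 2, 4, 3))
    cols <- im2col(xpp, layer$kh, layer$kw, s, hout, wout)
    wmat <- matrix(layer$params$w, layer$kh * layer$kw * layer$in_ch, layer$out_ch)
    om <- cols %*% wmat
    if (layer$has_bias) om <- sweep(om, 2, layer$params$b, "+")
    dim(om) <- c(hout, wout, n, layer$out_ch)
    list(out = aperm(om, c(1, 2, 4, 3)),
         cache = list(cols = cols, in_dim = d, hout = hout, wout = wout))
  }
}

conv2d_bwd <- function(layer, cache, dout) {
  d <- cache$in_dim; n <- d[4]; s <- layer$stride; p <- layer$padding
  hout <- cache$hout; wout <- cache$wout
  hp <- d[1] + 2L * p; wp <- d[2] + 2L * p
  if (layer$depthwise) {
    ch <- layer$in_ch
    dw <- array(0, dim(layer$params$w))
    dxp <- array(0, c(hp, wp, ch, n))
    idx <- 0
    for (i in seq_len(layer$kh)) for (j in seq_len(layer$kw)) {
      idx <- idx + 1
      xs <- cache$xs_list[[idx]]
      pm <- aperm(dout * xs, c(1, 2, 4, 3))
      dim(pm) <- c(hout * wout * n, ch)
      dw[i, j, 1, ] <- colSums(pm)
      wk <- layer$params$w[i, j, 1, ]
      contrib <- dout * rep(wk, each = hout * wout)
      ri <- seq(i, by = s, length.out = hout); cj <- seq(j, by = s, length.out = wout)
      dxp[ri, cj, , ] <- dxp[ri, cj, , ] + contrib
    }
    grads <- list(w = dw)
    if (layer$has_bias) {
      bm <- aperm(dout, c(1, 2, 4, 3)); dim(bm) <- c(hout * wout * n, ch)
      grads$b <- colSums(bm)
    }
    dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
    dim(dx) <- d
    list(dx = dx, grads = grads)
  } else {
    dm <- aperm(dout, c(1, 2, 4, 3))
    dim(dm) <- c(hout * wout * n, layer$out_ch)
    wmat <- matrix(layer$params$w, layer$kh * layer$kw * layer$in_ch, layer$out_ch)
    dwm <- crossprod(cache$cols, dm)
    grads <- list(w = array(dwm, dim(layer$params$w)))
    if (layer$has_bias) grads$b <- colSums(dm)
    dcols <- tcrossprod(dm, wmat)
    dim(dcols) <- c(hout, wout, n, layer$kh, layer$kw, layer$in_ch)
    dxp <- array(0, c(hp, wp, n, layer$in_ch))
    for (i in seq_len(layer$kh)) for (j in seq_len(layer$kw)) {
      ri <- seq(i, by = s, length.out = hout); cj <- seq(j, by = s, length.out = wout)
      dxp[ri, cj, , ] <- dxp[ri, cj, , ] + dcols[, , , i, j, ]
    }
    dxp <- aperm(dxp, c(1, 2, 4, 3))
    dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
    dim(dx) <- d
    list(dx = dx, grads = grads)
  }
}

# ---- forward ----------------------------------------------------------------

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv2d = conv2d_fwd(layer, x),
    act = {
      out <- act_fun(layer$fun, x)
      list(out = out, cache = list(x = x))
    },
    batchnorm2d = {
      d <- dim(x); hw_n <- d[1] * d[2] * d[4]
      xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(hw_n, d[3])
      if (train) {
        mu <- colMeans(xm)
        vr <- colMeans(sweep(xm, 2, mu)^2)
        layer$buffers$running_mean <-
          (1 - layer$momentum) * layer$buffers$running_mean + layer$momentum * mu
        layer$buffers$running_var <-
          (1 - layer$momentum) * layer$buffers$running_var +
          layer$momentum * vr * hw_n / max(1, hw_n - 1)
      } else {
        mu <- layer$buffers$running_mean
        vr <- layer$buffers$running_var
      }
      inv_sd <- 1 / sqrt(vr + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
      om <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
      dim(om) <- c(d[1], d[2], d[4], d[3])
      list(out = aperm(om, c(1, 2, 4, 3)),
           cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, train = train),
           layer = layer)
    },
    linear = {
      om <- x %*% layer$params$w
      if (layer$has_bias) om <- sweep(om, 2, layer$params$b, "+")
      list(out = om, cache = list(x = x))
    },
    maxpool2d = {
      d <- dim(x); s <- layer$stride; k <- layer$k; p <- layer$padding
      hout <- conv_out_len(d[1], k, s, p); wout <- conv_out_len(d[2], k, s, p)
      xp <- if (p > 0) {
        xq <- array(-Inf, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
        xq[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
        xq
      } else x
      out <- array(-Inf, c(hout, wout, d[3], d[4]))
      win <- array(1L, c(hout, wout, d[3], d[4]))
      idx <- 0
      for (i in seq_len(k)) for (j in seq_len(k)) {
        idx <- idx + 1
        xs <- xp[seq(i, by = s, length.out = hout),
                 seq(j, by = s, length.out = wout), , , drop = FALSE]
        dim(xs) <- dim(out)
        better <- xs > out
        out[better] <- xs[better]
        win[better] <- idx
      }
      list(out = out, cache = list(win = win, in_dim = d, hout = hout, wout = wout))
    },
    global_avgpool = {
      d <- dim(x)
      m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      out <- array(m, c(1, 1, d[3], d[4]))
      list(out = out, cache = list(in_dim = d))
    },
    flatten = {
      d <- dim(x)
      om <- t(matrix(x, d[1] * d[2] * d[3], d[4]))
      list(out = om, cache = list(in_dim = d))
    },
    dropout = list(out = x, cache = list()),
    se_block = {
      d <- dim(x); hw <- d[1] * d[2]
      m <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])  # (C, N)
      z1 <- sweep(layer$params$w1 %*% m, 1, layer$params$b1, "+")
      a1 <- act_fun(layer$act, z1)
      z2 <- sweep(layer$params$w2 %*% a1, 1, layer$params$b2, "+")
      gate <- act_fun(layer$gate, z2)
      out <- x * rep(gate, each = hw)
      list(out = out,
           cache = list(x = x, m = m, z1 = z1, a1 = a1, z2 = z2, gate = gate, hw = hw))
    },
    spatial_block = {
      d <- dim(x); k <- layer$k; pad <- (k - 1L) %/% 2L
      xp4 <- aperm(x, c(1, 2, 4, 3))                      # (H, W, N, C)
      xm <- matrix(xp4, d[1] * d[2] * d[4], d[3])
      avg <- rowMeans(xm)
      wmax <- max.col(xm, ties.method = "first")
      mx <- xm[cbind(seq_along(wmax), wmax)]
      pooled <- array(0, c(d[1], d[2], 2, d[4]))          # 2-channel descriptor
      pooled[, , 1, ] <- avg
      pooled[, , 2, ] <- mx
      cl <- layer_conv2d(2, 1, k, padding = pad, bias = TRUE)
      cl$params <- layer$params
      cf <- conv2d_fwd(cl, pooled)
      mask <- act_fun("sigmoid", cf$out)                  # (H, W, 1, N)
      mp <- array(mask[, , 1, ], c(d[1], d[2], d[4]))
      out <- aperm(aperm(x, c(1, 2, 4, 3)) * as.vector(mp), c(1, 2, 4, 3))
      list(out = out,
           cache = list(x = x, pooled = pooled, conv_cache = cf$cache,
                        pre = cf$out, mask = mask, wmax = wmax, dims = d))
    },
    sequential = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- layer_forward(layer$layers[[i]], x, train)
        if (!is.null(r$layer)) layer$layers[[i]] <- r$layer
        caches[[i]] <- r$cache
        x <- r$out
      }
      list(out = x, cache = caches, layer = layer)
    },
    residual = {
      x0 <- x
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- layer_forward(layer$layers[[i]], x, train)
        if (!is.null(r$layer)) layer$layers[[i]] <- r$layer
        caches[[i]] <- r$cache
        x <- r$out
      }
      list(out = x + x0, cache = caches, layer = layer)
    },
    concat = {
      outs <- vector("list", length(layer$branches))
      for (b in seq_along(layer$branches)) {
        r <- layer_forward(layer$branches[[b]], x, train)
        if (!is.null(r$layer)) layer$branches[[b]] <- r$layer
        outs[[b]] <- r$out
      }
      d1 <- dim(outs[[1]])
      chs <- vapply(outs, function(o) dim(o)[3], numeric(1))
      out <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
      at <- 0
      for (b in seq_along(outs)) {
        out[, , at + seq_len(chs[b]), ] <- outs[[b]]
        at <- at + chs[b]
      }
      list(out = out, cache = NULL, layer = layer)
    },
    shuffle_stride = {
      r1 <- layer_forward(layer$branch1[[1]], x, train)
      r2 <- layer_forward(layer$branch2[[1]], x, train)
      layer$branch1[[1]] <- r1$layer %||% layer$branch1[[1]]
      layer$branch2[[1]] <- r2$layer %||% layer$branch2[[1]]
      d1 <- dim(r1$out); c1 <- d1[3]; c2 <- dim(r2$out)[3]
      out <- array(0, c(d1[1], d1[2], c1 + c2, d1[4]))
      out[, , seq_len(c1), ] <- r1$out
      out[, , c1 + seq_len(c2), ] <- r2$out
      list(out = channel_shuffle(out, 2L), cache = NULL, layer = layer)
    },
    shuffle_basic = {
      d <- dim(x); half <- d[3] %/% 2L
      x1 <- x[, , seq_len(half), , drop = FALSE]
      r2 <- layer_forward(layer$branch2[[1]], x[, , half + seq_len(d[3] - half), , drop = FALSE], train)
      layer$branch2[[1]] <- r2$layer %||% layer$branch2[[1]]
      out <- array(0, d)
      out[, , seq_len(half), ] <- x1
      out[, , half + seq_len(d[3] - half), ] <- r2$out
      list(out = channel_shuffle(out, 2L), cache = NULL, layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

# Interleave channel groups: view channels as (groups x per), transpose, flatten.
channel_shuffle <- function(x, groups) {
  d <- dim(x)
  per <- d[3] %/% groups
  src <- as.vector(t(matrix(seq_len(d[3]), per, groups)))
  x2 <- x[, , src, , drop = FALSE]
  dim(x2) <- d
  x2
}

# ---- backward ---------------------------------------------------------------

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv2d = conv2d_bwd(layer, cache, dout),
    act = list(dx = dout * act_grad(layer$fun, cache$x), grads = list()),
    batchnorm2d = {
      d <- cache$dims; hw_n <- d[1] * d[2] * d[4]
      dm <- aperm(dout, c(1, 2, 4, 3)); dim(dm) <- c(hw_n, d[3])
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      if (cache$train) {
        dxhat <- sweep(dm, 2, layer$params$gamma, "*")
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
        dxm <- sweep(t1 - t2, 2, cache$inv_sd, "*")
      } else {
        dxm <- sweep(sweep(dm, 2, layer$params$gamma, "*"), 2, cache$inv_sd, "*")
      }
      dim(dxm) <- c(d[1], d[2], d[4], d[3])
      list(dx = aperm(dxm, c(1, 2, 4, 3)), grads = list(gamma = dgamma, beta = dbeta))
    },
    linear = {
      grads <- list(w = crossprod(cache$x, dout))
      if (layer$has_bias) grads$b <- colSums(dout)
      list(dx = tcrossprod(dout, layer$params$w), grads = grads)
    },
    maxpool2d = {
      d <- cache$in_dim; s <- layer$stride; k <- layer$k; p <- layer$padding
      hout <- cache$hout; wout <- cache$wout
      dxp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
      idx <- 0
      for (i in seq_len(k)) for (j in seq_len(k)) {
        idx <- idx + 1
        sel <- cache$win == idx
        if (!any(sel)) next
        contrib <- array(0, dim(dout)); contrib[sel] <- dout[sel]
        ri <- seq(i, by = s, length.out = hout); cj <- seq(j, by = s, length.out = wout)
        dxp[ri, cj, , ] <- dxp[ri, cj, , ] + contrib
      }
      dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    global_avgpool = {
      d <- cache$in_dim
      g <- array(dout, c(d[3], d[4]))
      dx <- array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    flatten = {
      d <- cache$in_dim
      dx <- array(t(dout), d)
      list(dx = dx, grads = list())
    },
    dropout = list(dx = dout, grads = list()),
    se_block = {
      d <- dim(cache$x); hw <- cache$hw
      # out = x * gate (gate broadcast over H, W)
      dgate_full <- dout * cache$x
      dg <- matrix(colSums(matrix(dgate_full, hw, d[3] * d[4])), d[3], d[4])
      dx_direct <- dout * rep(cache$gate, each = hw)
      dz2 <- dg * act_grad(layer$gate, cache$z2)
      da1 <- crossprod(layer$params$w2, dz2)
      dz1 <- da1 * act_grad(layer$act, cache$z1)
      dm <- crossprod(layer$params$w1, dz1)
      dx_pool <- array(rep(as.vector(dm) / hw, each = hw), d)
      list(dx = dx_direct + dx_pool,
           grads = list(w1 = tcrossprod(dz1, cache$m), b1 = rowSums(dz1),
                        w2 = tcrossprod(dz2, cache$a1), b2 = rowSums(dz2)))
    },
    spatial_block = {
      d <- cache$dims; k <- layer$k; pad <- (k - 1L) %/% 2L
      mp <- array(cache$mask[, , 1, ], c(d[1], d[2], d[4]))
      dx_direct <- aperm(aperm(dout, c(1, 2, 4, 3)) * as.vector(mp), c(1, 2, 4, 3))
      dmask_full <- dout * cache$x
      dmask <- array(0, c(d[1], d[2], 1, d[4]))
      dmask[, , 1, ] <- apply(dmask_full, c(1, 2, 4), sum)
      dpre <- dmask * act_grad("sigmoid", cache$pre)
      cl <- layer_conv2d(2, 1, k, padding = pad, bias = TRUE)
      cl$params <- layer$params
      cb <- conv2d_bwd(cl, cache$conv_cache, dpre)
      dpool <- cb$dx                                      # (H, W, 2, N)
      davg <- array(dpool[, , 1, ] / d[3], c(d[1], d[2], d[4]))
      dx_pool <- array(0, d)
      for (c in seq_len(d[3])) dx_pool[, , c, ] <- davg
      # max-pool branch routes gradient to the winning channel
      dmx <- dpool[, , 2, ]                               # (H, W, N)
      dmx_m <- as.vector(dmx)
      dxm_max <- matrix(0, d[1] * d[2] * d[4], d[3])
      dxm_max[cbind(seq_along(cache$wmax), cache$wmax)] <- dmx_m
      dx_max <- aperm(array(dxm_max, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx_direct + dx_pool + dx_max, grads = cb$grads)
    },
    sequential = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- layer_backward(layer$layers[[i]], cache[[i]], dout)
        grads[[i]] <- r$grads
        dout <- r$dx
      }
      list(dx = dout, grads = grads)
    },
    residual = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      dskip <- dout
      for (i in rev(seq_len(n))) {
        r <- layer_backward(layer$layers[[i]], cache[[i]], dout)
        grads[[i]] <- r$grads
        dout <- r$dx
      }
      list(dx = dout + dskip, grads = grads)
    },
    stop("backward not implemented for layer type: ", layer$type))
}

# ---- parameter bookkeeping --------------------------------------------------

params_tree <- function(layer) {
  if (is_container(layer)) {
    lapply(layer_children(layer), params_tree)
  } else {
    layer$params
  }
}

n_params_layer <- function(layer) {
  as.integer(sum(rapply(params_tree(layer), length, how = "unlist"), 0L))
}

flatten_arrays <- function(tree) {
  out <- list()
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else out[[length(out) + 1L]] <<- x
    invisible(NULL)
  }
  rec(tree)
  out
}

set_params_tree <- function(layer, tree) {
  if (is_container(layer)) {
    kids <- layer_children(layer)
    kids <- Map(set_params_tree, kids, tree)
    switch(layer$type,
      sequential = { layer$layers <- kids },
      residual   = { layer$layers <- kids },
      concat     = { layer$branches <- kids },
      shuffle_stride = { layer$branch1 <- kids[1]; layer$branch2 <- kids[2] },
      shuffle_basic  = { layer$branch2 <- kids[1] })
    layer
  } else {
    layer$params <- tree
    layer
  }
}

# ---- shape and FLOP propagation --------------------------------------------
# shp is c(H, W, C); FLOPs are multiply-accumulates of conv/linear layers.

layer_shape_flops <- function(layer, shp) {
  switch(layer$type,
    conv2d = {
      hout <- conv_out_len(shp[1], layer$kh, layer$stride, layer$padding)
      wout <- conv_out_len(shp[2], layer$kw, layer$stride, layer$padding)
      cin_g <- if (layer$depthwise) 1 else layer$in_ch
      list(shape = c(hout, wout, layer$out_ch),
           flops = hout * wout * layer$kh * layer$kw * cin_g * layer$out_ch)
    },
    linear = list(shape = c(layer$out_features), flops = layer$in_features * layer$out_features),
    maxpool2d = {
      hout <- conv_out_len(shp[1], layer$k, layer$stride, layer$padding)
      wout <- conv_out_len(shp[2], layer$k, layer$stride, layer$padding)
      list(shape = c(hout, wout, shp[3]), flops = 0)
    },
    global_avgpool = list(shape = c(1, 1, shp[3]), flops = 0),
    flatten = list(shape = prod(shp), flops = 0),
    se_block = list(shape = shp, flops = 2 * layer$ch * layer$squeeze_ch),
    spatial_block = list(shape = shp, flops = shp[1] * shp[2] * layer$k^2 * 2),
    sequential = ,
    residual = {
      fl <- 0
      for (l in layer$layers) {
        r <- layer_shape_flops(l, shp); shp <- r$shape; fl <- fl + r$flops
      }
      list(shape = shp, flops = fl)
    },
    concat = {
      fl <- 0; chs <- 0; sh <- NULL
      for (b in layer$branches) {
        r <- layer_shape_flops(b, shp); fl <- fl + r$flops
        chs <- chs + r$shape[3]; sh <- r$shape
      }
      list(shape = c(sh[1], sh[2], chs), flops = fl)
    },
    shuffle_stride = {
      r1 <- layer_shape_flops(layer$branch1[[1]], shp)
      r2 <- layer_shape_flops(layer$branch2[[1]], shp)
      list(shape = c(r1$shape[1], r1$shape[2], r1$shape[3] + r2$shape[3]),
           flops = r1$flops + r2$flops)
    },
    shuffle_basic = {
      half <- shp[3] %/% 2
      r2 <- layer_shape_flops(layer$branch2[[1]], c(shp[1], shp[2], shp[3] - half))
      list(shape = c(r2$shape[1], r2$shape[2], half + r2$shape[3]), flops = r2$flops)
    },
    list(shape = shp, flops = 0))
}
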