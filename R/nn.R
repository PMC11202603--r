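# Minimal reverse-mode neural-network kernels.
#
# Layers are environments holding `par` (named arrays) and `grad` (same
# shapes); `layer_forward()` caches activations, `layer_backward()` returns
# the input gradient and accumulates parameter gradients. Tensor layouts:
# [batch, channel, time] for 1-D, [batch, channel, height, width] for 2-D.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$par <- list()
  l$grad <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- "nn_layer"
  l
}

he_init <- function(fan_in, dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

nn_linear <- function(in_f, out_f) {
  l <- new_layer("linear", in_f = in_f, out_f = out_f)
  l$par$W <- he_init(in_f, c(out_f, in_f))
  l$par$b <- numeric(out_f)
  l
}

nn_conv1d <- function(in_ch, out_ch, kernel, stride = 1L, pad = kernel %/% 2) {
  l <- new_layer("conv1d", in_ch = in_ch, out_ch = out_ch,
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad))
  l$par$W <- he_init(in_ch * kernel, c(out_ch, in_ch * kernel))
  l$par$b <- numeric(out_ch)
  l
}

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = kernel %/% 2) {
  l <- new_layer("conv2d", in_ch = in_ch, out_ch = out_ch,
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad))
  l$par$W <- he_init(in_ch * kernel^2, c(out_ch, in_ch * kernel^2))
  l$par$b <- numeric(out_ch)
  l
}

nn_relu <- function() new_layer("relu")

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", ch = ch, momentum = momentum, eps = eps)
  l$par$gamma <- rep(1, ch)
  l$par$beta <- numeric(ch)
  l$run_mean <- numeric(ch)
  l$run_var <- rep(1, ch)
  l
}

nn_gap2d <- function() new_layer("gap2d")

nn_seq <- function(...) new_layer("seq", layers = list(...))

# residual unit: relu(x + conv-relu-conv(x)), shape preserving
nn_res1d <- function(ch, kernel) {
  new_layer("res1d", inner = nn_seq(
    nn_conv1d(ch, ch, kernel, 1L), nn_relu(), nn_conv1d(ch, ch, kernel, 1L)
  ))
}

# ---- forward ----

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    linear = {
      l$x <- x
      sweep(x %*% t(l$par$W), 2, l$par$b, `+`)
    },
    conv1d = conv1d_fwd(l, x),
    conv2d = conv2d_fwd(l, x),
    relu = {
      l$mask <- x > 0
      x * l$mask
    },
    bn = bn_fwd(l, x, train),
    gap2d = {
      d <- dim(x)
      l$in_dim <- d
      y <- apply(x, c(1, 2), mean)
      dim(y) <- d[1:2]
      y
    },
    seq = {
      for (sub in l$layers) x <- layer_forward(sub, x, train)
      x
    },
    res1d = {
      h <- layer_forward(l$inner, x, train)
      s <- x + h
      l$mask <- s > 0
      s * l$mask
    },
    stop("unknown layer type ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    linear = {
      l$grad$W <- acc(l$grad$W, t(dy) %*% l$x)
      l$grad$b <- acc(l$grad$b, colSums(dy))
      dy %*% l$par$W
    },
    conv1d = conv1d_bwd(l, dy),
    conv2d = conv2d_bwd(l, dy),
    relu = dy * l$mask,
    bn = bn_bwd(l, dy),
    gap2d = {
      d <- l$in_dim
      k <- prod(d[-(1:2)])
      array(rep(as.vector(dy), k) / k, dim = d)
    },
    seq = {
      for (sub in rev(l$layers)) dy <- layer_backward(sub, dy)
      dy
    },
    res1d = {
      ds <- dy * l$mask
      ds + layer_backward(l$inner, ds)
    },
    stop("unknown layer type ", l$type)
  )
}

acc <- function(g, delta) if (is.null(g)) delta else g + delta

# ---- conv1d via im2col ----
#
# 1-D convolutions run in [channel, time, batch] layout: the im2col gather,
# the matrix products and the col2im scatter all operate on that memory
# order directly, so no transposition is needed anywhere in the encoder
# chain (ReLU and residual blocks are elementwise and layout-agnostic).

conv1d_prepare <- function(l, C, T_in) {
  p <- l$pad; k <- l$kernel; s <- l$stride
  Tp <- T_in + 2L * p
  T_out <- (Tp - k) %/% s + 1L
  # row index into the (C x Tp) plane for each (c, kk, t_out)
  idx <- array(0L, dim = c(C, k, T_out))
  for (to in seq_len(T_out)) {
    for (kk in seq_len(k)) {
      t_in <- (to - 1L) * s + kk
      idx[, kk, to] <- seq_len(C) + C * (t_in - 1L)
    }
  }
  iv <- as.vector(idx)
  l$geom <- list(
    C = C, T_in = T_in, Tp = Tp, T_out = T_out, idx = iv,
    # sparse scatter operator for the backward col2im accumulation
    scatter = Matrix::sparseMatrix(
      i = iv, j = seq_along(iv), x = 1, dims = c(C * Tp, length(iv))
    )
  )
}

conv1d_fwd <- function(l, x) {
  d <- dim(x)  # [C, T, B]
  if (is.null(l$geom) || l$geom$T_in != d[2] || l$geom$C != d[1]) {
    conv1d_prepare(l, d[1], d[2])
  }
  g <- l$geom; B <- d[3]
  xp <- array(0, dim = c(g$C, g$Tp, B))
  xp[, l$pad + seq_len(d[2]), ] <- x
  dim(xp) <- c(g$C * g$Tp, B)
  A <- xp[g$idx, , drop = FALSE]           # (C*k*T_out) x B
  dim(A) <- c(g$C * l$kernel, g$T_out * B)
  l$A <- A
  y <- l$par$W %*% A + l$par$b             # (O) x (T_out*B)
  dim(y) <- c(l$out_ch, g$T_out, B)
  y
}

conv1d_bwd <- function(l, dy) {
  g <- l$geom
  B <- dim(dy)[3]
  dim(dy) <- c(l$out_ch, g$T_out * B)
  l$grad$W <- acc(l$grad$W, tcrossprod(dy, l$A))
  l$grad$b <- acc(l$grad$b, rowSums(dy))
  dA <- crossprod(l$par$W, dy)             # (C*k) x (T_out*B)
  dim(dA) <- c(g$C * l$kernel * g$T_out, B)
  dxp <- as.matrix(g$scatter %*% dA)
  dim(dxp) <- c(g$C, g$Tp, B)
  dxp[, l$pad + seq_len(g$T_in), , drop = FALSE]
}

# ---- conv2d via im2col ----

conv2d_prepare <- function(l, C, H, W) {
  p <- l$pad; k <- l$kernel; s <- l$stride
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  idx <- array(0L, dim = c(C * k * k, Ho * Wo))
  pos <- 0L
  for (wo in seq_len(Wo)) {
    for (ho in seq_len(Ho)) {
      pos <- pos + 1L
      h_in <- (ho - 1L) * s + seq_len(k)
      w_in <- (wo - 1L) * s + seq_len(k)
      base <- outer(C * (h_in - 1L), C * Hp * (w_in - 1L), `+`)
      idx[, pos] <- as.vector(outer(seq_len(C), as.vector(base), `+`))
    }
  }
  iv <- as.vector(idx)
  l$geom <- list(
    C = C, H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = iv,
    scatter = Matrix::sparseMatrix(
      i = iv, j = seq_along(iv), x = 1, dims = c(C * Hp * Wp, length(iv))
    )
  )
}

conv2d_fwd <- function(l, x) {
  d <- dim(x)  # [B, C, H, W]
  if (is.null(l$geom) || l$geom$H != d[3] || l$geom$W != d[4] || l$geom$C != d[2]) {
    conv2d_prepare(l, d[2], d[3], d[4])
  }
  g <- l$geom; B <- d[1]
  xp <- array(0, dim = c(g$C, g$Hp, g$Wp, B))
  xp[, l$pad + seq_len(g$H), l$pad + seq_len(g$W), ] <- aperm(x, c(2, 3, 4, 1))
  dim(xp) <- c(g$C * g$Hp * g$Wp, B)
  A <- xp[g$idx, , drop = FALSE]
  dim(A) <- c(g$C * l$kernel^2, g$Ho * g$Wo * B)
  l$A <- A
  y <- l$par$W %*% A + l$par$b
  dim(y) <- c(l$out_ch, g$Ho, g$Wo, B)
  aperm(y, c(4, 1, 2, 3))
}

conv2d_bwd <- function(l, dy) {
  g <- l$geom; B <- dim(dy)[1]
  dy_m <- aperm(dy, c(2, 3, 4, 1))
  dim(dy_m) <- c(l$out_ch, g$Ho * g$Wo * B)
  l$grad$W <- acc(l$grad$W, dy_m %*% t(l$A))
  l$grad$b <- acc(l$grad$b, rowSums(dy_m))
  dA <- t(l$par$W) %*% dy_m
  dim(dA) <- c(g$C * l$kernel^2 * g$Ho * g$Wo, B)
  dxp <- as.matrix(g$scatter %*% dA)
  dim(dxp) <- c(g$C, g$Hp, g$Wp, B)
  dx <- dxp[, l$pad + seq_len(g$H), l$pad + seq_len(g$W), , drop = FALSE]
  aperm(dx, c(4, 1, 2, 3))
}

# ---- batch norm (per channel, any spatial rank) ----

bn_fwd <- function(l, x, train) {
  d <- dim(x)
  xm <- aperm(x, c(2, seq_along(d)[-2]))
  dim(xm) <- c(d[2], prod(d[-2]))
  if (train) {
    m <- rowMeans(xm)
    v <- rowMeans(xm^2) - m^2
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * m
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    m <- l$run_mean; v <- l$run_var
  }
  inv <- 1 / sqrt(v + l$eps)
  xh <- (xm - m) * inv
  l$xh <- xh; l$inv <- inv; l$in_dim <- d; l$train <- train
  ym <- l$par$gamma * xh + l$par$beta
  y <- array(ym, dim = c(d[2], d[-2]))
  aperm(y, order(c(2, seq_along(d)[-2])))
}

bn_bwd <- function(l, dy) {
  d <- l$in_dim
  dym <- aperm(dy, c(2, seq_along(d)[-2]))
  dim(dym) <- c(d[2], prod(d[-2]))
  l$grad$gamma <- acc(l$grad$gamma, rowSums(dym * l$xh))
  l$grad$beta <- acc(l$grad$beta, rowSums(dym))
  dxh <- dym * l$par$gamma
  if (isTRUE(l$train)) {
    n <- ncol(dxh)
    dxm <- l$inv * (dxh - rowMeans(dxh) - l$xh * rowMeans(dxh * l$xh))
  } else {
    dxm <- l$inv * dxh
  }
  dx <- array(dxm, dim = c(d[2], d[-2]))
  aperm(dx, order(c(2, seq_along(d)[-2])))
}

# ---- parameter plumbing ----

collect_layers <- function(l) {
  if (l$type == "seq") {
    unlist(lapply(l$layers, collect_layers), recursive = FALSE)
  } else if (l$type == "res1d") {
    collect_layers(l$inner)
  } else if (length(l$par) > 0) {
    list(l)
  } else {
    list()
  }
}

zero_grads <- function(layers) {
  for (l in layers) l$grad <- list()
  invisible(NULL)
}

# snapshots carry the trainable parameters AND the batch-norm running
# statistics — a checkpoint is only reproducible with both
get_params <- function(layers) {
  lapply(layers, function(l) {
    list(par = l$par, run_mean = l$run_mean, run_var = l$run_var)
  })
}

set_params <- function(layers, snapshot) {
  for (i in seq_along(layers)) {
    layers[[i]]$par <- snapshot[[i]]$par
    if (!is.null(snapshot[[i]]$run_mean)) {
      layers[[i]]$run_mean <- snapshot[[i]]$run_mean
      layers[[i]]$run_var <- snapshot[[i]]$run_var
    }
  }
  invisible(NULL)
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, 1L)), 1))
}

# ---- Adam optimizer with optional decoupled L2 on weight matrices ----

adam_state <- function(layers) {
  list(
    m = lapply(layers, function(l) lapply(l$par, function(p) p * 0)),
    v = lapply(layers, function(l) lapply(l$par, function(p) p * 0)),
    t = 0L
  )
}

adam_step <- function(layers, state, lr, l2_weight = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 5) {
  if (is.finite(clip_norm)) {
    total <- 0
    for (l in layers) for (g in l$grad) total <- total + sum(g^2)
    scale <- if (total > clip_norm^2) clip_norm / sqrt(total) else 1
    if (scale < 1) {
      for (l in layers) for (nm in names(l$grad)) {
        l$grad[[nm]] <- l$grad[[nm]] * scale
      }
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      if (is.null(g)) next
      if (l2_weight > 0 && nm == "W") g <- g + l2_weight * l$par[[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      l$par[[nm]] <- l$par[[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) / (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  state
}
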