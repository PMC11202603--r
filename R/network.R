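#' Network configuration for the AC-regression model
#'
#' Architecture of the B-mode-guided attenuation-regression network: five
#' per-angle convolutional encoders (independent weights, residual blocks),
#' channel-wise fusion, a B-mode-guided adaptive denormalization (BGN) layer
#' whose per-time-slice scale and shift vectors are produced from the B-mode
#' image by 4 shared convolutional layers followed by 4 fully connected layers
#' per parameter, a 2-D convolutional trunk with batch normalization, and a
#' fully connected head with a bounded output mapping onto the physical AC
#' range.
#'
#' @param encoder_widths Channel widths of the per-angle encoder stages (one
#'   stride-2 convolution plus one residual block per stage).
#' @param encoder_kernel,encoder_stride 1-D convolution kernel size and
#'   down-sampling stride of each encoder stage.
#' @param residual Use residual blocks in the encoders.
#' @param bgn_conv_layers Number of shared convolutional layers in the B-mode
#'   branch (default 4).
#' @param bgn_fc_layers Number of fully connected layers per BGN parameter
#'   head (default 4).
#' @param bgn_conv_channels Channel width of the shared B-mode convolutions.
#' @param bgn_fc_width Hidden width of the BGN parameter heads.
#' @param bgn_per_channel If `TRUE`, gamma/beta are per-slice-and-channel
#'   vectors rather than scalars per time slice.
#' @param bgn_axis Standardization axis of the BGN layer: `"time"` (each
#'   feature channel standardized across time — the adaptive
#'   instance-normalization convention, default) or `"slice"` (each time
#'   slice standardized across channels).
#' @param trunk_widths Channel widths of the 2-D trunk convolutions.
#' @param trunk_kernel Trunk kernel size.
#' @param head_fc_layers Number of fully connected head layers (default 2).
#' @param head_width Hidden width of the head.
#' @param input_shape Envelope feature shape as (angles, channels, time).
#' @param bmode_shape B-mode conditioning image shape in pixels.
#' @param ac_range Output range in dB/cm/MHz (bounded activation).
#' @param eps Epsilon guarding the BGN standard deviation.
#' @param seed Weight-initialization seed.
#' @return An object of class `network_config`.
#' @export
network_config <- function(encoder_widths = c(16, 32, 64),
                           encoder_kernel = 7L,
                           encoder_stride = 2L,
                           residual = TRUE,
                           bgn_conv_layers = 4L,
                           bgn_fc_layers = 4L,
                           bgn_conv_channels = 8L,
                           bgn_fc_width = 32L,
                           bgn_per_channel = FALSE,
                           bgn_axis = c("time", "slice"),
                           trunk_widths = c(64, 128),
                           trunk_kernel = 3L,
                           head_fc_layers = 2L,
                           head_width = 32L,
                           input_shape = c(5L, 16L, 128L),
                           bmode_shape = c(32L, 32L),
                           ac_range = c(0, 1.2),
                           eps = 1e-5,
                           seed = 1L) {
  if (input_shape[1] != 5L) {
    stop_config("the model consumes exactly five angle frames")
  }
  if (bgn_conv_layers < 1 || bgn_fc_layers < 1) {
    stop_config("BGN branch needs at least one conv and one fc layer")
  }
  t_f <- input_shape[3]
  for (i in seq_along(encoder_widths)) t_f <- t_f %/% encoder_stride
  if (t_f < 2) stop_config("encoder downsamples the time axis away")
  structure(
    list(
      encoder_widths = encoder_widths, encoder_kernel = as.integer(encoder_kernel),
      encoder_stride = as.integer(encoder_stride), residual = residual,
      bgn_conv_layers = as.integer(bgn_conv_layers),
      bgn_fc_layers = as.integer(bgn_fc_layers),
      bgn_conv_channels = as.integer(bgn_conv_channels),
      bgn_fc_width = as.integer(bgn_fc_width),
      bgn_per_channel = isTRUE(bgn_per_channel),
      bgn_axis = match.arg(bgn_axis),
      trunk_widths = trunk_widths, trunk_kernel = as.integer(trunk_kernel),
      head_fc_layers = as.integer(head_fc_layers), head_width = as.integer(head_width),
      input_shape = as.integer(input_shape), bmode_shape = as.integer(bmode_shape),
      ac_range = ac_range, eps = eps, seed = as.integer(seed),
      fused_time = as.integer(t_f),
      fused_channels = as.integer(5L * encoder_widths[length(encoder_widths)])
    ),
    class = "network_config"
  )
}

#' Apply B-mode-guided adaptive denormalization to encoded features
#'
#' The BGN primitive: each time slice of the encoded feature map is
#' standardized across its entries (population mean `mu` and standard
#' deviation `sigma`), then rescaled and shifted by the conditioning
#' parameters: `X_t = gamma_t * (x_t - mu) / sigma + beta_t`. With
#' `gamma_t = sigma` and `beta_t = mu` the transform is the identity; for any
#' `gamma_t, beta_t` the slice mean of the output is `beta_t` and its
#' population standard deviation is `|gamma_t|`.
#'
#' @param x Encoded features: a numeric vector (one slice), a channels x time
#'   matrix, or a `[batch, channels, time]` array.
#' @param gamma,beta Scale and shift: scalars, per-slice vectors (length =
#'   time), `[batch, time]` matrices, or (per-channel mode) arrays shaped like
#'   `x`.
#' @param eps Lower guard on `sigma`; slices with population standard
#'   deviation below `eps` are stabilized at `eps`.
#' @return An array shaped like `x`, with attributes `mu` and `sigma` holding
#'   the per-slice statistics.
#' @export
bgn_apply <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  shape <- dim(x)
  if (is.null(shape)) {
    x <- array(x, dim = c(1L, length(x), 1L))
  } else if (length(shape) == 2L) {
    x <- array(x, dim = c(1L, shape))
  } else if (length(shape) != 3L) {
    stop_input("x must be a vector, matrix, or [batch, channel, time] array")
  }
  if (length(x) == 0) stop_input("x must be nonempty")
  d <- dim(x)
  mu <- apply(x, c(1, 3), mean)                    # [B, T]
  sig <- sqrt(apply(x, c(1, 3), function(v) mean((v - mean(v))^2)))
  sig <- pmax(sig, eps)
  mu_e <- aperm(array(mu, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  sig_e <- aperm(array(sig, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  expand_par <- function(p) {
    if (length(p) == 1) {
      array(p, dim = d)
    } else if (is.null(dim(p)) && length(p) == d[3]) {
      aperm(array(rep(p, each = d[1]), dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    } else if (identical(dim(p), d[c(1, 3)])) {
      aperm(array(p, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    } else if (identical(dim(p), d)) {
      p
    } else {
      stop_input("gamma/beta shape incompatible with x")
    }
  }
  g <- expand_par(gamma); b <- expand_par(beta)
  out <- g * (x - mu_e) / sig_e + b
  if (is.null(shape)) {
    out <- as.vector(out)
  } else if (length(shape) == 2L) {
    out <- array(out, dim = shape)
  }
  attr(out, "mu") <- drop(mu)
  attr(out, "sigma") <- drop(sig)
  out
}

# forward + cache for training. Internal layout: x [C, T, B]; gamma/beta are
# [B, T] head outputs (or [C, T, B] in per-channel mode). Per-slice moments
# are computed across the channel axis via column means of the C x (T*B)
# matrix view.
bgn_fwd <- function(x, gamma, beta, eps, axis = c("time", "slice")) {
  axis <- match.arg(axis)
  d <- dim(x); C <- d[1]; n <- d[2] * d[3]
  if (axis == "time") {
    # per-channel standardization across the time axis (the adaptive
    # instance-normalization convention): moments per (channel, batch item)
    xt <- aperm(x, c(2, 1, 3))
    dim(xt) <- c(d[2], C * d[3])
    mu_t <- colMeans(xt)
    sig_t <- pmax(sqrt(pmax(colMeans(xt^2) - mu_t^2, 0)), eps)
    xht <- (xt - rep(mu_t, each = d[2])) / rep(sig_t, each = d[2])
    dim(xht) <- c(d[2], C, d[3])
    xh <- aperm(xht, c(2, 1, 3))
    dim(xh) <- c(C, n)
    ge <- expand_bgn_par(gamma, d)
    be <- expand_bgn_par(beta, d)
    y <- ge * xh + be
    dim(y) <- d
    return(list(y = y, xh = xh, sig = sig_t, ge = ge, d = d, axis = axis))
  }
  xm <- x; dim(xm) <- c(C, n)
  mu <- colMeans(xm)
  v <- pmax(colMeans(xm^2) - mu^2, 0)
  sig <- pmax(sqrt(v), eps)
  xh <- (xm - rep(mu, each = C)) / rep(sig, each = C)
  ge <- expand_bgn_par(gamma, d)
  be <- expand_bgn_par(beta, d)
  y <- ge * xh + be
  dim(y) <- d
  list(y = y, xh = xh, sig = sig, ge = ge, d = d, axis = axis)
}

# gamma/beta given as [B, T] head outputs (broadcast across channels) or
# already shaped [C, T, B]; returns a C x (T*B) vector/matrix view
expand_bgn_par <- function(p, d) {
  if (identical(dim(p), d)) {
    dim(p) <- c(d[1], d[2] * d[3])
    p
  } else {
    rep(as.vector(t(p)), each = d[1])
  }
}

bgn_bwd <- function(cache, dy, per_channel) {
  d <- cache$d; C <- d[1]; n <- d[2] * d[3]
  dym <- dy; dim(dym) <- c(C, n)
  dgamma_full <- dym * cache$xh
  dxh <- dym * cache$ge
  if (identical(cache$axis, "time")) {
    # standardization backward along the time axis per (channel, batch item)
    to_t <- function(m) {
      dim(m) <- d
      mt <- aperm(m, c(2, 1, 3))
      dim(mt) <- c(d[2], C * d[3])
      mt
    }
    dxht <- to_t(dxh)
    xht <- to_t(cache$xh)
    m1 <- colMeans(dxht)
    m2 <- colMeans(dxht * xht)
    dxt <- (dxht - rep(m1, each = d[2]) - xht * rep(m2, each = d[2])) /
      rep(cache$sig, each = d[2])
    dim(dxt) <- c(d[2], C, d[3])
    dx <- aperm(dxt, c(2, 1, 3))
  } else {
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * cache$xh)
    dx <- (dxh - rep(m1, each = C) - cache$xh * rep(m2, each = C)) /
      rep(cache$sig, each = C)
    dim(dx) <- d
  }
  if (per_channel) {
    dgamma <- dgamma_full; dim(dgamma) <- d
    dbeta <- dym; dim(dbeta) <- d
  } else {
    # [T, B] column sums -> [B, T] for the parameter heads
    dgamma <- t(matrix(colSums(dgamma_full), d[2], d[3]))
    dbeta <- t(matrix(colSums(dym), d[2], d[3]))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Build an AC-regression network
#'
#' Instantiates the network described by a [network_config()] with seeded
#' weight initialization. `mode = "ablation"` builds the no-B-mode variant:
#' the BGN layer degenerates to plain per-slice normalization (gamma = 1,
#' beta = 0) and the B-mode branch is absent; everything else is identical.
#'
#' @param config A [network_config()].
#' @param mode `"bgn"` (full model) or `"ablation"`.
#' @return An object of class `ac_network`.
#' @export
build_ac_network <- function(config, mode = c("bgn", "ablation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, build_ac_network_impl(config, mode))
}

build_ac_network_impl <- function(cf, mode) {
  net <- new.env(parent = emptyenv())
  net$config <- cf
  net$mode <- mode
  C_in <- cf$input_shape[2]
  k <- cf$encoder_kernel; s <- cf$encoder_stride

  make_encoder <- function() {
    layers <- list()
    prev <- C_in
    for (w in cf$encoder_widths) {
      layers <- c(layers, list(nn_conv1d(prev, w, k, s), nn_relu()))
      if (cf$residual) layers <- c(layers, list(nn_res1d(w, k)))
      prev <- w
    }
    do.call(nn_seq, layers)
  }
  net$encoders <- lapply(1:5, function(i) make_encoder())

  if (mode == "bgn") {
    convs <- list()
    prev <- 1L
    hw <- cf$bmode_shape
    for (i in seq_len(cf$bgn_conv_layers)) {
      convs <- c(convs, list(nn_conv2d(prev, cf$bgn_conv_channels, 3L, 2L), nn_relu()))
      prev <- cf$bgn_conv_channels
      hw <- ceiling(hw / 2)
    }
    net$bgn_conv <- do.call(nn_seq, convs)
    net$bgn_flat_dim <- as.integer(prev * prod(hw))
    out_dim <- if (cf$bgn_per_channel) cf$fused_time * cf$fused_channels else cf$fused_time
    make_head <- function() {
      layers <- list()
      prev_f <- net$bgn_flat_dim
      for (i in seq_len(cf$bgn_fc_layers - 1L)) {
        layers <- c(layers, list(nn_linear(prev_f, cf$bgn_fc_width), nn_relu()))
        prev_f <- cf$bgn_fc_width
      }
      c(layers, list(nn_linear(prev_f, out_dim)))
    }
    net$gamma_head <- do.call(nn_seq, make_head())
    net$beta_head <- do.call(nn_seq, make_head())
    # near-zero-initialize the final projection of both heads so the layer
    # starts close to plain per-slice normalization (gamma ~ 1, beta ~ 0)
    # and the B-mode modulation is learned gradually — the standard
    # stabilization for conditional normalization layers (kept slightly
    # nonzero so gradient flows into the shared convolutions from step one)
    gl <- collect_layers(net$gamma_head)
    gl[[length(gl)]]$par$W <- gl[[length(gl)]]$par$W * 1e-2
    gl[[length(gl)]]$par$b[] <- 1
    bl <- collect_layers(net$beta_head)
    bl[[length(bl)]]$par$W <- bl[[length(bl)]]$par$W * 1e-2
    bl[[length(bl)]]$par$b[] <- 0
  }

  trunk <- list()
  prev <- 1L
  for (w in cf$trunk_widths) {
    trunk <- c(trunk, list(
      nn_conv2d(prev, w, cf$trunk_kernel, 2L), nn_bn(w), nn_relu()
    ))
    prev <- w
  }
  net$trunk <- do.call(nn_seq, c(trunk, list(nn_gap2d())))

  head <- list()
  prev_f <- cf$trunk_widths[length(cf$trunk_widths)]
  for (i in seq_len(cf$head_fc_layers - 1L)) {
    head <- c(head, list(nn_linear(prev_f, cf$head_width), nn_relu()))
    prev_f <- cf$head_width
  }
  net$head <- do.call(nn_seq, c(head, list(nn_linear(prev_f, 1L))))

  mods <- c(net$encoders, list(net$trunk, net$head))
  if (mode == "bgn") mods <- c(mods, list(net$bgn_conv, net$gamma_head, net$beta_head))
  net$layers <- unlist(lapply(mods, collect_layers), recursive = FALSE)
  net$model_id <- substr(rlang::hash(list(cf, mode)), 1, 8)
  class(net) <- "ac_network"
  net
}

#' @export
print.ac_network <- function(x, ...) {
  cat(sprintf(
    "<ac_network> mode=%s, %d parameters, input %s, bmode %s\n",
    x$mode, count_params(x$layers),
    paste(x$config$input_shape, collapse = "x"),
    paste(x$config$bmode_shape, collapse = "x")
  ))
  invisible(x)
}

#' Number of trainable parameters
#' @param net An `ac_network`.
#' @return Integer count.
#' @export
n_params <- function(net) count_params(net$layers)

#' Encode five envelope frames into the fused feature map
#'
#' Runs the five per-angle encoders (shared architecture, independent
#' weights) and concatenates their outputs along the channel axis.
#'
#' @param net An `ac_network`.
#' @param env5 Array `[batch, 5, channels, time]` of envelope features.
#' @param train Training mode (caches for backprop).
#' @return Array `[batch, 5 * encoder_channels, fused_time]`.
#' @export
encode <- function(net, env5, train = FALSE) {
  fused <- encode_ctb(net, env5, train)
  aperm(fused, c(3, 1, 2))
}

# internal encoder pass in [C, T, B] layout; returns [5*C_e, T_f, B]
encode_ctb <- function(net, env5, train = FALSE) {
  d <- dim(env5)
  if (length(d) != 4L || d[2] != 5L) {
    stop_input("env5 must be a [batch, 5, channels, time] array")
  }
  outs <- lapply(1:5, function(a) {
    xa <- env5[, a, , , drop = FALSE]
    dim(xa) <- d[-2]
    layer_forward(net$encoders[[a]], aperm(xa, c(2, 3, 1)), train)
  })
  ce <- dim(outs[[1]])[1]; tf <- dim(outs[[1]])[2]
  fused <- array(0, dim = c(5L * ce, tf, d[1]))
  for (a in 1:5) fused[(a - 1L) * ce + seq_len(ce), , ] <- outs[[a]]
  fused
}

# full forward pass with caches; returns list(pred, ...)
net_forward <- function(net, env5, bmode, train = TRUE) {
  cf <- net$config
  B <- dim(env5)[1]
  fused <- encode_ctb(net, env5, train)      # [C_f, T_f, B]
  if (net$mode == "bgn") {
    h <- layer_forward(net$bgn_conv, bmode, train)
    dim(h) <- c(B, net$bgn_flat_dim)
    gamma <- layer_forward(net$gamma_head, h, train)
    beta <- layer_forward(net$beta_head, h, train)
    if (cf$bgn_per_channel) {
      # head emits [B, C_f * T_f] in (channel fastest) order
      gamma <- aperm(array(gamma, dim = c(B, dim(fused)[1:2])), c(2, 3, 1))
      beta <- aperm(array(beta, dim = c(B, dim(fused)[1:2])), c(2, 3, 1))
    }
  } else {
    gamma <- matrix(1, B, cf$fused_time)
    beta <- matrix(0, B, cf$fused_time)
  }
  bg <- bgn_fwd(fused, gamma, beta, cf$eps, axis = cf$bgn_axis %||% "time")
  X <- aperm(bg$y, c(3, 1, 2))
  dim(X) <- c(B, 1L, dim(fused)[1], dim(fused)[2])
  feat <- layer_forward(net$trunk, X, train)
  u <- layer_forward(net$head, feat, train)
  sg <- 1 / (1 + exp(-as.vector(u)))
  pred <- cf$ac_range[1] + diff(cf$ac_range) * sg
  list(pred = pred, sg = sg, bgn = bg, fused_dim = dim(fused), B = B)
}

# backward pass; dpred is d(loss)/d(pred), length B. Returns gradients at the
# envelope input and (bgn mode) at the B-mode input, for wiring checks.
net_backward <- function(net, fw, dpred) {
  cf <- net$config
  B <- fw$B
  du <- matrix(dpred * diff(cf$ac_range) * fw$sg * (1 - fw$sg), B, 1)
  dfeat <- layer_backward(net$head, du)
  dXt <- layer_backward(net$trunk, dfeat)     # [B, 1, C_f, T_f]
  dim(dXt) <- c(B, fw$fused_dim[1], fw$fused_dim[2])
  dX <- aperm(dXt, c(2, 3, 1))                # [C_f, T_f, B]
  bb <- bgn_bwd(fw$bgn, dX, cf$bgn_per_channel)
  dbmode <- NULL
  if (net$mode == "bgn") {
    dg <- bb$dgamma; db <- bb$dbeta
    if (cf$bgn_per_channel) {
      dg <- aperm(dg, c(3, 1, 2)); dim(dg) <- c(B, prod(fw$fused_dim[1:2]))
      db <- aperm(db, c(3, 1, 2)); dim(db) <- c(B, prod(fw$fused_dim[1:2]))
    }
    dh <- layer_backward(net$gamma_head, dg) + layer_backward(net$beta_head, db)
    # restore the conv output shape
    hw <- cf$bmode_shape
    for (i in seq_len(cf$bgn_conv_layers)) hw <- ceiling(hw / 2)
    dim(dh) <- c(B, cf$bgn_conv_channels, hw[1], hw[2])
    dbmode <- layer_backward(net$bgn_conv, dh)
  }
  ce <- fw$fused_dim[1] %/% 5L
  denv <- array(0, dim = c(B, 5L, cf$input_shape[2], cf$input_shape[3]))
  for (a in 1:5) {
    da <- bb$dx[(a - 1L) * ce + seq_len(ce), , , drop = FALSE]
    denv[, a, , ] <- aperm(layer_backward(net$encoders[[a]], da), c(3, 1, 2))
  }
  list(denv = denv, dbmode = dbmode)
}

#' Predict liver attenuation coefficients
#'
#' @param object A (trained or initialized) `ac_network`.
#' @param env5 Array `[batch, 5, channels, time]` of envelope features.
#' @param bmode Array `[batch, 1, height, width]` of B-mode conditioning
#'   images (ignored by the ablation variant).
#' @param ids Optional input identifiers for provenance.
#' @param ... Unused.
#' @return A tibble (one row per batch item): `input_id`, `ac` (dB/cm/MHz),
#'   `model_id`.
#' @export
predict.ac_network <- function(object, env5, bmode = NULL, ids = NULL, ...) {
  d <- dim(env5)
  if (length(d) != 4L || d[2] != 5L ||
      !all(d[3:4] == object$config$input_shape[2:3])) {
    stop_input("env5 shape does not match the network input_shape")
  }
  if (object$mode == "bgn") {
    if (is.null(bmode)) stop_input("the B-mode-guided model requires bmode input")
    db <- dim(bmode)
    if (length(db) != 4L || !all(db[3:4] == object$config$bmode_shape)) {
      stop_input("bmode shape does not match the network bmode_shape")
    }
  } else {
    bmode <- array(0, dim = c(d[1], 1L, object$config$bmode_shape))
  }
  fw <- net_forward(object, env5, bmode, train = FALSE)
  tibble::tibble(
    input_id = ids %||% seq_len(d[1]),
    ac = fw$pred,
    model_id = object$model_id
  )
}
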