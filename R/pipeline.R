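#' Training configuration
#'
#' Optimization settings for [train_network()]. Defaults mirror the reference
#' protocol: L1 loss, L2 regularization, Adam with an initial learning rate of
#' 5e-6, early stopping when the validation loss converges, and an
#' 8000/1000/1000 train/validation/test split (any scale preserving 8:1:1 is
#' accepted by [build_dataset()]).
#'
#' @param n_train,n_val,n_test Split sizes (bookkeeping; actual splits come
#'   from the dataset, which preserves the 8:1:1 ratio).
#' @param loss Loss name; `"l1"`.
#' @param l2_weight L2 regularization coefficient on weight matrices.
#' @param optimizer `"adam"`.
#' @param lr Initial learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param min_delta Minimum validation-loss improvement counted as progress.
#' @param min_epochs Epochs trained before early stopping may fire (the
#'   best-validation checkpoint is still tracked from epoch one).
#' @param augment Lateral-mirror data augmentation: with probability 1/2 a
#'   training batch is flipped left-right (channels, B-mode columns and the
#'   steering-angle order all reverse) — an exact symmetry of the acquisition
#'   physics.
#' @param seed Master seed for initialization and shuffling streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_train = 8000L, n_val = 1000L, n_test = 1000L,
                         loss = "l1", l2_weight = 1e-4, optimizer = "adam",
                         lr = 5e-6, epochs = 300L, batch_size = 32L,
                         patience = 20L, min_delta = 1e-4, min_epochs = 10L,
                         augment = TRUE, seed = 1L) {
  stopifnot(loss == "l1", optimizer == "adam")
  structure(
    list(
      n_train = n_train, n_val = n_val, n_test = n_test, loss = loss,
      l2_weight = l2_weight, optimizer = optimizer, lr = lr,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      early_stop = list(patience = as.integer(patience), min_delta = min_delta,
                        min_epochs = as.integer(min_epochs)),
      augment = isTRUE(augment),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# lateral mirror of a feature batch: reverse the envelope channel axis and
# the steering-angle order, and the B-mode lateral axis
mirror_batch <- function(d) {
  d$env <- d$env[, 5:1, dim(d$env)[3]:1, , drop = FALSE]
  d$bm <- d$bm[, , , dim(d$bm)[4]:1, drop = FALSE]
  d
}

# small lateral translation (probe slide): shift envelope channels by `s`
# and B-mode columns by `2 s` (one envelope channel spans two B-mode pixels),
# replicating the entering edge
shift_batch <- function(d, s) {
  if (s == 0) return(d)
  shift_idx <- function(n, k) pmin(pmax(seq_len(n) + k, 1L), n)
  d$env <- d$env[, , shift_idx(dim(d$env)[3], s), , drop = FALSE]
  d$bm <- d$bm[, , , shift_idx(dim(d$bm)[4], 2L * s), drop = FALSE]
  d
}

# block-mean rebin of a matrix to (nr x nc); handles non-divisible sizes by
# averaging over index ranges
rebin_matrix <- function(m, nr, nc) {
  r_idx <- findInterval(seq_len(nrow(m)) - 1, seq(0, nrow(m), length.out = nr + 1),
                        rightmost.closed = TRUE)
  c_idx <- findInterval(seq_len(ncol(m)) - 1, seq(0, ncol(m), length.out = nc + 1),
                        rightmost.closed = TRUE)
  out <- rowsum(m, r_idx)
  out <- t(rowsum(t(out), c_idx))
  cnt <- outer(tabulate(r_idx, nr), tabulate(c_idx, nc))
  out / cnt
}

# envelope frames + B-mode -> network features
record_features <- function(frames, bmode, feat_channels, feat_time, bmode_px) {
  idx0 <- max(1L, ceiling(-frames$t0_us * frames$fs_mhz))
  n_t <- nrow(frames$env[[1]])
  usable <- n_t - idx0 + 1L
  dec <- max(1L, usable %/% feat_time)
  keep <- idx0:(idx0 + dec * feat_time - 1L)
  c_mm_us <- 1.54
  z_mm <- pmax(0, ((keep - 1) / frames$fs_mhz + frames$t0_us) * c_mm_us / 2)
  gain <- tgc_gain(z_mm, frames$probe$center_frequency)
  genv <- lapply(frames$env, function(e) e[keep, , drop = FALSE] * gain)
  mx <- max(vapply(genv, max, 1))
  env_feat <- array(0, dim = c(5L, feat_channels, feat_time))
  for (a in seq_along(genv)) {
    e <- genv[[a]]
    db <- 20 * log10(pmax(e, mx * 1e-6) / mx)       # [-120, 0] dB
    db <- pmax(db, -60)
    feat <- rebin_matrix(db, feat_time, feat_channels)  # time x channels
    env_feat[a, , ] <- t((feat + 60) / 60)
  }
  bpx <- rebin_matrix(bmode$pixels, bmode_px, bmode_px)
  bm_feat <- (bpx + bmode$dynamic_range) / bmode$dynamic_range
  list(env = env_feat, bmode = bm_feat)
}

#' Build a simulated training dataset
#'
#' Samples `n` phantoms, warps each to the probe arc, simulates the five-angle
#' plane-wave acquisition, compounds the B-mode image, and reduces envelopes
#' and B-mode to the network feature shapes. Records are split 8:1:1 into
#' train/validation/test by phantom id (disjoint by construction).
#'
#' @param n Number of records (>= 10).
#' @param spec A [phantom_spec()] serving as the sampling template (its seed
#'   is re-derived per record).
#' @param probe A [probe_config()].
#' @param seed Master seed; fans out to per-record phantom and noise streams.
#' @param feat_channels,feat_time Envelope feature shape per angle.
#' @param bmode_px B-mode conditioning image size (square).
#' @param snr_db Receiver SNR.
#' @param warp Apply the convex-probe axial warp to each phantom.
#' @param progress Print progress every 25 records.
#' @return An object of class `ac_dataset`: feature arrays, truths, ids and a
#'   split table.
#' @export
build_dataset <- function(n, spec = phantom_spec(), probe = probe_config(),
                          seed = 1L, feat_channels = 16L, feat_time = 128L,
                          bmode_px = 32L, snr_db = 40, warp = TRUE,
                          progress = FALSE) {
  if (n < 10) stop_input("n must be at least 10")
  env <- array(0, dim = c(n, 5L, feat_channels, feat_time))
  bm <- array(0, dim = c(n, 1L, bmode_px, bmode_px))
  truth <- numeric(n)
  ids <- sprintf("ph%05d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- derive_seed(seed, paste0("phantom", i))
    map <- sample_phantom(sp)
    if (warp) map <- warp_axial_grid(map, sp$probe_curvature_radius)
    frames <- acquire_frameset(map, probe, snr_db = snr_db,
                               seed = derive_seed(seed, paste0("acq", i)))
    bmode <- compound_bmode(frames)
    ft <- record_features(frames, bmode, feat_channels, feat_time, bmode_px)
    env[i, , , ] <- ft$env
    bm[i, 1, , ] <- ft$bmode
    truth[i] <- map$liver_ac_truth
    if (progress && i %% 25 == 0) {
      message(sprintf("[build_dataset] %d / %d", i, n))
    }
  }
  splits <- assign_splits(ids, seed)
  structure(
    list(
      env = env, bmode = bm, truth = truth, ids = ids, splits = splits,
      seed = as.integer(seed),
      feature_meta = list(feat_channels = feat_channels, feat_time = feat_time,
                          bmode_px = bmode_px, snr_db = snr_db),
      spec_hash = rlang::hash(unclass(spec)), probe = probe
    ),
    class = "ac_dataset"
  )
}

# 8:1:1 split by record id, seeded, disjoint and exhaustive
assign_splits <- function(ids, seed) {
  n <- length(ids)
  n_test <- max(1L, round(n / 10))
  n_val <- max(1L, round(n / 10))
  ord <- with_seed(derive_seed(seed, "split"), sample.int(n))
  split <- rep("train", n)
  split[ord[seq_len(n_val)]] <- "val"
  split[ord[n_val + seq_len(n_test)]] <- "test"
  tibble::tibble(id = ids, split = split)
}

#' @export
print.ac_dataset <- function(x, ...) {
  tab <- table(x$splits$split)
  cat(sprintf(
    "<ac_dataset> %d records (train %d / val %d / test %d), env %s, bmode %s\n",
    length(x$ids), tab[["train"]], tab[["val"]], tab[["test"]],
    paste(dim(x$env)[-1], collapse = "x"), paste(dim(x$bmode)[-1], collapse = "x")
  ))
  invisible(x)
}

dataset_split_idx <- function(dataset, split) {
  which(dataset$splits$split == split)
}

#' Mean normalized absolute error
#'
#' `100 * mean(|prediction - truth|) / range` where `range` defaults to the
#' 1.0 dB/cm/MHz span of the ground-truth liver AC. Range normalization is
#' used (rather than per-sample truth) because truths may be 0.
#'
#' @param predictions,truths Equal-length numeric vectors, dB/cm/MHz.
#' @param range Normalization constant, dB/cm/MHz.
#' @return MNAE in percent.
#' @export
mnae <- function(predictions, truths, range = 1.0) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop_input("predictions and truths must be nonempty and equal length")
  }
  100 * mean(abs(predictions - truths)) / range
}

#' Train the AC-regression network
#'
#' Minimizes the L1 loss between predicted and ground-truth liver AC with
#' Adam and L2 regularization, early-stopping on the validation loss and
#' returning the best-validation checkpoint.
#'
#' @param dataset An [build_dataset()] result.
#' @param net_config A [network_config()].
#' @param tc A [train_config()].
#' @param mode `"bgn"` or `"ablation"` (no B-mode guidance).
#' @param verbose Print per-epoch losses.
#' @return An object of class `ac_fit`: the trained network, an epoch history
#'   tibble and metadata.
#' @export
train_network <- function(dataset, net_config = network_config(),
                          tc = train_config(), mode = c("bgn", "ablation"),
                          verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "ac_dataset"))
  idx_tr <- dataset_split_idx(dataset, "train")
  idx_va <- dataset_split_idx(dataset, "val")
  if (length(idx_tr) == 0 || length(idx_va) == 0) {
    stop_config("dataset must contain nonempty train and val splits")
  }
  if (length(intersect(idx_tr, idx_va)) > 0) stop_config("split leakage")
  cf <- net_config
  cf$seed <- derive_seed(tc$seed, paste0("init-", mode))
  net <- build_ac_network(cf, mode)
  state <- adam_state(net$layers)

  slice <- function(idx) {
    list(
      env = dataset$env[idx, , , , drop = FALSE],
      bm = dataset$bmode[idx, , , , drop = FALSE],
      y = dataset$truth[idx]
    )
  }
  va <- slice(idx_va)

  eval_l1 <- function(d) {
    fw <- net_forward(net, d$env, d$bm, train = FALSE)
    mean(abs(fw$pred - d$y))
  }

  best_val <- Inf
  best_snapshot <- NULL
  best_epoch <- 0L
  wait <- 0L
  hist <- vector("list", tc$epochs)
  shuffle_seed <- derive_seed(tc$seed, "shuffle")

  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(shuffle_seed + ep, sample(idx_tr))
    ep_loss <- 0; n_seen <- 0
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      bi <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
      d <- slice(bi)
      if (isTRUE(tc$augment)) {
        step_i <- b0 %/% tc$batch_size
        if (step_i %% 2 == 1L) d <- mirror_batch(d)
        d <- shift_batch(d, ((step_i + ep) %% 3L) - 1L)
      }
      zero_grads(net$layers)
      fw <- net_forward(net, d$env, d$bm, train = TRUE)
      if (any(!is.finite(fw$pred))) {
        stop("training diverged: non-finite predictions at epoch ", ep)
      }
      err <- fw$pred - d$y
      ep_loss <- ep_loss + sum(abs(err)); n_seen <- n_seen + length(bi)
      dpred <- sign(err) / length(bi)
      net_backward(net, fw, dpred)
      state <- adam_step(net$layers, state, tc$lr, tc$l2_weight)
    }
    val_l1 <- eval_l1(va)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, train_l1 = ep_loss / n_seen, val_l1 = val_l1
    )
    if (verbose) {
      message(sprintf("[%s] epoch %3d train %.4f val %.4f",
                      mode, ep, ep_loss / n_seen, val_l1))
    }
    if (val_l1 < best_val - tc$early_stop$min_delta) {
      best_val <- val_l1
      best_snapshot <- get_params(net$layers)
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$early_stop$patience && ep >= tc$early_stop$min_epochs) break
    }
  }
  if (!is.null(best_snapshot)) set_params(net$layers, best_snapshot)
  structure(
    list(
      net = net, mode = mode,
      history = dplyr::bind_rows(hist),
      best_epoch = best_epoch, best_val_l1 = best_val,
      net_config = cf, train_config = tc,
      dataset_seed = dataset$seed,
      config_hash = rlang::hash(list(unclass(cf), unclass(tc), mode))
    ),
    class = "ac_fit"
  )
}

#' @export
print.ac_fit <- function(x, ...) {
  cat(sprintf(
    "<ac_fit> mode=%s, %d epochs (best %d, val L1 %.4f), %d parameters\n",
    x$mode, nrow(x$history), x$best_epoch, x$best_val_l1, n_params(x$net)
  ))
  invisible(x)
}

#' Evaluate a trained model on a dataset split
#'
#' Computes per-sample errors and MNAE on the requested split, plus the
#' mean-predictor baseline (predicting the train-split mean AC for every
#' record).
#'
#' @param fit An [train_network()] result.
#' @param dataset The dataset (same splits as used in training).
#' @param split `"test"`, `"val"` or `"train"`.
#' @return An object of class `eval_report`.
#' @export
evaluate_model <- function(fit, dataset, split = "test") {
  idx <- dataset_split_idx(dataset, split)
  if (length(idx) == 0) stop_input("empty split '%s'", split)
  env <- dataset$env[idx, , , , drop = FALSE]
  bm <- dataset$bmode[idx, , , , drop = FALSE]
  y <- dataset$truth[idx]
  pred <- predict(fit$net, env, bm, ids = dataset$ids[idx])$ac
  base <- mean(dataset$truth[dataset_split_idx(dataset, "train")])
  structure(
    list(
      split = split,
      samples = tibble::tibble(
        id = dataset$ids[idx], truth = y, prediction = pred,
        error = pred - y
      ),
      mnae = mnae(pred, y),
      baseline_mnae = mnae(rep(base, length(y)), y),
      mode = fit$mode,
      config_hash = fit$config_hash,
      dataset_seed = dataset$seed
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s split, n=%d: MNAE %.2f%% (mean-predictor baseline %.2f%%)\n",
    x$split, nrow(x$samples), x$mnae, x$baseline_mnae
  ))
  invisible(x)
}

#' Train and compare the B-mode-guided model against the no-B-mode ablation
#'
#' For each seed, trains the full model and the ablation variant on identical
#' dataset splits, evaluates both on the held-out test split, and reports the
#' seed-averaged MNAEs and the relative improvement
#' `100 * (ablation_mnae - mnae) / ablation_mnae`.
#'
#' @param dataset An [build_dataset()] result.
#' @param net_config A [network_config()].
#' @param tc A [train_config()]; its seed is replaced by each element of
#'   `seeds`.
#' @param seeds Training seeds (>= 1; >= 3 for a seed-averaged comparison).
#' @param verbose Passed to [train_network()].
#' @return An object of class `ablation_report` with per-seed and aggregate
#'   results.
#' @export
run_ablation <- function(dataset, net_config = network_config(),
                         tc = train_config(), seeds = 1:3, verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    tcs <- tc; tcs$seed <- as.integer(s)
    fit_b <- train_network(dataset, net_config, tcs, mode = "bgn", verbose = verbose)
    fit_a <- train_network(dataset, net_config, tcs, mode = "ablation", verbose = verbose)
    ev_b <- evaluate_model(fit_b, dataset, "test")
    ev_a <- evaluate_model(fit_a, dataset, "test")
    tibble::tibble(
      seed = s, mnae = ev_b$mnae, ablation_mnae = ev_a$mnae,
      baseline_mnae = ev_b$baseline_mnae
    )
  })
  per_seed <- dplyr::bind_rows(rows)
  m <- mean(per_seed$mnae)
  ma <- mean(per_seed$ablation_mnae)
  structure(
    list(
      per_seed = per_seed,
      mnae = m, ablation_mnae = ma,
      baseline_mnae = mean(per_seed$baseline_mnae),
      relative_improvement = 100 * (ma - m) / ma,
      seeds = seeds, dataset_seed = dataset$seed
    ),
    class = "ablation_report"
  )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf(
    "<ablation_report> %d seeds: MNAE %.2f%% vs ablation %.2f%% (improvement %.1f%%)\n",
    length(x$seeds), x$mnae, x$ablation_mnae, x$relative_improvement
  ))
  invisible(x)
}

# ---- broom-style accessors and plots ----

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @method tidy ac_fit
tidy.ac_fit <- function(x, ...) x$history

#' @export
#' @method glance ac_fit
glance.ac_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_l1 = x$best_val_l1, n_params = n_params(x$net),
    lr = x$train_config$lr, l2_weight = x$train_config$l2_weight
  )
}

#' @export
#' @method tidy eval_report
tidy.eval_report <- function(x, ...) x$samples

#' @export
#' @method glance eval_report
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    split = x$split, n = nrow(x$samples), mnae = x$mnae,
    baseline_mnae = x$baseline_mnae, mode = x$mode
  )
}

#' @export
#' @method tidy ablation_report
tidy.ablation_report <- function(x, ...) x$per_seed

#' @export
#' @method glance ablation_report
glance.ablation_report <- function(x, ...) {
  tibble::tibble(
    n_seeds = length(x$seeds), mnae = x$mnae, ablation_mnae = x$ablation_mnae,
    baseline_mnae = x$baseline_mnae,
    relative_improvement = x$relative_improvement
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method autoplot ac_fit
autoplot.ac_fit <- function(object, ...) {
  df <- tidyr_longer(object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "L1 loss [dB/cm/MHz]", color = NULL)
}

# local pivot to avoid a tidyr dependency for one call
tidyr_longer <- function(hist) {
  dplyr::bind_rows(
    tibble::tibble(epoch = hist$epoch, loss = hist$train_l1, which = "train"),
    tibble::tibble(epoch = hist$epoch, loss = hist$val_l1, which = "validation")
  )
}

#' @export
#' @method autoplot eval_report
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$truth, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1.05), ylim = c(0, 1.05)) +
    ggplot2::labs(
      x = "ground-truth liver AC [dB/cm/MHz]",
      y = "predicted AC [dB/cm/MHz]",
      title = sprintf("MNAE %.2f%% (%s split)", object$mnae, object$split)
    )
}
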