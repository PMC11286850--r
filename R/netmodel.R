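#' Model configuration for the contact-map predictor
#'
#' The network follows the sequence-plus-features design: a 1D convolutional
#' trunk (conv, per-channel normalization, max-pooling by 2 per block)
#' reduces 1-bp one-hot DNA to one embedding per 2048-bp bin; feature
#' channels are concatenated to the embedding; a dilated 1D stack learns
#' long-range dependencies; 1D representations are averaged to 2D
#' ((u_i + u_j)/2); and a dilated 2D head predicts the symmetric
#' log(observed/expected) contact map.
#'
#' @param window_bp Window size (default 2^20; smaller powers of two for
#'   desk-scale runs).
#' @param bin_bp Bin size; `log2(bin_bp)` pooling stages make the trunk
#'   depth (11 at the default 2048).
#' @param trunk_channels Channels per trunk block (scalar recycled).
#' @param trunk_kernel First-block kernel width (later blocks use 5).
#' @param trunk_pool Pooling type per block ("max"/"avg", recycled). Max
#'   pooling keeps the strongest feature in each pooled pair; average
#'   pooling in the last blocks preserves how many feature instances a bin
#'   contains (e.g. motif copy number) as amplitude.
#' @param feature_channels Character vector naming the feature channels
#'   (empty = sequence-only model).
#' @param n_dilated_1d,n_dilated_2d Depth of the dilated stacks.
#' @param d_channels Channel width of the dilated stacks and 2D head.
#' @param diag_offset Diagonal band excluded from the objective (default 2).
#' @param seed Weight-initialization seed.
#' @export
model_config <- function(window_bp = 2^20, bin_bp = 2048L,
                         trunk_channels = 8L, trunk_kernel = 11L,
                         trunk_pool = "max",
                         feature_channels = character(0),
                         n_dilated_1d = 3L, n_dilated_2d = 2L,
                         d_channels = 16L, diag_offset = 2L, seed = 1L) {
  n_blocks <- as.integer(round(log2(bin_bp)))
  if (2^n_blocks != bin_bp) stop("bin_bp must be a power of two")
  if (window_bp %% bin_bp != 0) stop("window_bp must be a multiple of bin_bp")
  n_bins <- window_bp %/% bin_bp
  if (2^round(log2(n_bins)) != n_bins) stop("window_bp/bin_bp must be a power of two")
  ch <- rep_len(trunk_channels, n_blocks)
  pool <- rep_len(trunk_pool, n_blocks)
  stopifnot(all(pool %in% c("max", "avg")))
  structure(list(window_bp = as.integer(window_bp), bin_bp = as.integer(bin_bp),
                 n_blocks = n_blocks, n_bins = n_bins,
                 trunk_channels = as.integer(ch),
                 trunk_kernel = as.integer(trunk_kernel),
                 trunk_pool = pool,
                 feature_channels = feature_channels,
                 n_features = length(feature_channels),
                 n_dilated_1d = as.integer(n_dilated_1d),
                 n_dilated_2d = as.integer(n_dilated_2d),
                 d_channels = as.integer(d_channels),
                 diag_offset = as.integer(diag_offset),
                 seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)),
                                           nr, nc)

#' Initialize model weights
#' @param cfg A [model_config()].
#' @return A `carna_model` list with `cfg` and `params`.
#' @export
init_model <- function(cfg) {
  with_seed(cfg$seed, {
    p <- list()
    cin <- 4L
    for (i in seq_len(cfg$n_blocks)) {
      k <- if (i == 1) cfg$trunk_kernel else 5L
      co <- cfg$trunk_channels[i]
      p[[paste0("trunk", i)]] <- list(W = he_init(k * cin, co, k * cin),
                                      b = numeric(co), gamma = rep(1, co),
                                      beta = numeric(co), k = k, dil = 1L)
      cin <- co
    }
    cin <- cin + cfg$n_features
    C <- cfg$d_channels
    p$proj <- list(W = he_init(cin, C, cin), b = numeric(C),
                   gamma = rep(1, C), beta = numeric(C), k = 1L, dil = 1L)
    for (j in seq_len(cfg$n_dilated_1d)) {
      p[[paste0("d1_", j)]] <- list(W = he_init(3L * C, C, 3L * C),
                                    b = numeric(C), gamma = rep(1, C),
                                    beta = numeric(C), k = 3L,
                                    dil = as.integer(2^(j - 1)))
    }
    for (j in seq_len(cfg$n_dilated_2d)) {
      p[[paste0("d2_", j)]] <- list(W = he_init(9L * C, C, 9L * C),
                                    b = numeric(C), gamma = rep(1, C),
                                    beta = numeric(C), k = 3L,
                                    dil = as.integer(j))
    }
    p$head <- list(W = he_init(C, 1L, C), b = numeric(1))
    structure(list(cfg = cfg, params = p), class = "carna_model")
  })
}

#' One-hot encode a DNA window
#'
#' A/C/G/T map to unit vectors; N (or any other letter) to 0.25 in every
#' channel.
#'
#' @param seq Character scalar or DNAString of length `window_bp`.
#' @param window_bp Expected length (NULL = accept any).
#' @return L x 4 matrix, channels ordered A, C, G, T.
#' @export
encode_sequence <- function(seq, window_bp = NULL) {
  s <- toupper(as.character(seq))
  if (!is.null(window_bp) && nchar(s) != window_bp)
    stop("sequence length ", nchar(s), " != window_bp ", window_bp)
  code <- utf8ToInt(s)
  L <- length(code)
  X <- matrix(0.25, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  lut <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (b in names(lut)) {
    hit <- code == utf8ToInt(b)
    X[hit, ] <- 0
    X[hit, lut[[b]]] <- 1
  }
  X
}

NORM_EPS <- 1e-5

conv_norm_relu_fwd <- function(x, layer, two_d = FALSE, n = NULL) {
  if (two_d) {
    xc <- array(x, c(n, n, ncol(x)))
    pre <- cnn_conv2d_fwd(xc, layer$W, layer$b, layer$k, layer$dil)
    pre <- matrix(pre, n * n, dim(pre)[3])
  } else {
    pre <- cnn_conv1d_fwd(x, layer$W, layer$b, layer$k, layer$dil)
  }
  nc <- cnn_norm_relu_fwd(pre, layer$gamma, layer$beta, NORM_EPS)
  list(y = nc$y, x = x, norm = nc)
}

conv_norm_relu_bwd <- function(gy, cache, layer, two_d = FALSE, n = NULL,
                               need_gx = TRUE) {
  nb <- cnn_norm_relu_bwd(gy, cache$norm$y, cache$norm$xhat,
                          cache$norm$isd, layer$gamma)
  if (two_d) {
    gpre <- array(nb$gx, c(n, n, ncol(nb$gx)))
    xc <- array(cache$x, c(n, n, ncol(cache$x)))
    cb <- cnn_conv2d_bwd(xc, layer$W, gpre, layer$k, layer$dil, need_gx)
    gx <- if (need_gx) matrix(cb$gx, n * n, ncol(cache$x)) else NULL
  } else {
    cb <- cnn_conv1d_bwd(cache$x, layer$W, nb$gx, layer$k, layer$dil, need_gx)
    gx <- if (need_gx) cb$gx else NULL
  }
  list(gx = gx, g = list(W = cb$gw, b = as.numeric(cb$gb),
                         gamma = as.numeric(nb$ggamma),
                         beta = as.numeric(nb$gbeta)))
}

#' Forward pass: predict a contact map
#'
#' Deterministic for fixed weights. The 1D->2D averaging makes the pair
#' representation exchange-symmetric and the output map is explicitly
#' symmetrized, so exchange symmetry is exact.
#'
#' @param model A `carna_model`.
#' @param onehot L x 4 encoded window ([encode_sequence()]).
#' @param features n_bins x n_features matrix (NULL for sequence-only).
#' @param keep Keep activations for a backward pass.
#' @return n_bins x n_bins predicted map (with `cache` attribute if `keep`).
#' @export
forward_map <- function(model, onehot, features = NULL, keep = FALSE) {
  cfg <- model$cfg; p <- model$params
  nf <- if (is.null(features)) 0L else ncol(features)
  if (nf != cfg$n_features)
    stop("feature channel mismatch: got ", nf, ", config expects ",
         cfg$n_features)
  if (nrow(onehot) != cfg$window_bp)
    stop("sequence length mismatch")
  cache <- list()
  h <- onehot
  for (i in seq_len(cfg$n_blocks)) {
    nm <- paste0("trunk", i)
    cv <- conv_norm_relu_fwd(h, p[[nm]])
    if (cfg$trunk_pool[i] == "max") {
      pl <- cnn_maxpool2_fwd(cv$y)
      if (keep) cache[[nm]] <- list(cv = cv, idx = pl$idx, L = nrow(cv$y))
      h <- pl$y
    } else {
      h <- avgpool2_fwd(cv$y)
      if (keep) cache[[nm]] <- list(cv = cv, idx = NULL, L = nrow(cv$y))
    }
  }
  if (!is.null(features)) h <- cbind(h, features)
  cache$concat <- if (keep) h else NULL
  pr <- conv_norm_relu_fwd(h, p$proj)
  if (keep) cache$proj <- pr
  u <- pr$y
  for (j in seq_len(cfg$n_dilated_1d)) {
    nm <- paste0("d1_", j)
    cv <- conv_norm_relu_fwd(u, p[[nm]])
    if (keep) cache[[nm]] <- cv
    u <- u + cv$y
  }
  n <- cfg$n_bins; C <- cfg$d_channels
  A <- matrix(0, n * n, C)
  for (c in seq_len(C)) {
    uc <- matrix(u[, c], n, n)   # uc[i,j] = u[i,c]
    A[, c] <- as.vector((uc + t(uc)) / 2)
  }
  if (keep) cache$u <- u
  a <- A
  for (j in seq_len(cfg$n_dilated_2d)) {
    nm <- paste0("d2_", j)
    cv <- conv_norm_relu_fwd(a, p[[nm]], two_d = TRUE, n = n)
    if (keep) cache[[nm]] <- cv
    a <- a + cv$y
  }
  if (keep) cache$a_final <- a
  m <- matrix(a %*% p$head$W + p$head$b, n, n)
  out <- symmetrize(m)
  if (!is.null(model$calib) && !keep)
    out <- model$calib[1] * out + model$calib[2]
  if (keep) attr(out, "cache") <- cache
  out
}

# Backward pass from a gradient on the symmetric output map. Returns
# parameter gradients and (optionally) the gradient on the feature matrix.
backward_map <- function(model, cache, gmap, need_feature_grad = FALSE) {
  cfg <- model$cfg; p <- model$params
  n <- cfg$n_bins; C <- cfg$d_channels
  g <- list()
  gm <- symmetrize(gmap)               # through final symmetrization
  ga <- matrix(as.vector(gm), n * n, 1) %*% t(p$head$W)
  g$head <- list(W = t(cache$a_final) %*% as.vector(gm),
                 b = sum(gm))
  for (j in rev(seq_len(cfg$n_dilated_2d))) {
    nm <- paste0("d2_", j)
    bk <- conv_norm_relu_bwd(ga, cache[[nm]], p[[nm]], two_d = TRUE, n = n)
    g[[nm]] <- bk$g
    ga <- ga + bk$gx                   # residual skip
  }
  # back through 1D->2D averaging
  gu <- matrix(0, n, C)
  for (c in seq_len(C)) {
    G <- matrix(ga[, c], n, n)
    gu[, c] <- (rowSums(G) + colSums(G)) / 2
  }
  for (j in rev(seq_len(cfg$n_dilated_1d))) {
    nm <- paste0("d1_", j)
    bk <- conv_norm_relu_bwd(gu, cache[[nm]], p[[nm]])
    g[[nm]] <- bk$g
    gu <- gu + bk$gx
  }
  bk <- conv_norm_relu_bwd(gu, cache$proj, p$proj)
  g$proj <- bk$g
  gz <- bk$gx
  ct <- utils::tail(cfg$trunk_channels, 1)
  gfeat <- if (cfg$n_features > 0)
    gz[, (ct + 1):(ct + cfg$n_features), drop = FALSE] else NULL
  if (need_feature_grad && is.null(gfeat) && cfg$n_features == 0)
    gfeat <- matrix(0, n, 0)
  gh <- gz[, seq_len(ct), drop = FALSE]
  for (i in rev(seq_len(cfg$n_blocks))) {
    nm <- paste0("trunk", i)
    gh <- if (cfg$trunk_pool[i] == "max")
      cnn_maxpool2_bwd(gh, cache[[nm]]$idx, cache[[nm]]$L)
    else avgpool2_bwd(gh, cache[[nm]]$L)
    bk <- conv_norm_relu_bwd(gh, cache[[nm]]$cv, p[[nm]], need_gx = (i > 1))
    g[[nm]] <- bk$g
    gh <- bk$gx
  }
  list(grads = g, gfeatures = gfeat)
}

#' Pearson-correlation training objective
#'
#' `loss = 1 - r` where r is the Pearson correlation between prediction and
#' target over the upper triangle excluding a diagonal band. Invariant under
#' affine transforms of the prediction. A zero-variance target yields loss 1
#' with a warning and a zero gradient.
#'
#' @param pred,target Same-geometry matrices.
#' @param offset Excluded diagonal band (|i - j| < offset).
#' @return List: `loss`, `grad` (matrix on pred), `r`, `mse`.
#' @export
pearson_loss <- function(pred, target, offset = 2L) {
  n <- nrow(pred)
  idx <- upper_tri_idx(n, offset)
  pv <- pred[idx]; tv <- target[idx]
  mse <- mean((pv - tv)^2)
  tc <- tv - mean(tv); pc <- pv - mean(pv)
  st <- sqrt(sum(tc^2)); sp <- sqrt(sum(pc^2))
  gmat <- matrix(0, n, n)
  if (st == 0) {
    warning("zero-variance target: Pearson undefined, loss set to 1")
    return(list(loss = 1, grad = gmat, r = NA_real_, mse = mse))
  }
  if (sp == 0) {
    # nudge away from the degenerate constant prediction
    gmat[idx] <- -tc / (st * length(idx))
    return(list(loss = 1, grad = gmat, r = 0, mse = mse))
  }
  r <- sum(pc * tc) / (sp * st)
  gv <- -(tc / (sp * st) - r * pc / sp^2)
  gmat[idx] <- gv
  list(loss = 1 - r, grad = gmat, r = r, mse = mse)
}

# --- Adam over the nested parameter list ------------------------------------

param_leaves <- function(p) {
  out <- list()
  for (nm in names(p))
    for (f in intersect(names(p[[nm]]), c("W", "b", "gamma", "beta")))
      out[[paste0(nm, ".", f)]] <- p[[nm]][[f]]
  out
}

set_leaf <- function(p, key, value) {
  ks <- strsplit(key, ".", fixed = TRUE)[[1]]
  p[[ks[1]]][[ks[2]]] <- value
  p
}

adam_init <- function(p) {
  lv <- param_leaves(p)
  list(m = lapply(lv, function(x) x * 0), v = lapply(lv, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 3e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  gl <- param_leaves(grads)
  pl <- param_leaves(params)
  for (key in names(gl)) {
    g <- gl[[key]]
    if (weight_decay > 0 && endsWith(key, ".W")) g <- g + weight_decay * pl[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params <- set_leaf(params, key,
                       pl[[key]] - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) for (f in names(b[[nm]]))
    a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) for (f in names(g[[nm]]))
    g[[nm]][[f]] <- g[[nm]][[f]] * s
  g
}

#' Train the contact-map predictor
#'
#' Minibatch Adam on the negative-Pearson objective. Training is
#' deterministic for a fixed seed. When validation windows are supplied the
#' returned model carries the parameters of the best validation epoch
#' (Pearson) and a per-epoch log.
#'
#' @param model An initialized `carna_model`.
#' @param data List of windows, each `list(onehot, features, target)`.
#' @param valid Optional validation windows, same shape.
#' @param epochs,lr,batch_size,weight_decay Optimization controls.
#' @param augment_rc Reverse-complement augmentation: each training example
#'   is presented in a random orientation per epoch (the map is flipped
#'   accordingly), discouraging orientation-specific memorization.
#' @param mse_weight Optional weight of an additional MSE term. The Pearson
#'   objective is invariant to each window's scale, so absolute contrast
#'   (e.g. boundary depth) is unsupervised under it; a small MSE anchor
#'   restores that signal. 0 (default) trains on pure negative Pearson.
#' @param seed Shuffling seed.
#' @param verbose Print per-epoch metrics.
#' @return The model with `log` (data.frame epoch, split, loss, pearson,
#'   mse) and, when `valid` given, best-validation params; `aborted` is TRUE
#'   if a NaN loss stopped training.
#' @export
train_model <- function(model, data, valid = NULL, epochs = 30L, lr = 3e-3,
                        batch_size = 4L, weight_decay = 1e-5,
                        augment_rc = TRUE, mse_weight = 0, seed = 1L,
                        verbose = FALSE) {
  state <- adam_init(model$params)
  log <- NULL
  best <- list(pearson = -Inf, params = model$params)
  aborted <- FALSE
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(data))
      ep_loss <- ep_r <- ep_mse <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        gacc <- NULL
        for (wi in bs) {
          w <- data[[wi]]
          if (augment_rc && runif(1) < 0.5) w <- rc_window(w)
          pred <- forward_map(model, w$onehot, w$features, keep = TRUE)
          pl <- pearson_loss(pred, w$target, model$cfg$diag_offset)
          if (mse_weight > 0) {
            n <- nrow(pred)
            idx <- upper_tri_idx(n, model$cfg$diag_offset)
            gm <- matrix(0, n, n)
            gm[idx] <- 2 * (pred[idx] - w$target[idx]) / length(idx)
            pl$grad <- pl$grad + mse_weight * gm
            pl$loss <- pl$loss + mse_weight * pl$mse
          }
          if (!is.finite(pl$loss)) { aborted <- TRUE; break }
          cache <- attr(pred, "cache")
          bk <- backward_map(model, cache, pl$grad)
          gacc <- sum_grads(gacc, bk$grads)
          ep_loss <- ep_loss + pl$loss; ep_r <- ep_r + (pl$r %||% 0)
          ep_mse <- ep_mse + pl$mse
        }
        if (aborted) break
        gacc <- scale_grads(gacc, 1 / length(bs))
        st <- adam_step(model$params, gacc, state, lr = lr,
                        weight_decay = weight_decay)
        model$params <- st$params; state <- st$state
      }
      if (aborted) break
      nw <- length(data)
      log <- rbind(log, data.frame(epoch = ep, split = "train",
                                   loss = ep_loss / nw, pearson = ep_r / nw,
                                   mse = ep_mse / nw))
      if (!is.null(valid)) {
        vm <- evaluate_model(model, valid)
        log <- rbind(log, data.frame(epoch = ep, split = "valid",
                                     loss = 1 - vm["pearson"],
                                     pearson = vm["pearson"],
                                     mse = vm["mse"]))
        if (is.finite(vm["pearson"]) && vm["pearson"] > best$pearson) {
          best$pearson <- vm["pearson"]; best$params <- model$params
          best$mse <- vm["mse"]
        }
      }
      if (verbose)
        message(sprintf("epoch %d train r=%.3f", ep, ep_r / nw))
    }
  })
  if (!is.null(valid) && is.finite(best$pearson)) model$params <- best$params
  # the Pearson objective fixes predictions only up to an affine transform;
  # anchor the scale on the training set so maps are in target units
  model$calib <- affine_calibration(model, data)
  model$log <- log
  model$aborted <- aborted
  if (!is.null(valid)) {
    vm <- evaluate_model(model, valid)   # calibrated scale
    model$valid_pearson <- unname(vm["pearson"])
    model$valid_mse <- unname(vm["mse"])
  } else {
    model$valid_pearson <- NA_real_
    model$valid_mse <- NA_real_
  }
  model
}

avgpool2_fwd <- function(x) {
  n <- nrow(x)
  (x[seq(1L, n - 1L, 2L), , drop = FALSE] +
     x[seq(2L, n, 2L), , drop = FALSE]) / 2
}

avgpool2_bwd <- function(gy, L) {
  gx <- matrix(0, L, ncol(gy))
  gx[seq(1L, L - 1L, 2L), ] <- gy / 2
  gx[seq(2L, L, 2L), ] <- gy / 2
  gx
}

# Reverse-complement a training window: flip + channel-swap the one-hot
# (A<->T, C<->G), reverse the bin order of features, flip the map.
rc_window <- function(w) {
  oh <- w$onehot[rev(seq_len(nrow(w$onehot))), c(4L, 3L, 2L, 1L)]
  colnames(oh) <- c("A", "C", "G", "T")
  n <- nrow(w$target)
  list(onehot = oh,
       features = if (is.null(w$features)) NULL else
         w$features[rev(seq_len(nrow(w$features))), , drop = FALSE],
       target = w$target[rev(seq_len(n)), rev(seq_len(n))])
}

# Least-squares affine map from raw network output to target units, pooled
# over the scored band of the given windows.
affine_calibration <- function(model, data) {
  model$calib <- NULL
  pv <- tv <- numeric(0)
  for (w in data) {
    raw <- forward_map(model, w$onehot, w$features)  # calib NULL here
    idx <- upper_tri_idx(nrow(raw), model$cfg$diag_offset)
    pv <- c(pv, raw[idx]); tv <- c(tv, w$target[idx])
  }
  vp <- var(pv)
  if (!is.finite(vp) || vp == 0) return(c(1, 0))
  a <- cov(pv, tv) / vp
  c(a, mean(tv) - a * mean(pv))
}

#' Mean Pearson/MSE of a model over a window set
#' @param model Trained model.
#' @param data List of windows (`onehot`, `features`, `target`).
#' @return Named vector `pearson`, `mse`.
#' @export
evaluate_model <- function(model, data) {
  rs <- vapply(data, function(w) {
    pred <- forward_map(model, w$onehot, w$features)
    pl <- pearson_loss(pred, w$target, model$cfg$diag_offset)
    c(pl$r %||% NA_real_, pl$mse)
  }, numeric(2))
  c(pearson = mean(rs[1, ], na.rm = TRUE), mse = mean(rs[2, ]))
}

#' Train several replicates and pick the best
#'
#' Each replicate uses its own initialization/shuffling seed. The selected
#' replicate has the best mean rank over (validation MSE ascending,
#' validation Pearson descending).
#'
#' @param cfg A [model_config()].
#' @param data,valid Training / validation windows.
#' @param seeds Integer vector, one per replicate (must be distinct).
#' @param ... Passed to [train_model()].
#' @return List: `models` (all replicates), `best` (selected model),
#'   `summary` (per-replicate validation metrics).
#' @export
train_replicates <- function(cfg, data, valid, seeds = 0:4, ...) {
  stopifnot(!anyDuplicated(seeds))
  models <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    m <- init_model(cfg)
    train_model(m, data, valid = valid, seed = s + 1000L, ...)
  })
  vp <- vapply(models, function(m) m$valid_pearson, numeric(1))
  vm <- vapply(models, function(m) m$valid_mse, numeric(1))
  rank_score <- rank(vm) + rank(-vp)
  best <- which.min(rank_score)
  list(models = models, best = models[[best]],
       summary = data.frame(seed = seeds, valid_pearson = vp, valid_mse = vm,
                            selected = seq_along(seeds) == best))
}

#' Predict maps for a batch of windows
#'
#' Order-preserving; attaches the model variant (feature channel names) to
#' the result.
#'
#' @param model Trained model.
#' @param data List of windows (`onehot`, `features`).
#' @return List of predicted maps.
#' @export
predict_batch <- function(model, data) {
  out <- lapply(data, function(w) forward_map(model, w$onehot, w$features))
  attr(out, "feature_channels") <- model$cfg$feature_channels
  out
}

# Scalar model output used for attribution and perturbation readouts: the
# mean predicted contact value over the evaluated band of the window.
mean_contact <- function(map, offset = 2L) {
  mean(map[upper_tri_idx(nrow(map), offset)])
}

# Value and gradient of mean_contact w.r.t. the feature matrix.
model_feature_grad <- function(model, onehot, features) {
  pred <- forward_map(model, onehot, features, keep = TRUE)
  n <- nrow(pred)
  idx <- upper_tri_idx(n, model$cfg$diag_offset)
  gmap <- matrix(0, n, n)
  gmap[idx] <- 1 / length(idx)
  bk <- backward_map(model, attr(pred, "cache"), gmap,
                     need_feature_grad = TRUE)
  list(value = mean(pred[idx]), grad = bk$gfeatures)
}
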