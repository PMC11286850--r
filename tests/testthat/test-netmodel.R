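tiny_cfg <- function(nf = 0L) {
  model_config(window_bp = 2^14, trunk_channels = 5L, trunk_kernel = 7L,
               d_channels = 6L,
               feature_channels = if (nf) paste0("f", seq_len(nf))
               else character(0), seed = 9L)
}

rand_window <- function(cfg, seed = 1) {
  with_seed(seed, {
    oh <- encode_sequence(paste(sample(c("A", "C", "G", "T"), cfg$window_bp,
                                       TRUE), collapse = ""))
    fx <- if (cfg$n_features) matrix(rnorm(cfg$n_bins * cfg$n_features),
                                     cfg$n_bins, cfg$n_features) else NULL
    tg <- matrix(rnorm(cfg$n_bins^2), cfg$n_bins, cfg$n_bins)
    list(onehot = oh, features = fx, target = (tg + t(tg)) / 2)
  })
}

test_that("sequence encoding is one-hot with N ambiguity and RC identity", {
  e <- encode_sequence("ACGT")
  expect_equal(e, diag(4), ignore_attr = TRUE)
  expect_equal(unname(encode_sequence("N")[1, ]), rep(0.25, 4))
  expect_error(encode_sequence("ACG", window_bp = 4), "length")
  s <- "ACGTTGCANNAC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  flip_swap <- encode_sequence(s)[rev(seq_len(nchar(s))), c(4, 3, 2, 1)]
  expect_equal(unname(encode_sequence(rc)), unname(flip_swap))
})

test_that("forward pass is deterministic, symmetric, and shape-checked", {
  cfg <- tiny_cfg(2L)
  m <- init_model(cfg)
  w <- rand_window(cfg, 2)
  p1 <- forward_map(m, w$onehot, w$features)
  p2 <- forward_map(m, w$onehot, w$features)
  expect_identical(p1, p2)
  expect_equal(p1, t(p1))            # exchange symmetry is exact
  expect_true(all(is.finite(p1)))
  expect_error(forward_map(m, w$onehot, NULL), "channel mismatch")
  # zeroing a channel's input is the same as supplying zeros
  f0 <- w$features; f0[, 2] <- 0
  expect_identical(forward_map(m, w$onehot, f0),
                   forward_map(m, w$onehot, cbind(w$features[, 1], 0)))
})

test_that("pearson loss has its fixed points and affine invariance", {
  cfg <- tiny_cfg()
  w <- rand_window(cfg, 3)
  t <- w$target
  expect_equal(pearson_loss(t, t)$loss, 0, tolerance = 1e-12)
  expect_equal(pearson_loss(-t, t)$loss, 2, tolerance = 1e-12)
  expect_equal(pearson_loss(2 * t + 3, t)$loss, 0, tolerance = 1e-12)
  expect_warning(out <- pearson_loss(t, matrix(1, nrow(t), ncol(t))),
                 "zero-variance")
  expect_equal(out$loss, 1)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_cfg(2L)
  m <- init_model(cfg)
  w <- rand_window(cfg, 4)
  pred <- forward_map(m, w$onehot, w$features, keep = TRUE)
  pl <- pearson_loss(pred, w$target, cfg$diag_offset)
  bk <- carnafold:::backward_map(m, attr(pred, "cache"), pl$grad, TRUE)
  eps <- 1e-5
  for (probe in list(c("trunk1", "W", 3), c("proj", "W", 5),
                     c("d1_1", "gamma", 2), c("d2_2", "W", 17),
                     c("head", "W", 1))) {
    m2 <- m
    i <- as.integer(probe[3])
    m2$params[[probe[1]]][[probe[2]]][i] <-
      m2$params[[probe[1]]][[probe[2]]][i] + eps
    l1 <- pearson_loss(forward_map(m2, w$onehot, w$features), w$target,
                       cfg$diag_offset)$loss
    m2$params[[probe[1]]][[probe[2]]][i] <-
      m2$params[[probe[1]]][[probe[2]]][i] - 2 * eps
    l0 <- pearson_loss(forward_map(m2, w$onehot, w$features), w$target,
                       cfg$diag_offset)$loss
    num <- (l1 - l0) / (2 * eps)
    ana <- bk$grads[[probe[1]]][[probe[2]]][i]
    expect_equal(ana, num, tolerance = 1e-3,
                 label = paste(probe, collapse = "."))
  }
  # feature gradient
  fx2 <- w$features; fx2[3, 1] <- fx2[3, 1] + eps
  l1 <- pearson_loss(forward_map(m, w$onehot, fx2), w$target,
                     cfg$diag_offset)$loss
  fx2[3, 1] <- fx2[3, 1] - 2 * eps
  l0 <- pearson_loss(forward_map(m, w$onehot, fx2), w$target,
                     cfg$diag_offset)$loss
  expect_equal(bk$gfeatures[3, 1], (l1 - l0) / (2 * eps), tolerance = 1e-4)
})

test_that("average pooling preserves pair means and routes gradients", {
  x <- matrix(c(1, 3, 2, 6, 0, 4, 8, 2), 4, 2)
  y <- carnafold:::avgpool2_fwd(x)
  expect_equal(y, matrix(c(2, 4, 2, 5), 2, 2))
  g <- carnafold:::avgpool2_bwd(matrix(c(2, 4, 6, 8), 2, 2), 4L)
  expect_equal(g, matrix(c(1, 1, 2, 2, 3, 3, 4, 4), 4, 2))
  # an avg-pooled trunk still yields finite symmetric maps
  cfg <- model_config(window_bp = 2^13, trunk_channels = 4L,
                      trunk_kernel = 7L, d_channels = 6L,
                      trunk_pool = c(rep("max", 9), "avg", "avg"), seed = 2)
  m <- init_model(cfg)
  w <- rand_window(cfg, 6)
  p <- forward_map(m, w$onehot)
  expect_true(all(is.finite(p)))
  expect_equal(p, t(p))
})

test_that("reverse-complement augmentation is an involution", {
  cfg <- tiny_cfg(2L)
  w <- rand_window(cfg, 5)
  w2 <- carnafold:::rc_window(carnafold:::rc_window(w))
  expect_equal(unname(w2$onehot), unname(w$onehot))
  expect_equal(w2$features, w$features)
  expect_equal(w2$target, w$target)
})

test_that("training is seed-deterministic and reduces the loss", {
  cfg <- tiny_cfg(1L)
  data <- lapply(1:4, function(s) {
    w <- rand_window(cfg, s)
    # make targets depend on the feature channel so learning is possible
    u <- outer(w$features[, 1], w$features[, 1], "+") / 2
    w$target <- u + 0.05 * w$target
    w
  })
  m1 <- train_model(init_model(cfg), data, epochs = 8, lr = 5e-3, seed = 3)
  m2 <- train_model(init_model(cfg), data, epochs = 8, lr = 5e-3, seed = 3)
  expect_identical(m1$log, m2$log)
  tr <- m1$log[m1$log$split == "train", ]
  expect_lt(tail(tr$loss, 1), head(tr$loss, 1))
  # batch prediction preserves order, geometry and metadata
  preds <- predict_batch(m1, data)
  expect_length(preds, 4L)
  expect_equal(dim(preds[[1]]), c(cfg$n_bins, cfg$n_bins))
  expect_identical(attr(preds, "feature_channels"), cfg$feature_channels)
})

test_that("replicate selection uses rank over validation MSE and Pearson", {
  cfg <- tiny_cfg(1L)
  data <- lapply(1:4, function(s) {
    w <- rand_window(cfg, s)
    u <- outer(w$features[, 1], w$features[, 1], "+") / 2
    w$target <- u + 0.05 * w$target
    w
  })
  reps <- train_replicates(cfg, data[1:3], data[4], seeds = 0:2, epochs = 5,
                           lr = 5e-3)
  expect_equal(sum(reps$summary$selected), 1L)
  expect_identical(reps$best$valid_pearson,
                   reps$summary$valid_pearson[reps$summary$selected])
  expect_error(train_replicates(cfg, data[1:3], data[4], seeds = c(1, 1)))
})
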