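# Conditional sigma-VAE on 3x3 pixel-profile patches.
#
# Encoder: a 1x1 "mixing" layer (channels + condition encoding -> 32) applied
# at each of the 9 patch positions, flatten, dense 32 -> 16 -> 16 (ReLU), then
# linear heads for the 16-d posterior mean and log-variance. Conditions pass
# through a shared two-layer (10, 10) encoder whose output is concatenated to
# every patch position before mixing and to the latent code before decoding.
# Decoder: a single linear map producing the reconstructed center pixel.
#
# The decoder's Gaussian output variance is set analytically per batch to the
# reconstruction MSE (sigma-VAE), treated as a constant within the gradient
# step:  total = D*ln(sigma) + D/(2 sigma^2) * MSE + KL(q(z|x,c) || N(0, I)).
#
# Implemented natively with BLAS matrix products, hand-derived gradients and
# Adam; no external deep-learning framework is involved.

#' Configuration of the conditional sigma-VAE
#'
#' @param latent_dim latent dimensionality (default 16)
#' @param conv_width width of the 1x1 channel-mixing layer (default 32)
#' @param encoder_widths widths of the dense encoder layers (default 32,16,16)
#' @param condition_encoder_widths widths of the condition encoder (10, 10)
#' @param epochs training epochs (default 25)
#' @param batch_size minibatch size (default 128)
#' @param learning_rate Adam learning rate (default 0.001)
#' @param sigma_floor lower bound for the decoder variance (default 1e-8)
#' @param seed integer seed for weight init and batch shuffling
#' @param conditional TRUE for the conditional model, FALSE for a plain VAE
#'   baseline (condition inputs ignored)
#' @param neighborhood patch window size the model expects (default 3)
#' @return a `CVAEConfig`
#' @export
cvae_config <- function(latent_dim = 16L, conv_width = 32L,
                        encoder_widths = c(32L, 16L, 16L),
                        condition_encoder_widths = c(10L, 10L),
                        epochs = 25L, batch_size = 128L,
                        learning_rate = 1e-3, sigma_floor = 1e-8,
                        seed = 0L, conditional = TRUE, neighborhood = 3L) {
  stopifnot(latent_dim >= 1, conv_width >= 1, all(encoder_widths >= 1),
            all(condition_encoder_widths >= 1), learning_rate > 0,
            sigma_floor > 0, batch_size >= 1, epochs >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 conv_width = as.integer(conv_width),
                 encoder_widths = as.integer(encoder_widths),
                 condition_encoder_widths = as.integer(condition_encoder_widths),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 sigma_floor = sigma_floor,
                 seed = as.integer(seed),
                 conditional = isTRUE(conditional),
                 neighborhood = as.integer(neighborhood)),
            class = "CVAEConfig")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# fast affine: one allocation for the bias broadcast
affine <- function(x, W, b) {
  out <- x %*% W
  out + rep(b, rep.int(nrow(out), length(b)))
}

init_mat <- function(nin, nout) {
  # fan-in uniform init
  matrix(runif(nin * nout, -1, 1) / sqrt(nin), nin, nout)
}

#' Build an (untrained) conditional sigma-VAE
#'
#' @param cfg a [cvae_config()]
#' @param n_channels number of image channels C
#' @param n_condition_onehot total one-hot width K of the condition schema
#' @return a `cvae_model` (weights initialized, `trained = FALSE`)
#' @export
build_cvae <- function(cfg, n_channels, n_condition_onehot) {
  stopifnot(n_channels >= 1, n_condition_onehot >= 0)
  set.seed(cfg$seed)
  C <- n_channels
  K <- n_condition_onehot
  ce <- if (cfg$conditional) cfg$condition_encoder_widths[2] else 0L
  P <- cfg$neighborhood^2
  ew <- cfg$encoder_widths
  w <- list(
    conv_W = init_mat(C + ce, cfg$conv_width), conv_b = rep(0, cfg$conv_width),
    fc1_W = init_mat(P * cfg$conv_width, ew[1]), fc1_b = rep(0, ew[1]),
    fc2_W = init_mat(ew[1], ew[2]), fc2_b = rep(0, ew[2]),
    fc3_W = init_mat(ew[2], ew[3]), fc3_b = rep(0, ew[3]),
    mu_W = init_mat(ew[3], cfg$latent_dim), mu_b = rep(0, cfg$latent_dim),
    lv_W = init_mat(ew[3], cfg$latent_dim), lv_b = rep(0, cfg$latent_dim),
    dec_W = init_mat(cfg$latent_dim + ce, C), dec_b = rep(0, C))
  if (cfg$conditional) {
    cw <- cfg$condition_encoder_widths
    w$cond1_W <- init_mat(K, cw[1]); w$cond1_b <- rep(0, cw[1])
    w$cond2_W <- init_mat(cw[1], cw[2]); w$cond2_b <- rep(0, cw[2])
  }
  structure(list(weights = w, config = cfg, n_channels = C,
                 n_condition_onehot = K, trained = FALSE,
                 training_log = NULL, fingerprints = NULL),
            class = "cvae_model")
}

#' Number of trainable parameters
#' @param model a `cvae_model`
#' @return integer
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, 1L))
}

# position-major (P*n) x C layout of a patch array: rows are the P window
# positions of sample 1, then of sample 2, ...
patches_to_X <- function(patches) {
  n <- dim(patches)[1]; P <- dim(patches)[2]; C <- dim(patches)[3]
  matrix(aperm(patches, c(2, 1, 3)), n * P, C)
}

# Shared condition-encoder forward: one-hot (n x K) -> (n x 10)
cond_forward <- function(w, onehot) {
  h1 <- relu(affine(onehot, w$cond1_W, w$cond1_b))
  list(h1 = h1, out = relu(affine(h1, w$cond2_W, w$cond2_b)))
}

# Full forward pass. patches: n x P x C array; onehot: n x K; eps: n x L
# gaussian draws, or NULL for the deterministic z = mu path.
cvae_forward <- function(model, patches, onehot, eps = NULL) {
  cvae_forward_X(model, patches_to_X(patches), dim(patches)[1],
                 dim(patches)[2], onehot, eps)
}

# forward on a precomputed position-major input matrix (training hot path)
cvae_forward_X <- function(model, X, n, P, onehot, eps = NULL) {
  w <- model$weights
  cfg <- model$config
  if (cfg$conditional) {
    cf <- cond_forward(w, onehot)
    ce <- cf$out
    Pin <- cbind(X, ce[rep(seq_len(n), each = P), , drop = FALSE])
  } else {
    cf <- NULL; ce <- NULL; Pin <- X
  }
  H0 <- relu(affine(Pin, w$conv_W, w$conv_b))            # (nP) x conv
  Fm <- t(matrix(t(H0), P * ncol(H0), n))                # n x (P*conv)
  H1 <- relu(affine(Fm, w$fc1_W, w$fc1_b))
  H2 <- relu(affine(H1, w$fc2_W, w$fc2_b))
  H3 <- relu(affine(H2, w$fc3_W, w$fc3_b))
  mu <- affine(H3, w$mu_W, w$mu_b)
  lv <- affine(H3, w$lv_W, w$lv_b)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  Dz <- if (cfg$conditional) cbind(z, ce) else z
  xhat <- affine(Dz, w$dec_W, w$dec_b)
  list(Pin = Pin, H0 = H0, Fm = Fm, H1 = H1, H2 = H2, H3 = H3,
       mu = mu, lv = lv, z = z, Dz = Dz, xhat = xhat, cf = cf, n = n, P = P)
}

#' Evidence-lower-bound loss components for a patch batch
#'
#' Reconstruction targets the center pixel. The decoder variance is the batch
#' MSE floored at `sigma_floor` (a scalar shared across the D = C output
#' dimensions, detached from gradients). The KL term is the closed-form
#' divergence of the diagonal-Gaussian posterior from N(0, I), averaged over
#' the batch.
#'
#' @param model a `cvae_model`
#' @param batch a `PixelPatchBatch`
#' @param sample if TRUE (default) draw the reparameterized z; if FALSE use
#'   z = mu (deterministic evaluation)
#' @return a `LossParts` list: `reconstruction`, `kl`, `sigma_sq`, `mse`,
#'   `total`
#' @export
elbo_loss <- function(model, batch, sample = TRUE) {
  if (n_patches(batch) == 0) stop("empty batch")
  cfg <- model$config
  n <- n_patches(batch)
  eps <- if (sample)
    matrix(rnorm(n * cfg$latent_dim), n, cfg$latent_dim) else NULL
  fw <- cvae_forward(model, batch$patches, batch$onehot, eps)
  loss_parts(fw, batch$centers, cfg)
}

loss_parts <- function(fw, centers, cfg) {
  D <- ncol(centers)
  err <- fw$xhat - centers
  mse <- mean(err^2)
  if (!is.finite(mse)) stop("non-finite activations in forward pass")
  sigma_sq <- max(mse, cfg$sigma_floor)
  recon <- D * 0.5 * log(sigma_sq) + D / (2 * sigma_sq) * mse
  kl <- mean(0.5 * rowSums(fw$mu^2 + exp(fw$lv) - 1 - fw$lv))
  structure(list(reconstruction = recon, kl = kl, sigma_sq = sigma_sq,
                 mse = mse, total = recon + kl), class = "LossParts")
}

# Gradients of the sigma-VAE loss w.r.t. all weights (sigma^2 held constant).
cvae_backward <- function(model, fw, centers, eps) {
  w <- model$weights
  cfg <- model$config
  n <- fw$n; P <- fw$P; D <- ncol(centers); L <- cfg$latent_dim
  err <- fw$xhat - centers
  mse <- mean(err^2)
  sigma_sq <- max(mse, cfg$sigma_floor)
  dxhat <- err * (D / (sigma_sq * n * D))  # = err / (sigma_sq * n)
  g <- list()
  g$dec_W <- crossprod(fw$Dz, dxhat)
  g$dec_b <- colSums(dxhat)
  dDz <- tcrossprod(dxhat, w$dec_W)
  dz <- dDz[, seq_len(L), drop = FALSE]
  dmu <- dz + fw$mu / n
  dlv <- 0.5 * (exp(fw$lv) - 1) / n
  if (!is.null(eps)) dlv <- dlv + dz * eps * 0.5 * exp(0.5 * fw$lv)
  g$mu_W <- crossprod(fw$H3, dmu); g$mu_b <- colSums(dmu)
  g$lv_W <- crossprod(fw$H3, dlv); g$lv_b <- colSums(dlv)
  dH3 <- (tcrossprod(dmu, w$mu_W) + tcrossprod(dlv, w$lv_W)) * (fw$H3 > 0)
  g$fc3_W <- crossprod(fw$H2, dH3); g$fc3_b <- colSums(dH3)
  dH2 <- tcrossprod(dH3, w$fc3_W) * (fw$H2 > 0)
  g$fc2_W <- crossprod(fw$H1, dH2); g$fc2_b <- colSums(dH2)
  dH1 <- tcrossprod(dH2, w$fc2_W) * (fw$H1 > 0)
  g$fc1_W <- crossprod(fw$Fm, dH1); g$fc1_b <- colSums(dH1)
  dFm <- tcrossprod(dH1, w$fc1_W)                       # n x (P*conv)
  dH0 <- t(matrix(t(dFm), ncol(fw$H0), n * P)) * (fw$H0 > 0)
  g$conv_W <- crossprod(fw$Pin, dH0); g$conv_b <- colSums(dH0)
  if (cfg$conditional) {
    dPin <- tcrossprod(dH0, w$conv_W)
    C <- ncol(centers)
    dce_enc <- rowsum(dPin[, -seq_len(C), drop = FALSE],
                      rep(seq_len(n), each = P))
    dce <- dce_enc + dDz[, -seq_len(L), drop = FALSE]
    dce <- dce * (fw$cf$out > 0)
    g$cond2_W <- crossprod(fw$cf$h1, dce); g$cond2_b <- colSums(dce)
    dh1 <- tcrossprod(dce, w$cond2_W) * (fw$cf$h1 > 0)
    # onehot input of the condition encoder
    g$cond1_W <- crossprod(fw$onehot_cached, dh1); g$cond1_b <- colSums(dh1)
  }
  lapply(g, unname)  # dimnames would otherwise leak in from batch matrices
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(w = w, st = st)
}

#' Train the conditional sigma-VAE
#'
#' Patches are sampled per cell from the train and validation splits, then
#' optimized with Adam over shuffled minibatches. Per-epoch train loss is the
#' mean over minibatches; validation loss is evaluated with freshly sampled
#' reparameterization noise at the end of each epoch.
#'
#' @param ds a preprocessed `MultiplexedDataset` with a split
#' @param cfg a [cvae_config()]
#' @param fraction_per_cell training-pixel fraction per cell (default 0.1)
#' @return a trained `cvae_model` with `training_log` (one row per epoch)
#' @export
train_cvae <- function(ds, cfg = cvae_config(), fraction_per_cell = 0.1) {
  train <- sample_training_pixels(ds, fraction_per_cell,
                                  seed = derive_seed(cfg$seed, 11L),
                                  split = "train",
                                  neighborhood = cfg$neighborhood)
  val <- sample_training_pixels(ds, fraction_per_cell,
                                seed = derive_seed(cfg$seed, 12L),
                                split = "val",
                                neighborhood = cfg$neighborhood)
  model <- build_cvae(cfg, n_channels(ds), onehot_width(ds$schema))
  model$fingerprints <- model_fingerprints(ds)
  if (cfg$epochs == 0L) return(model)
  w <- model$weights
  st <- adam_init(w)
  n <- n_patches(train)
  P <- dim(train$patches)[2]
  X_all <- patches_to_X(train$patches)
  L <- cfg$latent_dim
  log_rows <- vector("list", cfg$epochs)
  set.seed(derive_seed(cfg$seed, 13L))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tr_tot <- tr_rec <- tr_kl <- tr_sig <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      nb <- length(idx)
      if (nb == 0L) stop("empty minibatch")
      ridx <- rep((idx - 1L) * P, each = P) + seq_len(P)
      centers <- train$centers[idx, , drop = FALSE]
      onehot <- train$onehot[idx, , drop = FALSE]
      eps <- matrix(rnorm(nb * L), nb, L)
      model$weights <- w
      fw <- cvae_forward_X(model, X_all[ridx, , drop = FALSE], nb, P,
                           onehot, eps)
      fw$onehot_cached <- onehot
      lp <- loss_parts(fw, centers, cfg)
      if (!is.finite(lp$total))
        stop(sprintf("NaN loss at epoch %d, batch starting %d", epoch, s))
      g <- cvae_backward(model, fw, centers, eps)
      upd <- adam_step(w, g, st, cfg$learning_rate)
      w <- upd$w; st <- upd$st
      tr_tot <- tr_tot + lp$total; tr_rec <- tr_rec + lp$reconstruction
      tr_kl <- tr_kl + lp$kl; tr_sig <- tr_sig + lp$sigma_sq
    }
    nbatch <- length(starts)
    model$weights <- w
    vl <- elbo_loss(model, val, sample = TRUE)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch,
      train_total = tr_tot / nbatch, train_recon = tr_rec / nbatch,
      train_kl = tr_kl / nbatch,
      val_total = vl$total, val_recon = vl$reconstruction, val_kl = vl$kl,
      sigma_sq = tr_sig / nbatch)
  }
  model$weights <- w
  model$trained <- TRUE
  model$training_log <- do.call(rbind, log_rows)
  model
}

model_fingerprints <- function(ds) {
  list(channels = ds$panel$names,
       schema = lapply(ds$schema$levels, as.character))
}

check_fingerprints <- function(model, ds) {
  fp <- model_fingerprints(ds)
  if (!is.null(model$fingerprints) && !identical(model$fingerprints, fp))
    stop("dataset panel/schema do not match the model's fingerprints")
}

#' Encode a patch batch to posterior latent means
#'
#' Downstream stages always consume posterior means; reparameterization
#' sampling is used only inside the training loss.
#'
#' @param model a `cvae_model`
#' @param batch a `PixelPatchBatch`
#' @param chunk rows per forward chunk (memory bound; default 20000)
#' @return a `LatentMatrix`: list with `z` (n x latent_dim) and `provenance`
#' @export
encode <- function(model, batch, chunk = 20000L) {
  if (dim(batch$patches)[3] != model$n_channels)
    stop("batch channel count does not match the model")
  n <- n_patches(batch)
  z <- matrix(NA_real_, n, model$config$latent_dim)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- cvae_forward(model, batch$patches[idx, , , drop = FALSE],
                       batch$onehot[idx, , drop = FALSE], eps = NULL)
    z[idx, ] <- fw$mu
  }
  structure(list(z = z, provenance = batch$provenance),
            class = "LatentMatrix")
}

#' Encode every pixel of a dataset
#'
#' Convenience wrapper: extracts patches cell by cell, encodes posterior
#' means, and returns latents together with per-pixel metadata.
#'
#' @param model a trained `cvae_model`
#' @param ds the preprocessed `MultiplexedDataset` the model was trained on
#' @param split optional split restriction
#' @return list with `z` (N x latent_dim), `centers` (N x C normalized
#'   center-pixel profiles), `cell_id`, `pixel`, and `conditions` (data.frame,
#'   one row per pixel)
#' @export
encode_dataset <- function(model, ds, split = NULL) {
  check_fingerprints(model, ds)
  cells <- cells_in_split(ds, split)
  cbc <- conditions_by_cell(ds)
  zs <- vector("list", length(cells))
  centers <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    b <- extract_patches(cells[[i]], model$config$neighborhood)
    b <- patch_batch(list(b), ds$schema, cbc)
    zs[[i]] <- encode(model, b)$z
    centers[[i]] <- b$centers
  }
  n <- vapply(zs, nrow, 1L)
  conds <- do.call(rbind, lapply(seq_along(cells), function(i) {
    as.data.frame(as.list(unlist(cells[[i]]$conditions)),
                  stringsAsFactors = FALSE)[rep(1, n[i]), , drop = FALSE]
  }))
  rownames(conds) <- NULL
  list(z = do.call(rbind, zs), centers = do.call(rbind, centers),
       cell_id = rep(vapply(cells, function(x) x$cell_id, ""), n),
       pixel = unlist(lapply(n, seq_len), use.names = FALSE),
       conditions = conds)
}

#' Decode latent codes to center-pixel profiles
#'
#' The decoder is a single linear map applied to the latent code concatenated
#' with the condition encoding (affine in z for a fixed condition).
#'
#' @param model a `cvae_model`
#' @param z n x latent_dim matrix of latent codes
#' @param conditions data.frame of condition levels (one row per code, or a
#'   single row recycled); ignored by non-conditional models
#' @return n x C matrix of reconstructed profiles
#' @export
reconstruct <- function(model, z, conditions = NULL) {
  w <- model$weights
  if (!model$config$conditional) return(affine(z, w$dec_W, w$dec_b))
  if (is.null(conditions)) stop("conditional model needs condition levels")
  if (!is.data.frame(conditions)) conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 1L)
    conditions <- conditions[rep(1, nrow(z)), , drop = FALSE]
  if (is.null(model$fingerprints))
    stop("model carries no schema fingerprints; train it or attach them")
  # the one-hot must be built under the schema captured at training time
  oh <- condition_onehot(condition_schema(model$fingerprints$schema),
                         conditions)
  ce <- cond_forward(w, oh)$out
  affine(cbind(z, ce), w$dec_W, w$dec_b)
}

#' Save a model checkpoint as plain-text weight tables plus a YAML config
#'
#' @param model a `cvae_model`
#' @param dir checkpoint directory to create
#' @return `dir`, invisibly
#' @export
save_cvae <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(model$weights)) {
    write.csv(as.data.frame(as.matrix(model$weights[[nm]])),
              file.path(dir, paste0("weight_", nm, ".csv")),
              row.names = FALSE)
  }
  yaml::write_yaml(list(config = unclass(model$config),
                        n_channels = model$n_channels,
                        n_condition_onehot = model$n_condition_onehot,
                        trained = model$trained,
                        fingerprints = model$fingerprints),
                   file.path(dir, "config.yaml"))
  if (!is.null(model$training_log))
    write.csv(model$training_log, file.path(dir, "training_log.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint written by [save_cvae()]
#'
#' @param dir checkpoint directory
#' @param ds optional dataset whose panel/schema must match the stored
#'   fingerprints
#' @return a `cvae_model`
#' @export
load_cvae <- function(dir, ds = NULL) {
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(cvae_config, y$config[names(y$config) %in%
                                         names(formals(cvae_config))])
  model <- build_cvae(cfg, y$n_channels, y$n_condition_onehot)
  for (nm in names(model$weights)) {
    m <- as.matrix(read.csv(file.path(dir, paste0("weight_", nm, ".csv"))))
    dimnames(m) <- NULL
    model$weights[[nm]] <- if (is.null(dim(model$weights[[nm]]))) drop(m) else m
  }
  model$trained <- isTRUE(y$trained)
  model$fingerprints <- y$fingerprints
  lp <- file.path(dir, "training_log.csv")
  if (file.exists(lp)) model$training_log <- read.csv(lp)
  if (!is.null(ds)) check_fingerprints(model, ds)
  model
}
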