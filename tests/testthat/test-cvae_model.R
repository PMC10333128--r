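# Conditional sigma-VAE: architecture, loss closed forms, gradients,
# training behavior and encode/decode contracts.

param_count_oracle <- function(C, K, P = 9, conv = 32, ew = c(32, 16, 16),
                               cw = c(10, 10), L = 16, conditional = TRUE) {
  ce <- if (conditional) cw[2] else 0
  n <- (C + ce) * conv + conv +           # mixing layer
    P * conv * ew[1] + ew[1] +            # dense 1
    ew[1] * ew[2] + ew[2] +               # dense 2
    ew[2] * ew[3] + ew[3] +               # dense 3
    2 * (ew[3] * L + L) +                 # mean and log-variance heads
    (L + ce) * C + C                      # linear decoder
  if (conditional) n <- n + K * cw[1] + cw[1] + cw[1] * cw[2] + cw[2]
  n
}

test_that("parameter count matches the closed-form architecture sum", {
  m <- build_cvae(cvae_config(seed = 1), n_channels = 8,
                  n_condition_onehot = 2)
  expect_equal(n_parameters(m), param_count_oracle(8, 2))
  m2 <- build_cvae(cvae_config(seed = 1, conditional = FALSE), 34, 9)
  expect_equal(n_parameters(m2),
               param_count_oracle(34, 9, conditional = FALSE))
})

test_that("forward pass has the contracted shapes and conditional invariance", {
  cfg <- cvae_config(seed = 2)
  m <- build_cvae(cfg, 8, 2)
  n <- 17
  patches <- array(rnorm(n * 9 * 8), c(n, 9, 8))
  onehot <- cbind(1, 0)[rep(1, n), ]
  fw <- sublandmarks:::cvae_forward(m, patches, onehot)
  expect_equal(dim(fw$xhat), c(n, 8))
  expect_equal(dim(fw$mu), c(n, 16))
  expect_equal(dim(fw$lv), c(n, 16))
  # non-conditional model ignores the condition one-hot entirely
  m0 <- build_cvae(cvae_config(seed = 2, conditional = FALSE), 8, 2)
  fa <- sublandmarks:::cvae_forward(m0, patches, cbind(rep(1, n), 0))
  fb <- sublandmarks:::cvae_forward(m0, patches, cbind(rep(0, n), 1))
  expect_equal(fa$mu, fb$mu)
  expect_equal(fa$xhat, fb$xhat)
  # conditional model output differs across conditions at zero latent
  z0 <- matrix(0, 2, 16)
  sch <- condition_schema(list(perturbation = c("control", "treated")))
  m$fingerprints <- list(channels = paste0("ch", 1:8),
                         schema = sch$levels)
  r <- reconstruct(m, z0, data.frame(perturbation = c("control", "treated")))
  expect_false(isTRUE(all.equal(r[1, ], r[2, ])))
})

test_that("KL closed forms: zero at the prior, 0.5 for mu=1 sd=1", {
  cfg <- cvae_config(latent_dim = 1, seed = 3)
  m <- build_cvae(cfg, 2, 2)
  # force encoder output mu = 0, logvar = 0
  m$weights <- lapply(m$weights, function(w) w * 0)
  batch <- structure(list(patches = array(rnorm(10 * 9 * 2), c(10, 9, 2)),
                          centers = matrix(0, 10, 2),
                          onehot = cbind(rep(1, 10), 0),
                          provenance = data.frame(cell_id = "c", pixel = 1:10)),
                     class = "PixelPatchBatch")
  lp <- elbo_loss(m, batch, sample = FALSE)
  expect_equal(lp$kl, 0)
  # mu = 1, sd = 1 in a single latent dim: KL = 0.5 * (1 + 1 - 1 - 0) = 0.5
  m$weights$mu_b <- 1
  lp2 <- elbo_loss(m, batch, sample = FALSE)
  expect_equal(lp2$kl, 0.5)
  # perfect reconstruction floors sigma^2 and the term becomes D*ln(sigma)
  lp3 <- elbo_loss(m, batch, sample = FALSE)  # xhat = 0 = centers
  expect_equal(lp3$sigma_sq, cfg$sigma_floor)
  expect_equal(lp3$reconstruction, 2 * 0.5 * log(cfg$sigma_floor))
})

test_that("sigma^2 equals an independent MSE recomputation", {
  cfg <- cvae_config(seed = 4)
  m <- build_cvae(cfg, 3, 2)
  n <- 40
  batch <- structure(list(patches = array(rnorm(n * 9 * 3), c(n, 9, 3)),
                          centers = matrix(rnorm(n * 3), n, 3),
                          onehot = cbind(rep(1, n), 0),
                          provenance = data.frame(cell_id = "c",
                                                  pixel = seq_len(n))),
                     class = "PixelPatchBatch")
  lp <- elbo_loss(m, batch, sample = FALSE)
  fw <- sublandmarks:::cvae_forward(m, batch$patches, batch$onehot)
  mse_indep <- sum((fw$xhat - batch$centers)^2) / (n * 3)
  expect_equal(lp$sigma_sq, mse_indep, tolerance = 1e-6)
  expect_gte(lp$kl, 0)
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(42)
  cfg <- cvae_config(latent_dim = 3, conv_width = 4, encoder_widths = c(5, 4, 3),
                     condition_encoder_widths = c(3, 3), sigma_floor = 1e-12,
                     seed = 9)
  m <- build_cvae(cfg, 2, 2)
  # nudge biases off zero so no ReLU pre-activation sits exactly at the kink
  m$weights <- lapply(m$weights, function(w) w + rnorm(length(w), 0, 0.05))
  n <- 7
  patches <- array(rnorm(n * 9 * 2), c(n, 9, 2))
  onehot <- cbind(rep(c(1, 0), length.out = n), rep(c(0, 1), length.out = n))
  centers <- patches[, 5, ]
  eps <- matrix(rnorm(n * 3), n, 3)
  lossfun <- function(model) {
    fw <- sublandmarks:::cvae_forward(model, patches, onehot, eps)
    sublandmarks:::loss_parts(fw, centers, cfg)$total
  }
  fw <- sublandmarks:::cvae_forward(m, patches, onehot, eps)
  fw$onehot_cached <- onehot
  g <- sublandmarks:::cvae_backward(m, fw, centers, eps)
  h <- 1e-6
  for (nm in names(g)) {
    for (i in seq_len(min(length(g[[nm]]), 10))) {
      m2 <- m; m2$weights[[nm]][i] <- m2$weights[[nm]][i] + h
      m3 <- m; m3$weights[[nm]][i] <- m3$weights[[nm]][i] - h
      num <- (lossfun(m2) - lossfun(m3)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces validation loss, is seeded, and epochs=0 is the init", {
  out <- small_synth()
  ds <- fit_and_apply_quantile_norm(background_subtract(out$dataset))
  ds <- split_cells(ds, c(0.6, 0.2, 0.2), seed = 1)
  cfg <- cvae_config(epochs = 5, seed = 10)
  m1 <- train_cvae(ds, cfg, fraction_per_cell = 0.05)
  expect_equal(nrow(m1$training_log), 5)
  expect_true(all(is.finite(as.matrix(m1$training_log))))
  expect_lt(m1$training_log$val_total[5], m1$training_log$val_total[1])
  m2 <- train_cvae(ds, cfg, fraction_per_cell = 0.05)
  expect_equal(m1$training_log, m2$training_log)
  m0 <- train_cvae(ds, cvae_config(epochs = 0, seed = 10),
                   fraction_per_cell = 0.05)
  init <- build_cvae(cvae_config(epochs = 0, seed = 10), n_channels(ds),
                     onehot_width(ds$schema))
  expect_equal(m0$weights, init$weights)
})

test_that("encoding returns deterministic posterior means of the right shape", {
  out <- small_synth()
  ds <- fit_and_apply_quantile_norm(background_subtract(out$dataset))
  ds <- split_cells(ds, c(0.6, 0.2, 0.2), seed = 1)
  m <- train_cvae(ds, cvae_config(epochs = 2, seed = 11),
                  fraction_per_cell = 0.05)
  b <- sample_training_pixels(ds, 0.02, seed = 1)
  z1 <- encode(m, b)
  z2 <- encode(m, b)
  expect_identical(z1$z, z2$z)
  expect_equal(dim(z1$z), c(n_patches(b), 16))
  # channel mismatch is fatal
  bad <- b
  bad$patches <- bad$patches[, , 1:3, drop = FALSE]
  expect_error(encode(m, bad), "channel")
})

test_that("the linear decoder is affine in z for a fixed condition", {
  m <- build_cvae(cvae_config(seed = 12), 5, 2)
  m$fingerprints <- list(channels = paste0("ch", 1:5),
                         schema = list(perturbation = c("a", "b")))
  z1 <- matrix(rnorm(16), 1, 16)
  z2 <- matrix(rnorm(16), 1, 16)
  al <- 0.3
  cond <- data.frame(perturbation = "a")
  r_mix <- reconstruct(m, al * z1 + (1 - al) * z2, cond)
  r1 <- reconstruct(m, z1, cond)
  r2 <- reconstruct(m, z2, cond)
  expect_equal(r_mix, al * r1 + (1 - al) * r2)
})

test_that("a trained model reconstructs a noise-free homogeneous cell precisely", {
  flat <- structure_spec("blob", c(1, 1), c(2, 2), rep(1, 3))
  out <- generate_dataset(12, list(flat),
                          list(condition_effect("a", rep(1, 3)),
                               condition_effect("b", rep(1, 3))),
                          channels = c("x", "y", "z"), base_level = 80,
                          noise = list(gaussian_sd = 0, poisson = FALSE),
                          nucleus_radius_range = c(12, 14), seed = 31)
  ds <- fit_and_apply_quantile_norm(out$dataset)
  ds <- split_cells(ds, c(0.7, 0.15, 0.15), seed = 1)
  m <- train_cvae(ds, cvae_config(seed = 2), fraction_per_cell = 1.0)
  enc <- encode_dataset(m, ds)
  rec <- reconstruct(m, enc$z, enc$conditions)
  expect_lt(mean((rec - enc$centers)^2), 1e-2)
})

test_that("checkpoint save/load round-trips weights, config and log", {
  out <- small_synth()
  ds <- fit_and_apply_quantile_norm(background_subtract(out$dataset))
  ds <- split_cells(ds, c(0.6, 0.2, 0.2), seed = 1)
  m <- train_cvae(ds, cvae_config(epochs = 2, seed = 13),
                  fraction_per_cell = 0.02)
  dir <- withr::local_tempdir()
  save_cvae(m, file.path(dir, "ckpt"))
  m2 <- load_cvae(file.path(dir, "ckpt"), ds)
  for (nm in names(m$weights))
    expect_equal(m2$weights[[nm]], m$weights[[nm]], tolerance = 1e-12)
  expect_equal(m2$training_log$val_total, m$training_log$val_total,
               tolerance = 1e-10)
  # fingerprint mismatch is fatal
  ds_bad <- ds
  ds_bad$panel$names[1] <- "renamed"
  expect_error(load_cvae(file.path(dir, "ckpt"), ds_bad), "fingerprint")
})
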