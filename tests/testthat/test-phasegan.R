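test_that("the default generator is a 16-convolutional-layer U-Net", {
  cfg <- gan_config(base_channels = 4L, d_base_channels = 4L)
  set.seed(1)
  gen <- build_generator(cfg)
  expect_equal(n_conv_layers(gen), 16L)
  # shape contract and bounded output at the native size
  x <- matrix(runif(256 * 256), 256, 256)
  out <- synthesize_phase(gen, x, seed = 3)
  expect_equal(dim(out), c(256L, 256L))
  expect_true(all(out > -pi & out < pi))
  expect_error(gan_config(image_size = 100L), "multiple")
})

test_that("the default patch discriminator has a 70x70 receptive field", {
  cfg <- gan_config(base_channels = 4L, d_base_channels = 4L)
  set.seed(2)
  disc <- build_discriminator(cfg)
  expect_equal(disc$receptive_field, 70L)
  rf <- discriminator_receptive_field(disc, image_size = 128)
  expect_equal(unname(rf), c(70L, 70L))
  # output is an N x N score map with N > 1
  x2 <- array(rnorm(128 * 128 * 2), c(128, 128, 2))
  logits <- synthmri:::.disc_forward(disc, x2)$logits
  expect_gt(dim(logits)[1], 1)
  expect_gt(dim(logits)[2], 1)
  expect_error(build_discriminator(gan_config(image_size = 64L,
                                              generator_depth = 6L)),
               "receptive field")
})

test_that("discriminator responses are local to the receptive field", {
  cfg <- gan_config(base_channels = 4L, d_base_channels = 4L)
  set.seed(3)
  disc <- build_discriminator(cfg)
  x2 <- array(rnorm(128 * 128 * 2), c(128, 128, 2))
  base <- synthmri:::.disc_forward(disc, x2)$logits
  x2p <- x2; x2p[5, 5, 1] <- x2p[5, 5, 1] + 10
  pert <- synthmri:::.disc_forward(disc, x2p)$logits
  changed <- which(abs(pert - base) > 1e-9, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # a corner perturbation cannot reach units far down the map: with a
  # 70-pixel receptive field and stride 8 per output step, units beyond
  # ~ (70/8) + 1 steps are untouched
  expect_true(all(changed[, 1] <= 10))
  expect_true(all(changed[, 2] <= 10))
  # cross-check: the farthest changed unit sees pixel (5, 5) in its
  # gradient footprint
  far <- changed[which.max(changed[, 1] + changed[, 2]), ]
  fw <- synthmri:::.disc_forward(disc, x2)
  dy <- array(0, dim(base)); dy[far[1], far[2], 1] <- 1
  g <- synthmri:::.disc_backward(disc, fw$cache, dy)$dx
  expect_gt(max(abs(g[5, 5, ])), 0)
})

test_that("hybrid objective components match direct recomputation", {
  set.seed(4)
  dr <- matrix(runif(64, 0.05, 0.95), 8, 8)
  df <- matrix(runif(64, 0.05, 0.95), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  g <- matrix(rnorm(64), 8, 8)
  out <- cgan_loss(dr, df, y, g, lambda_l1 = 37)
  # independent scalar recomputation with explicit sums
  n <- length(dr)
  l_cgan <- sum(log(dr)) / n + sum(log(1 - df)) / n
  l_l1 <- sum(abs(y - g)) / n
  expect_lt(abs(out$l_cgan - l_cgan), 1e-6)
  expect_lt(abs(out$l_l1 - l_l1), 1e-6)
  expect_lt(abs(out$generator_loss - (-sum(log(df)) / n + 37 * l_l1)), 1e-6)
  expect_lt(abs(out$discriminator_loss + l_cgan), 1e-6)
  # closed forms
  half <- matrix(0.5, 4, 4)
  expect_equal(cgan_loss(half, half, y[1:4, 1:4], y[1:4, 1:4])$l_cgan,
               -2 * log(2), tolerance = 1e-12)
  expect_equal(cgan_loss(half, half, y[1:4, 1:4], y[1:4, 1:4])$l_l1, 0)
  z <- cgan_loss(dr, df, y, g, lambda_l1 = 0)
  expect_equal(z$generator_loss, -mean(log(df)), tolerance = 1e-12)
  expect_error(cgan_loss(dr * NA, df, y, g), "non-finite")
})

test_that("default epochs follow the training protocol", {
  expect_equal(gan_config()$epochs, 50L)
  expect_equal(gan_config()$learning_rate, 2e-4)
  expect_equal(gan_config()$adam_beta1, 0.5)
  expect_equal(gan_config()$batch_size, 1L)
})

test_that("short GAN training is bit-reproducible under a fixed seed", {
  pairs <- toy_phase_pairs(6, 4000, size = 32L)
  cfg <- toy_gan_config(seed = 11, size = 32L)
  f1 <- train_phase_gan(pairs[1:4], pairs[5:6], cfg, steps = 8)
  f2 <- train_phase_gan(pairs[1:4], pairs[5:6], cfg, steps = 8)
  expect_identical(f1$history$g_loss, f2$history$g_loss)
  expect_identical(f1$history$d_loss, f2$history$d_loss)
  expect_identical(f1$history$val_l1, f2$history$val_l1)
  expect_identical(f1$generator$params, f2$generator$params)
})

test_that("synthesize_phase: range contract and order preservation", {
  cfg <- toy_gan_config(seed = 5, size = 32L)
  set.seed(5)
  gen <- build_generator(cfg)
  z <- synthesize_phase(gen, matrix(0, 32, 32), seed = 1)
  expect_true(all(is.finite(z)))
  expect_true(all(z > -pi & z < pi))
  mags <- lapply(1:3, function(i) matrix(runif(1024), 32, 32))
  outs <- synthesize_phase(gen, mags, seed = 9)
  set.seed(9)
  ref1 <- synthesize_phase(gen, mags[[1]])
  expect_identical(outs[[1]], ref1)
  expect_length(outs, 3)
  expect_error(synthesize_phase(gen, matrix(0, 33, 33)), "compatible")
})
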