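# Finite-difference checks of the convolution kernels and the assembled
# networks. These guard the hand-written backward passes that all
# training code depends on.

fd_check <- function(fwd, par, analytic, n = 15, eps = 1e-6, tol = 1e-5) {
  set.seed(1)
  idx <- sample(length(par), min(n, length(par)))
  base <- fwd(par)
  for (i in idx) {
    p2 <- par; p2[i] <- p2[i] + eps
    num <- (fwd(p2) - base) / eps
    expect_lt(abs(num - analytic[i]), tol * max(1, abs(num)))
  }
}

test_that("conv2d forward/backward match finite differences", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- synthmri:::.conv_params(4, 3, 2, sd = 0.3)
  y <- synthmri:::.conv_f(p, x, 4L, 2L, 1L)
  expect_equal(dim(y), c(4L, 4L, 2L))
  dy <- array(rnorm(length(y)), dim(y))
  bb <- synthmri:::.conv_b(p, x, dy, 4L, 2L, 1L)
  fd_check(function(w) { pp <- p; pp$w <- w
    sum(synthmri:::.conv_f(pp, x, 4L, 2L, 1L) * dy) }, p$w, bb$dw)
  fd_check(function(xx) sum(synthmri:::.conv_f(p, array(xx, dim(x)),
                                               4L, 2L, 1L) * dy), x, bb$dx)
  expect_equal(bb$db, apply(dy, 3, sum))
})

test_that("transposed conv forward/backward match finite differences", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- synthmri:::.tconv_params(4, 3, 2, sd = 0.3)
  y <- synthmri:::.tconv_f(p, x, 4L, 2L, 1L)
  expect_equal(dim(y), c(16L, 16L, 2L))
  dy <- array(rnorm(length(y)), dim(y))
  bb <- synthmri:::.tconv_b(p, x, dy, 4L, 2L, 1L)
  fd_check(function(w) { pp <- p; pp$w <- w
    sum(synthmri:::.tconv_f(pp, x, 4L, 2L, 1L) * dy) }, p$w, bb$dw)
  fd_check(function(xx) sum(synthmri:::.tconv_f(p, array(xx, dim(x)),
                                                4L, 2L, 1L) * dy), x, bb$dx)
})

test_that("U-Net generator backward matches finite differences", {
  cfg <- gan_config(image_size = 16L, base_channels = 4L,
                    generator_depth = 4L, dropout_rate = 0, d_layers = 1L,
                    d_base_channels = 4L, seed = 2)
  set.seed(2)
  gen <- build_generator(cfg)
  x <- matrix(runif(256), 16, 16)
  yT <- matrix(runif(256, -1, 1), 16, 16)
  fw <- synthmri:::.gen_forward(gen, x, use_dropout = FALSE)
  bw <- synthmri:::.gen_backward(gen, fw$cache,
                                 sign(fw$out - yT) / length(yT))
  l0 <- mean(abs(fw$out - yT))
  eps <- 1e-6
  set.seed(4)
  for (trial in 1:10) {
    st <- sample(1:2, 1); li <- sample(1:4, 1)
    part <- if (st == 1) "enc" else "dec"
    wi <- sample(length(gen$params[[part]][[li]]$w), 1)
    gp <- gen
    gp$params[[part]][[li]]$w[wi] <- gp$params[[part]][[li]]$w[wi] + eps
    l1 <- mean(abs(synthmri:::.gen_forward(gp, x, use_dropout = FALSE)$out - yT))
    expect_lt(abs((l1 - l0) / eps - bw$grads[[part]][[li]]$w[wi]), 1e-5)
  }
})

test_that("variational network backward matches finite differences", {
  s <- generate_phantom_sample(small_spec(seed = 21, size = 32, coils = 4))
  msk <- make_equispaced_mask(32, 2, 0.08)
  k0 <- apply_mask(s$kspace, msk)
  cols <- which(msk$columns)
  set.seed(3)
  m <- build_varnet(varnet_config(n_cascades = 2, regularizer_channels = 4))
  ref <- s$magnitude
  fw <- synthmri:::.varnet_fwd(m, k0, cols, s$maps)
  bw <- synthmri:::.varnet_bwd(m, fw, s$maps, sign(fw$out - ref) / length(ref))
  l0 <- mean(abs(fw$out - ref))
  eps <- 1e-6
  set.seed(5)
  for (t in 1:2) for (l in names(m$params$cascades[[t]])) {
    wi <- sample(length(m$params$cascades[[t]][[l]]$w), 1)
    mp <- m
    mp$params$cascades[[t]][[l]]$w[wi] <- mp$params$cascades[[t]][[l]]$w[wi] + eps
    l1 <- mean(abs(synthmri:::.varnet_fwd(mp, k0, cols, s$maps)$out - ref))
    expect_lt(abs((l1 - l0) / eps - bw$grads$cascades[[t]][[l]]$w[wi]), 1e-5)
  }
  for (t in 1:2) {
    mp <- m; mp$params$eta[t] <- mp$params$eta[t] + eps
    l1 <- mean(abs(synthmri:::.varnet_fwd(mp, k0, cols, s$maps)$out - ref))
    expect_lt(abs((l1 - l0) / eps - bw$grads$eta[t]), 1e-5)
  }
})
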