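# Conditional GAN for magnitude -> phase translation: a U-Net generator
# with skip connections (16 convolutional layers at the default depth of
# 8) and a 70x70 patch discriminator that scores overlapping patches
# rather than the whole image. Trained with the hybrid objective
# L = L_cGAN + lambda * L_l1, alternating discriminator and generator
# Adam steps at batch size 1.

#' Conditional GAN configuration
#'
#' @param image_size training image side length; must be divisible by
#'   `2^generator_depth`.
#' @param base_channels channel width of the first generator stage.
#' @param generator_depth number of encoder (and decoder) stages; the
#'   default 8 yields a 16-convolutional-layer U-Net.
#' @param lambda_l1 weight of the l1 term in the hybrid objective.
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings (defaults
#'   2e-4, 0.5, 0.999).
#' @param batch_size training batch size; only 1 is supported.
#' @param epochs training epochs (default 50).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param dropout_rate dropout probability in the innermost decoder
#'   stages; this dropout realizes the latent code z and stays active at
#'   inference.
#' @param d_layers number of strided convolutions in the discriminator;
#'   3 gives the 70x70 receptive field, smaller values shrink it for
#'   small training images.
#' @param d_base_channels channel width of the first discriminator layer.
#' @return object of class `"gan_config"`.
#' @export
gan_config <- function(image_size = 256L, base_channels = 64L,
                       generator_depth = 8L, lambda_l1 = 100,
                       learning_rate = 2e-4, adam_beta1 = 0.5,
                       adam_beta2 = 0.999, batch_size = 1L, epochs = 50L,
                       seed = 1L, dropout_rate = 0.5, d_layers = 3L,
                       d_base_channels = 64L) {
  if (image_size %% (2^generator_depth) != 0)
    stop("image_size must be a multiple of 2^generator_depth")
  if (batch_size != 1L) stop("only batch_size = 1 is supported")
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 generator_depth = as.integer(generator_depth),
                 lambda_l1 = lambda_l1, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = 1L, epochs = as.integer(epochs),
                 seed = as.integer(seed), dropout_rate = dropout_rate,
                 d_layers = as.integer(d_layers),
                 d_base_channels = as.integer(d_base_channels)),
            class = "gan_config")
}

# ---- generator ----

#' Build the U-Net phase generator
#'
#' Encoder: `generator_depth` 4x4 stride-2 convolutions with leaky-ReLU,
#' channel widths `base_channels * min(2^(i-1), 8)`. Decoder: the same
#' number of 4x4 stride-2 transposed convolutions with ReLU and skip
#' concatenation from the mirrored encoder stage; dropout in the (up to
#' three) innermost decoder stages provides the stochastic latent z. The
#' single-channel output passes through `pi * tanh`, so every pixel lies
#' in `(-pi, pi)`. With the default depth of 8 the network has exactly 16
#' convolutional layers.
#'
#' @param config a [gan_config].
#' @return object of class `"unet_generator"`.
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  d <- config$generator_depth
  nb <- config$base_channels
  enc_ch <- nb * pmin(2^(seq_len(d) - 1), 8)
  enc <- vector("list", d)
  params_enc <- vector("list", d)
  for (i in seq_len(d)) {
    cin <- if (i == 1) 1L else enc_ch[i - 1]
    enc[[i]] <- list(k = 4L, s = 2L, p = 1L, cin = cin, cout = enc_ch[i])
    params_enc[[i]] <- .conv_params(4L, cin, enc_ch[i])
  }
  dec <- vector("list", d)
  params_dec <- vector("list", d)
  n_drop <- min(3L, d - 1L)
  prev <- enc_ch[d]
  for (j in seq_len(d)) {
    cin <- if (j == 1) prev else prev + enc_ch[d - j + 1]
    cout <- if (j < d) enc_ch[d - j] else 1L
    dec[[j]] <- list(k = 4L, s = 2L, p = 1L, cin = cin, cout = cout,
                     dropout = j <= n_drop)
    params_dec[[j]] <- .tconv_params(4L, cin, cout)
    prev <- cout
  }
  structure(list(enc = enc, dec = dec,
                 params = list(enc = params_enc, dec = params_dec),
                 config = config),
            class = "unet_generator")
}

#' Number of convolutional layers in a generator
#' @param generator a `unet_generator`.
#' @return integer count (encoder plus decoder convolutions).
#' @export
n_conv_layers <- function(generator) {
  length(generator$enc) + length(generator$dec)
}

# forward pass; x: (H, W) matrix of normalized magnitude
# dropout active whenever dropout_rate > 0 (train and inference alike:
# the dropout IS the latent z)
.gen_forward <- function(gen, x, use_dropout = TRUE) {
  d <- length(gen$enc)
  rate <- gen$config$dropout_rate
  a <- array(x, dim = c(dim(x), 1L))
  e_out <- vector("list", d)   # post-conv encoder activations
  e_pre <- vector("list", d)   # pre-conv (post-lrelu input) for backward
  h <- a
  for (i in seq_len(d)) {
    inp <- if (i == 1) h else .lrelu(h)
    e_pre[[i]] <- inp
    h <- .conv_f(gen$params$enc[[i]], inp, 4L, 2L, 1L)
    e_out[[i]] <- h
  }
  u <- e_out[[d]]
  d_in <- vector("list", d); d_rel <- vector("list", d)
  d_mask <- vector("list", d); d_out <- vector("list", d)
  for (j in seq_len(d)) {
    v <- if (j == 1) u else .cat3(u, e_out[[d - j + 1]])
    d_in[[j]] <- v
    r <- .relu(v)
    d_rel[[j]] <- r
    t <- .tconv_f(gen$params$dec[[j]], r, 4L, 2L, 1L)
    if (gen$dec[[j]]$dropout && use_dropout && rate > 0) {
      m <- array((runif(length(t)) >= rate) / (1 - rate), dim = dim(t))
      t <- t * m
      d_mask[[j]] <- m
    }
    d_out[[j]] <- t
    u <- t
  }
  th <- tanh(u[, , 1])
  out <- pi * th
  list(out = out,
       cache = list(e_pre = e_pre, e_out = e_out, d_in = d_in, d_rel = d_rel,
                    d_mask = d_mask, d_out = d_out, th = th))
}

# backward; dout: (H, W) gradient wrt the phase output
.gen_backward <- function(gen, cache, dout) {
  d <- length(gen$enc)
  du <- array(pi * dout * (1 - cache$th^2), dim = c(dim(dout), 1L))
  g_dec <- vector("list", d)
  skip_grads <- vector("list", d)  # gradients flowing into e_out via skips
  for (j in d:1) {
    if (!is.null(cache$d_mask[[j]])) du <- du * cache$d_mask[[j]]
    bb <- .tconv_b(gen$params$dec[[j]], cache$d_rel[[j]], du, 4L, 2L, 1L)
    g_dec[[j]] <- list(w = bb$dw, b = bb$db)
    dv <- bb$dx * .drelu(cache$d_in[[j]])
    if (j == 1) {
      du <- dv
    } else {
      nup <- dim(dv)[3] - dim(cache$e_out[[d - j + 1]])[3]
      du <- dv[, , seq_len(nup), drop = FALSE]
      skip_grads[[d - j + 1]] <- dv[, , (nup + 1):dim(dv)[3], drop = FALSE]
    }
  }
  # du now is gradient on e_out[[d]] coming through the decoder trunk
  g_enc <- vector("list", d)
  dh <- du
  dx <- NULL
  for (i in d:1) {
    if (!is.null(skip_grads[[i]])) dh <- dh + skip_grads[[i]]
    bb <- .conv_b(gen$params$enc[[i]], cache$e_pre[[i]], dh, 4L, 2L, 1L)
    g_enc[[i]] <- list(w = bb$dw, b = bb$db)
    if (i > 1) dh <- bb$dx * .dlrelu(cache$e_out[[i - 1]]) else dx <- bb$dx
  }
  list(dx = dx[, , 1], grads = list(enc = g_enc, dec = g_dec))
}

# ---- discriminator ----

#' Build the patch discriminator
#'
#' A convolutional classifier over the channel-concatenated
#' (magnitude, phase) pair. `d_layers` 4x4 stride-2 convolutions are
#' followed by two 4x4 stride-1 convolutions; the output is an N x N map
#' of patch logits. With the default `d_layers = 3` the receptive field
#' of each output element is exactly 70x70 input pixels.
#'
#' @param config a [gan_config].
#' @return object of class `"patch_discriminator"`.
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  L <- config$d_layers
  nb <- config$d_base_channels
  rf <- 7L
  for (i in seq_len(L)) rf <- rf * 2L + 2L
  if (config$image_size < rf)
    stop(sprintf("image_size %d is smaller than the %dx%d receptive field",
                 config$image_size, rf, rf))
  ch <- nb * pmin(2^(seq_len(L) - 1), 8)
  layers <- list(); params <- list()
  cin <- 2L
  for (i in seq_len(L)) {
    layers[[i]] <- list(k = 4L, s = 2L, p = 1L, cin = cin, cout = ch[i],
                        act = "lrelu")
    params[[i]] <- .conv_params(4L, cin, ch[i])
    cin <- ch[i]
  }
  cpen <- min(nb * 2^L, nb * 8)
  layers[[L + 1]] <- list(k = 4L, s = 1L, p = 1L, cin = cin, cout = cpen,
                          act = "lrelu")
  params[[L + 1]] <- .conv_params(4L, cin, cpen)
  layers[[L + 2]] <- list(k = 4L, s = 1L, p = 1L, cin = cpen, cout = 1L,
                          act = "none")
  params[[L + 2]] <- .conv_params(4L, cpen, 1L)
  structure(list(layers = layers, params = params, receptive_field = rf,
                 config = config),
            class = "patch_discriminator")
}

# x2: (H, W, 2) conditioning magnitude + (real or generated) phase
.disc_forward <- function(disc, x2) {
  n <- length(disc$layers)
  pre <- vector("list", n); act <- vector("list", n)
  h <- x2
  for (i in seq_len(n)) {
    l <- disc$layers[[i]]
    act[[i]] <- h
    h <- .conv_f(disc$params[[i]], h, l$k, l$s, l$p)
    pre[[i]] <- h
    if (l$act == "lrelu") h <- .lrelu(h)
  }
  list(logits = h, cache = list(pre = pre, act = act))
}

.disc_backward <- function(disc, cache, dy) {
  n <- length(disc$layers)
  grads <- vector("list", n)
  dh <- dy
  for (i in n:1) {
    l <- disc$layers[[i]]
    if (l$act == "lrelu") dh <- dh * .dlrelu(cache$pre[[i]])
    bb <- .conv_b(disc$params[[i]], cache$act[[i]], dh, l$k, l$s, l$p)
    grads[[i]] <- list(w = bb$dw, b = bb$db)
    dh <- bb$dx
  }
  list(dx = dh, grads = grads)
}

#' Measure the discriminator's receptive field by gradient probing
#'
#' Backpropagates a unit gradient from one interior output element to the
#' input and reports the side lengths of the bounding box of input pixels
#' with a nonzero gradient, i.e. the effective receptive field in pixels
#' per axis.
#'
#' @param disc a `patch_discriminator`.
#' @param image_size side length of the probe input (defaults to the
#'   configured training size).
#' @param seed seed for the random probe input.
#' @return named integer vector with elements `rows` and `cols`.
#' @export
discriminator_receptive_field <- function(disc, image_size = disc$config$image_size,
                                          seed = 1L) {
  set.seed(seed)
  x2 <- array(rnorm(image_size^2 * 2), dim = c(image_size, image_size, 2L))
  fw <- .disc_forward(disc, x2)
  dlog <- dim(fw$logits)
  unit <- floor(dlog[1:2] / 2) + 1L
  dy <- array(0, dim = dlog)
  dy[unit[1], unit[2], 1] <- 1
  bw <- .disc_backward(disc, fw$cache, dy)
  g <- apply(abs(bw$dx), c(1, 2), max)
  rows <- which(rowSums(g) > 0)
  cols <- which(colSums(g) > 0)
  c(rows = diff(range(rows)) + 1L, cols = diff(range(cols)) + 1L)
}

# ---- losses ----

#' Hybrid conditional-GAN loss components
#'
#' Given discriminator score maps (probabilities, i.e. after the sigmoid)
#' on a real pair and a generated pair, returns the two components of the
#' hybrid objective: the conditional adversarial value
#' `L_cGAN = mean(log D(x, y)) + mean(log(1 - D(x, G(x, z))))` and the l1
#' distance `L_l1 = mean(|y - G(x, z)|)`. The discriminator maximizes
#' `L_cGAN`; the generator minimizes the non-saturating surrogate
#' `-mean(log D(x, G))` plus `lambda_l1 * L_l1`.
#'
#' @param d_real,d_fake discriminator score maps in (0, 1).
#' @param target_phase,generated_phase phase images (radians).
#' @param lambda_l1 l1 weight.
#' @return list with `l_cgan`, `l_l1`, `generator_loss`,
#'   `discriminator_loss`.
#' @export
cgan_loss <- function(d_real, d_fake, target_phase, generated_phase,
                      lambda_l1 = 100) {
  if (!all(is.finite(d_real)) || !all(is.finite(d_fake)) ||
      !all(is.finite(target_phase)) || !all(is.finite(generated_phase)))
    stop("non-finite inputs to cgan_loss")
  l_cgan <- mean(log(d_real)) + mean(log(1 - d_fake))
  l_l1 <- mean(abs(target_phase - generated_phase))
  list(l_cgan = l_cgan, l_l1 = l_l1,
       generator_loss = -mean(log(d_fake)) + lambda_l1 * l_l1,
       discriminator_loss = -l_cgan)
}

# ---- training ----

.norm_mag <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m - 1)
  2 * m / mx - 1
}

.val_l1 <- function(gen, val_pairs, use_dropout = TRUE) {
  if (length(val_pairs) == 0) return(NA_real_)
  mean(vapply(val_pairs, function(p) {
    fw <- .gen_forward(gen, .norm_mag(p$magnitude), use_dropout = use_dropout)
    mean(abs(fw$out - p$phase))
  }, numeric(1)))
}

#' Train the magnitude-to-phase conditional GAN
#'
#' Alternates one discriminator Adam step and one generator Adam step per
#' training pair (batch size 1), using binary cross-entropy on the patch
#' logits and the hybrid objective for the generator. Magnitude inputs
#' are normalized to `[-1, 1]` by their per-image maximum; phase targets
#' stay in radians. Fully seeded: the same configuration and seed give a
#' bit-identical training trajectory. When a validation set is given the
#' returned generator is the checkpoint with the best validation mean l1.
#'
#' @param train_pairs list of `list(magnitude =, phase =)` matrices.
#' @param val_pairs optional validation list of the same form.
#' @param config a [gan_config].
#' @param steps total optimization steps; defaults to
#'   `config$epochs * length(train_pairs)`.
#' @param val_every evaluate validation l1 every this many steps
#'   (defaults to once per epoch).
#' @return object of class `"phase_gan"` with elements `generator`,
#'   `discriminator`, `history` and `config`.
#' @export
train_phase_gan <- function(train_pairs, val_pairs = list(), config,
                            steps = NULL, val_every = NULL) {
  stopifnot(inherits(config, "gan_config"), length(train_pairs) >= 1)
  set.seed(config$seed)
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  stG <- .adam_init(gen$params)
  stD <- .adam_init(disc$params)
  n <- length(train_pairs)
  if (is.null(steps)) steps <- config$epochs * n
  if (is.null(val_every)) val_every <- n
  lam <- config$lambda_l1
  lr <- config$learning_rate; b1 <- config$adam_beta1; b2 <- config$adam_beta2
  hist <- list(g_loss = numeric(steps), d_loss = numeric(steps),
               adv = numeric(steps), l1 = numeric(steps),
               val_step = integer(0), val_l1 = numeric(0))
  init_val <- .val_l1(gen, val_pairs)
  best_val <- init_val; best_params <- gen$params
  order <- integer(0)
  for (s in seq_len(steps)) {
    if (length(order) == 0) order <- sample.int(n)
    i <- order[1]; order <- order[-1]
    x <- .norm_mag(train_pairs[[i]]$magnitude)
    y <- train_pairs[[i]]$phase
    fwG <- .gen_forward(gen, x)
    fake <- fwG$out
    xr <- array(c(x, y), dim = c(dim(x), 2L))
    xf <- array(c(x, fake), dim = c(dim(x), 2L))
    # --- discriminator step (fake detached) ---
    fr <- .disc_forward(disc, xr)
    ff <- .disc_forward(disc, xf)
    np <- length(fr$logits)
    d_real_g <- (.sigmoid(fr$logits) - 1) / np
    d_fake_g <- .sigmoid(ff$logits) / np
    bR <- .disc_backward(disc, fr$cache, d_real_g)
    bF <- .disc_backward(disc, ff$cache, d_fake_g)
    gD <- .grad_add(bR$grads, bF$grads)
    up <- .adam_step(disc$params, gD, stD, lr, b1, b2)
    disc$params <- up$params; stD <- up$state
    d_loss <- mean(.softplus(-fr$logits)) + mean(.softplus(ff$logits))
    # --- generator step (through the updated discriminator) ---
    ff2 <- .disc_forward(disc, xf)
    dadv <- (.sigmoid(ff2$logits) - 1) / np
    bD <- .disc_backward(disc, ff2$cache, dadv)
    dfake <- bD$dx[, , 2] + lam * sign(fake - y) / length(fake)
    bG <- .gen_backward(gen, fwG$cache, dfake)
    upG <- .adam_step(gen$params, bG$grads, stG, lr, b1, b2)
    gen$params <- upG$params; stG <- upG$state
    adv <- mean(.softplus(-ff2$logits))
    l1 <- mean(abs(fake - y))
    hist$g_loss[s] <- adv + lam * l1
    hist$d_loss[s] <- d_loss
    hist$adv[s] <- adv
    hist$l1[s] <- l1
    if (!is.na(hist$g_loss[s]) && !is.finite(hist$g_loss[s]))
      stop(sprintf("non-finite generator loss at step %d; training aborted", s))
    if (s %% val_every == 0 || s == steps) {
      v <- .val_l1(gen, val_pairs)
      hist$val_step <- c(hist$val_step, s)
      hist$val_l1 <- c(hist$val_l1, v)
      if (!is.na(v) && (is.na(best_val) || v < best_val)) {
        best_val <- v; best_params <- gen$params
      }
    }
  }
  if (length(val_pairs) > 0) gen$params <- best_params
  hist$initial_val_l1 <- init_val
  hist$best_val_l1 <- best_val
  structure(list(generator = gen, discriminator = disc, history = hist,
                 config = config),
            class = "phase_gan")
}

#' @export
print.phase_gan <- function(x, ...) {
  h <- x$history
  cat(sprintf("<phase_gan> %d-layer U-Net generator, %dx%d patch discriminator\n",
              n_conv_layers(x$generator), x$discriminator$receptive_field,
              x$discriminator$receptive_field))
  cat(sprintf("  trained %d steps; final l1 %.4f rad",
              length(h$g_loss), h$l1[length(h$l1)]))
  if (length(h$val_l1) > 0)
    cat(sprintf("; best validation l1 %.4f rad", h$best_val_l1))
  cat("\n")
  invisible(x)
}

#' Synthesize phase from a magnitude image
#'
#' Runs one forward pass of a trained (or freshly built) generator. The
#' magnitude is normalized to `[-1, 1]` by its maximum, matching the
#' training normalization; the output lies in `(-pi, pi)`. Dropout stays
#' active (it realizes the latent code), so pass `seed` for a
#' reproducible draw.
#'
#' @param generator a `phase_gan` fit or a bare `unet_generator`.
#' @param magnitude numeric matrix, or a list of matrices (each is
#'   translated independently, order preserved).
#' @param seed optional seed for the dropout draw.
#' @return phase matrix in `(-pi, pi)`, or a list of them.
#' @export
synthesize_phase <- function(generator, magnitude, seed = NULL) {
  gen <- if (inherits(generator, "phase_gan")) generator$generator else generator
  stopifnot(inherits(gen, "unet_generator"))
  if (!is.null(seed)) set.seed(seed)
  one <- function(m) {
    if (nrow(m) %% (2^length(gen$enc)) != 0)
      stop("magnitude shape is not compatible with the generator depth")
    .gen_forward(gen, .norm_mag(m))$out
  }
  if (is.list(magnitude)) lapply(magnitude, one) else one(magnitude)
}

#' @export
#' @rdname synthesize_phase
#' @param object,newdata,... standard predict arguments; `newdata` is a
#'   magnitude matrix or list of matrices.
predict.phase_gan <- function(object, newdata, seed = NULL, ...) {
  synthesize_phase(object, newdata, seed = seed)
}
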