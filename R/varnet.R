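# Unrolled variational network: T cascades alternating a soft
# data-consistency step with a learned convolutional refinement applied in
# the coil-combined image domain,
#   k_{t+1} = k_t - eta_t * mask (k_t - k_0) + F S CNN_t(S^H F^{-1} k_t),
# followed by a SENSE combination and modulus to produce the magnitude
# image. Sensitivity maps are fixed inputs (ESPIRiT or phantom maps), not
# learned. Backpropagation runs through the cascades, the unitary FFTs
# and the sensitivity operators exactly.

#' Variational network configuration
#'
#' @param n_cascades number of unrolled cascades (>= 0; 0 gives the
#'   zero-filled SENSE-combined magnitude).
#' @param regularizer_channels hidden channel width of each cascade's
#'   refinement CNN.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (default 10).
#' @param seed integer seed.
#' @param loss training loss, `"l1"` on the output magnitude (default) or
#'   `"l2"`.
#' @return object of class `"varnet_config"`.
#' @export
varnet_config <- function(n_cascades = 2L, regularizer_channels = 32L,
                          learning_rate = 1e-3, epochs = 10L, seed = 1L,
                          loss = c("l1", "l2")) {
  loss <- match.arg(loss)
  if (n_cascades < 0) stop("n_cascades must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(n_cascades = as.integer(n_cascades),
                 regularizer_channels = as.integer(regularizer_channels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss),
            class = "varnet_config")
}

# one cascade's refinement network, operating on the real/imag channels
# of the coil-combined image: a small encoder-decoder
#   conv4s2 (2->ch) relu -> conv4s2 (ch->2ch) relu -> conv3 (2ch->2ch) relu
#   -> tconv4s2 (2ch->ch) relu -> tconv4s2 (ch->ch) relu -> conv3 (ch->2)
# The two stride-2 stages give the refinement a receptive field of several
# tens of pixels, enough to reach equispaced aliasing ghosts, at less cost
# than a full-resolution stack. He-style fan-in initialization with a
# deliberately small final layer, so the untrained refinement is a gentle
# perturbation of the data-consistency iteration.
.cnn_params <- function(ch) {
  list(e1 = .conv_params(4L, 2L, ch, sqrt(2 / (16 * 2))),
       e2 = .conv_params(4L, ch, 2L * ch, sqrt(2 / (16 * ch))),
       m  = .conv_params(3L, 2L * ch, 2L * ch, sqrt(2 / (9 * 2 * ch))),
       u1 = .tconv_params(4L, 2L * ch, ch, sqrt(2 / (16 * 2 * ch))),
       u2 = .tconv_params(4L, ch, ch, sqrt(2 / (16 * ch))),
       out = .conv_params(3L, ch, 2L, 0.05))
}

.cnn_forward <- function(p, x) {
  z1 <- .conv_f(p$e1, x, 4L, 2L, 1L);  a1 <- .relu(z1)
  z2 <- .conv_f(p$e2, a1, 4L, 2L, 1L); a2 <- .relu(z2)
  z3 <- .conv_f(p$m, a2, 3L, 1L, 1L);  a3 <- .relu(z3)
  z4 <- .tconv_f(p$u1, a3, 4L, 2L, 1L); a4 <- .relu(z4)
  z5 <- .tconv_f(p$u2, a4, 4L, 2L, 1L); a5 <- .relu(z5)
  out <- .conv_f(p$out, a5, 3L, 1L, 1L)
  list(out = out,
       cache = list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3,
                    a3 = a3, z4 = z4, a4 = a4, z5 = z5, a5 = a5))
}

.cnn_backward <- function(p, ca, dout) {
  bo <- .conv_b(p$out, ca$a5, dout, 3L, 1L, 1L)
  d5 <- bo$dx * .drelu(ca$z5)
  b5 <- .tconv_b(p$u2, ca$a4, d5, 4L, 2L, 1L)
  d4 <- b5$dx * .drelu(ca$z4)
  b4 <- .tconv_b(p$u1, ca$a3, d4, 4L, 2L, 1L)
  d3 <- b4$dx * .drelu(ca$z3)
  b3 <- .conv_b(p$m, ca$a2, d3, 3L, 1L, 1L)
  d2 <- b3$dx * .drelu(ca$z2)
  b2 <- .conv_b(p$e2, ca$a1, d2, 4L, 2L, 1L)
  d1 <- b2$dx * .drelu(ca$z1)
  b1 <- .conv_b(p$e1, ca$x, d1, 4L, 2L, 1L)
  g <- function(b) list(w = b$dw, b = b$db)
  list(dx = b1$dx,
       grads = list(e1 = g(b1), e2 = g(b2), m = g(b3), u1 = g(b4),
                    u2 = g(b5), out = g(bo)))
}

#' Build an untrained variational network
#'
#' @param config a [varnet_config].
#' @return object of class `"varnet_model"` with per-cascade CNN
#'   parameters and per-cascade data-consistency weights `eta`
#'   (initialized at 1).
#' @export
build_varnet <- function(config) {
  stopifnot(inherits(config, "varnet_config"))
  T <- config$n_cascades
  cascades <- if (T > 0) lapply(seq_len(T), function(i)
    .cnn_params(config$regularizer_channels)) else list()
  structure(list(params = list(cascades = cascades,
                               eta = rep(1, T)),
                 config = config),
            class = "varnet_model")
}

.c2ch <- function(z) array(c(Re(z), Im(z)), dim = c(dim(z), 2L))
.ch2c <- function(a) a[, , 1] + 1i * a[, , 2]

# forward through all cascades; returns output magnitude and caches
.varnet_fwd <- function(model, k0, mask_cols, maps) {
  T <- model$config$n_cascades
  k <- k0
  caches <- vector("list", T)
  W <- dim(k0)[2]
  mk <- rep(FALSE, W); mk[mask_cols] <- TRUE
  for (t in seq_len(T)) {
    x <- sense_combine(kspace_to_image(k), maps)
    cn <- .cnn_forward(model$params$cascades[[t]], .c2ch(x))
    r <- .ch2c(cn$out)
    resid <- apply_mask(k - k0, mk)
    k_new <- k - model$params$eta[t] * resid +
      image_to_kspace(apply_sensitivities(r, maps))
    caches[[t]] <- list(k = k, resid = resid, cnn = cn$cache)
    k <- k_new
  }
  z <- sense_combine(kspace_to_image(k), maps)
  out <- Mod(z)
  list(out = out, z = z, k = k, caches = caches, mask_cols = mask_cols,
       mask_logical = mk)
}

# backward from gradient on the output magnitude
.varnet_bwd <- function(model, fw, maps, dout) {
  T <- model$config$n_cascades
  az <- Mod(fw$z)
  sf <- ifelse(az > 0, dout / az, 0)
  dz <- sf * fw$z                      # gradient wrt complex SENSE output
  dk <- image_to_kspace(apply_sensitivities(dz, maps))
  g_casc <- vector("list", max(T, 0))
  g_eta <- rep(0, T)
  for (t in rev(seq_len(T))) {
    ca <- fw$caches[[t]]
    # eta gradient: k_{t+1} has term -eta_t * resid
    g_eta[t] <- -sum(Re(dk) * Re(ca$resid) + Im(dk) * Im(ca$resid))
    # branch through the CNN refinement
    dr <- sense_combine(kspace_to_image(dk), maps)
    cb <- .cnn_backward(model$params$cascades[[t]], ca$cnn, .c2ch(dr))
    g_casc[[t]] <- cb$grads
    dx_c <- .ch2c(cb$dx)
    dk_cnn <- image_to_kspace(apply_sensitivities(dx_c, maps))
    # direct path: dk * (1 - eta_t * mask)
    dk <- dk - model$params$eta[t] * apply_mask(dk, fw$mask_logical) + dk_cnn
  }
  list(grads = list(cascades = g_casc, eta = g_eta))
}

#' Reconstruct a magnitude image with a variational network
#'
#' Runs the unrolled cascades on masked multicoil k-space and returns the
#' modulus of the SENSE-combined result. With `n_cascades = 0` this is
#' the zero-filled SENSE-combined magnitude.
#'
#' @param kspace complex array `(H, W, C)`; zero outside the mask.
#' @param mask a [sampling_mask] (or logical column vector).
#' @param maps a [sens_maps] object.
#' @param model a `varnet_model` or `varnet` fit.
#' @return numeric magnitude matrix `(H, W)` (real, non-negative).
#' @export
varnet_forward <- function(kspace, mask, maps, model) {
  if (inherits(model, "varnet")) model <- model$model
  stopifnot(inherits(model, "varnet_model"))
  d <- dim(kspace)
  if (length(d) != 3L || !identical(d, dim(maps_values(maps))))
    stop("kspace and maps have mismatched shapes")
  cols <- which(.mask_columns(mask, d[2]))
  .varnet_fwd(model, kspace, cols, maps)$out
}

#' Zero-filled SENSE reconstruction
#' @inheritParams varnet_forward
#' @return magnitude matrix of the zero-filled SENSE combine.
#' @export
zero_filled_recon <- function(kspace, mask, maps) {
  Mod(sense_adjoint(kspace, maps, mask))
}

#' Train a variational network
#'
#' Adam optimization of all cascade CNN weights and the per-cascade
#' data-consistency weights, with an l1 (default) or l2 loss between the
#' reconstructed and reference magnitudes. One example per step, shuffled
#' per epoch, fully seeded. When a validation set is given, the returned
#' model is the checkpoint with the best validation loss.
#'
#' @param train list of items `list(kspace = masked (H,W,C) complex,
#'   mask =, maps =, reference = magnitude matrix)`.
#' @param val optional validation list of the same form.
#' @param config a [varnet_config].
#' @param steps total optimization steps; defaults to
#'   `config$epochs * length(train)`.
#' @param val_every validation cadence in steps (default once per epoch).
#' @return object of class `"varnet"` with elements `model`, `history`,
#'   `config`.
#' @export
train_varnet <- function(train, val = list(), config = varnet_config(),
                         steps = NULL, val_every = NULL) {
  stopifnot(inherits(config, "varnet_config"), length(train) >= 1)
  set.seed(config$seed)
  model <- build_varnet(config)
  st <- .adam_init(model$params)
  n <- length(train)
  if (is.null(steps)) steps <- config$epochs * n
  if (is.null(val_every)) val_every <- n
  lossf <- function(out, ref)
    if (config$loss == "l1") mean(abs(out - ref)) else mean((out - ref)^2)
  dlossf <- function(out, ref)
    if (config$loss == "l1") sign(out - ref) / length(ref)
    else 2 * (out - ref) / length(ref)
  val_loss <- function(m) {
    if (length(val) == 0) return(NA_real_)
    mean(vapply(val, function(it) {
      cols <- which(.mask_columns(it$mask, dim(it$kspace)[2]))
      lossf(.varnet_fwd(m, it$kspace, cols, it$maps)$out, it$reference)
    }, numeric(1)))
  }
  hist <- list(loss = numeric(steps), val_step = integer(0),
               val_loss = numeric(0))
  best_val <- val_loss(model); best_params <- model$params
  order <- integer(0)
  for (s in seq_len(steps)) {
    if (length(order) == 0) order <- sample.int(n)
    i <- order[1]; order <- order[-1]
    it <- train[[i]]
    cols <- which(.mask_columns(it$mask, dim(it$kspace)[2]))
    fw <- .varnet_fwd(model, it$kspace, cols, it$maps)
    l <- lossf(fw$out, it$reference)
    if (!is.finite(l))
      stop(sprintf("non-finite reconstruction loss at step %d; training aborted", s))
    hist$loss[s] <- l
    if (config$n_cascades > 0) {
      bw <- .varnet_bwd(model, fw, it$maps, dlossf(fw$out, it$reference))
      up <- .adam_step(model$params, bw$grads, st, config$learning_rate,
                       beta1 = 0.9, beta2 = 0.999)
      model$params <- up$params; st <- up$state
    }
    if (s %% val_every == 0 || s == steps) {
      v <- val_loss(model)
      hist$val_step <- c(hist$val_step, s)
      hist$val_loss <- c(hist$val_loss, v)
      if (!is.na(v) && (is.na(best_val) || v < best_val)) {
        best_val <- v; best_params <- model$params
      }
    }
  }
  if (length(val) > 0) model$params <- best_params
  hist$best_val_loss <- best_val
  structure(list(model = model, history = hist, config = config),
            class = "varnet")
}

#' @export
print.varnet <- function(x, ...) {
  cat(sprintf("<varnet> %d cascades, %d channels, loss %s; trained %d steps",
              x$config$n_cascades, x$config$regularizer_channels,
              x$config$loss, length(x$history$loss)))
  if (length(x$history$val_loss) > 0)
    cat(sprintf("; best val loss %.5f", x$history$best_val_loss))
  cat("\n")
  invisible(x)
}

#' @export
#' @rdname varnet_forward
#' @param object,newdata,... standard predict arguments; `newdata` is one
#'   item `list(kspace =, mask =, maps =)` or a list of such items.
predict.varnet <- function(object, newdata, ...) {
  one <- function(it) varnet_forward(it$kspace, it$mask, it$maps, object)
  if (!is.null(newdata$kspace)) one(newdata) else lapply(newdata, one)
}
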