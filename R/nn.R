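# Small explicit-backprop neural network core used by the conditional GAN
# and the variational network. Images are (H, W, C) arrays, batch size 1
# (the GAN is trained with batch size 1 by design). Convolutions run
# through the compiled im2col kernels; every layer exposes a forward that
# returns a cache and a backward that consumes it, and the optimizers are
# plain Adam over the parameter lists. All randomness goes through R's RNG
# so fixed seeds give bit-identical training runs.

.conv_params <- function(k, cin, cout, sd = 0.02) {
  list(w = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout))
}

# transposed conv stores the weight of its underlying (adjoint) conv:
# shape (k*k*cout, cin)
.tconv_params <- function(k, cin, cout, sd = 0.02) {
  list(w = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cout, cin),
       b = numeric(cout))
}

.add_bias <- function(y, b) {
  d <- dim(y)
  y + rep(b, each = d[1] * d[2])
}

.conv_f <- function(p, x, k, stride, pad) {
  .add_bias(cpp_conv_fwd(x, p$w, k, stride, pad), p$b)
}

.conv_b <- function(p, x, dy, k, stride, pad) {
  d <- dim(x)
  list(dx = cpp_conv_bwd_input(dy, p$w, k, stride, pad, d[1], d[2], d[3]),
       dw = cpp_conv_bwd_weight(x, dy, k, stride, pad),
       db = apply(dy, 3, sum))
}

.tconv_f <- function(p, x, k, stride, pad) {
  d <- dim(x)
  Ho <- (d[1] - 1L) * stride + k - 2L * pad
  Wo <- (d[2] - 1L) * stride + k - 2L * pad
  cout <- length(p$b)
  .add_bias(cpp_conv_bwd_input(x, p$w, k, stride, pad, Ho, Wo, cout), p$b)
}

.tconv_b <- function(p, x, dy, k, stride, pad) {
  list(dx = cpp_conv_fwd(dy, p$w, k, stride, pad),
       dw = cpp_conv_bwd_weight(dy, x, k, stride, pad),
       db = apply(dy, 3, sum))
}

.lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
.dlrelu <- function(x, a = 0.2) ifelse(x > 0, 1, a)
.relu <- function(x) pmax(x, 0)
.drelu <- function(x) (x > 0) * 1
.sigmoid <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.cat3 <- function(a, b) {
  d1 <- dim(a); d2 <- dim(b)
  array(c(a, b), dim = c(d1[1], d1[2], d1[3] + d2[3]))
}

# ---- Adam over nested parameter lists (numeric leaves) ----

.adam_init <- function(params) {
  zl <- function(p) if (is.list(p)) lapply(p, zl) else p * 0
  list(m = zl(params), v = zl(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# elementwise sum of two nested gradient lists
.grad_add <- function(a, b) {
  if (is.list(a)) return(Map(.grad_add, a, b))
  a + b
}
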