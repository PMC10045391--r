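# Reconstruction quality metrics (PSNR, NMSE, SSIM), dataset splitting,
# and the phase-model comparison harness that trains one variational
# network per (phase model, acceleration) cell and evaluates every model
# on the same ground-truth test split.

.gaussian_kernel <- function(sigma = 1.5, truncate = 3.5) {
  r <- floor(truncate * sigma + 0.5)
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

.gfilter_valid <- function(x, kern) {
  k <- nrow(kern)
  cpp_conv_fwd(array(x, dim = c(dim(x), 1L)),
               matrix(as.vector(kern), k * k, 1L), k, 1L, 0L)[, , 1]
}

#' Structural similarity index
#'
#' SSIM with Gaussian-weighted local statistics (11x11 window,
#' `sigma = 1.5`, population covariances, constants `K1 = 0.01`,
#' `K2 = 0.03`), averaged over the interior region where the window fits
#' entirely. The data range defaults to the maximum of the reference
#' image.
#'
#' @param reference,test numeric matrices of the same shape.
#' @param data_range dynamic range used for the stabilizing constants.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, data_range = max(reference)) {
  stopifnot(identical(dim(reference), dim(test)))
  kern <- .gaussian_kernel()
  ux <- .gfilter_valid(test, kern);      uy <- .gfilter_valid(reference, kern)
  uxx <- .gfilter_valid(test^2, kern);   uyy <- .gfilter_valid(reference^2, kern)
  uxy <- .gfilter_valid(test * reference, kern)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Reconstruction quality metrics
#'
#' Computes the standard triple for one reconstructed slice against its
#' reference: `nmse = ||test - ref||^2 / ||ref||^2`,
#' `psnr = 10 * log10(max(ref)^2 / mse)` (in dB; `Inf` for identical
#' images) and [ssim()] with data range `max(ref)`.
#'
#' @param reference,test numeric magnitude matrices of the same shape;
#'   the reference must not be all zero.
#' @return object of class `"recon_metrics"`: list with `psnr`, `nmse`,
#'   `ssim`.
#' @export
compute_metrics <- function(reference, test) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test have mismatched shapes")
  if (all(reference == 0))
    stop("metrics are undefined for an all-zero reference")
  mse <- mean((test - reference)^2)
  nmse <- sum((test - reference)^2) / sum(reference^2)
  psnr <- if (mse == 0) Inf else 10 * log10(max(reference)^2 / mse)
  structure(list(psnr = psnr, nmse = nmse,
                 ssim = ssim(reference, test)),
            class = "recon_metrics")
}

#' @export
print.recon_metrics <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | NMSE %.5f | SSIM %.4f\n", x$psnr, x$nmse, x$ssim))
  invisible(x)
}

#' Split a dataset into train/validation/test partitions
#'
#' Volume-level seeded shuffle, then `round(n * f)` items to validation
#' and test and the remainder to train. The three parts are disjoint and
#' exhaustive.
#'
#' @param items list of volumes (>= 3).
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed shuffle seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(items, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split")
  set.seed(seed)
  ord <- sample.int(n)
  n_val <- round(n * fractions[2]); n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("split leaves no training items")
  list(train = items[ord[seq_len(n_train)]],
       val = items[ord[n_train + seq_len(n_val)]],
       test = items[ord[n_train + n_val + seq_len(n_test)]])
}

.varnet_items <- function(samples, model, mask, maps_list = NULL) {
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    maps <- if (is.null(maps_list)) s$maps else maps_list[[i]]
    ph <- model_phase(model, s)
    ks <- synthesize_multicoil_kspace(s$magnitude, ph, maps, mask)
    list(kspace = ks, mask = mask, maps = maps, reference = s$magnitude)
  })
}

.gt_items <- function(samples, mask) {
  lapply(samples, function(s)
    list(kspace = apply_mask(s$kspace, mask), mask = mask, maps = s$maps,
         reference = s$magnitude))
}

#' Compare phase models through variational-network reconstruction
#'
#' For each phase model and each acceleration factor, synthesizes
#' undersampled multicoil training k-space from the training split's
#' magnitudes under that phase model, trains a variational network on it,
#' and evaluates the trained model on the shared ground-truth test split.
#' Returns one row per (phase model, R) cell with mean and standard
#' deviation of PSNR, NMSE and SSIM over the test slices.
#'
#' @param dataset list of `phantom_sample` volumes (e.g. from
#'   [generate_dataset()]).
#' @param phase_models character vector naming the models to compare
#'   (subset of `ground_truth`, `gan`, `sinusoidal`, `random`, `zero`).
#' @param accelerations numeric vector of acceleration factors R.
#' @param gan trained [train_phase_gan()] fit; required when `"gan"` is
#'   among the models.
#' @param center_fraction mask center fraction.
#' @param varnet_config a [varnet_config] template for every cell.
#' @param varnet_steps optimization steps per cell (`NULL` for
#'   `epochs * n_train`).
#' @param fractions train/val/test fractions.
#' @param seed master seed (splitting, phase draws, training).
#' @return `data.frame` with columns `phase_model`, `acceleration`,
#'   `coils`, `psnr_mean`, `psnr_sd`, `nmse_mean`, `nmse_sd`,
#'   `ssim_mean`, `ssim_sd`, `seed`; per-slice metrics are attached as
#'   attribute `"per_slice"`.
#' @export
run_phase_comparison <- function(dataset,
                                 phase_models = c("ground_truth", "gan",
                                                  "sinusoidal", "random",
                                                  "zero"),
                                 accelerations = c(4, 8), gan = NULL,
                                 center_fraction = 0.04,
                                 varnet_config = synthmri::varnet_config(
                                   n_cascades = 1L, regularizer_channels = 8L),
                                 varnet_steps = NULL,
                                 fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if ("gan" %in% phase_models && is.null(gan))
    stop("pipeline stage missing: phase model 'gan' needs a trained generator")
  parts <- split_dataset(dataset, fractions, seed = seed)
  W <- dim(parts$train[[1]]$magnitude)[2]
  C <- dim(maps_values(parts$train[[1]]$maps))[3]
  rows <- list(); per_slice <- list()
  for (pm in phase_models) {
    model <- phase_model(pm, gan = gan)
    for (R in accelerations) {
      mask <- make_equispaced_mask(W, R, center_fraction)
      set.seed(seed + 1000L * which(phase_models == pm) + R)
      tr <- .varnet_items(parts$train, model, mask)
      va <- .varnet_items(parts$val, model, mask)
      cfg <- varnet_config
      cfg$seed <- as.integer((seed * 131L + R * 17L +
                                which(phase_models == pm)) %% 2147483L)
      fit <- train_varnet(tr, va, cfg, steps = varnet_steps)
      te <- .gt_items(parts$test, mask)
      mets <- lapply(te, function(it)
        compute_metrics(it$reference,
                        varnet_forward(it$kspace, it$mask, it$maps, fit)))
      g <- function(f) vapply(mets, `[[`, numeric(1), f)
      rows[[length(rows) + 1L]] <- data.frame(
        phase_model = pm, acceleration = R, coils = C,
        psnr_mean = mean(g("psnr")), psnr_sd = sd(g("psnr")),
        nmse_mean = mean(g("nmse")), nmse_sd = sd(g("nmse")),
        ssim_mean = mean(g("ssim")), ssim_sd = sd(g("ssim")),
        seed = seed)
      per_slice[[paste(pm, R, sep = "_R")]] <-
        data.frame(phase_model = pm, acceleration = R,
                   slice = seq_along(mets), psnr = g("psnr"),
                   nmse = g("nmse"), ssim = g("ssim"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_slice") <- do.call(rbind, per_slice)
  out
}

#' @importFrom stats sd
NULL
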