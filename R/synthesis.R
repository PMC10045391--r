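# Training-data synthesis: combine a magnitude image with a phase model
# (GAN-generated or one of the zero / random / sinusoidal baselines) and
# coil sensitivity maps into multicoil k-space, optionally undersampled.
# Phase synthesis never alters the magnitude: the RSS of the coil images
# underlying the synthesized k-space equals the input magnitude wherever
# the maps are normalized.

#' Phase model descriptor
#'
#' @param kind one of `"gan"`, `"zero"`, `"random"`, `"sinusoidal"`,
#'   `"ground_truth"`.
#' @param gan a trained [train_phase_gan()] fit (required for
#'   `kind = "gan"`).
#' @param amplitude sinusoidal amplitude in radians (<= pi).
#' @param freq_range sinusoidal frequency range in cycles per field of
#'   view; one frequency is drawn uniformly per image.
#' @return object of class `"phase_model"`.
#' @export
phase_model <- function(kind, gan = NULL, amplitude = pi / 2,
                        freq_range = c(1, 8)) {
  kind <- match.arg(kind, c("gan", "zero", "random", "sinusoidal",
                            "ground_truth"))
  if (kind == "gan" && !inherits(gan, c("phase_gan", "unet_generator")))
    stop("kind = \"gan\" requires a trained generator in `gan`")
  if (amplitude < 0 || amplitude > pi) stop("amplitude must lie in [0, pi]")
  structure(list(kind = kind, gan = gan, amplitude = amplitude,
                 freq_range = freq_range),
            class = "phase_model")
}

#' Baseline phase generators
#'
#' The three non-generative phase models compared against the GAN:
#' `zero` (all-zero phase), `random` (i.i.d. uniform on `[-pi, pi)`) and
#' `sinusoidal` (a plane sinusoid `a * sin(2*pi*(fx*x/W + fy*y/H) + phi0)`
#' whose frequency magnitude is drawn uniformly from `freq_range` with a
#' random orientation, per image). Draws come from R's current RNG
#' stream; seed the caller for reproducibility.
#'
#' @param kind `"zero"`, `"random"` or `"sinusoidal"`, or a
#'   [phase_model] of one of those kinds.
#' @param shape integer vector `(H, W)`.
#' @param amplitude,freq_range sinusoidal parameters (ignored when `kind`
#'   is a `phase_model`, which carries its own).
#' @return phase matrix `(H, W)` in `[-pi, pi)`.
#' @export
baseline_phase <- function(kind, shape, amplitude = pi / 2,
                           freq_range = c(1, 8)) {
  if (inherits(kind, "phase_model")) {
    amplitude <- kind$amplitude; freq_range <- kind$freq_range
    kind <- kind$kind
  }
  if (!kind %in% c("zero", "random", "sinusoidal"))
    stop(sprintf("unknown baseline phase kind '%s'", kind))
  H <- shape[1]; W <- shape[2]
  switch(kind,
    zero = matrix(0, H, W),
    random = matrix(runif(H * W, -pi, pi), H, W),
    sinusoidal = {
      f <- runif(1, freq_range[1], freq_range[2])
      th <- runif(1, 0, 2 * pi)
      phi0 <- runif(1, 0, 2 * pi)
      r <- matrix(seq_len(H) / H, H, W)
      c <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
      amplitude * sin(2 * pi * (f * cos(th) * c + f * sin(th) * r) + phi0)
    })
}

#' Synthesize multicoil k-space from magnitude, phase and maps
#'
#' The exact composition `mask * FFT(S_c * (magnitude * exp(i*phase)))`
#' of the signal-model operators.
#'
#' @param magnitude non-negative matrix.
#' @param phase phase matrix (radians), same shape.
#' @param maps a [sens_maps] object or complex array `(H, W, C)`.
#' @param mask a [sampling_mask] or `NULL` for fully sampled.
#' @return complex array `(H, W, C)`.
#' @export
synthesize_multicoil_kspace <- function(magnitude, phase, maps, mask = NULL) {
  apply_mask(image_to_kspace(apply_sensitivities(
    assemble_complex(magnitude, phase), maps)), mask)
}

#' Assign sensitivity maps to synthetic items
#'
#' `same_volume` pairs each item with the maps estimated from its own
#' source acquisition (the pool must be index-aligned with the items);
#' `random_from_pool` samples maps with replacement from the pool,
#' seeded.
#'
#' @param items list of items to pair.
#' @param map_pool non-empty list of [sens_maps] objects.
#' @param strategy `"same_volume"` or `"random_from_pool"`.
#' @param seed seed for the random strategy.
#' @return list of `sens_maps`, one per item.
#' @export
pair_sensitivity_maps <- function(items, map_pool,
                                  strategy = c("same_volume",
                                               "random_from_pool"),
                                  seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(map_pool) == 0) stop("map_pool must be non-empty")
  n <- length(items)
  if (strategy == "same_volume") {
    if (length(map_pool) != n)
      stop("same_volume pairing requires one map set per item")
    return(map_pool)
  }
  set.seed(seed)
  map_pool[sample.int(length(map_pool), n, replace = TRUE)]
}

#' Phase for one item under a phase model
#'
#' Resolves a [phase_model] against a phantom sample: `ground_truth`
#' returns the sample's own phase, `gan` a generator forward pass on the
#' magnitude, and the baselines a fresh draw from [baseline_phase()].
#'
#' @param model a [phase_model].
#' @param sample a `phantom_sample` (or any list with `magnitude` and
#'   `phase`).
#' @return phase matrix.
#' @export
model_phase <- function(model, sample) {
  stopifnot(inherits(model, "phase_model"))
  switch(model$kind,
    ground_truth = sample$phase,
    gan = synthesize_phase(model$gan, sample$magnitude),
    baseline_phase(model, dim(sample$magnitude)))
}
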