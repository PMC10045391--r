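# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

small_spec <- function(seed = 1L, size = 64L, coils = 4L, ...) {
  phantom_spec(height = size, width = size, n_coils = coils, seed = seed, ...)
}

random_complex <- function(h, w, c = NULL) {
  n <- h * w * max(1, c %||% 1)
  v <- complex(real = rnorm(n), imaginary = rnorm(n))
  if (is.null(c)) matrix(v, h, w) else array(v, dim = c(h, w, c))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic toy task: phase is a fixed smooth function of the tissue
# labels (offset 0.45*(label-1) - 0.6 on a fixed polynomial background),
# so the magnitude -> phase mapping is learnable without ambiguity
toy_phase_pairs <- function(n, seed0, size = 64L) {
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(height = size, width = size, n_coils = 4L,
                       n_tissue_regions = 3L, noise_sigma_background = 0,
                       seed = seed0 + i)
    mp <- generate_magnitude_phantom(sp)
    ph <- generate_phase_field(mp$magnitude, mp$tissue_labels, sp,
                               poly_coefficients = c(0.3, 0.4, -0.3, 0.2, 0, 0.1),
                               offsets = 0.45 * (seq_len(max(1, max(mp$tissue_labels))) - 1) - 0.6)
    list(magnitude = mp$magnitude, phase = ph)
  })
}

toy_gan_config <- function(seed = 7L, size = 64L) {
  gan_config(image_size = size, base_channels = 8L,
             generator_depth = as.integer(log2(size)),
             d_layers = if (size >= 64) 2L else 1L,
             d_base_channels = 8L, seed = seed)
}

# masked ground-truth training items for the variational network
gt_varnet_items <- function(samples, mask) {
  lapply(samples, function(s)
    list(kspace = apply_mask(s$kspace, mask), mask = mask, maps = s$maps,
         reference = s$magnitude))
}
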