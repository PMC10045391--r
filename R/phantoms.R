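# Brain-like numerical phantoms: piecewise-smooth magnitude, spatially
# smooth phase with tissue contrast and a noisy background, and smooth
# complex coil profiles. These stand in for raw multicoil brain
# acquisitions so the whole pipeline can be exercised and tested without
# any external data.

#' Phantom specification
#'
#' Describes one 2D brain-like phantom: image geometry, an elliptical
#' "skull" support, a number of nested/overlapping elliptical tissue
#' regions, the coil array size, the background phase noise level and the
#' seed. All generator operations are pure functions of this object: the
#' same spec always yields bit-identical output.
#'
#' @param height,width image size in pixels (>= 32).
#' @param n_coils number of receiver coils (>= 1).
#' @param n_tissue_regions number of elliptical tissue regions inside the
#'   skull (0 gives the bare skull ellipse).
#' @param skull_ellipse list with `center` (row, col), `axes` (semi-axes in
#'   pixels) and `angle` (radians); `NULL` for a default centered ellipse.
#' @param noise_sigma_background standard deviation (radians) of the
#'   Gaussian phase noise added outside tissue, or the string `"uniform"`
#'   for uniform noise on `[-pi, pi)`.
#' @param seed integer seed.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, n_coils = 8L,
                         n_tissue_regions = 4L, skull_ellipse = NULL,
                         noise_sigma_background = 0.5, seed = 1L) {
  if (height < 32 || width < 32) stop("height and width must be >= 32")
  if (n_coils < 1) stop("n_coils must be >= 1")
  if (n_tissue_regions < 0) stop("n_tissue_regions must be >= 0")
  if (is.numeric(noise_sigma_background) && noise_sigma_background < 0)
    stop("noise_sigma_background must be >= 0")
  if (is.null(skull_ellipse)) {
    skull_ellipse <- list(center = c((height + 1) / 2, (width + 1) / 2),
                          axes = c(0.42 * height, 0.36 * width), angle = 0)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_coils = as.integer(n_coils),
                 n_tissue_regions = as.integer(n_tissue_regions),
                 skull_ellipse = skull_ellipse,
                 noise_sigma_background = noise_sigma_background,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, %d coils, %d tissue regions, seed %d\n",
              x$height, x$width, x$n_coils, x$n_tissue_regions, x$seed))
  invisible(x)
}

# pixel-center-inside test for a rotated ellipse
.ellipse_mask <- function(height, width, center, axes, angle) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- r - center[1]; dc <- c - center[2]
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate a piecewise-smooth magnitude phantom
#'
#' Background 0, skull ellipse filled at a base intensity, then
#' `n_tissue_regions` randomly placed elliptical regions with distinct
#' intensities in (0, 1], clipped to the skull. A mild low-frequency
#' multiplicative modulation prevents the image from being exactly
#' piecewise-constant. Values are clamped to `[0, 1]`.
#'
#' @param spec a [phantom_spec].
#' @return list with `magnitude` (matrix in `[0, 1]`) and `tissue_labels`
#'   (integer matrix; 0 background, 1 base tissue, 2.. the regions).
#' @export
generate_magnitude_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed((as.numeric(spec$seed) * 7) %% 2147483399 + 11)
  H <- spec$height; W <- spec$width
  sk <- spec$skull_ellipse
  skull <- .ellipse_mask(H, W, sk$center, sk$axes, sk$angle)
  base_int <- 0.35
  mag <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  mag[skull] <- base_int
  labels[skull] <- 1L
  if (spec$n_tissue_regions > 0) {
    for (i in seq_len(spec$n_tissue_regions)) {
      ctr <- sk$center + (runif(2) - 0.5) * sk$axes
      ax <- c(runif(1, 0.10, 0.45), runif(1, 0.10, 0.45)) * sk$axes
      ang <- runif(1, 0, pi)
      intensity <- runif(1, 0.30, 1.0)
      reg <- .ellipse_mask(H, W, ctr, ax, ang) & skull
      mag[reg] <- intensity
      labels[reg] <- i + 1L
    }
  }
  # mild smooth modulation so tissue is not piecewise-constant
  r <- matrix(seq_len(H) / H, H, W)
  c <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  ph1 <- runif(2, 0, 2 * pi)
  modu <- 1 + 0.08 * cos(2 * pi * r + ph1[1]) * cos(2 * pi * c + ph1[2])
  mag <- mag * modu
  mag[!skull] <- 0
  mag <- pmin(pmax(mag, 0), 1)
  list(magnitude = mag, tissue_labels = labels)
}

#' Generate a brain-like phase field
#'
#' The phase is the wrapped sum of a low-order 2D polynomial background
#' (smooth, low spatial frequency), a constant per-tissue-region offset
#' (tissue phase contrast) and i.i.d. noise restricted to the background
#' pixels (`tissue_labels == 0`). The result lies in `[-pi, pi)`.
#'
#' @param magnitude magnitude matrix (used only for shape validation).
#' @param tissue_labels integer matrix from [generate_magnitude_phantom()].
#' @param spec a [phantom_spec].
#' @param poly_coefficients optional length-6 numeric vector
#'   `(c00, c10, c01, c20, c11, c02)` overriding the random background.
#' @param offsets optional numeric vector of per-label offsets (radians),
#'   indexed by tissue label, overriding the random draw.
#' @return phase matrix in `[-pi, pi)`.
#' @export
generate_phase_field <- function(magnitude, tissue_labels, spec,
                                 poly_coefficients = NULL, offsets = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!identical(dim(magnitude), dim(tissue_labels)))
    stop("magnitude and tissue_labels have mismatched shapes")
  if (!identical(dim(magnitude), c(spec$height, spec$width)))
    stop("inputs do not match the spec dimensions")
  set.seed((as.numeric(spec$seed) * 13) %% 2147483399 + 29)
  H <- spec$height; W <- spec$width
  u <- matrix(2 * (seq_len(H) - 1) / (H - 1) - 1, H, W)
  v <- matrix(2 * (seq_len(W) - 1) / (W - 1) - 1, H, W, byrow = TRUE)
  if (is.null(poly_coefficients)) poly_coefficients <- rnorm(6, 0, 0.45)
  cf <- poly_coefficients
  phase <- cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v + cf[6] * v^2
  n_lab <- max(tissue_labels)
  if (n_lab > 0) {
    if (is.null(offsets)) offsets <- runif(n_lab, -1, 1)
    for (l in seq_len(n_lab)) {
      sel <- tissue_labels == l
      if (any(sel)) phase[sel] <- phase[sel] + offsets[l]
    }
  }
  bg <- tissue_labels == 0L
  if (identical(spec$noise_sigma_background, "uniform")) {
    phase[bg] <- runif(sum(bg), -pi, pi)
  } else if (spec$noise_sigma_background > 0) {
    phase[bg] <- phase[bg] + rnorm(sum(bg), 0, spec$noise_sigma_background)
  }
  wrap_phase(phase)
}

#' Generate smooth complex coil sensitivity profiles
#'
#' Each coil is a Gaussian magnitude bump centered on a point of a circle
#' around the image, multiplied by a smooth linear phase ramp. The stack is
#' normalized pixelwise so that `sum_c |S_c|^2 = 1` everywhere (the Gaussian
#' profiles are strictly positive, so the normalization is defined at every
#' pixel, in particular inside the skull support).
#'
#' @param spec a [phantom_spec].
#' @return a [sens_maps] object with full-image support.
#' @export
generate_coil_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed((as.numeric(spec$seed) * 17) %% 2147483399 + 43)
  H <- spec$height; W <- spec$width; C <- spec$n_coils
  rad <- 0.6 * min(H, W)
  sigma <- 0.5 * min(H, W)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  S <- array(0i, dim = c(H, W, C))
  for (k in seq_len(C)) {
    theta <- 2 * pi * (k - 1) / C
    pos <- ctr + rad * c(cos(theta), sin(theta))
    d2 <- (r - pos[1])^2 + (cc - pos[2])^2
    amp <- exp(-d2 / (2 * sigma^2))
    slope <- runif(2, -2, 2)
    ph0 <- runif(1, -pi, pi)
    ramp <- (slope[1] * (r - ctr[1]) + slope[2] * (cc - ctr[2])) / min(H, W) + ph0
    S[, , k] <- amp * exp(1i * ramp)
  }
  rss <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
  for (k in seq_len(C)) S[, , k] <- S[, , k] / rss
  sens_maps(S)
}

#' Generate one complete phantom sample
#'
#' Runs the magnitude, phase and coil-map generators and assembles the
#' fully sampled multicoil k-space through the exact forward signal model
#' (`FFT(S_c * |m| e^{i phi})`), so the k-space is constructed, not fit.
#'
#' @param spec a [phantom_spec].
#' @return object of class `"phantom_sample"`: list with `magnitude`,
#'   `phase`, `maps`, `kspace` (`(H, W, C)` complex), `tissue_labels`,
#'   and `spec`.
#' @export
generate_phantom_sample <- function(spec) {
  mp <- generate_magnitude_phantom(spec)
  phase <- generate_phase_field(mp$magnitude, mp$tissue_labels, spec)
  maps <- generate_coil_maps(spec)
  ks <- image_to_kspace(apply_sensitivities(assemble_complex(mp$magnitude, phase),
                                            maps))
  structure(list(magnitude = mp$magnitude, phase = phase, maps = maps,
                 kspace = ks, tissue_labels = mp$tissue_labels, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, %d coils, seed %d\n",
              x$spec$height, x$spec$width, x$spec$n_coils, x$spec$seed))
  invisible(x)
}

#' Generate a phantom dataset
#'
#' Draws `n_samples` independent phantom samples, each from a copy of
#' `spec` carrying a per-sample seed derived deterministically from `seed`.
#'
#' @param n_samples number of samples (>= 1).
#' @param spec a [phantom_spec] used as the template.
#' @param seed master seed for the per-sample seed stream.
#' @return list of `phantom_sample` objects.
#' @export
generate_dataset <- function(n_samples, spec, seed = spec$seed) {
  stopifnot(n_samples >= 1, inherits(spec, "phantom_spec"))
  set.seed(seed)
  seeds <- sample.int(2147483000L, n_samples)
  lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    generate_phantom_sample(sp)
  })
}
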