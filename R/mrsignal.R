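#' @useDynLib synthmri, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft
NULL

# ---- internal shift helpers (DC at floor(N/2), 0-based => floor(N/2)+1 in R) ----

.shift_idx <- function(n, k) {
  # circular shift of 1:n by +k
  ((seq_len(n) - 1L - k) %% n) + 1L
}

.fftshift2 <- function(x) {
  d <- dim(x)
  x[.shift_idx(d[1], floor(d[1] / 2)), .shift_idx(d[2], floor(d[2] / 2)), drop = FALSE]
}

.ifftshift2 <- function(x) {
  d <- dim(x)
  x[.shift_idx(d[1], -floor(d[1] / 2)), .shift_idx(d[2], -floor(d[2] / 2)), drop = FALSE]
}

.fft2c <- function(x, inverse = FALSE) {
  # centered, unitary 2D DFT of one matrix
  s <- sqrt(length(x))
  .fftshift2(stats::fft(.ifftshift2(x), inverse = inverse)) / s
}

.per_coil <- function(x, f) {
  if (length(dim(x)) == 2L) return(f(x))
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- f(x[, , c])
  out
}

#' Centered unitary 2D Fourier transform
#'
#' Transforms a complex image (or a per-coil stack with the coil axis last)
#' into its spatial-frequency representation. The transform is orthonormal
#' (Parseval holds exactly) and centered: the DC component sits at matrix
#' index `floor(N/2) + 1` on each axis, following the common convention for
#' Cartesian MRI k-space.
#'
#' @param x complex matrix `(H, W)` or array `(H, W, C)`.
#' @return object of the same shape containing the k-space spectrum.
#' @seealso [kspace_to_image()] for the inverse.
#' @export
#' @examples
#' img <- matrix(complex(real = rnorm(16)), 4, 4)
#' max(Mod(kspace_to_image(image_to_kspace(img)) - img)) < 1e-12
image_to_kspace <- function(x) {
  stopifnot(all(is.finite(Re(x))), all(is.finite(Im(x))))
  .per_coil(x + 0i, function(m) .fft2c(m, inverse = FALSE))
}

#' @rdname image_to_kspace
#' @export
kspace_to_image <- function(x) {
  stopifnot(all(is.finite(Re(x))), all(is.finite(Im(x))))
  .per_coil(x + 0i, function(m) .fft2c(m, inverse = TRUE))
}

#' Assemble a complex image from magnitude and phase
#'
#' Forms `m = |m| * exp(i * phase)`, i.e. the complex transverse
#' magnetization whose modulus is the stored magnitude image and whose
#' angle is the (synthetic or measured) phase map.
#'
#' @param magnitude non-negative numeric matrix.
#' @param phase numeric matrix of angles in radians, same shape.
#' @return complex matrix of the same shape.
#' @export
assemble_complex <- function(magnitude, phase) {
  if (!identical(dim(magnitude), dim(phase)))
    stop("magnitude and phase must have identical dimensions")
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  magnitude * exp(1i * phase)
}

#' Wrap angles to [-pi, pi)
#' @param x numeric array of angles in radians.
#' @return wrapped angles.
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Apply coil sensitivity profiles to a complex image
#'
#' Multiplies the coil-combined image elementwise by each coil's complex
#' sensitivity, producing the per-coil image stack `S_c * m`.
#'
#' @param image complex matrix `(H, W)`.
#' @param maps a [sens_maps] object or complex array `(H, W, C)`.
#' @return complex array `(H, W, C)`.
#' @export
apply_sensitivities <- function(image, maps) {
  S <- maps_values(maps)
  d <- dim(S)
  if (!identical(dim(image), d[1:2]))
    stop("image and sensitivity maps have mismatched spatial dimensions")
  out <- array(0i, dim = d)
  for (c in seq_len(d[3])) out[, , c] <- S[, , c] * image
  out
}

#' Root-sum-of-squares coil combination
#'
#' @param coil_images complex array `(H, W, C)`.
#' @return numeric matrix `(H, W)` with `sqrt(sum_c |x_c|^2)` per pixel.
#' @export
coil_combine_rss <- function(coil_images) {
  d <- dim(coil_images)
  stopifnot(length(d) == 3L, d[3] >= 1L)
  sqrt(apply(Mod(coil_images)^2, c(1, 2), sum))
}

#' SENSE coil combination
#'
#' Combines a per-coil image stack by weighting each coil with the conjugate
#' of its sensitivity: `sum_c conj(S_c) * x_c`. With RSS-normalized maps this
#' is the adjoint of [apply_sensitivities()].
#'
#' @param coil_images complex array `(H, W, C)`.
#' @param maps a [sens_maps] object or complex array `(H, W, C)`.
#' @return complex matrix `(H, W)`.
#' @export
sense_combine <- function(coil_images, maps) {
  S <- maps_values(maps)
  stopifnot(identical(dim(coil_images), dim(S)))
  out <- matrix(0i, dim(S)[1], dim(S)[2])
  for (c in seq_len(dim(S)[3])) out <- out + Conj(S[, , c]) * coil_images[, , c]
  out
}

# ---- sensitivity map container ----

#' Coil sensitivity maps
#'
#' Container for a stack of smooth complex coil profiles `S_c(x, y)` plus a
#' logical support mask. Inside the support the maps are normalized so that
#' `sum_c |S_c|^2 = 1` per pixel; outside the support the maps are either 0
#' (estimated maps) or still normalized (analytic phantom maps whose support
#' covers the full field of view).
#'
#' @param values complex array `(H, W, C)`.
#' @param support logical matrix `(H, W)`; defaults to all `TRUE`.
#' @return object of class `"sens_maps"`.
#' @export
sens_maps <- function(values, support = NULL) {
  d <- dim(values)
  stopifnot(length(d) == 3L, d[3] >= 1L)
  if (is.null(support)) support <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(support), d[1:2]))
  structure(list(values = values + 0i, support = support), class = "sens_maps")
}

#' @export
print.sens_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sens_maps> %d coils, %dx%d, support %d/%d pixels\n",
              d[3], d[1], d[2], sum(x$support), d[1] * d[2]))
  invisible(x)
}

#' Extract the complex array from a maps object
#' @param maps a `sens_maps` object or a bare complex array.
#' @return complex array `(H, W, C)`.
#' @export
maps_values <- function(maps) {
  if (inherits(maps, "sens_maps")) maps$values else maps
}

# ---- sampling masks ----

#' Equispaced Cartesian undersampling mask
#'
#' Builds a column-wise (phase-encode) mask with a fully sampled contiguous
#' center block of `round(width * center_fraction)` columns and a total
#' budget of `round(width / acceleration)` sampled columns, the remainder
#' placed at a constant stride through the non-center columns starting at
#' `offset`. The effective acceleration is therefore exactly
#' `width / round(width / acceleration)`.
#'
#' @param width number of k-space columns (>= 8).
#' @param acceleration acceleration factor R >= 1.
#' @param center_fraction fraction of columns kept at the center, in `[0, 1]`.
#' @param offset 0-based starting index into the non-center columns for the
#'   equispaced remainder.
#' @return object of class `"sampling_mask"` with logical element `columns`.
#' @export
#' @examples
#' m <- make_equispaced_mask(320, 4, 0.04)
#' sum(m$columns)  # 80 columns kept -> effective acceleration exactly 4
make_equispaced_mask <- function(width, acceleration, center_fraction = 0.04,
                                 offset = 0L) {
  if (width < 8) stop("width must be at least 8")
  if (acceleration < 1) stop("acceleration must be >= 1")
  if (center_fraction < 0 || center_fraction > 1)
    stop("center_fraction must lie in [0, 1]")
  n_total <- round(width / acceleration)
  n_center <- round(width * center_fraction)
  if (n_total < n_center)
    stop("center exceeds budget: round(width/R) < round(width*center_fraction)")
  cols <- rep(FALSE, width)
  c_start <- floor((width - n_center) / 2) + 1L
  if (n_center > 0) cols[c_start:(c_start + n_center - 1L)] <- TRUE
  n_rem <- n_total - n_center
  non_center <- which(!cols)
  if (n_rem >= length(non_center)) {
    cols[] <- TRUE
  } else if (n_rem > 0) {
    stride <- length(non_center) / n_rem
    pick <- floor(offset + stride * (seq_len(n_rem) - 1L)) %% length(non_center) + 1L
    cols[non_center[unique(pick)]] <- TRUE
  }
  structure(list(columns = cols, acceleration = acceleration,
                 center_fraction = center_fraction, offset = as.integer(offset),
                 width = as.integer(width)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> width %d, R=%g, cf=%g: %d columns kept\n",
              x$width, x$acceleration, x$center_fraction, sum(x$columns)))
  invisible(x)
}

.mask_columns <- function(mask, width) {
  if (is.null(mask)) return(rep(TRUE, width))
  cols <- if (inherits(mask, "sampling_mask")) mask$columns else as.logical(mask)
  if (length(cols) != width) stop("mask width does not match k-space width")
  cols
}

#' Apply a column mask to k-space
#'
#' @param kspace complex matrix `(H, W)` or array `(H, W, C)`.
#' @param mask a [sampling_mask], logical vector over columns, or `NULL` for
#'   fully sampled.
#' @return masked k-space of the same shape (unsampled columns zeroed).
#' @export
apply_mask <- function(kspace, mask) {
  d <- dim(kspace)
  w <- if (length(d) == 2L) d[2] else d[2]
  cols <- .mask_columns(mask, w)
  keep <- rep(0, w); keep[cols] <- 1
  if (length(d) == 2L) return(sweep(kspace, 2, keep, `*`))
  out <- kspace
  for (c in seq_len(d[3])) out[, , c] <- sweep(kspace[, , c], 2, keep, `*`)
  out
}

# ---- SENSE forward / adjoint ----

#' Multicoil SENSE forward and adjoint operators
#'
#' `sense_forward` maps a coil-combined complex image to masked multicoil
#' k-space: `mask * FFT(S_c * m)`. `sense_adjoint` maps masked multicoil
#' k-space back: `sum_c conj(S_c) * IFFT(mask * k_c)`. With the unitary
#' centered FFT the two satisfy the adjoint identity
#' `<A x, y> = <x, A^H y>` exactly.
#'
#' @param image complex matrix `(H, W)`.
#' @param kspace complex array `(H, W, C)`.
#' @param maps a [sens_maps] object or complex array `(H, W, C)`.
#' @param mask a [sampling_mask] or `NULL` for fully sampled.
#' @return `sense_forward`: complex array `(H, W, C)`;
#'   `sense_adjoint`: complex matrix `(H, W)`.
#' @export
sense_forward <- function(image, maps, mask = NULL) {
  apply_mask(image_to_kspace(apply_sensitivities(image, maps)), mask)
}

#' @rdname sense_forward
#' @export
sense_adjoint <- function(kspace, maps, mask = NULL) {
  sense_combine(kspace_to_image(apply_mask(kspace, mask)), maps)
}
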