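# ESPIRiT coil-sensitivity estimation: eigen-analysis of the calibration
# matrix built from the fully sampled central (autocalibration) region of
# multicoil k-space. Direct image-domain eigendecomposition, one map per
# pixel.

#' ESPIRiT configuration
#'
#' @param kernel_size k-space kernel side length in samples.
#' @param calib_width side length of the central autocalibration block.
#' @param sv_threshold singular values below `sv_threshold * sigma_max` are
#'   dropped from the row space of the calibration matrix.
#' @param eig_threshold pixels whose leading eigenvalue falls below this are
#'   treated as outside the coil support and their maps set to 0.
#' @param n_maps number of eigenmaps per pixel (only 1 supported).
#' @return object of class `"espirit_config"`.
#' @export
espirit_config <- function(kernel_size = 6L, calib_width = 24L,
                           sv_threshold = 0.02, eig_threshold = 0.95,
                           n_maps = 1L) {
  if (kernel_size >= calib_width) stop("kernel_size must be < calib_width")
  if (sv_threshold <= 0 || sv_threshold >= 1) stop("sv_threshold must be in (0,1)")
  if (eig_threshold <= 0 || eig_threshold >= 1) stop("eig_threshold must be in (0,1)")
  if (n_maps != 1L) stop("only n_maps = 1 is supported")
  structure(list(kernel_size = as.integer(kernel_size),
                 calib_width = as.integer(calib_width),
                 sv_threshold = sv_threshold, eig_threshold = eig_threshold,
                 n_maps = 1L),
            class = "espirit_config")
}

#' Extract the central autocalibration block
#'
#' @param kspace complex array `(H, W, C)` of fully sampled k-space.
#' @param calib_width side length of the central block.
#' @return complex array `(calib_width, calib_width, C)`.
#' @export
extract_calibration <- function(kspace, calib_width) {
  d <- dim(kspace)
  stopifnot(length(d) == 3L)
  if (calib_width > min(d[1:2]))
    stop("calib_width exceeds the k-space extent")
  r0 <- floor(d[1] / 2) - floor(calib_width / 2) + 1L
  c0 <- floor(d[2] / 2) - floor(calib_width / 2) + 1L
  kspace[r0:(r0 + calib_width - 1L), c0:(c0 + calib_width - 1L), , drop = FALSE]
}

#' Estimate coil sensitivity maps with ESPIRiT
#'
#' Builds the block-Hankel calibration matrix from all
#' `kernel_size x kernel_size` patches of the autocalibration block across
#' coils, takes its SVD and keeps the right-singular vectors whose singular
#' value is at least `sv_threshold * sigma_max`. The retained kernels are
#' transformed to image space, where each pixel carries a small linear
#' operator whose leading eigenvector (eigenvalue close to 1 inside the
#' coil support) is the sensitivity vector at that pixel. Pixels with a
#' leading eigenvalue below `eig_threshold` are zeroed; inside the support
#' the maps are unit-norm across coils by construction and the per-pixel
#' phase is normalized so the first coil's map is real and non-negative.
#'
#' @param kspace complex array `(H, W, C)`, fully sampled at least over the
#'   central calibration block.
#' @param config an [espirit_config].
#' @return a [sens_maps] object; element `eigenvalues` of its attribute
#'   carries the per-pixel leading eigenvalue map.
#' @export
estimate_maps <- function(kspace, config = espirit_config()) {
  stopifnot(inherits(config, "espirit_config"))
  d <- dim(kspace)
  stopifnot(length(d) == 3L)
  H <- d[1]; W <- d[2]; C <- d[3]
  k <- config$kernel_size
  calib <- extract_calibration(kspace, config$calib_width)
  ac <- config$calib_width
  np <- (ac - k + 1L)^2
  # block-Hankel calibration matrix: rows = patches, cols = (k, k, coil)
  A <- matrix(0i, np, k * k * C)
  row <- 1L
  for (cc in 1:(ac - k + 1L)) {
    for (rr in 1:(ac - k + 1L)) {
      patch <- calib[rr:(rr + k - 1L), cc:(cc + k - 1L), , drop = FALSE]
      A[row, ] <- as.vector(patch)
      row <- row + 1L
    }
  }
  sv <- svd(A)
  if (sv$d[1] <= 0 || !is.finite(sv$d[1]))
    stop("degenerate calibration region (zero or non-finite energy)")
  keep <- which(sv$d >= config$sv_threshold * sv$d[1])
  V <- sv$v[, keep, drop = FALSE]            # (k*k*C, n_kern) row-space kernels
  n_kern <- ncol(V)
  # transform kernels to image space: flip, conjugate, zero-pad, centered FFT
  kerimg <- array(0i, dim = c(H, W, C, n_kern))
  r0 <- floor(H / 2) - floor(k / 2) + 1L
  c0 <- floor(W / 2) - floor(k / 2) + 1L
  scale <- sqrt(H * W) / k
  for (j in seq_len(n_kern)) {
    kern <- array(V[, j], dim = c(k, k, C))
    for (cl in seq_len(C)) {
      pad <- matrix(0i, H, W)
      pad[r0:(r0 + k - 1L), c0:(c0 + k - 1L)] <- Conj(kern[k:1, k:1, cl])
      kerimg[, , cl, j] <- .fft2c(pad, inverse = FALSE) * scale
    }
  }
  # per-pixel C x C operator G^H G; leading eigenvector = sensitivity vector
  S <- array(0i, dim = c(H, W, C))
  ev <- matrix(0, H, W)
  for (x in seq_len(W)) {
    Gx <- matrix(kerimg[, x, , ], nrow = H)   # (H, C*n_kern)
    for (y in seq_len(H)) {
      G <- matrix(Gx[y, ], nrow = C, ncol = n_kern)  # coil x kernel
      M <- G %*% Conj(t(G))
      e <- eigen(M, symmetric = TRUE)
      ev[y, x] <- Re(e$values[1])
      if (Re(e$values[1]) >= config$eig_threshold) {
        vvec <- e$vectors[, 1]
        # unit norm already; rotate so first coil is real non-negative
        ph <- Arg(vvec[1])
        S[y, x, ] <- vvec * exp(-1i * ph)
      }
    }
  }
  support <- ev >= config$eig_threshold
  out <- sens_maps(S, support)
  attr(out, "eigenvalues") <- ev
  out
}
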