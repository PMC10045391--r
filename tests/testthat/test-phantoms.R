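test_that("phantom generation is a pure function of spec and seed", {
  sp <- small_spec(seed = 5)
  a <- generate_phantom_sample(sp)
  b <- generate_phantom_sample(sp)
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$phase, b$phase)
  expect_identical(a$maps$values, b$maps$values)
  expect_identical(a$kspace, b$kspace)
  d1 <- generate_dataset(3, sp, seed = 99)
  d2 <- generate_dataset(3, sp, seed = 99)
  for (i in 1:3) expect_identical(d1[[i]]$kspace, d2[[i]]$kspace)
})

test_that("magnitude phantom: support, range, degenerate case", {
  sp <- small_spec(seed = 2)
  mp <- generate_magnitude_phantom(sp)
  expect_gte(min(mp$magnitude), 0)
  expect_lte(max(mp$magnitude), 1)
  expect_true(all(mp$magnitude[mp$tissue_labels == 0] == 0))
  expect_true(all(mp$magnitude[mp$tissue_labels > 0] > 0))
  # no tissue regions: only background and the base skull ellipse remain
  sp0 <- small_spec(seed = 2, n_tissue_regions = 0L)
  mp0 <- generate_magnitude_phantom(sp0)
  expect_setequal(unique(as.vector(mp0$tissue_labels)), c(0L, 1L))
  inside <- mp0$magnitude[mp0$tissue_labels == 1L]
  expect_true(all(inside >= 0.35 * 0.92 & inside <= 0.35 * 1.08))
  expect_error(phantom_spec(height = 16), ">= 32")
})

test_that("phase field: wrap range, zero case, tissue contrast", {
  sp <- small_spec(seed = 3)
  mp <- generate_magnitude_phantom(sp)
  ph <- generate_phase_field(mp$magnitude, mp$tissue_labels, sp)
  expect_true(all(ph >= -pi & ph < pi))
  # all-zero coefficients, offsets and noise give identically zero phase
  sp0 <- small_spec(seed = 3, noise_sigma_background = 0)
  ph0 <- generate_phase_field(mp$magnitude, mp$tissue_labels, sp0,
                              poly_coefficients = rep(0, 6),
                              offsets = rep(0, max(mp$tissue_labels)))
  expect_true(all(ph0 == 0))
  # within-region variance of (phase - polynomial background) is smaller
  # than the variance across two regions offset by 1 rad
  cf <- c(0.2, 0.3, -0.2, 0.1, 0, 0.05)
  offs <- rep(0, max(mp$tissue_labels)); offs[2] <- 1
  ph1 <- generate_phase_field(mp$magnitude, mp$tissue_labels, sp0,
                              poly_coefficients = cf, offsets = offs)
  u <- matrix(2 * (seq_len(sp$height) - 1) / (sp$height - 1) - 1,
              sp$height, sp$width)
  v <- matrix(2 * (seq_len(sp$width) - 1) / (sp$width - 1) - 1,
              sp$height, sp$width, byrow = TRUE)
  bg_poly <- cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v +
    cf[6] * v^2
  resid <- ph1 - bg_poly
  in1 <- mp$tissue_labels == 1; in2 <- mp$tissue_labels == 2
  var_within <- var(resid[in1])
  var_across <- var(resid[in1 | in2])
  expect_lt(var_within, var_across)
  expect_error(generate_phase_field(mp$magnitude[1:10, ], mp$tissue_labels, sp),
               "mismatched")
})

test_that("coil maps are smooth, normalized, and unit for one coil", {
  one <- generate_coil_maps(small_spec(seed = 6, coils = 1))
  expect_lt(max(abs(Mod(one$values[, , 1]) - 1)), 1e-10)
  maps <- generate_coil_maps(phantom_spec(seed = 6))  # 128x128, 8 coils
  rss <- apply(Mod(maps$values)^2, c(1, 2), sum)
  expect_lt(max(abs(rss - 1)), 1e-6)
  fd <- 0
  for (k in seq_len(dim(maps$values)[3])) {
    a <- Mod(maps$values[, , k])
    fd <- max(fd, max(abs(diff(a))), max(abs(t(diff(t(a))))))
  }
  expect_lt(fd, 0.1)
})

test_that("dataset k-space equals step-by-step forward recomputation", {
  ds <- generate_dataset(10, small_spec(seed = 8, size = 48), seed = 31)
  expect_length(generate_dataset(1, small_spec(seed = 8)), 1)
  for (s in ds) {
    k <- image_to_kspace(apply_sensitivities(
      assemble_complex(s$magnitude, s$phase), s$maps))
    expect_identical(k, s$kspace)
  }
})

test_that("inverse FFT + RSS reproduces the magnitude (self-consistency)", {
  s <- generate_phantom_sample(small_spec(seed = 12))
  rec <- coil_combine_rss(kspace_to_image(s$kspace))
  sup <- s$magnitude > 0
  expect_lt(max(abs(rec[sup] - s$magnitude[sup]) / s$magnitude[sup]), 1e-6)
})

test_that("generated phase concentrates energy at low spatial frequency", {
  for (seed in 1:3) {
    s <- generate_phantom_sample(small_spec(seed = seed, size = 64))
    ph <- s$phase
    ph[s$tissue_labels == 0] <- 0  # exclude the noisy background
    E <- Mod(image_to_kspace(ph))^2
    H <- nrow(E); W <- ncol(E)
    r <- sqrt(outer((seq_len(H) - (floor(H / 2) + 1))^2,
                    (seq_len(W) - (floor(W / 2) + 1))^2, `+`))
    cutoff <- quantile(r, 0.10)
    expect_gte(sum(E[r <= cutoff]) / sum(E), 0.90)
  }
})
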