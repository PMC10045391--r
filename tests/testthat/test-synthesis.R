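test_that("baseline phase models have the advertised distributions", {
  expect_true(all(baseline_phase("zero", c(16, 16)) == 0))
  set.seed(51)
  r <- baseline_phase("random", c(128, 128))
  expect_true(all(r >= -pi & r < pi))
  # uniform on [-pi, pi): mean within 3 standard errors of 0
  se <- (2 * pi / sqrt(12)) / sqrt(length(r))
  expect_lt(abs(mean(r)), 3 * se)
  set.seed(52)
  s <- baseline_phase("sinusoidal", c(64, 64), amplitude = pi / 2)
  expect_lte(max(abs(s)), pi / 2)
  expect_error(baseline_phase("warped", c(8, 8)), "unknown")
  expect_error(phase_model("gan"), "trained generator")
})

test_that("k-space synthesis equals the component-wise composition", {
  set.seed(53)
  for (i in 1:10) {
    s <- generate_phantom_sample(small_spec(seed = 530 + i, size = 32))
    mask <- make_equispaced_mask(32, 4, 0.08)
    ph <- baseline_phase("random", c(32, 32))
    got <- synthesize_multicoil_kspace(s$magnitude, ph, s$maps, mask)
    want <- apply_mask(image_to_kspace(apply_sensitivities(
      assemble_complex(s$magnitude, ph), s$maps)), mask)
    expect_identical(got, want)
  }
})

test_that("undersampled synthesis keeps exactly the budgeted columns", {
  s <- generate_phantom_sample(small_spec(seed = 54, size = 64))
  mask <- make_equispaced_mask(64, 4, 0.04)
  k <- synthesize_multicoil_kspace(s$magnitude, s$phase, s$maps, mask)
  nz <- apply(k, 2, function(col) any(col != 0))
  expect_equal(sum(nz), round(64 / 4))
})

test_that("phase synthesis never alters the magnitude", {
  s <- generate_phantom_sample(small_spec(seed = 55, size = 32))
  set.seed(55)
  for (kind in c("zero", "random", "sinusoidal")) {
    ph <- baseline_phase(kind, c(32, 32))
    k <- synthesize_multicoil_kspace(s$magnitude, ph, s$maps, NULL)
    rec <- coil_combine_rss(kspace_to_image(k))
    expect_lt(max(abs(rec - s$magnitude)), 1e-6)
  }
})

test_that("changing only the phase model changes k-space off-center", {
  s <- generate_phantom_sample(small_spec(seed = 56, size = 32))
  set.seed(56)
  k0 <- synthesize_multicoil_kspace(s$magnitude,
                                    baseline_phase("zero", c(32, 32)),
                                    s$maps)
  kr <- synthesize_multicoil_kspace(s$magnitude,
                                    baseline_phase("random", c(32, 32)),
                                    s$maps)
  off_dc <- setdiff(seq_len(32), 17)
  expect_gt(max(Mod(k0[, off_dc, ] - kr[, off_dc, ])), 1e-3)
})

test_that("sensitivity-map pairing strategies", {
  ds <- generate_dataset(3, small_spec(seed = 57, size = 32), seed = 3)
  pool <- lapply(ds, `[[`, "maps")
  same <- pair_sensitivity_maps(ds, pool, "same_volume")
  expect_identical(same[[2]], ds[[2]]$maps)
  one <- pair_sensitivity_maps(ds, pool[1], "random_from_pool", seed = 2)
  expect_identical(one[[1]], pool[[1]])
  expect_identical(one[[3]], pool[[1]])
  a <- pair_sensitivity_maps(ds, pool, "random_from_pool", seed = 5)
  b <- pair_sensitivity_maps(ds, pool, "random_from_pool", seed = 5)
  expect_identical(a, b)
  expect_error(pair_sensitivity_maps(ds, list(), "same_volume"), "non-empty")
  expect_error(pair_sensitivity_maps(ds, pool[1:2], "same_volume"),
               "one map set per item")
})

test_that("same-volume pairing with ESPIRiT pools recovers phantom maps", {
  ds <- generate_dataset(2, small_spec(seed = 58, size = 64, coils = 4),
                         seed = 8)
  pool <- lapply(ds, function(s)
    estimate_maps(s$kspace, espirit_config(calib_width = 16)))
  paired <- pair_sensitivity_maps(ds, pool, "same_volume")
  for (i in 1:2) {
    est <- paired[[i]]; S <- ds[[i]]$maps$values
    sel <- which(est$support & ds[[i]]$tissue_labels > 0)
    dif <- vapply(sel, function(q) {
      yx <- arrayInd(q, dim(est$support))
      ip <- sum(Conj(est$values[yx[1], yx[2], ]) * S[yx[1], yx[2], ])
      mean(Mod(est$values[yx[1], yx[2], ] * exp(1i * Arg(ip)) -
                 S[yx[1], yx[2], ]))
    }, numeric(1))
    expect_lt(mean(dif), 0.05)
  }
})
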