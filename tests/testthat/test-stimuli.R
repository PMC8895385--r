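test_that("gratings honour their specification invariants", {
  # zero contrast: constant mid-grey (all zero)
  expect_true(all(make_grating(grating_spec(37, contrast = 0)) == 0))
  # orientation is taken modulo 180 degrees
  expect_equal(unclass(make_grating(grating_spec(30, 0.7, 1.1))),
               unclass(make_grating(grating_spec(210, 0.7, 1.1))))
  # 90 degrees = vertical stripes: every column is constant
  g <- unclass(make_grating(grating_spec(90, 1)))
  expect_equal(g, matrix(rep(g[1, ], each = nrow(g)), nrow(g)),
               ignore_attr = TRUE)
  # 0 degrees = horizontal stripes: every row is constant
  g0 <- unclass(make_grating(grating_spec(0, 1)))
  expect_equal(g0, matrix(rep(g0[, 1], times = ncol(g0)), nrow(g0)),
               ignore_attr = TRUE)
  # deterministic pure function of the spec
  expect_identical(make_grating(grating_spec(33, 0.4, 2)),
                   make_grating(grating_spec(33, 0.4, 2)))
  # aperture must fit inside the patch
  expect_error(grating_spec(0, aperture = 33, patch_size = 33), "aperture")
  # outside an aperture the patch is mid-grey
  ga <- make_grating(grating_spec(45, 1, aperture = 11))
  expect_equal(ga[1, 1], 0)
  expect_gt(max(abs(ga)), 0.5)
})

test_that("texture generation is bit-identical under a fixed seed", {
  tp <- texture_params()
  set.seed(42)
  a <- make_texture_patch(tp)
  set.seed(42)
  b <- make_texture_patch(tp)
  expect_identical(a, b)
})

test_that("isotropic textures have equal energy across the four orientations", {
  bank <- default_bank()
  tp <- texture_params()
  # systematic (noise-free) check: expected filter energy from the
  # spectral mask directly
  n <- tp$size
  h <- (bank$kernel_size - 1) / 2
  ctr <- (n + 1) / 2
  analytic <- vapply(c(0, 45, 90, 135), function(o) {
    k <- matrix(0, n, n)
    k[ctr + (-h:h), ctr + (-h:h)] <- bank$kernels[[paste0(o, "_even")]]
    sum(Mod(stats::fft(k))^2 * tp$radial^2)
  }, 0)
  expect_lt(max(analytic) / min(analytic), 1.05)
  # Monte-Carlo check on energy shares (the patch-wide mixer cancels)
  set.seed(31)
  shares <- matrix(0, 4000, 4)
  for (i in seq_len(4000)) {
    e <- center_energies(extract_responses(make_texture_patch(tp), bank))
    shares[i, ] <- e / sum(e)
  }
  m <- colMeans(shares)
  expect_lt(max(m) / min(m), 1.1)
})

test_that("the anisotropy knob concentrates energy on its axis", {
  bank <- default_bank()
  tp <- texture_params(anisotropy = 0.8, patch_anisotropy = 0)
  set.seed(17)
  E <- matrix(0, 300, 4)
  for (i in seq_len(300)) {
    E[i, ] <- center_energies(extract_responses(make_texture_patch(tp),
                                                bank))
  }
  expect_equal(which.max(colMeans(E)), 1)  # 0-degree channel greatest
})

test_that("texture filter responses are heavy-tailed", {
  bank <- default_bank()
  tp <- texture_params()
  set.seed(23)
  v <- vapply(seq_len(600), function(i) {
    extract_responses(make_texture_patch(tp), bank)$c[1]
  }, 0)
  kurt <- mean(v^4) / mean(v^2)^2
  expect_gt(kurt, 3.5)  # well above the Gaussian value of 3
})

test_that("mixed dataset sampling is reproducible and respects its spec", {
  spec <- mixed_dataset_spec(n_patches = 60, seed = 99)
  a <- sample_mixed_dataset(spec)
  b <- sample_mixed_dataset(spec)
  expect_length(a, 60)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))

  # degenerate distribution: all gratings at exactly the adaptor
  spec1 <- mixed_dataset_spec(n_patches = 30, grating_fraction = 1,
                              adaptor_orientation_deg = 90,
                              orientation_spread_deg = 0, seed = 5)
  man <- attr(sample_mixed_dataset(spec1), "manifest")
  expect_true(all(man$type == "grating"))
  expect_true(all(man$orientation_deg == 90))

  # no gratings at all
  spec0 <- mixed_dataset_spec(n_patches = 30, grating_fraction = 0,
                              seed = 6)
  man0 <- attr(sample_mixed_dataset(spec0), "manifest")
  expect_true(all(man0$type == "texture"))
})

test_that("grating orientations follow the wrapped Gaussian around the adaptor", {
  spec <- mixed_dataset_spec(n_patches = 12000, grating_fraction = 1,
                             adaptor_orientation_deg = 90,
                             orientation_spread_deg = 5, seed = 8)
  set.seed(spec$seed)
  draws <- v1adapt:::mixed_draws(spec)
  ks <- suppressWarnings(
    stats::ks.test(draws$orientation_deg, "pnorm", mean = 90, sd = 5))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(draws$orientation_deg >= 0 &
                    draws$orientation_deg < 180))
})

test_that("grating contrast and phase draws cover their configured ranges", {
  spec <- mixed_dataset_spec(n_patches = 4000, grating_fraction = 1,
                             contrast_min = 0.2, contrast_max = 1,
                             seed = 9)
  set.seed(spec$seed)
  draws <- v1adapt:::mixed_draws(spec)
  expect_gte(min(draws$contrast), 0.2)
  expect_lte(max(draws$contrast), 1)
  expect_gt(diff(range(draws$phase_rad)), 5)  # spans most of [0, 2 pi)
})
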