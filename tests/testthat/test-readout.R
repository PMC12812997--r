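test_that("visibility is a Euclidean pseudometric under the default read-out", {
  idm <- identity_model()
  cfg <- readout_config("input")
  u <- uniform_opp(50, g_small)
  expect_equal(compute_visibility(idm, u, u, cfg), 0)
  gb <- make_gabor(gabor_params(4, contrast = 0.2, mean_luminance = 50),
                   g_small)
  v <- compute_visibility(idm, gb, u, cfg)
  expect_equal(v, sqrt(sum((gb$A - 50)^2)), tolerance = 1e-12)
  expect_equal(compute_visibility(idm, u, gb, cfg), v)   # symmetric
  # Minkowski exponent changes the summation, not the zero
  cfg4 <- readout_config("input", exponent = 4)
  expect_equal(compute_visibility(idm, gb, u, cfg4),
               sum(abs(gb$A - 50)^4)^(1 / 4), tolerance = 1e-12)
  expect_error(compute_visibility(idm, gb, u, readout_config("nope")),
               "available layers")
})

test_that("linear models are background independent", {
  lc <- linear_control(g_small)
  cfg <- readout_config("filtered")
  tmod <- decalogue:::scale_to_contrast(
    decalogue:::gabor_mod(g_small, 4), 0.2, 50)
  vis <- vapply(1:4, function(i) {
    bg <- uniform_opp(50, g_small)
    bg$A <- bg$A + decalogue:::noise_mod(g_small, 6, seed = i) * 5
    test <- bg; test$A <- test$A + tmod
    compute_visibility(lc, test, bg, cfg)
  }, 0)
  expect_lt(max(abs(vis - vis[1])) / vis[1], 1e-9)
  # superposition holds exactly
  a <- uniform_opp(50, g_small); a$A <- a$A + tmod
  b <- uniform_opp(50, g_small)
  b$A <- b$A + decalogue:::noise_mod(g_small, 6, seed = 2)
  s <- uniform_opp(100, g_small); s$A <- a$A + b$A
  ra <- lc(a)$filtered; rb <- lc(b)$filtered; rs <- lc(s)$filtered
  expect_lt(max(abs(rs - ra - rb)), 1e-9)
})

test_that("orthonormal linear read-out preserves input-space distance", {
  n <- g_small$n
  Q <- with_seed(42, qr.Q(qr(matrix(stats::rnorm(n^2 * n^2), n^2))))
  om <- model_adapter(function(img) list(rot = Q %*% as.vector(img$A)),
                      name = "orthonormal", layers = "rot",
                      input_space = "opponent")
  u <- uniform_opp(50, g_small)
  gb <- make_gabor(gabor_params(4, contrast = 0.2), g_small)
  v <- compute_visibility(om, gb, u, readout_config("rot"))
  expect_equal(v, sqrt(sum((gb$A - u$A)^2)), tolerance = 1e-6)
})

test_that("identity model measures a flat CSF across frequencies", {
  idm <- identity_model()
  b <- csf_battery(frequencies = c(2, 4, 8, 12), n_seeds = 10, seed = 3,
                   geometry = g_small)
  cs <- measure_csf(idm, b, readout_config("input"))
  expect_lt(diff(range(cs$sensitivity)) / mean(cs$sensitivity), 0.02)
  expect_true(all(cs$n_seeds == 10))
})

test_that("a known linear filter's CSF is recovered from noise probes", {
  H <- exp(-decalogue:::geom_freqs(g_small)$fr / 8)
  fm <- model_adapter(function(img)
    list(out = decalogue:::fft_filter(img$A - mean(img$A), H)),
    name = "filter", layers = "out", input_space = "opponent")
  freqs <- c(2, 4, 8)
  b <- csf_battery(frequencies = freqs, n_seeds = 6, seed = 2,
                   geometry = g_small)
  cs <- measure_csf(fm, b, readout_config("out"))
  pred <- exp(-freqs / 8)
  ratio <- cs$sensitivity / pred
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("delta probes return the kernel of a convolutional model", {
  H <- decalogue:::gauss_blur_transfer(g_small, 0.1)
  cm <- model_adapter(function(img) list(out = decalogue:::fft_filter(img$A, H)),
                      name = "conv", layers = "out", input_space = "opponent")
  b <- rf_probe_battery(channels = "A", amplitude = 10, geometry = g_small)
  maps <- measure_receptive_fields(cm, b, readout_config("out"))
  expect_equal(length(maps), 1)
  n <- g_small$n
  ctr <- round((n + 1) / 2)
  delta <- matrix(0, n, n); delta[ctr, ctr] <- 10
  expected <- decalogue:::fft_filter(delta, H)
  expect_equal(matrix(maps[[1]]$map, n, n), expected, tolerance = 1e-9)
  # zero-amplitude probes are excluded as zero-test anchors
  expect_equal(maps[[1]]$channel, "A")
})

test_that("adaptation ratios are unity without adaptors or nonlinearity", {
  lc <- linear_control(g_small)
  b <- adaptation_csf_battery(probe_frequencies = c(2, 4, 8),
                              adaptor_frequencies = c(4), n_seeds = 2,
                              geometry = g_small)
  m <- blakemore_campbell(lc, b, readout_config("filtered"))
  expect_equal(unname(m["none", ]), rep(1, 3))
  expect_lt(max(abs(m["4", ] - 1)), 1e-6)
})
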