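test_that("gabor patches realize nominal contrast over their support", {
  supp <- decalogue:::support_window(g_full, 0.25)
  for (cc in c(0.05, 0.3)) {
    gb <- make_gabor(gabor_params(6, contrast = cc), g_full)
    expect_equal(rmse_contrast(gb, support = supp), cc, tolerance = 1e-6)
  }
  flat <- make_gabor(gabor_params(6, contrast = 0), g_full)
  expect_equal(flat$A, matrix(50, 128, 128))
  expect_error(make_gabor(gabor_params(40, contrast = 0.1), g_full),
               "Nyquist")
  # chromatic Gabor keeps the achromatic plane flat
  gt <- make_gabor(gabor_params(4, contrast = 0.2, channel = "T"), g_full)
  expect_equal(gt$A, matrix(50, 128, 128))
  expect_gt(max(abs(gt$T)), 0)
})

test_that("band-pass noise is seeded, band-limited and centred", {
  p <- noise_params(4, contrast = 0.2, seed = 7)
  n1 <- make_bandpass_noise(p, g_full)
  n2 <- make_bandpass_noise(p, g_full)
  expect_identical(n1$A, n2$A)
  p2 <- p; p2$seed <- 8L
  expect_false(identical(make_bandpass_noise(p2, g_full)$A, n1$A))
  expect_equal(rmse_contrast(n1), 0.2, tolerance = 1e-6)

  mod <- n1$A - mean(n1$A)
  fr <- decalogue:::geom_freqs(g_full)$fr
  pow <- Mod(stats::fft(mod))^2
  outside <- fr < 2 | fr > 8            # one octave either side of 4 cpd
  expect_lt(sum(pow[outside]) / sum(pow), 0.01)
  rs <- radial_spectrum(mod, g_full)
  expect_equal(rs$frequency[which.max(rs$amplitude)], 4)
})

test_that("every battery honours the zero-test and geometry invariants", {
  bats <- decalogue_batteries(seed = 5, profile = "quick")
  for (b in bats) {
    zero <- Filter(function(it) isTRUE(it$condition$is_zero_test), b$items)
    expect_gt(length(zero), 0)
    for (it in zero) {
      expect_identical(it$test$A, it$reference$A)
      expect_identical(it$test$T, it$reference$T)
      expect_identical(it$test$D, it$reference$D)
    }
    for (it in b$items)
      expect_true(decalogue:::same_geometry(it$test$geometry, b$geometry))
    expect_equal(b$geometry$n, 128)
  }
})

test_that("CSF probes share the nominal low contrast and a flat reference", {
  for (ch in c("A", "T")) {
    b <- csf_battery(frequencies = c(2, 4, 8), channel = ch, n_seeds = 2,
                     geometry = g_full)
    probes <- Filter(function(it) !isTRUE(it$condition$is_zero_test), b$items)
    for (it in probes) {
      expect_equal(rmse_contrast(it$test, ch), 0.05, tolerance = 1e-6)
      expect_equal(it$reference[[ch]],
                   matrix(mean(it$test[[ch]]), 128, 128), tolerance = 1e-9)
      if (ch != "A")     # chromatic probes are equiluminant
        expect_equal(it$test$A, it$reference$A)
    }
  }
})

test_that("brightness battery realizes the printed luminance grids", {
  b <- brightness_battery(geometry = g_full)
  conds <- lapply(b$items, `[[`, "condition")
  tests <- vapply(Filter(function(cd) !cd$is_zero_test, conds),
                  `[[`, 0, "test_level")
  bgs <- vapply(conds, `[[`, 0, "adaptor_level")
  expect_equal(range(tests), c(0.5, 120))
  expect_equal(range(bgs), c(1, 160))
  # a test equal to its background is invisible to any model
  bg <- 40
  b2 <- brightness_battery(test_luminances = c(20, 40, 80),
                           background_luminances = bg, geometry = g_full)
  it <- Filter(function(it) it$condition$test_level == 40 &&
                 !it$condition$is_zero_test, b2$items)[[1]]
  expect_equal(it$test$A, it$reference$A)
})

test_that("chromatic battery is equiluminant and spans +/-20 units", {
  b <- chromatic_battery(geometry = g_full)
  tvals <- c()
  for (it in b$items) {
    expect_lt(max(abs(it$test$A - it$reference$A)), 1e-9)
    tvals <- c(tvals, range(it$test$T), range(it$test$D))
  }
  expect_equal(range(tvals), c(-20, 20))
  fams <- unique(vapply(b$items, function(it) it$condition$family, ""))
  expect_setequal(fams, c("T_pos", "T_neg", "D_pos", "D_neg"))
})

test_that("masking batteries embed their no-mask and grid contracts", {
  # zero-mask energy family duplicates the contrast-response stimuli
  cg <- c(0, 0.15, 0.3)
  be <- energy_masking_battery(test_frequencies = 3, mask_contrasts = c(0, 0.2),
                               test_contrasts = cg, geometry = g_full)
  bc <- contrast_response_battery(frequencies = 3, contrast_grid = cg,
                                  geometry = g_full)
  e0 <- Filter(function(it) it$condition$adaptor_level == 0, be$items)
  for (i in seq_along(e0))
    expect_equal(e0[[i]]$test$A, bc$items[[i]]$test$A, tolerance = 1e-12)

  bf <- frequency_masking_battery(geometry = g_full)
  lev3 <- vapply(Filter(function(it) it$condition$family == "A_f3", bf$items),
                 function(it) it$condition$adaptor_level, 0)
  expect_true(Inf %in% lev3)
  expect_false(anyDuplicated(setdiff(unique(lev3), Inf)) > 0)

  bo <- orientation_masking_battery(geometry = g_full)
  oris <- vapply(bo$items, function(it) it$condition$orientation_difference, 0)
  expect_true(all(c(0, 90) %in% oris))

  # fig7 preset calibration: 4 cpd tests in [0,0.3] on masks in [0,0.25]
  b7 <- preset_energy_masking("fig7", geometry = g_full)
  conds <- lapply(b7$items, `[[`, "condition")
  expect_equal(max(vapply(conds, `[[`, 0, "test_level")), 0.3)
  expect_equal(max(vapply(conds, `[[`, 0, "adaptor_level")), 0.25)
  expect_true(all(vapply(conds, `[[`, 0, "test_frequency") == 4))
  expect_equal(mean(b7$items[[1]]$reference$A), 50)
})
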