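cfg_norm <- readout_config("normalized")

test_that("uniform fields silence every post-retinal cascade stage", {
  tc <- toy_cascade(geometry = g_small)
  out <- tc(uniform_opp(70, g_small))
  expect_equal(max(abs(out$contrast)), 0)
  expect_equal(max(abs(out$csf)), 0)
  expect_equal(max(abs(out$normalized)), 0)
  expect_true(all(is.finite(out$opponent)))
})

test_that("cascade outputs stay finite on extreme battery stimuli", {
  tc <- toy_cascade(geometry = g_small)
  loud <- make_bandpass_noise(noise_params(6, contrast = 0.5,
                                           mean_luminance = 150), g_small)
  expect_true(all(vapply(tc(loud), function(x) all(is.finite(x)), TRUE)))
  dark <- uniform_opp(0.5, g_small)
  expect_true(all(vapply(tc(dark), function(x) all(is.finite(x)), TRUE)))
})

test_that("a large pool constant collapses masking families together", {
  b9 <- frequency_masking_battery(test_frequencies = 3,
                                  test_contrasts = c(0, 0.15, 0.3),
                                  geometry = g_full)
  rel_gap <- function(model) {
    m <- family_matrix(run_battery(model, b9, cfg_norm)$families$A_f3)
    max(apply(m, 1, max) - apply(m, 1, min)) / max(m)
  }
  gap_default <- rel_gap(toy_cascade(geometry = g_full))
  gap_large <- rel_gap(
    toy_cascade(intervene_dn_constant(cascade_config(), 1e6), g_full))
  expect_gt(gap_default, 0.05)
  expect_lt(gap_large, 1e-3)
  expect_lt(gap_large, 0.01 * gap_default)
})

test_that("scaling the pool constant only rescales the nonlinearity", {
  cc <- cascade_config()
  expect_identical(intervene_dn_constant(cc, 1), cc)
  b6 <- contrast_response_battery(frequencies = 3,
                                  contrast_grid = seq(0, 0.3, 0.05),
                                  geometry = g_full)
  curve_for <- function(scale) {
    tc <- toy_cascade(intervene_dn_constant(cc, scale), g_full)
    run_battery(tc, b6, cfg_norm)$families$A$curves[[1]]
  }
  v1 <- curve_for(1); v10 <- curve_for(10); v01 <- curve_for(0.1)
  curvature <- function(cv) max(abs(diff(diff(cv$visibility /
                                                max(cv$visibility)))))
  expect_lt(curvature(v10), curvature(v1))   # larger b: shallower, more linear
  half_sat <- function(cv) {
    r <- cv$visibility / max(cv$visibility)
    i <- min(which(r >= 0.5))           # first crossing, linear interpolation
    if (i == 1) return(cv$abscissa[1])
    cv$abscissa[i - 1] + (0.5 - r[i - 1]) / (r[i] - r[i - 1]) *
      (cv$abscissa[i] - cv$abscissa[i - 1])
  }
  expect_lt(half_sat(v01), half_sat(v1))     # smaller b: earlier saturation
})

test_that("cascade reproduces the human curve orderings and CSF shape", {
  tc <- toy_cascade(geometry = g_full)
  tcs <- seq(0, 0.3, length.out = 4)

  r8 <- run_battery(tc, energy_masking_battery(
    test_frequencies = 3, mask_contrasts = c(0, 0.1, 0.2, 0.3),
    test_contrasts = tcs, geometry = g_full), cfg_norm)
  lev <- vapply(r8$families$A_f3$curves, `[[`, 0, "adaptor_level")
  expect_equal(as.numeric(kendall_curve_rank(
    r8$families$A_f3, get_rank_template(8, lev))), 1)

  r10 <- run_battery(tc, orientation_masking_battery(
    test_contrasts = tcs, geometry = g_full), cfg_norm)
  lev <- vapply(r10$families$A$curves, `[[`, 0, "adaptor_level")
  expect_equal(as.numeric(kendall_curve_rank(
    r10$families$A, get_rank_template(10, lev))), 1)
  # visibility at fixed mid contrast: maximal at 90 deg, minimal aligned
  mid <- family_matrix(r10$families$A)[3, ]
  expect_equal(which.max(mid), length(mid))
  expect_equal(which.min(mid), 1L)

  # saturating contrast response: concave beyond the lowest contrasts
  r6 <- run_battery(tc, contrast_response_battery(
    frequencies = 3, contrast_grid = seq(0, 0.3, 0.05), geometry = g_full),
    cfg_norm)
  v <- r6$families$A$curves[[1]]$visibility
  expect_true(all(diff(diff(v)) <= 0))

  # band-pass CSF with an interior maximum
  cs <- measure_csf(tc, csf_battery(frequencies = c(1, 2, 4, 8, 16, 24),
                                    n_seeds = 2, geometry = g_full), cfg_norm)
  k <- which.max(cs$sensitivity)
  expect_gt(k, 1); expect_lt(k, nrow(cs))
})

test_that("frequency adaptation attenuates most at the adaptor frequency", {
  tc <- toy_cascade(geometry = g_full)
  b <- adaptation_csf_battery(probe_frequencies = c(1.5, 3, 6, 12),
                              adaptor_frequencies = c(3, 12), n_seeds = 2,
                              geometry = g_full)
  m <- blakemore_campbell(tc, b, cfg_norm)
  expect_equal(unname(m["none", ]), rep(1, 4))
  # attenuation at the adaptor frequency, strongest right there
  expect_lt(m["3", "3"], 1)
  expect_lt(m["12", "12"], 1)
  expect_equal(colnames(m)[which.min(m["3", ])], "3")
  expect_equal(colnames(m)[which.min(m["12", ])], "12")
})
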