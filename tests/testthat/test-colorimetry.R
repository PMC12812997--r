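test_that("display gamma law maps digital gray to calibrated luminance", {
  g <- stim_geometry(0.25, 16)               # 4 x 4
  d <- display_model(peak_white_luminance = 100, black_level = 0, gamma = 2.2)
  expect_equal(device_to_luminance(array(0, c(4, 4, 3)), d, g)$values,
               matrix(0, 4, 4))
  expect_equal(device_to_luminance(array(1, c(4, 4, 3)), d, g)$values,
               matrix(100, 4, 4), tolerance = 1e-12)
  for (gray in c(0.2, 0.5, 0.8))
    expect_equal(device_to_luminance(array(gray, c(4, 4, 3)), d, g)$values,
                 matrix(100 * gray^2.2, 4, 4), tolerance = 1e-12)
  expect_error(device_to_luminance(array(1.5, c(4, 4, 3)), d, g), "\\[0, 1\\]")
})

test_that("device round-trip is exact to 1e-6 and respects the gamut policy", {
  d <- display_model()
  u <- uniform_opp(50, g_small)
  rgb <- luminance_to_device(u, d)
  back <- device_to_opponent(rgb, d, g_small)
  expect_lt(max(abs(back$A - 50)) / 50, 1e-6)
  expect_equal(attr(rgb, "clipped_fraction"), 0)

  # random in-gamut image: moderate chromatic content on a mid pedestal
  img <- with_seed(11, opponent_image(
    matrix(runif(g_small$n^2, 30, 90), g_small$n),
    matrix(runif(g_small$n^2, -5, 5), g_small$n),
    matrix(runif(g_small$n^2, -5, 5), g_small$n), g_small))
  rt <- device_to_opponent(luminance_to_device(img, d), d, g_small)
  expect_lt(max(abs(rt$A - img$A)) / mean(img$A), 1e-6)
  expect_lt(max(abs(rt$T - img$T)) / mean(img$A), 1e-6)

  expect_equal(attr(luminance_to_device(uniform_opp(160, g_small), d),
                    "clipped_fraction"), 0)  # within the 180 cd/m2 peak
  expect_error(luminance_to_device(uniform_opp(200, g_small), d,
                                   clip_policy = "error"), "gamut")
  expect_warning(luminance_to_device(uniform_opp(200, g_small), d), "clip")
})

test_that("achromatic device input yields vanishing opponent channels", {
  d <- display_model()
  for (gray in c(0.1, 0.5, 0.9)) {
    img <- device_to_opponent(array(gray, c(g_small$n, g_small$n, 3)), d,
                              g_small)
    expect_lt(max(abs(img$T)), 1e-9 * mean(img$A))
    expect_lt(max(abs(img$D)), 1e-9 * mean(img$A))
  }
})

test_that("opponent transform is an invertible linear map with A = luminance", {
  n <- g_small$n
  XYZ <- with_seed(3, lapply(1:3, function(i) matrix(runif(n * n, 0, 80), n)))
  op <- opponent_transform(XYZ[[1]], XYZ[[2]], XYZ[[3]], g_small)
  expect_equal(op$A, XYZ[[2]])                    # A is CIE luminance
  back <- opponent_inverse(op)
  expect_lt(max(abs(back$X - XYZ[[1]])), 1e-9)
  expect_lt(max(abs(back$Z - XYZ[[3]])), 1e-9)
  # linearity: scaling the input scales all three planes
  op2 <- opponent_transform(2 * XYZ[[1]], 2 * XYZ[[2]], 2 * XYZ[[3]], g_small)
  expect_equal(op2$T, 2 * op$T, tolerance = 1e-12)
  # +20 along T survives the round trip
  op$T <- op$T + 20
  xyz2 <- opponent_inverse(op)
  op3 <- opponent_transform(xyz2$X, xyz2$Y, xyz2$Z, g_small)
  expect_lt(max(abs(op3$T - op$T)), 1e-9)
})

test_that("quasi-monochromatic stimuli follow V(lambda) as bandwidth shrinks", {
  cmf <- cie_cmf()
  v <- function(wl) stats::approx(cmf$wavelength, cmf$ybar, wl)$y
  target <- v(510) / v(610)
  err <- vapply(c(5, 2, 1), function(bw) {
    r <- quasi_monochromatic_xyz(510, bw)[["Y"]] /
      quasi_monochromatic_xyz(610, bw)[["Y"]]
    abs(r - target) / target
  }, 0)
  expect_lt(err[1], 0.01)
  expect_lt(err[3], err[1] + 1e-9)     # error shrinks with bandwidth
  # wavelength sweep at fixed radiance is proportional to V(lambda)
  wls <- seq(420, 680, by = 20)
  ys <- vapply(wls, function(w) quasi_monochromatic_xyz(w, 5)[["Y"]], 0)
  expect_gt(stats::cor(ys, v(wls)), 0.999)
  expect_equal(unname(quasi_monochromatic_xyz(550, 5, radiance = 0)),
               c(0, 0, 0))
  expect_error(quasi_monochromatic_xyz(900, 5), "\\[360, 830\\]")
})
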