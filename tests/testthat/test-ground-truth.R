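test_that("achromatic CSF template is band-pass with its peak at 4 cpd", {
  f <- seq(0.5, 32, by = 0.25)
  s <- csf_achromatic(f)
  expect_equal(f[which.max(s)], 4)
  expect_gt(s[f == 32], 0)                       # sensitivity extends to 32
  expect_lt(s[f == 32], 0.02 * max(s))
})

test_that("chromatic CSF templates are low-pass and below the achromatic peak", {
  f <- seq(2, 32, by = 0.5)
  for (ch in c("T", "D")) {
    s <- csf_chromatic(f, ch)
    expect_true(all(diff(s) <= 0))               # non-increasing above 2 cpd
    expect_lt(csf_chromatic(4, ch), csf_achromatic(4))
    expect_lt(csf_chromatic(15, ch) / csf_chromatic(0, ch), 0.05)
  }
})

test_that("packaged spectral curves peak correctly and load deterministically", {
  cmf <- cie_cmf()
  expect_equal(cmf$wavelength[which.max(cmf$ybar)], 555)
  gt1 <- get_ground_truth(1)
  A <- gt1[[1]]
  expect_equal(max(abs(A$values)), 1)            # normalized to unit peak
  expect_equal(A$abscissa[which.max(A$values)], 555)
  # opponent valence curves change sign across the spectrum
  expect_lt(min(gt1[[2]]$values) * max(gt1[[2]]$values), 0)
  expect_lt(min(gt1[[3]]$values) * max(gt1[[3]]$values), 0)
  # checksum-pinned tables
  expect_equal(sum(cmf$ybar), 21.3846138812, tolerance = 1e-9)
  expect_equal(csf_achromatic(2), 0.8243606354, tolerance = 1e-9)
})

test_that("contrast-response templates saturate and scale with the CSF", {
  gt <- get_ground_truth(6, "A", frequencies = c(3, 12),
                         contrasts = seq(0, 0.3, 0.05))
  expect_equal(length(gt), 2)
  for (cv in gt) {
    # saturating beyond the expansive foot, monotone throughout
    upper <- cv$values[cv$abscissa >= 0.1]
    expect_true(all(diff(diff(upper)) <= 1e-12))
    expect_true(all(diff(cv$values) >= 0))
    expect_equal(cv$values[1], 0)
  }
  expect_gt(max(gt[[1]]$values), max(gt[[2]]$values))  # 3 cpd above 12 cpd
  expect_error(get_ground_truth(2), "no packaged")
})

test_that("rank templates are total orders with the human polarity", {
  t8 <- get_rank_template(8, c(0, 0.1, 0.2, 0.3))
  expect_setequal(t8$expected_rank, 1:4)
  expect_equal(t8$expected_rank[1], 1)           # no mask ranked first
  expect_equal(t8$expected_rank[4], 4)           # strongest mask last
  t10 <- get_rank_template(10, c(0, 30, 60, 90))
  expect_equal(t10$expected_rank[t10$adaptor_levels == 90], 1)
  expect_equal(t10$expected_rank[t10$adaptor_levels == 0], 4)
  t9 <- get_rank_template(9, c(0, 0.5, 1, Inf))
  expect_equal(t9$expected_rank[is.infinite(t9$adaptor_levels)], 1)
  t2 <- get_rank_template(2, c(1, 54, 107, 160))
  expect_equal(t2$expected_rank[1], 1)           # dimmest background on top
  t7 <- get_rank_template(7, c(1.5, 3, 6, 12), channel = "A")
  expect_equal(t7$adaptor_levels[t7$expected_rank == 1], 3)  # CSF peak wins
  expect_error(get_rank_template(8, c(0.1, 0.1)))
})

test_that("ground truth survives a CSV round trip", {
  gt <- c(get_ground_truth(3, "A"), get_ground_truth(4, "T"))
  path <- tempfile(fileext = ".csv")
  write_ground_truth_csv(gt, path)
  back <- read_ground_truth_csv(path)
  expect_equal(length(back), 2)
  orig <- gt[[1]]
  got <- back[[orig$curve_id]]
  expect_equal(got$values, orig$values, tolerance = 1e-9)
  expect_equal(got$group_id, orig$group_id)
})
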