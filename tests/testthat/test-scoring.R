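fake_curve <- function(ab, val) list(abscissa = ab, values = val)

test_that("grouped Pearson is scale-invariant globally but not relatively", {
  ab <- seq(0, 1, 0.1)
  truth <- list(
    decalogue:::gt_curve(ab, ab^2, "grp", 6, "A", "c1"),
    decalogue:::gt_curve(ab, 0.3 * ab^2, "grp", 6, "T", "c2"))
  pred_same <- lapply(truth, function(cv) fake_curve(cv$abscissa, cv$values))
  expect_equal(as.numeric(pearson_grouped(pred_same, truth)), 1)
  pred_scaled <- lapply(truth, function(cv)
    fake_curve(cv$abscissa, 7 * cv$values))
  expect_equal(as.numeric(pearson_grouped(pred_scaled, truth)), 1)
  # doubling one curve relative to the other hurts the grouped score
  pred_rel <- pred_same
  pred_rel[[2]]$values <- pred_rel[[2]]$values * 2
  rho <- as.numeric(pearson_grouped(pred_rel, truth))
  expect_lt(rho, 0.999)
  expect_equal(stats::cor(pred_rel[[2]]$values, truth[[2]]$values), 1)
  # zero-variance prediction is reported absent, not zero
  dead <- lapply(truth, function(cv) fake_curve(cv$abscissa, cv$values * 0))
  expect_true(is.na(pearson_grouped(dead, truth)))
  expect_match(attr(pearson_grouped(dead, truth), "reason"), "variance")
  # truth points outside the predicted range are dropped and counted
  short <- lapply(truth, function(cv)
    fake_curve(cv$abscissa[1:8], cv$values[1:8]))
  r <- pearson_grouped(short, truth)
  expect_equal(attr(r, "n_dropped"), 6)
})

test_that("tau-b agrees with the reference implementation on tie-free data", {
  with_seed(9, for (i in 1:25) {
    x <- sample(100, 8); y <- stats::rnorm(8)
    expect_equal(kendall_tau_b(x, y),
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
  })
  # and with ties
  x <- c(1, 2, 2, 3, 4); y <- c(2, 1, 1, 3, 3)
  expect_equal(kendall_tau_b(x, y),
               stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
  expect_equal(kendall_tau_b(1:4, c(2, 4, 6, 9)), 1)
  expect_equal(kendall_tau_b(1:4, c(9, 6, 4, 2)), -1)
  tied <- kendall_tau_b(1:4, rep(5, 4))
  expect_equal(as.numeric(tied), 0)
  expect_true(attr(tied, "degenerate"))
})

test_that("curve-rank score hits +/-1 on ordered families and 0 on nulls", {
  ab <- seq(0, 0.3, length.out = 5)
  mk_family <- function(scales) list(channel = "A", curves = lapply(
    seq_along(scales), function(i) list(abscissa = ab,
                                        visibility = scales[i] * ab,
                                        adaptor_level = c(0, 0.1, 0.2, 0.3)[i])))
  tmpl <- get_rank_template(8, c(0, 0.1, 0.2, 0.3))
  expect_equal(as.numeric(kendall_curve_rank(mk_family(c(4, 3, 2, 1)), tmpl)), 1)
  expect_equal(as.numeric(kendall_curve_rank(mk_family(c(1, 2, 3, 4)), tmpl)), -1)
  expect_error(kendall_curve_rank(mk_family(c(1, 2, 3, 4)),
                                  get_rank_template(8, c(0, 0.05, 0.1, 0.15))),
               "cover")
  # permutation null: mean tau over random orders is close to 0
  taus <- with_seed(123, vapply(seq_len(10000), function(i)
    as.numeric(kendall_tau_b(1:5, sample(5))), 0))
  expect_lt(abs(mean(taus)), 0.05)
})

test_that("aggregate matches the two-point formula and a streaming oracle", {
  one <- aggregate_scores(0.5)
  expect_equal(one$mean, 0.5); expect_equal(one$std, 0)
  a <- aggregate_scores(c(1, 0))
  expect_equal(a$mean, 0.5); expect_equal(a$std, 0.5)
  xs <- with_seed(7, stats::runif(100, -1, 1))
  # streaming (Welford) oracle
  m <- 0; s <- 0
  for (i in seq_along(xs)) {
    d <- xs[i] - m; m <- m + d / i; s <- s + d * (xs[i] - m)
  }
  agg <- aggregate_scores(xs)
  expect_equal(agg$mean, m, tolerance = 1e-12)
  expect_equal(agg$std, sqrt(s / length(xs)), tolerance = 1e-12)
  expect_equal(aggregate_scores(c(0.2, NA, 0.4))$n_excluded, 1)
})

test_that("two-sample KS matches an exhaustive enumeration oracle at n=m=4", {
  a <- c(0.1, 0.25, 0.6, 0.9); b <- c(0.15, 0.4, 0.55, 0.7)
  got <- compare_models_ks(a, b)
  ks_stat <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(vapply(v, function(t) mean(x <= t) - mean(y <= t), 0)))
  }
  expect_equal(got$statistic, ks_stat(a, b), tolerance = 1e-12)
  pool <- c(a, b)
  splits <- utils::combn(8, 4)
  stats_all <- apply(splits, 2, function(ix) ks_stat(pool[ix], pool[-ix]))
  p_exact <- mean(stats_all >= got$statistic - 1e-12)
  expect_equal(got$p_value, p_exact, tolerance = 1e-9)
  expect_equal(compare_models_ks(a, a)$statistic, 0)
  expect_equal(compare_models_ks(1:4 / 10, 5:8 / 10)$statistic, 1)
})

test_that("bootstrap of the aggregate is seeded and CLT-consistent", {
  bz <- bootstrap_aggregate(rep(0.4, 6), n_boot = 200, seed = 1)
  expect_equal(unname(diff(bz$ci)), 0)
  b1 <- bootstrap_aggregate(c(0.1, 0.5, 0.9, 0.3), n_boot = 500, seed = 5)
  b2 <- bootstrap_aggregate(c(0.1, 0.5, 0.9, 0.3), n_boot = 500, seed = 5)
  expect_identical(b1$ci, b2$ci)
  xs <- with_seed(11, stats::rnorm(200))
  bb <- bootstrap_aggregate(xs, n_boot = 10000, seed = 2)
  pop_sd <- sqrt(mean((xs - mean(xs))^2))
  expect_lt(abs(bb$boot_sd - pop_sd / sqrt(200)) / (pop_sd / sqrt(200)), 0.1)
})
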