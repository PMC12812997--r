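# Alignment scoring: grouped Pearson against packaged ground truth,
# Kendall rank correlation of curve orderings against rank templates,
# plain-average aggregation with bootstrap intervals, and two-sample
# Kolmogorov-Smirnov comparison between models.

#' Grouped Pearson correlation against ground truth
#'
#' All curves of a group are concatenated into a single pair of vectors and
#' one Pearson coefficient is computed. The result is insensitive to one
#' global scale but sensitive to wrong relative scales between the curves of
#' the group (e.g. chromatic responses too large relative to achromatic).
#' Predicted curves are resampled onto each truth abscissa by linear
#' interpolation; truth points outside the predicted range are dropped and
#' counted (no extrapolation).
#'
#' @param predicted list of curves, each a list with elements `abscissa` and
#'   `values` (or `visibility`), matched positionally to `truth`.
#' @param truth list of `ground_truth_curve`s (see [get_ground_truth()]).
#' @return Pearson coefficient in \[-1, 1\], with attributes `n_points` and
#'   `n_dropped`; `NA` with attribute `reason` if either concatenated vector
#'   has zero variance.
#' @export
pearson_grouped <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth groups must contain the same number of curves")
  xs <- ys <- numeric(0)
  dropped <- 0L
  for (i in seq_along(truth)) {
    p <- predicted[[i]]
    pv <- if (!is.null(p$values)) p$values else p$visibility
    t_ab <- truth[[i]]$abscissa
    inside <- t_ab >= min(p$abscissa) & t_ab <= max(p$abscissa)
    dropped <- dropped + sum(!inside)
    if (!any(inside)) next
    pi <- stats::approx(p$abscissa, pv, xout = t_ab[inside])$y
    xs <- c(xs, pi)
    ys <- c(ys, truth[[i]]$values[inside])
  }
  if (length(xs) < 3) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 3 comparable points"
    return(out)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero-variance curve"
    attr(out, "n_points") <- length(xs)
    return(out)
  }
  out <- stats::cor(xs, ys)
  attr(out, "n_points") <- length(xs)
  attr(out, "n_dropped") <- dropped
  out
}

#' Kendall tau-b with a tie tolerance
#'
#' Tie-corrected Kendall rank correlation; pairs whose values differ by less
#' than `tol` (relative to the value range) are treated as tied. Returns 0
#' when either vector is fully tied (with attribute `degenerate`).
#'
#' @param x,y numeric vectors of equal length.
#' @param tol tie tolerance relative to the largest magnitude in each
#'   vector (so numerically coincident curves are recognized as tied even
#'   when rounding noise orders them systematically).
#' @return tau-b in \[-1, 1\].
#' @export
kendall_tau_b <- function(x, y, tol = 0) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  sx <- tol * max(abs(x)); sy <- tol * max(abs(y))
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    tiex <- abs(dx) <= sx; tiey <- abs(dy) <= sy
    if (tiex && tiey) next
    else if (tiex) tx <- tx + 1
    else if (tiey) ty <- ty + 1
    else if (sign(dx) == sign(dy)) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((nc + nd + tx) * (nc + nd + ty))
  if (den == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (nc - nd) / den
}

#' Kendall rank score of a curve family against a template
#'
#' At each of `n_eval` abscissa positions (evenly spaced over the shared
#' abscissa range, excluding the lowest 20% where responses are near zero
#' and ranks degenerate), the Kendall tau-b between the template ordering
#' and the ordering of the interpolated curve values is computed; the score
#' is the mean over positions.
#'
#' @param family a family from [run_battery()] (list with `curves`, each
#'   carrying `abscissa`, `visibility`, `adaptor_level`).
#' @param template a [get_rank_template()] whose adaptor levels are covered
#'   by the family.
#' @param n_eval number of evaluation abscissas.
#' @param tie_tol relative tie tolerance on curve values.
#' @return mean tau-b in \[-1, 1\], attribute `per_abscissa`.
#' @export
kendall_curve_rank <- function(family, template, n_eval = 5, tie_tol = 1e-8) {
  curves <- family$curves
  if (length(curves) < 2) stop("need at least 2 curves to rank")
  lev <- vapply(curves, function(cv) cv$adaptor_level, 0)
  ix <- match(template$adaptor_levels, lev)
  if (anyNA(ix)) stop("family does not cover the template's adaptor levels")
  curves <- curves[ix]
  ab <- curves[[1]]$abscissa
  for (cv in curves)
    if (!isTRUE(all.equal(cv$abscissa, ab)))
      stop("curves in a family must share their abscissa")
  qr <- template$eval_quantile_range
  lo <- min(ab) + qr[1] * diff(range(ab))
  hi <- min(ab) + qr[2] * diff(range(ab))
  pos <- seq(lo, hi, length.out = n_eval)
  taus <- vapply(pos, function(a) {
    vals <- vapply(curves, function(cv)
      stats::approx(cv$abscissa, cv$visibility, xout = a)$y, 0)
    kendall_tau_b(-as.numeric(template$expected_rank), vals, tol = tie_tol)
  }, 0)
  out <- mean(taus)
  attr(out, "per_abscissa") <- taus
  out
}

#' Aggregate alignment descriptors
#'
#' Plain arithmetic mean and population standard deviation over the flat
#' descriptor list; `NA` descriptors are excluded and reported.
#'
#' @param scores numeric vector of descriptors in \[-1, 1\].
#' @return list `mean`, `std`, `n`, `n_excluded`.
#' @export
aggregate_scores <- function(scores) {
  keep <- scores[!is.na(scores)]
  m <- mean(keep)
  list(mean = m, std = sqrt(mean((keep - m)^2)), n = length(keep),
       n_excluded = sum(is.na(scores)))
}

#' Two-sample Kolmogorov-Smirnov comparison of two models' descriptors
#'
#' @param scores_a,scores_b numeric descriptor vectors.
#' @return list `statistic` (D), `p_value` (exact where feasible).
#' @export
compare_models_ks <- function(scores_a, scores_b) {
  a <- scores_a[!is.na(scores_a)]; b <- scores_b[!is.na(scores_b)]
  kt <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Bootstrap of the aggregate score
#'
#' Resamples the descriptor list with replacement and returns the percentile
#' confidence interval and dispersion of the aggregate mean under that
#' resampling; exposes how much the global score depends on the (arguable)
#' selection of descriptors.
#'
#' @param scores numeric descriptors.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (results are reproducible).
#' @param conf confidence level.
#' @return list `ci` (length 2), `boot_sd`, `n_boot`, `conf`.
#' @export
bootstrap_aggregate <- function(scores, n_boot = 2000, seed = 1, conf = 0.95) {
  keep <- scores[!is.na(scores)]
  bm <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(sample(keep, length(keep), replace = TRUE)), 0))
  alpha <- (1 - conf) / 2
  list(ci = unname(stats::quantile(bm, c(alpha, 1 - alpha))),
       boot_sd = stats::sd(bm), n_boot = n_boot, conf = conf)
}
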