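# Bundled image-computable reference models.
#
# `identity_model()` returns its input; `linear_control()` is a purely
# linear opponent + fixed-filter model (negative control: no adaptation, no
# masking); `toy_cascade()` is a four-stage linear+nonlinear cascade with
# divisive normalization that qualitatively reproduces the human curve
# shapes and orderings. None of these carries trained weights; the cascade
# is illustrative, tuned only for qualitatively human-like behavior.

stack_planes <- function(img)
  array(c(img$A, img$T, img$D), c(dim(img$A), 3))

#' Identity model
#'
#' Single layer `"input"` returning the stacked opponent planes unchanged.
#' @return a [model_adapter()].
#' @export
identity_model <- function() {
  model_adapter(function(img) list(input = stack_planes(img)),
                name = "identity", layers = "input",
                input_space = "opponent")
}

# Gaussian low-pass transfer in the Fourier domain
gauss_blur_transfer <- function(geometry, sigma_deg) {
  fr <- geom_freqs(geometry)$fr
  exp(-2 * pi^2 * sigma_deg^2 * fr^2)
}

fft_filter <- function(x, H) {
  n <- nrow(x)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / (n * n)
}

#' Linear control model
#'
#' Opponent planes, mean-subtracted and passed through a fixed isotropic
#' low-pass filter. Exactly linear: superposition holds, so it shows no
#' adaptation and no masking of any kind. Layers: `"opponent"` (raw
#' planes), `"filtered"`.
#'
#' @param geometry a [stim_geometry()].
#' @param cutoff filter scale, cycles/degree.
#' @return a [model_adapter()].
#' @export
linear_control <- function(geometry = stim_geometry(), cutoff = 10) {
  fr <- geom_freqs(geometry)$fr
  H <- exp(-fr / cutoff)
  model_adapter(function(img) {
    planes <- stack_planes(img) / 50      # fixed gain, keeps numbers O(1)
    filt <- array(0, dim(planes))
    for (k in 1:3) filt[, , k] <- fft_filter(planes[, , k], H)
    list(opponent = planes, filtered = filt)
  }, name = "linear_control", layers = c("opponent", "filtered"),
  input_space = "opponent")
}

#' Toy cascade configuration
#'
#' Parameters of the four-stage cascade: (1) opponent representation with
#' divisive luminance/chromatic adaptation (response gain divided by a
#' semi-saturation constant plus the background mean), (2) contrast
#' computation (deviation from the local mean, scaled by the global mean
#' luminance response), (3) contrast-sensitivity filtering (band-pass
#' achromatic, low-pass chromatic), (4) even-symmetric Gabor bank with
#' divisive normalization `y_i = sign(x_i) |x_i|^gamma / (b + sum_j H_ij
#' |x_j|^gamma)`, H a separable Gaussian pool over space, log-frequency and
#' orientation.
#'
#' @param adaptation_semi_saturation cd/m2 added to the background mean in
#'   the luminance gain.
#' @param chromatic_semi_saturation tristimulus units for the chromatic
#'   gain.
#' @param contrast_local_sigma degrees; scale of the local mean.
#' @param bank_frequencies,bank_orientations Gabor bank grid (cycles/degree,
#'   degrees).
#' @param bank_sigma_oct,bank_sigma_theta bank filter bandwidths.
#' @param dn_exponent gamma (> 0); 2 is energy pooling.
#' @param dn_constant b (> 0), the pool-weight constant; larger b means a
#'   more linear (less masked) response. Intervention target.
#' @param dn_pool_gain overall gain of the pool kernel H; must be large
#'   enough for the divisive term to dominate the expansive numerator, so
#'   that masks attenuate rather than boost responses.
#' @param pool_space_sigma,pool_freq_sigma,pool_orient_sigma Gaussian pool
#'   widths (degrees, octaves, degrees).
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(adaptation_semi_saturation = 5,
                           chromatic_semi_saturation = 20,
                           contrast_local_sigma = 0.5,
                           bank_frequencies = c(1.5, 3, 6, 12, 24),
                           bank_orientations = seq(0, 150, by = 30),
                           bank_sigma_oct = 0.6, bank_sigma_theta = 20,
                           dn_exponent = 1, dn_constant = 0.05,
                           dn_pool_gain = 1,
                           pool_space_sigma = 0.1, pool_freq_sigma = 0.35,
                           pool_orient_sigma = 12) {
  stopifnot(dn_constant > 0, dn_exponent > 0, all(bank_frequencies > 0))
  structure(list(adaptation_semi_saturation = adaptation_semi_saturation,
                 chromatic_semi_saturation = chromatic_semi_saturation,
                 contrast_local_sigma = contrast_local_sigma,
                 bank_frequencies = bank_frequencies,
                 bank_orientations = bank_orientations,
                 bank_sigma_oct = bank_sigma_oct,
                 bank_sigma_theta = bank_sigma_theta,
                 dn_exponent = dn_exponent, dn_constant = dn_constant,
                 dn_pool_gain = dn_pool_gain,
                 pool_space_sigma = pool_space_sigma,
                 pool_freq_sigma = pool_freq_sigma,
                 pool_orient_sigma = pool_orient_sigma),
            class = "cascade_config")
}

#' Scale the divisive-normalization pool constant
#'
#' Returns a copy of the configuration with `dn_constant` multiplied by
#' `scale_factor` and nothing else changed; increasing b weakens the pool
#' (more linear response), decreasing it sharpens the nonlinearity.
#'
#' @param config a [cascade_config()].
#' @param scale_factor positive multiplier.
#' @return modified [cascade_config()].
#' @export
intervene_dn_constant <- function(config, scale_factor) {
  stopifnot(scale_factor > 0)
  config$dn_constant <- config$dn_constant * scale_factor
  config
}

wrap_angle_180 <- function(d) {
  d <- d %% 180
  pmin(d, 180 - d)
}

#' Toy linear+nonlinear cascade with divisive normalization
#'
#' See [cascade_config()] for the stages. Layers: `"opponent"` (adapted
#' opponent planes), `"brightness"` (saturating luminance/saturation
#' responses, read with sign for adaptation curves), `"contrast"`, `"csf"`,
#' `"normalized"` (Gabor bank after divisive normalization, the default
#' read-out location).
#'
#' @param config a [cascade_config()].
#' @param geometry a [stim_geometry()]; filters are precomputed for it.
#' @return a [model_adapter()].
#' @export
toy_cascade <- function(config = cascade_config(),
                        geometry = stim_geometry()) {
  n <- geometry$n
  fr <- geom_freqs(geometry)
  csfH <- list(A = csf_achromatic(fr$fr),
               T = csf_chromatic(fr$fr, "T"),
               D = csf_chromatic(fr$fr, "D"))
  csfH$A[fr$fr == 0] <- 0
  Hloc <- gauss_blur_transfer(geometry, config$contrast_local_sigma)
  Hpool <- gauss_blur_transfer(geometry, config$pool_space_sigma)
  FF <- config$bank_frequencies
  OO <- config$bank_orientations
  nf <- length(FF); no <- length(OO)
  # one-sided (analytic) filters: 2*Re gives the even-symmetric Gabor
  # response, 2*Mod its quadrature envelope (phase-insensitive energy for
  # the normalization pool)
  bank <- vector("list", nf * no)
  k <- 0
  for (f0 in FF) for (th0 in OO) {
    k <- k + 1
    Hr <- matrix(0, n, n)
    nz <- fr$fr > 0
    Hr[nz] <- exp(-(log2(fr$fr[nz] / f0))^2 / (2 * config$bank_sigma_oct^2))
    spec_th <- th0 + 90                  # stripes at th0 -> energy at th0+90
    d1 <- (fr$theta - spec_th) %% 360
    d1 <- pmin(d1, 360 - d1)             # one lobe only
    Ha <- exp(-d1^2 / (2 * config$bank_sigma_theta^2))
    bank[[k]] <- Hr * Ha
  }
  # separable pool weights over (frequency, orientation), rows sum to 1
  Wf <- outer(FF, FF, function(a, b)
    exp(-(log2(a / b))^2 / (2 * config$pool_freq_sigma^2)))
  Wo <- outer(OO, OO, function(a, b)
    exp(-wrap_angle_180(a - b)^2 / (2 * config$pool_orient_sigma^2)))
  W <- kronecker(Wf, Wo)                  # index order: (f, o) nested, o fast
  W <- config$dn_pool_gain * W / rowSums(W)
  gam <- config$dn_exponent; b <- config$dn_constant

  model_adapter(function(img) {
    Abar <- mean(img$A)
    gA <- 1 / (config$adaptation_semi_saturation + Abar)
    A1 <- img$A * gA
    gT <- gA / (1 + abs(mean(img$T)) / config$chromatic_semi_saturation)
    gD <- gA / (1 + abs(mean(img$D)) / config$chromatic_semi_saturation)
    opp <- array(c(A1, img$T * gT, img$D * gD), c(n, n, 3))
    # saturating brightness/saturation responses: Naka-Rushton with
    # semi-saturation tied to the background (mean luminance / mean
    # chromatic offset); read out with sign for the adaptation curves
    sA <- config$adaptation_semi_saturation + Abar
    sT <- config$chromatic_semi_saturation + abs(mean(img$T))
    sD <- config$chromatic_semi_saturation + abs(mean(img$D))
    bright <- array(c(img$A^2 / (img$A^2 + sA^2),
                      sign(img$T) * img$T^2 / (img$T^2 + sT^2),
                      sign(img$D) * img$D^2 / (img$D^2 + sD^2)),
                    c(n, n, 3))
    m1 <- mean(A1)
    ctr <- array(0, c(n, n, 3))
    for (kk in 1:3)
      ctr[, , kk] <- (opp[, , kk] - fft_filter(opp[, , kk], Hloc)) /
        (m1 + 0.01)
    csf <- array(0, c(n, n, 3))
    Fc <- vector("list", 3)
    for (kk in 1:3) {
      Fc[[kk]] <- stats::fft(ctr[, , kk]) * csfH[[c("A", "T", "D")[kk]]]
      csf[, , kk] <- Re(stats::fft(Fc[[kk]], inverse = TRUE)) / (n * n)
    }
    nb <- nf * no
    norm_out <- array(0, c(n, n, nb * 3))
    for (kk in 1:3) {
      x <- array(0, c(n, n, nb))
      eb <- array(0, c(n, n, nb))
      for (j in seq_len(nb)) {
        z <- stats::fft(Fc[[kk]] * bank[[j]], inverse = TRUE) / (n * n)
        x[, , j] <- 2 * Re(z)
        eb[, , j] <- fft_filter((2 * Mod(z))^gam, Hpool)
      }
      em <- matrix(eb, n * n, nb)
      pool <- em %*% t(W)
      y <- sign(x) * abs(x)^gam /
        (b + array(pool, c(n, n, nb)))
      norm_out[, , (kk - 1) * nb + seq_len(nb)] <- y
    }
    list(opponent = opp, brightness = bright, contrast = ctr, csf = csf,
         normalized = norm_out)
  }, name = "toy_cascade",
  layers = c("opponent", "brightness", "contrast", "csf", "normalized"),
  input_space = "opponent")
}
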