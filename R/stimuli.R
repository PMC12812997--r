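#' RMSE contrast of an image plane
#'
#' `C_RMSE = sd(plane) / mean(luminance)`, with the population standard
#' deviation taken over the full image. For chromatic planes (`T`, `D`) the
#' denominator is the mean of the achromatic plane, so achromatic and
#' chromatic contrasts share a scale.
#'
#' @param image an [opponent_image()] or [luminance_image()].
#' @param channel `"A"`, `"T"` or `"D"`.
#' @param support optional logical matrix restricting the computation to a
#'   window (used for spatially windowed stimuli).
#' @return dimensionless contrast.
#' @export
rmse_contrast <- function(image, channel = "A", support = NULL) {
  img <- as_opponent(image)
  p <- img[[channel]]
  if (!is.null(support)) p <- p[support]
  sdp <- sqrt(mean((p - mean(p))^2))
  sdp / mean(img$A)
}

# zero-mean modulation scaled so sd_pop(mod) = contrast * mean_luminance.
# For spatially windowed stimuli (Gabors, noise patches) the RMSE is taken
# over the support window (pixels where the envelope exceeds exp(-2), i.e.
# within 2 sigma) so that nominal contrast describes the local modulation
# rather than being diluted by the empty surround.
scale_to_contrast <- function(mod, contrast, mean_luminance, support = NULL) {
  mod <- mod - mean(mod)
  if (contrast == 0) return(mod * 0)
  s <- if (is.null(support)) sqrt(mean(mod^2)) else
    sqrt(mean(mod[support]^2) - mean(mod[support])^2)
  if (s == 0) stop("cannot renormalize an identically-zero modulation")
  mod * (contrast * mean_luminance / s)
}

support_window <- function(geometry, envelope_sigma) {
  ax <- geom_axes(geometry)
  exp(-(ax$x^2 + ax$y^2) / (2 * envelope_sigma^2)) >= exp(-2)
}

opp_uniform <- function(mean_luminance, geometry, T_level = 0, D_level = 0) {
  n <- geometry$n
  opponent_image(A = matrix(mean_luminance, n, n),
                 T = matrix(T_level, n, n),
                 D = matrix(D_level, n, n), geometry = geometry)
}

add_mod <- function(img, channel, mod) {
  img[[channel]] <- img[[channel]] + mod
  img
}

#' Gabor patch parameters
#'
#' @param frequency carrier frequency, cycles/degree (below Nyquist).
#' @param orientation stripe orientation, degrees (0 = horizontal stripes).
#' @param phase carrier phase, radians.
#' @param envelope_sigma Gaussian envelope sigma, degrees.
#' @param contrast RMSE contrast (see [rmse_contrast()]).
#' @param mean_luminance pedestal, cd/m2.
#' @param channel opponent channel carrying the modulation.
#' @return list of class `gabor_params`.
#' @export
gabor_params <- function(frequency, orientation = 0, phase = 0,
                         envelope_sigma = 0.25, contrast = 0.1,
                         mean_luminance = 50, channel = "A") {
  stopifnot(frequency > 0, contrast >= 0, envelope_sigma > 0,
            mean_luminance > 0, channel %in% c("A", "T", "D"))
  structure(list(frequency = frequency, orientation = orientation,
                 phase = phase, envelope_sigma = envelope_sigma,
                 contrast = contrast, mean_luminance = mean_luminance,
                 channel = channel), class = "gabor_params")
}

# raw (unscaled) Gabor modulation
gabor_mod <- function(geometry, frequency, orientation = 0, phase = 0,
                      envelope_sigma = 0.25) {
  if (frequency >= geometry$nyquist)
    stop("carrier frequency must be below the Nyquist limit")
  ax <- geom_axes(geometry)
  th <- orientation * pi / 180
  carrier <- cos(2 * pi * frequency * (-ax$x * sin(th) + ax$y * cos(th)) + phase)
  env <- exp(-(ax$x^2 + ax$y^2) / (2 * envelope_sigma^2))
  carrier * env
}

# full-field cosine grating modulation (used as adaptor)
grating_mod <- function(geometry, frequency, orientation = 0, phase = 0) {
  if (frequency >= geometry$nyquist)
    stop("grating frequency must be below the Nyquist limit")
  ax <- geom_axes(geometry)
  th <- orientation * pi / 180
  cos(2 * pi * frequency * (-ax$x * sin(th) + ax$y * cos(th)) + phase)
}

#' Generate a Gabor patch
#'
#' Cosine carrier times a Gaussian envelope on a uniform pedestal,
#' renormalized so the realized RMSE contrast over the envelope support
#' window (within 2 sigma) equals the nominal contrast exactly.
#'
#' @param params a [gabor_params()].
#' @param geometry a [stim_geometry()].
#' @return [opponent_image()] with the modulation in `params$channel`.
#' @export
make_gabor <- function(params, geometry = stim_geometry()) {
  mod <- gabor_mod(geometry, params$frequency, params$orientation,
                   params$phase, params$envelope_sigma)
  mod <- scale_to_contrast(mod, params$contrast, params$mean_luminance,
                           support_window(geometry, params$envelope_sigma))
  add_mod(opp_uniform(params$mean_luminance, geometry), params$channel, mod)
}

#' Band-pass noise parameters
#'
#' @param center_frequency radial centre frequency, cycles/degree.
#' @param frequency_bandwidth full bandwidth at half amplitude, octaves.
#' @param orientation stripe orientation in degrees, or `NULL` for isotropic
#'   noise.
#' @param orientation_bandwidth angular Gaussian sigma, degrees.
#' @param contrast RMSE contrast.
#' @param mean_luminance pedestal, cd/m2.
#' @param channel opponent channel carrying the modulation.
#' @param seed integer; identical seeds give identical realizations.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(center_frequency, frequency_bandwidth = 1,
                         orientation = NULL, orientation_bandwidth = 15,
                         contrast = 0.1, mean_luminance = 50,
                         channel = "A", seed = 1) {
  stopifnot(center_frequency > 0, frequency_bandwidth > 0, contrast >= 0,
            mean_luminance > 0, channel %in% c("A", "T", "D"))
  structure(list(center_frequency = center_frequency,
                 frequency_bandwidth = frequency_bandwidth,
                 orientation = orientation,
                 orientation_bandwidth = orientation_bandwidth,
                 contrast = contrast, mean_luminance = mean_luminance,
                 channel = channel, seed = as.integer(seed)),
            class = "noise_params")
}

# zero-mean band-pass noise modulation with unit-free scale
noise_mod <- function(geometry, center_frequency, frequency_bandwidth = 1,
                      orientation = NULL, orientation_bandwidth = 15,
                      seed = 1, window_sigma = NULL) {
  if (center_frequency >= geometry$nyquist)
    stop("noise band must lie below the Nyquist limit")
  n <- geometry$n
  fr <- geom_freqs(geometry)
  w <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  sig_oct <- frequency_bandwidth / (2 * sqrt(2 * log(2)))
  H <- matrix(0, n, n)
  nz <- fr$fr > 0
  H[nz] <- exp(-(log2(fr$fr[nz] / center_frequency))^2 / (2 * sig_oct^2))
  if (!is.null(orientation)) {
    # stripes at `orientation` put spectral energy at orientation + 90
    d <- (fr$theta - (orientation + 90)) %% 180
    d <- pmin(d, 180 - d)
    H <- H * exp(-d^2 / (2 * orientation_bandwidth^2))
  }
  mod <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (n * n)
  if (!is.null(window_sigma)) {
    ax <- geom_axes(geometry)
    mod <- mod * exp(-(ax$x^2 + ax$y^2) / (2 * window_sigma^2))
  }
  mod - mean(mod)
}

#' Generate band-pass filtered noise
#'
#' White Gaussian noise filtered in the Fourier domain by a log-frequency
#' Gaussian annulus (stated octave bandwidth at half amplitude) and an
#' optional angular Gaussian window, renormalized to the requested RMSE
#' contrast on a uniform pedestal. Deterministic for a fixed seed.
#'
#' @param params a [noise_params()].
#' @param geometry a [stim_geometry()].
#' @param window_sigma optional Gaussian spatial window sigma (degrees) to
#'   confine the noise to a patch.
#' @return [opponent_image()].
#' @export
make_bandpass_noise <- function(params, geometry = stim_geometry(),
                                window_sigma = NULL) {
  mod <- noise_mod(geometry, params$center_frequency,
                   params$frequency_bandwidth, params$orientation,
                   params$orientation_bandwidth, params$seed, window_sigma)
  mod <- scale_to_contrast(mod, params$contrast, params$mean_luminance)
  add_mod(opp_uniform(params$mean_luminance, geometry), params$channel, mod)
}

#' Radially averaged amplitude spectrum
#'
#' Mean FFT amplitude in 1-bin-wide annuli of radial frequency; used to
#' verify the calibration of noise stimuli.
#'
#' @param mod zero-mean modulation matrix.
#' @param geometry a [stim_geometry()].
#' @return data.frame with columns `frequency` (cycles/degree) and
#'   `amplitude`.
#' @export
radial_spectrum <- function(mod, geometry) {
  fr <- geom_freqs(geometry)$fr
  amp <- Mod(stats::fft(mod))
  step <- geometry$spd / geometry$n
  bin <- round(fr / step)
  agg <- tapply(amp, bin, mean)
  data.frame(frequency = as.numeric(names(agg)) * step,
             amplitude = as.numeric(agg))
}

# ---- Battery container ----------------------------------------------------

new_battery <- function(property_id, items, geometry, display = NULL) {
  structure(list(property_id = property_id, items = items,
                 geometry = geometry, display = display),
            class = "stimulus_battery")
}

#' @export
print.stimulus_battery <- function(x, ...) {
  cat(sprintf("<stimulus_battery> property %s: %d items, %dx%d px (%g deg @ %g spd)\n",
              paste(x$property_id, collapse = "/"), length(x$items),
              x$geometry$n, x$geometry$n, x$geometry$fov, x$geometry$spd))
  invisible(x)
}

# `is_zero_test` marks the identical-pair anchor required at every adaptor
# level; `in_grid` says whether that anchor's test level belongs to the
# family's shared abscissa (a zero-contrast item does, a test-equals-
# background item does not and is kept out of the curves).
make_condition <- function(property_id, channel, test_level, adaptor_level,
                           family, test_frequency = NA, mask_frequency = NA,
                           orientation_difference = NA, wavelength = NA,
                           seed = NA, is_zero_test = FALSE,
                           in_grid = !is_zero_test) {
  list(property_id = property_id, channel = channel, test_level = test_level,
       adaptor_level = adaptor_level, family = family,
       test_frequency = test_frequency, mask_frequency = mask_frequency,
       orientation_difference = orientation_difference,
       wavelength = wavelength, seed = seed, is_zero_test = is_zero_test,
       in_grid = in_grid)
}

make_item <- function(test, reference, condition)
  list(test = test, reference = reference, condition = condition)

# ---- Property 1: spectral sensitivity ------------------------------------

#' Quasi-monochromatic spectral battery (property 1)
#'
#' Equal-energy quasi-monochromatic patches on a common dim neutral
#' reference; an ideal achromatic observer read out over this battery
#' recovers V(lambda).
#'
#' @param wavelengths nm grid.
#' @param radiance energy per stimulus (equal across wavelengths).
#' @param bandwidth spectral sigma, nm.
#' @param geometry a [stim_geometry()].
#' @param pedestal_luminance neutral pedestal, cd/m2.
#' @return [new_battery()] object, property 1.
#' @export
spectral_battery <- function(wavelengths = seq(400, 700, by = 15),
                             radiance = 50, bandwidth = 5,
                             geometry = stim_geometry(),
                             pedestal_luminance = 1) {
  ref <- opp_uniform(pedestal_luminance, geometry)
  items <- list(make_item(ref, ref,
    make_condition(1, "A", 0, 0, "spectral", is_zero_test = TRUE)))
  for (wl in wavelengths) {
    img <- quasi_monochromatic_image(wl, bandwidth, radiance, geometry,
                                     pedestal_luminance)
    items[[length(items) + 1]] <- make_item(img, ref,
      make_condition(1, "A", wl, 0, "spectral", wavelength = wl))
  }
  new_battery(1, items, geometry)
}

# ---- Property 2: brightness / chromatic adaptation -----------------------

#' Brightness battery (property 2, achromatic)
#'
#' Central square luminance tests on uniform backgrounds of different
#' luminance. Defaults span tests in \[0.5, 120\] cd/m2 on backgrounds in
#' \[1, 160\] cd/m2, linearly spaced.
#'
#' @param test_luminances cd/m2 grid (shared across backgrounds).
#' @param background_luminances cd/m2 grid.
#' @param geometry a [stim_geometry()].
#' @param patch_fraction test-square side as fraction of the field side.
#' @return [new_battery()] object, property 2.
#' @export
brightness_battery <- function(test_luminances = seq(0.5, 120, length.out = 9),
                               background_luminances = seq(1, 160, length.out = 5),
                               geometry = stim_geometry(),
                               patch_fraction = 1 / 3) {
  stopifnot(all(test_luminances > 0), all(background_luminances > 0),
            !is.unsorted(test_luminances, strictly = TRUE))
  if (patch_fraction >= 1) stop("test patch must be smaller than the field")
  mask <- patch_mask(geometry, patch_fraction)
  items <- list()
  for (bg in background_luminances) {
    ref <- opp_uniform(bg, geometry)
    items[[length(items) + 1]] <- make_item(ref, ref,
      make_condition(2, "A", bg, bg, "A", is_zero_test = TRUE))
    for (t in test_luminances) {
      img <- ref
      img$A <- bg + (t - bg) * mask
      items[[length(items) + 1]] <- make_item(img, ref,
        make_condition(2, "A", t, bg, "A"))
    }
  }
  new_battery(2, items, geometry)
}

#' Chromatic adaptation battery (property 2, chromatic)
#'
#' Equiluminant central patches deviating from neutral along the red-green
#' (`T`) or yellow-blue (`D`) axis, shown on neutral and saturated uniform
#' backgrounds. One curve family per axis and background sign (`T_pos`,
#' `T_neg`, `D_pos`, `D_neg`); within a family the tests run along the
#' family's own direction (`test_level` is the deviation magnitude), so the
#' battery realizes deviations from -20 to +20 tristimulus units across
#' families while each family's adaptor strength |background saturation| is
#' a total order.
#'
#' @param deviation_magnitudes nonnegative grid of deviation magnitudes
#'   along each axis direction (default up to 20 tristimulus units).
#' @param background_saturations nonnegative magnitudes; applied with both
#'   signs along each axis, with 0 the neutral background.
#' @param axes subset of `c("T", "D")`.
#' @param mean_luminance equiluminant level, cd/m2.
#' @param geometry a [stim_geometry()].
#' @param patch_fraction test-square side fraction.
#' @return [new_battery()] object, property 2.
#' @export
chromatic_battery <- function(deviation_magnitudes = seq(0, 20, length.out = 5),
                              background_saturations = c(0, 10, 20),
                              axes = c("T", "D"), mean_luminance = 50,
                              geometry = stim_geometry(),
                              patch_fraction = 1 / 3) {
  stopifnot(!is.unsorted(deviation_magnitudes, strictly = TRUE),
            all(deviation_magnitudes >= 0),
            all(background_saturations >= 0))
  mask <- patch_mask(geometry, patch_fraction)
  items <- list()
  for (ax in axes) for (sgn in c(1, -1)) {
    fam <- paste0(ax, if (sgn > 0) "_pos" else "_neg")
    for (bs in background_saturations) {
      bg_val <- sgn * bs
      ref <- opp_uniform(mean_luminance, geometry)
      ref[[ax]][] <- bg_val
      items[[length(items) + 1]] <- make_item(ref, ref,
        make_condition(2, ax, bs, bs, fam, is_zero_test = TRUE))
      for (dmag in deviation_magnitudes) {
        d <- sgn * dmag
        img <- ref
        img[[ax]] <- bg_val + (d - bg_val) * mask
        items[[length(items) + 1]] <- make_item(img, ref,
          make_condition(2, ax, dmag, bs, fam))
      }
    }
  }
  new_battery(2, items, geometry)
}

# ---- Properties 3-4: contrast sensitivity --------------------------------

#' CSF probe battery (properties 3 and 4)
#'
#' Narrow-band isotropic noise probes of fixed low RMSE contrast (default
#' 0.05), one per spatial frequency, each paired with a flat reference of the
#' same mean colour. Several noise realizations per frequency support
#' seed-averaged sensitivity estimates.
#'
#' @param frequencies cycles/degree grid (below Nyquist).
#' @param channel `"A"` (property 3) or `"T"`/`"D"` (property 4).
#' @param probe_contrast shared RMSE contrast.
#' @param mean_luminance pedestal, cd/m2.
#' @param n_seeds noise realizations per frequency.
#' @param seed base seed.
#' @param geometry a [stim_geometry()].
#' @return [new_battery()] object, property 3 or 4.
#' @export
csf_battery <- function(frequencies = c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24),
                        channel = "A", probe_contrast = 0.05,
                        mean_luminance = 50, n_seeds = 5, seed = 1,
                        geometry = stim_geometry()) {
  if (any(frequencies >= geometry$nyquist))
    stop("probe frequencies must be below the Nyquist limit")
  ref <- opp_uniform(mean_luminance, geometry)
  items <- list(make_item(ref, ref,
    make_condition(if (channel == "A") 3 else 4, channel, 0, 0, channel,
                   is_zero_test = TRUE)))
  prop <- if (channel == "A") 3 else 4
  for (i in seq_along(frequencies)) for (s in seq_len(n_seeds)) {
    sd_i <- seed + 7919L * ((i - 1L) * n_seeds + s)
    mod <- noise_mod(geometry, frequencies[i], seed = sd_i)
    mod <- scale_to_contrast(mod, probe_contrast, mean_luminance)
    img <- add_mod(ref, channel, mod)
    items[[length(items) + 1]] <- make_item(img, ref,
      make_condition(prop, channel, probe_contrast, 0, channel,
                     test_frequency = frequencies[i], seed = sd_i))
  }
  new_battery(prop, items, geometry)
}

# ---- Property 5: receptive fields ----------------------------------------

#' Delta-probe receptive-field battery (property 5, physiological route)
#'
#' Single-pixel increments in each opponent channel on a neutral pedestal.
#'
#' @param channels subset of `c("A","T","D")`.
#' @param positions list of `c(x, y)` offsets in degrees from centre.
#' @param amplitude increment amplitude (cd/m2 or tristimulus units).
#' @param mean_luminance pedestal, cd/m2.
#' @param geometry a [stim_geometry()].
#' @return [new_battery()] object, property 5.
#' @export
rf_probe_battery <- function(channels = c("A", "T", "D"),
                             positions = list(c(0, 0)), amplitude = 10,
                             mean_luminance = 50,
                             geometry = stim_geometry()) {
  ref <- opp_uniform(mean_luminance, geometry)
  items <- list(make_item(ref, ref,
    make_condition(5, "A", 0, 0, "delta_A", is_zero_test = TRUE)))
  n <- geometry$n
  for (ch in channels) for (p in positions) {
    i <- round((n + 1) / 2 + p[2] * geometry$spd)
    j <- round((n + 1) / 2 + p[1] * geometry$spd)
    if (i < 1 || i > n || j < 1 || j > n) stop("delta position outside field")
    img <- ref
    img[[ch]][i, j] <- img[[ch]][i, j] + amplitude
    items[[length(items) + 1]] <- make_item(img, ref,
      make_condition(5, ch, amplitude, 0, paste0("delta_", ch)))
  }
  new_battery(5, items, geometry)
}

#' Adaptation CSF battery (property 5, psychophysical route)
#'
#' CSF noise probes superimposed on full-field grating adaptors of several
#' frequencies (plus a no-adaptor condition), for frequency-adaptation
#' experiments in the Blakemore-Campbell style: the adapted/unadapted CSF
#' ratio localizes the band of the underlying sensors.
#'
#' @param probe_frequencies cycles/degree grid.
#' @param adaptor_frequencies cycles/degree; `0` rows are added automatically
#'   for the no-adaptor condition.
#' @param adaptor_contrast RMSE contrast of the grating adaptor.
#' @param probe_contrast RMSE contrast of the probes.
#' @param mean_luminance pedestal, cd/m2.
#' @param n_seeds noise realizations per cell.
#' @param seed base seed.
#' @param geometry a [stim_geometry()].
#' @return [new_battery()] object, property 5.
#' @export
adaptation_csf_battery <- function(probe_frequencies = c(1.5, 3, 6, 12, 24),
                                   adaptor_frequencies = c(3, 6, 12),
                                   adaptor_contrast = 0.5,
                                   probe_contrast = 0.05,
                                   mean_luminance = 50, n_seeds = 3,
                                   seed = 1, geometry = stim_geometry()) {
  items <- list()
  adaptors <- c(0, adaptor_frequencies)
  for (ai in seq_along(adaptors)) {
    af <- adaptors[ai]
    base <- opp_uniform(mean_luminance, geometry)
    if (af > 0) {
      am <- scale_to_contrast(grating_mod(geometry, af), adaptor_contrast,
                              mean_luminance)
      base <- add_mod(base, "A", am)
    }
    items[[length(items) + 1]] <- make_item(base, base,
      make_condition(5, "A", 0, af, "A", mask_frequency = af,
                     is_zero_test = TRUE))
    # probe seeds shared across adaptor rows: the same probe realizations
    # are measured with and without adaptation, so CSF ratios are exact
    for (i in seq_along(probe_frequencies)) for (s in seq_len(n_seeds)) {
      sd_i <- seed + 7919L * ((i - 1L) * n_seeds + s)
      mod <- noise_mod(geometry, probe_frequencies[i], seed = sd_i)
      mod <- scale_to_contrast(mod, probe_contrast, mean_luminance)
      items[[length(items) + 1]] <- make_item(add_mod(base, "A", mod), base,
        make_condition(5, "A", probe_contrast, af, "A",
                       test_frequency = probe_frequencies[i],
                       mask_frequency = af, seed = sd_i))
    }
  }
  new_battery(5, items, geometry)
}

# ---- Properties 6-7: contrast response in isolation ----------------------

#' Contrast-response battery (properties 6 and 7)
#'
#' Gabor tests seen in isolation against a uniform reference of the same
#' mean colour; one curve per frequency, contrasts in \[0, 0.3\].
#'
#' @param frequencies cycles/degree; one response curve per frequency.
#' @param channel opponent channel of the tests.
#' @param contrast_grid RMSE contrast grid including 0.
#' @param mean_luminance pedestal, cd/m2.
#' @param geometry a [stim_geometry()].
#' @param orientation Gabor stripe orientation, degrees.
#' @return [new_battery()] object, property 6 (achromatic) or 7 (chromatic).
#' @export
contrast_response_battery <- function(frequencies = c(1.5, 3, 6, 12, 24),
                                      channel = "A",
                                      contrast_grid = seq(0, 0.3, length.out = 7),
                                      mean_luminance = 50,
                                      geometry = stim_geometry(),
                                      orientation = 0) {
  stopifnot(!is.unsorted(contrast_grid, strictly = TRUE))
  prop <- if (channel == "A") 6 else 7
  ref <- opp_uniform(mean_luminance, geometry)
  items <- list()
  supp <- support_window(geometry, 0.25)
  for (f in frequencies) {
    for (cc in contrast_grid) {
      img <- if (cc == 0) ref else {
        mod <- scale_to_contrast(
          gabor_mod(geometry, f, orientation), cc, mean_luminance, supp)
        add_mod(ref, channel, mod)
      }
      items[[length(items) + 1]] <- make_item(img, ref,
        make_condition(prop, channel, cc, f, channel, test_frequency = f,
                       is_zero_test = (cc == 0), in_grid = TRUE))
    }
  }
  new_battery(prop, items, geometry)
}

# ---- Properties 8-10: masking --------------------------------------------

#' Energy (same-channel) masking battery (property 8)
#'
#' Tests on band-pass noise masks of the same frequency and orientation,
#' with mask RMSE contrast as the adaptor level. Test and mask modulations
#' add on the shared pedestal; the composite is not renormalized so the mask
#' statistics are unchanged by the test.
#'
#' @param test_frequencies cycles/degree; one curve family per frequency.
#' @param mask_contrasts mask RMSE contrast grid including 0 (no mask).
#' @param test_contrasts test RMSE contrast grid including 0.
#' @param mean_luminance pedestal, cd/m2.
#' @param test_type `"gabor"` for Gabor tests or `"noise"` for
#'   Gaussian-windowed noise-patch tests.
#' @param geometry a [stim_geometry()].
#' @param seed base seed for the noise realizations.
#' @param n_mask_seeds mask realizations per condition; the same realization
#'   set is reused (contrast-scaled) across adaptor levels, so seed
#'   averaging reduces realization noise without confounding the curve
#'   ordering.
#' @return [new_battery()] object, property 8.
#' @export
energy_masking_battery <- function(test_frequencies = c(3, 12),
                                   mask_contrasts = seq(0, 0.3, length.out = 5),
                                   test_contrasts = seq(0, 0.3, length.out = 5),
                                   mean_luminance = 50,
                                   test_type = c("gabor", "noise"),
                                   geometry = stim_geometry(), seed = 1,
                                   n_mask_seeds = 3) {
  test_type <- match.arg(test_type)
  stopifnot(!is.unsorted(test_contrasts, strictly = TRUE),
            !is.unsorted(mask_contrasts, strictly = TRUE), n_mask_seeds >= 1)
  supp <- support_window(geometry, 0.25)
  items <- list()
  for (fi in seq_along(test_frequencies)) {
    tf <- test_frequencies[fi]
    fam <- paste0("A_f", tf)
    tmod_raw <- if (test_type == "gabor")
      gabor_mod(geometry, tf, 0)
    else noise_mod(geometry, tf, seed = seed + 31L * fi, window_sigma = 0.25)
    morient <- if (test_type == "gabor") 0 else NULL
    for (k in seq_len(n_mask_seeds)) {
      sd_k <- seed + 1009L * fi + 131L * k
      mm <- noise_mod(geometry, tf, orientation = morient, seed = sd_k)
      for (mi in seq_along(mask_contrasts)) {
        mc <- mask_contrasts[mi]
        if (mc == 0 && k > 1) next      # the no-mask condition has no seed
        base <- opp_uniform(mean_luminance, geometry)
        if (mc > 0)
          base <- add_mod(base, "A", scale_to_contrast(mm, mc, mean_luminance))
        for (tc in test_contrasts) {
          img <- if (tc == 0) base else
            add_mod(base, "A",
                    scale_to_contrast(tmod_raw, tc, mean_luminance, supp))
          items[[length(items) + 1]] <- make_item(img, base,
            make_condition(8, "A", tc, mc, fam, test_frequency = tf,
                           seed = if (mc > 0) sd_k else NA,
                           is_zero_test = (tc == 0), in_grid = TRUE))
        }
      }
    }
  }
  new_battery(8, items, geometry)
}

#' Frequency cross-masking battery (property 9)
#'
#' Gabor tests on noise masks that differ from the test in frequency only
#' (fixed mask contrast, default 0.2). The adaptor level is
#' `|log2(mask_f / test_f)|`, with `Inf` coding the no-mask condition; mask
#' frequency sets are one-sided per test so the adaptor levels are distinct.
#'
#' @param test_frequencies cycles/degree.
#' @param mask_frequencies named list (one entry per test frequency) of mask
#'   frequencies, or `NULL` for one-sided octave defaults.
#' @param mask_contrast mask RMSE contrast.
#' @param test_contrasts test RMSE contrast grid including 0.
#' @param mean_luminance pedestal, cd/m2.
#' @param geometry a [stim_geometry()].
#' @param seed base seed.
#' @param n_mask_seeds mask realizations per condition, averaged by the
#'   read-out; the seed set is shared across mask frequencies.
#' @return [new_battery()] object, property 9.
#' @export
frequency_masking_battery <- function(test_frequencies = c(3, 12),
                                      mask_frequencies = NULL,
                                      mask_contrast = 0.2,
                                      test_contrasts = seq(0, 0.3, length.out = 5),
                                      mean_luminance = 50,
                                      geometry = stim_geometry(), seed = 1,
                                      n_mask_seeds = 3) {
  stopifnot(!is.unsorted(test_contrasts, strictly = TRUE), n_mask_seeds >= 1)
  if (is.null(mask_frequencies)) {
    # one-sided sets toward higher frequencies with distinct |log2|
    # distances: lower-frequency masks carry a contrast-sensitivity
    # amplitude advantage that competes with channel proximity and muddles
    # the expected ordering; octave steps where the Nyquist limit allows,
    # half-octave steps otherwise
    mask_frequencies <- lapply(test_frequencies, function(tf) {
      mf <- tf * 2^(0:3)
      if (max(mf) >= geometry$nyquist) mf <- tf * 2^seq(0, 1, by = 0.5)
      mf <- mf[mf < geometry$nyquist]
      mf
    })
    names(mask_frequencies) <- as.character(test_frequencies)
  }
  supp <- support_window(geometry, 0.25)
  items <- list()
  for (fi in seq_along(test_frequencies)) {
    tf <- test_frequencies[fi]
    fam <- paste0("A_f", tf)
    tmod_raw <- gabor_mod(geometry, tf, 0)
    mfs <- mask_frequencies[[as.character(tf)]]
    for (mi in seq_along(c(NA, mfs))) {
      mf <- c(NA, mfs)[mi]
      lvl <- if (is.na(mf)) Inf else abs(log2(mf / tf))
      for (k in seq_len(if (is.na(mf)) 1L else n_mask_seeds)) {
        sd_k <- seed + 1013L * fi + 131L * k
        base <- opp_uniform(mean_luminance, geometry)
        if (!is.na(mf)) {
          # white-noise seed shared across mask frequencies: paired masks
          # differ in their pass band only
          mm <- noise_mod(geometry, mf, seed = sd_k)
          base <- add_mod(base, "A", scale_to_contrast(mm, mask_contrast,
                                                       mean_luminance))
        }
        for (tc in test_contrasts) {
          img <- if (tc == 0) base else
            add_mod(base, "A",
                    scale_to_contrast(tmod_raw, tc, mean_luminance, supp))
          items[[length(items) + 1]] <- make_item(img, base,
            make_condition(9, "A", tc, lvl, fam, test_frequency = tf,
                           mask_frequency = mf,
                           seed = if (is.na(mf)) NA else sd_k,
                           is_zero_test = (tc == 0), in_grid = TRUE))
        }
      }
    }
  }
  new_battery(9, items, geometry)
}

#' Orientation cross-masking battery (property 10)
#'
#' Horizontal Gabor tests (default 6 cpd at 50 cd/m2) on oriented band-pass
#' noise masks of the same frequency (contrast 0.2) whose orientation differs
#' from the test by the stated angle; 0 (aligned) and 90 (orthogonal) degrees
#' are always present.
#'
#' @param test_frequency cycles/degree.
#' @param orientation_differences degrees grid, containing 0 and 90.
#' @param mask_contrast mask RMSE contrast.
#' @param test_contrasts test RMSE contrast grid including 0.
#' @param mean_luminance pedestal, cd/m2.
#' @param geometry a [stim_geometry()].
#' @param seed base seed.
#' @param n_mask_seeds mask realizations per condition, averaged by the
#'   read-out; the seed set is shared across orientations.
#' @return [new_battery()] object, property 10.
#' @export
orientation_masking_battery <- function(test_frequency = 6,
                                        orientation_differences = c(0, 30, 60, 90),
                                        mask_contrast = 0.2,
                                        test_contrasts = seq(0, 0.3, length.out = 5),
                                        mean_luminance = 50,
                                        geometry = stim_geometry(), seed = 1,
                                        n_mask_seeds = 3) {
  stopifnot(all(c(0, 90) %in% orientation_differences),
            !is.unsorted(test_contrasts, strictly = TRUE), n_mask_seeds >= 1)
  tmod_raw <- gabor_mod(geometry, test_frequency, 0)
  supp <- support_window(geometry, 0.25)
  items <- list()
  for (oi in seq_along(orientation_differences)) for (k in seq_len(n_mask_seeds)) {
    dth <- orientation_differences[oi]
    sd_k <- seed + 1019L + 131L * k
    base <- opp_uniform(mean_luminance, geometry)
    # white-noise seed shared across orientations: paired masks differ in
    # their orientation band only
    mm <- noise_mod(geometry, test_frequency, orientation = dth, seed = sd_k)
    base <- add_mod(base, "A", scale_to_contrast(mm, mask_contrast,
                                                 mean_luminance))
    for (tc in test_contrasts) {
      img <- if (tc == 0) base else
        add_mod(base, "A", scale_to_contrast(tmod_raw, tc, mean_luminance, supp))
      items[[length(items) + 1]] <- make_item(img, base,
        make_condition(10, "A", tc, dth, "A",
                       test_frequency = test_frequency,
                       orientation_difference = dth, seed = sd_k,
                       is_zero_test = (tc == 0), in_grid = TRUE))
    }
  }
  new_battery(10, items, geometry)
}

# ---- Presets --------------------------------------------------------------

#' Battery presets for the ten properties
#'
#' Assembles the full set of batteries at the packaged study conditions.
#' `profile = "quick"` uses thinner grids and fewer noise seeds for fast
#' model evaluation; `"full"` uses the figure-level grids.
#'
#' @param seed integer base seed for all noise stimuli.
#' @param geometry a [stim_geometry()].
#' @param profile `"quick"` or `"full"`.
#' @return named list of batteries, one or more per property.
#' @export
decalogue_batteries <- function(seed = 1, geometry = stim_geometry(),
                                profile = c("quick", "full")) {
  profile <- match.arg(profile)
  q <- profile == "quick"
  list(
    p1_spectral = spectral_battery(
      wavelengths = if (q) seq(410, 690, by = 25) else seq(400, 700, by = 10),
      geometry = geometry),
    p2_brightness = brightness_battery(
      test_luminances = seq(0.5, 120, length.out = if (q) 6 else 9),
      background_luminances = seq(1, 160, length.out = if (q) 4 else 5),
      geometry = geometry),
    p2_chromatic = chromatic_battery(
      deviation_magnitudes = seq(0, 20, length.out = if (q) 5 else 9),
      geometry = geometry),
    p3_csf_A = csf_battery(
      frequencies = if (q) c(1, 2, 4, 6, 8, 12, 16, 24) else
        c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24),
      channel = "A", n_seeds = if (q) 2 else 5, seed = seed,
      geometry = geometry),
    p4_csf_T = csf_battery(
      frequencies = if (q) c(1, 2, 4, 6, 8, 12) else
        c(0.5, 1, 2, 3, 4, 6, 8, 12, 16),
      channel = "T", n_seeds = if (q) 2 else 5, seed = seed + 1,
      geometry = geometry),
    p4_csf_D = csf_battery(
      frequencies = if (q) c(1, 2, 4, 6, 8, 12) else
        c(0.5, 1, 2, 3, 4, 6, 8, 12, 16),
      channel = "D", n_seeds = if (q) 2 else 5, seed = seed + 2,
      geometry = geometry),
    p5_rf = rf_probe_battery(geometry = geometry),
    p5_adaptation = adaptation_csf_battery(
      probe_frequencies = if (q) c(1.5, 3, 6, 12) else c(1.5, 3, 6, 12, 24),
      adaptor_frequencies = if (q) c(3, 12) else c(3, 6, 12),
      n_seeds = if (q) 2 else 3, seed = seed + 3, geometry = geometry),
    p6_contrast_A = contrast_response_battery(
      frequencies = if (q) c(1.5, 3, 6, 12) else c(1.5, 3, 6, 12, 24),
      channel = "A",
      contrast_grid = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry),
    p7_contrast_T = contrast_response_battery(
      frequencies = if (q) c(1, 4) else c(1, 2, 4, 8), channel = "T",
      contrast_grid = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry),
    p7_contrast_D = contrast_response_battery(
      frequencies = if (q) c(1, 4) else c(1, 2, 4, 8), channel = "D",
      contrast_grid = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry),
    p8_energy = energy_masking_battery(
      test_frequencies = c(3, 12),
      mask_contrasts = seq(0, 0.3, length.out = if (q) 4 else 6),
      test_contrasts = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry, seed = seed + 4),
    p9_frequency = frequency_masking_battery(
      test_contrasts = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry, seed = seed + 5),
    p10_orientation = orientation_masking_battery(
      test_contrasts = seq(0, 0.3, length.out = if (q) 5 else 7),
      geometry = geometry, seed = seed + 6)
  )
}

#' Figure-style masking presets
#'
#' `preset_energy_masking("fig7")` reproduces the demonstration conditions of
#' the energy-masking figure: Gaussian-windowed 4 cpd test noise patches at
#' 50 cd/m2 with test contrasts in \[0, 0.3\] on same-frequency noise masks
#' with contrasts in \[0, 0.25\]. `"fig12"` uses 3 and 12 cpd Gabor tests on
#' masks with contrasts in \[0, 0.3\].
#'
#' @param preset `"fig7"` or `"fig12"`.
#' @param geometry a [stim_geometry()].
#' @param seed base seed.
#' @return [new_battery()] object, property 8.
#' @export
preset_energy_masking <- function(preset = c("fig7", "fig12"),
                                  geometry = stim_geometry(), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "fig7")
    energy_masking_battery(test_frequencies = 4,
                           mask_contrasts = seq(0, 0.25, length.out = 6),
                           test_contrasts = seq(0, 0.3, length.out = 7),
                           mean_luminance = 50, test_type = "noise",
                           geometry = geometry, seed = seed)
  else
    energy_masking_battery(test_frequencies = c(3, 12),
                           mask_contrasts = seq(0, 0.3, length.out = 6),
                           test_contrasts = seq(0, 0.3, length.out = 7),
                           mean_luminance = 50, test_type = "gabor",
                           geometry = geometry, seed = seed)
}
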