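#' Wrap an image-computable model as an adapter
#'
#' The adapter contract: a deterministic function mapping a calibrated
#' [opponent_image()] (or device-RGB array, depending on `input_space`) to an
#' ordered named list of numeric activation arrays, one per layer, with layer
#' names stable across calls. Models declaring `input_space = "rgb"` receive
#' stimuli rendered through [luminance_to_device()] with the battery's
#' display model.
#'
#' @param fun function(image) -> named list of numeric arrays.
#' @param name model name used in reports.
#' @param layers character vector of layer names `fun` returns.
#' @param input_space `"opponent"` or `"rgb"`.
#' @return function of class `model_adapter`.
#' @export
model_adapter <- function(fun, name, layers, input_space = c("opponent", "rgb")) {
  input_space <- match.arg(input_space)
  stopifnot(is.function(fun), length(layers) >= 1)
  structure(fun, class = c("model_adapter", "function"), name = name,
            layers = layers, input_space = input_space)
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter> %s (%s input): layers %s\n", attr(x, "name"),
              attr(x, "input_space"),
              paste(attr(x, "layers"), collapse = ", ")))
  invisible(x)
}

#' Read-out configuration
#'
#' @param layer layer name to read from (must exist in the adapter).
#' @param exponent Minkowski summation exponent p > 0; `2` is the Euclidean
#'   read-out.
#' @param spatial_window optional logical/0-1 matrix restricting the norm to
#'   a region (applied where the layer output has image shape).
#' @param mode `"norm"` (default: Minkowski distance between activations) or
#'   `"mean"` (signed mean activation difference; used for spectral
#'   sensitivities).
#' @return list of class `readout_config`.
#' @export
readout_config <- function(layer, exponent = 2, spatial_window = NULL,
                           mode = c("norm", "mean")) {
  stopifnot(exponent > 0)
  mode <- match.arg(mode)
  structure(list(layer = layer, exponent = exponent,
                 spatial_window = spatial_window, mode = mode),
            class = "readout_config")
}

model_activations <- function(model, image, battery = NULL) {
  if (attr(model, "input_space") == "rgb") {
    display <- if (!is.null(battery) && !is.null(battery$display))
      battery$display else display_model()
    image <- suppressWarnings(luminance_to_device(image, display))
  }
  model(image)
}

get_layer <- function(acts, layer) {
  if (!layer %in% names(acts))
    stop(sprintf("layer '%s' not found; available layers: %s", layer,
                 paste(names(acts), collapse = ", ")))
  acts[[layer]]
}

#' Visibility of a test on a background
#'
#' The Minkowski-p norm of the difference between the model's activations to
#' test-plus-background and to the background alone, at the configured layer.
#' With `p = 2` this is the Euclidean departure read-out; with
#' `mode = "mean"` it is the signed mean response difference instead.
#'
#' @param model a [model_adapter()].
#' @param test_plus_background,background_alone [opponent_image()]s sharing
#'   geometry.
#' @param config a [readout_config()].
#' @param battery optional battery providing the display model for RGB-input
#'   adapters.
#' @return nonnegative scalar (signed for `mode = "mean"`).
#' @export
compute_visibility <- function(model, test_plus_background, background_alone,
                               config, battery = NULL) {
  if (!same_geometry(test_plus_background$geometry, background_alone$geometry))
    stop("test and background images must share geometry")
  a1 <- get_layer(model_activations(model, test_plus_background, battery),
                  config$layer)
  a0 <- get_layer(model_activations(model, background_alone, battery),
                  config$layer)
  visibility_from_acts(a1, a0, config)
}

visibility_from_acts <- function(a1, a0, config) {
  if (!all(dim1(a1) == dim1(a0)))
    stop("activation shapes differ between test and background")
  d <- a1 - a0
  if (!is.null(config$spatial_window)) {
    w <- config$spatial_window
    if (length(dim(d)) >= 2 && all(dim(d)[1:2] == dim(w))) {
      d <- array(d, c(dim(w), length(d) / length(w)))
      d <- d * as.vector(w)
    }
  }
  if (config$mode == "mean") return(mean(d))
  p <- config$exponent
  sum(abs(d)^p)^(1 / p)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Activation cache keyed on reference-object identity: batteries reuse the
# same reference object across the items of a family.
acts_cached <- function(model, image, battery, cache) {
  for (e in cache$entries)
    if (identical(e$img, image)) return(e$acts)
  acts <- model_activations(model, image, battery)
  cache$entries[[length(cache$entries) + 1]] <- list(img = image, acts = acts)
  if (length(cache$entries) > 40) cache$entries <- cache$entries[-1]
  acts
}

#' Run a model through a stimulus battery
#'
#' Computes the visibility of every item and assembles response-curve
#' families: one family per `condition$family` label, one curve per adaptor
#' level within the family, visibility as a function of the test level.
#' Items sharing identical conditions up to their noise seed are averaged
#' across seeds.
#'
#' @param model a [model_adapter()].
#' @param battery a battery from the `stimuli` generators.
#' @param config a [readout_config()].
#' @return list of class `curve_family_set`: `property_id`, `families`
#'   (each with `channel`, `curves`), `layer`.
#' @export
run_battery <- function(model, battery, config) {
  cache <- new.env()
  cache$entries <- list()
  rows <- lapply(battery$items, function(item) {
    a1 <- acts_cached(model, item$test, battery, cache)
    a0 <- acts_cached(model, item$reference, battery, cache)
    v <- tryCatch(
      visibility_from_acts(get_layer(a1, config$layer),
                           get_layer(a0, config$layer), config),
      error = function(e) stop(sprintf(
        "read-out failed at property %s, family %s, test_level %s: %s",
        item$condition$property_id, item$condition$family,
        item$condition$test_level, conditionMessage(e)), call. = FALSE))
    c(item$condition[c("family", "adaptor_level", "test_level",
                       "is_zero_test", "in_grid")], list(visibility = v,
      channel = item$condition$channel, seed = item$condition$seed))
  })
  df <- data.frame(
    family = vapply(rows, function(r) as.character(r$family), ""),
    adaptor_level = vapply(rows, function(r) as.numeric(r$adaptor_level), 0),
    test_level = vapply(rows, function(r) as.numeric(r$test_level), 0),
    visibility = vapply(rows, function(r) as.numeric(r$visibility), 0),
    is_zero_test = vapply(rows, function(r) isTRUE(r$is_zero_test), TRUE),
    in_grid = vapply(rows, function(r) !isFALSE(r$in_grid), TRUE),
    channel = vapply(rows, function(r) as.character(r$channel), ""),
    stringsAsFactors = FALSE)
  families <- lapply(split(df, df$family), function(fd) {
    # zero-test anchors stay in the curve when their level belongs to the
    # shared grid (zero contrast); background-matched anchors do not
    fd <- fd[!(fd$is_zero_test & !fd$in_grid), , drop = FALSE]
    curves <- lapply(split(fd, fd$adaptor_level), function(cd) {
      agg <- stats::aggregate(visibility ~ test_level, data = cd, FUN = mean)
      nse <- stats::aggregate(visibility ~ test_level, data = cd,
                              FUN = length)
      agg <- agg[order(agg$test_level), , drop = FALSE]
      list(abscissa = agg$test_level, visibility = agg$visibility,
           adaptor_level = cd$adaptor_level[1], n_seeds = max(nse$visibility),
           channel = cd$channel[1])
    })
    curves <- curves[order(vapply(curves, function(cv) cv$adaptor_level, 0))]
    list(channel = fd$channel[1], curves = unname(curves))
  })
  structure(list(property_id = battery$property_id, families = families,
                 layer = config$layer),
            class = "curve_family_set")
}

#' Measure a contrast sensitivity function
#'
#' Sensitivity at each probe frequency is the (seed-averaged) visibility of
#' the fixed-contrast noise probe. Achromatic and chromatic probes measured
#' with the same read-out keep a meaningful relative scale.
#'
#' @param model a [model_adapter()].
#' @param csf_batt a [csf_battery()].
#' @param config a [readout_config()].
#' @return data.frame with `frequency`, `sensitivity`, `sd`, `n_seeds`,
#'   `channel`.
#' @export
measure_csf <- function(model, csf_batt, config) {
  cache <- new.env(); cache$entries <- list()
  keep <- Filter(function(it) !isTRUE(it$condition$is_zero_test),
                 csf_batt$items)
  vis <- vapply(keep, function(item) {
    a1 <- acts_cached(model, item$test, csf_batt, cache)
    a0 <- acts_cached(model, item$reference, csf_batt, cache)
    visibility_from_acts(get_layer(a1, config$layer),
                         get_layer(a0, config$layer), config)
  }, 0)
  f <- vapply(keep, function(it) it$condition$test_frequency, 0)
  ch <- vapply(keep, function(it) it$condition$channel, "")
  out <- do.call(rbind, lapply(split(seq_along(f), f), function(ix)
    data.frame(frequency = f[ix[1]], sensitivity = mean(vis[ix]),
               sd = stats::sd(vis[ix]), n_seeds = length(ix),
               channel = ch[ix[1]])))
  out <- out[order(out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measure receptive fields with delta probes
#'
#' Activation-difference maps at the configured layer for each delta
#' position and channel; for a purely convolutional layer the map is the
#' kernel cross-correlation at the delta position.
#'
#' @param model a [model_adapter()].
#' @param rf_batt a [rf_probe_battery()].
#' @param config a [readout_config()] (only `layer` is used).
#' @return list of entries `channel`, `amplitude`, `map` (activation
#'   difference, image-shaped where possible).
#' @export
measure_receptive_fields <- function(model, rf_batt, config) {
  cache <- new.env(); cache$entries <- list()
  keep <- Filter(function(it) !isTRUE(it$condition$is_zero_test),
                 rf_batt$items)
  lapply(keep, function(item) {
    a1 <- get_layer(acts_cached(model, item$test, rf_batt, cache),
                    config$layer)
    a0 <- get_layer(acts_cached(model, item$reference, rf_batt, cache),
                    config$layer)
    d <- a1 - a0
    n <- rf_batt$geometry$n
    if (length(d) %% (n * n) == 0 && length(d) >= n * n)
      d <- array(d, c(n, n, length(d) / (n * n)))
    list(channel = item$condition$channel,
         amplitude = item$condition$test_level, map = d)
  })
}

#' Frequency-adaptation CSF ratios
#'
#' Runs an [adaptation_csf_battery()] and returns the matrix of adapted /
#' unadapted CSF ratios, one row per adaptor frequency (row `"none"` is
#' identically 1). Narrow-band sensors show a row minimum at the adaptor
#' frequency; a linear model shows ratios of 1 everywhere.
#'
#' @param model a [model_adapter()].
#' @param adaptation_batt an [adaptation_csf_battery()].
#' @param config a [readout_config()].
#' @return matrix, rows named by adaptor frequency (`"none"` first), columns
#'   by probe frequency.
#' @export
blakemore_campbell <- function(model, adaptation_batt, config) {
  cache <- new.env(); cache$entries <- list()
  keep <- Filter(function(it) !isTRUE(it$condition$is_zero_test),
                 adaptation_batt$items)
  vis <- vapply(keep, function(item) {
    a1 <- acts_cached(model, item$test, adaptation_batt, cache)
    a0 <- acts_cached(model, item$reference, adaptation_batt, cache)
    visibility_from_acts(get_layer(a1, config$layer),
                         get_layer(a0, config$layer), config)
  }, 0)
  pf <- vapply(keep, function(it) it$condition$test_frequency, 0)
  af <- vapply(keep, function(it) it$condition$mask_frequency, 0)
  probe_f <- sort(unique(pf))
  adapt_f <- sort(unique(af))            # 0 = no adaptor
  m <- matrix(NA_real_, length(adapt_f), length(probe_f),
              dimnames = list(ifelse(adapt_f == 0, "none", adapt_f), probe_f))
  for (i in seq_along(adapt_f)) for (j in seq_along(probe_f)) {
    ix <- af == adapt_f[i] & pf == probe_f[j]
    if (any(ix)) m[i, j] <- mean(vis[ix])
  }
  sweep(m, 2, m["none", ], "/")
}

#' Spectral sensitivity read-out
#'
#' Signed mean-response read-out of each opponent plane over a spectral
#' battery, giving achromatic and opponent spectral sensitivity curves.
#'
#' @param model a [model_adapter()] whose configured layer is image-shaped
#'   with one slab per opponent plane (e.g. the bundled reference models'
#'   `"opponent"` layer).
#' @param spec_batt a [spectral_battery()].
#' @param layer layer to read.
#' @return data.frame `wavelength`, `A`, `T`, `D` (mean response
#'   differences over the patch support).
#' @export
measure_spectral_sensitivity <- function(model, spec_batt, layer) {
  cache <- new.env(); cache$entries <- list()
  keep <- Filter(function(it) !isTRUE(it$condition$is_zero_test),
                 spec_batt$items)
  n <- spec_batt$geometry$n
  mask <- patch_mask(spec_batt$geometry) > 0
  rows <- lapply(keep, function(item) {
    a1 <- get_layer(acts_cached(model, item$test, spec_batt, cache), layer)
    a0 <- get_layer(acts_cached(model, item$reference, spec_batt, cache),
                    layer)
    d <- array(a1 - a0, c(n, n, length(a1) / (n * n)))
    ns <- dim(d)[3]
    v <- vapply(seq_len(min(3, ns)), function(k) mean(d[, , k][mask]), 0)
    data.frame(wavelength = item$condition$wavelength,
               A = v[1], T = if (ns >= 2) v[2] else NA_real_,
               D = if (ns >= 3) v[3] else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$wavelength), , drop = FALSE]
}
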