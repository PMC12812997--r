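# Packaged human reference curves and rank templates.
#
# Quantitative standards (spectral sensitivities, CSFs, saturating contrast
# response) are embedded parametric/tabulated constants; the scoring module
# compares model curves to them with grouped Pearson correlation so that
# relative scales within a group (achromatic vs chromatic) matter while a
# single global scale does not. Qualitative knowledge (order of response
# curves under increasing adaptor strength) is packaged as rank templates
# for Kendall scoring.

#' Parametric human achromatic contrast sensitivity
#'
#' Band-pass curve `(f / fp) * exp(1 - f / fp)` with peak at `fp = 4`
#' cycles/degree and sensitivity extending above 32 cpd, normalized to 1 at
#' the peak.
#'
#' @param f frequency, cycles/degree.
#' @param peak peak frequency, cycles/degree.
#' @return sensitivity, dimensionless.
#' @export
csf_achromatic <- function(f, peak = 4) (f / peak) * exp(1 - f / peak)

#' Parametric human chromatic contrast sensitivity
#'
#' Low-pass exponentials with cut-offs around 15 cpd, scaled below the
#' achromatic peak sensitivity (red-green 0.8, yellow-blue 0.7 of the
#' achromatic maximum at zero frequency).
#'
#' @param f frequency, cycles/degree.
#' @param channel `"T"` (red-green) or `"D"` (yellow-blue).
#' @return sensitivity on the same scale as [csf_achromatic()].
#' @export
csf_chromatic <- function(f, channel = c("T", "D")) {
  channel <- match.arg(channel)
  if (channel == "T") 0.8 * exp(-f / 4.3) else 0.7 * exp(-f / 4.0)
}

#' Naka-Rushton saturating contrast response
#'
#' `R(c) = c^n / (c^n + c50^n)`, the canonical saturating response shape
#' used as the property-6/7 quantitative template.
#'
#' @param contrast RMSE contrast.
#' @param c50 semi-saturation contrast.
#' @param n exponent.
#' @return response in \[0, 1\).
#' @export
naka_rushton <- function(contrast, c50 = 0.1, n = 2)
  contrast^n / (contrast^n + c50^n)

gt_curve <- function(abscissa, values, group_id, property_id, channel,
                     curve_id = channel) {
  structure(list(abscissa = abscissa, values = values, group_id = group_id,
                 property_id = property_id, channel = channel,
                 curve_id = curve_id), class = "ground_truth_curve")
}

#' Packaged human ground-truth curves
#'
#' Returns the reference curves for a property as a list of
#' `ground_truth_curve` objects sharing a `group_id`; within a group the
#' relative scales are fixed (no per-curve renormalization), so grouped
#' Pearson scoring is sensitive to wrong relative scaling between, e.g.,
#' achromatic and chromatic responses.
#'
#' Property 1: V(lambda) and the opponent spectral valence curves (the
#' opponent transform of the CIE 1931 observer). Properties 3-4: achromatic
#' band-pass CSF peaking at 4 cpd plus low-pass chromatic CSFs. Properties
#' 6-7 (and the no-mask curves of 8-10): Naka-Rushton saturating responses
#' scaled per frequency by the CSFs.
#'
#' @param property_id 1, 3, 4, 6 or 7 (8-10 return their no-mask curves).
#' @param channel `"A"`, `"T"`, `"D"` or `"all"`.
#' @param frequencies for properties 6-10, the test frequencies of the
#'   curves.
#' @param contrasts abscissa grid for contrast-response curves.
#' @param wavelengths abscissa grid for property 1.
#' @return list of `ground_truth_curve` objects.
#' @export
get_ground_truth <- function(property_id, channel = "all",
                             frequencies = c(1.5, 3, 6, 12),
                             contrasts = seq(0, 0.3, by = 0.025),
                             wavelengths = seq(400, 700, by = 5)) {
  chans <- if (identical(channel, "all")) c("A", "T", "D") else channel
  if (!all(chans %in% c("A", "T", "D"))) stop("unknown channel")
  if (property_id == 1) {
    cmf <- cmf_interp(wavelengths)
    M <- opponent_matrix()
    atd <- cmf %*% t(M)
    sc <- max(abs(atd[, 1]))
    out <- lapply(seq_along(chans), function(k) {
      i <- match(chans[k], c("A", "T", "D"))
      gt_curve(wavelengths, atd[, i] / sc, "spectral", 1, chans[k])
    })
    return(out)
  }
  if (property_id %in% c(3, 4)) {
    f <- seq(0.5, 32, by = 0.25)
    out <- lapply(chans, function(ch) {
      v <- if (ch == "A") csf_achromatic(f) else csf_chromatic(f, ch)
      gt_curve(f, v, "CSF", if (ch == "A") 3 else 4, ch)
    })
    return(out)
  }
  if (property_id %in% 6:10) {
    out <- list()
    for (ch in chans) for (fq in frequencies) {
      s <- if (ch == "A") csf_achromatic(fq) else csf_chromatic(fq, ch)
      out[[length(out) + 1]] <- gt_curve(
        contrasts, s * naka_rushton(contrasts), "contrast_response",
        property_id, ch, curve_id = paste0(ch, "_f", fq))
    }
    return(out)
  }
  stop("no packaged quantitative ground truth for property ", property_id)
}

#' Rank templates for adaptation and masking properties
#'
#' The known human ordering of response curves by adaptor strength:
#' property 2, weaker backgrounds (lower luminance / closer to neutral)
#' give higher curves; property 7, curves ordered by the contrast
#' sensitivity at their frequency; property 8, the no-mask curve is highest
#' and curves descend with mask contrast; property 9, curves descend as the
#' mask frequency approaches the test frequency (no-mask, coded `Inf`,
#' first); property 10, curves descend as the mask orientation approaches
#' the test orientation (orthogonal first, aligned last).
#'
#' @param property_id 2, 7, 8, 9 or 10.
#' @param adaptor_levels the family's adaptor levels (for property 7 these
#'   are the test frequencies).
#' @param channel channel label (used by property 7 to pick the CSF).
#' @return list of class `rank_template`: `property_id`, `adaptor_levels`,
#'   `expected_rank` (1 = highest curve), `eval_quantile_range`.
#' @export
get_rank_template <- function(property_id, adaptor_levels, channel = "A") {
  stopifnot(length(adaptor_levels) >= 2,
            !anyDuplicated(adaptor_levels))
  key <- switch(as.character(property_id),
    "2" = -as.numeric(adaptor_levels),          # weakest adaptor on top
    "7" = if (channel == "A") csf_achromatic(as.numeric(adaptor_levels))
          else csf_chromatic(as.numeric(adaptor_levels), channel),
    "8" = -as.numeric(adaptor_levels),          # no mask (0) on top
    "9" = as.numeric(adaptor_levels),           # far mask / Inf (no mask) on top
    "10" = as.numeric(adaptor_levels),          # orthogonal (90) on top
    stop("no rank template for property ", property_id))
  if (anyDuplicated(key)) stop("adaptor levels produce tied ranks")
  structure(list(property_id = property_id, adaptor_levels = adaptor_levels,
                 expected_rank = rank(-key), eval_quantile_range = c(0.2, 1)),
            class = "rank_template")
}

#' Export / import ground truth as CSV
#'
#' @param curves list of `ground_truth_curve`s.
#' @param path CSV file path.
#' @return `read_ground_truth_csv` returns a list of curves.
#' @export
write_ground_truth_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(property_id = cv$property_id, channel = cv$channel,
               curve_id = cv$curve_id, group_id = cv$group_id,
               abscissa = cv$abscissa, value = cv$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$curve_id), function(d)
    gt_curve(d$abscissa, d$value, d$group_id[1], d$property_id[1],
             d$channel[1], d$curve_id[1]))
}
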