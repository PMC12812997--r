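# Serialization: batteries as 16-bit TIFF planes + JSON manifest, response
# curves as long-format CSV + JSON metadata, score reports as JSON + HTML.

quantize16 <- function(x, lo, hi) {
  if (hi <= lo) hi <- lo + 1
  round((x - lo) / (hi - lo) * 65535) / 65535
}

#' Save a stimulus battery to disk
#'
#' Each opponent plane of each image is stored as a 16-bit grayscale TIFF;
#' the JSON manifest records property, condition fields, file pairs,
#' geometry, display model and the per-plane quantization ranges, so the
#' loader reconstructs the battery bit-exactly at the stored precision and
#' calibration is never implicit.
#'
#' @param battery a battery from the `stimuli` generators.
#' @param dir output directory (created).
#' @param display a [display_model()] recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
save_battery <- function(battery, dir, display = display_model()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_img <- function(img, stem) {
    planes <- list()
    for (ch in c("A", "T", "D")) {
      p <- img[[ch]]
      lo <- min(p); hi <- max(p)
      fn <- sprintf("%s_%s.tif", stem, ch)
      tiff::writeTIFF(quantize16(p, lo, hi), file.path(dir, fn),
                      bits.per.sample = 16L)
      planes[[ch]] <- list(file = fn, min = lo, max = hi)
    }
    planes
  }
  entries <- lapply(seq_along(battery$items), function(i) {
    it <- battery$items[[i]]
    stem <- sprintf("item%04d", i)
    list(condition = it$condition,
         test = write_img(it$test, paste0(stem, "_test")),
         reference = write_img(it$reference, paste0(stem, "_ref")))
  })
  manifest <- list(
    format = "decalogue-battery-v1",
    property_id = battery$property_id,
    geometry = list(field_of_view = battery$geometry$fov,
                    samples_per_degree = battery$geometry$spd),
    display = list(peak_white_luminance = display$peak_white_luminance,
                   black_level = display$black_level, gamma = display$gamma,
                   primaries = display$primaries),
    items = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a stimulus battery saved by [save_battery()]
#'
#' @param dir directory containing `manifest.json`.
#' @return reconstructed battery.
#' @export
load_battery <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  geometry <- stim_geometry(man$geometry$field_of_view,
                            man$geometry$samples_per_degree)
  read_img <- function(planes) {
    vals <- lapply(c("A", "T", "D"), function(ch) {
      p <- planes[[ch]]
      m <- tiff::readTIFF(file.path(dir, p$file))
      lo <- p$min; hi <- if (p$max <= p$min) p$min + 1 else p$max
      m * (hi - lo) + lo
    })
    opponent_image(vals[[1]], vals[[2]], vals[[3]], geometry)
  }
  items <- lapply(man$items, function(e) {
    cond <- e$condition
    cond$mask_frequency <- null2na(cond$mask_frequency)
    cond$orientation_difference <- null2na(cond$orientation_difference)
    cond$wavelength <- null2na(cond$wavelength)
    cond$seed <- null2na(cond$seed)
    cond$test_frequency <- null2na(cond$test_frequency)
    cond$adaptor_level <- json_num(cond$adaptor_level)
    make_item(read_img(e$test), read_img(e$reference), cond)
  })
  new_battery(man$property_id, items, geometry)
}

null2na <- function(x) if (is.null(x)) NA else json_num(x)
json_num <- function(x)
  if (identical(x, "Inf")) Inf else if (identical(x, "-Inf")) -Inf else x

#' Write curve families as long-format CSV
#'
#' Columns: property, family, channel, adaptor_level, test_level,
#' visibility, n_seeds.
#'
#' @param cfs a [run_battery()] result (or list of them).
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_curves_csv <- function(cfs, path) {
  if (inherits(cfs, "curve_family_set")) cfs <- list(cfs)
  rows <- list()
  for (s in cfs) for (nm in names(s$families)) {
    fam <- s$families[[nm]]
    for (cv in fam$curves)
      rows[[length(rows) + 1]] <- data.frame(
        property = s$property_id, family = nm, channel = fam$channel,
        adaptor_level = cv$adaptor_level, test_level = cv$abscissa,
        visibility = cv$visibility, n_seeds = cv$n_seeds)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read curve families written by [write_curves_csv()]
#' @param path CSV path.
#' @return list of `curve_family_set`s, one per property.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$property), function(pd) {
    fams <- lapply(split(pd, pd$family), function(fd) {
      curves <- lapply(split(fd, fd$adaptor_level), function(cd) {
        cd <- cd[order(cd$test_level), , drop = FALSE]
        list(abscissa = cd$test_level, visibility = cd$visibility,
             adaptor_level = cd$adaptor_level[1],
             n_seeds = cd$n_seeds[1], channel = cd$channel[1])
      })
      curves <- curves[order(vapply(curves, function(cv) cv$adaptor_level, 0))]
      list(channel = fd$channel[1], curves = unname(curves))
    })
    structure(list(property_id = pd$property[1], families = fams,
                   layer = NA), class = "curve_family_set")
  })
}

#' Serialize a score report as JSON
#' @param report a [score_decalogue()] result.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_score_report <- function(report, path) {
  jsonlite::write_json(list(
    model = report$model, layer = report$layer,
    scores = as.list(report$scores), inclusion = report$inclusion,
    aggregate = report$aggregate,
    bootstrap = list(ci = report$bootstrap$ci,
                     boot_sd = report$bootstrap$boot_sd,
                     n_boot = report$bootstrap$n_boot,
                     conf = report$bootstrap$conf)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render one or two score reports as an HTML table
#'
#' Two-panel layout (Pearson descriptors, Kendall descriptors); when two
#' reports are given the per-descriptor maximum is highlighted in green and
#' the pairwise Kolmogorov-Smirnov comparison is appended.
#'
#' @param reports list of one or two `score_report`s.
#' @param path output HTML path.
#' @return the path, invisibly.
#' @export
write_score_html <- function(reports, path) {
  if (inherits(reports, "score_report")) reports <- list(reports)
  nms <- unique(unlist(lapply(reports, function(r) names(r$scores))))
  panel <- function(keep, title) {
    rows <- vapply(keep, function(nm) {
      vals <- vapply(reports, function(r)
        if (nm %in% names(r$scores)) r$scores[[nm]] else NA_real_, 0)
      best <- which.max(vals)
      cells <- vapply(seq_along(vals), function(k) {
        style <- if (k == best && length(vals) > 1)
          " style='background:#b6e3b6'" else ""
        sprintf("<td%s>%+.3f</td>", style, vals[k])
      }, "")
      sprintf("<tr><td>%s</td>%s</tr>", nm, paste(cells, collapse = ""))
    }, "")
    sprintf("<h3>%s</h3><table border='1'><tr><th>descriptor</th>%s</tr>%s</table>",
            title,
            paste(sprintf("<th>%s</th>",
                          vapply(reports, function(r) r$model, "")),
                  collapse = ""),
            paste(rows, collapse = "\n"))
  }
  pe <- grepl("pearson", nms)
  html <- c("<html><body><h2>Model alignment report</h2>",
            panel(nms[pe], "Pearson correlation (vs ground truth)"),
            panel(nms[!pe], "Kendall rank correlation (vs curve order)"),
            vapply(reports, function(r) sprintf(
              "<p>%s aggregate: %.3f &plusmn; %.3f (bootstrap CI [%.3f, %.3f])</p>",
              r$model, r$aggregate$mean, r$aggregate$std,
              r$bootstrap$ci[1], r$bootstrap$ci[2]), ""))
  if (length(reports) == 2) {
    ks <- compare_models_ks(reports[[1]]$scores, reports[[2]]$scores)
    html <- c(html, sprintf(
      "<p>Two-sample KS: D = %.3f, p = %.3g</p>", ks$statistic, ks$p_value))
  }
  writeLines(c(html, "</body></html>"), path)
  invisible(path)
}

#' Plot a response-curve family
#'
#' Curves colored from blue (weakest adaptor, highest expected response)
#' through grays to red (strongest adaptor), mirroring the qualitative
#' human ordering.
#'
#' @param family a family from [run_battery()].
#' @param main plot title.
#' @param xlab abscissa label.
#' @export
plot_curve_family <- function(family, main = "", xlab = "test level") {
  curves <- family$curves
  k <- length(curves)
  pal <- grDevices::colorRampPalette(
    c("#2166ac", "#4d4d4d", "#bababa", "#b2182b"))(max(k, 2))
  ylim <- range(unlist(lapply(curves, function(cv) cv$visibility)))
  graphics::plot(NULL, xlim = range(curves[[1]]$abscissa), ylim = ylim,
                 xlab = xlab, ylab = "visibility", main = main)
  for (i in seq_len(k))
    graphics::lines(curves[[i]]$abscissa, curves[[i]]$visibility,
                    col = pal[i], lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, col = pal[seq_len(k)],
                   legend = vapply(curves, function(cv)
                     format(cv$adaptor_level, digits = 3), ""))
  invisible(NULL)
}
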