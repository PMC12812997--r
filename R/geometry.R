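#' Stimulus geometry
#'
#' Spatial geometry shared by every stimulus in a battery: the visual field
#' subtense in degrees and the retinal sampling rate in samples per degree.
#' The default emulates a 2-degree foveal field sampled at 64 samples/degree,
#' i.e. 128 x 128 pixel images with a Nyquist frequency of 32 cycles/degree.
#'
#' @param field_of_view field subtense, degrees of visual angle.
#' @param samples_per_degree sampling rate, samples per degree.
#' @return object of class `stim_geometry` with elements `fov`, `spd`, `n`
#'   (side length in pixels) and `nyquist` (cycles/degree).
#' @export
stim_geometry <- function(field_of_view = 2, samples_per_degree = 64) {
  stopifnot(field_of_view > 0, samples_per_degree > 0)
  n <- round(field_of_view * samples_per_degree)
  structure(
    list(fov = field_of_view, spd = samples_per_degree, n = n,
         nyquist = samples_per_degree / 2),
    class = "stim_geometry")
}

# Pixel-centre coordinates in degrees, measured from the image centre.
# Row-major images, top-left origin; x runs along columns, y along rows.
geom_axes <- function(geometry) {
  n <- geometry$n
  v <- (seq_len(n) - (n + 1) / 2) / geometry$spd
  list(x = matrix(v, n, n, byrow = TRUE), y = matrix(v, n, n))
}

# FFT frequency grids in cycles/degree (unshifted, matching stats::fft).
geom_freqs <- function(geometry) {
  n <- geometry$n
  f1 <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / n * geometry$spd
  fx <- matrix(f1, n, n, byrow = TRUE)
  fy <- matrix(f1, n, n)
  list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2),
       theta = atan2(fy, fx) * 180 / pi)
}

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$fov - b$fov) < tol && abs(a$spd - b$spd) < tol && a$n == b$n
}

# Run expr with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
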