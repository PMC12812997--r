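#' Parametric display model
#'
#' Calibration of the simulated display: a gamma law per channel, a linear
#' primaries matrix mapping device-linear RGB to CIE XYZ, and the luminance
#' range. Defaults are sRGB primaries (D65), gamma 2.2, zero black level and
#' a 180 cd/m2 peak white, chosen so the brightest battery background
#' (160 cd/m2) stays inside the gamut.
#'
#' @param peak_white_luminance luminance of device white, cd/m2.
#' @param black_level luminance of device black, cd/m2.
#' @param gamma exponent of the device transfer function.
#' @param primaries 3x3 matrix, device-linear RGB -> CIE XYZ (rows X, Y, Z),
#'   normalized so that RGB = (1,1,1) gives Y = 1.
#' @return object of class `display_model`.
#' @export
display_model <- function(peak_white_luminance = 180, black_level = 0,
                          gamma = 2.2, primaries = srgb_primaries()) {
  stopifnot(peak_white_luminance > black_level, black_level >= 0, gamma > 0)
  primaries <- as.matrix(primaries)
  stopifnot(nrow(primaries) == 3, ncol(primaries) == 3)
  if (abs(det(primaries)) < 1e-12) stop("primaries matrix must be invertible")
  structure(
    list(peak_white_luminance = peak_white_luminance,
         black_level = black_level, gamma = gamma,
         primaries = primaries, primaries_inv = solve(primaries)),
    class = "display_model")
}

#' sRGB primaries matrix (linear RGB to XYZ, D65 white)
#' @return 3x3 matrix with rows X, Y, Z.
#' @export
srgb_primaries <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041),
         3, 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Calibrated luminance image
#'
#' @param values matrix of luminances, cd/m2, dimensions matching `geometry`.
#' @param geometry a [stim_geometry()].
#' @return object of class `luminance_image`.
#' @export
luminance_image <- function(values, geometry) {
  values <- as.matrix(values)
  if (!all(dim(values) == geometry$n))
    stop("image dimensions must equal round(field_of_view * samples_per_degree)")
  if (any(values < 0)) stop("luminance values must be nonnegative")
  structure(list(values = values, geometry = geometry),
            class = "luminance_image")
}

#' Calibrated opponent-space image
#'
#' Three coplanar image planes in a Jameson-Hurvich style opponent space:
#' `A` achromatic (CIE luminance, cd/m2), `T` red-green and `D` yellow-blue
#' (signed tristimulus units). Achromatic stimuli have `T = D = 0`.
#'
#' @param A,T,D matrices of identical dimensions matching `geometry`.
#' @param geometry a [stim_geometry()].
#' @return object of class `opponent_image`.
#' @export
opponent_image <- function(A, T = NULL, D = NULL, geometry) {
  A <- as.matrix(A)
  if (is.null(T)) T <- matrix(0, nrow(A), ncol(A))
  if (is.null(D)) D <- matrix(0, nrow(A), ncol(A))
  if (!all(dim(A) == geometry$n) || !all(dim(T) == dim(A)) ||
      !all(dim(D) == dim(A)))
    stop("plane dimensions must match the geometry")
  structure(list(A = A, T = T, D = D, geometry = geometry),
            class = "opponent_image")
}

#' @export
as_opponent <- function(x, ...) UseMethod("as_opponent")

#' @export
as_opponent.luminance_image <- function(x, ...)
  opponent_image(A = x$values, geometry = x$geometry)

#' @export
as_opponent.opponent_image <- function(x, ...) x

# ---- CIE 1931 2-degree colour matching functions -------------------------
# Multi-lobe Gaussian representation of the 1931 standard observer,
# tabulated at 5 nm on [360, 830] nm with linear interpolation between
# knots. ybar doubles as the photopic luminous efficiency curve V(lambda).

pw_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

cmf_xbar_fun <- function(l)
  1.056 * pw_gauss(l, 599.8, 37.9, 31.0) +
  0.362 * pw_gauss(l, 442.0, 16.0, 26.7) -
  0.065 * pw_gauss(l, 501.1, 20.4, 26.2)

cmf_ybar_fun <- function(l)
  0.821 * pw_gauss(l, 568.8, 46.9, 40.5) +
  0.286 * pw_gauss(l, 530.9, 16.3, 31.1)

cmf_zbar_fun <- function(l)
  1.217 * pw_gauss(l, 437.0, 11.8, 36.0) +
  0.681 * pw_gauss(l, 459.0, 26.0, 13.8)

#' CIE 1931 2-degree colour matching functions
#'
#' Tabulated at 5 nm over 360-830 nm; `ybar` is the photopic luminous
#' efficiency function V(lambda).
#'
#' @return data.frame with columns `wavelength`, `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function() {
  wl <- seq(360, 830, by = 5)
  data.frame(wavelength = wl, xbar = cmf_xbar_fun(wl),
             ybar = cmf_ybar_fun(wl), zbar = cmf_zbar_fun(wl))
}

cmf_interp <- function(wavelengths) {
  tab <- cie_cmf()
  sapply(c("xbar", "ybar", "zbar"), function(k)
    stats::approx(tab$wavelength, tab[[k]], xout = wavelengths,
                  rule = 2)$y)
}

# ---- Opponent transform ---------------------------------------------------
# Linear Jameson-Hurvich style opponent axes referenced to the D65 white
# point so that any achromatic (R=G=B) device stimulus maps to T = D = 0:
#   A = Y,   T = X/Xn - Y,   D = 0.4 (Y - Z/Zn)
# The white point is taken from the sRGB primaries row sums so the
# achromatic invariant holds to machine precision on the default display.
D65_WHITE <- local({
  w <- rowSums(srgb_primaries())
  c(X = w[["X"]] / w[["Y"]], Y = 1, Z = w[["Z"]] / w[["Y"]])
})

#' Opponent transform matrix (XYZ to ATD)
#' @return 3x3 matrix, rows A, T, D.
#' @export
opponent_matrix <- function() {
  matrix(c(0, 1, 0,
           1 / D65_WHITE[["X"]], -1, 0,
           0, 0.4, -0.4 / D65_WHITE[["Z"]]),
         3, 3, byrow = TRUE,
         dimnames = list(c("A", "T", "D"), c("X", "Y", "Z")))
}

#' Convert CIE XYZ planes to the opponent space (and back)
#'
#' A linear 3x3 map; `A` equals CIE luminance and `opponent_inverse()` is its
#' exact inverse.
#'
#' @param X,Y,Z matrices of tristimulus values.
#' @param geometry a [stim_geometry()].
#' @return [opponent_image()] for the forward map; a list of `X`, `Y`, `Z`
#'   matrices for the inverse.
#' @export
opponent_transform <- function(X, Y, Z, geometry) {
  if (!all(is.finite(X)) || !all(is.finite(Y)) || !all(is.finite(Z)))
    stop("tristimulus values must be finite")
  M <- opponent_matrix()
  opponent_image(A = M[1, 1] * X + M[1, 2] * Y + M[1, 3] * Z,
                 T = M[2, 1] * X + M[2, 2] * Y + M[2, 3] * Z,
                 D = M[3, 1] * X + M[3, 2] * Y + M[3, 3] * Z,
                 geometry = geometry)
}

#' @rdname opponent_transform
#' @param img an [opponent_image()].
#' @export
opponent_inverse <- function(img) {
  Mi <- solve(opponent_matrix())
  list(X = Mi[1, 1] * img$A + Mi[1, 2] * img$T + Mi[1, 3] * img$D,
       Y = Mi[2, 1] * img$A + Mi[2, 2] * img$T + Mi[2, 3] * img$D,
       Z = Mi[3, 1] * img$A + Mi[3, 2] * img$T + Mi[3, 3] * img$D)
}

# ---- Device <-> calibrated conversions -----------------------------------

#' Convert a device RGB image to calibrated luminance
#'
#' Gamma-expands digital values, maps through the primaries matrix and
#' rescales to the display's luminance range.
#'
#' @param image array `n x n x 3` (or `n x n` grayscale) of digital values
#'   in \[0, 1\].
#' @param display a [display_model()].
#' @param geometry a [stim_geometry()].
#' @return [luminance_image()].
#' @export
device_to_luminance <- function(image, display, geometry) {
  xyz <- device_to_xyz(image, display)
  lum <- display$black_level +
    (display$peak_white_luminance - display$black_level) * xyz$Y
  luminance_image(lum, geometry)
}

#' Convert a device RGB image to a calibrated opponent image
#' @inheritParams device_to_luminance
#' @return [opponent_image()] with `A` in cd/m2.
#' @export
device_to_opponent <- function(image, display, geometry) {
  xyz <- device_to_xyz(image, display)
  s <- display$peak_white_luminance - display$black_level
  # black level is achromatic: it adds to A only
  img <- opponent_transform(s * xyz$X, s * xyz$Y, s * xyz$Z, geometry)
  img$A <- img$A + display$black_level
  img
}

device_to_xyz <- function(image, display) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 3))
  if (any(image < -1e-12) || any(image > 1 + 1e-12))
    stop("digital values must lie in [0, 1]")
  image <- pmin(pmax(image, 0), 1)
  lin <- image^display$gamma
  P <- display$primaries
  d <- dim(image)[1:2]
  chan <- function(i) matrix(lin[, , 1] * P[i, 1] + lin[, , 2] * P[i, 2] +
                               lin[, , 3] * P[i, 3], d[1], d[2])
  # normalize so device white has Y = 1
  ywhite <- sum(P[2, ])
  list(X = chan(1) / ywhite, Y = chan(2) / ywhite, Z = chan(3) / ywhite)
}

#' Render a calibrated image to device RGB
#'
#' Inverse of [device_to_luminance()] / [device_to_opponent()]. Out-of-gamut
#' pixels are clipped with a warning (`clip_policy = "clip"`) or raise an
#' error (`"error"`); the clipped-pixel fraction is attached as attribute
#' `clipped_fraction`.
#'
#' @param target a [luminance_image()] or [opponent_image()].
#' @param display a [display_model()].
#' @param clip_policy `"clip"` or `"error"`.
#' @return array `n x n x 3` of digital values in \[0, 1\].
#' @export
luminance_to_device <- function(target, display, clip_policy = c("clip", "error")) {
  clip_policy <- match.arg(clip_policy)
  img <- as_opponent(target)
  s <- display$peak_white_luminance - display$black_level
  rel <- img
  rel$A <- (img$A - display$black_level) / s
  rel$T <- img$T / s
  rel$D <- img$D / s
  xyz <- opponent_inverse(rel)
  P <- display$primaries / sum(display$primaries[2, ])
  Pi <- solve(P)
  n <- img$geometry$n
  lin <- array(0, c(n, n, 3))
  for (i in 1:3)
    lin[, , i] <- Pi[i, 1] * xyz$X + Pi[i, 2] * xyz$Y + Pi[i, 3] * xyz$Z
  bad <- lin < -1e-12 | lin > 1 + 1e-12
  frac <- mean(bad)
  if (frac > 0) {
    if (clip_policy == "error")
      stop(sprintf("gamut violation: %.2f%% of pixel components out of range",
                   100 * frac))
    warning(sprintf("clipping %.2f%% of pixel components to the display gamut",
                    100 * frac))
  }
  lin <- pmin(pmax(lin, 0), 1)
  out <- lin^(1 / display$gamma)
  attr(out, "clipped_fraction") <- frac
  out
}

#' Quasi-monochromatic stimulus colour
#'
#' Integrates a Gaussian spectral radiance line (centre `wavelength`, standard
#' deviation `bandwidth`) against the CIE 1931 colour matching functions; as
#' the bandwidth shrinks the luminance converges to
#' `radiance * V(lambda)`.
#'
#' @param wavelength centre wavelength, nm (within \[360, 830\]).
#' @param bandwidth spectral standard deviation, nm (> 0).
#' @param radiance total radiant energy of the line, arbitrary energy units.
#' @return named vector `c(X=, Y=, Z=)` of tristimulus values.
#' @export
quasi_monochromatic_xyz <- function(wavelength, bandwidth = 5, radiance = 1) {
  if (wavelength < 360 || wavelength > 830)
    stop("wavelength outside [360, 830] nm")
  stopifnot(bandwidth > 0)
  wl <- seq(max(360, wavelength - 6 * bandwidth),
            min(830, wavelength + 6 * bandwidth), length.out = 201)
  e <- exp(-0.5 * ((wl - wavelength) / bandwidth)^2)
  e <- e / sum(e * diff(wl)[1]) * radiance        # unit-integral line x radiance
  cmf <- cmf_interp(wl)
  dw <- diff(wl)[1]
  c(X = sum(e * cmf[, "xbar"]) * dw,
    Y = sum(e * cmf[, "ybar"]) * dw,
    Z = sum(e * cmf[, "zbar"]) * dw)
}

#' Quasi-monochromatic patch image
#'
#' A centred square patch of quasi-monochromatic light on a dim neutral
#' pedestal, expressed in the opponent space.
#'
#' @inheritParams quasi_monochromatic_xyz
#' @param geometry a [stim_geometry()].
#' @param pedestal_luminance neutral pedestal, cd/m2.
#' @param patch_fraction side of the square patch as a fraction of the field.
#' @return [opponent_image()].
#' @export
quasi_monochromatic_image <- function(wavelength, bandwidth = 5, radiance = 1,
                                      geometry = stim_geometry(),
                                      pedestal_luminance = 1,
                                      patch_fraction = 1 / 3) {
  xyz <- quasi_monochromatic_xyz(wavelength, bandwidth, radiance)
  n <- geometry$n
  mask <- patch_mask(geometry, patch_fraction)
  op <- opponent_transform(matrix(xyz[["X"]], n, n) * mask,
                           matrix(xyz[["Y"]], n, n) * mask,
                           matrix(xyz[["Z"]], n, n) * mask, geometry)
  op$A <- op$A + pedestal_luminance
  op
}

# Central square patch indicator (1 inside, 0 outside).
patch_mask <- function(geometry, patch_fraction = 1 / 3) {
  ax <- geom_axes(geometry)
  half <- geometry$fov * patch_fraction / 2
  (abs(ax$x) <= half & abs(ax$y) <= half) * 1
}
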