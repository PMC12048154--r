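# Geometric optics models: asphere sag, focal surfaces, radial PSF size,
# magnification/distortion calibration and radial intensity fall-off.
# All models are rotationally symmetric: outputs depend on the radial
# distance r (um) only.

#' Aspheric surface profile
#' @param c curvature, 1/um (inverse of the radius of curvature).
#' @param k conic constant (dimensionless; `k = -1` is a paraboloid).
#' @param alpha numeric vector of asphericity coefficients `alpha_n` for the
#'   even polynomial terms `r^(2n)`, `n = 1, 2, ...`.
#' @return an `asphere_profile` list.
#' @export
asphere_profile <- function(c = 0, k = 0, alpha = numeric(0)) {
  structure(list(c = c, k = k, alpha = alpha), class = "asphere_profile")
}

#' Evaluate the asphere sag
#'
#' `Z(r) = c r^2 / (1 + sqrt(1 - (1+k) c^2 r^2)) + sum_n alpha_n r^(2n)`.
#'
#' @param r radial distance(s) from the optical axis, um.
#' @param profile an [asphere_profile()].
#' @return sag Z in um.
#' @export
asphere_sag <- function(r, profile) {
  stopifnot(inherits(profile, "asphere_profile"), all(r >= 0))
  arg <- 1 - (1 + profile$k) * profile$c^2 * r^2
  if (any(arg < 0)) {
    rmax <- 1 / (abs(profile$c) * sqrt(1 + profile$k))
    stop(sprintf("sag undefined beyond r = %.6g um", rmax))
  }
  z <- profile$c * r^2 / (1 + sqrt(arg))
  for (n in seq_along(profile$alpha))
    z <- z + profile$alpha[n] * r^(2 * n)
  z
}

#' Focal-surface model
#'
#' Corrected probes image along a single rotationally symmetric surface given
#' by a polynomial in r (up to fifth order); uncorrected probes are
#' astigmatic and image along two spherical shells of different curvature
#' radius, each contributing an excitation pass.
#'
#' @param kind `"polynomial"` or `"spherical_shells"`.
#' @param poly_coeffs coefficients of `r, r^2, ..., r^5` (um output), used for
#'   `"polynomial"`.
#' @param shell_radii one or two curvature radii, um, for
#'   `"spherical_shells"`.
#' @param sign +1 if the surface bends deeper into the sample with r, -1
#'   for the opposite orientation.
#' @return a `focal_surface` list.
#' @export
focal_surface <- function(kind = c("polynomial", "spherical_shells"),
                          poly_coeffs = numeric(5), shell_radii = NULL,
                          sign = 1) {
  kind <- match.arg(kind)
  if (kind == "spherical_shells") stopifnot(length(shell_radii) %in% 1:2,
                                            all(shell_radii > 0))
  structure(list(kind = kind,
                 poly_coeffs = c(poly_coeffs, numeric(5))[1:5],
                 shell_radii = shell_radii, sign = sign),
            class = "focal_surface")
}

#' Height of the focal surface(s) above the on-axis focus
#'
#' Surfaces are anchored at the axis: `z(0) = 0`. Shells return one height
#' per shell, `z = R - sqrt(R^2 - r^2)`.
#'
#' @param r radial distance(s), um.
#' @param model a [focal_surface()].
#' @return for `"polynomial"`, a vector matching `r`; for
#'   `"spherical_shells"`, a matrix with one column per shell.
#' @export
focal_surface_height <- function(r, model) {
  stopifnot(inherits(model, "focal_surface"), all(r >= 0))
  if (model$kind == "polynomial") {
    z <- numeric(length(r))
    for (n in 1:5) z <- z + model$poly_coeffs[n] * r^n
    model$sign * z
  } else {
    if (any(vapply(model$shell_radii, function(R) any(r >= R), TRUE)))
      stop("r beyond shell curvature radius")
    out <- vapply(model$shell_radii,
                  function(R) model$sign * (R - sqrt(R^2 - r^2)),
                  numeric(length(r)))
    matrix(out, nrow = length(r))
  }
}

# dz/dr of one surface (shell index for the shells kind)
focal_surface_slope <- function(r, model, shell = 1L) {
  if (model$kind == "polynomial") {
    s <- numeric(length(r))
    for (n in 1:5) s <- s + n * model$poly_coeffs[n] * r^(n - 1)
    model$sign * s
  } else {
    R <- model$shell_radii[shell]
    model$sign * r / sqrt(R^2 - r^2)
  }
}

#' Unit normal of a focal surface
#'
#' Normal of the rotationally symmetric surface `z(r)` at radius `r` and
#' azimuth `phi`, oriented with a positive z component (towards increasing
#' imaging depth). The excitation ellipsoid's axial direction is set along
#' this normal.
#'
#' @param r radial distance, um.
#' @param model a [focal_surface()].
#' @param phi azimuth, radians.
#' @param shell shell index (shells kind only).
#' @return unit 3-vector `c(x, y, z)`.
#' @export
surface_normal <- function(r, model, phi = 0, shell = 1L) {
  s <- focal_surface_slope(r, model, shell)
  v <- c(-s * cos(phi), -s * sin(phi), 1)
  v / sqrt(sum(v^2))
}

#' PSF-size model: quartic lateral and axial FWHM vs radius
#'
#' The quartics are fitted to characterization data over a finite radial
#' range; outside it the excitation volume is taken to saturate at
#' `axial_max` / `lateral_max` rather than follow the quartic extrapolation
#' (strongly aberrated marginal foci are large but not unbounded).
#'
#' @param axial,lateral coefficients `c(a, b, c)` of `f(r) = a r^4 + b r^2 + c`
#'   (um output).
#' @param axial_max,lateral_max saturation caps, um.
#' @return a `psf_size_model` list.
#' @export
psf_size_model <- function(axial, lateral, axial_max = 60, lateral_max = 8) {
  stopifnot(length(axial) == 3, length(lateral) == 3)
  structure(list(axial = axial, lateral = lateral, axial_max = axial_max,
                 lateral_max = lateral_max),
            class = "psf_size_model")
}

quartic_eval <- function(r, co) co[1] * r^4 + co[2] * r^2 + co[3]

#' Lateral and axial FWHM of the excitation volume at radius r
#' @param r radial distance(s), um.
#' @param model a [psf_size_model()].
#' @return matrix with columns `lateral`, `axial` (um).
#' @export
psf_axes <- function(r, model) {
  stopifnot(inherits(model, "psf_size_model"), all(r >= 0))
  out <- cbind(lateral = pmin(quartic_eval(r, model$lateral),
                              model$lateral_max %||% Inf),
               axial = pmin(quartic_eval(r, model$axial),
                            model$axial_max %||% Inf))
  if (any(out <= 0)) stop("PSF size model must be positive over the FOV")
  out
}

#' Effective FOV radius at an axial-resolution threshold
#'
#' Smallest radius at which the axial FWHM reaches `threshold` (default
#' 10 um), found by bisection; `Inf` if the threshold is never reached within
#' `rmax`.
#'
#' @param model a [psf_size_model()].
#' @param threshold axial FWHM threshold, um.
#' @param rmax search limit, um.
#' @return radius in um.
#' @export
effective_fov_radius <- function(model, threshold = 10, rmax = 250) {
  f <- function(r) quartic_eval(r, model$axial) - threshold
  if (f(0) >= 0) return(0)
  if (f(rmax) < 0) return(Inf)
  uniroot(f, c(0, rmax), tol = 1e-9)$root
}

#' Magnification / field-distortion calibration model
#'
#' `magnification` holds `c(a, b, c)` of the local magnification factor
#' `f(r) = a r^4 + b r^2 + c` (nominal over local pixel size, dimensionless,
#' vs real radial distance in um). `distance` holds `c(d, e, f, h)` of the
#' cumulative calibration `g(x) = d x^4 + e x^2 + f x + h` mapping a real
#' radial distance x (um) to the nominal radial distance (um).
#'
#' @param magnification quartic coefficients `c(a, b, c)`.
#' @param distance quartic coefficients `c(d, e, f, h)`.
#' @param nominal_pixel_size um per pixel under undistorted conditions.
#' @param rmax calibrated range, um (real distance).
#' @return a `magnification_model` list.
#' @export
magnification_model <- function(magnification = c(0, 0, 1),
                                distance = c(0, 0, 1, 0),
                                nominal_pixel_size = 1, rmax = 300) {
  stopifnot(length(magnification) == 3, length(distance) == 4,
            magnification[3] > 0)
  m <- structure(list(magnification = magnification, distance = distance,
                      nominal_pixel_size = nominal_pixel_size, rmax = rmax),
                 class = "magnification_model")
  # g must be monotone increasing over the calibrated range
  x <- seq(0, rmax, length.out = 512)
  if (any(diff(nominal_distance(x, m)) <= 0))
    stop("distance calibration g is not monotone over the range")
  m
}

#' Local magnification factor at a (real) radial distance
#' @param r real radial distance(s), um.
#' @param model a [magnification_model()].
#' @return dimensionless factor(s).
#' @export
magnification_factor <- function(r, model) {
  quartic_eval(r, model$magnification)
}

#' Nominal radial distance corresponding to a real distance
#' @param r_real real radial distance(s), um.
#' @param model a [magnification_model()].
#' @return nominal distance(s), um.
#' @export
nominal_distance <- function(r_real, model) {
  d <- model$distance
  d[1] * r_real^4 + d[2] * r_real^2 + d[3] * r_real + d[4]
}

#' Real radial distance corresponding to a nominal distance
#'
#' Numerical inverse of [nominal_distance()] by monotone bisection. Values
#' beyond the calibrated range trigger an extrapolation warning.
#'
#' @param r_nominal nominal radial distance(s), um.
#' @param model a [magnification_model()].
#' @return real distance(s), um.
#' @export
real_distance <- function(r_nominal, model) {
  gmax <- nominal_distance(model$rmax, model)
  if (any(r_nominal > gmax))
    warning("nominal distance beyond calibrated range; extrapolating")
  vapply(r_nominal, function(rn) {
    if (rn <= nominal_distance(0, model)) return(0)
    hi <- model$rmax
    while (nominal_distance(hi, model) < rn) hi <- hi * 2
    uniroot(function(x) nominal_distance(x, model) - rn, c(0, hi),
            tol = 1e-9)$root
  }, 1)
}

#' Radial excitation-intensity profile
#'
#' Relative excitation efficiency vs radial distance, an even polynomial
#' clamped to `[0, 1]` and normalized to 1 on axis. Models the fluorescence
#' loss in the marginal portions of the FOV.
#'
#' @param coeffs coefficients `c(c2, c4)` of `1 + c2 r^2 + c4 r^4`.
#' @return a function of r returning values in `[0, 1]`.
#' @export
radial_intensity_profile <- function(coeffs = c(0, 0)) {
  force(coeffs)
  function(r) pmin(1, pmax(0, 1 + coeffs[1] * r^2 + coeffs[2] * r^4))
}

# Solve a, b of a r^4 + b r^2 + c0 through (r1, v1) and (r2, v2). If the
# anchor pair implies a negative leading coefficient (a curve that would
# eventually turn negative), drop the quartic term and keep the primary
# anchor (r1, v1) exact with the parabola alone.
solve_quartic_through <- function(c0, r1, v1, r2, v2) {
  A <- rbind(c(r1^4, r1^2), c(r2^4, r2^2))
  ab <- solve(A, c(v1 - c0, v2 - c0))
  if (ab[1] < 0) ab <- c(0, (v1 - c0) / r1^2)
  c(a = ab[1], b = ab[2], c = c0)
}

#' Default optics configuration for one probe type
#'
#' Builds the full optics block for one of the four probe designs: GRIN rod
#' length 6.4 or 8.8 mm, with (`corrected`) or without (`uncorrected`) the
#' aspheric corrective back-end lens. Quantitative coefficients are
#' *reconstructed*: they are chosen so that the models reproduce the headline
#' characterization numbers (effective FOV radii of 100/46 um for the 6.4 mm
#' designs and 52/34 um for the 8.8 mm designs at the 10 um axial-resolution
#' threshold; shell curvature radii 273/2000 um and 992/2000 um for the
#' uncorrected probes; FOV sides 400 and 360 um; edge radii 200 and 180 um),
#' not fitted to raw characterization stacks.
#'
#' The distance calibration g is derived from the magnification quartic f by
#' quadrature (nominal distance = integral of the local magnification factor)
#' and refitted on the quartic-plus-linear basis, so the two are mutually
#' consistent.
#'
#' @param probe one of `"corrected-6.4"`, `"uncorrected-6.4"`,
#'   `"corrected-8.8"`, `"uncorrected-8.8"`.
#' @param fov_pixels pixels per FOV side (default 256).
#' @return an `optics_config` list: `probe`, `corrected`, `focal_surface`,
#'   `psf`, `magnification`, `radial_intensity`, `fov_um`, `edge_radius`,
#'   `vertex_depth`, `fov_pixels`, `nominal_pixel_size`.
#' @export
default_optics <- function(probe = c("corrected-6.4", "uncorrected-6.4",
                                     "corrected-8.8", "uncorrected-8.8"),
                           fov_pixels = 256) {
  probe <- match.arg(probe)
  len64 <- grepl("6.4", probe, fixed = TRUE)
  corrected <- grepl("corrected", probe) && !grepl("uncorrected", probe)
  fov_um <- if (len64) 400 else 360
  edge_radius <- if (len64) 200 else 180
  depth <- if (len64) 170 else 200
  if (probe == "corrected-6.4") {
    axial <- solve_quartic_through(6.0, 100, 10, 175, 20)
    lateral <- solve_quartic_through(0.8, 100, 1.4, 175, 2.5)
    fs <- focal_surface("polynomial", poly_coeffs = c(0, 1.5e-4, 0, 2e-9, 0))
    mag <- c(4e-11, 8e-6, 1)
    intens <- c(-8e-6, 0)
  } else if (probe == "uncorrected-6.4") {
    axial <- solve_quartic_through(6.5, 46, 10, 75, 25)
    lateral <- solve_quartic_through(1.0, 46, 1.8, 75, 3.5)
    fs <- focal_surface("spherical_shells", shell_radii = c(273, 2000))
    mag <- c(0, 2e-6, 1)
    intens <- c(-1.8e-5, 0)
  } else if (probe == "corrected-8.8") {
    axial <- solve_quartic_through(6.5, 52, 10, 150, 40)
    lateral <- solve_quartic_through(0.9, 52, 1.5, 150, 3.0)
    fs <- focal_surface("polynomial", poly_coeffs = c(0, 8e-4, 0, 0, 0))
    mag <- c(6e-11, 1e-5, 1)
    intens <- c(-9e-6, 0)
  } else {
    axial <- solve_quartic_through(7.0, 34, 10, 75, 25)
    lateral <- solve_quartic_through(1.1, 34, 1.9, 75, 3.6)
    fs <- focal_surface("spherical_shells", shell_radii = c(992, 2000))
    mag <- c(0, 2e-6, 1)
    intens <- c(-2e-5, 0)
  }
  psf <- psf_size_model(axial = unname(axial), lateral = unname(lateral))
  # distance calibration from quadrature of the magnification factor
  xs <- seq(0, edge_radius * 1.5, length.out = 400)
  fval <- quartic_eval(xs, mag)
  gnum <- c(0, cumsum((fval[-1] + fval[-length(fval)]) / 2 * diff(xs)))
  gfit <- fit_quartic(xs, gnum, with_linear_term = TRUE)
  dist <- unname(c(gfit$coefficients["a"], gfit$coefficients["b"],
                   gfit$coefficients["f"], 0))
  magm <- magnification_model(magnification = mag, distance = dist,
                              nominal_pixel_size = fov_um / fov_pixels,
                              rmax = edge_radius * 1.5)
  structure(list(probe = probe, corrected = corrected, focal_surface = fs,
                 psf = psf, magnification = magm,
                 radial_intensity = radial_intensity_profile(intens),
                 fov_um = fov_um, edge_radius = edge_radius,
                 vertex_depth = depth / 2, fov_pixels = fov_pixels,
                 nominal_pixel_size = fov_um / fov_pixels),
            class = "optics_config")
}

#' Effective-FOV fold report for the two probe lengths
#'
#' Computes the fold change in effective FOV radius and area obtained by
#' adding the corrective lens, from the configured effective FOV radii at the
#' 10 um axial threshold. Folds are reported at the printed precision
#' (two decimals for radius, one for area).
#'
#' @param radii named list with entries `uncorrected` and `corrected` per
#'   probe length; default: radii of the default configurations.
#' @return data frame with columns `grin_length_mm`, `radius_uncorrected_um`,
#'   `radius_corrected_um`, `radius_fold`, `area_fold`.
#' @export
fov_fold_report <- function(radii = NULL) {
  if (is.null(radii)) {
    radii <- list(
      "6.4" = c(uncorrected = effective_fov_radius(default_optics("uncorrected-6.4")$psf),
                corrected = effective_fov_radius(default_optics("corrected-6.4")$psf)),
      "8.8" = c(uncorrected = effective_fov_radius(default_optics("uncorrected-8.8")$psf),
                corrected = effective_fov_radius(default_optics("corrected-8.8")$psf)))
  }
  do.call(rbind, lapply(names(radii), function(nm) {
    r <- radii[[nm]]
    data.frame(grin_length_mm = as.numeric(nm),
               radius_uncorrected_um = unname(r["uncorrected"]),
               radius_corrected_um = unname(r["corrected"]),
               radius_fold = round(r[["corrected"]] / r[["uncorrected"]], 2),
               area_fold = round((r[["corrected"]] / r[["uncorrected"]])^2, 1))
  }))
}
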