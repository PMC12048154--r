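# Optical-characterization fitting: Gaussian / double-Gaussian profiles of
# sub-resolved beads and films, and quartic fits of resolution, magnification
# and distance-calibration curves.

fwhm_factor <- function() 2 * sqrt(2 * log(2))

#' Fit a Gaussian to an intensity profile and return its FWHM
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2)) + b`;
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param position sample positions, um.
#' @param intensity intensities (positive peak).
#' @return a `profile_fit` list: `model = "gaussian"`, `parameters`
#'   (`A, mu, sigma, b`), `fwhm` (um), `rss`, `converged`.
#' @export
fit_gaussian_fwhm <- function(position, intensity) {
  stopifnot(length(position) >= 5, length(position) == length(intensity))
  if (var(intensity) == 0 || max(intensity) <= min(intensity)) {
    return(structure(list(model = "gaussian", parameters = NULL, fwhm = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "profile_fit"))
  }
  b0 <- min(intensity)
  w <- pmax(intensity - b0, 0)
  mu0 <- sum(position * w) / sum(w)
  s0 <- sqrt(sum(w * (position - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(position)) / 6
  resfun <- function(p)
    intensity - (p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(max(intensity) - b0, mu0, s0, b0),
                       fn = resfun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4 && is.finite(fit$deviance)
  if (!ok) {
    return(structure(list(model = "gaussian", parameters = NULL, fwhm = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "profile_fit"))
  }
  p <- setNames(fit$par, c("A", "mu", "sigma", "b"))
  p[["sigma"]] <- abs(p[["sigma"]])
  # a flat or inverted solution is not a usable peak fit
  if (p[["A"]] <= 0 || p[["sigma"]] > 10 * diff(range(position))) {
    return(structure(list(model = "gaussian", parameters = NULL, fwhm = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "profile_fit"))
  }
  structure(list(model = "gaussian", parameters = p,
                 fwhm = fwhm_factor() * p[["sigma"]],
                 rss = fit$deviance, converged = TRUE),
            class = "profile_fit")
}

# Double-Gaussian fit; returns NULL on failure.
fit_double_gaussian <- function(position, intensity) {
  b0 <- min(intensity)
  w <- pmax(intensity - b0, 0)
  ctr <- sum(position * w) / sum(w)
  span <- diff(range(position))
  s0 <- span / 10
  a0 <- max(intensity) - b0
  resfun <- function(p)
    intensity - (p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) +
                   p[4] * exp(-(position - p[5])^2 / (2 * p[6]^2)) + p[7])
  best <- NULL
  for (sep in c(1 / 8, 1 / 16, 1 / 4)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, ctr - span * sep, s0,
                                 a0, ctr + span * sep, s0, b0),
                         fn = resfun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(par = setNames(best$par, c("A1", "m1", "s1", "A2", "m2", "s2", "b")),
       rss = best$deviance)
}

#' Axial resolution from a z intensity profile
#'
#' Fits one and two Gaussian curves; the double model is selected when it
#' reduces the residual sum of squares by more than `improvement` (default
#' 20%). For a single Gaussian the resolution is its FWHM; for two Gaussians
#' it is the sum of the two half-widths at half maximum plus the distance
#' between the peaks (astigmatic probes produce two axially displaced foci).
#'
#' @param position z positions, um.
#' @param intensity intensities.
#' @param improvement required relative RSS reduction to accept the double
#'   model.
#' @return a `profile_fit` list with `model` one of `"gaussian"`,
#'   `"double_gaussian"`, `resolution` (um) and `converged`.
#' @export
axial_resolution_from_profile <- function(position, intensity,
                                          improvement = 0.2) {
  single <- fit_gaussian_fwhm(position, intensity)
  if (!single$converged) return(single)
  dbl <- fit_double_gaussian(position, intensity)
  use_double <- FALSE
  # require a real misfit of the single model before considering the double
  # one: near-zero residuals make the RSS ratio meaningless
  signal_ss <- sum((intensity - mean(intensity))^2)
  if (!is.null(dbl) && single$rss > 5e-3 * signal_ss) {
    use_double <- dbl$rss < (1 - improvement) * single$rss
  }
  if (use_double) {
    p <- dbl$par
    hwhm <- fwhm_factor() / 2 * abs(c(p[["s1"]], p[["s2"]]))
    res <- sum(hwhm) + abs(p[["m1"]] - p[["m2"]])
    structure(list(model = "double_gaussian", parameters = p,
                   resolution = res, fwhm = NA_real_,
                   rss = dbl$rss, converged = TRUE),
              class = "profile_fit")
  } else {
    single$resolution <- single$fwhm
    single
  }
}

#' Fit a quartic on the even (or even-plus-linear) basis
#'
#' Least squares of `y = a x^4 + b x^2 + c` or, with the linear term,
#' `y = a x^4 + b x^2 + f x + h` (the basis used for the distance
#' calibration).
#'
#' @param x,y data.
#' @param with_linear_term include the linear term (and rename the intercept
#'   `h`).
#' @return list `coefficients` (named `a, b, c` or `a, b, f, h`), `rss`,
#'   `residuals`, `fitted`.
#' @export
fit_quartic <- function(x, y, with_linear_term = FALSE) {
  n_coef <- if (with_linear_term) 4L else 3L
  stopifnot(length(x) == length(y), length(x) >= n_coef)
  X <- if (with_linear_term) cbind(x^4, x^2, x, 1) else cbind(x^4, x^2, 1)
  if (qr(X)$rank < n_coef) stop("rank-deficient quartic design")
  fit <- lm.fit(X, y)
  co <- fit$coefficients
  names(co) <- if (with_linear_term) c("a", "b", "f", "h") else c("a", "b", "c")
  list(coefficients = co, rss = sum(fit$residuals^2),
       residuals = fit$residuals, fitted = fit$fitted.values)
}

#' Simulated axial bead-profile through the package's own optics
#'
#' Places a sub-resolved bead (a tiny fluorescent sphere with no nucleus) at
#' the focal-surface point of a given radial distance and records the signal
#' of the pixel on top of it while the focus is stepped axially, using the
#' same excitation-scanning code that renders movies. With the
#' Gaussian-weighted excitation option the profile is the axial excitation
#' profile itself, so re-fitting it with [axial_resolution_from_profile()]
#' closes the loop between the configured PSF model and rendered data.
#'
#' @param optics an `optics_config`.
#' @param radius_um radial position of the bead, um.
#' @param z_span half-span of the focus sweep, um.
#' @param dz axial step, um.
#' @param excitation `"gaussian"` (default) or `"binary"`.
#' @param bead_radius bead radius, um.
#' @return data frame `z` (focus offset, um), `intensity`.
#' @export
bead_phantom_profile <- function(optics, radius_um, z_span = 25, dz = 0.5,
                                 excitation = "gaussian", bead_radius = 0.4) {
  ax <- psf_axes(radius_um, optics$psf)
  zg <- seq(-z_span, z_span, by = dz)
  # bead sits at the (first-shell) focal point for this radius
  zb <- focal_surface_height(radius_um, optics$focal_surface)[1]
  # tiny local volume around the bead, fine voxels
  half <- max(8, 2 * ax[, "lateral"])
  vox <- c(0.25, 0.25, 0.25)
  dims <- c(2 * half, 2 * half, 2 * z_span + 20)
  tissue <- structure(list(
    dims = dims, voxel_size = vox,
    neurons = data.frame(id = 1L, x = half, y = half, z = z_span + 10,
                         soma_radius = bead_radius, nucleus_halfwidth = 0),
    density_target = 0, realized_density = 0, seed = NULL, jammed = FALSE),
    class = "tissue_volume")
  lab <- rasterize(tissue)
  nvox <- dim(lab)
  nrm <- surface_normal(radius_um, optics$focal_surface)
  vals <- vapply(zg, function(dz0) {
    res <- cpp_scan_excitation(
      as.integer(lab), as.integer(nvox), vox, 1L,
      half, half, z_span + 10 + dz0,
      nrm[1], nrm[2], nrm[3],
      ax[, "lateral"], ax[, "axial"], identical(excitation, "binary"))
    if (length(res$shell)) sum(res$shell) / max(res$total, 1) else 0
  }, 1)
  data.frame(z = zg, intensity = vals)
}
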