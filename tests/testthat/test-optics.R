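test_that("asphere sag matches closed-form limits", {
  sphere <- asphere_profile(c = 1 / 200)
  expect_equal(asphere_sag(0, sphere), 0)
  # pure sphere: Z = R - sqrt(R^2 - r^2)
  expect_equal(asphere_sag(50, sphere), 200 - sqrt(200^2 - 50^2),
               tolerance = 1e-10)
  # paraboloid (k = -1): Z = c r^2 / 2 for any r
  parab <- asphere_profile(c = 1 / 150, k = -1)
  r <- c(10, 100, 500, 2000)
  expect_equal(asphere_sag(r, parab), r^2 / (2 * 150), tolerance = 1e-10)
  # polynomial terms add on top of the conic
  asp <- asphere_profile(c = 1 / 200, alpha = c(1e-4, -1e-9))
  expect_equal(asphere_sag(30, asp),
               asphere_sag(30, sphere) + 1e-4 * 30^2 - 1e-9 * 30^4,
               tolerance = 1e-12)
  # domain error names the admissible radius
  expect_error(asphere_sag(300, sphere), "200")
})

test_that("focal surfaces anchor at the axis and shells follow sphere sag", {
  flat <- focal_surface("polynomial", poly_coeffs = numeric(5))
  expect_equal(focal_surface_height(c(0, 10, 50), flat), c(0, 0, 0))
  sh <- focal_surface("spherical_shells", shell_radii = c(273, 2000))
  h <- focal_surface_height(100, sh)
  expect_equal(h[1, 1], 273 - sqrt(273^2 - 100^2), tolerance = 1e-12)
  expect_equal(h[1, 2], 2000 - sqrt(2000^2 - 100^2), tolerance = 1e-12)
  expect_equal(focal_surface_height(0, sh)[1, ], c(0, 0))
  expect_error(focal_surface_height(273, sh), "shell")
})

test_that("surface normals are unit vectors matching finite differences", {
  flat <- focal_surface("polynomial", poly_coeffs = numeric(5))
  expect_equal(surface_normal(37, flat), c(0, 0, 1))
  poly <- focal_surface("polynomial", poly_coeffs = c(0, 2e-4, 0, 1e-9, 0))
  expect_equal(surface_normal(0, poly), c(0, 0, 1))
  for (mod in list(poly, focal_surface("spherical_shells",
                                       shell_radii = 273))) {
    r0 <- 80
    n <- surface_normal(r0, mod, phi = 0)
    expect_equal(sum(n^2), 1, tolerance = 1e-12)
    eps <- 1e-5
    z <- function(r) {
      h <- focal_surface_height(r, mod)
      if (is.matrix(h)) h[1, 1] else h
    }
    slope_fd <- (z(r0 + eps) - z(r0 - eps)) / (2 * eps)
    tangent <- c(1, 0, slope_fd)
    expect_lt(abs(sum(n * tangent)), 1e-6)
  }
  # shell normal points toward the sphere center
  sh <- focal_surface("spherical_shells", shell_radii = 273)
  n <- surface_normal(100, sh)
  expect_equal(n, c(-100, 0, sqrt(273^2 - 100^2)) / 273, tolerance = 1e-9)
})

test_that("PSF quartics are even, positive and capped", {
  m <- psf_size_model(axial = c(1e-7, 5e-4, 6), lateral = c(0, 1e-4, 1))
  ax <- psf_axes(c(0, 30, 80), m)
  expect_equal(ax[1, ], c(lateral = 1, axial = 6))
  # even polynomial: f(r) only depends on r^2
  expect_equal(quantile(ax[, "axial"], 0),
               min(ax[, "axial"]), ignore_attr = TRUE)
  cst <- psf_size_model(axial = c(0, 0, 6), lateral = c(0, 0, 1))
  expect_true(all(psf_axes(c(0, 50, 200), cst)[, "axial"] == 6))
  capped <- psf_axes(300, m)
  expect_lte(capped[, "axial"], m$axial_max)
  bad <- psf_size_model(axial = c(0, 0, -1), lateral = c(0, 0, 1))
  expect_error(psf_axes(10, bad), "positive")
})

test_that("effective FOV radius from bisection equals a brute-force scan", {
  m <- psf_size_model(axial = c(2e-7, 8e-4, 6.2), lateral = c(0, 0, 1))
  r_bis <- effective_fov_radius(m, threshold = 10)
  scan <- seq(0, 250, by = 0.01)
  r_scan <- scan[which(2e-7 * scan^4 + 8e-4 * scan^2 + 6.2 >= 10)[1]]
  expect_lt(abs(r_bis - r_scan), 0.011)
  expect_equal(effective_fov_radius(m, threshold = 5), 0)
  expect_equal(effective_fov_radius(psf_size_model(c(0, 0, 6), c(0, 0, 1))),
               Inf)
})

test_that("magnification and distance calibration invert consistently", {
  ident <- magnification_model()
  expect_equal(magnification_factor(c(0, 50, 100), ident), c(1, 1, 1))
  expect_equal(real_distance(c(0, 40, 90), ident), c(0, 40, 90))
  m <- magnification_model(magnification = c(4e-11, 8e-6, 1),
                           distance = c(1e-11, 3e-6, 1, 0), rmax = 250)
  r <- c(0, 25, 80, 140, 200)
  round_trip <- real_distance(nominal_distance(r, m), m)
  expect_equal(round_trip, r, tolerance = 1e-6)
  # non-monotone calibration is rejected
  expect_error(magnification_model(distance = c(0, 0, -1, 0)), "monotone")
})

test_that("default distance calibration agrees with quadrature of f", {
  o <- default_optics("corrected-6.4")
  xs <- seq(0, 200, by = 0.5)
  fv <- magnification_factor(xs, o$magnification)
  g_quad <- c(0, cumsum((fv[-1] + fv[-length(fv)]) / 2 * diff(xs)))
  g_cfg <- nominal_distance(xs, o$magnification)
  expect_lt(max(abs(g_quad - g_cfg)), 0.5)
})

test_that("corrected probes have larger effective FOVs than uncorrected", {
  r_c64 <- effective_fov_radius(default_optics("corrected-6.4")$psf)
  r_u64 <- effective_fov_radius(default_optics("uncorrected-6.4")$psf)
  r_c88 <- effective_fov_radius(default_optics("corrected-8.8")$psf)
  r_u88 <- effective_fov_radius(default_optics("uncorrected-8.8")$psf)
  expect_gt(r_c64, r_u64)
  expect_gt(r_c88, r_u88)
  rep <- fov_fold_report()
  expect_equal(rep$radius_fold, c(2.17, 1.53))
  expect_equal(rep$area_fold, c(4.7, 2.3))
})

test_that("radial intensity profiles normalize at the axis and clamp", {
  p <- radial_intensity_profile(c(-1e-5, 0))
  expect_equal(p(0), 1)
  expect_true(all(p(seq(0, 500, 25)) >= 0 & p(seq(0, 500, 25)) <= 1))
  expect_equal(p(100), 1 - 1e-5 * 100^2)
})
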