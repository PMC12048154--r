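# Shared fixtures: miniature optics configurations and tissue volumes built
# in code, plus brute-force oracles kept deliberately independent of the
# package implementation paths they check.

# A flat, undistorted optics configuration over a tiny pixel grid. The edge
# radius exceeds the FOV diagonal so every pixel is scanned.
flat_optics <- function(fov_um = 16, fov_pixels = 16, lateral = 2, axial = 6,
                        vertex_depth = 10, edge_radius = 2 * fov_um) {
  structure(list(
    probe = "test-flat", corrected = TRUE,
    focal_surface = focal_surface("polynomial", poly_coeffs = numeric(5)),
    psf = psf_size_model(axial = c(0, 0, axial), lateral = c(0, 0, lateral)),
    magnification = magnification_model(nominal_pixel_size = fov_um / fov_pixels,
                                        rmax = 4 * fov_um),
    radial_intensity = radial_intensity_profile(c(0, 0)),
    fov_um = fov_um, edge_radius = edge_radius, vertex_depth = vertex_depth,
    fov_pixels = fov_pixels, nominal_pixel_size = fov_um / fov_pixels),
    class = "optics_config")
}

# Hand-built tissue volume with the given neuron table (no placement RNG).
manual_tissue <- function(neurons, dims = c(16, 16, 20),
                          voxel_size = c(0.8, 0.8, 1)) {
  neurons$id <- seq_len(nrow(neurons))
  structure(list(dims = dims, voxel_size = voxel_size, neurons = neurons,
                 density_target = 0,
                 realized_density = nrow(neurons) / (prod(dims) * 1e-9),
                 seed = NULL, jammed = FALSE),
            class = "tissue_volume")
}

# Brute-force all-pairs overlap check: smallest center gap minus radius sum.
min_pair_gap <- function(neurons) {
  d <- as.matrix(dist(neurons[, c("x", "y", "z")]))
  s <- outer(neurons$soma_radius, neurons$soma_radius, "+")
  diag(d) <- Inf
  min(d - s)
}

# Brute-force voxel oracle for the mixing weight of one pixel and one neuron:
# triple loop over a voxel bounding box, binary ellipsoid support.
oracle_pixel_weight <- function(center, normal, lat_fwhm, ax_fwhm, neuron,
                                voxel_size, nvox) {
  aL <- lat_fwhm / 2
  aA <- ax_fwhm / 2
  h <- max(aL, aA)
  tot <- 0
  hit <- 0
  occ <- 0
  for (ix in floor((center[1] - h) / voxel_size[1] - 1):
       ceiling((center[1] + h) / voxel_size[1] + 1)) {
    for (iy in floor((center[2] - h) / voxel_size[2] - 1):
         ceiling((center[2] + h) / voxel_size[2] + 1)) {
      for (iz in floor((center[3] - h) / voxel_size[3] - 1):
           ceiling((center[3] + h) / voxel_size[3] + 1)) {
        v <- c((ix + 0.5) * voxel_size[1], (iy + 0.5) * voxel_size[2],
               (iz + 0.5) * voxel_size[3])
        d <- v - center
        t <- sum(d * normal)
        l2 <- sum(d^2) - t^2
        if (l2 / aL^2 + t^2 / aA^2 > 1) next
        tot <- tot + 1
        if (ix < 0 || ix >= nvox[1] || iy < 0 || iy >= nvox[2] ||
            iz < 0 || iz >= nvox[3]) next
        dn <- v - c(neuron$x, neuron$y, neuron$z)
        r2 <- sum(dn^2)
        if (r2 <= neuron$soma_radius^2) {
          occ <- occ + 1
          if (r2 > neuron$nucleus_halfwidth^2) hit <- hit + 1
        }
      }
    }
  }
  list(weight = if (tot > 0) hit / tot else 0, total = tot, occ = occ)
}

# Sort-based percentile band mean oracle (type-7 quantiles via R's quantile).
oracle_band_mean <- function(vals, lo = 0.80, hi = 0.95) {
  q <- quantile(vals, c(lo, hi), names = FALSE, type = 7)
  sel <- vals[vals >= q[1] & vals <= q[2]]
  if (!length(sel)) sel <- vals[vals >= max(vals[vals <= q[1]])]
  mean(sel)
}

# Brute-force sliding-window percentile baseline.
oracle_running_quantile <- function(x, halfwin, p) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    w <- x[max(1, t - halfwin):min(n, t + halfwin)]
    quantile(w, p, names = FALSE, type = 7)
  }, 1)
}
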