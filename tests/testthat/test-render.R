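test_that("mixing weights equal the brute-force voxel oracle", {
  o <- flat_optics(fov_um = 16, fov_pixels = 8, lateral = 3, axial = 8,
                   vertex_depth = 10)
  n <- data.frame(x = 8, y = 8, z = 10, soma_radius = 5,
                  nucleus_halfwidth = 2)
  tv <- manual_tissue(n, dims = c(16, 16, 20))
  mx <- build_mixing_matrix(tv, o)
  lab <- rasterize(tv)
  for (p in c(1, 12, 29, 37, 64)) {
    ctr <- c(tv$dims[1] / 2 + mx$pixels$x_real[p],
             tv$dims[2] / 2 + mx$pixels$y_real[p], 10)
    orc <- oracle_pixel_weight(ctr, c(0, 0, 1), 3, 8, n[1, ],
                               tv$voxel_size, dim(lab))
    expect_equal(mx$weights[p, 1], orc$weight, tolerance = 1e-12)
    expect_equal(mx$total[p], orc$total, tolerance = 1e-12)
  }
})

test_that("mixing handles empty tissue and out-of-reach neurons", {
  o <- flat_optics()
  empty <- manual_tissue(data.frame(x = numeric(0), y = numeric(0),
                                    z = numeric(0), soma_radius = numeric(0),
                                    nucleus_halfwidth = numeric(0)))
  mx0 <- build_mixing_matrix(empty, o)
  expect_equal(sum(mx0$weights), 0)
  expect_true(all(mx0$occupancy == 0))
  # neuron deeper than focal surface + axial half-extent: zero weight
  deep <- manual_tissue(data.frame(x = 8, y = 8, z = 18, soma_radius = 3,
                                   nucleus_halfwidth = 1))
  mxd <- build_mixing_matrix(deep, o)  # focus at z=10, axial semi=3
  expect_equal(sum(mxd$weights), 0)
})

test_that("static noise maps reproduce the fitted mixture and linear laws", {
  o <- flat_optics(fov_um = 64, fov_pixels = 128, edge_radius = 20)
  tv <- manual_tissue(data.frame(x = 32, y = 32, z = 10, soma_radius = 6,
                                 nucleus_halfwidth = 3),
                      dims = c(64, 64, 20))
  mx <- build_mixing_matrix(tv, o)
  nm <- sample_static_noise_maps(noise_model(), mx, seed = 1)
  edge <- nm$regime == "edge"
  expect_gt(sum(edge), 5000)
  # mixture mean of edge means: 0.35*137.48 + 0.65*126.83 = 130.56
  mix_mean <- 0.35 * 137.48 + 0.65 * 126.83
  mix_var <- 0.35 * (48.96^2 + 137.48^2) + 0.65 * (5.02^2 + 126.83^2) -
    mix_mean^2
  expect_lt(abs(mean(nm$mean[edge]) - mix_mean),
            3 * sqrt(mix_var / sum(edge)))
  # edge SD law: clamp(-175.39 + 1.57 * mean, 0)
  expect_equal(nm$sd[edge], pmax(0, -175.39 + 1.57 * nm$mean[edge]))
  # background SD law on empty pixels: 29.91 + 7.75 sqrt(mean)
  emp <- nm$regime == "empty"
  expect_equal(nm$sd[emp], 29.91 + 7.75 * sqrt(nm$mean[emp]))
  # the law itself at mean 0 gives the intercept
  nmod <- noise_model()
  expect_equal(nmod$background_sd_sqrt[1] + nmod$background_sd_sqrt[2] * 0,
               29.91)
})

test_that("factorized rendering equals brute-force voxel rendering", {
  # noiseless: all SDs zero, constant background voxel mean
  o <- flat_optics(fov_um = 16, fov_pixels = 16, lateral = 3, axial = 8,
                   vertex_depth = 10)
  n <- data.frame(x = c(5, 14), y = c(8, 10), z = c(9, 11),
                  soma_radius = c(4.5, 3), nucleus_halfwidth = c(2, 1.5))
  tv <- manual_tissue(n, dims = c(16, 16, 20))
  lab <- rasterize(tv)
  mx <- build_mixing_matrix(tv, o)
  nz <- noiseless_noise_model(bg_meanlog = log(100))
  set.seed(5)
  traces <- matrix(100 * (1 + 0.4 * matrix(runif(2 * 30), 30, 2)), 30, 2)
  mv <- render_movie(mx, traces, noise = nz, seed = 3)
  # brute force: average voxel values over each pixel's excitation volume
  for (p in c(18, 40, 120, 136, 200)) {
    ctr <- c(tv$dims[1] / 2 + mx$pixels$x_real[p],
             tv$dims[2] / 2 + mx$pixels$y_real[p], 10)
    o1 <- oracle_pixel_weight(ctr, c(0, 0, 1), 3, 8, n[1, ],
                              tv$voxel_size, dim(lab))
    o2 <- oracle_pixel_weight(ctr, c(0, 0, 1), 3, 8, n[2, ],
                              tv$voxel_size, dim(lab))
    stopifnot(min_pair_gap(tv$neurons) >= 0)
    for (f in c(1, 17, 30)) {
      # empty voxels carry the constant background mean 100
      val <- o1$weight * traces[f, 1] + o2$weight * traces[f, 2] +
        (1 - (o1$occ + o2$occ) / max(o1$total, 1)) * 100
      expect_equal(mv$frames[p, f], val, tolerance = 1e-6)
    }
  }
})

test_that("rendered movies are reproducible and sized correctly", {
  o <- flat_optics(fov_um = 16, fov_pixels = 8)
  tv <- manual_tissue(data.frame(x = 8, y = 8, z = 10, soma_radius = 5,
                                 nucleus_halfwidth = 2))
  mx <- build_mixing_matrix(tv, o)
  traces <- matrix(1000, 30, 1)
  m1 <- render_movie(mx, traces, seed = 11)
  m2 <- render_movie(mx, traces, seed = 11)
  expect_identical(m1$frames, m2$frames)
  # 30 Hz for 1 s = 30 frames
  expect_equal(ncol(m1$frames), 30)
  # chunked rendering through a frame source matches the all-at-once movie
  src <- render_frame_source(mx, traces, seed = 11)
  expect_equal(cbind(src(1:13), src(14:30)), m1$frames, tolerance = 1e-12)
  # zero activity and zero noise: constant in time
  nz <- noiseless_noise_model(bg_meanlog = log(50))
  m3 <- render_movie(mx, traces, noise = nz, seed = 2)
  expect_equal(apply(m3$frames, 1, sd), rep(0, 64), tolerance = 1e-12)
})

test_that("corrected optics give brighter marginal neurons than uncorrected", {
  # one neuron at 90 um radial distance, rendered noiselessly through both
  # default probe models: the corrected probe concentrates excitation
  oc <- default_optics("corrected-6.4", fov_pixels = 128)
  ou <- default_optics("uncorrected-6.4", fov_pixels = 128)
  amp <- vapply(list(oc, ou), function(o) {
    rr <- real_distance(90, o$magnification)
    tv <- manual_tissue(data.frame(x = 200 + rr, y = 200,
                                   z = o$vertex_depth +
                                     mean(focal_surface_height(rr, o$focal_surface)),
                                   soma_radius = 10, nucleus_halfwidth = 5),
                        dims = c(400, 400, 170))
    mx <- build_mixing_matrix(tv, o)
    traces <- matrix(5000, 10, 1)
    nz <- noiseless_noise_model(bg_meanlog = -Inf)
    mv <- render_movie(mx, traces, noise = nz, seed = 1)
    max(mv$frames)
  }, 1)
  expect_gt(amp[1], amp[2])
})

test_that("edge-region temporal mean is stationary", {
  o <- flat_optics(fov_um = 32, fov_pixels = 32, edge_radius = 10)
  tv <- manual_tissue(data.frame(x = 16, y = 16, z = 10, soma_radius = 5,
                                 nucleus_halfwidth = 2),
                      dims = c(32, 32, 20))
  mx <- build_mixing_matrix(tv, o)
  traces <- matrix(1000, 120, 1)
  mv <- render_movie(mx, traces, seed = 21)
  edge <- mx$pixels$r_real > 10
  m_t <- colMeans(mv$frames[edge, ])
  tr <- radial_trend(seq_along(m_t), m_t)
  expect_gt(tr$p, 0.05)
})
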