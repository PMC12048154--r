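test_that("percentile-band ROI selection matches the sort-based oracle", {
  # 100 distinct values: band [80th, 95th]
  v <- sample(1:100)
  expect_equal(percentile_band_mean(v), oracle_band_mean(v))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(20:400, 1))
    expect_equal(percentile_band_mean(v), oracle_band_mean(v))
  }
  # degenerate constant distribution keeps the whole box
  expect_equal(percentile_band_mean(rep(7, 50)), 7)
})

test_that("the C++ extraction pass agrees with the R reference per frame", {
  set.seed(2)
  n <- 12
  fr <- matrix(rnorm(n * n * 5, 100, 20), n * n, 5)
  boxes <- data.frame(roi_id = 1:2, neuron_id = NA,
                      x0 = c(1, 6), x1 = c(5, 11), y0 = c(2, 5),
                      y1 = c(6, 10))
  out <- extract_traces(fr, boxes, fov_pixels = n)
  for (f in 1:5) {
    v <- fr[, f]
    roi <- vapply(1:2, function(b) {
      px <- grinsim:::box_pixels(boxes[b, ], n)
      oracle_band_mean(v[px])
    }, 1)
    bmax <- max(v[unlist(lapply(1:2, function(b)
      grinsim:::box_pixels(boxes[b, ], n)))])
    in_box <- rep(FALSE, n * n)
    for (b in 1:2) in_box[grinsim:::box_pixels(boxes[b, ], n)] <- TRUE
    sel <- !in_box & v < bmax  # no edge mask: corner mean is -Inf
    bg <- mean(v[sel])
    expect_equal(out$background[f], bg, tolerance = 1e-12)
    expect_equal(out$F[f, ], roi - bg, tolerance = 1e-12)
  }
})

test_that("an empty background set carries the previous frame forward", {
  # one box covering the whole FOV leaves no background pixels
  fr <- matrix(rnorm(16 * 3, 10), 16, 3)
  boxes <- data.frame(roi_id = 1L, neuron_id = NA, x0 = 0, x1 = 4, y0 = 0,
                      y1 = 4)
  expect_warning(out <- extract_traces(fr, boxes, fov_pixels = 4),
                 "background")
  expect_equal(out$background, rep(0, 3))
})

test_that("dF/F0 uses a sliding 20th-percentile baseline", {
  # constant positive trace: dF/F0 identically 0
  d0 <- compute_dff(rep(5, 100), frame_rate = 10)
  expect_equal(as.numeric(d0), rep(0, 100))
  # step trace: matches the brute-force windowed-percentile oracle
  f <- c(rep(10, 60), rep(20, 60)) + sin(1:120)
  d <- compute_dff(f, frame_rate = 10, window_s = 4)
  halfwin <- round(4 * 10 / 2)
  f0 <- oracle_running_quantile(f, halfwin, 0.2)
  expect_equal(as.numeric(d), (f - f0) / f0, tolerance = 1e-12)
  expect_equal(attr(d, "f0"), f0, tolerance = 1e-12)
  # window longer than the trace: global percentile everywhere
  dg <- compute_dff(f, frame_rate = 10, window_s = 1000)
  q <- quantile(f, 0.2, names = FALSE)
  expect_equal(attr(dg, "f0"), rep(q, 120), tolerance = 1e-12)
  # non-positive baseline flags the trace invalid
  dneg <- compute_dff(c(rep(-1, 30), rep(1, 21)), frame_rate = 10)
  expect_false(attr(dneg, "valid"))
  expect_true(all(is.na(dneg)))
})

test_that("peak SNR follows its definition and edge cases", {
  # zero-noise trace is flagged
  z <- c(rep(0, 100), 1, rep(0, 20))
  s <- peak_snr(z)
  expect_false(attr(s, "valid"))
  # Gaussian noise plus one transient: matches the direct formula
  set.seed(3)
  d <- rnorm(3000, 0, 0.05)
  d[1500:1510] <- d[1500:1510] + 1
  s2 <- peak_snr(d)
  q25 <- quantile(d, 0.25, names = FALSE)
  expect_equal(as.numeric(s2), max(d) / sd(d[d < q25]), tolerance = 1e-12)
  expect_true(attr(s2, "valid"))
  # invariant under affine rescaling of the trace
  s3 <- peak_snr(3.7 * d)
  expect_equal(as.numeric(s3), as.numeric(s2), tolerance = 1e-10)
  # the tested cutoff grid
  expect_equal(snr_threshold_grid(),
               c(0, 5, 10, 11, 12.5, 15, 16.5, 17.5, 20, 22.5, 25, 27.5, 30))
})

test_that("centroid calibration maps pixels to real microns", {
  o <- flat_optics(fov_um = 100, fov_pixels = 100)
  ctr <- centroid_to_um(c(50, 50), o)
  expect_equal(ctr$r_um, 0)
  # identity calibration: real equals nominal
  c2 <- centroid_to_um(c(80, 50), o)
  expect_equal(c2$r_um, 30)
  expect_equal(c2$xy_um, c(30, 0))
  # quartic calibration round-trips through the inverse
  o2 <- flat_optics(fov_um = 100, fov_pixels = 100)
  o2$magnification <- magnification_model(magnification = c(4e-11, 8e-6, 1),
                                          distance = c(1e-11, 3e-6, 1, 0),
                                          nominal_pixel_size = 1, rmax = 300)
  c3 <- centroid_to_um(c(90, 50), o2)
  expect_equal(nominal_distance(c3$r_um, o2$magnification), 40,
               tolerance = 1e-6)
})

test_that("ground-truth detection boxes the footprint bounding rectangle", {
  o <- flat_optics(fov_um = 32, fov_pixels = 32, lateral = 2, axial = 6,
                   vertex_depth = 10)
  tv <- manual_tissue(data.frame(x = c(16, 26), y = c(16, 26),
                                 z = c(10, 60), soma_radius = c(6, 6),
                                 nucleus_halfwidth = c(3, 3)),
                      dims = c(32, 32, 80))
  mx <- build_mixing_matrix(tv, o)
  det <- detect_rois(mx, detector_spec(min_weight = 0))
  # neuron 2 is far below the focal plane: no box
  expect_equal(det$neuron_id, 1L)
  px <- which(mx$weights[, 1] > 0)
  ix <- (px - 1) %% 32
  iy <- (px - 1) %/% 32
  expect_equal(c(det$x0, det$x1, det$y0, det$y1),
               c(min(ix), max(ix) + 1, min(iy), max(iy) + 1))
  # a visibility threshold shrinks or removes boxes but never widens them
  det2 <- detect_rois(mx, detector_spec(min_weight = 0.5))
  if (nrow(det2)) {
    expect_gte(det2$x0, det$x0)
    expect_lte(det2$x1, det$x1)
  }
})

test_that("blob detection finds well-separated somata on a phantom", {
  img <- matrix(0, 64, 64)
  for (d in list(c(20, 20), c(45, 40))) {
    for (i in -3:3) for (j in -3:3)
      if (i^2 + j^2 <= 9) img[d[1] + i, d[2] + j] <- 10
  }
  det <- detect_rois(detector = detector_spec("intensity_blob", blob_size = 6,
                                              blob_quantile = 0.99),
                     median_image = img)
  expect_equal(nrow(det), 2)
  cx <- (det$x0 + det$x1) / 2
  cy <- (det$y0 + det$y1) / 2
  d1 <- min(sqrt((cx - 19.5)^2 + (cy - 19.5)^2))
  d2 <- min(sqrt((cx - 44.5)^2 + (cy - 39.5)^2))
  expect_lt(d1, 7)
  expect_lt(d2, 7)
})

test_that("extraction recovers a noiseless single neuron's time course", {
  o <- flat_optics(fov_um = 24, fov_pixels = 24, lateral = 2, axial = 8,
                   vertex_depth = 10)
  tv <- manual_tissue(data.frame(x = 12, y = 12, z = 10, soma_radius = 6,
                                 nucleus_halfwidth = 3),
                      dims = c(24, 24, 20))
  mx <- build_mixing_matrix(tv, o)
  act <- simulate_activity(1, p_pair = 0, duration = 20, out_dt = 1 / 30,
                           sensor = sensor_params(baseline = 1000), seed = 7)
  nz <- noiseless_noise_model(bg_meanlog = log(100))
  src <- render_frame_source(mx, act$traces, noise = nz, seed = 1)
  ext <- extract_fov(src, mx, o, detector = detector_spec(min_weight = 0))
  expect_equal(nrow(ext$rois), 1)
  expect_gt(cor(ext$F[, 1], act$traces[1:600, 1]), 0.999)
})
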