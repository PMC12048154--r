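test_that("expected pair correlation matches a hand-computed oracle", {
  set.seed(1)
  a <- rnorm(50)
  X <- cbind(a, a + rnorm(50, 0, 0.5), rnorm(50))
  ep <- expected_pair_correlation(list(X))
  cc <- cor(X)
  vals <- cc[upper.tri(cc)]
  expect_equal(ep$mean, mean(vals))
  expect_equal(ep$sd, sd(vals))
  expect_equal(ep$threshold, mean(vals) + 3 * sd(vals))
  expect_equal(ep$n_pairs, 3)
  # multiple FOVs: mean of per-FOV means, SD across pooled pairs
  Y <- cbind(rnorm(50), rnorm(50))
  ep2 <- expected_pair_correlation(list(X, Y))
  cy <- cor(Y)[1, 2]
  expect_equal(ep2$mean, mean(c(mean(vals), cy)))
  expect_equal(ep2$sd, sd(c(vals, cy)))
  # a single pair has no spread to estimate
  expect_error(expected_pair_correlation(list(Y)), "two")
})

test_that("adjacent-pair fractions match exhaustive enumeration", {
  rois <- data.frame(
    roi_id = 1:4,
    x_um = c(0, 10, 100, 108), y_um = c(0, 0, 0, 0),
    r_um = c(0, 10, 100, 108),
    peak_snr = c(30, 12, 30, 30), snr_valid = TRUE)
  set.seed(2)
  base <- rnorm(80)
  dff <- cbind(base, base + rnorm(80, 0, 0.2), rnorm(80), rnorm(80))
  res <- adjacent_pair_analysis(rois, dff, threshold = 0.5,
                                snr_grid = c(0, 15), adjacency_um = 25)
  # pairs (1,2) and (3,4) are adjacent; (1,2) is highly correlated
  expect_equal(res$by_cutoff$n_pairs, c(2, 1))
  c12 <- cor(dff[, 1], dff[, 2])
  c34 <- cor(dff[, 3], dff[, 4])
  expect_equal(res$by_cutoff$n_above[1], sum(c(c12, c34) > 0.5))
  # at cutoff 15 ROI 2 drops out, leaving only pair (3,4)
  expect_equal(res$by_cutoff$fraction[2], as.numeric(c34 > 0.5))
  # single ROI: no pairs, fraction missing (NA, not 0)
  res1 <- adjacent_pair_analysis(rois[1, ], dff[, 1, drop = FALSE], 0.5,
                                 snr_grid = 0)
  expect_true(is.na(res1$by_cutoff$fraction))
  # pair radial distance is the midpoint distance from the FOV center
  expect_equal(sort(res$pairs$pair_r_um), c(5, 104))
  # wider adjacency criterion keeps more pairs
  res30 <- adjacent_pair_analysis(rois, dff, 0.5, snr_grid = 0,
                                  adjacency_um = 110)
  expect_gt(res30$by_cutoff$n_pairs[1], res$by_cutoff$n_pairs[1])
})

test_that("adjacent-pair counts never increase with the SNR cutoff", {
  set.seed(3)
  n <- 30
  rois <- data.frame(roi_id = 1:n, x_um = runif(n, -50, 50),
                     y_um = runif(n, -50, 50), r_um = runif(n, 0, 70),
                     peak_snr = rexp(n, 1 / 15), snr_valid = TRUE)
  dff <- matrix(rnorm(100 * n), 100, n)
  res <- adjacent_pair_analysis(rois, dff, 0.3)
  expect_true(all(diff(res$by_cutoff$n_pairs) <= 0))
})

test_that("the purity index follows its definition", {
  set.seed(4)
  X <- matrix(rnorm(600), 200, 3)
  # single source: purity 1
  p1 <- purity_glm(2 * X[, 1] + 5, X[, 1, drop = FALSE])
  expect_equal(p1$purity, 1)
  expect_equal(p1$coefficients, 2, tolerance = 1e-10)
  # coefficient arithmetic: (1,1) -> 0.5; (3,1) -> 0.9
  y11 <- X[, 1] + X[, 2] + 1
  expect_equal(purity_glm(y11, X[, 1:2])$purity, 0.5, tolerance = 1e-10)
  y31 <- 3 * X[, 1] + X[, 2]
  expect_equal(purity_glm(y31, X[, 1:2])$purity, 9 / 10, tolerance = 1e-10)
  # exact least-squares recovery
  y <- 0.8 * X[, 1] + 0.2 * X[, 2] + 0.7
  pg <- purity_glm(y, X[, 1:2])
  expect_equal(pg$coefficients, c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(pg$intercept, 0.7, tolerance = 1e-8)
  expect_equal(pg$purity, 0.64 / 0.68, tolerance = 1e-8)
  # collinear sources fall back with a warning
  Xc <- cbind(X[, 1], 2 * X[, 1])
  expect_warning(pc <- purity_glm(X[, 1], Xc), "collinear")
  expect_true(is.finite(pc$purity))
})

test_that("rescaling a regressor rescales its coefficient inversely", {
  set.seed(5)
  X <- matrix(rnorm(400), 200, 2)
  y <- X[, 1] + X[, 2] + rnorm(200, 0, 0.1)
  g0 <- purity_glm(y, X)
  g1 <- purity_glm(y, cbind(X[, 1], 5 * X[, 2]))
  # the fit itself is unchanged: coefficient of the scaled source shrinks 5x
  expect_equal(g1$coefficients[1], g0$coefficients[1], tolerance = 1e-8)
  expect_equal(g1$coefficients[2], g0$coefficients[2] / 5, tolerance = 1e-8)
  # purity is defined on raw coefficients, so it tracks the rescaling
  a <- g1$coefficients
  expect_equal(g1$purity, max(a^2) / sum(a^2), tolerance = 1e-12)
})

test_that("first-source correlation takes the maximum over sources", {
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 2]
  fs <- first_source_correlation(y, X)
  expect_equal(fs$which, 2L)
  expect_equal(fs$correlation, 1)
  y2 <- 0.5 * X[, 1] + rnorm(100)
  fs2 <- first_source_correlation(y2, X)
  expect_equal(fs2$correlation,
               max(cor(y2, X[, 1]), cor(y2, X[, 2]), cor(y2, X[, 3])))
})

test_that("radial trends handle noiseless, constant and truncated inputs", {
  x <- seq(0, 100, length.out = 30)
  # exact line
  tr <- radial_trend(x, 2 * x + 1)
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-12)
  # constant response: slope 0, p near 1
  tr0 <- radial_trend(x, rep(3, 30))
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
  expect_gte(tr0$p, 0.99)
  # range restriction drops the tail points
  set.seed(7)
  y <- 2 * x + rnorm(30)
  tr_cut <- radial_trend(x, y, x_max = 50)
  expect_equal(tr_cut$n, sum(x <= 50))
  expect_error(radial_trend(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("radial-trend confidence intervals cover a known slope", {
  set.seed(8)
  hits <- vapply(1:200, function(i) {
    x <- runif(40, 0, 100)
    y <- 0.02 * x + rnorm(40, 0, 0.5)
    fit <- radial_trend(x, y)
    abs(fit$slope - 0.02) <= qt(0.975, 38) * fit$se
  }, TRUE)
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("contributing sources require at least one pixel of overlap", {
  o <- flat_optics(fov_um = 32, fov_pixels = 32, lateral = 2, axial = 6,
                   vertex_depth = 10)
  tv <- manual_tissue(data.frame(x = c(8, 24), y = c(8, 24), z = c(10, 10),
                                 soma_radius = c(5, 5),
                                 nucleus_halfwidth = c(2, 2)),
                      dims = c(32, 32, 20))
  mx <- build_mixing_matrix(tv, o)
  boxes <- detect_rois(mx, detector_spec(min_weight = 0))
  contrib <- contributing_sources(boxes, mx)
  # each box overlaps only its own well-separated neuron
  expect_equal(contrib[[1]], 1L)
  expect_equal(contrib[[2]], 2L)
})
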