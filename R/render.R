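# Synthetic t-series assembly: static pixel x neuron mixing matrix from
# excitation-ellipsoid scanning along the focal surface(s), plus the three
# empirically fitted pixel-noise regimes, at a 30 Hz frame rate.

#' Empirical pixel-noise model
#'
#' Three regimes fitted to in vivo recordings: dark noise at the FOV edge
#' (two-component Gaussian mixture of temporal means, SD linear in the mean),
#' background noise in the empty central FOV (lognormal means, SD linear in
#' the square root of the mean), and noise added to voxels occupied by a
#' neuron (zero-mean, SD linear in the square root of the voxel mean).
#'
#' @param edge_gmm list `w`, `mean`, `sd` of the edge mixture components.
#' @param edge_sd_linear `c(p0, p1)`: edge SD = `max(0, p0 + p1 * mean)`.
#' @param background_lognormal `c(meanlog, sdlog)` (log-space parameters).
#' @param background_sd_sqrt `c(p0, p1)`: background SD = `p0 + p1 sqrt(mean)`.
#' @param roi_sd_sqrt `c(p0, p1)`: occupied-pixel (or neuron-voxel) SD =
#'   `p0 + p1 sqrt(mean)`.
#' @param level where the square-root noise laws act. All coefficients were
#'   fitted to per-pixel temporal statistics of in vivo recordings, so
#'   `"pixel"` (default) applies them to the rendered pixel value and
#'   reproduces those statistics for any excitation-volume size. `"voxel"`
#'   draws independent noise per excitation voxel and averages; pixel noise
#'   then shrinks as `1/sqrt(V)` with the excitation-volume voxel count.
#' @return a `noise_model` list.
#' @export
noise_model <- function(edge_gmm = list(w = c(0.35, 0.65),
                                        mean = c(137.48, 126.83),
                                        sd = c(48.96, 5.02)),
                        edge_sd_linear = c(p0 = -175.39, p1 = 1.57),
                        background_lognormal = c(meanlog = 6.54, sdlog = 0.78),
                        background_sd_sqrt = c(p0 = 29.91, p1 = 7.75),
                        roi_sd_sqrt = c(p0 = 322.18, p1 = 0.98),
                        level = c("pixel", "voxel")) {
  stopifnot(abs(sum(edge_gmm$w) - 1) < 1e-8)
  structure(list(edge_gmm = edge_gmm,
                 edge_sd_linear = unname(edge_sd_linear),
                 background_lognormal = unname(background_lognormal),
                 background_sd_sqrt = unname(background_sd_sqrt),
                 roi_sd_sqrt = unname(roi_sd_sqrt),
                 level = match.arg(level)),
            class = "noise_model")
}

# A noiseless variant used by oracles and phantoms: all SDs zero, background
# means degenerate at exp(meanlog).
noiseless_noise_model <- function(bg_meanlog = 6.54) {
  noise_model(edge_gmm = list(w = c(0.35, 0.65), mean = c(137.48, 126.83),
                              sd = c(0, 0)),
              edge_sd_linear = c(0, 0),
              background_lognormal = c(bg_meanlog, 0),
              background_sd_sqrt = c(0, 0), roi_sd_sqrt = c(0, 0))
}

# Pixel-center table for an optics config: nominal coordinates relative to
# the FOV center, nominal and real radial distance, intensity modulation.
pixel_table <- function(optics) {
  n <- optics$fov_pixels
  px <- optics$nominal_pixel_size
  coord <- (seq_len(n) - 0.5) * px - optics$fov_um / 2
  x <- rep(coord, times = n)
  y <- rep(coord, each = n)
  r_nom <- sqrt(x^2 + y^2)
  # fast monotone inverse of the distance calibration
  grid <- seq(0, optics$magnification$rmax, length.out = 4096)
  gn <- nominal_distance(grid, optics$magnification)
  r_real <- stats::approx(gn, grid, xout = pmin(r_nom, max(gn)),
                          rule = 2)$y
  scale <- ifelse(r_nom > 0, r_real / r_nom, 1)
  data.frame(x_nom = x, y_nom = y, r_nom = r_nom, r_real = r_real,
             x_real = x * scale, y_real = y * scale,
             intensity = optics$radial_intensity(r_real))
}

#' Build the static pixel x neuron mixing matrix
#'
#' For every pixel, an excitation ellipsoid (lateral/axial FWHM from the PSF
#' model at the pixel's real radial distance) is centered on the focal-surface
#' point and oriented along the local surface normal; every voxel within the
#' excitation volume contributes to the pixel. The weight of (pixel, neuron)
#' is the fraction of excitation-volume voxels falling in that neuron's
#' fluorescent shell. For astigmatic (two-shell) models each shell contributes
#' one excitation pass and the passes are averaged with equal weight.
#'
#' @param tissue a `tissue_volume`.
#' @param optics an `optics_config`.
#' @param excitation `"binary"` ellipsoid support (default) or `"gaussian"`
#'   weighting.
#' @param labels optional precomputed [rasterize()] output.
#' @return a `mixing_matrix` list: `weights` (sparse pixels x neurons,
#'   fraction of excitation voxels in each shell region), `occupancy`
#'   (per-pixel fraction of excitation voxels containing any neuron),
#'   `shell_counts`, `occ_counts` (sparse, voxel counts), `total` (voxels per
#'   excitation volume), `pixels` (pixel table), `n_pixels`, `n_neurons`.
#' @export
build_mixing_matrix <- function(tissue, optics,
                                excitation = c("binary", "gaussian"),
                                labels = NULL) {
  stopifnot(inherits(tissue, "tissue_volume"), inherits(optics, "optics_config"))
  excitation <- match.arg(excitation)
  if (abs(tissue$dims[1] - optics$fov_um) > 1e-9 ||
      abs(tissue$dims[2] - optics$fov_um) > 1e-9)
    stop("tissue lateral dims must match the optics FOV")
  if (is.null(labels)) labels <- rasterize(tissue)
  nvox <- dim(labels)
  n_neurons <- nrow(tissue$neurons)
  ptab <- pixel_table(optics)
  npx <- nrow(ptab)
  ax <- psf_axes(ptab$r_real, optics$psf)
  fs <- optics$focal_surface
  n_shells <- if (fs$kind == "spherical_shells") length(fs$shell_radii) else 1L
  phi <- atan2(ptab$y_real, ptab$x_real)
  cx <- tissue$dims[1] / 2 + ptab$x_real
  cy <- tissue$dims[2] / 2 + ptab$y_real
  # pixels beyond the circular FOV carry only dark noise; skip their scan
  act_px <- which(ptab$r_real <= optics$edge_radius)
  acc <- NULL
  for (sh in seq_len(n_shells)) {
    zh <- focal_surface_height(ptab$r_real[act_px], fs)
    zh <- if (is.matrix(zh)) zh[, sh] else zh
    slope <- focal_surface_slope(ptab$r_real[act_px], fs, shell = sh)
    nn <- cbind(-slope * cos(phi[act_px]), -slope * sin(phi[act_px]), 1)
    nn <- nn / sqrt(rowSums(nn^2))
    res <- cpp_scan_excitation(as.integer(labels), as.integer(nvox),
                               tissue$voxel_size, n_neurons,
                               cx[act_px], cy[act_px],
                               optics$vertex_depth + zh,
                               nn[, 1], nn[, 2], nn[, 3],
                               ax[act_px, "lateral"], ax[act_px, "axial"],
                               excitation == "binary")
    m_shell <- Matrix::sparseMatrix(i = act_px[res$i], j = res$j,
                                    x = res$shell,
                                    dims = c(npx, max(n_neurons, 1)))
    m_occ <- Matrix::sparseMatrix(i = act_px[res$i], j = res$j, x = res$occ,
                                  dims = c(npx, max(n_neurons, 1)))
    total <- numeric(npx)
    total[act_px] <- res$total
    if (is.null(acc)) {
      acc <- list(shell = m_shell, occ = m_occ, total = total)
    } else {
      acc$shell <- acc$shell + m_shell
      acc$occ <- acc$occ + m_occ
      acc$total <- acc$total + total
    }
  }
  shell_counts <- acc$shell / n_shells
  occ_counts <- acc$occ / n_shells
  total <- acc$total / n_shells
  weights <- shell_counts / pmax(total, 1e-12)
  occupancy <- as.numeric(Matrix::rowSums(occ_counts)) / pmax(total, 1e-12)
  structure(list(weights = weights, occupancy = occupancy,
                 shell_counts = shell_counts, occ_counts = occ_counts,
                 total = total, pixels = ptab, n_pixels = npx,
                 n_neurons = n_neurons, excitation = excitation,
                 fov_pixels = optics$fov_pixels,
                 edge_radius = optics$edge_radius),
            class = "mixing_matrix")
}

#' Sample the static per-pixel noise maps
#'
#' Edge pixels (real radial distance beyond the edge radius) get a temporal
#' mean drawn from the two-component Gaussian mixture and an SD linear in the
#' mean (clamped at zero). Central pixels get, per empty excitation voxel, a
#' mean drawn from the lognormal background distribution with SD linear in
#' the square root of the mean; the per-voxel draws are aggregated into the
#' pixel-level background mean contribution and noise variance.
#'
#' @param noise a [noise_model()].
#' @param mixing a [build_mixing_matrix()] result.
#' @param seed optional integer seed.
#' @return a `noise_maps` list: `regime` (`"edge"`, `"empty"`, `"occupied"`),
#'   `mean` (per-frame expected pixel value, excluding neuron signal),
#'   `sd` (per-frame pixel SD, excluding the neuron-voxel term),
#'   `occ_var_coeff` fields used at render time.
#' @export
sample_static_noise_maps <- function(noise, mixing, seed = NULL) {
  stopifnot(inherits(noise, "noise_model"), inherits(mixing, "mixing_matrix"))
  npx <- mixing$n_pixels
  r <- mixing$pixels$r_real
  occ_tot <- as.numeric(Matrix::rowSums(mixing$occ_counts))
  edge <- r > mixing$edge_radius
  occupied <- !edge & occ_tot > 0
  regime <- ifelse(edge, "edge", ifelse(occupied, "occupied", "empty"))
  mean_map <- numeric(npx)
  sd_map <- numeric(npx)
  with_seed(seed, {
    # edge: GMM mean, SD linear in mean
    ne <- sum(edge)
    if (ne) {
      comp <- sample.int(2, ne, replace = TRUE, prob = noise$edge_gmm$w)
      mu <- rnorm(ne, noise$edge_gmm$mean[comp], noise$edge_gmm$sd[comp])
      mean_map[edge] <- mu
      sd_map[edge] <- pmax(0, noise$edge_sd_linear[1] +
                             noise$edge_sd_linear[2] * mu)
    }
    # empty center: one lognormal mean per pixel
    emp <- !edge & !occupied
    nc <- sum(emp)
    if (nc) {
      mu <- rlnorm(nc, noise$background_lognormal[1],
                   noise$background_lognormal[2])
      mean_map[emp] <- mu
      sd_map[emp] <- noise$background_sd_sqrt[1] +
        noise$background_sd_sqrt[2] * sqrt(mu)
    }
    # occupied center: aggregate per-empty-voxel lognormal draws
    idx <- which(occupied)
    if (length(idx)) {
      n_empty <- pmax(0, round(mixing$total[idx] - occ_tot[idx]))
      tot_draws <- sum(n_empty)
      mu_all <- rlnorm(tot_draws, noise$background_lognormal[1],
                       noise$background_lognormal[2])
      sd_all <- noise$background_sd_sqrt[1] +
        noise$background_sd_sqrt[2] * sqrt(mu_all)
      sum_mu <- numeric(length(idx))
      sum_var <- numeric(length(idx))
      if (tot_draws) {
        grp <- rep.int(seq_along(idx), n_empty)
        nz <- which(n_empty > 0)
        sum_mu[nz] <- rowsum(mu_all, grp, reorder = TRUE)[, 1]
        sum_var[nz] <- rowsum(sd_all^2, grp, reorder = TRUE)[, 1]
      }
      tot <- pmax(mixing$total[idx], 1e-12)
      mean_map[idx] <- sum_mu / tot          # empty-voxel contribution
      sd_map[idx] <- sqrt(sum_var) / tot     # empty-voxel noise only
    }
  })
  structure(list(regime = regime, mean = mean_map, sd = sd_map),
            class = "noise_maps")
}

# Static per-pixel quantities reused across frames. Two modulation modes:
#
# * "signal" (default): the radial excitation-efficiency profile modulates the
#   fluorescence signal and the background it excites, the square-root noise
#   laws are evaluated on the *modulated* (observed) pixel means, and the edge
#   dark noise -- a detector property -- is not modulated at all. This is the
#   physically consistent reading: dimmer marginal pixels keep the additive
#   noise floor and lose SNR.
# * "full": the modulation multiplies the complete pixel value (signal,
#   background and noise draws alike).
#
# At the default pixel noise level the occupied-pixel SD follows the fitted
# ROI-pixel law on the pixel's own mean intensity; at the voxel level it
# aggregates independent per-voxel draws (SD shrinking with the excitation
# volume).
render_static <- function(mixing, noise, noise_maps, traces, n_frames,
                          intensity_mode = "signal") {
  neuron_means <- colMeans(traces[seq_len(n_frames), , drop = FALSE])
  occupied <- noise_maps$regime == "occupied"
  edge <- noise_maps$regime == "edge"
  intens <- mixing$pixels$intensity
  voxel_level <- identical(noise$level %||% "pixel", "voxel")
  if (intensity_mode == "full") {
    sd_total <- noise_maps$sd
    if (voxel_level) {
      occ_sd <- occupied_noise_sd(mixing, noise, neuron_means)
      sd_total[occupied] <- sqrt(noise_maps$sd[occupied]^2 +
                                   occ_sd[occupied]^2)
    } else {
      sig_mean <- as.numeric(mixing$weights %*% neuron_means)
      m_tot <- pmax(noise_maps$mean + sig_mean, 0)
      sd_total[occupied] <- pmax(0, noise$roi_sd_sqrt[1] +
                                   noise$roi_sd_sqrt[2] * sqrt(m_tot[occupied]))
    }
    return(list(mean_eff = noise_maps$mean * intens,
                sd_eff = sd_total * intens, intens = intens))
  }
  # "signal" mode
  mean_eff <- ifelse(edge, noise_maps$mean, noise_maps$mean * intens)
  sd_eff <- noise_maps$sd                       # edge: dark noise as fitted
  emp <- noise_maps$regime == "empty"
  sd_eff[emp] <- pmax(0, noise$background_sd_sqrt[1] +
                        noise$background_sd_sqrt[2] *
                          sqrt(pmax(noise_maps$mean[emp] * intens[emp], 0)))
  sig_mean <- as.numeric(mixing$weights %*% neuron_means)
  m_obs <- pmax((noise_maps$mean + sig_mean) * intens, 0)
  if (voxel_level) {
    occ_sd <- occupied_noise_sd(mixing, noise, neuron_means)
    sd_eff[occupied] <- sqrt((noise_maps$sd[occupied]^2 +
                                occ_sd[occupied]^2)) * intens[occupied]
  } else {
    sd_eff[occupied] <- pmax(0, noise$roi_sd_sqrt[1] +
                               noise$roi_sd_sqrt[2] * sqrt(m_obs[occupied]))
  }
  list(mean_eff = mean_eff, sd_eff = sd_eff, intens = intens)
}

# Per-pixel SD contribution of neuron-occupied voxels, given per-neuron mean
# voxel intensities (shell voxels at the neuron's mean fluorescence, nucleus
# voxels dark).
occupied_noise_sd <- function(mixing, noise, neuron_means) {
  p0 <- noise$roi_sd_sqrt[1]
  p1 <- noise$roi_sd_sqrt[2]
  sd_shell <- (p0 + p1 * sqrt(pmax(neuron_means, 0)))^2
  nuc_counts <- mixing$occ_counts - mixing$shell_counts
  var_px <- as.numeric(mixing$shell_counts %*% sd_shell) +
    as.numeric(Matrix::rowSums(nuc_counts)) * p0^2
  sqrt(var_px) / pmax(mixing$total, 1e-12)
}

#' Render a synthetic movie
#'
#' Per frame and pixel: edge and empty-center pixels draw from their static
#' normal distributions; occupied pixels average the excitation-volume voxels
#' (neuron fluorescence plus zero-mean noise for neuron voxels, static
#' background draws for empty voxels), which factorizes into a sparse
#' mixing-matrix product plus aggregated Gaussian noise. The radial
#' intensity modulation is applied according to `intensity_mode`.
#'
#' @param mixing a [build_mixing_matrix()] result.
#' @param traces frame-rate fluorescence matrix (frames x neurons), e.g.
#'   [spikes_to_fluorescence()] with `out_dt = 1/frame_rate`.
#' @param noise a [noise_model()].
#' @param noise_maps optional precomputed [sample_static_noise_maps()].
#' @param frame_rate Hz (default 30).
#' @param duration seconds; defaults to the full trace length.
#' @param seed integer seed (per-frame noise substreams).
#' @param intensity_mode `"signal"` (default: modulation applies to the
#'   excited fluorescence and background, noise SD follows the observed
#'   modulated mean, edge dark noise untouched) or `"full"` (modulation
#'   multiplies the complete pixel value including noise).
#' @param frames optional integer vector of frame indices to render.
#' @param static optional precomputed static maps (internal; see
#'   [render_frame_source()]).
#' @return a `synthetic_movie` list: `frames` (pixels x time matrix),
#'   `frame_rate`, `duration`, `fov_pixels`, plus the static maps used.
#' @export
render_movie <- function(mixing, traces, noise = noise_model(),
                         noise_maps = NULL, frame_rate = 30, duration = NULL,
                         seed = NULL, intensity_mode = c("signal", "full"),
                         frames = NULL, static = NULL) {
  stopifnot(inherits(mixing, "mixing_matrix"))
  intensity_mode <- match.arg(intensity_mode)
  n_frames_avail <- nrow(traces)
  duration <- duration %||% (n_frames_avail / frame_rate)
  n_frames <- as.integer(round(duration * frame_rate))
  if (n_frames > n_frames_avail) stop("activity shorter than movie duration")
  if (is.null(frames)) frames <- seq_len(n_frames)
  if (is.null(noise_maps))
    noise_maps <- sample_static_noise_maps(
      noise, mixing,
      seed = if (is.null(seed)) NULL else substream_seed(seed, "noisemap"))
  if (is.null(static))
    static <- render_static(mixing, noise, noise_maps, traces, n_frames,
                            intensity_mode)
  npx <- mixing$n_pixels
  out <- as.matrix(mixing$weights %*% t(traces[frames, , drop = FALSE]))
  out <- out * static$intens
  out <- out + static$mean_eff
  # noise streams are tied to fixed 128-frame blocks of the absolute frame
  # index, so any chunking of the render reproduces the same movie
  block <- 128L
  for (b in unique((frames - 1L) %/% block)) {
    in_b <- which((frames - 1L) %/% block == b)
    zb <- if (is.null(seed)) matrix(rnorm(npx * block), npx, block) else
      with_seed(substream_seed(seed, "noiseblock", b),
                matrix(rnorm(npx * block), npx, block))
    out[, in_b] <- out[, in_b] +
      zb[, (frames[in_b] - 1L) %% block + 1L, drop = FALSE] * static$sd_eff
    rm(zb)
  }
  structure(list(frames = out, frame_rate = frame_rate,
                 duration = length(frames) / frame_rate,
                 fov_pixels = mixing$fov_pixels, frame_index = frames,
                 noise_maps = noise_maps, intensity_mode = intensity_mode,
                 seed = seed),
            class = "synthetic_movie")
}

#' Frame-chunk generator for large movies
#'
#' Same computation as [render_movie()] but returned as a function
#' `source(frame_indices)` producing pixel x frame matrices on demand, so
#' full-length movies never need to be materialized. Noise is drawn from
#' per-frame substreams, so the output is independent of the chunking.
#'
#' @inheritParams render_movie
#' @return function mapping an integer frame-index vector to a matrix, with
#'   attributes `n_frames`, `noise_maps`, `fov_pixels`.
#' @export
render_frame_source <- function(mixing, traces, noise = noise_model(),
                                noise_maps = NULL, frame_rate = 30,
                                duration = NULL, seed = NULL,
                                intensity_mode = c("signal", "full")) {
  intensity_mode <- match.arg(intensity_mode)
  duration <- duration %||% (nrow(traces) / frame_rate)
  n_frames <- as.integer(round(duration * frame_rate))
  if (is.null(noise_maps))
    noise_maps <- sample_static_noise_maps(
      noise, mixing,
      seed = if (is.null(seed)) NULL else substream_seed(seed, "noisemap"))
  static <- render_static(mixing, noise, noise_maps, traces, n_frames)
  src <- function(frame_idx) {
    render_movie(mixing, traces, noise, noise_maps, frame_rate,
                 duration = NULL, seed = seed,
                 intensity_mode = intensity_mode, frames = frame_idx,
                 static = static)$frames
  }
  attr(src, "n_frames") <- n_frames
  attr(src, "noise_maps") <- noise_maps
  attr(src, "fov_pixels") <- mixing$fov_pixels
  src
}

#' Write a movie as multi-page TIFF with a JSON metadata sidecar
#'
#' @param movie a `synthetic_movie`.
#' @param path output TIFF path.
#' @param meta optional list embedded in `<path>.json`.
#' @export
write_movie_tiff <- function(movie, path, meta = list()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  n <- movie$fov_pixels
  lo <- min(movie$frames)
  hi <- max(movie$frames)
  pages <- lapply(seq_len(ncol(movie$frames)), function(k) {
    m <- matrix((movie$frames[, k] - lo) / max(hi - lo, 1e-12), n, n)
    t(m)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(c(list(frame_rate = movie$frame_rate,
                              duration = movie$duration,
                              intensity_range = c(lo, hi),
                              seed = movie$seed), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
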