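# Orchestration: full simulate -> render -> extract -> metrics experiments,
# paired corrected/uncorrected comparisons, reproducible seed substreams and
# tabular export.

#' Experiment configuration
#'
#' Bundles the tissue, activity, optics, noise and detection settings of one
#' simulated imaging experiment (one probe type, several FOVs). Tissue and
#' activity substreams depend only on (seed, fov), not on the probe, so
#' corrected and uncorrected experiments sharing a seed image the same ground
#' truth (a paired design).
#'
#' @param probe probe type, see [default_optics()].
#' @param n_fovs number of simulated FOVs (13 for the 6.4 mm probes and 15
#'   for the 8.8 mm probes in the full-scale design).
#' @param duration movie duration, seconds.
#' @param fov_pixels pixels per FOV side.
#' @param frame_rate Hz.
#' @param density_target cells per mm^3.
#' @param p_pair pairing probability.
#' @param total_rate per-neuron rate, Hz.
#' @param shared_rate shared-process rate, Hz.
#' @param sensor a [sensor_params()] list (baseline in movie intensity units).
#' @param noise a [noise_model()].
#' @param detector a [detector_spec()].
#' @param excitation `"binary"` or `"gaussian"`.
#' @param seed master integer seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(probe = "corrected-6.4",
                              n_fovs = if (grepl("6.4", probe)) 13L else 15L,
                              duration = 300, fov_pixels = 512,
                              frame_rate = 30, density_target = 26.8e4,
                              p_pair = 0.05, total_rate = 0.3,
                              shared_rate = shared_rate_default(),
                              sensor = sensor_params(baseline = 5000),
                              noise = noise_model(),
                              detector = detector_spec(),
                              excitation = "binary", seed = 1L) {
  structure(list(probe = probe, n_fovs = as.integer(n_fovs),
                 duration = duration, fov_pixels = fov_pixels,
                 frame_rate = frame_rate, density_target = density_target,
                 p_pair = p_pair, total_rate = total_rate,
                 shared_rate = shared_rate, sensor = sensor, noise = noise,
                 detector = detector, excitation = excitation,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Simulate and analyze one FOV
#'
#' Runs the full pipeline for FOV number `fov`: tissue placement, activity
#' simulation, mixing-matrix construction, streamed rendering, ROI detection
#' and trace extraction.
#'
#' @param config an [experiment_config()].
#' @param fov FOV index.
#' @return list `rois` (ROI table with calibrated positions and peak SNR),
#'   `dff` (frames x ROI), `gt_traces` (frames x contributing sources, column
#'   names = neuron ids), `contributing` (per-ROI neuron-id vectors),
#'   `n_neurons`, `realized_density`, `fov`, `probe`.
#' @export
run_fov <- function(config, fov = 1L) {
  optics <- default_optics(config$probe, fov_pixels = config$fov_pixels)
  depth <- if (grepl("6.4", config$probe)) 170 else 200
  tissue <- place_neurons(dims = c(optics$fov_um, optics$fov_um, depth),
                          density_target = config$density_target,
                          seed = substream_seed(config$seed, "tissue", fov))
  act <- simulate_activity(
    n_neurons = nrow(tissue$neurons), p_pair = config$p_pair,
    total_rate = config$total_rate, duration = config$duration,
    shared_rate = config$shared_rate, sensor = config$sensor,
    out_dt = 1 / config$frame_rate,
    seed = substream_seed(config$seed, "activity", fov))
  mixing <- build_mixing_matrix(tissue, optics, excitation = config$excitation)
  src <- render_frame_source(
    mixing, act$traces, config$noise, frame_rate = config$frame_rate,
    duration = config$duration,
    seed = substream_seed(config$seed, paste0("render-", config$probe), fov))
  ext <- extract_fov(src, mixing, optics, detector = config$detector,
                     frame_rate = config$frame_rate)
  contrib <- contributing_sources(ext$boxes, mixing)
  visible <- which(Matrix::colSums(mixing$weights) > 0)
  gt <- act$traces[seq_len(nrow(ext$dff)), visible, drop = FALSE]
  colnames(gt) <- as.character(visible)
  list(rois = cbind(probe = config$probe, fov = fov, ext$rois),
       dff = ext$dff, gt_traces = gt, contributing = contrib,
       n_neurons = nrow(tissue$neurons),
       realized_density = tissue$realized_density,
       fov = fov, probe = config$probe)
}

#' Run a full experiment (all FOVs of one probe type)
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; per-FOV ROI tables and a manifest are
#'   written there as CSV/JSON.
#' @return an `experiment_result` list: `fovs` (list of [run_fov()] results),
#'   `rois` (pooled ROI table), `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  fovs <- lapply(seq_len(config$n_fovs), function(k) {
    r <- run_fov(config, k)
    gc(FALSE)
    cpp_release_memory()
    r
  })
  rois <- do.call(rbind, lapply(fovs, `[[`, "rois"))
  res <- structure(list(fovs = fovs, rois = rois, config = config),
                   class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rois, file.path(out_dir, paste0("rois_", config$probe, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(probe = config$probe, n_fovs = config$n_fovs,
           duration = config$duration, fov_pixels = config$fov_pixels,
           seed = config$seed, shared_rate = config$shared_rate,
           n_neurons = vapply(fovs, `[[`, 1, "n_neurons"),
           realized_density = vapply(fovs, `[[`, 1, "realized_density"),
           package_version = as.character(utils::packageVersion("grinsim"))),
      file.path(out_dir, paste0("manifest_", config$probe, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Per-condition metric tables from an experiment
#'
#' Computes the ROI-count SNR sweep, the expected-correlation threshold, the
#' pooled adjacent-pair analysis, per-ROI purity and first-source
#' correlations (peak SNR > `snr_min`).
#'
#' @param res an `experiment_result`.
#' @param snr_grid peak-SNR cutoffs.
#' @param adjacency_um adjacency criterion, um.
#' @param snr_min SNR filter for purity / first-source analyses.
#' @param max_expected_sources cap on the per-FOV source count entering the
#'   expected-correlation estimate (an evenly spaced subset; the all-pairs
#'   mean and SD are insensitive to subsetting while the full quadratic
#'   correlation matrix is not affordable for thousands of sources).
#' @return list `roi_counts`, `expected`, `adjacent`, `purity`,
#'   `first_source`.
#' @export
experiment_metrics <- function(res, snr_grid = snr_threshold_grid(),
                               adjacency_um = 25, snr_min = 10,
                               max_expected_sources = 600) {
  probe <- res$config$probe
  # ROI counts per cutoff (mean over FOVs and total)
  counts <- do.call(rbind, lapply(snr_grid, function(ct) {
    per_fov <- vapply(res$fovs, function(fv)
      sum(fv$rois$snr_valid & fv$rois$peak_snr > ct), 1)
    data.frame(probe = probe, cutoff = ct, mean_count = mean(per_fov),
               total = sum(per_fov))
  }))
  expected <- expected_pair_correlation(lapply(res$fovs, function(fv) {
    gt <- fv$gt_traces
    if (ncol(gt) > max_expected_sources)
      gt <- gt[, round(seq(1, ncol(gt), length.out = max_expected_sources)),
               drop = FALSE]
    gt
  }))
  # pooled adjacent pairs: pairs are formed within FOVs
  adj_fov <- lapply(res$fovs, function(fv)
    adjacent_pair_analysis(fv$rois, fv$dff, expected$threshold, snr_grid,
                           adjacency_um)$by_cutoff)
  adjacent <- do.call(rbind, lapply(seq_along(snr_grid), function(i) {
    np <- sum(vapply(adj_fov, function(a) a$n_pairs[i], 1))
    na_ <- sum(vapply(adj_fov, function(a) a$n_above[i], 1))
    data.frame(probe = probe, cutoff = snr_grid[i], n_pairs = np,
               n_above = na_,
               fraction = if (np > 0) na_ / np else NA_real_)
  }))
  # purity and first-source correlation per ROI with SNR > snr_min
  pur_rows <- list()
  fs_rows <- list()
  for (fv in res$fovs) {
    sel <- which(fv$rois$snr_valid & is.finite(fv$rois$peak_snr) &
                   fv$rois$peak_snr > snr_min)
    for (i in sel) {
      ids <- fv$contributing[[i]]
      ids <- ids[as.character(ids) %in% colnames(fv$gt_traces)]
      if (!length(ids)) next
      X <- fv$gt_traces[, as.character(ids), drop = FALSE]
      pg <- suppressWarnings(purity_glm(fv$dff[, i], X))
      fsc <- first_source_correlation(fv$dff[, i], X)
      pur_rows[[length(pur_rows) + 1]] <-
        data.frame(probe = probe, fov = fv$fov, roi_id = fv$rois$roi_id[i],
                   r_um = fv$rois$r_um[i], k = pg$k, purity = pg$purity)
      fs_rows[[length(fs_rows) + 1]] <-
        data.frame(probe = probe, fov = fv$fov, roi_id = fv$rois$roi_id[i],
                   r_um = fv$rois$r_um[i], correlation = fsc$correlation)
    }
  }
  list(roi_counts = counts, expected = expected,
       adjacent = adjacent,
       purity = if (length(pur_rows)) do.call(rbind, pur_rows) else NULL,
       first_source = if (length(fs_rows)) do.call(rbind, fs_rows) else NULL)
}

#' Compare corrected and uncorrected conditions
#'
#' Runs [experiment_metrics()] on both experiments and assembles the
#' cross-condition statistics: purity-vs-radius slopes (full and common
#' radial range) with a slope-difference permutation test, first-source
#' correlation medians with a rank test, and the adjacent-pair fraction
#' tables.
#'
#' @param res_corrected,res_uncorrected `experiment_result` objects.
#' @param snr_grid,adjacency_um,snr_min see [experiment_metrics()].
#' @param seed seed for the permutation tests.
#' @return a `comparison_result` list.
#' @export
compare_conditions <- function(res_corrected, res_uncorrected,
                               snr_grid = snr_threshold_grid(),
                               adjacency_um = 25, snr_min = 10, seed = 1L) {
  mc <- experiment_metrics(res_corrected, snr_grid, adjacency_um, snr_min)
  mu <- experiment_metrics(res_uncorrected, snr_grid, adjacency_um, snr_min)
  out <- list(corrected = mc, uncorrected = mu)
  if (!is.null(mc$purity) && !is.null(mu$purity)) {
    pc <- mc$purity[is.finite(mc$purity$purity), ]
    pu <- mu$purity[is.finite(mu$purity$purity), ]
    common_max <- min(max(pc$r_um), max(pu$r_um))
    out$purity_trend <- list(
      corrected = radial_trend(pc$r_um, pc$purity, seed = seed),
      uncorrected = radial_trend(pu$r_um, pu$purity, seed = seed),
      corrected_common = radial_trend(pc$r_um, pc$purity, x_max = common_max,
                                      seed = seed),
      uncorrected_common = radial_trend(pu$r_um, pu$purity,
                                        x_max = common_max, seed = seed),
      common_max_um = common_max,
      slope_difference = perm_test_slope_difference(
        pc$r_um[pc$r_um <= common_max], pc$purity[pc$r_um <= common_max],
        pu$r_um[pu$r_um <= common_max], pu$purity[pu$r_um <= common_max],
        seed = seed))
  }
  if (!is.null(mc$first_source) && !is.null(mu$first_source)) {
    out$first_source <- list(
      median_corrected = median(mc$first_source$correlation),
      median_uncorrected = median(mu$first_source$correlation),
      rank_p = rank_test(mc$first_source$correlation,
                         mu$first_source$correlation))
  }
  structure(out, class = "comparison_result")
}

#' Write comparison tables as tidy CSV plus a summary JSON
#'
#' @param cmp a `comparison_result`.
#' @param out_dir output directory.
#' @export
write_comparison <- function(cmp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in c("corrected", "uncorrected")) {
    m <- cmp[[cond]]
    write.csv(m$roi_counts,
              file.path(out_dir, paste0("roi_counts_", cond, ".csv")),
              row.names = FALSE)
    write.csv(m$adjacent,
              file.path(out_dir, paste0("adjacent_pairs_", cond, ".csv")),
              row.names = FALSE)
    if (!is.null(m$purity))
      write.csv(m$purity, file.path(out_dir, paste0("purity_", cond, ".csv")),
                row.names = FALSE)
    if (!is.null(m$first_source))
      write.csv(m$first_source,
                file.path(out_dir, paste0("first_source_", cond, ".csv")),
                row.names = FALSE)
  }
  summary <- list(
    expected_threshold = list(corrected = cmp$corrected$expected$threshold,
                              uncorrected = cmp$uncorrected$expected$threshold))
  if (!is.null(cmp$purity_trend))
    summary$purity_trend <- list(
      slope_corrected = cmp$purity_trend$corrected$slope,
      slope_uncorrected = cmp$purity_trend$uncorrected$slope,
      slope_corrected_common = cmp$purity_trend$corrected_common$slope,
      slope_uncorrected_common = cmp$purity_trend$uncorrected_common$slope,
      common_max_um = cmp$purity_trend$common_max_um,
      slope_difference_p = cmp$purity_trend$slope_difference$p)
  if (!is.null(cmp$first_source)) summary$first_source <- cmp$first_source
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
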