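# ROI detection and trace extraction: percentile-band ROIs inside bounding
# boxes, frame-wise background subtraction, sliding-percentile dF/F0 baseline
# and peak SNR.

#' Peak-SNR threshold grid
#'
#' The grid of peak-SNR cutoffs swept in the ROI-count and pair-correlation
#' analyses.
#' @return numeric vector.
#' @export
snr_threshold_grid <- function() {
  c(0, 5, 10, 11, 12.5, 15, 16.5, 17.5, 20, 22.5, 25, 27.5, 30)
}

#' Detector specification
#'
#' The trained-network detector used on real recordings is out of scope here;
#' detection is pluggable. `"ground_truth_projection"` (default, deterministic)
#' draws the bounding rectangle of each neuron's mixing-matrix footprint above
#' `min_weight`. The default `min_weight = 0.1` defines a detectable cell as
#' one contributing at least 10% of the excitation volume of some pixel:
#' neurons only grazed by a large aberrated excitation volume are smeared
#' into the background of the median projection and are not cells a detector
#' could draw a box around (set `min_weight = 0` to box every neuron with any
#' nonzero footprint). `"intensity_blob"` finds local maxima of the median
#' intensity projection. `"external_boxes"` accepts a user-supplied box
#' table.
#'
#' @param mode detector mode.
#' @param min_weight visibility threshold on the per-pixel weight
#'   (ground-truth mode).
#' @param blob_size box half-size in pixels (blob mode).
#' @param blob_quantile detection threshold quantile (blob mode).
#' @param boxes data frame for `"external_boxes"`.
#' @return a `detector_spec` list.
#' @export
detector_spec <- function(mode = c("ground_truth_projection", "intensity_blob",
                                   "external_boxes"),
                          min_weight = 0.1, blob_size = 8L,
                          blob_quantile = 0.995, boxes = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, min_weight = min_weight, blob_size = blob_size,
                 blob_quantile = blob_quantile, boxes = boxes),
            class = "detector_spec")
}

#' Detect ROIs as rectangular bounding boxes
#'
#' @param mixing a `mixing_matrix` (required for ground-truth mode).
#' @param detector a [detector_spec()].
#' @param median_image optional median-projection matrix (blob mode).
#' @return data frame `roi_id, neuron_id, x0, x1, y0, y1` with 0-based
#'   half-open pixel bounds (`x` = column, `y` = row of the FOV grid).
#' @export
detect_rois <- function(mixing = NULL, detector = detector_spec(),
                        median_image = NULL) {
  empty <- data.frame(roi_id = integer(0), neuron_id = integer(0),
                      x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0))
  if (detector$mode == "external_boxes") {
    b <- detector$boxes
    stopifnot(all(c("x0", "x1", "y0", "y1") %in% names(b)))
    b$roi_id <- seq_len(nrow(b))
    if (is.null(b$neuron_id)) b$neuron_id <- NA_integer_
    return(b[, c("roi_id", "neuron_id", "x0", "x1", "y0", "y1")])
  }
  if (detector$mode == "ground_truth_projection") {
    stopifnot(inherits(mixing, "mixing_matrix"))
    n <- mixing$fov_pixels
    w <- mixing$weights
    out <- empty
    for (j in seq_len(ncol(w))) {
      px <- which(w[, j] >= pmax(detector$min_weight, 1e-12))
      if (!length(px)) next
      ix <- (px - 1) %% n          # x index, 0-based
      iy <- (px - 1) %/% n         # y index, 0-based
      out <- rbind(out, data.frame(roi_id = nrow(out) + 1L, neuron_id = j,
                                   x0 = min(ix), x1 = max(ix) + 1L,
                                   y0 = min(iy), y1 = max(iy) + 1L))
    }
    if (nrow(out) && any(out$x1 - out$x0 < 1)) stop("degenerate box")
    return(out)
  }
  # intensity_blob on the median projection (matrix indexed [x, y])
  stopifnot(is.matrix(median_image))
  n <- nrow(median_image)
  thr <- quantile(median_image, detector$blob_quantile)
  cand <- which(median_image >= thr, arr.ind = TRUE)
  ord <- order(median_image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  taken <- matrix(FALSE, n, ncol(median_image))
  out <- empty
  h <- detector$blob_size
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]   # x, y (1-based)
    if (taken[i, j]) next
    x0 <- max(0L, i - 1L - h); x1 <- min(n, i + h)
    y0 <- max(0L, j - 1L - h); y1 <- min(ncol(median_image), j + h)
    taken[(x0 + 1):x1, (y0 + 1):y1] <- TRUE
    out <- rbind(out, data.frame(roi_id = nrow(out) + 1L,
                                 neuron_id = NA_integer_,
                                 x0 = x0, x1 = x1, y0 = y0, y1 = y1))
  }
  out
}

# Linear pixel indices (1-based; x varies fastest) of a box on an n x n FOV.
box_pixels <- function(box, n) {
  ix <- seq.int(box$x0, box$x1 - 1L)
  iy <- seq.int(box$y0, box$y1 - 1L)
  as.vector(outer(ix + 1L, iy, function(x, y) x + n * y))
}

# Mean of the pixels with intensity in the [lo, hi] percentile band
# (type-7 quantiles). A degenerate (constant) distribution keeps every pixel.
percentile_band_mean <- function(vals, lo = 0.80, hi = 0.95) {
  q <- quantile(vals, c(lo, hi), names = FALSE, type = 7)
  sel <- vals >= q[1] & vals <= q[2]
  if (!any(sel)) sel <- vals >= max(vals[vals <= q[1]])
  mean(vals[sel])
}

#' Extract raw fluorescence traces for a set of boxes
#'
#' Per frame, the ROI of each box is the set of its pixels with intensity in
#' the 80th-95th percentile band of the box's intensity distribution, and
#' `F(t)` is the ROI mean minus the frame background. The background is the
#' mean of pixels that (i) belong to no box, (ii) exceed the mean corner-noise
#' level (pixels beyond the circular FOV), and (iii) are below the maximum
#' intensity found inside the boxes. If the background set is empty in a
#' frame, the previous frame's value is carried forward with a warning.
#'
#' @param frame_source a pixels x frames matrix or a [render_frame_source()]
#'   function.
#' @param boxes box table from [detect_rois()].
#' @param fov_pixels FOV side, pixels.
#' @param edge_mask logical per-pixel vector marking corner pixels (outside
#'   the circular FOV); computed from `mixing` if supplied.
#' @param mixing optional `mixing_matrix` (provides `fov_pixels` and the
#'   corner mask).
#' @param band percentile band, default `c(0.80, 0.95)`.
#' @param chunk frames per chunk when streaming (keep at the 128-frame noise-block size for best performance).
#' @return list `F` (frames x boxes matrix), `background` (per frame).
#' @export
extract_traces <- function(frame_source, boxes, fov_pixels = NULL,
                           edge_mask = NULL, mixing = NULL,
                           band = c(0.80, 0.95), chunk = 128L) {
  if (!is.null(mixing)) {
    fov_pixels <- fov_pixels %||% mixing$fov_pixels
    edge_mask <- edge_mask %||% (mixing$pixels$r_real > mixing$edge_radius)
  }
  if (is.matrix(frame_source)) {
    mat <- frame_source
    n_frames <- ncol(mat)
    getf <- function(idx) mat[, idx, drop = FALSE]
  } else {
    n_frames <- attr(frame_source, "n_frames")
    getf <- frame_source
  }
  stopifnot(!is.null(fov_pixels))
  npx <- fov_pixels^2
  if (is.null(edge_mask)) edge_mask <- rep(FALSE, npx)
  nb <- nrow(boxes)
  px_list <- lapply(seq_len(nb), function(i) box_pixels(boxes[i, ], fov_pixels))
  in_box <- rep(FALSE, npx)
  for (p in px_list) in_box[p] <- TRUE
  edge_px <- which(edge_mask)
  Fmat <- matrix(NA_real_, n_frames, max(nb, 1))
  bg <- numeric(n_frames)
  bg_ok <- logical(n_frames)
  for (start in seq(1, n_frames, by = chunk)) {
    idx <- start:min(n_frames, start + chunk - 1L)
    fr <- getf(idx)
    res <- cpp_extract_chunk(fr, px_list, band[1], band[2], in_box,
                             as.integer(edge_px))
    Fmat[idx, ] <- res$F
    bg[idx] <- res$bg
    bg_ok[idx] <- res$bg_ok
    rm(fr, res)
    gc(FALSE)
    cpp_release_memory()
  }
  if (any(!bg_ok)) {
    warning("empty background set in ", sum(!bg_ok),
            " frame(s); carrying previous frame's background")
    last <- 0
    for (t in seq_len(n_frames)) {
      if (bg_ok[t]) last <- bg[t] else bg[t] <- last
    }
  }
  Fmat <- Fmat[, seq_len(nb), drop = FALSE] - bg  # recycles down columns
  list(F = Fmat, background = bg)
}

#' Sliding-percentile baseline dF/F0
#'
#' `F0(t)` is the 20th percentile of the trace in a window of `window_s`
#' seconds centered on `t` (truncated at the trace ends);
#' `dF/F0 = (F - F0) / F0`. Traces whose baseline is not strictly positive
#' anywhere are flagged (attribute `valid = FALSE`) and excluded from SNR
#' statistics downstream.
#'
#' @param f numeric trace.
#' @param frame_rate Hz.
#' @param window_s window length, seconds (default 10).
#' @param q baseline percentile (default 0.20).
#' @return numeric dF/F0 trace with attributes `f0` and `valid`.
#' @export
compute_dff <- function(f, frame_rate = 30, window_s = 10, q = 0.20) {
  stopifnot(length(f) > 1)
  halfwin <- max(0L, as.integer(round(window_s * frame_rate / 2)))
  f0 <- cpp_running_quantile(as.numeric(f), halfwin, q)
  valid <- all(f0 > 0)
  dff <- (f - f0) / f0
  if (!valid) dff[] <- NA_real_
  attr(dff, "f0") <- f0
  attr(dff, "valid") <- valid
  dff
}

#' Peak SNR of a dF/F0 trace
#'
#' `max(dF/F0)` divided by the SD of the trace values lying below the trace's
#' 25th percentile. A zero (or undefined) noise estimate returns `Inf` with
#' attribute `valid = FALSE`, to be excluded from threshold sweeps.
#'
#' @param dff dF/F0 trace.
#' @return scalar peak SNR with attribute `valid`.
#' @export
peak_snr <- function(dff) {
  if (anyNA(dff)) return(structure(NA_real_, valid = FALSE))
  q25 <- quantile(dff, 0.25, names = FALSE)
  low <- dff[dff < q25]
  ns <- if (length(low) >= 2) sd(low) else 0
  if (!is.finite(ns) || ns == 0)
    return(structure(Inf, valid = FALSE))
  structure(max(dff) / ns, valid = TRUE)
}

#' Convert a box centroid to calibrated sample-space position
#'
#' Centroid pixel coordinates are converted to nominal microns with the
#' nominal pixel size (relative to the FOV center) and the radial distance is
#' then mapped through the distance-calibration inverse to a real distance.
#'
#' @param centroid_px `c(x, y)` pixel coordinates (0-based pixel grid; pixel
#'   centers at index + 0.5).
#' @param optics an `optics_config`.
#' @return list `r_um` (real radial distance), `xy_um` (real position),
#'   `r_nominal_um`.
#' @export
centroid_to_um <- function(centroid_px, optics) {
  ctr <- optics$fov_pixels / 2
  xy_nom <- (centroid_px - ctr) * optics$nominal_pixel_size
  r_nom <- sqrt(sum(xy_nom^2))
  r_real <- if (r_nom == 0) 0 else real_distance(r_nom, optics$magnification)
  scale <- if (r_nom > 0) r_real / r_nom else 1
  list(r_um = r_real, xy_um = xy_nom * scale, r_nominal_um = r_nom)
}

#' Full per-FOV extraction
#'
#' Detects boxes, extracts traces, computes dF/F0, peak SNR and calibrated
#' centroids.
#'
#' @param frame_source matrix or [render_frame_source()] output.
#' @param mixing a `mixing_matrix`.
#' @param optics the `optics_config` used to render.
#' @param detector a [detector_spec()].
#' @param frame_rate Hz.
#' @return list `rois` (data frame `roi_id, neuron_id, cx_px, cy_px, r_um,
#'   x_um, y_um, peak_snr, snr_valid, dff_valid`, plus box bounds), `F`,
#'   `dff` (frames x ROI matrices), `background`, `boxes`.
#' @export
extract_fov <- function(frame_source, mixing, optics,
                        detector = detector_spec(), frame_rate = 30) {
  boxes <- detect_rois(mixing, detector)
  tr <- extract_traces(frame_source, boxes, mixing = mixing)
  nb <- nrow(boxes)
  dff <- matrix(NA_real_, nrow(tr$F), max(nb, 1))[, seq_len(nb), drop = FALSE]
  snr <- numeric(nb)
  snr_valid <- logical(nb)
  dff_valid <- logical(nb)
  cx <- cy <- r_um <- x_um <- y_um <- numeric(nb)
  for (i in seq_len(nb)) {
    d <- compute_dff(tr$F[, i], frame_rate = frame_rate)
    dff[, i] <- d
    dff_valid[i] <- attr(d, "valid")
    s <- if (dff_valid[i]) peak_snr(d) else structure(NA_real_, valid = FALSE)
    snr[i] <- as.numeric(s)
    snr_valid[i] <- attr(s, "valid")
    cx[i] <- (boxes$x0[i] + boxes$x1[i]) / 2
    cy[i] <- (boxes$y0[i] + boxes$y1[i]) / 2
    cal <- centroid_to_um(c(cx[i], cy[i]), optics)
    r_um[i] <- cal$r_um
    x_um[i] <- cal$xy_um[1]
    y_um[i] <- cal$xy_um[2]
  }
  rois <- cbind(boxes,
                data.frame(cx_px = cx, cy_px = cy, r_um = r_um,
                           x_um = x_um, y_um = y_um, peak_snr = snr,
                           snr_valid = snr_valid, dff_valid = dff_valid))
  list(rois = rois, F = tr$F, dff = dff, background = tr$background,
       boxes = boxes)
}
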