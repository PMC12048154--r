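# Ground-truth-aware evaluation: expected pair-correlation threshold,
# adjacent-pair cross-contamination, GLM source-purity index, first-source
# correlation and radial-trend regressions.

#' Expected cell-pair correlation threshold
#'
#' The mean Pearson correlation over all ground-truth source pairs, computed
#' per FOV and averaged across FOVs, plus three standard deviations of the
#' pooled pair correlations. Detected cell pairs more correlated than this
#' threshold cannot be explained by the ground-truth activity and are
#' attributed to optical source mixing.
#'
#' @param trace_list list with one time x sources matrix per FOV.
#' @return list `threshold`, `mean`, `sd`, `n_pairs`, `fov_means`.
#' @export
expected_pair_correlation <- function(trace_list) {
  stopifnot(is.list(trace_list), length(trace_list) >= 1)
  pooled <- list()
  fov_means <- numeric(length(trace_list))
  for (k in seq_along(trace_list)) {
    # constant traces yield NaN correlations; they are filtered below
    cc <- suppressWarnings(cor(trace_list[[k]]))
    vals <- cc[upper.tri(cc)]
    vals <- vals[is.finite(vals)]
    pooled[[k]] <- vals
    fov_means[k] <- mean(vals)
  }
  pooled <- unlist(pooled)
  if (length(pooled) < 2) stop("need at least two source pairs")
  s <- sd(pooled)
  m <- mean(fov_means)
  list(threshold = m + 3 * s, mean = m, sd = s, n_pairs = length(pooled),
       fov_means = fov_means)
}

#' Adjacent-pair correlation analysis across peak-SNR cutoffs
#'
#' Adjacent pairs are ROIs whose calibrated centroids are within
#' `adjacency_um` of each other. For each peak-SNR cutoff, only ROIs with
#' `peak_snr > cutoff` (and finite, valid SNR) are kept, and the fraction of
#' adjacent pairs whose trace correlation exceeds `threshold` is reported
#' together with the raw counts. An undefined fraction (no adjacent pairs at
#' a cutoff) is reported as `NA`, not 0.
#'
#' @param rois ROI table from [extract_fov()] (needs `x_um`, `y_um`, `r_um`,
#'   `peak_snr`, `snr_valid`).
#' @param dff frames x ROI matrix of dF/F0 traces.
#' @param threshold expected-correlation threshold.
#' @param snr_grid cutoffs (default [snr_threshold_grid()]).
#' @param adjacency_um centroid-distance criterion, um (25 or 30).
#' @return list `by_cutoff` (data frame `cutoff, n_pairs, n_above, fraction`),
#'   `pairs` (data frame per adjacent pair at cutoff 0: ids, distance,
#'   pair radial distance, correlation).
#' @export
adjacent_pair_analysis <- function(rois, dff, threshold,
                                   snr_grid = snr_threshold_grid(),
                                   adjacency_um = 25) {
  keep0 <- rois$snr_valid & is.finite(rois$peak_snr)
  ids <- which(keep0)
  pair_rows <- list()
  if (length(ids) >= 2) {
    cmb <- utils::combn(ids, 2)
    dx <- rois$x_um[cmb[1, ]] - rois$x_um[cmb[2, ]]
    dy <- rois$y_um[cmb[1, ]] - rois$y_um[cmb[2, ]]
    d <- sqrt(dx^2 + dy^2)
    adj <- d <= adjacency_um
    if (any(adj)) {
      a <- cmb[1, adj]; b <- cmb[2, adj]
      rr <- sqrt(((rois$x_um[a] + rois$x_um[b]) / 2)^2 +
                   ((rois$y_um[a] + rois$y_um[b]) / 2)^2)
      cc <- vapply(seq_along(a),
                   function(i) cor(dff[, a[i]], dff[, b[i]]), 1)
      pair_rows <- data.frame(roi_a = a, roi_b = b, distance_um = d[adj],
                              pair_r_um = rr, correlation = cc)
    }
  }
  pairs <- if (is.data.frame(pair_rows)) pair_rows else
    data.frame(roi_a = integer(0), roi_b = integer(0),
               distance_um = numeric(0), pair_r_um = numeric(0),
               correlation = numeric(0))
  by_cutoff <- do.call(rbind, lapply(snr_grid, function(ct) {
    ok <- pairs$roi_a %in% which(keep0 & rois$peak_snr > ct) &
      pairs$roi_b %in% which(keep0 & rois$peak_snr > ct)
    np <- sum(ok)
    na_ <- sum(ok & pairs$correlation > threshold)
    data.frame(cutoff = ct, n_pairs = np, n_above = na_,
               fraction = if (np > 0) na_ / np else NA_real_)
  }))
  list(by_cutoff = by_cutoff, pairs = pairs)
}

#' Ground-truth sources contributing to each box
#'
#' A ground-truth neuron contributes to a box if its projected footprint
#' (pixels with nonzero mixing weight) overlaps the box by at least one
#' pixel.
#'
#' @param boxes box table.
#' @param mixing a `mixing_matrix`.
#' @return list of neuron-id vectors, one per box.
#' @export
contributing_sources <- function(boxes, mixing) {
  n <- mixing$fov_pixels
  lapply(seq_len(nrow(boxes)), function(i) {
    px <- box_pixels(boxes[i, ], n)
    sub <- mixing$weights[px, , drop = FALSE]
    which(Matrix::colSums(sub) > 0)
  })
}

#' Source-purity index of one extracted trace
#'
#' Fits `Y(t) = sum_j a_j X_j(t) + q` by least squares (identity-link
#' Gaussian GLM) over the contributing ground-truth source traces and
#' computes `purity = max_j(a_j^2) / sum_j(a_j^2)`: 1 when a single source
#' explains the trace, smaller under source mixing.
#'
#' @param y extracted trace.
#' @param X time x sources matrix of contributing ground-truth traces
#'   (k >= 1).
#' @return list `coefficients`, `intercept`, `purity`, `k`. Collinear source
#'   sets fall back to the minimum-norm solution with a warning; an all-zero
#'   coefficient vector yields `purity = NA` with a warning.
#' @export
purity_glm <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, nrow(X) == length(y))
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear sources; using minimum-norm least squares")
    co <- c(MASS_ginv(D) %*% y)
  } else {
    co <- qr.coef(qrD, y)
  }
  a <- co[-1]
  if (all(a == 0)) {
    warning("all-zero source coefficients; purity undefined")
    pur <- NA_real_
  } else {
    pur <- max(a^2) / sum(a^2)
  }
  list(coefficients = unname(a), intercept = unname(co[1]), purity = pur,
       k = ncol(X))
}

# Moore-Penrose pseudoinverse via SVD (minimum-norm fallback).
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Correlation of an extracted trace with its first ground-truth source
#'
#' Pearson correlation of the trace with each contributing source; the
#' maximum (most correlated, "first" source) is returned.
#'
#' @param y extracted trace.
#' @param X time x sources matrix (k >= 1).
#' @return list `correlation` (max), `which` (column index), `all`.
#' @export
first_source_correlation <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1)
  cc <- suppressWarnings(vapply(seq_len(ncol(X)),
                                function(j) cor(y, X[, j]), 1))
  cc[!is.finite(cc)] <- -Inf
  list(correlation = max(cc), which = which.max(cc), all = cc)
}

#' Linear trend of a metric against radial distance
#'
#' Ordinary least squares of y on x. The slope's significance is assessed
#' with a Wald t-test when the residuals pass the normality gate and with a
#' pairings permutation test otherwise. Optionally restricts both inputs to
#' `x <= x_max` so two conditions can be compared over a common radial range.
#'
#' @param x radial distances, um.
#' @param y metric values.
#' @param x_max optional common range truncation.
#' @param n_perm permutation count override.
#' @param seed seed for the permutation path.
#' @return list `slope`, `intercept`, `se`, `p`, `method`, `n`.
#' @export
radial_trend <- function(x, y, x_max = NULL, n_perm = NULL, seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(x_max)) keep <- keep & x <= x_max
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("degenerate x range")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  res <- resid(fit)
  gate <- if (sd(res) == 0) list(normal = TRUE, test = "degenerate") else
    normality_gate(res)
  if (gate$normal) {
    p <- sm["x", "Pr(>|t|)"]
    if (se == 0 || !is.finite(p))  # noiseless fit: exact line or constant y
      p <- if (abs(slope) <= .Machine$double.eps^0.5) 1 else 0
    method <- paste0("wald (residuals normal, ", gate$test, ")")
  } else {
    p <- perm_test_slope_zero(x, y, n_perm = n_perm, seed = seed)$p
    method <- "permutation (residuals non-normal)"
  }
  list(slope = slope, intercept = sm["(Intercept)", "Estimate"], se = se,
       p = p, method = method, n = length(x))
}
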