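# Ground-truth activity: correlated Poisson spiking shared within groups of
# paired neurons, converted to calcium-sensor fluorescence traces.

#' Build the shared-activity group structure
#'
#' Every unordered neuron pair is included independently with probability
#' `p_pair`. Two readings of "groups of neurons with shared activity" are
#' supported:
#'
#' * `"components"` (default): a group is a connected component of the pairing
#'   graph; every neuron in a component shares that component's common Poisson
#'   process. At `n * p_pair >> 1` the graph has a giant component, so most
#'   neurons share one global process; this is the reading under which the
#'   calibrated shared rate reproduces a mean all-pairs ground-truth
#'   correlation of about 0.04 (see the methods vignette).
#' * `"pairs"`: each sampled pair is its own group of size two; a neuron
#'   belongs to as many groups as pairs it appears in. Under this reading the
#'   mean all-pairs correlation is bounded by about 1/n once the per-neuron
#'   total rate is held fixed.
#'
#' @param n_neurons number of neurons.
#' @param p_pair pairing probability in `[0, 1]` (default 0.05).
#' @param group_mode `"components"` or `"pairs"`.
#' @param seed optional integer seed.
#' @return a `group_structure` list: `pairs` (2-column matrix), `groups`
#'   (list of member id vectors, size >= 2), `membership` (per-neuron list of
#'   group indices), `p_pair`, `group_mode`, `n_neurons`.
#' @export
build_groups <- function(n_neurons, p_pair = 0.05,
                         group_mode = c("components", "pairs"), seed = NULL) {
  stopifnot(n_neurons >= 1, p_pair >= 0, p_pair <= 1)
  group_mode <- match.arg(group_mode)
  pairs <- with_seed(seed, {
    if (n_neurons < 2 || p_pair == 0) {
      matrix(integer(0), ncol = 2)
    } else if (p_pair == 1) {
      t(utils::combn(n_neurons, 2))
    } else {
      m <- n_neurons * (n_neurons - 1) / 2
      sel <- which(runif(m) < p_pair)
      if (!length(sel)) matrix(integer(0), ncol = 2) else {
        # linear index k (1-based, row-major over i<j) -> (i, j)
        k <- sel - 1
        i <- floor((2 * n_neurons - 1 - sqrt((2 * n_neurons - 1)^2 - 8 * k)) / 2)
        j <- k - i * (2 * n_neurons - 3 - i + 2) / 2 + i + 1
        cbind(as.integer(i + 1), as.integer(j + 1))
      }
    }
  })
  groups <- if (group_mode == "pairs") {
    if (nrow(pairs)) lapply(seq_len(nrow(pairs)), function(r) pairs[r, ]) else list()
  } else if (nrow(pairs)) {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_neurons - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    mem <- split(seq_len(n_neurons), comp)
    unname(mem[vapply(mem, length, 1L) >= 2])
  } else list()
  membership <- vector("list", n_neurons)
  for (gi in seq_along(groups))
    for (id in groups[[gi]]) membership[[id]] <- c(membership[[id]], gi)
  structure(list(pairs = pairs, groups = groups, membership = membership,
                 p_pair = p_pair, group_mode = group_mode,
                 n_neurons = n_neurons),
            class = "group_structure")
}

#' Default shared-process rate
#'
#' Rate (Hz) of each group's common Poisson process, calibrated once by
#' bisection ([calibrate_shared_rate()]) so that the default activity model
#' (pairing probability 0.05, total rate 0.3 Hz, 300 s, component groups,
#' default sensor) yields a mean all-pairs Pearson correlation of ground-truth
#' fluorescence of 0.041.
#' @return rate in Hz.
#' @export
shared_rate_default <- function() 0.0123

#' Simulate spike trains with shared-group correlations
#'
#' Each neuron fires as the superposition of an independent Poisson process
#' and the common process of every group it belongs to. The configured total
#' rate per neuron is `total_rate`; the independent rate is
#' `total_rate - n_groups * shared_rate`, clamped at zero with a warning when
#' a neuron's shared processes alone exceed the total.
#'
#' @param groups a [build_groups()] structure.
#' @param total_rate per-neuron total rate, Hz (default 0.3).
#' @param duration seconds (default 300).
#' @param dt bin width in seconds (default 1 ms).
#' @param shared_rate per-group common rate, Hz.
#' @param seed optional integer seed.
#' @return a `spike_set` list: `spikes` (per-neuron integer vector of 1-based
#'   bin indices, repeated for multi-spike bins), `n_bins`, `dt`, `duration`,
#'   `rates` (data frame `independent`, `shared_total`, `configured_total`).
#' @export
simulate_spikes <- function(groups, total_rate = 0.3, duration = 300,
                            dt = 1e-3, shared_rate = shared_rate_default(),
                            seed = NULL) {
  stopifnot(inherits(groups, "group_structure"))
  if (total_rate < 0 || shared_rate < 0) stop("rates must be non-negative")
  n <- groups$n_neurons
  n_bins <- as.integer(round(duration / dt))
  n_groups_of <- vapply(groups$membership, length, 1L)
  indep <- total_rate - n_groups_of * shared_rate
  if (any(indep < 0)) {
    warning("independent rate clamped to 0 for ",
            sum(indep < 0), " neuron(s)")
    indep <- pmax(indep, 0)
  }
  with_seed(seed, {
    draw_bins <- function(rate) {
      k <- rpois(1, rate * duration)
      if (k == 0) integer(0) else
        as.integer(pmin(n_bins, floor(runif(k) * duration / dt) + 1L))
    }
    shared_bins <- lapply(groups$groups, function(g) draw_bins(shared_rate))
    spikes <- vector("list", n)
    for (i in seq_len(n)) {
      own <- draw_bins(indep[i])
      sh <- unlist(shared_bins[groups$membership[[i]]], use.names = FALSE)
      spikes[[i]] <- sort(c(own, as.integer(sh)))
    }
    structure(list(spikes = spikes, n_bins = n_bins, dt = dt,
                   duration = duration,
                   rates = data.frame(
                     independent = indep,
                     shared_total = n_groups_of * shared_rate,
                     configured_total = indep + n_groups_of * shared_rate)),
              class = "spike_set")
  })
}

#' Calcium-sensor parameters
#'
#' Configurable difference-of-exponentials response kernel with optional Hill
#' saturation, standing in for a fast GCaMP-family indicator. Defaults (2 ms
#' rise, 70 ms half decay, unitary dF/F 0.4) are plausible fast-sensor values,
#' not measured ones; adjust them to match a specific indicator.
#'
#' @param rise_ms rise time constant, ms.
#' @param half_decay_ms decay half-time, ms (decay tau = half_decay / ln 2).
#' @param unitary_dff peak dF/F of an isolated single spike.
#' @param baseline baseline fluorescence, arbitrary units (> 0).
#' @param saturation `NULL` (linear) or a list `list(f_max=, k_half=, hill=)`
#'   applied to the summed spike drive.
#' @return a `sensor_params` list.
#' @export
sensor_params <- function(rise_ms = 2, half_decay_ms = 70, unitary_dff = 0.4,
                          baseline = 1, saturation = NULL) {
  stopifnot(rise_ms > 0, half_decay_ms > 0, baseline > 0)
  structure(list(rise_ms = rise_ms, half_decay_ms = half_decay_ms,
                 unitary_dff = unitary_dff, baseline = baseline,
                 saturation = saturation),
            class = "sensor_params")
}

# Discrete single-spike kernel on the dt grid, peak-normalized to unitary_dff.
sensor_kernel <- function(sensor, dt, n = NULL) {
  tau_r <- sensor$rise_ms / 1000
  tau_d <- sensor$half_decay_ms / 1000 / log(2)
  if (is.null(n)) n <- ceiling(10 * tau_d / dt)
  tt <- (seq_len(n) - 1) * dt
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  k * sensor$unitary_dff / max(k)
}

#' Convert spike trains to fluorescence traces
#'
#' Each spike drives the sensor kernel (exponential rise and decay); the
#' summed drive is optionally passed through a Hill saturation and offset by
#' the baseline: `F = baseline * (1 + drive)` in the linear regime. The
#' convolution is computed exactly with two recursive exponential filters.
#' Traces are bin-averaged from the native `dt` grid to `out_dt`.
#'
#' @param spikes a `spike_set` from [simulate_spikes()].
#' @param sensor a [sensor_params()] list.
#' @param out_dt output sampling interval, seconds (default: native `dt`).
#' @return matrix (time x neurons) of fluorescence, attribute `dt` = `out_dt`.
#' @export
spikes_to_fluorescence <- function(spikes, sensor = sensor_params(),
                                   out_dt = NULL) {
  stopifnot(inherits(spikes, "spike_set"), inherits(sensor, "sensor_params"))
  dt <- spikes$dt
  n_bins <- spikes$n_bins
  out_dt <- out_dt %||% dt
  tau_r <- sensor$rise_ms / 1000
  tau_d <- sensor$half_decay_ms / 1000 / log(2)
  a_r <- exp(-dt / tau_r)
  a_d <- exp(-dt / tau_d)
  # peak-normalize the kernel evaluated on the dt grid
  tt <- (seq_len(ceiling(10 * tau_d / dt)) - 1) * dt
  gain <- sensor$unitary_dff / max(exp(-tt / tau_d) - exp(-tt / tau_r))
  if (is.null(sensor$saturation)) {
    grp <- if (out_dt > dt) frame_groups(n_bins, dt, out_dt) else
      seq_len(n_bins)
    out <- cpp_spikes_to_traces(lapply(spikes$spikes, as.integer), n_bins,
                                a_d, a_r, gain, sensor$baseline,
                                as.integer(grp), max(grp))
    attr(out, "dt") <- out_dt
    return(out)
  }
  groups_idx <- if (out_dt > dt) frame_groups(n_bins, dt, out_dt) else NULL
  counts <- if (is.null(groups_idx)) NULL else tabulate(groups_idx)
  n_out <- if (is.null(groups_idx)) n_bins else max(groups_idx)
  out <- matrix(0, n_out, length(spikes$spikes))
  for (i in seq_along(spikes$spikes)) {
    x <- numeric(n_bins)
    s <- spikes$spikes[[i]]
    if (length(s)) x <- as.numeric(tabulate(s, n_bins))
    drive <- gain * cpp_double_exp(x, a_d, a_r)
    if (!is.null(sensor$saturation)) {
      s3 <- sensor$saturation
      drive <- s3$f_max * drive^s3$hill / (drive^s3$hill + s3$k_half^s3$hill)
    }
    f <- sensor$baseline * (1 + drive)
    out[, i] <- if (is.null(groups_idx)) f else
      bin_average(f, groups_idx, counts)
  }
  attr(out, "dt") <- out_dt
  out
}

#' Mean and SD of the all-pairs Pearson correlation of ground-truth traces
#'
#' @param traces time x neurons matrix.
#' @return list `mean`, `sd`, `n_pairs`. Pairs involving constant traces are
#'   excluded with a warning.
#' @export
ground_truth_pair_statistics <- function(traces) {
  stopifnot(is.matrix(traces), ncol(traces) >= 2)
  v <- apply(traces, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant trace(s) excluded from pair statistics")
    traces <- traces[, v > 0, drop = FALSE]
  }
  if (ncol(traces) < 2) stop("fewer than 2 non-constant traces")
  cc <- cor(traces)
  vals <- cc[upper.tri(cc)]
  list(mean = mean(vals), sd = sd(vals), n_pairs = length(vals))
}

#' Simulate a full activity set
#'
#' Convenience wrapper: groups -> spikes -> fluorescence.
#'
#' @param n_neurons number of neurons.
#' @param p_pair pairing probability.
#' @param total_rate per-neuron rate, Hz.
#' @param duration seconds.
#' @param dt spike bin, seconds.
#' @param shared_rate per-group shared rate, Hz.
#' @param sensor a [sensor_params()] list.
#' @param out_dt fluorescence sampling interval, seconds.
#' @param group_mode see [build_groups()].
#' @param seed integer seed (expanded into substreams for pairing and spiking).
#' @return an `activity_set` list: `groups`, `spikes`, `traces` (time x
#'   neurons, attr `dt`), plus the generating parameters.
#' @export
simulate_activity <- function(n_neurons, p_pair = 0.05, total_rate = 0.3,
                              duration = 300, dt = 1e-3,
                              shared_rate = shared_rate_default(),
                              sensor = sensor_params(), out_dt = dt,
                              group_mode = "components", seed = NULL) {
  gseed <- if (is.null(seed)) NULL else substream_seed(seed, "groups")
  sseed <- if (is.null(seed)) NULL else substream_seed(seed, "spikes")
  groups <- build_groups(n_neurons, p_pair, group_mode, seed = gseed)
  spikes <- simulate_spikes(groups, total_rate, duration, dt, shared_rate,
                            seed = sseed)
  traces <- spikes_to_fluorescence(spikes, sensor, out_dt = out_dt)
  structure(list(groups = groups, spikes = spikes, traces = traces,
                 total_rate = total_rate, shared_rate = shared_rate,
                 duration = duration, dt = dt, sensor = sensor, seed = seed),
            class = "activity_set")
}

#' Write an activity set's spikes and parameters to CSV + JSON
#'
#' Spike trains are stored sparsely (one row per event: neuron id, 1-based
#' bin index); rates, sensor parameters and the seed go to a JSON sidecar.
#' Fluorescence is deterministic given spikes and sensor, so it is
#' reconstructed on read rather than stored.
#'
#' @param activity an `activity_set`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_activity_csv <- function(activity, path) {
  stopifnot(inherits(activity, "activity_set"))
  sp <- activity$spikes$spikes
  ev <- data.frame(neuron = rep.int(seq_along(sp), lengths(sp)),
                   bin = unlist(sp, use.names = FALSE))
  write.csv(ev, path, row.names = FALSE)
  jsonlite::write_json(
    list(n_neurons = length(sp), n_bins = activity$spikes$n_bins,
         dt = activity$dt, duration = activity$duration,
         total_rate = activity$total_rate, shared_rate = activity$shared_rate,
         out_dt = attr(activity$traces, "dt"), seed = activity$seed,
         sensor = unclass(activity$sensor)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an activity set written by [write_activity_csv()]
#' @param path CSV path.
#' @return an `activity_set` (without the group structure, which is not
#'   needed downstream; traces are regenerated from the stored spikes).
#' @export
read_activity_csv <- function(path) {
  ev <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spikes <- vector("list", meta$n_neurons)
  split_ev <- split(as.integer(ev$bin), factor(ev$neuron, seq_len(meta$n_neurons)))
  for (i in seq_len(meta$n_neurons)) spikes[[i]] <- sort(split_ev[[i]])
  sp <- structure(list(spikes = spikes, n_bins = meta$n_bins, dt = meta$dt,
                       duration = meta$duration),
                  class = "spike_set")
  sensor <- do.call(sensor_params, meta$sensor[c("rise_ms", "half_decay_ms",
                                                 "unitary_dff", "baseline")])
  traces <- spikes_to_fluorescence(sp, sensor, out_dt = meta$out_dt)
  structure(list(groups = NULL, spikes = sp, traces = traces,
                 total_rate = meta$total_rate, shared_rate = meta$shared_rate,
                 duration = meta$duration, dt = meta$dt, sensor = sensor,
                 seed = meta$seed),
            class = "activity_set")
}

#' Calibrate the shared-process rate against a target mean pair correlation
#'
#' Bisection on simulations: for each candidate shared rate, simulates
#' `n_seeds` activity sets and measures the mean all-pairs Pearson correlation
#' of the fluorescence traces; the rate is adjusted until the average matches
#' `target` to within `tol`. The correlation is monotone increasing in the
#' shared rate, so bisection is valid.
#'
#' @param target target mean all-pairs correlation (default 0.041).
#' @param n_neurons,duration,p_pair,total_rate study conditions.
#' @param n_seeds simulations per evaluation.
#' @param lower,upper bracketing shared rates, Hz.
#' @param tol tolerance on the mean correlation.
#' @param out_dt trace sampling interval used for the correlation, seconds.
#' @param seed integer seed.
#' @return list `shared_rate`, `achieved`, `evaluations` (data frame).
#' @export
calibrate_shared_rate <- function(target = 0.041, n_neurons = 200,
                                  duration = 300, p_pair = 0.05,
                                  total_rate = 0.3, n_seeds = 40,
                                  lower = 0.001, upper = 0.05, tol = 5e-4,
                                  out_dt = 0.01, seed = 1) {
  evalrate <- function(r) {
    mean(vapply(seq_len(n_seeds), function(k) {
      a <- simulate_activity(n_neurons, p_pair, total_rate, duration,
                             shared_rate = r, out_dt = out_dt,
                             seed = substream_seed(seed, "calib", k))
      ground_truth_pair_statistics(a$traces)$mean
    }, 1))
  }
  evals <- data.frame(rate = numeric(0), mean_corr = numeric(0))
  lo <- lower; hi <- upper
  flo <- evalrate(lo); fhi <- evalrate(hi)
  evals <- rbind(evals, data.frame(rate = c(lo, hi), mean_corr = c(flo, fhi)))
  if ((flo - target) * (fhi - target) > 0)
    stop("target not bracketed by [lower, upper]")
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    fm <- evalrate(mid)
    evals <- rbind(evals, data.frame(rate = mid, mean_corr = fm))
    if (abs(fm - target) < tol) break
    if ((fm - target) * (flo - target) < 0) { hi <- mid; fhi <- fm }
    else { lo <- mid; flo <- fm }
  }
  list(shared_rate = mid, achieved = fm, evaluations = evals)
}
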