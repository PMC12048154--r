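# Shared helpers: seed substreams, binning, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single experiment seed is expanded into independent substreams, one per
#' (stage, index) pair, so that each stage (tissue placement, spiking, noise
#' sampling, ...) can be re-run in isolation and still reproduce the full
#' experiment bit for bit.
#'
#' @param seed integer master seed.
#' @param stage character stage label (e.g. `"tissue"`, `"spikes"`).
#' @param index integer substream index (e.g. the FOV number).
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage, index = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  x <- (abs(as.numeric(seed)) %% 2147483647)
  x <- (x * 48271 + h * 2654435 + as.numeric(index) * 97003) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Average x in consecutive groups defined by integer group ids (1-based,
# non-decreasing). Used to resample 1 ms activity onto the frame grid.
bin_average <- function(x, groups, counts = tabulate(groups)) {
  n_out <- length(counts)
  if (length(x) %% n_out == 0 && all(counts == counts[1])) {
    # uniform groups: reshape and column-average
    colMeans(matrix(x, length(x) %/% n_out, n_out))
  } else {
    as.numeric(rowsum(x, groups, reorder = FALSE)) / counts
  }
}

# Group ids mapping 1 ms bins onto frames of length frame_dt (seconds).
frame_groups <- function(n_bins, dt, frame_dt) {
  t_mid <- (seq_len(n_bins) - 0.5) * dt
  pmin(floor(t_mid / frame_dt) + 1L, ceiling(n_bins * dt / frame_dt))
}
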