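# Ground-truth tissue: non-overlapping spherical neurons with non-fluorescent
# nuclei, placed by random sequential insertion and rasterized on a voxel grid.

#' Default neuron geometry parameters
#'
#' Soma radii are drawn from N(10, 3) um and the nuclear size from N(5, 1) um,
#' values typical of excitatory neurons in the olfactory cortex. The nuclear
#' draw is interpreted as a half-width (radius) by default; set
#' `nucleus_measure = "diameter"` to halve the draw instead.
#'
#' @param radius_mean,radius_sd soma radius distribution, um.
#' @param nucleus_mean,nucleus_sd nuclear size distribution, um.
#' @param nucleus_measure whether the nuclear draw is a half-width or a
#'   diameter.
#' @return a `geometry_params` list.
#' @export
geometry_params <- function(radius_mean = 10, radius_sd = 3,
                            nucleus_mean = 5, nucleus_sd = 1,
                            nucleus_measure = c("halfwidth", "diameter")) {
  if (!is.numeric(radius_mean) || radius_mean <= 0)
    stop("radius_mean must be positive")
  structure(list(radius_mean = radius_mean, radius_sd = radius_sd,
                 nucleus_mean = nucleus_mean, nucleus_sd = nucleus_sd,
                 nucleus_measure = match.arg(nucleus_measure)),
            class = "geometry_params")
}

#' Sample neuron geometries
#'
#' Draws soma radius and nuclear half-width from Gaussian distributions,
#' resampling any draw that violates `0 <= nucleus < soma` or `soma > 0`.
#'
#' @param n number of neurons to draw.
#' @param params a [geometry_params()] list.
#' @return data frame with columns `soma_radius` and `nucleus_halfwidth` (um).
#' @export
sample_neuron_geometry <- function(n = 1L, params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  # soma radii: reject only non-positive draws, keeping the marginal Gaussian
  soma <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    s <- rnorm(length(todo), params$radius_mean, params$radius_sd)
    soma[todo] <- s
    todo <- todo[s <= 0]
  }
  # nuclear draws: resample until the nucleus fits strictly inside its soma,
  # so an invalid nucleus never biases the soma distribution; tiny somata
  # (where a valid draw is vanishingly rare) clip the nucleus to half the
  # soma radius
  nuc <- numeric(n)
  tries <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    w <- rnorm(length(todo), params$nucleus_mean, params$nucleus_sd)
    if (params$nucleus_measure == "diameter") w <- w / 2
    nuc[todo] <- w
    tries[todo] <- tries[todo] + 1L
    bad <- !(w >= 0 & w < soma[todo])
    clip <- bad & tries[todo] >= 50L
    nuc[todo[clip]] <- soma[todo[clip]] / 2
    todo <- todo[bad & !clip]
  }
  data.frame(soma_radius = soma, nucleus_halfwidth = nuc)
}

#' Place neurons by random sequential insertion
#'
#' Candidate neurons (geometry from [sample_neuron_geometry()], centers uniform
#' in the volume) are inserted one at a time and kept only if their center is
#' at least `r_i + r_j` away from every accepted neuron. Insertion stops when
#' the realized density reaches `density_target` or when
#' `max_consecutive_rejections` candidates in a row are rejected (the volume is
#' effectively jammed; the target density of 26.8e4 cells/mm^3 exceeds what
#' non-overlapping spheres of ~10 um mean radius can reach, so jamming is the
#' normal terminating condition at the default density).
#'
#' @param dims volume size `c(x, y, z)` in um (e.g. `c(400, 400, 170)`).
#' @param voxel_size voxel size in um, default `c(0.8, 0.8, 1)`.
#' @param density_target target density, cells per mm^3.
#' @param geometry a [geometry_params()] list.
#' @param seed integer seed (placement is bit-reproducible given the seed).
#' @param max_consecutive_rejections jamming criterion.
#' @param initial optional data frame of pre-seeded neurons with columns
#'   `x, y, z, soma_radius, nucleus_halfwidth`.
#' @return a `tissue_volume` list: `dims`, `voxel_size`, `neurons` (data frame
#'   `id, x, y, z, soma_radius, nucleus_halfwidth`), `density_target`,
#'   `realized_density` (per mm^3), `seed`, `jammed`.
#' @export
place_neurons <- function(dims = c(400, 400, 170), voxel_size = c(0.8, 0.8, 1),
                          density_target = 26.8e4,
                          geometry = geometry_params(), seed = NULL,
                          max_consecutive_rejections = 1e4, initial = NULL) {
  stopifnot(length(dims) == 3, all(dims > 0), all(voxel_size > 0),
            density_target >= 0)
  vol_mm3 <- prod(dims) * 1e-9
  target_n <- floor(density_target * vol_mm3)
  acc <- if (is.null(initial)) {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               soma_radius = numeric(0), nucleus_halfwidth = numeric(0))
  } else {
    initial[, c("x", "y", "z", "soma_radius", "nucleus_halfwidth")]
  }
  jammed <- FALSE
  with_seed(seed, {
    consec <- 0L
    while (nrow(acc) < target_n) {
      b <- 2000L
      geom <- sample_neuron_geometry(b, geometry)
      cand <- cbind(runif(b, 0, dims[1]), runif(b, 0, dims[2]),
                    runif(b, 0, dims[3]))
      res <- cpp_rsa_insert(cand, geom$soma_radius,
                            as.matrix(acc[, c("x", "y", "z")]),
                            acc$soma_radius, dims, target_n,
                            as.integer(max_consecutive_rejections), consec)
      if (length(res$accepted)) {
        keep <- res$accepted
        acc <- rbind(acc, data.frame(x = cand[keep, 1], y = cand[keep, 2],
                                     z = cand[keep, 3],
                                     soma_radius = geom$soma_radius[keep],
                                     nucleus_halfwidth = geom$nucleus_halfwidth[keep]))
      }
      consec <- res$consec_rej
      if (res$jammed) { jammed <- TRUE; break }
    }
  })
  neurons <- cbind(id = seq_len(nrow(acc)), acc)
  rownames(neurons) <- NULL
  structure(list(dims = dims, voxel_size = voxel_size, neurons = neurons,
                 density_target = density_target,
                 realized_density = nrow(neurons) / vol_mm3,
                 seed = seed, jammed = jammed),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  cat(sprintf(
    "tissue_volume: %d neurons in %g x %g x %g um^3 (%.3g /mm^3%s)\n",
    nrow(x$neurons), x$dims[1], x$dims[2], x$dims[3], x$realized_density,
    if (isTRUE(x$jammed)) ", jammed" else ""))
  invisible(x)
}

#' Rasterize a tissue volume onto its voxel grid
#'
#' Marks every voxel whose center lies in the fluorescent shell of a neuron
#' (between the nuclear boundary and the soma boundary) with that neuron's id,
#' nucleus voxels with the negative id, and all other voxels 0. Only the shell
#' expresses the indicator, so nucleus voxels carry zero fluorescence.
#'
#' @param volume a `tissue_volume`.
#' @return integer 3D array (x, y, z) of labels with attribute `voxel_size`.
#' @export
rasterize <- function(volume) {
  stopifnot(inherits(volume, "tissue_volume"), all(volume$voxel_size > 0))
  nvox <- as.integer(ceiling(volume$dims / volume$voxel_size))
  n <- volume$neurons
  lab <- cpp_label_grid(n$x, n$y, n$z, n$soma_radius, n$nucleus_halfwidth,
                        nvox, volume$voxel_size)
  dim(lab) <- nvox
  attr(lab, "voxel_size") <- volume$voxel_size
  lab
}

#' Count fluorescent-shell voxels of one neuron
#' @param labels output of [rasterize()].
#' @param id neuron id.
#' @return integer voxel count.
#' @export
shell_voxel_count <- function(labels, id) sum(labels == id)

#' Write ground-truth geometry to CSV (+ JSON sidecar)
#' @param volume a `tissue_volume`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_tissue_csv <- function(volume, path) {
  write.csv(volume$neurons, path, row.names = FALSE)
  jsonlite::write_json(
    list(dims = volume$dims, voxel_size = volume$voxel_size,
         seed = volume$seed, density_target = volume$density_target,
         realized_density = volume$realized_density, jammed = volume$jammed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground-truth geometry written by [write_tissue_csv()]
#' @param path CSV path.
#' @return a `tissue_volume`.
#' @export
read_tissue_csv <- function(path) {
  neurons <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(dims = meta$dims, voxel_size = meta$voxel_size,
                 neurons = neurons, density_target = meta$density_target,
                 realized_density = meta$realized_density, seed = meta$seed,
                 jammed = meta$jammed),
            class = "tissue_volume")
}
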