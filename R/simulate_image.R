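#' Image simulation parameters
#'
#' Geometry and optics for rendering synthetic two-channel widefield stacks:
#' one ellipsoidal cell containing an ellipsoidal nucleus, a Gaussian
#' point-spread function, flat background with optional per-slice gain, and
#' Poisson shot noise plus Gaussian read noise.
#'
#' @param shape Integer `(z, y, x)` stack dimensions.
#' @param psf_sigma Gaussian PSF sigma `(z, y, x)` in voxels (default
#'   `c(1, 1.5, 1.5)`, a widefield PSF at ~0.1 um pixels / 0.3 um z-step).
#' @param background Flat background level, a.u. (default 10).
#' @param z_gain Optional numeric vector of length `shape[1]`: per-slice
#'   multiplicative gain (depth attenuation).
#' @param amp_per_unit Peak amplitude (above background) of a spot of
#'   truth intensity 1 (default 50).
#' @param read_noise_sd Gaussian read noise sd (default 2).
#' @param poisson_noise Apply Poisson shot noise (default `TRUE`).
#' @param cell_center,cell_radii,nucleus_center,nucleus_radii Ellipsoid
#'   geometry `(z, y, x)`, defaulting to a cell filling most of the volume
#'   with a nucleus in its centre.
#' @param dapi_level DAPI intensity inside the nucleus (default 100).
#' @return List of class `image_sim_params`.
#' @export
image_sim_params <- function(shape = c(20L, 64L, 64L),
                             psf_sigma = c(1, 1.5, 1.5),
                             background = 10, z_gain = NULL,
                             amp_per_unit = 50, read_noise_sd = 2,
                             poisson_noise = TRUE,
                             cell_center = (shape + 1) / 2,
                             cell_radii = shape * 0.45,
                             nucleus_center = (shape + 1) / 2,
                             nucleus_radii = shape * 0.22,
                             dapi_level = 100) {
  stopifnot(all(shape > 0), all(psf_sigma > 0))
  structure(list(shape = as.integer(shape), psf_sigma = psf_sigma,
                 background = background, z_gain = z_gain,
                 amp_per_unit = amp_per_unit,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = poisson_noise,
                 cell_center = cell_center, cell_radii = cell_radii,
                 nucleus_center = nucleus_center,
                 nucleus_radii = nucleus_radii,
                 dapi_level = dapi_level),
            class = "image_sim_params")
}

ellipsoid_mask <- function(shape, center, radii) {
  z <- ((seq_len(shape[1L]) - center[1L]) / radii[1L])^2
  y <- ((seq_len(shape[2L]) - center[2L]) / radii[2L])^2
  x <- ((seq_len(shape[3L]) - center[3L]) / radii[3L])^2
  outer(outer(z, y, "+"), x, "+") <= 1
}

#' Render a 3D two-channel stack from a truth spot table
#'
#' The FISH channel is a sum of 3D Gaussian spots (peak amplitude
#' `amp_per_unit` times the spot's truth intensity) over a flat background,
#' optionally modulated by a per-slice gain, then corrupted with Poisson
#' shot noise and Gaussian read noise. The DAPI channel is the nucleus
#' ellipsoid at `dapi_level` plus the same background and noise model.
#'
#' @param spots Data frame with columns `z, y, x` (voxel coordinates, may
#'   be fractional) and `intensity` (truth units).
#' @param params An [image_sim_params()].
#' @param seed Integer seed for the noise.
#' @return List with `stack` (an `image_stack`), `cell_masks` (integer 3D
#'   label array, the cell ellipsoid), `nucleus_mask` (logical 3D array) and
#'   `truth` (the input spots, rounded voxel coordinates attached).
#' @export
render_image <- function(spots, params = image_sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- params$shape
  if (nrow(spots) > 0 &&
      any(spots$z < 1 | spots$z > d[1L] | spots$y < 1 | spots$y > d[2L] |
          spots$x < 1 | spots$x > d[3L])) {
    stop("spot outside the image volume")
  }
  fish <- array(params$background, dim = d)
  sig <- params$psf_sigma
  r <- ceiling(4 * sig)
  for (i in seq_len(nrow(spots))) {
    zi <- max(1L, floor(spots$z[i] - r[1L])):min(d[1L], ceiling(spots$z[i] + r[1L]))
    yi <- max(1L, floor(spots$y[i] - r[2L])):min(d[2L], ceiling(spots$y[i] + r[2L]))
    xi <- max(1L, floor(spots$x[i] - r[3L])):min(d[3L], ceiling(spots$x[i] + r[3L]))
    g <- outer(outer(exp(-(zi - spots$z[i])^2 / (2 * sig[1L]^2)),
                     exp(-(yi - spots$y[i])^2 / (2 * sig[2L]^2)), "*"),
               exp(-(xi - spots$x[i])^2 / (2 * sig[3L]^2)), "*")
    fish[zi, yi, xi] <- fish[zi, yi, xi] +
      params$amp_per_unit * spots$intensity[i] * g
  }
  nucleus <- ellipsoid_mask(d, params$nucleus_center, params$nucleus_radii)
  dapi <- array(params$background, dim = d)
  dapi[nucleus] <- dapi[nucleus] + params$dapi_level
  add_noise <- function(img) {
    if (params$poisson_noise) {
      img <- array(stats::rpois(length(img), lambda = img), dim = dim(img))
    }
    if (params$read_noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), sd = params$read_noise_sd),
                         dim = dim(img))
    }
    # depth attenuation rescales the recorded slice (signal and noise alike),
    # so per-slice spread normalization can undo it exactly
    if (!is.null(params$z_gain)) {
      for (z in seq_len(dim(img)[1L])) img[z, , ] <- img[z, , ] * params$z_gain[z]
    }
    img
  }
  fish <- add_noise(fish)
  dapi <- add_noise(dapi)
  cell <- ellipsoid_mask(d, params$cell_center, params$cell_radii)
  truth <- spots
  truth$z_vox <- round(truth$z); truth$y_vox <- round(truth$y)
  truth$x_vox <- round(truth$x)
  list(stack = structure(list(channels = list(dapi = dapi, fish = fish),
                              voxel_size = c(0.3, 0.1, 0.1)),
                         class = "image_stack"),
       cell_masks = array(as.integer(cell), dim = d),
       nucleus_mask = nucleus,
       truth = truth)
}

#' Sample well-separated spot positions inside a compartment
#'
#' Draws voxel positions uniformly inside the requested compartment of the
#' simulated cell (relative to the ellipsoid geometry in `params`),
#' enforcing a minimum pairwise Euclidean separation against all previously
#' placed spots, and keeping a margin from the volume borders.
#'
#' @param n Number of spots.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param params An [image_sim_params()].
#' @param min_separation Minimum pairwise distance in voxels.
#' @param existing Optional matrix/data frame of already-placed `z, y, x`.
#' @param margin Border margin in voxels (default 3).
#' @return Data frame `z, y, x`.
#' @export
sample_spot_positions <- function(n, compartment, params,
                                  min_separation = 5, existing = NULL,
                                  margin = 3) {
  d <- params$shape
  nucleus <- ellipsoid_mask(d, params$nucleus_center, params$nucleus_radii)
  cell <- ellipsoid_mask(d, params$cell_center, params$cell_radii)
  region <- if (compartment == "nucleus") nucleus else cell & !nucleus
  # stay clear of the borders so detection patches fit
  region[c(seq_len(min(margin, d[1L])),
           (d[1L] - margin + 1L):d[1L]), , ] <- FALSE
  region[, c(seq_len(min(margin, d[2L])), (d[2L] - margin + 1L):d[2L]), ] <- FALSE
  region[, , c(seq_len(min(margin, d[3L])), (d[3L] - margin + 1L):d[3L])] <- FALSE
  idx <- which(region)
  placed <- if (is.null(existing)) {
    matrix(numeric(0), ncol = 3)
  } else as.matrix(existing[, c("z", "y", "x")])
  out <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place ", n, " spots at separation ",
                             min_separation)
    v <- vox_coords(idx[sample.int(length(idx), 1L)], d)
    all_pts <- rbind(placed, out)
    if (nrow(all_pts)) {
      d2 <- (all_pts[, 1L] - v[1L])^2 + (all_pts[, 2L] - v[2L])^2 +
        (all_pts[, 3L] - v[3L])^2
      if (any(d2 < min_separation^2)) next
    }
    out <- rbind(out, v)
  }
  data.frame(z = out[, 1L], y = out[, 2L], x = out[, 3L])
}

#' Simulate a complete smFISH stack with ground truth
#'
#' Convenience wrapper: places `n_cyto` unit-intensity mature-transcript
#' spots in the cytoplasm and `n_nuclear` in the nucleus (plus optional
#' brighter TS spots of intensity `ts_intensity`), renders the two-channel
#' stack, and returns the truth table with compartment labels.
#'
#' @param n_cyto,n_nuclear Numbers of unit spots per compartment.
#' @param ts_intensity Numeric vector of TS spot intensities (in units of
#'   one transcript); `numeric(0)` for none. TS spots are nuclear.
#' @param params An [image_sim_params()].
#' @param min_separation Minimum spot separation in voxels (default 5).
#' @param seed Integer seed (placement and noise).
#' @return As [render_image()], with `truth` carrying `compartment` and
#'   `type` columns.
#' @export
simulate_image <- function(n_cyto = 8L, n_nuclear = 4L,
                           ts_intensity = numeric(0),
                           params = image_sim_params(),
                           min_separation = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nuc <- sample_spot_positions(n_nuclear + length(ts_intensity), "nucleus",
                               params, min_separation)
  cyto <- sample_spot_positions(n_cyto, "cytoplasm", params, min_separation,
                                existing = nuc)
  spots <- rbind(
    if (nrow(nuc)) cbind(nuc,
                         intensity = c(rep(1, n_nuclear), ts_intensity),
                         compartment = "nucleus",
                         type = c(rep("mature", n_nuclear),
                                  rep("TS", length(ts_intensity)))),
    if (nrow(cyto)) cbind(cyto, intensity = 1, compartment = "cytoplasm",
                          type = "mature")
  )
  out <- render_image(spots, params)
  out$truth <- spots
  out
}
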