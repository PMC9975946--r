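#' Denoise an image channel
#'
#' Separable 3D Gaussian smoothing with per-axis sigma, reflective borders.
#' Defaults (0.5 slice axially, 1 px in-plane) are matched to a
#' diffraction-limited widefield spot sampled at ~0.1 um pixels and 0.3 um
#' z-steps: narrow enough to preserve single-molecule foci, wide enough to
#' suppress pixel noise.
#'
#' @param channel 3D array `[z, y, x]`.
#' @param sigma Numeric `(z, y, x)` smoothing sigma in voxels; 0 disables
#'   smoothing along an axis.
#' @return Smoothed array, same shape.
#' @export
denoise <- function(channel, sigma = c(0.5, 1, 1)) {
  gaussian_smooth_3d(channel, sigma)
}

#' Normalize stack brightness across z
#'
#' Widefield stacks lose signal with depth; to make foci at different depths
#' comparable, each z-slice is rescaled based on the (denoised) signal's
#' spread per slice. The default method `"mad"` multiplies every slice by
#' `reference / slice_mad`, where `slice_mad` is the slice's median absolute
#' deviation and the reference is the median of the per-slice MADs: because
#' foci occupy few voxels, the MAD tracks the background level (which scales
#' with depth gain) and not the spot content, so relative spot amplitudes
#' are preserved while depth attenuation is undone. Method `"slice"`
#' equalizes the plain per-slice standard deviation instead (every
#' non-degenerate slice ends with the reference sd exactly); `"global"`
#' divides the whole stack by its overall sd. Slices with zero spread are
#' left untouched under either per-slice method.
#'
#' Because depth attenuation varies smoothly with z while a slice's own
#' spread estimate is perturbed by the spots it happens to contain, the
#' per-slice spread profile is median-filtered across z (window
#' `profile_window`) before the scale factors are computed; the `"slice"`
#' method skips this by default so that every slice's sd equals the
#' reference exactly.
#'
#' @param channel Denoised 3D array `[z, y, x]`.
#' @param method `"mad"` (default), `"slice"` or `"global"`.
#' @param profile_window Odd rolling-median window applied to the per-slice
#'   spread profile along z; `NULL` (default) means 5 for `"mad"` and 1 (no
#'   filtering) for `"slice"`.
#' @return Rescaled array, same shape.
#' @export
normalize_brightness <- function(channel, method = c("mad", "slice", "global"),
                                 profile_window = NULL) {
  method <- match.arg(method)
  if (method == "global") {
    s <- stats::sd(channel)
    return(if (s == 0) channel else channel / s)
  }
  if (is.null(profile_window)) {
    profile_window <- if (method == "mad") 5L else 1L
  }
  nz <- dim(channel)[1L]
  spread <- if (method == "mad") {
    vapply(seq_len(nz), function(z) stats::mad(channel[z, , ]), numeric(1))
  } else {
    vapply(seq_len(nz), function(z) stats::sd(channel[z, , ]), numeric(1))
  }
  smooth_spread <- rolling_median(spread, min(profile_window,
                                              if (nz %% 2L) nz else nz - 1L))
  ref <- stats::median(spread)
  if (ref == 0) ref <- stats::median(spread[spread > 0])
  if (!is.finite(ref) || ref == 0 || is.na(ref)) return(channel)
  for (z in seq_len(nz)) {
    if (smooth_spread[z] > 0) {
      channel[z, , ] <- channel[z, , ] * (ref / smooth_spread[z])
    }
  }
  channel
}

#' Segment nuclei from the DAPI channel
#'
#' Global Otsu threshold on the denoised DAPI signal, 3D connected
#' components (6-connectivity), and removal of components below a minimum
#' volume (debris, hot pixels).
#'
#' @param dapi Denoised DAPI 3D array `[z, y, x]`.
#' @param min_volume Minimum component volume in voxels (default 50).
#' @param threshold Absolute threshold overriding Otsu (optional).
#' @return Integer 3D label array of nuclei (0 = background).
#' @export
segment_nuclei <- function(dapi, min_volume = 50L, threshold = NULL) {
  rng <- range(dapi)
  if (rng[1L] == rng[2L]) return(array(0L, dim = dim(dapi)))
  if (is.null(threshold)) {
    scaled <- (dapi - rng[1L]) / (rng[2L] - rng[1L])
    # Otsu is histogram-based, so the voxels can be passed as one 2D plane
    th01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = dim(dapi)[3L])),
                          range = c(0, 1))
    threshold <- rng[1L] + th01 * (rng[2L] - rng[1L])
  }
  lab <- label_components_3d(dapi > threshold)
  if (max(lab) > 0L && min_volume > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_volume)
    relabel <- integer(length(sizes))
    relabel[keep] <- seq_along(keep)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  lab
}

#' Partition each cell into nucleus, nuclear periphery and cytoplasm
#'
#' Within each cell mask: nucleus = nucleus mask restricted to the cell;
#' periphery = an in-plane dilation shell of the nucleus boundary (width
#' `shell_width_vox` voxels, per z-slice) clipped to the cell and excluding
#' the nucleus; cytoplasm = the remainder. The three compartments partition
#' every cell exactly.
#'
#' @param cell_masks Integer 3D label array of cells (see
#'   [read_cell_masks()]).
#' @param nucleus_mask Logical or integer 3D array marking nuclear voxels.
#' @param shell_width_vox In-plane shell width in voxels (default 2); 0
#'   yields an empty periphery.
#' @return Object of class `compartment_map`: integer 3D array coded
#'   0 outside, 1 nucleus, 2 periphery, 3 cytoplasm, with attribute `codes`.
#' @export
assign_compartments <- function(cell_masks, nucleus_mask,
                                shell_width_vox = 2L) {
  stopifnot(identical(dim(cell_masks), dim(nucleus_mask)))
  nuc <- nucleus_mask > 0
  dil <- nuc
  if (shell_width_vox > 0L) {
    brush <- EBImage::makeBrush(2L * shell_width_vox + 1L, shape = "disc")
    for (z in seq_len(dim(nuc)[1L])) {
      sl <- nuc[z, , ]
      if (any(sl)) {
        dil[z, , ] <- EBImage::dilate(EBImage::Image(sl * 1), brush) > 0
      }
    }
  }
  comp <- array(0L, dim = dim(cell_masks))
  in_cell <- cell_masks > 0L
  comp[in_cell] <- 3L
  comp[in_cell & dil] <- 2L
  comp[in_cell & nuc] <- 1L
  structure(comp, codes = c(outside = 0L, nucleus = 1L, periphery = 2L,
                            cytoplasm = 3L),
            class = c("compartment_map", class(comp)))
}

compartment_name <- function(code) {
  c("outside", "nucleus", "periphery", "cytoplasm")[code + 1L]
}

#' Detect fluorescent foci in 3D
#'
#' Threshold-based spot identification on the denoised, brightness-
#' normalized FISH channel: candidate peaks are 3D local maxima
#' (26-connectivity) brighter than a robust background threshold; peaks
#' closer than `min_separation_vox` (Euclidean, voxels) are resolved
#' greedily in favour of the brighter one; peaks outside every cell are
#' discarded. Each focus's intensity is the integrated signal over an
#' ellipsoidal patch around the peak minus the local median background times
#' the patch size, floored at a small positive epsilon. The focus is
#' assigned to the cell and compartment of its peak voxel.
#'
#' Because image units are arbitrary, the default threshold is a robust
#' z-score: a peak qualifies when its value exceeds
#' `median(channel) + detect_threshold * mad(channel)`. This is the
#' package's adaptation of classical single-molecule spot detection to high,
#' spatially varying background. Set `threshold_mode = "absolute"` to use
#' `detect_threshold` as a raw intensity cutoff.
#'
#' @param fish Denoised, normalized FISH 3D array `[z, y, x]`.
#' @param compartments A [assign_compartments()] map.
#' @param cell_masks Integer 3D cell label array.
#' @param detect_threshold Peak threshold (default 5 robust z-score units).
#' @param min_separation_vox Minimum peak separation in voxels (default 2).
#' @param patch_radius_vox Ellipsoid semi-axes `(z, y, x)` of the
#'   integration patch in voxels (default `c(1, 2, 2)`).
#' @param threshold_mode `"mad"` (robust z-score, default) or `"absolute"`.
#' @return Data frame of class `foci`: `focus_id, cell_id, compartment,
#'   z, y, x, intensity`, ordered by decreasing peak value.
#' @export
detect_foci <- function(fish, compartments, cell_masks,
                        detect_threshold = 5,
                        min_separation_vox = 2,
                        patch_radius_vox = c(1, 2, 2),
                        threshold_mode = c("mad", "absolute")) {
  threshold_mode <- match.arg(threshold_mode)
  d <- dim(fish)
  thr <- if (threshold_mode == "mad") {
    stats::median(fish) + detect_threshold * stats::mad(fish)
  } else detect_threshold
  cand <- which(local_maxima_3d(fish) & fish > thr)
  if (length(cand) == 0L) return(empty_foci())
  # brightest first; linear index breaks exact ties deterministically
  cand <- cand[order(-fish[cand], cand)]
  co <- vox_coords(cand, d)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- co[keep, , drop = FALSE]
    dist2 <- (prev[, 1L] - co[i, 1L])^2 + (prev[, 2L] - co[i, 2L])^2 +
      (prev[, 3L] - co[i, 3L])^2
    keep[i] <- all(dist2 >= min_separation_vox^2)
  }
  cand <- cand[keep]
  co <- co[keep, , drop = FALSE]
  in_cell <- cell_masks[cand] > 0L
  cand <- cand[in_cell]
  co <- co[in_cell, , drop = FALSE]
  if (length(cand) == 0L) return(empty_foci())

  pr <- rep_len(patch_radius_vox, 3L)
  rows <- lapply(seq_along(cand), function(i) {
    z <- co[i, 1L]; y <- co[i, 2L]; x <- co[i, 3L]
    zi <- max(1L, z - pr[1L]):min(d[1L], z + pr[1L])
    yi <- max(1L, y - pr[2L]):min(d[2L], y + pr[2L])
    xi <- max(1L, x - pr[3L]):min(d[3L], x + pr[3L])
    box <- fish[zi, yi, xi, drop = FALSE]
    ell <- outer(outer(((zi - z) / max(pr[1L], 0.5))^2,
                       ((yi - y) / max(pr[2L], 0.5))^2, "+"),
                 ((xi - x) / max(pr[3L], 0.5))^2, "+") <= 1
    patch_sum <- sum(box[ell])
    n_patch <- sum(ell)
    # background: median over a box twice the patch size, patch excluded
    z2 <- max(1L, z - 2L * pr[1L]):min(d[1L], z + 2L * pr[1L])
    y2 <- max(1L, y - 2L * pr[2L]):min(d[2L], y + 2L * pr[2L])
    x2 <- max(1L, x - 2L * pr[3L]):min(d[3L], x + 2L * pr[3L])
    big <- fish[z2, y2, x2, drop = FALSE]
    inner <- array(FALSE, dim = dim(big))
    inner[match(zi, z2), match(yi, y2), match(xi, x2)] <- ell
    bg_vox <- big[!inner]
    bg <- if (length(bg_vox)) stats::median(bg_vox) else 0
    data.frame(cell_id = cell_masks[cand[i]],
               compartment = compartment_name(compartments[cand[i]]),
               z = z, y = y, x = x,
               intensity = max(patch_sum - bg * n_patch, 1e-6),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(focus_id = seq_len(nrow(out)), out)
  class(out) <- c("foci", "data.frame")
  out
}

empty_foci <- function() {
  out <- data.frame(focus_id = integer(0), cell_id = integer(0),
                    compartment = character(0), z = integer(0),
                    y = integer(0), x = integer(0), intensity = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("foci", "data.frame")
  out
}

#' Run the full smFISH foci pipeline on one stack
#'
#' Denoise both channels, normalize FISH brightness across z, segment nuclei
#' from DAPI, partition cells into nucleus / periphery / cytoplasm, and
#' detect foci. Optional `genotype` and `embryo_id` are attached to every
#' focus row.
#'
#' @param stack An `image_stack` (see [read_stack()]) or path to a TIFF.
#' @param cell_masks Integer 3D label array or path to a mask JSON.
#' @param genotype,embryo_id Optional labels carried into the foci table.
#' @param denoise_sigma,shell_width_vox,detect_threshold,min_separation_vox,patch_radius_vox,min_nucleus_volume
#'   Tuning parameters passed to the stages.
#' @param out_tsv Optional path; the foci table is written there
#'   byte-stably.
#' @return The foci table (with `genotype`/`embryo_id` columns when given).
#' @export
run_fish_pipeline <- function(stack, cell_masks, genotype = NULL,
                              embryo_id = NULL,
                              denoise_sigma = c(0.5, 1, 1),
                              shell_width_vox = 2L,
                              detect_threshold = 5,
                              min_separation_vox = 2,
                              patch_radius_vox = c(1, 2, 2),
                              min_nucleus_volume = 50L,
                              out_tsv = NULL) {
  if (is.character(stack)) stack <- read_stack(stack)
  if (is.character(cell_masks)) {
    cell_masks <- read_cell_masks(cell_masks, dim(stack$channels$fish))
  }
  dapi <- denoise(stack$channels$dapi, denoise_sigma)
  fish <- denoise(stack$channels$fish, denoise_sigma)
  fish <- normalize_brightness(fish)
  nuclei <- segment_nuclei(dapi, min_volume = min_nucleus_volume)
  comp <- assign_compartments(cell_masks, nuclei,
                              shell_width_vox = shell_width_vox)
  foci <- detect_foci(fish, comp, cell_masks,
                      detect_threshold = detect_threshold,
                      min_separation_vox = min_separation_vox,
                      patch_radius_vox = patch_radius_vox)
  if (!is.null(embryo_id)) foci <- cbind(embryo_id = embryo_id, foci)
  if (!is.null(genotype)) foci <- cbind(genotype = genotype, foci)
  if (!is.null(out_tsv)) write_tsv_stable(as.data.frame(foci), out_tsv)
  foci
}
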