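#' Read a two-channel 3D image stack from TIFF
#'
#' Pages are expected channel-interleaved in z-major order: for `nc`
#' channels, page `(z - 1) * nc + c` holds slice `z` of channel `c`. The
#' returned arrays are indexed `[z, y, x]` regardless of on-disk layout.
#'
#' @param path Multi-page TIFF file.
#' @param channel_map Named integer vector mapping channel names to their
#'   interleave position, e.g. `c(dapi = 1, fish = 2)`.
#' @param voxel_size Numeric `(z, y, x)` voxel size in micrometres; default
#'   `c(0.3, 0.1, 0.1)` (0.3 um z-step widefield series).
#' @return An object of class `image_stack`: list with `channels` (named
#'   list of 3D arrays) and `voxel_size`.
#' @export
read_stack <- function(path, channel_map = c(dapi = 1, fish = 2),
                       voxel_size = c(0.3, 0.1, 0.1)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1L]])) != 2L) {
    stop("expected single-sample (grayscale) TIFF pages")
  }
  nc <- length(channel_map)
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map)))) {
    stop("channel_map must be a named vector")
  }
  if (length(pages) %% nc != 0L || length(pages) < nc) {
    stop("file has ", length(pages), " page(s); cannot deinterleave ",
         nc, " channel(s)")
  }
  nz <- length(pages) %/% nc
  dims <- dim(pages[[1L]])
  channels <- lapply(channel_map, function(ci) {
    arr <- array(0, dim = c(nz, dims[1L], dims[2L]))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(z - 1L) * nc + ci]]
    arr
  })
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' Write an image stack to TIFF
#'
#' Inverse of [read_stack()] (channel-interleaved pages, z-major). Values
#' are mapped affinely to `[0, 1]` by the global minimum and maximum across
#' channels, since the 32-bit float TIFF writer clamps outside that range;
#' intensities are arbitrary units and all downstream statistics are
#' invariant to a global affine rescaling.
#'
#' @param stack An `image_stack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mn <- min(vapply(stack$channels, min, numeric(1)))
  mx <- max(vapply(stack$channels, max, numeric(1)))
  scale <- max(mx - mn, 1e-12)
  nz <- dim(stack$channels[[1L]])[1L]
  pages <- list()
  for (z in seq_len(nz)) {
    for (ci in seq_along(stack$channels)) {
      pages[[(z - 1L) * length(stack$channels) + ci]] <-
        (stack$channels[[ci]][z, , ] - mn) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read manual 2D cell masks and extrude them over z
#'
#' Cells are outlined manually on one z-slice; the outline is projected to
#' the slices spanning the cell. Input is JSON: an array of objects with
#' `cell_id`, `z_low`, `z_high` and `polygon` (list of `[x, y]` vertices in
#' 1-based pixel coordinates). Voxel centres inside the polygon are labelled
#' with `cell_id` for every slice in `[z_low, z_high]`. Masks of distinct
#' cells must be disjoint so no focus can be counted twice.
#'
#' @param source JSON file path or an already-parsed list of cell records.
#' @param shape Integer `(z, y, x)` dimensions of the image stack.
#' @return Integer 3D label array (0 = outside every cell).
#' @export
read_cell_masks <- function(source, shape) {
  cells <- if (is.character(source)) {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else source
  lab <- array(0L, dim = shape)
  grid <- cbind(rep(seq_len(shape[3L]), each = shape[2L]),  # x
                rep(seq_len(shape[2L]), times = shape[3L])) # y
  for (cell in cells) {
    poly <- do.call(rbind, lapply(cell$polygon, unlist))
    inside <- mgcv::in.out(poly, grid)
    zr <- max(1L, cell$z_low):min(shape[1L], cell$z_high)
    sl <- matrix(inside, nrow = shape[2L])  # grid is y-fastest -> [y, x]
    for (z in zr) {
      plane <- lab[z, , ]
      if (any(plane[sl] != 0L)) {
        stop("cell masks overlap at z = ", z, " (cell ", cell$cell_id, ")")
      }
      plane[sl] <- as.integer(cell$cell_id)
      lab[z, , ] <- plane
    }
  }
  lab
}
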