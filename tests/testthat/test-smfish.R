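test_that("stacks round-trip through TIFF with declared (z, y, x) axes", {
  set.seed(1)
  arr1 <- array(runif(30 * 16 * 12), dim = c(30, 16, 12))
  arr2 <- array(runif(30 * 16 * 12), dim = c(30, 16, 12))
  stack <- structure(list(channels = list(dapi = arr1, fish = arr2),
                          voxel_size = c(0.3, 0.1, 0.1)),
                     class = "image_stack")
  f <- tempfile(fileext = ".tif")
  write_stack(stack, f)
  back <- read_stack(f, c(dapi = 1, fish = 2))
  expect_equal(dim(back$channels$dapi), c(30, 16, 12))
  # writer maps affinely to [0, 1]; shape and relative values survive
  mn <- min(arr1, arr2); mx <- max(arr1, arr2)
  expect_equal(back$channels$dapi, (arr1 - mn) / (mx - mn), tolerance = 1e-6)
  expect_equal(back$channels$fish, (arr2 - mn) / (mx - mn), tolerance = 1e-6)
  expect_equal(back$voxel_size[1], 0.3)

  # requesting two channels from a single-channel file fails
  f1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.2, 8, 8), matrix(0.1, 8, 8)),
                  f1, bits.per.sample = 32L)
  expect_error(read_stack(f1, c(dapi = 1, fish = 2)), "deinterleave")
})

test_that("denoising smooths noise, preserves constants, and sigma 0 is identity", {
  const <- array(7, dim = c(6, 10, 10))
  expect_equal(denoise(const), const)
  expect_equal(denoise(const, sigma = c(0, 0, 0)), const)
  set.seed(5)
  noise <- array(rnorm(20 * 32 * 32), dim = c(20, 32, 32))
  expect_lt(sd(denoise(noise)), sd(noise))
  expect_equal(denoise(noise, sigma = c(0, 0, 0)), noise)
  expect_error(denoise(noise, sigma = c(-1, 1, 1)), "sigma")
})

test_that("brightness normalization equalizes slices and undoes depth gain", {
  set.seed(6)
  arr <- array(rnorm(10 * 20 * 20, mean = 10), dim = c(10, 20, 20))
  # exact per-slice std equalization variant
  out <- normalize_brightness(arr, method = "slice")
  sds <- apply(out, 1, sd)
  expect_equal(sds, rep(median(apply(arr, 1, sd)), 10), tolerance = 1e-9)
  # all-constant stack unchanged under every method
  const <- array(3, dim = c(5, 8, 8))
  for (m in c("mad", "slice", "global")) {
    expect_equal(normalize_brightness(const, method = m), const)
  }
  # two identical spots at different depths under a depth-dependent gain:
  # post-normalization peak amplitudes agree within 5%
  params <- image_sim_params(shape = c(24L, 40L, 40L), read_noise_sd = 0.3,
                             poisson_noise = FALSE,
                             z_gain = seq(1, 0.4, length.out = 24))
  spots <- data.frame(z = c(6, 18), y = c(15, 25), x = c(15, 25),
                      intensity = 1)
  img <- render_image(spots, params, seed = 8)
  fish <- normalize_brightness(denoise(img$stack$channels$fish))
  amp <- c(fish[6, 15, 15] - median(fish[6, , ]),
           fish[18, 25, 25] - median(fish[18, , ]))
  expect_lt(abs(amp[1] - amp[2]) / mean(amp), 0.05)
})

test_that("nucleus segmentation recovers ellipsoids and their multiplicity", {
  params <- image_sim_params(shape = c(16L, 48L, 48L))
  img <- render_image(data.frame(z = numeric(0), y = numeric(0),
                                 x = numeric(0), intensity = numeric(0)),
                      params, seed = 10)
  lab <- segment_nuclei(denoise(img$stack$channels$dapi))
  expect_equal(max(lab), 1L)
  iou <- sum(lab > 0 & img$nucleus_mask) / sum(lab > 0 | img$nucleus_mask)
  expect_gte(iou, 0.9)

  # blank image: no components
  blank <- array(0, dim = c(6, 16, 16))
  expect_equal(max(segment_nuclei(blank)), 0L)

  # two disjoint bright ellipsoids: two components
  two <- array(0, dim = c(10, 40, 40))
  mk <- function(c0) netburst:::ellipsoid_mask(c(10, 40, 40), c0, c(3, 5, 5))
  two[mk(c(5, 10, 10))] <- 100
  two[mk(c(5, 30, 30))] <- 100
  expect_equal(max(segment_nuclei(two, threshold = 50)), 2L)
})

test_that("compartments partition every cell and respect the shell width", {
  shape <- c(8L, 24L, 24L)
  cell <- array(0L, dim = shape)
  cell[netburst:::ellipsoid_mask(shape, c(4, 12, 12), c(3.5, 10, 10))] <- 1L
  nuc <- netburst:::ellipsoid_mask(shape, c(4, 12, 12), c(2, 4, 4))
  comp <- assign_compartments(cell, nuc, shell_width_vox = 2L)
  # partition: nucleus + periphery + cytoplasm = cell, exactly
  expect_equal(sum(comp > 0L), sum(cell > 0L))
  expect_true(all(comp[cell == 0L] == 0L))
  expect_true(all(c(1L, 2L, 3L) %in% comp))
  # shell width 0: no periphery
  comp0 <- assign_compartments(cell, nuc, shell_width_vox = 0L)
  expect_false(any(comp0 == 2L))
  # nucleus touching the cell border: periphery clipped to the cell
  nuc_edge <- netburst:::ellipsoid_mask(shape, c(4, 12, 3), c(2, 4, 4))
  compe <- assign_compartments(cell, nuc_edge)
  expect_true(all(compe[cell == 0L] == 0L))
})

test_that("detection finds isolated spots with correct compartments and scaling", {
  params <- image_sim_params(shape = c(20L, 64L, 64L))
  sim <- simulate_image(n_cyto = 8, n_nuclear = 4, ts_intensity = 5,
                        params = params, min_separation = 5, seed = 3)
  fish <- normalize_brightness(denoise(sim$stack$channels$fish))
  nuc <- segment_nuclei(denoise(sim$stack$channels$dapi))
  comp <- assign_compartments(sim$cell_masks, nuc)
  foci <- detect_foci(fish, comp, sim$cell_masks)
  m <- match_foci(sim$truth, foci)
  expect_gte(m$tp, 12)
  expect_lte(m$fp, 1)
  expect_lte(median(m$errors), 1)
  # blank stack: no foci
  blank <- render_image(data.frame(z = numeric(0), y = numeric(0),
                                   x = numeric(0), intensity = numeric(0)),
                        params, seed = 4)
  bf <- detect_foci(normalize_brightness(denoise(blank$stack$channels$fish)),
                    comp, blank$cell_masks)
  expect_equal(nrow(bf), 0L)
})

test_that("spot amplitude doubles detected intensity within tolerance", {
  params <- image_sim_params(shape = c(20L, 48L, 48L), read_noise_sd = 1)
  spots <- data.frame(z = c(10, 10), y = c(14, 34), x = c(14, 34),
                      intensity = c(1, 2))
  img <- render_image(spots, params, seed = 12)
  fish <- normalize_brightness(denoise(img$stack$channels$fish))
  comp <- assign_compartments(img$cell_masks,
                              segment_nuclei(denoise(img$stack$channels$dapi)))
  foci <- detect_foci(fish, comp, img$cell_masks)
  expect_equal(nrow(foci), 2L)
  ratio <- max(foci$intensity) / min(foci$intensity)
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("raising the detection threshold never increases the focus count", {
  sim <- simulate_image(n_cyto = 6, n_nuclear = 3, seed = 21)
  fish <- normalize_brightness(denoise(sim$stack$channels$fish))
  comp <- assign_compartments(sim$cell_masks,
                              segment_nuclei(denoise(sim$stack$channels$dapi)))
  counts <- vapply(c(2, 4, 6, 10, 20), function(th) {
    nrow(detect_foci(fish, comp, sim$cell_masks, detect_threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant under whole-voxel translations", {
  sim <- simulate_image(n_cyto = 5, n_nuclear = 3, seed = 31)
  fish <- normalize_brightness(denoise(sim$stack$channels$fish))
  comp <- assign_compartments(sim$cell_masks,
                              segment_nuclei(denoise(sim$stack$channels$dapi)))
  foci <- detect_foci(fish, comp, sim$cell_masks)
  # shift everything by one voxel along y (wrap; interior spots unaffected)
  shift <- function(a) a[, c(dim(a)[2], 1:(dim(a)[2] - 1)), , drop = FALSE]
  foci2 <- detect_foci(shift(fish), shift(comp), shift(sim$cell_masks))
  ord1 <- foci[order(foci$z, foci$y, foci$x), ]
  ord2 <- foci2[order(foci2$z, foci2$y, foci2$x), ]
  interior <- ord1$y < dim(fish)[2] - 1
  expect_equal(ord2$y[interior], ord1$y[interior] + 1L, ignore_attr = TRUE)
})

test_that("polygon cell masks rasterize, extrude over z and reject overlap", {
  shape <- c(6L, 20L, 20L)
  cells <- list(
    list(cell_id = 1, z_low = 2, z_high = 4,
         polygon = list(c(2, 2), c(9, 2), c(9, 9), c(2, 9))),
    list(cell_id = 2, z_low = 1, z_high = 6,
         polygon = list(c(12, 12), c(18, 12), c(18, 18), c(12, 18)))
  )
  lab <- read_cell_masks(cells, shape)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_true(all(lab[1, , ] != 1L))          # z extrusion honoured
  expect_equal(lab[3, 5, 5], 1L)              # inside polygon 1 (y=5, x=5)
  expect_equal(lab[3, 15, 15], 2L)
  # overlapping masks violate the one-cell-per-voxel invariant
  cells_bad <- list(cells[[1]],
                    list(cell_id = 3, z_low = 2, z_high = 3,
                         polygon = list(c(4, 4), c(11, 4), c(11, 11), c(4, 11))))
  expect_error(read_cell_masks(cells_bad, shape), "overlap")
})
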