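# shared low-level helpers

# deterministic TSV writer: fixed significant digits, no quoting, "." decimal
write_tsv_stable <- function(df, path, digits = 10L) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# 1D Gaussian kernel, radius 3*sigma (min 1), normalized
gauss_kernel <- function(sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# convolution matrix along one axis with reflective boundary handling
conv_matrix <- function(n, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (d in -r:r) {
    j <- seq_len(n) + d
    # reflect indices at the borders (a b c | c b a)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    for (i in seq_len(n)) K[i, j[i]] <- K[i, j[i]] + k[d + r + 1L]
  }
  K
}

# smooth a 3D array along axis 1 by left-multiplying with a kernel matrix
smooth_axis1 <- function(arr, sigma) {
  d <- dim(arr)
  if (sigma == 0) return(arr)
  K <- conv_matrix(d[1L], sigma)
  array(K %*% matrix(arr, nrow = d[1L]), dim = d)
}

# separable 3D Gaussian smoothing; sigma = c(z, y, x), array is [z, y, x]
gaussian_smooth_3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3L)
  sigma <- rep_len(sigma, 3L)
  if (any(sigma < 0)) stop("sigma must be >= 0 on every axis")
  out <- smooth_axis1(arr, sigma[1L])
  out <- aperm(smooth_axis1(aperm(out, c(2, 1, 3)), sigma[2L]), c(2, 1, 3))
  aperm(smooth_axis1(aperm(out, c(3, 2, 1)), sigma[3L]), c(3, 2, 1))
}

# 3D connected-component labelling of a logical array, 6-connectivity
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nzy <- d[1L] * d[2L]
  current <- 0L
  for (seed_vox in fg) {
    if (lab[seed_vox] != 0L) next
    current <- current + 1L
    queue <- seed_vox
    lab[seed_vox] <- current
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      z <- ((v - 1L) %% d[1L]) + 1L
      y <- (((v - 1L) %/% d[1L]) %% d[2L]) + 1L
      x <- ((v - 1L) %/% nzy) + 1L
      nb <- c(v[z > 1L] - 1L, v[z < d[1L]] + 1L,
              v[y > 1L] - d[1L], v[y < d[2L]] + d[1L],
              v[x > 1L] - nzy, v[x < d[3L]] + nzy)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      if (length(nb)) {
        lab[nb] <- current
        queue <- nb
      }
    }
  }
  lab
}

# strict-or-equal 3D local maxima (26-connectivity): voxel >= all neighbours
local_maxima_3d <- function(arr) {
  d <- dim(arr)
  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- arr
  is_max <- array(TRUE, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pad[(2:(d[1L] + 1L)) + dz, (2:(d[2L] + 1L)) + dy,
              (2:(d[3L] + 1L)) + dx]
    is_max <- is_max & (arr >= nb)
  }
  is_max
}

# named list of linear-index -> (z, y, x) conversion
vox_coords <- function(idx, d) {
  nzy <- d[1L] * d[2L]
  cbind(z = ((idx - 1L) %% d[1L]) + 1L,
        y = (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L,
        x = ((idx - 1L) %/% nzy) + 1L)
}

# lognormal multiplicative noise with mean exactly 1 and the given CV
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
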