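#' Remove splicing-intermediate read ends
#'
#' Nascent 3'-end sequencing also captures RNAs associated with the
#' transcription machinery but no longer attached to Pol II, notably
#' intermediates of splicing after 5' splice-site cleavage, whose 3' ends sit
#' exactly at donor sites. Reads whose end position maps precisely to a donor
#' site of the gene are removed; everything else passes unchanged, order
#' preserved. The operation is idempotent.
#'
#' @param reads A `read_ends` data frame (see [load_read_ends()]).
#' @param model A [gene_model()].
#' @return The filtered `read_ends` data frame, with attribute `n_removed`.
#' @export
filter_splice_intermediates <- function(reads, model) {
  donors <- donor_sites(model)
  keep <- !(reads$rel_pos %in% donors)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Restrict reads to a primer's window
#'
#' Keeps reads of the window's primer whose 3' end lies within the window
#' (`primer_last_nt + 1` to `primer_last_nt + window_len`, inclusive).
#'
#' @param reads A `read_ends` data frame.
#' @param window A [primer_window()].
#' @return Filtered `read_ends` data frame.
#' @export
filter_primer_window <- function(reads, window) {
  lo <- window$primer_last_nt + 1L
  hi <- window$primer_last_nt + window$window_len
  keep <- reads$primer_id == window$primer_id &
    reads$rel_pos >= lo & reads$rel_pos <= hi
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rolling median
#'
#' Centered rolling median. At the edges the window shrinks symmetrically to
#' the positions available (no padding), so the output has the length of the
#' input and the first/last values are plain copies.
#'
#' @param values Numeric vector.
#' @param window_nt Odd window width >= 1 (default 11).
#' @return Numeric vector, same length as `values`.
#' @export
rolling_median <- function(values, window_nt = 11L) {
  window_nt <- as.integer(window_nt)
  if (window_nt < 1L || window_nt %% 2L == 0L) {
    stop("window_nt must be an odd integer >= 1")
  }
  n <- length(values)
  if (n == 0L) return(numeric(0))
  h <- (window_nt - 1L) %/% 2L
  out <- numeric(n)
  if (n >= window_nt && window_nt > 1L) {
    out <- stats::runmed(values, window_nt, endrule = "keep")
    attributes(out) <- NULL
  } else {
    out[] <- values
  }
  # symmetric shrink at positions where a full window does not fit
  edge <- which(pmin(seq_len(n) - 1L, n - seq_len(n)) < h)
  for (i in edge) {
    k <- min(h, i - 1L, n - i)
    out[i] <- stats::median(values[(i - k):(i + k)])
  }
  out
}

#' Build a normalized Pol II density profile
#'
#' Tallies read 3' ends per nucleotide over a primer window, substitutes the
#' pseudocount at zero-read positions, normalizes each position by the total
#' number of (raw, un-pseudocounted) reads from the primer, and smooths with
#' a centered rolling median. The resulting ratio track reads as the fraction
#' of polymerases observed at each nucleotide, independent of library depth:
#' a locally elevated ratio marks Pol II dwelling (pausing or slow
#' elongation) rather than more transcription overall.
#'
#' @param reads A `read_ends` data frame; all rows must share one
#'   (primer_id, replicate_id, genotype). Reads outside the window are
#'   ignored.
#' @param window A [primer_window()].
#' @param pseudocount Value substituted at zero-read positions (default 0.1).
#' @param smooth_window Rolling-median width in nt (default 11).
#' @param pseudo_in_denominator If `TRUE`, the normalizing total is the sum
#'   of pseudocounted counts instead of the raw read count. Default `FALSE`:
#'   pseudocounts live in the numerator only, so ratios over covered
#'   positions sum to exactly 1.
#' @return An object of class `density_profile`: a data frame with columns
#'   `position, count, ratio, smoothed` and attributes `primer_id`,
#'   `replicate_id`, `genotype`, `raw_total`.
#' @export
build_profile <- function(reads, window, pseudocount = 0.1,
                          smooth_window = 11L,
                          pseudo_in_denominator = FALSE) {
  for (col in c("primer_id", "replicate_id", "genotype")) {
    if (length(unique(reads[[col]])) > 1L) {
      stop("reads mix several values of ", col,
           "; build one profile per library")
    }
  }
  reads <- filter_primer_window(reads, window)
  raw_total <- nrow(reads)
  if (raw_total == 0L) {
    stop("no reads in the window of primer '", window$primer_id,
         "'; profile cannot be normalized")
  }
  offs <- reads$rel_pos - window$primer_last_nt
  counts <- tabulate(offs, nbins = window$window_len)
  counts <- ifelse(counts == 0L, pseudocount, as.numeric(counts))
  denom <- if (pseudo_in_denominator) sum(counts) else raw_total
  ratios <- counts / denom
  prof <- data.frame(position = window$positions,
                     count = counts,
                     ratio = ratios,
                     smoothed = rolling_median(ratios, smooth_window))
  class(prof) <- c("density_profile", "data.frame")
  attr(prof, "primer_id") <- window$primer_id
  attr(prof, "replicate_id") <- reads$replicate_id[1L]
  attr(prof, "genotype") <- reads$genotype[1L]
  attr(prof, "raw_total") <- raw_total
  prof
}

profile_meta <- function(p, what) attr(p, what, exact = TRUE)

#' Average replicate profiles per genotype
#'
#' Position-wise arithmetic mean of the smoothed ratio tracks of biological
#' replicates, grouped by genotype. All profiles must share one primer
#' window.
#'
#' @param profiles List of [build_profile()] outputs.
#' @return Data frame with columns `genotype, position, mean_smoothed`.
#' @export
average_replicates <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles given")
  pos <- profiles[[1L]]$position
  for (p in profiles) {
    if (!identical(p$position, pos)) {
      stop("profiles span different windows; cannot average")
    }
  }
  genos <- vapply(profiles, profile_meta, character(1), what = "genotype")
  out <- lapply(sort(unique(genos)), function(g) {
    m <- rowMeans(vapply(profiles[genos == g], `[[`, numeric(length(pos)),
                         "smoothed"))
    data.frame(genotype = g, position = pos, mean_smoothed = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

bin_starts <- function(first, len, bin_nt) seq.int(first, first + len - 1L, by = bin_nt)

# per-replicate bin values: mean of per-nt values within each 25-nt tile
bin_values <- function(values, positions, bin_nt) {
  first <- positions[1L]
  idx <- (positions - first) %/% bin_nt
  as.numeric(tapply(values, idx, mean))
}

# two-sample two-tailed Student's (pooled-variance) t-test with the
# zero-variance convention: both groups constant -> p = 1 if means equal,
# 0 otherwise
pooled_t_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Binned genotype comparison of Pol II density
#'
#' Tiles each primer window into `bin_nt` bins from its first position
#' (trailing partial bin allowed), takes each replicate's bin value as the
#' mean of its per-nucleotide ratios (unsmoothed by default; the rolling
#' median is presentation-layer smoothing and would correlate neighbouring
#' positions within a bin), and compares genotypes per bin with a two-tailed
#' Student's pooled-variance t-test. Bonferroni correction is applied over
#' all bins of all primers passed in one call. The fold-change is computed
#' from the cross-replicate mean bin values, alt over ref.
#'
#' @param profiles_ref,profiles_alt Lists of [build_profile()] outputs for
#'   the reference and alternative genotype; may cover several primers, with
#'   at least two replicates per genotype per primer.
#' @param bin_nt Bin width in nt (default 25).
#' @param use_smoothed Bin the rolling-median track instead of raw ratios.
#' @return Data frame of class `bin_comparison` with columns `primer_id,
#'   bin_start, bin_end, mean_ref, mean_alt, log2_fc, p_raw, p_bonf, n_ref,
#'   n_alt`.
#' @export
compare_bins <- function(profiles_ref, profiles_alt, bin_nt = 25L,
                         use_smoothed = FALSE) {
  col <- if (use_smoothed) "smoothed" else "ratio"
  prim_ref <- vapply(profiles_ref, profile_meta, character(1), what = "primer_id")
  prim_alt <- vapply(profiles_alt, profile_meta, character(1), what = "primer_id")
  primers <- sort(unique(c(prim_ref, prim_alt)))
  res <- list()
  for (pr in primers) {
    ref <- profiles_ref[prim_ref == pr]
    alt <- profiles_alt[prim_alt == pr]
    if (length(ref) < 2L || length(alt) < 2L) {
      stop("primer '", pr, "': need >= 2 replicates per genotype ",
           "(got ", length(ref), " ref, ", length(alt), " alt)")
    }
    pos <- ref[[1L]]$position
    for (p in c(ref, alt)) {
      if (!identical(p$position, pos)) {
        stop("primer '", pr, "': replicate windows differ")
      }
    }
    ref_mat <- vapply(ref, function(p) bin_values(p[[col]], pos, bin_nt),
                      numeric(ceiling(length(pos) / bin_nt)))
    alt_mat <- vapply(alt, function(p) bin_values(p[[col]], pos, bin_nt),
                      numeric(ceiling(length(pos) / bin_nt)))
    ref_mat <- matrix(ref_mat, ncol = length(ref))
    alt_mat <- matrix(alt_mat, ncol = length(alt))
    starts <- bin_starts(pos[1L], length(pos), bin_nt)
    n_bins <- length(starts)
    res[[pr]] <- data.frame(
      primer_id = pr,
      bin_start = starts,
      bin_end = pmin(starts + bin_nt - 1L, pos[length(pos)]),
      mean_ref = rowMeans(ref_mat),
      mean_alt = rowMeans(alt_mat),
      log2_fc = log2(rowMeans(alt_mat) / rowMeans(ref_mat)),
      p_raw = vapply(seq_len(n_bins), function(i) {
        pooled_t_p(ref_mat[i, ], alt_mat[i, ])
      }, numeric(1)),
      n_ref = length(ref),
      n_alt = length(alt),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_bonf <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out <- out[, c("primer_id", "bin_start", "bin_end", "mean_ref", "mean_alt",
                 "log2_fc", "p_raw", "p_bonf", "n_ref", "n_alt")]
  class(out) <- c("bin_comparison", "data.frame")
  out
}
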