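# shared in-code fixtures

# three-exon plus-strand toy gene: exons 101-200, 301-400, 501-600
toy_model <- function() {
  gene_model("AT1", "chr5", "+",
             exons = cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)))
}

# two-exon gene whose only donor (rel 700) lies outside a 51-650 window,
# so uniform window reads never coincide with donor positions
sim_model <- function() {
  gene_model("simgene", "chrS", "+",
             exons = cbind(c(1L, 801L), c(700L, 1400L)))
}

sim_window <- function() primer_window("p1", primer_last_nt = 50L,
                                       window_len = 600L)

# a read_ends data frame built by hand
make_reads <- function(rel_pos, primer_id = "p1", replicate_id = "r1",
                       genotype = "WT") {
  n <- length(rel_pos)
  out <- data.frame(rel_pos = as.integer(rel_pos),
                    primer_id = rep_len(primer_id, n),
                    replicate_id = rep_len(replicate_id, n),
                    genotype = rep_len(genotype, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_ends", "data.frame")
  out
}

# one-cell foci table for the TS-calling worked examples
make_cell <- function(intensities, compartment = "nucleus", cell_id = 1L) {
  data.frame(focus_id = seq_along(intensities), cell_id = cell_id,
             compartment = rep_len(compartment, length(intensities)),
             intensity = intensities, stringsAsFactors = FALSE)
}

# fabricate a density_profile with given per-position ratios (for testing
# the bin comparison in isolation from read tallying)
make_profile <- function(ratios, positions = seq_along(ratios),
                         primer_id = "p1", replicate_id = "r1",
                         genotype = "WT") {
  prof <- data.frame(position = as.integer(positions),
                     count = ratios, ratio = ratios,
                     smoothed = ratios)
  class(prof) <- c("density_profile", "data.frame")
  attr(prof, "primer_id") <- primer_id
  attr(prof, "replicate_id") <- replicate_id
  attr(prof, "genotype") <- genotype
  attr(prof, "raw_total") <- NA_integer_
  prof
}

# independent per-position sorted-median oracle for the rolling median
rolling_median_oracle <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    win <- sort(v[(i - k):(i + k)])
    m <- length(win)
    if (m %% 2 == 1) win[(m + 1) / 2] else (win[m / 2] + win[m / 2 + 1]) / 2
  }, numeric(1))
}

# textbook pooled-variance two-sample t-test oracle
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df = n1 + n2 - 2)
}

# write the toy gene as a GFF3 file
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr5\ttest\tgene\t101\t600\t.\t+\t.\tID=gene:AT1",
    "chr5\ttest\tmRNA\t101\t600\t.\t+\t.\tID=tx:AT1.1;Parent=gene:AT1",
    "chr5\ttest\texon\t101\t200\t.\t+\t.\tParent=tx:AT1.1",
    "chr5\ttest\texon\t301\t400\t.\t+\t.\tParent=tx:AT1.1",
    "chr5\ttest\texon\t501\t600\t.\t+\t.\tParent=tx:AT1.1"
  ), path)
  path
}

# greedy truth-to-detection matching within a distance tolerance
match_foci <- function(truth, foci, tol = 2) {
  if (nrow(foci) == 0L) {
    return(list(tp = 0L, fn = nrow(truth), fp = 0L, errors = numeric(0)))
  }
  used <- rep(FALSE, nrow(foci))
  errors <- numeric(0)
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((foci$z - truth$z[i])^2 + (foci$y - truth$y[i])^2 +
                (foci$x - truth$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
      errors <- c(errors, d[j])
    }
  }
  list(tp = tp, fn = nrow(truth) - tp, fp = sum(!used), errors = errors)
}
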